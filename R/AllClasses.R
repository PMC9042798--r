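#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' Simulation configuration for synthetic Circle-Seq data
#'
#' Holds every tunable of the synthetic-data generator: the toy reference
#' genome (number and length of chromosomes, background GC, planted element
#' plan), the circle population (count, four-component size mixture, GC bias
#' of the origin site, junction direct-repeat and palindrome planting rates)
#' and the sequencing model (read length, fragment size, junction depth,
#' linear background depth).
#'
#' The default size mixture places components at 207, 358, 553 and 732 bp
#' with the 358-bp component roughly tenfold heavier than the others
#' (weights 0.06/0.82/0.06/0.06, sd 20 bp, truncated to [50, 2000] bp),
#' emulating the mono- to tetra-nucleosomal fragment ladder typical of
#' cell-free eccDNA.
#'
#' @slot seed integer master seed; all generator functions derive their RNG
#'   state from it.
#' @slot nChroms,chromLength genome dimensions (bases).
#' @slot gcBackground background GC fraction in (0,1).
#' @slot elementPlan data.frame with columns \code{class},
#'   \code{genome_fraction}, \code{mean_length}: repeat-class intervals to
#'   plant (fractions must sum to <= 1).
#' @slot geneFraction,meanGeneLength gene plan: fraction of each chromosome
#'   covered by gene bodies and their mean length.
#' @slot cpgFraction,meanCpgLength,cpgGc CpG-island plan; island sequence is
#'   rewritten at GC fraction \code{cpgGc}.
#' @slot nMirna number of miRNA genes (60-100 bp) to plant per genome.
#' @slot nCircles number of true circles to draw.
#' @slot sizePeaks data.frame with columns \code{mean}, \code{sd},
#'   \code{weight}; weights must sum to 1.
#' @slot sizeRange truncation bounds of the size mixture (bases).
#' @slot gcBiasBeta origin-site GC bias: sampling weight of a 200-bp window
#'   is proportional to exp(gcBiasBeta * GC).
#' @slot pDirectRepeat,drLengthRange probability that a circle gets an
#'   identical direct repeat planted at its two junctions, and the repeat
#'   length bounds (within [4, 18] bp).
#' @slot pPalindrome probability of planting a 10-bp trinucleotide
#'   palindromic unit (triplet + 4-base spacer + reverse-complement triplet)
#'   straddling the start junction.
#' @slot readLength,fragmentMean,fragmentSd paired-end sequencing model
#'   (bases).
#' @slot circleDepth mean junction-spanning read coverage per circle.
#' @slot backgroundDepth mean coverage of linear background reads.
#' @slot mapqUnique MAPQ assigned to planted reads.
#' @slot fracMapq0 fraction of background reads assigned MAPQ 0.
#' @export
setClass("SimConfig", representation(
    seed = "integer",
    nChroms = "integer",
    chromLength = "integer",
    gcBackground = "numeric",
    elementPlan = "data.frame",
    geneFraction = "numeric",
    meanGeneLength = "integer",
    cpgFraction = "numeric",
    meanCpgLength = "integer",
    cpgGc = "numeric",
    nMirna = "integer",
    nCircles = "integer",
    sizePeaks = "data.frame",
    sizeRange = "integer",
    gcBiasBeta = "numeric",
    pDirectRepeat = "numeric",
    drLengthRange = "integer",
    pPalindrome = "numeric",
    readLength = "integer",
    fragmentMean = "integer",
    fragmentSd = "numeric",
    circleDepth = "numeric",
    backgroundDepth = "numeric",
    mapqUnique = "integer",
    fracMapq0 = "numeric"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    probs <- c(gcBackground = object@gcBackground,
               pDirectRepeat = object@pDirectRepeat,
               pPalindrome = object@pPalindrome,
               fracMapq0 = object@fracMapq0)
    bad <- probs < 0 | probs > 1
    if (any(bad))
        msg <- c(msg, paste0("probabilities outside [0,1]: ",
                             paste(names(probs)[bad], collapse = ", ")))
    if (object@gcBackground <= 0 || object@gcBackground >= 1)
        msg <- c(msg, "gcBackground must lie strictly in (0,1)")
    if (abs(sum(object@sizePeaks$weight) - 1) > 1e-8)
        msg <- c(msg, "size-peak weights must sum to 1")
    if (any(object@drLengthRange < 4L) || any(object@drLengthRange > 18L))
        msg <- c(msg, "drLengthRange must lie within [4, 18]")
    if (object@drLengthRange[1] > object@drLengthRange[2])
        msg <- c(msg, "drLengthRange must be increasing")
    ep <- object@elementPlan
    if (nrow(ep) &&
        !all(c("class", "genome_fraction", "mean_length") %in% names(ep)))
        msg <- c(msg, "elementPlan needs columns class/genome_fraction/mean_length")
    totFrac <- sum(ep$genome_fraction) + object@geneFraction +
        object@cpgFraction
    if (totFrac > 1)
        msg <- c(msg, "element genome fractions (incl. genes, CpG) exceed 1")
    if (object@gcBiasBeta < 0)
        msg <- c(msg, "gcBiasBeta must be >= 0")
    if (object@nChroms < 1L || object@chromLength < 1000L)
        msg <- c(msg, "genome must have >= 1 chromosome of >= 1000 bases")
    if (object@sizeRange[1] >= object@sizeRange[2])
        msg <- c(msg, "sizeRange must be increasing")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param seed master RNG seed.
#' @param nChroms,chromLength genome dimensions.
#' @param gcBackground background GC fraction.
#' @param elementPlan data.frame(class, genome_fraction, mean_length) of
#'   repeat classes to plant; the default plants SINE/LINE/LTR/Simple_repeat
#'   at realistic toy fractions.
#' @param geneFraction,meanGeneLength,cpgFraction,meanCpgLength,cpgGc,nMirna
#'   annotation plan (see \linkS4class{SimConfig}).
#' @param nCircles number of circles to draw.
#' @param sizePeaks data.frame(mean, sd, weight) of the size mixture.
#' @param sizeRange truncation bounds of circle sizes.
#' @param gcBiasBeta GC bias strength of circle origins.
#' @param pDirectRepeat,drLengthRange,pPalindrome junction motif planting.
#' @param readLength,fragmentMean,fragmentSd,circleDepth,backgroundDepth,
#'   mapqUnique,fracMapq0 sequencing model.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1, nChroms = 2, chromLength = 50000)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      nChroms = 2L,
                      chromLength = 1000000L,
                      gcBackground = 0.41,
                      elementPlan = data.frame(
                          class = c("SINE", "LINE", "LTR", "Simple_repeat"),
                          genome_fraction = c(0.10, 0.06, 0.04, 0.02),
                          mean_length = c(300L, 900L, 500L, 80L)),
                      geneFraction = 0.40,
                      meanGeneLength = 8000L,
                      cpgFraction = 0.02,
                      meanCpgLength = 800L,
                      cpgGc = 0.65,
                      nMirna = 30L,
                      nCircles = 500L,
                      sizePeaks = data.frame(
                          mean = c(207, 358, 553, 732),
                          sd = c(20, 20, 20, 20),
                          weight = c(0.06, 0.82, 0.06, 0.06)),
                      sizeRange = c(50L, 2000L),
                      gcBiasBeta = 2,
                      pDirectRepeat = 0.66,
                      drLengthRange = c(4L, 18L),
                      pPalindrome = 0.4,
                      readLength = 150L,
                      fragmentMean = 300L,
                      fragmentSd = 60,
                      circleDepth = 20,
                      backgroundDepth = 1,
                      mapqUnique = 60L,
                      fracMapq0 = 0.05) {
    new("SimConfig",
        seed = as.integer(seed), nChroms = as.integer(nChroms),
        chromLength = as.integer(chromLength), gcBackground = gcBackground,
        elementPlan = elementPlan, geneFraction = geneFraction,
        meanGeneLength = as.integer(meanGeneLength),
        cpgFraction = cpgFraction, meanCpgLength = as.integer(meanCpgLength),
        cpgGc = cpgGc, nMirna = as.integer(nMirna),
        nCircles = as.integer(nCircles), sizePeaks = sizePeaks,
        sizeRange = as.integer(sizeRange), gcBiasBeta = gcBiasBeta,
        pDirectRepeat = pDirectRepeat,
        drLengthRange = as.integer(drLengthRange),
        pPalindrome = pPalindrome, readLength = as.integer(readLength),
        fragmentMean = as.integer(fragmentMean), fragmentSd = fragmentSd,
        circleDepth = circleDepth, backgroundDepth = backgroundDepth,
        mapqUnique = as.integer(mapqUnique), fracMapq0 = fracMapq0)
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: ", object@nChroms, " chrom x ", object@chromLength,
        " bp, GC ", object@gcBackground, "\n", sep = "")
    cat("  circles: n=", object@nCircles, ", peaks at ",
        paste(object@sizePeaks$mean, collapse = "/"),
        " bp, gcBiasBeta=", object@gcBiasBeta, "\n", sep = "")
    cat("  junction motifs: P(DR)=", object@pDirectRepeat, " len [",
        object@drLengthRange[1], ",", object@drLengthRange[2],
        "], P(palindrome)=", object@pPalindrome, "\n", sep = "")
    cat("  reads: PE", object@readLength, ", junction depth ",
        object@circleDepth, "x, background ", object@backgroundDepth,
        "x, seed ", object@seed, "\n", sep = "")
})

#' Aligned Circle-Seq reads
#'
#' A lightweight container for coordinate-sorted alignment records produced
#' by \code{\link{simulateReads}} or read back from SAM via
#' \code{\link{readSam}}. The \code{alignments} slot is a data.frame in SAM
#' column order (1-based \code{pos}); \code{mappedReads} counts primary
#' (non-supplementary, non-secondary) mapped records and is the denominator
#' of EPM normalization.
#'
#' @slot alignments data.frame with columns qname, flag, rname, pos, mapq,
#'   cigar, rnext, pnext, tlen, seq, sa (SA tag value or NA).
#' @slot mappedReads integer count of primary mapped records.
#' @export
setClass("AlignmentSet", representation(
    alignments = "data.frame",
    mappedReads = "integer"
))

setValidity("AlignmentSet", function(object) {
    need <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq", "sa")
    if (!all(need %in% names(object@alignments)))
        return(paste0("alignments must have columns: ",
                      paste(need, collapse = ", ")))
    if (object@mappedReads < 0L)
        return("mappedReads must be >= 0")
    TRUE
})

#' @describeIn AlignmentSet constructor; sorts records by (rname, pos) and
#'   counts primary mapped reads unless \code{mappedReads} is supplied.
#' @param alignments data.frame of SAM-like records.
#' @param mappedReads optional primary mapped-read count.
#' @export
AlignmentSet <- function(alignments, mappedReads = NULL) {
    if (nrow(alignments)) {
        ord <- order(alignments$rname, alignments$pos)
        alignments <- alignments[ord, , drop = FALSE]
        rownames(alignments) <- NULL
    }
    if (is.null(mappedReads)) {
        primary <- bitwAnd(alignments$flag, 0x900L) == 0L &
            bitwAnd(alignments$flag, 0x4L) == 0L
        mappedReads <- sum(primary)
    }
    new("AlignmentSet", alignments = alignments,
        mappedReads = as.integer(mappedReads))
}

setMethod("show", "AlignmentSet", function(object) {
    n <- nrow(object@alignments)
    cat("AlignmentSet: ", n, " records (", object@mappedReads,
        " primary mapped) on ",
        length(unique(object@alignments$rname)), " sequence(s)\n", sep = "")
})

#' A sample's deduplicated circle calls
#'
#' Per-sample unit of EPM normalization and cohort statistics: the
#' deduplicated circle calls (a GRanges carrying the junction-evidence
#' metric columns), the sample's primary mapped-read count and group
#' metadata.
#'
#' @slot sampleId sample label.
#' @slot group cohort group, e.g. "healthy" or "disease".
#' @slot sex "M", "F" or "unknown".
#' @slot age years (NA when unknown).
#' @slot circles GRanges of deduplicated circles.
#' @slot mappedReads primary mapped reads (> 0).
#' @export
setClass("SampleCircleSet", representation(
    sampleId = "character",
    group = "character",
    sex = "character",
    age = "numeric",
    circles = "GRanges",
    mappedReads = "numeric"
))

setValidity("SampleCircleSet", function(object) {
    msg <- character()
    if (object@mappedReads <= 0)
        msg <- c(msg, "mappedReads must be > 0")
    key <- paste(seqnames(object@circles), start(object@circles),
                 end(object@circles))
    if (anyDuplicated(key))
        msg <- c(msg, "circles must be unique by (chrom, start, end)")
    if (!object@sex %in% c("M", "F", "unknown"))
        msg <- c(msg, "sex must be one of M/F/unknown")
    if (length(msg)) msg else TRUE
})

#' @describeIn SampleCircleSet constructor.
#' @param sampleId,group,sex,age sample metadata.
#' @param circles GRanges of deduplicated circle calls.
#' @param mappedReads primary mapped-read count.
#' @export
SampleCircleSet <- function(sampleId, circles, mappedReads,
                            group = "healthy", sex = "unknown", age = NA_real_) {
    new("SampleCircleSet", sampleId = sampleId, group = group, sex = sex,
        age = as.numeric(age), circles = circles,
        mappedReads = as.numeric(mappedReads))
}

setMethod("show", "SampleCircleSet", function(object) {
    cat("SampleCircleSet '", object@sampleId, "' (", object@group, "): ",
        length(object@circles), " circles / ", object@mappedReads,
        " mapped reads, EPM = ", format(epm(object), digits = 5),
        "\n", sep = "")
})

#' @export
setGeneric("circles", function(x) standardGeneric("circles"))
#' @describeIn SampleCircleSet circle calls as GRanges.
#' @param x a SampleCircleSet.
#' @export
setMethod("circles", "SampleCircleSet", function(x) x@circles)

#' @export
setGeneric("mappedReads", function(x) standardGeneric("mappedReads"))
#' @describeIn SampleCircleSet mapped-read count.
#' @export
setMethod("mappedReads", "SampleCircleSet", function(x) x@mappedReads)
#' @describeIn AlignmentSet primary mapped-read count.
#' @export
setMethod("mappedReads", "AlignmentSet", function(x) x@mappedReads)

#' @export
setGeneric("alignments", function(x) standardGeneric("alignments"))
#' @describeIn AlignmentSet alignment records as data.frame.
#' @export
setMethod("alignments", "AlignmentSet", function(x) x@alignments)

#' @export
setGeneric("sampleGroup", function(x) standardGeneric("sampleGroup"))
#' @describeIn SampleCircleSet cohort group label.
#' @export
setMethod("sampleGroup", "SampleCircleSet", function(x) x@group)

#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @describeIn SampleCircleSet sample label.
#' @export
setMethod("sampleId", "SampleCircleSet", function(x) x@sampleId)

#' Circles per million mapped reads (EPM)
#'
#' Depth-normalized circle count: \code{length(circles) /
#' (mappedReads / 1e6)}. EPM is invariant under joint scaling of circle
#' count and read count, making samples of different sequencing depth
#' comparable.
#'
#' @param x a \linkS4class{SampleCircleSet}.
#' @return numeric EPM value.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' s <- SampleCircleSet("s1", rep(gr, 3), mappedReads = 1e6)
#' epm(s)  # 3
#' @export
setGeneric("epm", function(x) standardGeneric("epm"))

#' @rdname epm
#' @export
setMethod("epm", "SampleCircleSet", function(x) {
    if (x@mappedReads <= 0)
        stop("EPM undefined: mappedReads must be > 0")
    length(x@circles) / (x@mappedReads / 1e6)
})
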