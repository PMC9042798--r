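#' Draw true eccDNA circles on a simulated genome
#'
#' Circle sizes come from the configured truncated-normal mixture (default
#' components at 207/358/553/732 bp, nucleosomal ladder). Origin sites are
#' drawn GC-biased: the genome is tiled into 200-bp windows and a window is
#' chosen with probability proportional to \code{exp(gcBiasBeta * GC)};
#' \code{gcBiasBeta = 0} recovers the uniform null. Circles running past the
#' chromosome end are resampled (retry cap 100 per circle).
#'
#' With probability \code{pDirectRepeat}, a direct repeat is planted: the
#' genome is rewritten so that the s-bp substrings beginning at the start
#' and at the end coordinate are identical (s drawn uniformly from
#' \code{drLengthRange}); rewrites that collide with an earlier rewrite are
#' applied last-wins and logged. With probability \code{pPalindrome} a 10-bp
#' unit (random triplet, 4-base spacer, reverse-complement triplet) is
#' written straddling the start junction.
#'
#' Because motif planting edits the reference, the (possibly modified)
#' genome is returned alongside the truth set and must be the one used for
#' read simulation and junction-sequence analysis.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param genome named DNAStringSet from \code{\link{generateReference}}.
#' @param annotations optional annotation GRanges (unused by the sampler but
#'   accepted for interface symmetry).
#' @param seed RNG seed; defaults to \code{config@seed + 1}.
#' @return list with \code{circles} (GRanges with metadata
#'   \code{planted_dr_length}, \code{planted_palindrome}), \code{genome}
#'   (rewritten DNAStringSet) and \code{rewriteLog} (data.frame of
#'   overlapping rewrite conflicts, last-wins).
#' @examples
#' ref <- generateReference(simConfig(seed = 1, chromLength = 50000,
#'                                    nCircles = 20L))
#' tc <- sampleTrueCircles(simConfig(seed = 1, chromLength = 50000,
#'                                   nCircles = 20L), ref$genome)
#' tc$circles
#' @export
sampleTrueCircles <- function(config, genome, annotations = NULL,
                              seed = config@seed + 1L) {
    validObject(config)
    stopifnot(config@nCircles >= 1L)
    withSeed(seed, .sampleTrueCircles(config, genome))
}

.sampleTrueCircles <- function(config, genome) {
    n <- config@nCircles
    seqlens <- genomeSeqlengths(genome)
    chromNames <- names(genome)

    ## genome-wide 200-bp tiles with GC-dependent sampling weight
    win <- 200L
    tileTab <- do.call(rbind, lapply(chromNames, function(ch) {
        L <- seqlens[[ch]]
        ts <- seq(0L, L - win, by = win)
        data.frame(chrom = ch, tile0 = ts)
    }))
    gcw <- unlist(lapply(chromNames, function(ch) {
        L <- seqlens[[ch]]
        ts <- seq(0L, L - win, by = win)
        gcFraction(Views(genome[[ch]], start = ts + 1L, width = win))
    }), use.names = FALSE)
    gcw[is.nan(gcw)] <- 0
    wts <- exp(config@gcBiasBeta * gcw)

    ## sizes from the truncated mixture
    comp <- sample(nrow(config@sizePeaks), n, replace = TRUE,
                   prob = config@sizePeaks$weight)
    lens <- round(rtruncnorm(n, config@sizePeaks$mean[comp],
                             config@sizePeaks$sd[comp],
                             config@sizeRange[1], config@sizeRange[2]))

    chrom <- character(n)
    s0 <- integer(n)
    for (i in seq_len(n)) {
        ok <- FALSE
        for (t in 1:100) {
            k <- sample.int(nrow(tileTab), 1, prob = wts)
            cand0 <- tileTab$tile0[k] + sample.int(win, 1) - 1L
            ## leave headroom for the direct-repeat rewrite past the end
            if (cand0 + lens[i] + config@drLengthRange[2] <=
                seqlens[[tileTab$chrom[k]]]) {
                chrom[i] <- tileTab$chrom[k]
                s0[i] <- cand0
                ok <- TRUE
                break
            }
        }
        if (!ok)
            stop("could not place circle ", i, " within the retry cap; ",
             "chromosomes may be too short for the configured sizes")
    }
    e0 <- s0 + lens

    ## motif planting rewrites the genome; work on character vectors
    chars <- lapply(chromNames, function(ch) as.character(genome[[ch]]))
    names(chars) <- chromNames

    drLen <- rep(NA_integer_, n)
    pal <- logical(n)
    written <- list()  # per chrom IRanges of rewritten spans
    for (ch in chromNames) written[[ch]] <- IRanges()
    conflicts <- list()

    logRewrite <- function(ch, a1, b1, what, i) {
        prior <- written[[ch]]
        ## conflicts with a circle's own earlier write are by construction
        ## consistent (palindrome is planted before the repeat is copied)
        other <- prior[mcols(prior)$circle != i]
        if (length(other) && any(IRanges::overlapsAny(IRanges(a1, b1), other)))
            conflicts[[length(conflicts) + 1L]] <<- data.frame(
                circle = i, chrom = ch, start = a1, end = b1, what = what)
        added <- IRanges(a1, b1)
        mcols(added)$circle <- i
        written[[ch]] <<- c(prior, added)
    }

    doDR <- runif(n) < config@pDirectRepeat
    doPal <- runif(n) < config@pPalindrome
    drRange <- seq(config@drLengthRange[1], config@drLengthRange[2])
    drDraw <- drRange[sample.int(length(drRange), n, replace = TRUE)]
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(n)) {
        ch <- chrom[i]
        ## palindrome first: the DR motif is read from the start junction
        ## afterwards, so a same-circle palindrome stays consistent with it
        if (doPal[i] && s0[i] >= 5L) {
            t1 <- paste0(sample(bases, 3, replace = TRUE), collapse = "")
            sp <- paste0(sample(bases, 4, replace = TRUE), collapse = "")
            t2 <- as.character(reverseComplement(DNAString(t1)))
            unit <- paste0(t1, sp, t2)
            substr(chars[[ch]], s0[i] - 4L, s0[i] + 5L) <- unit
            logRewrite(ch, s0[i] - 4L, s0[i] + 5L, "palindrome", i)
            pal[i] <- TRUE
        }
        if (doDR[i]) {
            s <- drDraw[i]
            motif <- substr(chars[[ch]], s0[i] + 1L, s0[i] + s)
            substr(chars[[ch]], e0[i] + 1L, e0[i] + s) <- motif
            logRewrite(ch, e0[i] + 1L, e0[i] + s, "direct_repeat", i)
            ## the source span is registered too: a later rewrite there
            ## would silently invalidate this repeat pair
            logRewrite(ch, s0[i] + 1L, s0[i] + s, "direct_repeat_source", i)
            drLen[i] <- s
        }
    }

    newGenome <- DNAStringSet(unlist(chars))
    names(newGenome) <- chromNames

    circles <- grFrom0(chrom, s0, e0, seqlens = seqlens)
    mcols(circles)$circle_id <- paste0("circle", seq_len(n))
    mcols(circles)$planted_dr_length <- drLen
    mcols(circles)$planted_palindrome <- pal

    rewriteLog <- if (length(conflicts)) do.call(rbind, conflicts)
                  else data.frame(circle = integer(), chrom = character(),
                                  start = integer(), end = integer(),
                                  what = character())
    list(circles = circles, genome = newGenome, rewriteLog = rewriteLog)
}
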