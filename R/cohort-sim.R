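#' Simulate a two-group Circle-Seq cohort
#'
#' Generates one shared reference genome (from \code{configHealthy}) and
#' per-sample circle sets and aligned reads for a healthy and a disease
#' group. Disease samples take their circle rate, size mixture and depths
#' from \code{configDisease} (typically a higher \code{nCircles} and a
#' shifted size mixture), and additionally carry a configurable set of
#' recurrent circles that each fully contain a miRNA gene, shared across
#' all disease samples -- the recurrence signal the cohort statistics are
#' designed to detect. Per-sample seeds are derived from the master seed,
#' so the whole cohort is reproducible.
#'
#' @param configHealthy,configDisease \linkS4class{SimConfig} for the two
#'   groups; the genome/annotation fields of \code{configHealthy} define
#'   the shared reference.
#' @param nHealthy,nDisease samples per group (>= 3 each).
#' @param nRecurrentMirna number of recurrent miRNA-containing circles
#'   planted in every disease sample.
#' @param mirnaPad bases added on each side of the miRNA when building the
#'   recurrent circles.
#' @param seed master seed; defaults to \code{configHealthy@seed}.
#' @return list with \code{genome}, \code{annotations},
#'   \code{recurrentMirnaIds} and \code{samples}: a list of per-sample
#'   lists (sample_id, group, reads = AlignmentSet, truth = GRanges).
#' @export
simulateCohort <- function(configHealthy, configDisease,
                           nHealthy, nDisease,
                           nRecurrentMirna = 2L, mirnaPad = 150L,
                           seed = configHealthy@seed) {
    validObject(configHealthy)
    validObject(configDisease)
    if (nHealthy < 3L || nDisease < 3L)
        stop("each group needs at least 3 samples (got ", nHealthy, " and ",
             nDisease, ")")

    ref <- generateReference(configHealthy)
    ann <- ref$annotations
    mir <- ann[mcols(ann)$type == "miRNA"]
    recIds <- character(0)
    recCircles <- GRanges()
    if (nRecurrentMirna > 0L) {
        if (length(mir) < nRecurrentMirna)
            stop("reference has ", length(mir), " miRNA genes; cannot plant ",
                 nRecurrentMirna, " recurrent circles")
        pick <- withSeed(seed, sample(length(mir), nRecurrentMirna))
        mirSel <- mir[pick]
        recIds <- mcols(mirSel)$id
        recCircles <- GRanges(seqnames(mirSel),
                              IRanges(pmax(1L, start(mirSel) - mirnaPad),
                                      end(mirSel) + mirnaPad))
        mcols(recCircles)$circle_id <- paste0("rec_", recIds)
        mcols(recCircles)$planted_dr_length <- NA_integer_
        mcols(recCircles)$planted_palindrome <- FALSE
    }

    makeSample <- function(cfg, k, group) {
        sid <- sprintf("%s%02d", substr(group, 1, 1), k)
        sSeed <- seed + 1000L * (k + ifelse(group == "disease", 500L, 0L))
        tc <- sampleTrueCircles(cfg, ref$genome, seed = sSeed)
        truth <- tc$circles
        if (group == "disease" && length(recCircles)) {
            GenomeInfoDb::seqlevels(recCircles) <-
                GenomeInfoDb::seqlevels(truth)
            GenomeInfoDb::seqlengths(recCircles) <-
                GenomeInfoDb::seqlengths(truth)
            truth <- c(truth, recCircles)
        }
        reads <- simulateReads(truth, tc$genome, cfg, seed = sSeed + 1L)
        list(sample_id = sid, group = group, reads = reads, truth = truth)
    }

    samples <- c(
        lapply(seq_len(nHealthy), function(k)
            makeSample(configHealthy, k, "healthy")),
        lapply(seq_len(nDisease), function(k)
            makeSample(configDisease, k, "disease")))

    list(genome = ref$genome, annotations = ann,
         recurrentMirnaIds = recIds, samples = samples)
}

#' Run the calling pipeline on one simulated sample
#'
#' Convenience wrapper: candidates -> six-criterion filter -> exact
#' deduplication -> \linkS4class{SampleCircleSet}.
#'
#' @param sample one element of \code{simulateCohort()$samples}.
#' @param genome the cohort reference genome.
#' @param thresholds \code{\link{filterThresholds}}.
#' @return a \linkS4class{SampleCircleSet}.
#' @export
callSample <- function(sample, genome, thresholds = filterThresholds()) {
    cand <- callCandidates(sample$reads, genome)
    filt <- dedupCircles(applyFilters(cand, thresholds))
    SampleCircleSet(sample$sample_id, filt,
                    mappedReads = mappedReads(sample$reads),
                    group = sample$group)
}
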