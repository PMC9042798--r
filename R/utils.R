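#' @importFrom Biostrings DNAStringSet DNAString letterFrequency
#'   reverseComplement subseq writeXStringSet
#' @importFrom GenomeInfoDb seqlengths seqlevels seqnames<- seqlengths<-
#' @importFrom IRanges Views coverage reduce
#' @importFrom stats rnorm runif density cor.test wilcox.test sd rpois
#'   setNames
#' @importFrom graphics hist
#' @importFrom utils head
NULL

## 0-based half-open interval table <-> GRanges (1-based closed).
## width(gr) == end0 - start0, so circle length is width() everywhere.
grFrom0 <- function(chrom, start0, end0, seqlens = NULL, ...) {
    gr <- GRanges(chrom, IRanges(start = start0 + 1L, end = end0), ...)
    if (!is.null(seqlens))
        seqlengths(gr) <- seqlens[seqlevels(gr)]
    gr
}

start0 <- function(gr) start(gr) - 1L
end0 <- function(gr) end(gr)

## statistical mode; ties broken toward the smaller value
modeInt <- function(x) {
    tab <- table(x)
    as.integer(names(tab)[which.max(tab)])
}

## truncated normal by rejection, vectorised resampling
rtruncnorm <- function(n, mean, sd, lower, upper, maxIter = 100L) {
    x <- rnorm(n, mean, sd)
    for (i in seq_len(maxIter)) {
        bad <- x < lower | x > upper
        if (!any(bad)) break
        x[bad] <- rnorm(sum(bad), mean[bad], sd[bad])
    }
    if (any(x < lower | x > upper))
        stop("truncated-normal sampling failed after ", maxIter, " retries")
    x
}

## GC fraction of DNAStringSet / Views; ambiguous bases excluded from the
## denominator; all-N windows return NaN
gcFraction <- function(x) {
    gc <- letterFrequency(x, letters = "GC")
    acgt <- letterFrequency(x, letters = "ACGT")
    as.numeric(gc) / as.numeric(acgt)
}

## place n non-overlapping intervals of the given lengths uniformly on
## [0, L); rejection sampling against previously placed starts
placeNonOverlapping <- function(L, lens, occupied = IRanges(), maxTries = 200L) {
    placed <- occupied
    starts <- integer(length(lens))
    keep <- logical(length(lens))
    for (k in seq_along(lens)) {
        len <- lens[k]
        ok <- FALSE
        for (t in seq_len(maxTries)) {
            s0 <- as.integer(floor(runif(1, 0, L - len)))
            cand <- IRanges(s0 + 1L, s0 + len)
            if (!length(placed) ||
                !any(IRanges::overlapsAny(cand, placed))) {
                placed <- c(placed, cand)
                starts[k] <- s0
                ok <- TRUE
                break
            }
        }
        keep[k] <- ok
    }
    list(start0 = starts[keep], length = lens[keep], dropped = sum(!keep))
}

## local-RNG guard: run expr under a seed without disturbing caller RNG
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

sumSeqlengths <- function(genome) {
    if (is(genome, "DNAStringSet")) sum(as.numeric(Biostrings::width(genome)))
    else sum(as.numeric(genome))
}

genomeSeqlengths <- function(genome) {
    if (is(genome, "DNAStringSet")) {
        sl <- Biostrings::width(genome)
        names(sl) <- names(genome)
        sl
    } else genome
}
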