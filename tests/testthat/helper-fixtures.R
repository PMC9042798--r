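suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
    library(S4Vectors)
})

## genome from literal strings, e.g. toyGenome(chr1 = "ACGT...")
toyGenome <- function(...) {
    seqs <- DNAStringSet(unlist(list(...)))
    seqs
}

## a candidate GRanges with all metric columns, defaulting to pass every
## filter criterion
makeCandidates <- function(chrom, start0, end0,
                           split = 4L, score = 40, disc = 1L,
                           mean_cov = 30, sd_cov = 5,
                           incS = 0.5, incE = 0.5, cont = 0) {
    n <- length(start0)
    gr <- GRanges(rep_len(chrom, n), IRanges(start0 + 1L, end0))
    mcols(gr) <- DataFrame(
        discordant_count = rep_len(as.integer(disc), n),
        split_count = rep_len(as.integer(split), n),
        circle_score = rep_len(score, n),
        mean_cov = rep_len(mean_cov, n),
        sd_cov = rep_len(sd_cov, n),
        cov_inc_start = rep_len(incS, n),
        cov_inc_end = rep_len(incE, n),
        cov_continuity = rep_len(cont, n))
    gr
}

randWindow <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

randContext <- function(w = 10L) {
    list(start_window = randWindow(2L * w), end_window = randWindow(2L * w),
         w = w)
}

## quadratic brute-force oracle: longest common substring with length in
## [minLen, maxLen], ties by smallest start offset in a then in b
bruteDirectRepeat <- function(ctx, minLen = 4L, maxLen = 18L) {
    a <- ctx$start_window[[1]]; b <- ctx$end_window[[1]]
    w <- ctx$w[[1]]
    na <- nchar(a); nb <- nchar(b)
    best <- NULL
    for (len in seq(min(maxLen, na, nb), minLen)) {
        for (i in seq_len(na - len + 1L)) {
            sub <- substr(a, i, i + len - 1L)
            for (j in seq_len(nb - len + 1L)) {
                if (sub == substr(b, j, j + len - 1L)) {
                    best <- list(length = len, sequence = sub,
                                 offset_start = i - 1L - w,
                                 offset_end = j - 1L - w)
                    break
                }
            }
            if (!is.null(best)) break
        }
        if (!is.null(best)) break
    }
    best
}

## brute-force palindromic-unit enumeration over all decompositions
brutePalindrome <- function(ctx, straddle = TRUE) {
    w <- ctx$w[[1]]
    scan <- function(win, site) {
        out <- list()
        for (u in 0:(nchar(win) - 10L)) {
            lastIdx <- u + 9L  # 0-based index of the unit's final base
            if (straddle && !(u < w && w <= lastIdx)) next
            t1 <- substr(win, u + 1L, u + 3L)
            t2 <- substr(win, u + 8L, u + 10L)
            if (grepl("[^ACGT]", paste0(t1, t2))) next
            rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(t1, "")[[1]]),
                                               collapse = ""))
            if (t2 == rc)
                out[[length(out) + 1L]] <-
                    data.frame(site = site, offset = u - w,
                               unit = substr(win, u + 1L, u + 10L))
        }
        if (length(out)) do.call(rbind, out) else NULL
    }
    hits <- rbind(scan(ctx$start_window[[1]], "start"),
                  scan(ctx$end_window[[1]], "end"))
    list(detected = !is.null(hits) && nrow(hits) > 0, hits = hits)
}

## enumeration oracle for the exact two-sided rank-sum p of two groups
## with no ties: enumerate all assignments of ranks to group A
bruteRankSumP <- function(a, b) {
    n <- length(a) + length(b)
    ranks <- rank(c(a, b))
    wObs <- sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
    combs <- utils::combn(n, length(a))
    wAll <- apply(combs, 2, function(idx)
        sum(rank(c(a, b))[idx]) - length(a) * (length(a) + 1) / 2)
    ## two-sided: double the smaller tail (as the exact Wilcoxon does)
    lo <- mean(wAll <= wObs)
    hi <- mean(wAll >= wObs)
    min(1, 2 * min(lo, hi))
}
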