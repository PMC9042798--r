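#' Compare EPM between two sample groups
#'
#' Two-sided Wilcoxon rank-sum test on per-sample EPM values: exact
#' enumeration when both groups have at most 10 samples and there are no
#' ties, otherwise the normal approximation with tie-corrected variance
#' (and continuity correction). Group means are reported with normal-theory
#' 95 percent confidence intervals (mean +/- 1.96 SE).
#'
#' @param samplesA,samplesB lists of \linkS4class{SampleCircleSet} (>= 3
#'   each), or numeric vectors of EPM values.
#' @param labelA,labelB group labels for the report.
#' @return list with group_a, group_b, n_a, n_b, mean_a, mean_b, ci95_a,
#'   ci95_b, p_value, test.
#' @examples
#' compareEpm(c(1, 2, 3), c(101, 102, 103))$p_value  # exact: 0.1
#' @export
compareEpm <- function(samplesA, samplesB, labelA = "A", labelB = "B") {
    epmOf <- function(x) {
        if (is.numeric(x)) return(as.numeric(x))
        vapply(x, epm, numeric(1))
    }
    a <- epmOf(samplesA); b <- epmOf(samplesB)
    if (length(a) < 3L || length(b) < 3L)
        stop("each group needs at least 3 samples")
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- length(a) <= 10L && length(b) <= 10L && !ties
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact,
                                       correct = !exact))
    ## fully tied data has zero rank variance; the two groups are then
    ## indistinguishable and the two-sided p is 1 by symmetry
    if (is.na(wt$p.value)) wt$p.value <- 1
    ci <- function(x) {
        se <- sd(x) / sqrt(length(x))
        mean(x) + c(-1.96, 1.96) * se
    }
    list(group_a = labelA, group_b = labelB,
         n_a = length(a), n_b = length(b),
         mean_a = mean(a), mean_b = mean(b),
         ci95_a = ci(a), ci95_b = ci(b),
         p_value = wt$p.value,
         test = if (exact) "wilcoxon-exact" else "wilcoxon-normal-ties")
}

#' Pearson correlation with two-sided p value
#'
#' Product-moment correlation; p from the t transform with n - 2 degrees
#' of freedom. Zero-variance input is an error naming the degenerate
#' vector.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list(r, p, n).
#' @examples
#' correlatePearson(1:3, c(2, 4, 6))$r  # 1
#' @export
correlatePearson <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3L) stop("need at least 3 paired observations")
    if (sd(x) == 0) stop("zero variance in x")
    if (sd(y) == 0) stop("zero variance in y")
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Recurrence of miRNA-gene-containing circles across samples
#'
#' A circle carries a miRNA gene when it fully contains the miRNA interval
#' (circle start <= miRNA start and miRNA end <= circle end, half-open
#' logic). Recurrence is the number of distinct samples with at least one
#' carrying circle. Hits are ranked by recurrence, ties by total carrying
#' circle count, then lexicographically by miRNA id.
#'
#' @param samples list of \linkS4class{SampleCircleSet}.
#' @param mirnaAnnotations GRanges of miRNA genes with an \code{id}
#'   metadata column (rows with other \code{type}s are ignored if a
#'   \code{type} column is present).
#' @param topN number of top hits to return (default 20).
#' @return DataFrame with mirna_id, recurrence, n_circles, sample_ids,
#'   circle_coords (top \code{topN} rows).
#' @export
mirnaRecurrence <- function(samples, mirnaAnnotations, topN = 20L) {
    typ <- mcols(mirnaAnnotations)$type
    if (!is.null(typ)) mirnaAnnotations <- mirnaAnnotations[typ == "miRNA"]
    ids <- mcols(mirnaAnnotations)$id
    if (is.null(ids)) ids <- paste0("mir", seq_along(mirnaAnnotations))

    perMir <- lapply(seq_along(mirnaAnnotations), function(m) {
        sids <- character(0); coords <- character(0); nCirc <- 0L
        for (s in samples) {
            gr <- circles(s)
            hit <- IRanges::overlapsAny(mirnaAnnotations[m], gr,
                                        type = "within",
                                        ignore.strand = TRUE)
            if (hit) {
                ov <- GenomicRanges::findOverlaps(mirnaAnnotations[m], gr,
                                                  type = "within",
                                                  ignore.strand = TRUE)
                carr <- gr[S4Vectors::subjectHits(ov)]
                sids <- c(sids, sampleId(s))
                nCirc <- nCirc + length(carr)
                coords <- c(coords, paste0(seqnames(carr), ":",
                                           start(carr) - 1L, "-", end(carr)))
            }
        }
        DataFrame(mirna_id = ids[m], recurrence = length(sids),
                  n_circles = nCirc,
                  sample_ids = paste(sids, collapse = ","),
                  circle_coords = paste(unique(coords), collapse = ","))
    })
    tab <- do.call(rbind, perMir)
    ord <- order(-tab$recurrence, -tab$n_circles, tab$mirna_id)
    head(tab[ord, ], topN)
}

#' Compare circle length distributions between groups
#'
#' Pools per-circle lengths within each group and compares them with a
#' two-sided Wilcoxon rank-sum test; histograms share bin edges. With
#' fewer than \code{minCircles} circles in either group only the
#' histograms are returned.
#'
#' @param samplesA,samplesB lists of \linkS4class{SampleCircleSet}, or
#'   numeric length vectors.
#' @param binWidth histogram bin width in bp.
#' @param minCircles minimum pooled circles per group for testing.
#' @return list with lengths_a, lengths_b, breaks, counts_a, counts_b,
#'   p_value (NA when not tested).
#' @export
compareLengthDistributions <- function(samplesA, samplesB, binWidth = 50,
                                       minCircles = 100L) {
    lensOf <- function(x) {
        if (is.numeric(x)) return(as.numeric(x))
        unlist(lapply(x, function(s) width(circles(s))))
    }
    la <- lensOf(samplesA); lb <- lensOf(samplesB)
    hi <- max(la, lb, 1)
    breaks <- seq(0, ceiling(hi / binWidth) * binWidth, by = binWidth)
    ha <- hist(la, breaks = breaks, plot = FALSE)
    hb <- hist(lb, breaks = breaks, plot = FALSE)
    p <- NA_real_
    if (length(la) >= minCircles && length(lb) >= minCircles) {
        p <- suppressWarnings(
            wilcox.test(la, lb, alternative = "two.sided")$p.value)
    } else {
        message("fewer than ", minCircles,
                " circles in a group: histograms only, no test")
    }
    list(lengths_a = la, lengths_b = lb, breaks = breaks,
         counts_a = ha$counts, counts_b = hb$counts, p_value = p)
}
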