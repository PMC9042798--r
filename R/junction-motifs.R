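#' Extract the +/- w bp reference windows around circle junctions
#'
#' For each circle, the start window is \code{genome[start-w, start+w)} and
#' the end window \code{genome[end-w, end+w)} (0-based half-open), both
#' read from the plus strand. Circles whose windows would run off the
#' chromosome are flagged and excluded (not fatal).
#'
#' @param circlesGr circles as GRanges.
#' @param genome named DNAStringSet.
#' @param w half-window in bp (default 10; the maximum detectable direct
#'   repeat inside the windows is \code{min(18, 2w)}, so set \code{w = 18}
#'   for full-range detection).
#' @return DataFrame with circle_id, chrom, start0, end0, start_window,
#'   end_window, w; flagged circle ids in \code{metadata()$flagged}.
#' @export
extractJunctionFlanks <- function(circlesGr, genome, w = 10L) {
    w <- as.integer(w)
    chrom <- as.character(seqnames(circlesGr))
    s0 <- start(circlesGr) - 1L
    e0 <- end(circlesGr)
    seqlens <- genomeSeqlengths(genome)
    ids <- mcols(circlesGr)$circle_id
    if (is.null(ids)) ids <- paste0("circle", seq_along(circlesGr))

    ok <- s0 - w >= 0L & e0 + w <= seqlens[chrom]
    sw <- character(sum(ok)); ew <- character(sum(ok))
    okChrom <- chrom[ok]; okS <- s0[ok]; okE <- e0[ok]
    for (ch in unique(okChrom)) {
        sel <- okChrom == ch
        sw[sel] <- as.character(Views(genome[[ch]], start = okS[sel] - w + 1L,
                                      width = 2L * w))
        ew[sel] <- as.character(Views(genome[[ch]], start = okE[sel] - w + 1L,
                                      width = 2L * w))
    }
    out <- DataFrame(circle_id = ids[ok], chrom = okChrom,
                     start0 = okS, end0 = okE,
                     start_window = sw, end_window = ew,
                     w = rep(w, sum(ok)))
    metadata(out)$flagged <- ids[!ok]
    out
}

#' Per-base nucleotide frequency matrix around a junction
#'
#' Column j of the 4 x 2w matrix holds the A/C/G/T frequencies at offset
#' j - w - 1 relative to the junction coordinate (columns are labelled
#' -w..-1, +1..+w). Columns sum to 1 over non-ambiguous bases; the matrix
#' is directly renderable as a sequence logo.
#'
#' @param contexts DataFrame from \code{\link{extractJunctionFlanks}}.
#' @param site which window, "start" or "end".
#' @return numeric matrix with rows A, C, G, T.
#' @export
baseFrequencyMatrix <- function(contexts, site = c("start", "end")) {
    site <- match.arg(site)
    if (!nrow(contexts)) stop("no junction contexts supplied")
    win <- if (site == "start") contexts$start_window else contexts$end_window
    w <- contexts$w[1]
    cm <- Biostrings::consensusMatrix(DNAStringSet(win))
    acgt <- matrix(0, nrow = 4, ncol = 2 * w,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
    for (b in rownames(acgt))
        if (b %in% rownames(cm)) acgt[b, ] <- cm[b, ]
    tot <- colSums(acgt)
    tot[tot == 0] <- NA
    freq <- sweep(acgt, 2, tot, "/")
    colnames(freq) <- c(-w:-1, 1:w)
    freq
}

#' Longest direct repeat shared by the two junction windows
#'
#' Finds the longest common substring of the start and end windows with
#' length in \code{[minLen, min(maxLen, 2w)]} -- the microhomology
#' signature of circle formation. Ties are broken by the smallest offset in
#' the start window, then the smallest offset in the end window. Offsets
#' are signed positions of the repeat's first base relative to the
#' junction coordinate (0 = the first base at/after the junction).
#'
#' @param context one row of \code{\link{extractJunctionFlanks}} output
#'   (or a list with start_window/end_window/w).
#' @param minLen,maxLen repeat length bounds in bp (defaults 4 and 18).
#' @return list(length, sequence, offset_start, offset_end), or NULL when
#'   no common substring reaches \code{minLen}.
#' @examples
#' ctx <- list(start_window = "TTTTTACGTATTTTTTTTTT",
#'             end_window   = "GGGGGGGGGGACGTAGGGGG", w = 10L)
#' findDirectRepeats(ctx)
#' @export
findDirectRepeats <- function(context, minLen = 4L, maxLen = 18L) {
    a <- strsplit(context$start_window[[1]], "")[[1]]
    b <- strsplit(context$end_window[[1]], "")[[1]]
    w <- context$w[[1]]
    na <- length(a); nb <- length(b)
    cap <- min(maxLen, na, nb)

    ## common-suffix-length dynamic programme: M[i, j] is the length of
    ## the longest common substring ending at a[i], b[j]
    M <- matrix(0L, na, nb)
    for (i in seq_len(na)) for (j in seq_len(nb)) {
        if (a[i] == b[j])
            M[i, j] <- if (i > 1L && j > 1L) M[i - 1L, j - 1L] + 1L else 1L
    }
    best <- min(max(M), cap)
    if (best < minLen) return(NULL)
    ends <- which(M >= best, arr.ind = TRUE)
    startA <- ends[, 1] - best  # 0-based window index of substring start
    startB <- ends[, 2] - best
    ord <- order(startA, startB)
    sa <- startA[ord[1]]; sb <- startB[ord[1]]
    list(length = best,
         sequence = paste0(a[(sa + 1):(sa + best)], collapse = ""),
         offset_start = as.integer(sa - w),
         offset_end = as.integer(sb - w))
}

#' Trinucleotide palindromic units straddling a junction
#'
#' Scans each junction window for a 10-bp unit t1 + spacer + t2 with
#' |t1| = |t2| = 3, |spacer| = 4 and t2 the reverse complement of t1. By
#' default the unit must straddle the junction coordinate (its first base
#' strictly before the junction and its last base at or after it); set
#' \code{straddle = FALSE} to accept units anywhere in the window.
#'
#' @param context one junction context (as for
#'   \code{\link{findDirectRepeats}}).
#' @param straddle require the unit to straddle the junction.
#' @return list(detected = logical, hits = data.frame(site, offset, unit))
#'   where offset is the signed window position of the unit's first base
#'   relative to the junction.
#' @examples
#' ctx <- list(start_window = "AAAAAACGTTTTCGTAAAAA",
#'             end_window   = "CCCCCCCCCCCCCCCCCCCC", w = 10L)
#' findPalindromicPairs(ctx)
#' @export
findPalindromicPairs <- function(context, straddle = TRUE) {
    w <- context$w[[1]]
    scan <- function(win, site) {
        n <- nchar(win)
        us <- if (straddle) seq(max(0L, w - 9L), w - 1L) else 0:(n - 10L)
        us <- us[us >= 0L & us + 10L <= n]
        hits <- lapply(us, function(u) {
            t1 <- substr(win, u + 1L, u + 3L)
            t2 <- substr(win, u + 8L, u + 10L)
            if (grepl("[^ACGT]", t1) || grepl("[^ACGT]", t2)) return(NULL)
            if (t2 == as.character(reverseComplement(DNAString(t1))))
                data.frame(site = site, offset = u - w,
                           unit = substr(win, u + 1L, u + 10L))
            else NULL
        })
        do.call(rbind, hits)
    }
    hs <- scan(context$start_window[[1]], "start")
    he <- scan(context$end_window[[1]], "end")
    hits <- rbind(hs, he)
    if (is.null(hits))
        hits <- data.frame(site = character(), offset = integer(),
                           unit = character())
    list(detected = nrow(hits) > 0, hits = hits)
}

#' Junction motif summary over all circles
#'
#' Convenience wrapper: runs \code{\link{findDirectRepeats}} and
#' \code{\link{findPalindromicPairs}} over every junction context and
#' returns one row per circle (DR length/sequence/offsets, palindrome
#' flag), the DR fraction and the modal DR length.
#'
#' @param contexts DataFrame from \code{\link{extractJunctionFlanks}}.
#' @param minLen,maxLen DR length bounds.
#' @param straddle palindrome straddle rule.
#' @return list(table, dr_fraction, dr_modal_length).
#' @export
junctionMotifSummary <- function(contexts, minLen = 4L, maxLen = 18L,
                                 straddle = TRUE) {
    n <- nrow(contexts)
    drLen <- rep(NA_integer_, n); drSeq <- rep(NA_character_, n)
    offS <- rep(NA_integer_, n); offE <- rep(NA_integer_, n)
    pal <- logical(n)
    for (i in seq_len(n)) {
        ctx <- contexts[i, ]
        hit <- findDirectRepeats(ctx, minLen, maxLen)
        if (!is.null(hit)) {
            drLen[i] <- hit$length; drSeq[i] <- hit$sequence
            offS[i] <- hit$offset_start; offE[i] <- hit$offset_end
        }
        pal[i] <- findPalindromicPairs(ctx, straddle)$detected
    }
    tab <- DataFrame(circle_id = contexts$circle_id,
                     dr_length = drLen, dr_sequence = drSeq,
                     dr_offset_start = offS, dr_offset_end = offE,
                     palindrome = pal)
    list(table = tab,
         dr_fraction = mean(!is.na(drLen)),
         dr_modal_length = if (any(!is.na(drLen)))
             modeInt(drLen[!is.na(drLen)]) else NA_integer_)
}

#' Size-binned junction frequency matrices
#'
#' Circles are assigned to size bins (default edges at the midpoints
#' between the 207/358/553/732 bp peaks) and one start/end frequency
#' matrix pair is computed per non-empty bin; empty bins are reported as
#' absent.
#'
#' @param circlesGr circles as GRanges (for lengths; must carry
#'   \code{circle_id} matching the contexts, or be in the same order).
#' @param contexts DataFrame from \code{\link{extractJunctionFlanks}}.
#' @param peakBins numeric peak centres defining the bins.
#' @return named list per bin: list(start, end) matrices, or NULL for an
#'   empty bin.
#' @export
sizeBinnedMotifs <- function(circlesGr, contexts,
                             peakBins = c(207, 358, 553, 732)) {
    peakBins <- sort(peakBins)
    edges <- c(-Inf, peakBins[-length(peakBins)] + diff(peakBins) / 2, Inf)
    lens <- width(circlesGr)
    ids <- mcols(circlesGr)$circle_id
    if (is.null(ids)) ids <- paste0("circle", seq_along(circlesGr))
    lenOf <- stats::setNames(lens, ids)
    ctxLens <- lenOf[contexts$circle_id]
    bin <- cut(ctxLens, edges, labels = paste0("peak", peakBins))
    out <- stats::setNames(vector("list", length(peakBins)),
                           levels(bin))
    for (b in levels(bin)) {
        sel <- which(bin == b)
        if (!length(sel)) {
            message("size bin ", b, " is empty; matrix absent")
            next
        }
        out[[b]] <- list(start = baseFrequencyMatrix(contexts[sel, ], "start"),
                         end = baseFrequencyMatrix(contexts[sel, ], "end"))
    }
    out
}
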