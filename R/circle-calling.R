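#' Filter thresholds for circle candidates
#'
#' The six confidence criteria applied to junction-evidence candidates:
#' split reads >= \code{minSplit}, circle score >= \code{minScore},
#' coverage increase at the start and end coordinates >= \code{minIncStart}
#' / \code{minIncEnd}, coverage continuity (fraction of zero-coverage
#' positions inside the circle) <= \code{maxContinuity}, and coverage SD
#' strictly smaller than mean coverage when \code{requireSdLtMean}. All
#' threshold comparisons are inclusive except the SD criterion, which is
#' strict.
#'
#' @param minSplit,minScore,minIncStart,minIncEnd,maxContinuity numeric
#'   thresholds (all >= 0).
#' @param requireSdLtMean logical.
#' @return a list of class \code{FilterThresholds}.
#' @examples
#' filterThresholds()
#' @export
filterThresholds <- function(minSplit = 2, minScore = 20,
                             minIncStart = 0.33, minIncEnd = 0.33,
                             maxContinuity = 0.1, requireSdLtMean = TRUE) {
    th <- list(minSplit = minSplit, minScore = minScore,
               minIncStart = minIncStart, minIncEnd = minIncEnd,
               maxContinuity = maxContinuity,
               requireSdLtMean = isTRUE(requireSdLtMean))
    num <- unlist(th[1:5])
    if (any(!is.finite(num)) || any(num < 0))
        stop("all numeric thresholds must be finite and >= 0")
    class(th) <- "FilterThresholds"
    th
}

#' Read a Circle-Map-style candidate table
#'
#' Parses the 11-column tab-separated dialect: chrom, start, end,
#' discordant, split, score, mean_cov, sd_cov, inc_start, inc_end,
#' continuity. Coordinates are interpreted as 0-based half-open (BED-like),
#' so the fragment length is \code{end - start}. Lines starting with
#' \code{#} are skipped. Malformed rows abort with the offending line
#' number.
#'
#' @param path TSV file path.
#' @return GRanges of candidates with the metric metadata columns.
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t1000\t1378\t5\t4\t45.1\t30.2\t8.0\t0.5\t0.6\t0.0", f)
#' readCircleTable(f)
#' @export
readCircleTable <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(trimws(lines))
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) {
        warning("empty circle table: ", path)
        return(.emptyCandidates())
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nc <- lengths(fields)
    if (any(nc != 11L)) {
        bad <- which(nc != 11L)[1]
        stop("line ", lineNo[bad], ": expected 11 columns, got ", nc[bad])
    }
    m <- do.call(rbind, fields)
    numCols <- m[, 2:11, drop = FALSE]
    suppressWarnings(storage.mode(numCols) <- "numeric")
    if (anyNA(numCols)) {
        bad <- which(apply(is.na(numCols), 1, any))[1]
        stop("line ", lineNo[bad], ": non-numeric metric value")
    }
    gr <- grFrom0(m[, 1], as.integer(numCols[, 1]), as.integer(numCols[, 2]))
    mcols(gr) <- DataFrame(
        discordant_count = as.integer(numCols[, 3]),
        split_count = as.integer(numCols[, 4]),
        circle_score = numCols[, 5],
        mean_cov = numCols[, 6],
        sd_cov = numCols[, 7],
        cov_inc_start = numCols[, 8],
        cov_inc_end = numCols[, 9],
        cov_continuity = numCols[, 10])
    gr
}

.emptyCandidates <- function() {
    gr <- GRanges()
    mcols(gr) <- DataFrame(discordant_count = integer(),
                           split_count = integer(),
                           circle_score = numeric(),
                           mean_cov = numeric(), sd_cov = numeric(),
                           cov_inc_start = numeric(),
                           cov_inc_end = numeric(),
                           cov_continuity = numeric())
    gr
}

## reference span consumed by a CIGAR (M/D/N/=/X operations)
.cigarRefSpan <- function(cigar) {
    vapply(cigar, function(cg) {
        ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
        len <- as.integer(sub("[MIDNSHP=X]", "", ops))
        op <- sub("\\d+", "", ops)
        sum(len[op %in% c("M", "D", "N", "=", "X")])
    }, integer(1), USE.NAMES = FALSE)
}

#' Call circle candidates from junction evidence
#'
#' Split alignments (records carrying an \code{SA} tag) whose two segments
#' map to the same chromosome in back-to-junction configuration are
#' clustered by breakpoint pair within \code{clusterTol} bp; the cluster
#' consensus breakpoint is the modal coordinate (ties toward the smaller
#' value). Each cluster becomes one candidate interval \code{[start, end)}
#' with:
#' \itemize{
#'   \item \code{split_count}: supporting split reads (primaries only),
#'   \item \code{circle_score}: sum of \code{min(MAPQ, 10)} over those
#'     reads, so two uniquely mapped split reads score 20,
#'   \item \code{discordant_count}: read pairs in outward orientation
#'     (leftmost mate reverse) with both mates inside the interval,
#'   \item coverage statistics from all primary alignments: mean and SD of
#'     per-base coverage over the interval, the relative coverage increase
#'     \code{(c_in - c_out)/c_in} over \code{covWindow}-bp windows just
#'     inside/outside each breakpoint (0 when \code{c_in} is 0), and the
#'     continuity (fraction of zero-coverage positions inside).
#' }
#' Only primary alignments (not supplementary, secondary, duplicate or
#' QC-fail) contribute to coverage.
#'
#' @param reads an \linkS4class{AlignmentSet} or path to a SAM file.
#' @param genome named DNAStringSet or named chromosome-length vector.
#' @param clusterTol breakpoint clustering tolerance in bp (default 5).
#' @param covWindow coverage-increase window in bp (default 50).
#' @return GRanges of candidates with metric metadata columns, sorted.
#' @export
callCandidates <- function(reads, genome, clusterTol = 5L, covWindow = 50L) {
    if (is.character(reads)) reads <- readSam(reads)
    aln <- alignments(reads)
    seqlens <- genomeSeqlengths(genome)
    if (nrow(aln) == 0L) return(.emptyCandidates())

    unknown <- setdiff(unique(aln$rname), names(seqlens))
    if (length(unknown))
        stop("reads reference unknown chromosome: ",
             paste(unknown, collapse = ", "))
    byChromPos <- unlist(tapply(aln$pos, factor(aln$rname, unique(aln$rname)),
                                function(p) !is.unsorted(p)))
    if (!all(byChromPos))
        stop("input reads must be coordinate-sorted")

    isSupp <- bitwAnd(aln$flag, 0x800L) != 0L
    isSec <- bitwAnd(aln$flag, 0x100L) != 0L
    isDup <- bitwAnd(aln$flag, 0x400L) != 0L
    isQcf <- bitwAnd(aln$flag, 0x200L) != 0L
    isUnmapped <- bitwAnd(aln$flag, 0x4L) != 0L
    primary <- !isSupp & !isSec & !isDup & !isQcf & !isUnmapped

    refSpan <- .cigarRefSpan(aln$cigar)

    ## ---- split-read junctions (one per primary with SA tag)
    splitIdx <- which(primary & !is.na(aln$sa))
    junc <- NULL
    if (length(splitIdx)) {
        saField <- vapply(strsplit(aln$sa[splitIdx], ";", fixed = TRUE),
                          `[`, character(1), 1)
        saParts <- strsplit(saField, ",", fixed = TRUE)
        saChrom <- vapply(saParts, `[`, character(1), 1)
        saPos <- as.integer(vapply(saParts, `[`, character(1), 2))
        saCigar <- vapply(saParts, `[`, character(1), 4)
        same <- saChrom == aln$rname[splitIdx]
        splitIdx <- splitIdx[same]
        if (length(splitIdx)) {
            saPos <- saPos[same]
            saSpan <- .cigarRefSpan(saCigar[same])
            selfPos <- aln$pos[splitIdx]
            selfSpan <- refSpan[splitIdx]
            j_s0 <- pmin(selfPos, saPos) - 1L
            j_e0 <- pmax(selfPos - 1L + selfSpan, saPos - 1L + saSpan)
            junc <- data.frame(chrom = aln$rname[splitIdx],
                               s0 = j_s0, e0 = j_e0,
                               mapq = aln$mapq[splitIdx])
        }
    }
    if (is.null(junc) || nrow(junc) == 0L) return(.emptyCandidates())

    ## cluster: gap-split on start then on end, consensus = mode
    junc <- junc[order(junc$chrom, junc$s0, junc$e0), , drop = FALSE]
    cl <- integer(nrow(junc))
    cid <- 0L
    for (ch in unique(junc$chrom)) {
        sel <- which(junc$chrom == ch)
        gs <- cumsum(c(TRUE, diff(junc$s0[sel]) > clusterTol))
        for (g in unique(gs)) {
            sub <- sel[gs == g]
            sub <- sub[order(junc$e0[sub])]
            ge <- cumsum(c(TRUE, diff(junc$e0[sub]) > clusterTol))
            for (h in unique(ge)) {
                cid <- cid + 1L
                cl[sub[ge == h]] <- cid
            }
        }
    }
    junc$cluster <- cl

    cons <- do.call(rbind, lapply(split(junc, junc$cluster), function(d) {
        data.frame(chrom = d$chrom[1],
                   s0 = modeInt(d$s0), e0 = modeInt(d$e0),
                   split_count = nrow(d),
                   circle_score = sum(pmin(d$mapq, 10)))
    }))

    ## ---- discordant (outward-oriented) pairs
    pairTab <- NULL
    simplePrimary <- primary & is.na(aln$sa)
    sp <- which(simplePrimary)
    if (length(sp)) {
        qn <- aln$qname[sp]
        cnt <- table(qn)
        both <- names(cnt)[cnt == 2L]
        sp2 <- sp[qn %in% both]
        if (length(sp2)) {
            d <- data.frame(idx = sp2, qname = aln$qname[sp2],
                            chrom = aln$rname[sp2], pos = aln$pos[sp2],
                            end = aln$pos[sp2] + refSpan[sp2] - 1L,
                            rev = bitwAnd(aln$flag[sp2], 0x10L) != 0L)
            d <- d[order(d$qname, d$pos), ]
            if (nrow(d) >= 2L) {
                odd <- seq(1, nrow(d) - 1, by = 2)
                left <- d[odd, ]; right <- d[odd + 1L, ]
                disc <- left$chrom == right$chrom & left$rev & !right$rev
                pairTab <- data.frame(chrom = left$chrom[disc],
                                      lo = left$pos[disc],
                                      hi = right$end[disc])
            }
        }
    }

    ## ---- coverage from primary alignments
    covByChrom <- list()
    for (ch in unique(aln$rname[primary])) {
        sel <- primary & aln$rname == ch
        ir <- IRanges(aln$pos[sel], width = refSpan[sel])
        covByChrom[[ch]] <- coverage(ir, width = seqlens[[ch]])
    }

    n <- nrow(cons)
    disc_n <- integer(n); mean_cov <- numeric(n); sd_cov <- numeric(n)
    incS <- numeric(n); incE <- numeric(n); contin <- numeric(n)
    ## outside-window coverage measures linear background, so positions
    ## falling inside ANOTHER candidate circle are excluded from it --
    ## overlapping circles must not suppress each other's coverage-increase
    ## signal
    candByChrom <- split(IRanges(cons$s0 + 1L, cons$e0),
                         factor(cons$chrom, unique(cons$chrom)))
    outsideMean <- function(cov, lo, hi, mask) {
        if (lo > hi) return(0)
        win <- IRanges(lo, hi)
        keep <- IRanges::setdiff(win, mask)
        if (!sum(width(keep))) return(0)
        vals <- unlist(lapply(seq_along(keep), function(j)
            as.numeric(S4Vectors::window(cov, start(keep)[j],
                                         end(keep)[j]))))
        mean(vals)
    }
    for (k in seq_len(n)) {
        ch <- cons$chrom[k]; s0k <- cons$s0[k]; e0k <- cons$e0[k]
        cov <- covByChrom[[ch]]
        inside <- as.numeric(S4Vectors::window(cov, s0k + 1L, e0k))
        mean_cov[k] <- mean(inside)
        sd_cov[k] <- stats::sd(inside)
        if (is.na(sd_cov[k])) sd_cov[k] <- 0
        contin[k] <- mean(inside == 0)
        chrCands <- candByChrom[[ch]]
        self <- start(chrCands) == s0k + 1L & end(chrCands) == e0k
        mask <- reduce(chrCands[!self])

        cin <- mean(inside[seq_len(min(covWindow, length(inside)))])
        cout <- outsideMean(cov, max(1L, s0k + 1L - covWindow), s0k, mask)
        incS[k] <- if (cin > 0) (cin - cout) / cin else 0
        cinE <- mean(inside[seq(max(1L, length(inside) - covWindow + 1L),
                                length(inside))])
        coutE <- outsideMean(cov, e0k + 1L, min(length(cov), e0k + covWindow),
                             mask)
        incE[k] <- if (cinE > 0) (cinE - coutE) / cinE else 0
        if (!is.null(pairTab) && nrow(pairTab)) {
            disc_n[k] <- sum(pairTab$chrom == ch &
                             pairTab$lo >= s0k + 1L - clusterTol &
                             pairTab$hi <= e0k + clusterTol)
        }
    }

    gr <- grFrom0(cons$chrom, cons$s0, cons$e0, seqlens = seqlens)
    mcols(gr) <- DataFrame(discordant_count = disc_n,
                           split_count = cons$split_count,
                           circle_score = cons$circle_score,
                           mean_cov = mean_cov, sd_cov = sd_cov,
                           cov_inc_start = incS, cov_inc_end = incE,
                           cov_continuity = contin)
    sort(gr, ignore.strand = TRUE)
}

#' Apply the six-criterion confidence filter
#'
#' Keeps exactly the candidates with \code{split_count >= minSplit},
#' \code{circle_score >= minScore}, \code{cov_inc_start >= minIncStart},
#' \code{cov_inc_end >= minIncEnd}, \code{cov_continuity <= maxContinuity}
#' and, when required, \code{sd_cov < mean_cov} (strict). All other
#' comparisons are inclusive. Order is preserved; the operation is
#' idempotent.
#'
#' @param candidates GRanges with the candidate metric columns.
#' @param thresholds a \code{\link{filterThresholds}} object.
#' @return filtered GRanges (subset of the input, same order).
#' @export
applyFilters <- function(candidates, thresholds = filterThresholds()) {
    if (!length(candidates)) return(candidates)
    m <- mcols(candidates)
    keep <- m$split_count >= thresholds$minSplit &
        m$circle_score >= thresholds$minScore &
        m$cov_inc_start >= thresholds$minIncStart &
        m$cov_inc_end >= thresholds$minIncEnd &
        m$cov_continuity <= thresholds$maxContinuity
    if (thresholds$requireSdLtMean)
        keep <- keep & m$sd_cov < m$mean_cov
    candidates[keep]
}

#' Deduplicate circles by exact coordinates
#'
#' Unique by exact (chrom, start, end); among duplicates the record with
#' the highest \code{circle_score} is retained (first occurrence on ties).
#' Intervals differing by a single base are distinct circles and both kept.
#'
#' @param candidates GRanges of candidates.
#' @return deduplicated GRanges, input order of retained records.
#' @export
dedupCircles <- function(candidates) {
    if (length(candidates) < 2L) return(candidates)
    key <- paste(seqnames(candidates), start(candidates), end(candidates))
    score <- mcols(candidates)$circle_score
    if (is.null(score)) score <- rep(0, length(candidates))
    ord <- order(match(key, unique(key)), -score)
    first <- !duplicated(key[ord])
    keep <- sort(ord[first])
    candidates[keep]
}
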