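#' Simulate aligned Circle-Seq reads from circular templates
#'
#' Paired-end fragments are drawn from each circle's circular coordinate
#' space: fragment start positions are uniform on the circle and all read
#' coordinates are taken modulo the circle length, mimicking the
#' rolling-circle concatemers of Circle-Seq libraries. A read whose
#' alignment crosses the junction is emitted as a split alignment (primary
#' plus supplementary record, each carrying an SA tag pointing at the
#' other); a fragment that straddles the junction without either read
#' crossing it is emitted as a discordant pair (mate order inconsistent
#' with a linear template, proper-pair flag unset). Linear background
#' fragments are emitted genome-wide at \code{backgroundDepth}, a fraction
#' \code{fracMapq0} of them at MAPQ 0.
#'
#' Each circle receives Poisson(\code{circleDepth * L / (2 * readLength)})
#' fragments, so the expected junction-spanning read count equals
#' \code{circleDepth} and scales linearly with it. Circles shorter than
#' the read length are handled by wraparound (the alignment is soft-clipped
#' after one full circle copy), never dropped.
#'
#' @param circles GRanges of true circles (from
#'   \code{\link{sampleTrueCircles}}).
#' @param genome named DNAStringSet -- the (motif-rewritten) genome the
#'   circles were drawn on.
#' @param config a \linkS4class{SimConfig}.
#' @param seed RNG seed; defaults to \code{config@seed + 2}.
#' @return An \linkS4class{AlignmentSet}, coordinate-sorted.
#' @examples
#' cfg <- simConfig(seed = 1, chromLength = 20000, nCircles = 3L,
#'                  backgroundDepth = 0)
#' ref <- generateReference(cfg)
#' tc <- sampleTrueCircles(cfg, ref$genome)
#' simulateReads(tc$circles, tc$genome, cfg)
#' @export
simulateReads <- function(circles, genome, config, seed = config@seed + 2L) {
    validObject(config)
    seqlens <- genomeSeqlengths(genome)
    if (length(circles)) {
        bad <- end(circles) > seqlens[as.character(seqnames(circles))]
        if (any(bad))
            stop("circle(s) extend past chromosome end: ",
                 paste(head(which(bad)), collapse = ", "))
    }
    withSeed(seed, .simulateReads(circles, genome, config))
}

.simulateReads <- function(circles, genome, config) {
    rl <- config@readLength
    chars <- lapply(names(genome), function(ch) as.character(genome[[ch]]))
    names(chars) <- names(genome)
    seqlens <- genomeSeqlengths(genome)

    recs <- list()

    ## ---- circular templates
    for (i in seq_along(circles)) {
        ch <- as.character(seqnames(circles)[i])
        s0 <- start(circles)[i] - 1L
        L <- width(circles)[i]
        nFrag <- rpois(1, config@circleDepth * L / (2 * rl))
        if (nFrag == 0L) next
        ## circle sequence tiled enough times that any read is a substring
        cs <- substr(chars[[ch]], s0 + 1L, s0 + L)
        cs2 <- paste(rep(cs, ceiling((rl + L) / L) + 1L), collapse = "")

        phi <- floor(runif(nFrag, 0, L))
        flen <- round(rtruncnorm(nFrag, rep(config@fragmentMean, nFrag),
                                 rep(config@fragmentSd, nFrag),
                                 rl, 4 * config@fragmentMean))
        qn <- paste0("c", i, "_f", seq_len(nFrag))
        fragWraps <- phi + flen > L

        ## per-read circle-space start (mate 1 forward, mate 2 reverse)
        a1 <- phi %% L
        a2 <- (phi + flen - rl) %% L
        recs[[length(recs) + 1L]] <-
            .circleReadRecords(a1, a2, rl, L, s0, ch, cs2,
                               config@mapqUnique, qn, fragWraps)
    }

    ## ---- linear background
    if (config@backgroundDepth > 0) {
        G <- sum(as.numeric(seqlens))
        nBg <- rpois(1, config@backgroundDepth * G / (2 * rl))
        if (nBg > 0) {
            bgChrom <- sample(names(seqlens), nBg, replace = TRUE,
                              prob = as.numeric(seqlens))
            bgFlen <- round(rtruncnorm(nBg, rep(config@fragmentMean, nBg),
                                       rep(config@fragmentSd, nBg),
                                       rl, 4 * config@fragmentMean))
            bgMapq <- ifelse(runif(nBg) < config@fracMapq0, 0L,
                             config@mapqUnique)
            p1 <- integer(nBg)
            for (j in seq_len(nBg))
                p1[j] <- floor(runif(1, 0, seqlens[[bgChrom[j]]] -
                                            bgFlen[j])) + 1L
            p2 <- p1 + bgFlen - rl
            seq1 <- seq2 <- character(nBg)
            for (ch in unique(bgChrom)) {
                sel <- bgChrom == ch
                seq1[sel] <- substring(chars[[ch]], p1[sel],
                                       p1[sel] + rl - 1L)
                seq2[sel] <- substring(chars[[ch]], p2[sel],
                                       p2[sel] + rl - 1L)
            }
            qn <- paste0("bg_f", seq_len(nBg))
            recs[[length(recs) + 1L]] <- data.frame(
                qname = rep(qn, 2L),
                flag = rep(c(99L, 147L), each = nBg),  # proper FR pair
                rname = rep(bgChrom, 2L),
                pos = c(p1, p2),
                mapq = rep(bgMapq, 2L),
                cigar = paste0(rl, "M"),
                rnext = "=",
                pnext = c(p2, p1),
                tlen = c(bgFlen, -bgFlen),
                seq = c(seq1, seq2),
                sa = NA_character_)
        }
    }

    aln <- if (length(recs)) do.call(rbind, recs)
           else data.frame(qname = character(), flag = integer(),
                           rname = character(), pos = integer(),
                           mapq = integer(), cigar = character(),
                           rnext = character(), pnext = integer(),
                           tlen = integer(), seq = character(),
                           sa = character())
    AlignmentSet(aln)
}

## vectorised record construction for one circle's fragments; a1/a2 are the
## circle-space starts of the two mates
.circleReadRecords <- function(a1, a2, rl, L, s0, ch, cs2, mapq, qn,
                               fragWraps) {
    mateFlag <- function(first, proper) {
        base <- 0x1L + ifelse(proper, 0x2L, 0L)
        if (first) base + 0x20L + 0x40L else base + 0x10L + 0x80L
    }
    build <- function(a, first, proper, matePrimaryPos) {
        len1 <- pmin(L - a, rl)
        split <- len1 < rl
        len2 <- pmin(rl - len1, L)
        rest <- rl - len1 - len2
        pos1 <- s0 + a + 1L
        pos2 <- s0 + 1L
        seqStr <- substring(cs2, a + 1L, a + rl)
        fl <- mateFlag(first, proper)
        cig1 <- ifelse(split, paste0(len1, "M", rl - len1, "S"),
                       paste0(rl, "M"))
        cig2 <- paste0(len1, "S", len2, "M",
                       ifelse(rest > 0, paste0(rest, "S"), ""))
        saOf1 <- paste0(ch, ",", pos1, ",+,", cig1, ",", mapq, ",0;")
        saOf2 <- paste0(ch, ",", pos2, ",+,", cig2, ",", mapq, ",0;")
        primaryIs1 <- len1 >= len2

        rec1 <- data.frame(qname = qn, flag = fl, rname = ch, pos = pos1,
                           mapq = mapq, cigar = cig1, rnext = "=",
                           pnext = matePrimaryPos, tlen = 0L, seq = seqStr,
                           sa = ifelse(split, saOf2, NA_character_))
        rec1$flag <- rec1$flag + ifelse(split & !primaryIs1, 0x800L, 0L)
        if (!any(split)) return(rec1)
        sp <- which(split)
        rec2 <- data.frame(qname = qn[sp], flag = fl[sp], rname = ch,
                           pos = pos2, mapq = mapq, cigar = cig2[sp],
                           rnext = "=", pnext = matePrimaryPos[sp],
                           tlen = 0L, seq = seqStr[sp],
                           sa = saOf1[sp])
        rec2$flag <- rec2$flag + ifelse(primaryIs1[sp], 0x800L, 0L)
        rbind(rec1, rec2)
    }
    ## a mate's primary position: its longer segment's start
    primaryPos <- function(a) {
        len1 <- pmin(L - a, rl)
        len2 <- pmin(rl - len1, L)
        ifelse(len1 >= len2, s0 + a + 1L, s0 + 1L)
    }
    proper <- !fragWraps
    rbind(build(a1, TRUE, proper, primaryPos(a2)),
          build(a2, FALSE, proper, primaryPos(a1)))
}
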