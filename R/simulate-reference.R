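#' Generate a toy reference genome with planted annotations
#'
#' Builds a random genome of \code{nChroms} chromosomes at the configured
#' background GC, then plants: non-overlapping protein-coding genes (with
#' exon/intron structure, 5'/3' UTRs and derived strand-aware 2-kb
#' upstream/downstream flanks), CpG islands (sequence rewritten at elevated
#' GC), repeat-class intervals per the element plan, and short miRNA genes
#' (60-100 bp) placed both inside and outside gene bodies. The result stands
#' in for a real assembly plus its annotation tracks so the downstream
#' statistics can be validated against known truth.
#'
#' Deterministic for a fixed \code{config@seed}: the same configuration
#' yields byte-identical genome and annotations.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{genome} (named DNAStringSet) and
#'   \code{annotations} (GRanges with metadata columns \code{type},
#'   \code{id}, \code{biotype}).
#' @examples
#' ref <- generateReference(simConfig(seed = 1, chromLength = 50000,
#'                                    nMirna = 4L))
#' ref$genome
#' table(ref$annotations$type)
#' @export
generateReference <- function(config) {
    validObject(config)
    withSeed(config@seed, .generateReference(config))
}

.generateReference <- function(config) {
    L <- config@chromLength
    gc <- config@gcBackground
    baseProb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    chromNames <- paste0("chr", seq_len(config@nChroms))

    seqs <- list()
    annRows <- list()
    geneCounter <- 0L

    for (ci in seq_len(config@nChroms)) {
        chrom <- chromNames[ci]
        bases <- sample(names(baseProb), L, replace = TRUE, prob = baseProb)

        ## --- genes: sequential placement with >= 4.2 kb gaps so 2-kb
        ## flanks never reach a neighbouring gene body
        minGap <- 4200L
        nGenes <- max(1L, round(config@geneFraction * L / config@meanGeneLength))
        glens <- round(rtruncnorm(nGenes, rep(config@meanGeneLength, nGenes),
                                  rep(0.25 * config@meanGeneLength, nGenes),
                                  2000, 3 * config@meanGeneLength))
        slack <- L - sum(glens) - (nGenes + 1L) * minGap
        if (slack < 0)
            stop("element plan exceeding genome capacity: gene")
        cuts <- sort(runif(nGenes, 0, slack))
        extra <- diff(c(0, cuts, slack))
        gaps <- minGap + floor(extra[seq_len(nGenes)])
        gstart0 <- cumsum(gaps) + cumsum(c(0L, glens[-nGenes]))
        gend0 <- gstart0 + glens
        gstrand <- sample(c("+", "-"), nGenes, replace = TRUE)

        geneRows <- data.frame(chrom = chrom, start0 = gstart0, end0 = gend0,
                               strand = gstrand, type = "gene",
                               id = paste0("GENE", geneCounter + seq_len(nGenes)),
                               biotype = "protein_coding")
        geneCounter <- geneCounter + nGenes
        annRows[[length(annRows) + 1L]] <- geneRows

        for (g in seq_len(nGenes)) {
            annRows[[length(annRows) + 1L]] <-
                .geneStructure(chrom, gstart0[g], gend0[g], gstrand[g],
                               geneRows$id[g], L)
        }

        ## --- CpG islands: anywhere (promoter overlap is realistic);
        ## sequence rewritten at elevated GC
        nCpg <- round(config@cpgFraction * L / config@meanCpgLength)
        if (nCpg > 0) {
            clens <- round(rtruncnorm(nCpg, rep(config@meanCpgLength, nCpg),
                                      rep(0.3 * config@meanCpgLength, nCpg),
                                      200, 3 * config@meanCpgLength))
            pl <- placeNonOverlapping(L, clens)
            if (pl$dropped > 0)
                stop("element plan exceeding genome capacity: CpG")
            cpgProb <- c(A = (1 - config@cpgGc) / 2, C = config@cpgGc / 2,
                         G = config@cpgGc / 2, T = (1 - config@cpgGc) / 2)
            for (k in seq_along(pl$start0)) {
                idx <- (pl$start0[k] + 1L):(pl$start0[k] + pl$length[k])
                bases[idx] <- sample(names(cpgProb), length(idx),
                                     replace = TRUE, prob = cpgProb)
            }
            annRows[[length(annRows) + 1L]] <- data.frame(
                chrom = chrom, start0 = pl$start0,
                end0 = pl$start0 + pl$length, strand = "*", type = "CpG",
                id = paste0(chrom, "_CpG", seq_along(pl$start0)),
                biotype = NA_character_)
        }

        ## --- repeat classes from the element plan (non-overlapping
        ## within a class; cross-class overlap permitted, as in RepeatMasker
        ## annotations collapsed per class)
        ep <- config@elementPlan
        for (r in seq_len(nrow(ep))) {
            cls <- ep$class[r]
            nEl <- round(ep$genome_fraction[r] * L / ep$mean_length[r])
            if (nEl < 1) next
            elens <- round(rtruncnorm(nEl, rep(ep$mean_length[r], nEl),
                                      rep(0.2 * ep$mean_length[r], nEl),
                                      30, 4 * ep$mean_length[r]))
            pl <- placeNonOverlapping(L, elens)
            if (pl$dropped > 0)
                stop("element plan exceeding genome capacity: ", cls)
            annRows[[length(annRows) + 1L]] <- data.frame(
                chrom = chrom, start0 = pl$start0,
                end0 = pl$start0 + pl$length, strand = "*", type = cls,
                id = paste0(chrom, "_", cls, seq_along(pl$start0)),
                biotype = NA_character_)
        }

        seqs[[chrom]] <- bases
    }

    ann <- do.call(rbind, annRows)

    ## --- miRNA genes: ~half inside gene bodies (intronic placement),
    ## half intergenic
    mir <- .placeMirnas(config, ann, chromNames, L)
    if (!is.null(mir)) ann <- rbind(ann, mir)

    genome <- DNAStringSet(vapply(seqs, paste0, character(1), collapse = ""))
    names(genome) <- chromNames
    seqlens <- setNames(rep(L, config@nChroms), chromNames)

    annotations <- grFrom0(ann$chrom, ann$start0, ann$end0,
                           seqlens = seqlens, strand = ann$strand)
    mcols(annotations)$type <- ann$type
    mcols(annotations)$id <- ann$id
    mcols(annotations)$biotype <- ann$biotype
    annotations <- sort(annotations, ignore.strand = TRUE)

    list(genome = genome, annotations = annotations)
}

## exon/intron/UTR structure plus strand-aware 2-kb flanks for one gene
.geneStructure <- function(chrom, gs0, ge0, strand, geneId, L) {
    glen <- ge0 - gs0
    nEx <- sample(3:8, 1)
    exLens <- round(runif(nEx, 80, 300))
    if (sum(exLens) > 0.5 * glen)
        exLens <- pmax(40L, floor(exLens * 0.5 * glen / sum(exLens)))
    intronTotal <- glen - sum(exLens)
    props <- diff(c(0, sort(runif(nEx - 2)), 1))
    inLens <- floor(props * intronTotal)
    inLens[length(inLens)] <- intronTotal - sum(inLens[-length(inLens)])

    segLens <- integer(2 * nEx - 1)
    segLens[seq(1, 2 * nEx - 1, by = 2)] <- exLens
    segLens[seq(2, 2 * nEx - 2, by = 2)] <- inLens
    segEnd <- gs0 + cumsum(segLens)
    segStart <- c(gs0, segEnd[-length(segEnd)])
    isExon <- rep(c(TRUE, FALSE), length.out = 2 * nEx - 1)

    rows <- data.frame(chrom = chrom, start0 = segStart, end0 = segEnd,
                       strand = strand,
                       type = ifelse(isExon, "exon", "intron"),
                       id = paste0(geneId, "_",
                                   ifelse(isExon, "ex", "in"),
                                   cumsum(isExon) * isExon +
                                       cumsum(!isExon) * !isExon),
                       biotype = NA_character_)

    ## UTRs live at the transcript ends, inside the terminal exons
    u5 <- min(round(runif(1, 60, 200)), exLens[1] - 10, exLens[nEx] - 10)
    u3 <- min(round(runif(1, 100, 400)), exLens[nEx] - 10, exLens[1] - 10)
    if (strand == "+") {
        utr <- data.frame(chrom = chrom,
                          start0 = c(gs0, ge0 - u3),
                          end0 = c(gs0 + u5, ge0),
                          strand = strand, type = c("5UTR", "3UTR"),
                          id = paste0(geneId, c("_5utr", "_3utr")),
                          biotype = NA_character_)
        fl <- data.frame(chrom = chrom,
                         start0 = c(max(0, gs0 - 2000), ge0),
                         end0 = c(gs0, min(L, ge0 + 2000)),
                         strand = strand, type = c("gene2kbU", "gene2kbD"),
                         id = paste0(geneId, c("_up2kb", "_down2kb")),
                         biotype = NA_character_)
    } else {
        utr <- data.frame(chrom = chrom,
                          start0 = c(ge0 - u5, gs0),
                          end0 = c(ge0, gs0 + u3),
                          strand = strand, type = c("5UTR", "3UTR"),
                          id = paste0(geneId, c("_5utr", "_3utr")),
                          biotype = NA_character_)
        fl <- data.frame(chrom = chrom,
                         start0 = c(ge0, max(0, gs0 - 2000)),
                         end0 = c(min(L, ge0 + 2000), gs0),
                         strand = strand, type = c("gene2kbU", "gene2kbD"),
                         id = paste0(geneId, c("_up2kb", "_down2kb")),
                         biotype = NA_character_)
    }
    rbind(rows, utr, fl)
}

.placeMirnas <- function(config, ann, chromNames, L) {
    nMir <- config@nMirna
    if (nMir < 1) return(NULL)
    genes <- ann[ann$type == "gene", , drop = FALSE]
    rows <- vector("list", nMir)
    for (m in seq_len(nMir)) {
        mlen <- round(runif(1, 60, 100))
        if (nrow(genes) && runif(1) < 0.5) {
            g <- genes[sample(nrow(genes), 1), ]
            s0 <- g$start0 + floor(runif(1, 200, g$end0 - g$start0 - 200 - mlen))
            chrom <- g$chrom
        } else {
            chrom <- sample(chromNames, 1)
            for (t in 1:200) {
                s0 <- floor(runif(1, 0, L - mlen))
                inGene <- any(genes$chrom == chrom & s0 < genes$end0 &
                              s0 + mlen > genes$start0)
                if (!inGene) break
            }
        }
        rows[[m]] <- data.frame(chrom = chrom, start0 = s0, end0 = s0 + mlen,
                                strand = sample(c("+", "-"), 1),
                                type = "miRNA", id = sprintf("MIR%03d", m),
                                biotype = "miRNA")
    }
    do.call(rbind, rows)
}
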