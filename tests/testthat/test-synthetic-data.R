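test_that("reference generation is deterministic and dimensioned by config", {
    cfg <- simConfig(seed = 11, nChroms = 2, chromLength = 50000L,
                     nMirna = 6L)
    r1 <- generateReference(cfg)
    r2 <- generateReference(cfg)
    expect_identical(as.character(r1$genome), as.character(r2$genome))
    expect_identical(as.data.frame(r1$annotations),
                     as.data.frame(r2$annotations))
    expect_identical(names(r1$genome), c("chr1", "chr2"))
    expect_identical(unname(width(r1$genome)), c(50000L, 50000L))

    r3 <- generateReference(simConfig(seed = 12, nChroms = 2,
                                      chromLength = 50000L, nMirna = 6L))
    expect_false(identical(as.character(r1$genome),
                           as.character(r3$genome)))
})

test_that("planted element classes occupy their configured genome fraction", {
    cfg <- simConfig(seed = 5, nChroms = 2, chromLength = 500000L)
    ref <- generateReference(cfg)
    ann <- ref$annotations
    G <- sum(as.numeric(width(ref$genome)))
    for (k in seq_len(nrow(cfg@elementPlan))) {
        cls <- cfg@elementPlan$class[k]
        frac <- sum(width(reduce(ann[ann$type == cls],
                                 ignore.strand = TRUE))) / G
        expect_lt(abs(frac - cfg@elementPlan$genome_fraction[k]), 0.02)
    }
    ## CpG islands carry elevated GC relative to background
    cpg <- ann[ann$type == "CpG"]
    gcCpg <- mean(letterFrequency(Views(ref$genome[[1]],
        start(cpg[seqnames(cpg) == "chr1"]),
        end(cpg[seqnames(cpg) == "chr1"])), "GC", as.prob = TRUE))
    expect_gt(gcCpg, cfg@gcBackground + 0.1)
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(sizePeaks = data.frame(mean = 358, sd = 20,
                                                  weight = 0.5)),
                 "sum to 1")
    expect_error(simConfig(drLengthRange = c(3L, 18L)), "\\[4, 18\\]")
    expect_error(simConfig(pDirectRepeat = 1.4), "probabilities")
    expect_error(simConfig(geneFraction = 0.9, cpgFraction = 0.2),
                 "exceed 1")
})

test_that("circle origins follow the configured GC bias", {
    cfg0 <- simConfig(seed = 21, nChroms = 1, chromLength = 800000L,
                      nCircles = 5000L, gcBiasBeta = 0,
                      pDirectRepeat = 0, pPalindrome = 0,
                      cpgFraction = 0)  # no GC structure beyond background
    ref <- generateReference(cfg0)
    tc <- sampleTrueCircles(cfg0, ref$genome)
    gcCirc <- letterFrequency(Views(ref$genome[[1]],
                                    start(tc$circles), end(tc$circles)),
                              "GC", as.prob = TRUE)
    gcGenome <- letterFrequency(ref$genome[[1]], "GC", as.prob = TRUE)
    ## unbiased origins: mean circle GC compatible with the genome mean
    tt <- t.test(gcCirc, mu = as.numeric(gcGenome))
    expect_gt(tt$p.value, 0.01)

    cfg4 <- simConfig(seed = 21, nChroms = 1, chromLength = 800000L,
                      nCircles = 2000L, gcBiasBeta = 4,
                      pDirectRepeat = 0, pPalindrome = 0)
    ref4 <- generateReference(cfg4)
    tc4 <- sampleTrueCircles(cfg4, ref4$genome)
    gc4 <- letterFrequency(Views(ref4$genome[[1]],
                                 start(tc4$circles), end(tc4$circles)),
                           "GC", as.prob = TRUE)
    g4 <- letterFrequency(ref4$genome[[1]], "GC", as.prob = TRUE)
    tt4 <- t.test(gc4, mu = as.numeric(g4), alternative = "greater")
    expect_lt(tt4$p.value, 0.01)
})

test_that("forced direct-repeat planting writes identical junction substrings", {
    cfg <- simConfig(seed = 31, nChroms = 1, chromLength = 300000L,
                     nCircles = 60L, pDirectRepeat = 1,
                     drLengthRange = c(5L, 5L), pPalindrome = 0)
    ref <- generateReference(cfg)
    tc <- sampleTrueCircles(cfg, ref$genome)
    expect_identical(nrow(tc$rewriteLog), 0L)
    chr <- as.character(tc$genome[[1]])
    for (i in seq_along(tc$circles)) {
        s0 <- start(tc$circles)[i] - 1L
        e0 <- end(tc$circles)[i]
        expect_identical(substr(chr, s0 + 1, s0 + 5),
                         substr(chr, e0 + 1, e0 + 5))
    }
    expect_true(all(tc$circles$planted_dr_length == 5L))
})

test_that("circle sizes respect the truncation bounds and mixture seeds", {
    cfg <- simConfig(seed = 41, nChroms = 1, chromLength = 400000L,
                     nCircles = 2000L)
    ref <- generateReference(cfg)
    tc1 <- sampleTrueCircles(cfg, ref$genome)
    tc2 <- sampleTrueCircles(cfg, ref$genome)
    expect_identical(as.data.frame(tc1$circles), as.data.frame(tc2$circles))
    expect_true(all(width(tc1$circles) >= cfg@sizeRange[1]))
    expect_true(all(width(tc1$circles) <= cfg@sizeRange[2]))
})

test_that("a single circle yields split reads at the exact breakpoints", {
    cfg <- simConfig(seed = 51, nChroms = 1, chromLength = 60000L,
                     nCircles = 1L, circleDepth = 30, backgroundDepth = 0,
                     pDirectRepeat = 0, pPalindrome = 0)
    ref <- generateReference(cfg)
    circle <- GRanges("chr1", IRanges(20001, 20378),
                      seqlengths = c(chr1 = 60000L))  # 378 bp
    reads <- simulateReads(circle, ref$genome, cfg)
    aln <- alignments(reads)
    splitPrim <- aln[bitwAnd(aln$flag, 0x800L) == 0L & !is.na(aln$sa), ]
    expect_gte(nrow(splitPrim), 2L)
    cand <- callCandidates(reads, ref$genome)
    expect_length(cand, 1L)
    expect_identical(start(cand), 20001L)
    expect_identical(end(cand), 20378L)
    expect_identical(width(cand), 378L)
})

test_that("junction-spanning read count scales linearly with circle depth", {
    base <- simConfig(seed = 61, nChroms = 1, chromLength = 200000L,
                      nCircles = 12L, circleDepth = 30, backgroundDepth = 0)
    ref <- generateReference(base)
    tc <- sampleTrueCircles(base, ref$genome)
    countSplit <- function(cfg, seed) {
        aln <- alignments(simulateReads(tc$circles, tc$genome, cfg,
                                        seed = seed))
        sum(bitwAnd(aln$flag, 0x800L) == 0L & !is.na(aln$sa))
    }
    n1 <- countSplit(base, seed = 100)
    dbl <- simConfig(seed = 61, nChroms = 1, chromLength = 200000L,
                     nCircles = 12L, circleDepth = 60, backgroundDepth = 0)
    n2 <- countSplit(dbl, seed = 200)
    expect_gt(n2 / n1, 1.6)
    expect_lt(n2 / n1, 2.4)
})

test_that("background-only libraries contain no junction evidence", {
    cfg <- simConfig(seed = 71, nChroms = 1, chromLength = 100000L,
                     nCircles = 1L, circleDepth = 0, backgroundDepth = 2)
    ref <- generateReference(cfg)
    reads <- simulateReads(GRanges(), ref$genome, cfg)
    aln <- alignments(reads)
    expect_gt(nrow(aln), 0L)
    expect_true(all(is.na(aln$sa)))
})

test_that("every split alignment reconstructs a true junction", {
    cfg <- simConfig(seed = 81, nChroms = 2, chromLength = 150000L,
                     nCircles = 30L, circleDepth = 10, backgroundDepth = 0.5)
    ref <- generateReference(cfg)
    tc <- sampleTrueCircles(cfg, ref$genome)
    aln <- alignments(simulateReads(tc$circles, tc$genome, cfg))
    prim <- aln[bitwAnd(aln$flag, 0x800L) == 0L & !is.na(aln$sa), ]
    refSpan <- function(cg) {
        ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
        sum(as.integer(sub("[A-Z=]", "", ops))[grepl("[MDN=X]", ops)])
    }
    truthKey <- paste(seqnames(tc$circles), start(tc$circles) - 1L,
                      end(tc$circles))
    for (k in seq_len(nrow(prim))) {
        sa <- strsplit(prim$sa[k], ",")[[1]]
        s0 <- min(prim$pos[k], as.integer(sa[2])) - 1L
        e0 <- max(prim$pos[k] - 1L + refSpan(prim$cigar[k]),
                  as.integer(sa[2]) - 1L + refSpan(sa[4]))
        expect_true(paste(prim$rname[k], s0, e0) %in% truthKey)
    }
})

test_that("cohort simulation plants the group contrast and recurrent circles", {
    cfgH <- simConfig(seed = 91, nChroms = 2, chromLength = 120000L,
                      nCircles = 30L, circleDepth = 8, backgroundDepth = 0.2,
                      nMirna = 8L)
    cfgD <- simConfig(seed = 91, nChroms = 2, chromLength = 120000L,
                      nCircles = 90L, circleDepth = 8, backgroundDepth = 0.2,
                      nMirna = 8L)
    expect_error(simulateCohort(cfgH, cfgD, 0, 5), "at least 3")

    coh <- simulateCohort(cfgH, cfgD, 5, 5, nRecurrentMirna = 1L)
    grp <- vapply(coh$samples, `[[`, character(1), "group")
    nTruth <- vapply(coh$samples, function(s) length(s$truth), numeric(1))
    ratio <- mean(nTruth[grp == "disease"]) / mean(nTruth[grp == "healthy"])
    expect_gt(ratio, 2.5)
    expect_lt(ratio, 3.5)

    mir <- coh$annotations[coh$annotations$type == "miRNA" &
                           coh$annotations$id == coh$recurrentMirnaIds[1]]
    for (s in coh$samples[grp == "disease"]) {
        expect_true(any(start(s$truth) <= start(mir) &
                        end(mir) <= end(s$truth) &
                        as.character(seqnames(s$truth)) ==
                            as.character(seqnames(mir))))
    }
})
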