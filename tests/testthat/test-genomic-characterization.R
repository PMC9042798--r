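test_that("GC profile computes windowed GC with flank exclusion rules", {
    genome <- toyGenome(chr1 = paste0(strrep("A", 100), "GCGCGC",
                                      strrep("T", 100)))
    circ <- GRanges("chr1", IRanges(101, 106))  # the GCGCGC block
    prof <- gcProfile(circ, genome)
    expect_equal(prof$table$gc_circle, 1.0)
    expect_equal(prof$table$gc_upstream, 0.0)
    expect_false(prof$table$flagged)

    circ2 <- GRanges("chr1", IRanges(101, 104))
    genome2 <- toyGenome(chr1 = paste0(strrep("A", 100), "ACGT",
                                       strrep("T", 100)))
    expect_equal(gcProfile(circ2, genome2)$table$gc_circle, 0.5)

    ## a circle too close to the chromosome edge is flagged
    edge <- GRanges("chr1", IRanges(3, 40))
    expect_true(gcProfile(edge, genome)$table$flagged)
})

test_that("planted high-GC circles show the built-in GC contrast", {
    set.seed(202)
    L <- 200000L
    bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3))
    s0 <- seq(2000L, by = 3000L, length.out = 50L)
    for (s in s0) {
        bases[(s + 1):(s + 200)] <- sample(c("A", "C", "G", "T"), 200,
                                           replace = TRUE,
                                           prob = c(0.1, 0.4, 0.4, 0.1))
    }
    genome <- toyGenome(chr1 = paste(bases, collapse = ""))
    circ <- GRanges("chr1", IRanges(s0 + 1L, s0 + 200L))
    prof <- gcProfile(circ, genome)
    diffGc <- mean(prof$table$gc_circle) -
        mean(c(prof$table$gc_upstream, prof$table$gc_downstream))
    expect_lt(abs(diffGc - 0.4), 0.02)
    expect_gt(prof$peaks["circle"], prof$peaks["upstream"])
})

test_that("length peak calling finds mixture peaks and periodicity", {
    expect_warning(lp <- lengthPeaks(rep(358, 50)), "histogram only")
    expect_length(lp$peaks, 0L)

    lp1 <- lengthPeaks(rep(358, 500))
    expect_length(lp1$peaks, 1L)
    expect_lt(abs(lp1$peaks - 358), 2)
    expect_equal(lp1$frac_below_1kb, 1)

    set.seed(7)
    lens <- c(round(rnorm(5000, 207, 20)), round(rnorm(5000, 358, 20)))
    lp2 <- lengthPeaks(lens)
    expect_length(lp2$peaks, 2L)
    expect_lt(abs(lp2$peaks[1] - 207), 5)
    expect_lt(abs(lp2$peaks[2] - 358), 5)
    expect_lt(abs(lp2$periodicity - 151), 7)
})

test_that("chromosome density correlations behave on constructed inputs", {
    seqlens <- setNames(rep(1e6, 5), paste0("chr", 1:5))
    nGenes <- c(10L, 20L, 30L, 40L, 50L)
    ann <- GRanges(rep(names(seqlens), nGenes),
                   IRanges(start = unlist(lapply(nGenes, function(n)
                       seq(1000, by = 10000, length.out = n))),
                       width = 500))
    mcols(ann)$type <- "gene"
    mcols(ann)$id <- paste0("g", seq_along(ann))
    mcols(ann)$biotype <- "protein_coding"

    ## circle counts exactly proportional to gene counts -> r = 1
    circ <- GRanges(rep(names(seqlens), nGenes * 3L),
                    IRanges(start = 5000, width = 300))
    cd <- chromosomeDensity(circ, seqlens, ann)
    expect_equal(cd$gene_cor$r, 1.0, tolerance = 1e-12)
    expect_equal(sum(cd$table$percent_of_total), 100, tolerance = 1e-9)

    ## constant circle counts with varying gene counts -> no association
    circ2 <- GRanges(rep(names(seqlens), each = 4L),
                     IRanges(start = 5000, width = 300))
    cd2 <- chromosomeDensity(circ2, seqlens, ann)
    expect_equal(cd2$gene_cor$r, 0)

    ## fewer than 3 chromosomes: correlation absent
    cd3 <- chromosomeDensity(
        circ[as.character(seqnames(circ)) %in% c("chr1", "chr2")],
        seqlens[1:2], ann)
    expect_true(is.na(cd3$gene_cor$r))
})

test_that("element enrichment is calibrated on uniform circles", {
    seqlens <- c(chr1 = 600000L, chr2 = 200000L)
    ## one class covering 10% of the genome in 400-bp blocks
    starts <- seq(0L, 599999L - 400L, by = 4000L)
    starts2 <- seq(0L, 199999L - 400L, by = 4000L)
    cls <- GRanges(rep(c("chr1", "chr2"), c(length(starts), length(starts2))),
                   IRanges(c(starts, starts2) + 1L, width = 400L),
                   seqlengths = seqlens)
    mcols(cls)$type <- "SINE"
    mcols(cls)$id <- paste0("s", seq_along(cls))
    mcols(cls)$biotype <- NA_character_

    sets <- generateInsilico(nullConfig(50000L, seed = 99), seqlens)
    er <- elementEnrichment(sets[[1]], cls, seqlens, classes = "SINE")
    expect_equal(er$expected_fraction, 0.1, tolerance = 0.01)
    expect_lt(abs(er$ratio - 1), 0.05)

    ## whole-genome class: ratio exactly 1
    whole <- GRanges(names(seqlens), IRanges(1L, seqlens))
    mcols(whole)$type <- "all"
    er2 <- elementEnrichment(sets[[1]][1:100], whole, seqlens,
                             classes = "all")
    expect_identical(er2$ratio, 1)

    ## class untouched by any junction: ratio 0
    far <- GRanges("chr2", IRanges(1, 10), seqlengths = seqlens)
    mcols(far)$type <- "rare"
    circ <- GRanges("chr1", IRanges(1000, 1400), seqlengths = seqlens)
    er3 <- elementEnrichment(circ, far, seqlens, classes = "rare")
    expect_identical(er3$ratio, 0)

    expect_error(elementEnrichment(circ, far, seqlens, classes = "LINE"),
                 "unknown element class: LINE")
})

test_that("repeat mapping ratio normalizes read overlap by class size", {
    seqlens <- c(chr1 = 100000L)
    half <- GRanges("chr1", IRanges(1, 50000))
    mcols(half)$type <- "LINE"
    mkReads <- function(pos, cigar = "100M") {
        AlignmentSet(data.frame(qname = paste0("r", seq_along(pos)),
                                flag = 0L, rname = "chr1", pos = pos,
                                mapq = 60L, cigar = cigar, rnext = "=",
                                pnext = 0L, tlen = 0L, seq = "A",
                                sa = NA_character_))
    }
    ## all reads inside a class covering half the genome -> ratio 2
    r <- repeatMappingRatio(mkReads(seq(1000L, 40000L, by = 100L)),
                            half, seqlens)
    expect_equal(r$mapping_ratio, 2.0)
    ## no overlapping reads -> ratio 0
    r0 <- repeatMappingRatio(mkReads(seq(60000L, 90000L, by = 100L)),
                             half, seqlens)
    expect_equal(r0$mapping_ratio, 0)
    ## uniform reads over a 10% class -> ratio ~ 1
    set.seed(31)
    tenth <- GRanges("chr1", IRanges(seq(1L, 99000L, by = 10000L),
                                     width = 1000L))
    mcols(tenth)$type <- "SINE"
    pos <- sort(sample.int(99000L, 20000L, replace = TRUE))
    r1 <- repeatMappingRatio(mkReads(pos, cigar = "10M"), tenth, seqlens)
    expect_lt(abs(r1$mapping_ratio - 1), 0.05)
})

test_that("genome coverage fraction merges circle intervals", {
    seqlens <- c(chr1 = 1000L)
    two <- GRanges("chr1", IRanges(c(1, 51), c(100, 150)))
    expect_equal(genomeCoverageFraction(two, seqlens)$fraction, 0.15)
    disj <- GRanges("chr1", IRanges(c(1, 501), c(100, 600)))
    expect_equal(genomeCoverageFraction(disj, seqlens)$fraction, 0.20)
    expect_equal(genomeCoverageFraction(two[0], seqlens)$fraction, 0)
    ## union <= summed lengths, equality iff disjoint
    expect_lt(genomeCoverageFraction(two, seqlens)$bases,
              sum(width(two)))
    expect_equal(genomeCoverageFraction(disj, seqlens)$bases,
                 sum(width(disj)))
})

test_that("intragenic fractions and the gene-length correlation", {
    seqlens <- c(chr1 = 1000000L)
    gene <- GRanges("chr1", IRanges(1000, 11000))
    mcols(gene)$type <- "gene"
    mcols(gene)$id <- "G1"
    mcols(gene)$biotype <- "protein_coding"
    inCirc <- GRanges("chr1", IRanges(c(2000, 3000, 4000),
                                      c(2400, 3400, 4400)))
    st <- intragenicStats(inCirc, gene)
    expect_equal(st$frac_intragenic, 1.0)
    expect_equal(st$frac_protein_coding, 1.0)

    ## uniform circles over genes covering 40% of the genome
    gstarts <- seq(0L, 999999L - 20000L, by = 50000L)
    genes <- GRanges("chr1", IRanges(gstarts + 1L, width = 20000L))
    mcols(genes)$type <- "gene"
    mcols(genes)$id <- paste0("G", seq_along(genes))
    mcols(genes)$biotype <- "protein_coding"
    sets <- generateInsilico(nullConfig(20000L, seed = 13), seqlens)
    stU <- intragenicStats(sets[[1]], genes)
    expect_lt(abs(stU$frac_intragenic - 0.40), 0.03)

    ## per-gene counts proportional to gene length -> strong correlation
    set.seed(5)
    glen <- round(runif(200, 2000, 30000))
    gpos <- cumsum(glen + 3000)
    genes2 <- GRanges("chr1", IRanges(gpos - glen + 1L, gpos))
    mcols(genes2)$type <- "gene"
    mcols(genes2)$id <- paste0("H", 1:200)
    mcols(genes2)$biotype <- "protein_coding"
    circStarts <- unlist(lapply(seq_along(genes2), function(g) {
        n <- round(width(genes2)[g] / 1000)
        if (n == 0) return(integer(0))
        start(genes2)[g] + sort(sample.int(width(genes2)[g] - 300L, n))
    }))
    circ3 <- GRanges("chr1", IRanges(circStarts, width = 300L))
    seqlens2 <- c(chr1 = max(end(circ3)) + 1000L)
    st3 <- intragenicStats(circ3, genes2)
    expect_gte(st3$length_cor$r, 0.9)
})
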