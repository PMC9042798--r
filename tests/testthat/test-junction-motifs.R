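test_that("junction flank extraction follows the half-open window rule", {
    seqStr <- paste(rep(c("A", "C", "G", "T"), 100), collapse = "")
    genome <- toyGenome(chr1 = seqStr)
    circ <- GRanges("chr1", IRanges(101, 300))  # 0-based [100, 300)
    ctx <- extractJunctionFlanks(circ, genome, w = 10L)
    expect_identical(nrow(ctx), 1L)
    expect_identical(ctx$start_window, substr(seqStr, 91, 110))
    expect_identical(ctx$end_window, substr(seqStr, 291, 310))
    expect_identical(nchar(ctx$start_window), 20L)

    ## start too close to the chromosome edge: flagged, no context
    edge <- GRanges("chr1", IRanges(6, 200))  # 0-based start 5 < w
    ctxE <- extractJunctionFlanks(edge, genome, w = 10L)
    expect_identical(nrow(ctxE), 0L)
    expect_length(S4Vectors::metadata(ctxE)$flagged, 1L)
})

test_that("base frequency matrices are column-normalized", {
    ctx <- DataFrame(circle_id = c("a", "b"), chrom = "chr1",
                     start0 = 100L, end0 = 300L,
                     start_window = c(strrep("A", 20), strrep("C", 20)),
                     end_window = c(strrep("G", 20), strrep("T", 20)),
                     w = 10L)
    m <- baseFrequencyMatrix(ctx, "start")
    expect_identical(dim(m), c(4L, 20L))
    expect_true(all(m["A", ] == 0.5) && all(m["C", ] == 0.5))
    expect_equal(unname(colSums(m)), rep(1, 20), tolerance = 1e-12)

    m1 <- baseFrequencyMatrix(ctx[1, ], "start")
    expect_true(all(m1["A", ] == 1))
    expect_error(baseFrequencyMatrix(ctx[0, ], "start"), "no junction")

    ## uniform random windows: all entries near 0.25
    set.seed(41)
    rc <- DataFrame(circle_id = paste0("c", 1:1000), chrom = "chr1",
                    start0 = 0L, end0 = 0L,
                    start_window = vapply(1:1000, function(i)
                        randWindow(20), character(1)),
                    end_window = strrep("A", 20), w = 10L)
    mu <- baseFrequencyMatrix(rc, "start")
    expect_true(all(abs(mu - 0.25) < 0.05))
})

test_that("direct repeat finder matches planted and degenerate cases", {
    ctx <- list(start_window = "TTTTTACGTATTTTTTTTTT",
                end_window = "GGGGGGGGGGACGTAGGGGG", w = 10L)
    hit <- findDirectRepeats(ctx)
    expect_identical(hit$length, 5L)
    expect_identical(hit$sequence, "ACGTA")
    expect_identical(hit$offset_start, -5L)
    expect_identical(hit$offset_end, 0L)

    none <- list(start_window = strrep("A", 20),
                 end_window = strrep("C", 20), w = 10L)
    expect_null(findDirectRepeats(none))
})

test_that("direct repeat finder agrees with the brute-force oracle", {
    set.seed(53)
    for (i in 1:500) {
        ctx <- randContext()
        mine <- findDirectRepeats(ctx)
        ref <- bruteDirectRepeat(ctx)
        if (is.null(ref)) {
            expect_null(mine)
        } else {
            expect_identical(mine$length, ref$length)
            expect_identical(mine$sequence, ref$sequence)
            expect_identical(mine$offset_start, ref$offset_start)
            expect_identical(mine$offset_end, ref$offset_end)
        }
    }
})

test_that("palindromic unit detection matches definition and oracle", {
    ## revcomp(ACG) = CGT with a 4-base spacer, straddling the junction
    win <- paste0(strrep("T", 6), "ACGTTTTCGT", strrep("T", 4))
    ctx <- list(start_window = win, end_window = strrep("C", 20), w = 10L)
    res <- findPalindromicPairs(ctx)
    expect_true(res$detected)
    expect_identical(res$hits$site, "start")
    expect_identical(res$hits$unit, "ACGTTTTCGT")

    homo <- list(start_window = strrep("A", 20),
                 end_window = strrep("A", 20), w = 10L)
    expect_false(findPalindromicPairs(homo)$detected)

    set.seed(67)
    for (i in 1:500) {
        ctx <- randContext()
        mine <- findPalindromicPairs(ctx)
        ref <- brutePalindrome(ctx)
        expect_identical(mine$detected, ref$detected)
        if (ref$detected) {
            expect_identical(paste(mine$hits$site, mine$hits$offset,
                                   mine$hits$unit),
                             paste(ref$hits$site, ref$hits$offset,
                                   ref$hits$unit))
        }
    }
})

test_that("forced planting is fully recovered through the whole path", {
    cfg <- simConfig(seed = 77, nChroms = 1, chromLength = 400000L,
                     nCircles = 80L, pDirectRepeat = 1,
                     drLengthRange = c(5L, 5L), pPalindrome = 0)
    ref <- generateReference(cfg)
    tc <- sampleTrueCircles(cfg, ref$genome)
    ctx <- extractJunctionFlanks(tc$circles, tc$genome, w = 10L)
    sm <- junctionMotifSummary(ctx)
    expect_equal(sm$dr_fraction, 1.0)
    expect_identical(sm$dr_modal_length, 5L)

    cfgP <- simConfig(seed = 78, nChroms = 1, chromLength = 400000L,
                      nCircles = 60L, pDirectRepeat = 0, pPalindrome = 1)
    refP <- generateReference(cfgP)
    tcP <- sampleTrueCircles(cfgP, refP$genome)
    ctxP <- extractJunctionFlanks(tcP$circles, tcP$genome, w = 10L)
    smP <- junctionMotifSummary(ctxP)
    expect_equal(mean(smP$table$palindrome), 1.0)
})

test_that("size-binned matrices assign circles by peak midpoints", {
    mk <- function(id, len) {
        GRanges("chr1", IRanges(1000L, width = len),
                circle_id = id)
    }
    circ <- c(mk("a", 280L), mk("b", 283L), mk("c", 358L))
    ctx <- DataFrame(circle_id = c("a", "b", "c"), chrom = "chr1",
                     start0 = 999L, end0 = 1200L,
                     start_window = strrep("A", 20),
                     end_window = strrep("C", 20), w = 10L)
    suppressMessages(bins <- sizeBinnedMotifs(circ, ctx))
    ## midpoint between 207 and 358 is 282.5
    expect_false(is.null(bins$peak207))
    expect_false(is.null(bins$peak358))
    expect_null(bins$peak553)

    ## a homogeneous population gives the same matrix binned or not
    circH <- do.call(c, lapply(1:50, function(i)
        mk(paste0("h", i), 358L)))
    set.seed(3)
    ctxH <- DataFrame(circle_id = paste0("h", 1:50), chrom = "chr1",
                      start0 = 999L, end0 = 1357L,
                      start_window = vapply(1:50, function(i)
                          randWindow(20), character(1)),
                      end_window = vapply(1:50, function(i)
                          randWindow(20), character(1)), w = 10L)
    suppressMessages(binsH <- sizeBinnedMotifs(circH, ctxH))
    expect_equal(binsH$peak358$start, baseFrequencyMatrix(ctxH, "start"),
                 tolerance = 1e-12)
    expect_null(binsH$peak207)
})
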