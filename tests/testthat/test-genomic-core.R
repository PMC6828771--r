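# Gene/peak I/O and the interval operations behind peak-to-gene marking.

test_that("BED6 gene models are parsed, validated and round-tripped", {
    path <- writeBedFixture(c(
        "chr1\t999\t2000\tWIND1\t0\t+",
        "chr1\t5000\t7000\tLBD16\t0\t-"))
    genes <- readGeneModels(path)
    expect_identical(genes$gene_id, c("WIND1", "LBD16"))
    # 0-based half-open [999, 2000) becomes 1-based closed 1000..2000
    expect_equal(GenomicRanges::start(genes), c(1000L, 5001L))
    expect_equal(GenomicRanges::end(genes), c(2000L, 7000L))
    expect_equal(as.character(GenomicRanges::strand(genes)), c("+", "-"))

    out <- tempfile(fileext = ".bed")
    writeGeneModels(genes, out)
    back <- readGeneModels(out)
    expect_equal(GenomicRanges::start(back), GenomicRanges::start(genes))
    expect_equal(GenomicRanges::end(back), GenomicRanges::end(genes))
    expect_identical(readLines(out),
                     sub("\\r$", "", readLines(path)))  # exact round trip

    expect_error(readGeneModels(writeBedFixture(
        c("chr1\t0\t100\tA\t0\t+", "chr1\t200\t300\tA\t0\t+"))),
        "duplicate gene_id")
    expect_error(readGeneModels(writeBedFixture(
        "chr1\t0\t100\tA\t0\t.")), "strand")
    expect_error(readGeneModels(writeBedFixture(
        c("chr1\t0\t100\tA\t0\t+", "chr1\tx\t300\tB\t0\t+"))), "line 2")
})

test_that("GFF3 gene coordinates convert from 1-based inclusive", {
    path <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
        "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=WIND1",
        "chr1\tsrc\tmRNA\t1000\t2000\t.\t+\t.\tID=t1;Parent=WIND1",
        "chr1\tsrc\tgene\t5001\t7000\t.\t-\t.\tID=LBD16"), path)
    genes <- readGeneModels(path)
    expect_identical(genes$gene_id, c("WIND1", "LBD16"))
    expect_equal(GenomicRanges::start(genes), c(1000L, 5001L))
    expect_equal(GenomicRanges::end(genes), c(2000L, 7000L))
    # same interval as the equivalent BED 999..2000 record
    bed <- readGeneModels(writeBedFixture("chr1\t999\t2000\tWIND1\t0\t+"))
    expect_equal(GenomicRanges::start(genes)[1], GenomicRanges::start(bed))
})

test_that("peak reading applies the significance filter", {
    df <- data.frame(chrom = "chr1", start = c(0, 100, 200, 300),
                     end = c(50, 150, 250, 350), name = paste0("p", 1:4),
                     score = 0, strand = ".", signal = 1, pval = -1,
                     qval = c(5, 4, 3, 2), peak = -1)
    path <- writePeakFixture(df)
    expect_message(pk <- readPeaks(path, "H3K4me3", 0, 1), "1 peak")
    expect_equal(length(pk), 3L)            # q >= 3 retained
    expect_true(all(pk$neg_log10_q >= 3))
    expect_equal(pk$mark[1], "H3K4me3")

    pk2 <- readPeaks(path, "H3K4me3", 0, 1, minNegLog10Q = 0)
    expect_equal(length(pk2), 4L)

    expect_error(readPeaks(writePeakFixture(df[, 1:5]), "m", 0, 1),
                 "columns")
    dfNeg <- df; dfNeg$start[1] <- -5
    expect_error(readPeaks(writePeakFixture(dfNeg), "m", 0, 1),
                 "coordinates")
})

test_that("analysis windows extend 1 kb upstream, strand-aware, clamped", {
    g <- grWindows(c(5001, 5001, 301), c(7000, 7000, 900),
                   c("plus", "minus", "edge"),
                   strand = c("+", "-", "+"))
    w <- analysisWindow(g)
    expect_equal(GenomicRanges::start(w), c(4001L, 5001L, 1L))
    expect_equal(GenomicRanges::end(w), c(7000L, 8000L, 900L))
    expect_equal(as.character(GenomicRanges::strand(w)),
                 c("+", "-", "+"))
    expect_error(analysisWindow(g, promoterBp = -1), ">= 0")
})

test_that("peaks map to closest windows with ties kept and gaps reported", {
    win <- grWindows(c(4001, 201, 501), c(7000, 300, 600),
                     c("big", "near", "far"))
    pk <- GenomicRanges::GRanges(c("chr1", "chr1", "chr2"),
        IRanges::IRanges(start = c(4501, 1, 1), end = c(4600, 100, 50)))
    a <- assignPeaksToGenes(pk, win)
    expect_equal(a$gene_id[a$peak == 1], "big")
    expect_equal(a$distance_bp[a$peak == 1], 0)
    expect_equal(a$gene_id[a$peak == 2], "near")
    expect_equal(a$distance_bp[a$peak == 2], 100)
    expect_true(is.na(a$gene_id[a$peak == 3]))   # unknown chromosome

    # exact tie: 0-based peak [400,450) between windows [0,300) and [550,900)
    winT <- grWindows(c(1, 551), c(300, 900), c("left", "right"))
    pkT <- GenomicRanges::GRanges("chr1", IRanges::IRanges(401, 450))
    aT <- assignPeaksToGenes(pkT, winT)
    expect_setequal(aT$gene_id, c("left", "right"))
    expect_equal(aT$distance_bp, c(100, 100))
})

test_that("closest assignment agrees with a brute-force scan", {
    set.seed(7)
    for (rep in 1:5) {
        ng <- sample(5:50, 1)
        starts <- sort(sample.int(50000, ng))
        win <- grWindows(starts, starts + sample(100:500, ng, TRUE),
                         paste0("g", seq_len(ng)))
        np <- sample(20:200, 1)
        ps <- sample.int(52000, np)
        pk <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(ps, ps + sample(10:100, np, TRUE)))
        a <- assignPeaksToGenes(pk, win)
        for (i in sample(np, 10)) {
            d <- vapply(seq_len(ng), function(j) gapDistance(
                GenomicRanges::start(pk)[i], GenomicRanges::end(pk)[i],
                GenomicRanges::start(win)[j], GenomicRanges::end(win)[j]),
                0L)
            expect_setequal(a$gene_id[a$peak == i],
                            win$gene_id[d == min(d)])
            expect_equal(unique(a$distance_bp[a$peak == i]), min(d))
        }
    }
})

test_that("a gene is marked only with peaks in both replicates", {
    win <- grWindows(c(1, 1001, 2001), c(500, 1500, 2500),
                     c("A", "B", "C"))
    mk <- function(starts) {
        pk <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(starts, starts + 50))
        assignPeaksToGenes(pk, win)
    }
    r1 <- mk(c(10, 1010))    # hits A, B
    r2 <- mk(c(1010, 2010))  # hits B, C
    expect_identical(markedGenes(r1, r2), "B")
    expect_identical(markedGenes(r1, r2), markedGenes(r2, r1))
    expect_identical(markedGenes(mk(10), mk(1010)), character(0))
    # distance cap: a peak 100 bp away counts only if allowed
    r3 <- mk(601)            # 100 bp from A's window end
    expect_identical(markedGenes(r1, r3), character(0))
    expect_identical(markedGenes(r1, r3, maxDistanceBp = 100), "A")
})
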