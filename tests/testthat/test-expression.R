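# TMM normalization and the NB conditional exact test.

test_that("TMM factors behave on symmetric and depth-only fixtures", {
    set.seed(1)
    base <- rnbinom(200, mu = 100, size = 10) + 1
    eq <- cbind(s1 = base, s2 = base)
    expect_equal(unname(normalizeLibraries(eq)), c(1, 1))

    # pure depth difference: factors stay 1 after library-size division
    dbl <- cbind(s1 = base, s2 = 2L * base)
    f <- normalizeLibraries(dbl)
    expect_equal(unname(f), c(1, 1), tolerance = 1e-10)

    z <- cbind(s1 = base, s2 = 0L * base)
    expect_error(normalizeLibraries(z), "all-zero")
})

test_that("TMM recovers the depth-only oracle on a DE-contaminated fixture", {
    set.seed(2)
    n <- 20
    mu <- rlnorm(n, log(200), 0.3)
    a <- rpois(n, mu)
    b <- rpois(n, mu * 1.4)          # sample B is 1.4x deeper
    b[1:2] <- b[1:2] * 20            # two strongly DE genes
    counts <- cbind(A = a, B = b)
    f <- normalizeLibraries(counts)
    # oracle: effective-size ratio from non-DE genes only, by hand
    ratioOracle <- sum(b[-(1:2)]) / sum(a[-(1:2)])
    effRatio <- (sum(b) * f["B"]) / (sum(a) * f["A"])
    expect_equal(unname(effRatio), ratioOracle, tolerance = 0.02)
})

test_that("TMM factors track the edgeR implementation", {
    set.seed(3)
    counts <- matrix(rnbinom(500 * 6, mu = 80, size = 5), ncol = 6,
                     dimnames = list(NULL, paste0("s", 1:6)))
    counts[1:50, 4:6] <- counts[1:50, 4:6] * 4L
    f <- normalizeLibraries(counts)
    fe <- edgeR::calcNormFactors(counts)
    fe <- fe / exp(mean(log(fe)))
    expect_lt(max(abs(log2(f / fe))), 0.1)
})

test_that("the exact test matches the binomial oracle in the Poisson limit", {
    # equal library sizes so adjusted counts equal raw counts
    set.seed(4)
    base <- rep(50L, 60)
    mk <- function(yA, yB) {
        m <- cbind(r1 = base, r2 = base, r3 = base, r4 = base)
        m[1, ] <- c(floor(yA / 2), ceiling(yA / 2),
                    floor(yB / 2), ceiling(yB / 2))
        m[2, ] <- 0L
        cs <- colSums(m)
        m[2, ] <- max(cs) - cs + 50L     # equalize library sizes exactly
        rownames(m) <- paste0("g", seq_len(nrow(m)))
        m
    }
    meta <- data.frame(time_h = c(0, 0, 3, 3), replicate = c(1, 2, 1, 2))
    for (pair in list(c(10, 10), c(2, 18), c(15, 5))) {
        counts <- mk(pair[1], pair[2])
        stopifnot(length(unique(colSums(counts))) == 1L)
        de <- testDE(counts, 3, factors = rep(1, 4), colData = meta,
                     dispersion = 1e-10)
        oracle <- binom.test(pair[2], sum(pair), 0.5)$p.value
        expect_equal(de$p_value[1], oracle, tolerance = 1e-6)
    }
})

test_that("identical groups give null results and zero genes are flagged", {
    meta <- data.frame(time_h = c(0, 0, 1, 1), replicate = c(1, 2, 1, 2))
    counts <- matrix(rep(c(5L, 9L, 0L), each = 4), ncol = 4, byrow = TRUE,
                     dimnames = list(c("a", "b", "zero"), NULL))
    de <- testDE(counts, 1, factors = rep(1, 4), colData = meta,
                 dispersion = 0.05)
    expect_equal(de$logFC, c(0, 0, 0))
    expect_equal(de$p_value, c(1, 1, 1))
    expect_identical(de$untestable, c(FALSE, FALSE, TRUE))
})

test_that("fold-change sign matches group means and BH is monotone", {
    set.seed(5)
    meta <- data.frame(time_h = rep(c(0, 6), each = 3),
                       replicate = rep(1:3, 2))
    counts <- matrix(rnbinom(300 * 6, mu = 60, size = 8), ncol = 6)
    rownames(counts) <- paste0("g", 1:300)
    de <- testDE(counts, 6, colData = meta)
    eff <- colSums(counts) * normalizeLibraries(counts)
    norm <- sweep(counts, 2, median(eff) / eff, `*`)
    diff <- rowMeans(norm[, 4:6]) - rowMeans(norm[, 1:3])
    expect_true(all(sign(de$logFC[diff != 0]) == sign(diff[diff != 0])))
    ord <- order(de$p_value)
    expect_true(all(diff(de$fdr[ord]) >= -1e-12))
})

test_that("p-values are invariant to doubling one sample's counts", {
    set.seed(6)
    meta <- data.frame(time_h = rep(c(0, 1, 3, 6, 12), each = 3),
                       replicate = rep(1:3, 5))
    counts <- matrix(rnbinom(200 * 15, mu = 100, size = 10), ncol = 15)
    rownames(counts) <- paste0("g", 1:200)
    colnames(counts) <- sprintf("t%g_r%d", meta$time_h, meta$replicate)
    de1 <- testDE(counts, 3, colData = meta)
    counts2 <- counts
    jmax <- which.max(colSums(counts))   # stays above the median effective
    counts2[, jmax] <- 2L * counts2[, jmax]  # size, so scaling is untouched
    de2 <- testDE(counts2, 3, colData = meta)
    expect_lt(max(abs(de1$p_value - de2$p_value)), 1e-6)
})

test_that("type-I error is controlled in a moderate null simulation", {
    set.seed(7)
    n <- 600
    meta <- data.frame(time_h = rep(c(0, 3), each = 3),
                       replicate = rep(1:3, 2))
    mu <- rlnorm(n, log(100), 0.5)
    counts <- sapply(1:6, function(j) rnbinom(n, mu = mu, size = 10))
    rownames(counts) <- paste0("g", 1:n)
    de <- testDE(counts, 3, colData = meta)
    expect_gt(mean(de$p_value < 0.05), 0.02)
    expect_lt(mean(de$p_value < 0.05), 0.085)
})

test_that("wound-responsive calls apply both thresholds at any time", {
    de <- data.frame(
        gene_id = rep(c("a", "b", "c", "d", "e"), each = 2),
        time_h = rep(c(1, 3), 5),
        logFC = c(log2(1.4), log2(1.4),      # a: fold below cut
                  log2(2.0), 0,              # b: induced at 1 h
                  0, -log2(1.6),             # c: repressed at 3 h
                  log2(1.8), log2(1.8),      # d: fails FDR
                  log2(1.7), -log2(1.7)),    # e: both directions
        fdr = c(1e-9, 1e-9, 1e-4, 1, 1, 1e-5, 0.5, 0.01, 1e-4, 1e-4),
        untestable = FALSE)
    expect_warning(r <- callWoundResponsive(de), "both")
    expect_setequal(r$induced, c("b", "e"))
    expect_setequal(r$repressed, c("c", "e"))
    expect_identical(r$both, "e")
})
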