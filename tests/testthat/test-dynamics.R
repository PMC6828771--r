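# Timing-integration analyses and the reporting convention.

test_that("rank-LOESS handles degenerate, monotone and transformed input", {
    genes <- paste0("g", 1:60)
    lv <- setNames(seq(0.1, 6, length.out = 60), genes)

    flat <- setNames(rep(3L, 60), genes)
    rF <- rankLoessTiming(lv, flat)
    expect_true(rF$flat)
    expect_equal(rF$rho, 0)
    expect_lt(max(abs(rF$curve$smoothed - 3)), 1e-8)

    dec <- setNames(rev(seq_len(60)), genes)
    rD <- rankLoessTiming(lv, dec)
    expect_equal(rD$rho, -1)
    expect_true(all(diff(rD$curve$smoothed) <= 1e-8))

    # monotone transform of the levels leaves the curve unchanged
    rT <- rankLoessTiming(lv^3, dec)
    expect_equal(rT$curve$smoothed, rD$curve$smoothed)

    expect_error(rankLoessTiming(lv, dec, span = 0), "span")
})

test_that("timing PCA standardizes, drops constants and fixes the sign", {
    set.seed(15)
    n <- 2000
    x <- rnorm(n)
    perf <- cbind(m1 = x, m2 = 2 * x + 5)
    rownames(perf) <- paste0("g", 1:n)
    lab <- setNames(sample(1:8, n, TRUE), rownames(perf))
    er <- setNames(sample(n), rownames(perf))
    expect_warning(
        p1 <- timingPCA(cbind(perf, const = 1), lab, er), "constant")

    p2 <- timingPCA(perf[, 1, drop = FALSE] + 0 * perf[, 2],
                    lab, er)  # independent variables: ~equal shares
    expect_lt(max(p2$varExplained), 0.55)
    expect_gt(min(p2$varExplained), 0.28)
    expect_gte(p2$loadings[1, 1], 0)

    # two perfectly correlated variables alone: PC1 carries everything
    pr <- prcomp(cbind(rank(perf[, 1]), rank(perf[, 2])), scale. = TRUE)
    expect_equal(pr$sdev[1]^2 / sum(pr$sdev^2), 1, tolerance = 1e-6)
})

test_that("acetylation categories follow the rule table", {
    genes <- paste0("g", 1:6)
    marked <- matrix(FALSE, 6, 2,
                     dimnames = list(genes, c("H3K9K14ac", "H3K4me3")))
    marked[c(1, 2), "H3K9K14ac"] <- TRUE
    lev <- array(1, c(6, 2, 1),
                 dimnames = list(genes, colnames(marked), "0"))
    st <- new("MarkStateTable", genes = genes,
              marks = colnames(marked), times = 0, marked = marked,
              levels = lev, markedTime = 0)
    changes <- rbind(
        data.frame(gene_id = genes, mark = "H3K9K14ac",
                   first_gain_time = c(Inf, 1, 1, Inf, 12, Inf),
                   first_loss_time = Inf, any_gain = FALSE,
                   any_loss = FALSE),
        data.frame(gene_id = genes, mark = "H3K4me3",
                   first_gain_time = c(Inf, Inf, 3, 3, Inf, Inf),
                   first_loss_time = Inf, any_gain = FALSE,
                   any_loss = FALSE))
    ac <- classifyAcCategory(st, changes)
    expect_identical(ac$category,
        c("preac_no_gain",     # marked, never gains
          "preac_plus_gain",   # marked, gains at 1 h
          "gain_only",         # unmarked, gains at 1 h (RAP2.6-type)
          "no_ac",             # unmarked, me3 gain only
          "no_ac",             # gain at 12 h is beyond the 6 h window
          "no_ac"))
    expect_identical(ac$me3_gain, c(FALSE, FALSE, TRUE, TRUE, FALSE,
                                    FALSE))
    expect_error(classifyAcCategory(st, changes, genes = "missing"),
                 "missing")
})

test_that("precedence categories partition genes with the tie rule", {
    changes <- rbind(
        data.frame(gene_id = paste0("g", 1:5), mark = "H3K9K14ac",
                   first_gain_time = c(1, 3, 3, Inf, Inf),
                   first_loss_time = Inf, any_gain = TRUE,
                   any_loss = FALSE),
        data.frame(gene_id = paste0("g", 1:5), mark = "H3K4me3",
                   first_gain_time = c(3, 1, 3, 6, Inf),
                   first_loss_time = Inf, any_gain = TRUE,
                   any_loss = FALSE))
    pr <- precedenceCounts(changes)
    expect_identical(pr$calls$category,
                     c("ac_first", "me3_first", "simultaneous",
                       "only_me3", "neither"))
    expect_equal(sum(pr$counts), 5L)
    expect_equal(unname(pr$countsInclusive["ac_first"]), 1L)
    expect_equal(unname(pr$countsInclusive["me3_first"]), 2L)
})

test_that("temporal profiles aggregate means with SD and warn on gaps", {
    lev <- array(seq_len(12), c(2, 2, 3),
                 dimnames = list(c("g1", "g2"), c("m1", "m2"),
                                 c(0, 1, 3)))
    groups <- setNames(c("solo", "solo"), c("g1", "g2"))
    pr <- temporalProfiles(lev, groups)
    expect_equal(nrow(pr$marks), 6L)
    one <- temporalProfiles(lev, setNames("alone", "g1"))
    expect_true(all(one$marks$sd == 0))
    expect_equal(one$marks$mean[one$marks$mark == "m1" &
                                one$marks$time_h == 0], 1)
    expect_warning(temporalProfiles(lev, setNames("ghost", "gX")),
                   "empty group")
})

test_that("marking/expression correlation matches closed cases", {
    set.seed(16)
    n <- 2000
    x <- rnorm(n)
    marking <- data.frame(gene_id = paste0("g", 1:n), mark = "ac",
                          time_h = 1, M = x, A = 0, M_rescaled = x,
                          call = "none")
    de <- data.frame(gene_id = paste0("g", 1:n), time_h = 1,
                     logFC = 2 * x, p_value = 1, fdr = 1,
                     untestable = FALSE)
    r <- markingExpressionCorrelation(marking, de)
    expect_equal(r$r, 1)

    de$logFC <- rnorm(n)   # independent: |r| small
    r2 <- markingExpressionCorrelation(marking, de)
    expect_lt(abs(r2$r), 0.05)

    marking$M_rescaled <- 0
    expect_warning(r3 <- markingExpressionCorrelation(marking, de),
                   "zero variance")
    expect_true(is.na(r3$r))
})

test_that("reported fractions reproduce the printed rounding convention", {
    expect_identical(as.character(reportFraction(961, 5777)), "17%")
    expect_identical(as.character(reportFraction(1436, 5777)), "25%")
    expect_identical(as.character(reportFraction(416, 1436)), "29%")
    expect_identical(as.character(reportFraction(545, 4341)), "13%")
    expect_identical(as.character(reportFraction(1639, 3665)), "45%")
    expect_identical(as.character(reportFraction(116, 3665)), "3.2%")
    expect_identical(as.character(reportFraction(80, 3665)), "2.2%")
    expect_identical(as.character(reportFraction(2791, 3665)), "76%")
    expect_identical(as.character(reportFraction(0, 7)), "0.0%")
    expect_error(reportFraction(1, 0), "denominator")
    expect_error(reportFraction(5, 3), "<=")
})
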