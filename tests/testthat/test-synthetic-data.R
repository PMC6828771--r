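# The planted-truth generator: determinism, class schedules and the
# closed-form expectations of its noise models.

test_that("config validity catches bad parameters", {
    expect_error(woundSimConfig(classProportions = c(
        rapid_preacetylated = 0.5, slow_gain_ac_then_me3 = 0.15,
        prc2_bivalent_induced = 0.05, prc2_only_silent = 0.15,
        repressed_lose_ac = 0.15, stable = 0.40)), "sum")
    expect_error(woundSimConfig(nbDispersion = 0), "nbDispersion")
    expect_error(woundSimConfig(peakDropoutProb = 1.5), "peakDropoutProb")
})

test_that("planted truth is deterministic and honours class schedules", {
    cfg <- woundSimConfig(nGenes = 300, seed = 5)
    t1 <- plantTruth(cfg)
    t2 <- plantTruth(cfg)
    expect_identical(t1$truth, t2$truth)
    expect_identical(as.data.frame(t1$genes), as.data.frame(t2$genes))

    tr <- t1$truth
    expect_equal(nrow(tr), 300L)
    # genes tile one chromosome without overlap
    expect_true(all(diff(GenomicRanges::start(t1$genes)) > 0))
    expect_equal(length(GenomicRanges::reduce(t1$genes)), 300L)

    # slow-gain class: acetylation gain strictly before H3K4me3 gain
    sg <- tr[tr$class == "slow_gain_ac_then_me3", ]
    expect_gt(nrow(sg), 0)
    expect_true(all(sg$gain_H3K4me3 > sg$gain_H3K9K14ac))

    # silent PRC2 targets never induced, only H3K27me3-marked
    sil <- tr[tr$class == "prc2_only_silent", ]
    expect_true(all(!is.finite(sil$t_star)))
    expect_true(all(sil$pre_H3K27me3) && all(!sil$pre_H3K9K14ac))

    # degenerate config: everything stable
    cfgS <- woundSimConfig(nGenes = 50, seed = 1, classProportions = c(
        rapid_preacetylated = 0, slow_gain_ac_then_me3 = 0,
        prc2_bivalent_induced = 0, prc2_only_silent = 0,
        repressed_lose_ac = 0, stable = 1))
    trS <- plantTruth(cfgS)$truth
    expect_true(all(!is.finite(trS$t_star)))
    expect_true(all(is.na(as.matrix(
        trS[, grep("^gain_", names(trS))]))))
})

test_that("expression counts reproduce planted folds and dispersion", {
    cfg <- woundSimConfig(nGenes = 400, seed = 9)
    pt <- plantTruth(cfg)
    se <- simulateExpression(pt$truth, cfg)
    counts <- SummarizedExperiment::assay(se)
    meta <- as.data.frame(SummarizedExperiment::colData(se))
    tr <- pt$truth

    # stable genes: group means constant up to NB noise
    stab <- tr$gene_id[tr$class == "stable"]
    m0 <- rowMeans(counts[stab, meta$time_h == 0])
    m12 <- rowMeans(counts[stab, meta$time_h == 12])
    expect_lt(abs(mean(log2((m12 + 0.5) / (m0 + 0.5)))), 0.15)

    # planted fold recovered by the sample mean ratio (forced fold 4)
    trF <- tr
    idx <- which(trF$class == "stable")[1:150]
    trF$direction[idx] <- "up"; trF$t_star[idx] <- 1
    trF$fold[idx] <- 4; trF$transient[idx] <- FALSE
    seF <- simulateExpression(trF, cfg)
    cF <- SummarizedExperiment::assay(seF)
    ratio <- mean(cF[idx, meta$time_h == 1]) / mean(cF[idx, meta$time_h == 0])
    expect_gt(ratio, 3.2); expect_lt(ratio, 4.8)

    # phi -> 0 limit: counts concentrate on mu * L
    cfg0 <- woundSimConfig(nGenes = 200, seed = 9, nbDispersion = 1e-6)
    pt0 <- plantTruth(cfg0)
    c0 <- SummarizedExperiment::assay(simulateExpression(pt0$truth, cfg0))
    cv <- apply(c0[, 1:3], 1, sd) / rowMeans(c0[, 1:3])
    expect_lt(median(cv, na.rm = TRUE), 0.25)  # library noise only

    # method-of-moments dispersion sanity at defaults
    grp <- split(seq_len(ncol(counts)), meta$time_h)
    num <- den <- 0
    for (cols in grp) {
        mm <- rowMeans(counts[, cols]); vv <- apply(counts[, cols], 1, var)
        num <- num + sum(vv - mm); den <- den + sum(mm^2)
    }
    phiHat <- num / den
    expect_gt(phiHat, 0.05); expect_lt(phiHat, 0.2)
})

test_that("ChIP ratios, peak emission and replicate dropout match design", {
    cfg <- woundSimConfig(nGenes = 600, seed = 13)
    pt <- plantTruth(cfg)
    chip <- simulateChip(pt$truth, pt$genes, cfg)
    lev <- enrichmentLevels(chip$coverage)
    tr <- pt$truth

    marked <- tr$gene_id[tr$pre_H3K9K14ac]
    unmarked <- tr$gene_id[!tr$pre_H3K9K14ac]
    expect_lt(abs(mean(lev[unmarked, "H3K9K14ac", "0"]) - 0.4), 0.05)
    expect_lt(abs(mean(lev[marked, "H3K9K14ac", "0"]) - 2.5), 0.2)
    # stochastic ordering of marked vs unmarked levels
    p <- wilcox.test(lev[marked, "H3K9K14ac", "0"],
                     lev[unmarked, "H3K9K14ac", "0"],
                     alternative = "greater")$p.value
    expect_lt(p, 1e-10)

    # slow-gain schedule: ac ratio steps before me3 ratio
    sg <- tr$gene_id[tr$class == "slow_gain_ac_then_me3" &
                     tr$t_star == 3]
    expect_gt(mean(lev[sg, "H3K9K14ac", "1"] / lev[sg, "H3K9K14ac", "0"]),
              1.7)
    expect_lt(mean(lev[sg, "H3K4me3", "1"] / lev[sg, "H3K4me3", "0"]),
              1.2)
    expect_gt(mean(lev[sg, "H3K4me3", "3"] / lev[sg, "H3K4me3", "0"]),
              1.7)

    # replicate-consistent peak fraction ~ (1 - dropout)^2
    cfgD <- woundSimConfig(nGenes = 2000, seed = 13,
                           peakDropoutProb = 0.5, classProportions = c(
        rapid_preacetylated = 0, slow_gain_ac_then_me3 = 0,
        prc2_bivalent_induced = 0, prc2_only_silent = 0,
        repressed_lose_ac = 0, stable = 1))
    ptD <- plantTruth(cfgD)
    chipD <- simulateChip(ptD$truth, ptD$genes, cfgD)
    markedD <- ptD$truth$gene_id[ptD$truth$pre_H3K9K14ac]
    mm <- markedAtTime(chipD$peaks, ptD$genes, 0)
    frac <- mean(mm[markedD, "H3K9K14ac"])
    expect_gt(frac, 0.20); expect_lt(frac, 0.30)
})

test_that("the written dataset is byte-identical across runs", {
    cfg <- woundSimConfig(nGenes = 120, seed = 3)
    d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
    unlink(c(d1, d2), recursive = TRUE)
    s1 <- simulateWoundDataset(cfg, d1)
    s2 <- simulateWoundDataset(cfg, d2)
    f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
    expect_identical(f1, f2)
    md1 <- tools::md5sum(file.path(d1, f1))
    md2 <- tools::md5sum(file.path(d2, f2))
    expect_identical(unname(md1), unname(md2))
})
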