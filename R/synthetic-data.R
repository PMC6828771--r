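## Planted-truth simulator: six gene classes with known pre-wound chromatin
## states, induction/repression times, and mark gain/loss schedules, so every
## downstream statistic can be checked against ground truth.

.bern <- function(n, p) stats::runif(n) < p

#' Plant the ground truth for a synthetic wound time course
#'
#' Draws a gene class for every gene and derives its planted transcriptional
#' response (direction, onset time, fold) and chromatin schedule (pre-wound
#' mark states, mark gain/loss times). Genes are tiled without overlap on one
#' pseudo-chromosome (alternating strands). Deterministic given the config
#' seed.
#'
#' The six classes: \code{rapid_preacetylated} (pre-acetylated, induced at
#' 1 h), \code{slow_gain_ac_then_me3} (unmarked, gains H3K9/14ac one sampling
#' step before H3K4me3, induced at 3 or 6 h), \code{prc2_bivalent_induced}
#' (H3K27me3 + H3K4me3 co-marked, induced late), \code{prc2_only_silent}
#' (H3K27me3 only, never induced), \code{repressed_lose_ac} (active marks,
#' repressed, loses acetylation) and \code{stable}.
#'
#' @param config A \code{\link{woundSimConfig}}.
#' @param bodyBp,gapBp Gene body length and intergenic gap (bp).
#' @return list with \code{truth} (data.frame, one row per gene) and
#'   \code{genes} (\code{GRanges} gene models).
#' @export
plantTruth <- function(config, bodyBp = 3000, gapBp = 2000) {
    stopifnot(is(config, "WoundSimConfig"))
    validObject(config)
    set.seed(config@seed)
    n <- config@nGenes
    marks <- woundMarks()

    cnt <- round(n * config@classProportions)
    cnt["stable"] <- cnt["stable"] + (n - sum(cnt))
    if (cnt["stable"] < 0) stop("class proportions leave no room for 'stable'")
    cls <- sample(rep(names(cnt), times = cnt))

    ids <- sprintf("G%05d", seq_len(n))
    start0 <- gapBp + (seq_len(n) - 1) * (bodyBp + gapBp)
    genes <- GenomicRanges::GRanges(
        "chrS1", IRanges::IRanges(start = start0 + 1, end = start0 + bodyBp),
        strand = ifelse(seq_len(n) %% 2 == 1, "+", "-"))
    genes$gene_id <- ids
    names(genes) <- ids

    tr <- data.frame(gene_id = ids, class = cls, direction = "none",
                     t_star = Inf, fold = 1, transient = FALSE,
                     stringsAsFactors = FALSE)
    for (m in marks) {
        tr[[paste0("pre_", m)]] <- FALSE
        tr[[paste0("gain_", m)]] <- NA_real_
        tr[[paste0("loss_", m)]] <- NA_real_
    }
    lfold <- function(k, lo, hi) exp(stats::runif(k, log(lo), log(hi)))

    i <- which(cls == "rapid_preacetylated"); k <- length(i)
    if (k) {
        tr$direction[i] <- "up"; tr$t_star[i] <- 1
        tr$fold[i] <- lfold(k, 4, 8); tr$transient[i] <- TRUE
        tr$pre_H3K9K14ac[i] <- TRUE; tr$pre_H3K27ac[i] <- TRUE
        tr$pre_H3K4me3[i] <- TRUE; tr$pre_H3K36me3[i] <- .bern(k, 0.5)
        extra <- i[.bern(k, 0.3)]   # pre-acetylated genes that also gain
        tr$gain_H3K9K14ac[extra] <- 1
        tr$gain_H3K27ac[extra[.bern(length(extra), 0.5)]] <- 1
    }

    i <- which(cls == "slow_gain_ac_then_me3"); k <- length(i)
    if (k) {
        ts <- sample(c(3, 6), k, replace = TRUE)
        tr$direction[i] <- "up"; tr$t_star[i] <- ts
        tr$fold[i] <- lfold(k, 3, 8)
        tr$pre_H3K36me3[i] <- .bern(k, 0.5)
        tr$gain_H3K9K14ac[i] <- ifelse(ts == 3, 1, 3)  # ac one step early
        tr$gain_H3K4me3[i] <- ts
        j <- i[.bern(k, 0.5)]
        tr$gain_H3K27ac[j] <- tr$gain_H3K9K14ac[j]
    }

    i <- which(cls == "prc2_bivalent_induced"); k <- length(i)
    if (k) {
        ts <- sample(c(6, 12), k, replace = TRUE)
        tr$direction[i] <- "up"; tr$t_star[i] <- ts
        tr$fold[i] <- lfold(k, 3, 6)
        tr$pre_H3K27me3[i] <- TRUE; tr$pre_H3K4me3[i] <- TRUE
        tr$pre_H3K36me3[i] <- .bern(k, 0.5)
        tr$gain_H3K9K14ac[i] <- ifelse(ts == 6, 3, 6)
        j <- i[.bern(k, 0.5)]
        tr$loss_H3K27me3[j] <- tr$gain_H3K9K14ac[j]
    }

    i <- which(cls == "prc2_only_silent")
    tr$pre_H3K27me3[i] <- TRUE

    i <- which(cls == "repressed_lose_ac"); k <- length(i)
    if (k) {
        on <- sample(c(1, 3), k, replace = TRUE)
        tr$direction[i] <- "down"; tr$t_star[i] <- on
        tr$fold[i] <- 1 / lfold(k, 3, 6)
        tr$pre_H3K9K14ac[i] <- TRUE; tr$pre_H3K27ac[i] <- TRUE
        tr$pre_H3K4me3[i] <- TRUE; tr$pre_H3K36me3[i] <- TRUE
        tr$loss_H3K9K14ac[i] <- on
        j <- i[.bern(k, 0.5)]; tr$loss_H3K27ac[j] <- on[match(j, i)]
        j <- i[.bern(k, 0.5)]
        tr$loss_H3K4me3[j] <- ifelse(on[match(j, i)] == 1, 3, 6)
    }

    i <- which(cls == "stable"); k <- length(i)
    if (k) {
        act <- i[.bern(k, 0.5)]
        tr$pre_H3K9K14ac[act] <- TRUE; tr$pre_H3K27ac[act] <- TRUE
        tr$pre_H3K4me3[act] <- TRUE; tr$pre_H3K36me3[act] <- TRUE
    }
    list(truth = tr, genes = genes)
}

## planted expression trajectory multiplier at time t
.trajectory <- function(truth, times) {
    n <- nrow(truth)
    f <- matrix(1, n, length(times), dimnames = list(truth$gene_id, times))
    for (j in seq_along(times)) {
        t <- times[j]
        on <- is.finite(truth$t_star) & t >= truth$t_star
        f[on, j] <- truth$fold[on]
        # transient induction decays two sampling steps after onset
        tra <- on & truth$transient & truth$direction == "up"
        stepsPast <- vapply(which(tra), function(i) {
            sum(times > truth$t_star[i] & times <= t)
        }, 0)
        decay <- c(1, 1, 0.5, 0.25, 0.25)[pmin(stepsPast, 4) + 1]
        f[tra, j] <- truth$fold[tra]^decay
    }
    f
}

#' Simulate the RNA-seq count matrix
#'
#' Counts are negative-binomial with mean \eqn{\mu_g f_g(t) L_r}: a
#' log-normal per-gene baseline around a class-specific centre, the planted
#' class trajectory (step to the planted fold at the onset time; transient
#' rapid genes decay back), and log-normal library factors (sd 0.1).
#'
#' @param truth Output of \code{\link{plantTruth}} (the \code{truth} element
#'   or the whole list).
#' @param config The same \code{\link{woundSimConfig}}.
#' @param inhibitor If \code{TRUE}, emulate a histone-acetyltransferase
#'   inhibitor arm: planted induction folds of acetylation-dependent classes
#'   are damped to 25\% of their excess over baseline.
#' @return \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{counts} assay and colData \code{time_h}, \code{replicate}.
#' @export
simulateExpression <- function(truth, config, inhibitor = FALSE) {
    if (is.list(truth) && !is.data.frame(truth)) truth <- truth$truth
    if (config@nbDispersion <= 0) stop("nbDispersion must be > 0")
    set.seed(config@seed + 1L + if (inhibitor) 97L else 0L)
    times <- config@rnaTimes
    nr <- config@nRnaReps
    n <- nrow(truth)

    centre <- c(rapid_preacetylated = 50, slow_gain_ac_then_me3 = 30,
                prc2_bivalent_induced = 10, prc2_only_silent = 5,
                repressed_lose_ac = 150, stable = 100)
    mu <- stats::rlnorm(n, meanlog = log(centre[truth$class]),
                        sdlog = config@baselineMeanLogSd)

    tr <- truth
    if (inhibitor) {
        dep <- tr$class %in% c("rapid_preacetylated", "slow_gain_ac_then_me3",
                               "prc2_bivalent_induced")
        tr$fold[dep] <- 1 + (tr$fold[dep] - 1) * 0.25
    }
    f <- .trajectory(tr, times)

    samples <- expand.grid(replicate = seq_len(nr), time_h = times)[, 2:1]
    L <- exp(stats::rnorm(nrow(samples), 0, 0.1))
    counts <- matrix(0L, n, nrow(samples),
                     dimnames = list(truth$gene_id,
                         sprintf("t%g_r%d", samples$time_h,
                                 samples$replicate)))
    for (j in seq_len(nrow(samples))) {
        m <- mu * f[, as.character(samples$time_h[j])] * L[j]
        counts[, j] <- stats::rnbinom(n, mu = m,
                                      size = 1 / config@nbDispersion)
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(samples, row.names = colnames(counts)))
}

## mark/H3 ratio for every gene at time t, honouring planted gains/losses
.markRatio <- function(truth, mark, t, config, inhibitor = FALSE) {
    pre <- truth[[paste0("pre_", mark)]]
    g <- truth[[paste0("gain_", mark)]]
    l <- truth[[paste0("loss_", mark)]]
    if (inhibitor && mark %in% c("H3K9K14ac", "H3K27ac"))
        g[] <- NA_real_                       # inhibitor blocks ac gains
    rM <- config@markRatioMarked
    rU <- config@markRatioUnmarked
    r <- ifelse(pre, rM, rU)
    gained <- !is.na(g) & t >= g
    lost <- pre & !is.na(l) & t >= l
    r[gained & !pre] <- rU * config@gainFold
    r[gained & pre] <- rM * config@gainFold   # pre-marked genes that gain
    r[lost] <- rM / config@gainFold
    if (inhibitor && mark %in% c("H3K9K14ac", "H3K27ac"))
        r[pre] <- r[pre] * 0.6                # global acetylation damping
    present <- (pre & !lost) | gained
    list(ratio = r, present = present)
}

#' Simulate ChIP-seq coverage and peak calls
#'
#' Histone H3 depth per (gene, time, replicate) is Gamma(shape 20, mean 30);
#' each mark's depth is the same H3 depth times the planted mark/H3 ratio
#' times multiplicative log-normal noise. Where a mark is present a peak
#' interval overlapping the gene's analysis window is emitted per replicate
#' with probability 1 - \code{peakDropoutProb} and a q-value above the
#' significance filter; sub-threshold decoy peaks and distal intergenic
#' peaks are added so the filtering and distance logic is exercised.
#'
#' @inheritParams simulateExpression
#' @param genes \code{GRanges} from \code{\link{plantTruth}}.
#' @return list: \code{coverage} (long data.frame gene_id, track, time_h,
#'   replicate, mean_depth; track is a mark or \code{"H3"}) and \code{peaks}
#'   (named list \code{mark -> time -> replicate} of \code{GRanges}).
#' @export
simulateChip <- function(truth, genes, config, inhibitor = FALSE) {
    if (is.list(truth) && !is.data.frame(truth)) {
        genes <- truth$genes; truth <- truth$truth
    }
    set.seed(config@seed + 2L + if (inhibitor) 97L else 0L)
    times <- config@chipTimes
    reps <- seq_len(config@nChipReps)
    marks <- woundMarks()
    n <- nrow(truth)
    body0 <- GenomicRanges::start(genes) - 1L   # 0-based body start

    cov <- vector("list", length(times) * length(reps))
    peaks <- stats::setNames(
        lapply(marks, function(m) stats::setNames(
            lapply(times, function(t) list()), paste0("t", times))), marks)
    ci <- 0L
    for (t in times) {
        ratios <- lapply(marks, function(m)
            .markRatio(truth, m, t, config, inhibitor))
        names(ratios) <- marks
        for (r in reps) {
            h3 <- stats::rgamma(n, shape = 20, scale = 30 / 20)
            rows <- data.frame(gene_id = truth$gene_id, track = "H3",
                               time_h = t, replicate = r, mean_depth = h3)
            for (m in marks) {
                noise <- exp(stats::rnorm(n, 0, config@noiseSdLog))
                depth <- h3 * ratios[[m]]$ratio * noise
                rows <- rbind(rows, data.frame(
                    gene_id = truth$gene_id, track = m, time_h = t,
                    replicate = r, mean_depth = depth))
                emit <- ratios[[m]]$present &
                    !.bern(n, config@peakDropoutProb)
                idx <- which(emit)
                nd <- max(1L, round(0.03 * n))    # sub-threshold decoys
                di <- sample.int(n, nd)
                ndist <- max(1L, round(0.01 * n)) # distal, above threshold
                cand <- which(seq_len(n) %% 2 == 1 & seq_len(n) < n)
                if (!length(cand)) cand <- 1L
                si <- cand[sample.int(length(cand), ndist,
                                      replace = ndist > length(cand))]
                pk <- GenomicRanges::GRanges("chrS1", IRanges::IRanges(
                    start = c(body0[idx] + 501, body0[di] - 1800,
                              body0[si] + 3000 + 901),
                    end = c(body0[idx] + 2500, body0[di] - 1401,
                            body0[si] + 3000 + 1100)))
                pk$name <- sprintf("%s_t%g_r%d_p%d", m, t, r,
                                   seq_along(pk))
                pk$mark <- m; pk$time_h <- t; pk$replicate <- r
                pk$neg_log10_q <- c(stats::runif(length(idx), 5, 50),
                                    stats::runif(nd, 0.5, 2.9),
                                    stats::runif(ndist, 4, 8))
                peaks[[m]][[paste0("t", t)]][[r]] <- pk
            }
            ci <- ci + 1L
            cov[[ci]] <- rows
        }
    }
    list(coverage = do.call(rbind, cov), peaks = peaks)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits \code{genes.bed}, \code{counts.tsv}, \code{coverage.tsv},
#' \code{truth.tsv}, one \code{peaks_<mark>_t<time>_rep<k>.narrowPeak} per
#' track, \code{config.yaml} and a \code{manifest.json} with the seed and
#' md5 checksums. Byte-identical across runs with the same config.
#'
#' @inheritParams simulateExpression
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (\code{truth},
#'   \code{genes}, \code{se}, \code{coverage}, \code{peaks}) and the
#'   \code{manifest}.
#' @export
simulateWoundDataset <- function(config, dir, inhibitor = FALSE) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pt <- plantTruth(config)
    se <- simulateExpression(pt$truth, config, inhibitor)
    chip <- simulateChip(pt$truth, pt$genes, config, inhibitor)

    writeGeneModels(pt$genes, file.path(dir, "genes.bed"))
    counts <- SummarizedExperiment::assay(se, "counts")
    utils::write.table(
        data.frame(gene_id = rownames(counts), counts, check.names = FALSE),
        file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    utils::write.table(chip$coverage, file.path(dir, "coverage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pt$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (m in names(chip$peaks)) for (tn in names(chip$peaks[[m]])) {
        for (r in seq_along(chip$peaks[[m]][[tn]])) {
            pk <- chip$peaks[[m]][[tn]][[r]]
            df <- data.frame(
                chrom = as.character(GenomicRanges::seqnames(pk)),
                start = GenomicRanges::start(pk) - 1L,
                end = GenomicRanges::end(pk), name = pk$name, score = 0L,
                strand = ".", signalValue = 0,
                pValue = -1, qValue = sprintf("%.6g", pk$neg_log10_q),
                peak = -1L)
            utils::write.table(df, file.path(dir, sprintf(
                "peaks_%s_%s_rep%d.narrowPeak", m, tn, r)), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
        }
    }
    yaml::write_yaml(.configAsList(config), file.path(dir, "config.yaml"))
    files <- sort(setdiff(list.files(dir), "manifest.json"))
    manifest <- list(seed = config@seed, n_genes = config@nGenes,
                     inhibitor = inhibitor,
                     checksums = as.list(tools::md5sum(
                         file.path(dir, files))))
    names(manifest$checksums) <- files
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(c(pt, list(se = se, coverage = chip$coverage,
                         peaks = chip$peaks, manifest = manifest)))
}

.configAsList <- function(config) {
    list(n_genes = config@nGenes, rna_times = config@rnaTimes,
         chip_times = config@chipTimes, n_rna_reps = config@nRnaReps,
         n_chip_reps = config@nChipReps,
         class_proportions = as.list(config@classProportions),
         nb_dispersion = config@nbDispersion,
         baseline_mean_log_sd = config@baselineMeanLogSd,
         mark_ratio_marked = config@markRatioMarked,
         mark_ratio_unmarked = config@markRatioUnmarked,
         gain_fold = config@gainFold,
         peak_dropout_prob = config@peakDropoutProb,
         noise_sd_log = config@noiseSdLog, seed = config@seed)
}

#' Read a counts.tsv written by \code{\link{simulateWoundDataset}}
#'
#' @param path Path to the TSV (first column gene_id, then one column per
#'   sample named \code{t<time>_r<rep>}).
#' @return \code{SummarizedExperiment} with a counts assay.
#' @export
readCounts <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- tab[[1]]
    m <- regmatches(colnames(counts),
                    regexec("^t([0-9.]+)_r([0-9]+)$", colnames(counts)))
    if (any(lengths(m) != 3L))
        stop("sample columns must be named t<time>_r<rep>")
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(
            time_h = as.numeric(vapply(m, `[`, "", 2L)),
            replicate = as.integer(vapply(m, `[`, "", 3L)),
            row.names = colnames(counts)))
}

#' Read a coverage.tsv (gene_id, track, time_h, replicate, mean_depth)
#'
#' @param path Path to the TSV.
#' @return data.frame in the long coverage format.
#' @export
readCoverage <- function(path) {
    cov <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("gene_id", "track", "time_h", "replicate", "mean_depth")
    if (!all(need %in% names(cov)))
        stop("coverage table must have columns: ",
             paste(need, collapse = ", "))
    if (any(!is.finite(cov$mean_depth)) || any(cov$mean_depth < 0))
        stop("coverage depths must be finite and >= 0")
    cov
}
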