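## Wound-responsive gene detection: trimmed-mean-of-M-values library
## normalization and a conditional negative-binomial exact test of each
## post-wounding time point against 0 h.

.countsAndMeta <- function(x, colData = NULL) {
    if (is(x, "SummarizedExperiment")) {
        counts <- SummarizedExperiment::assay(x, "counts")
        meta <- as.data.frame(SummarizedExperiment::colData(x))
    } else {
        counts <- as.matrix(x)
        if (is.null(colData))
            stop("colData (time_h, replicate) required for a bare matrix")
        meta <- as.data.frame(colData)
    }
    if (any(counts < 0)) stop("negative counts")
    if (!"time_h" %in% names(meta)) stop("colData must contain time_h")
    list(counts = counts, meta = meta)
}

#' TMM library-scaling factors
#'
#' Trimmed mean of M-values between each sample and a reference (the sample
#' whose 75th-percentile count fraction is closest to the mean across
#' samples): genes with zero counts in either sample are excluded, the
#' 30\% most extreme M values in each tail (keeping the central 40\%) and
#' 5\% of A values in each tail are trimmed, and the remaining M values
#' are averaged. The mean is unweighted, which makes the factors exactly
#' invariant to rescaling any one library.
#' Factors are normalized to geometric mean 1; effective library size =
#' library size x factor.
#'
#' @param x Count matrix (genes x samples) or \code{SummarizedExperiment}.
#' @return Named numeric vector of scaling factors (geometric mean 1).
#' @export
normalizeLibraries <- function(x) {
    counts <- if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts") else as.matrix(x)
    if (ncol(counts) < 2L) stop("need >= 2 samples")
    lib <- colSums(counts)
    if (any(lib == 0))
        stop("all-zero sample(s): ",
             paste(colnames(counts)[lib == 0], collapse = ", "))
    f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
    ref <- which.min(abs(f75 - mean(f75)))
    f <- rep(1, ncol(counts))
    for (j in seq_len(ncol(counts))) {
        if (j == ref) next
        keep <- counts[, j] > 0 & counts[, ref] > 0
        if (!any(keep)) stop("no genes shared with reference for sample ", j)
        yj <- counts[keep, j]; yr <- counts[keep, ref]
        pj <- yj / lib[j]; pr <- yr / lib[ref]
        M <- log2(pj / pr)
        A <- (log2(pj) + log2(pr)) / 2
        # double trim, rank-based: 30% of M and 5% of A from each tail
        nk <- length(M)
        loM <- floor(nk * 0.3) + 1; hiM <- nk + 1 - loM
        loA <- floor(nk * 0.05) + 1; hiA <- nk + 1 - loA
        rM <- rank(M); rA <- rank(A)
        use <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
        f[j] <- if (any(use)) 2^mean(M[use]) else 1
    }
    f <- f / exp(mean(log(f)))
    stats::setNames(f, colnames(counts))
}

## method-of-moments NB dispersion pooled over time groups, shrunk toward
## the all-gene median with a fixed prior weight
.estimateDispersion <- function(adj, meta, priorWeight = 20) {
    groups <- split(seq_len(ncol(adj)), meta$time_h)
    num <- den <- df <- 0
    for (cols in groups) {
        if (length(cols) < 2L) next
        m <- rowMeans(adj[, cols, drop = FALSE])
        v <- apply(adj[, cols, drop = FALSE], 1, stats::var)
        w <- length(cols) - 1L
        num <- num + w * (v - m)
        den <- den + w * m^2
        df <- df + w
    }
    raw <- ifelse(den > 0, pmax(num / den, 0), NA_real_)
    common <- stats::median(raw, na.rm = TRUE)
    if (!is.finite(common)) common <- 0.1
    shrunk <- (df * ifelse(is.na(raw), common, raw) + priorWeight * common) /
        (df + priorWeight)
    ## one-sided moderation: per-gene moment estimates at ~10 residual df
    ## scatter widely, and genes squeezed below the common value inflate the
    ## extreme p-value tail; never test with less than the common dispersion
    pmax(shrunk, common)
}

## two-sided conditional NB exact test for one gene: the conditional law of
## the group-B total given the overall total is beta-binomial(s, nB/phi,
## nA/phi); p sums all outcomes no more probable than the observed one.
.condPValue <- function(yA, yB, nA, nB, phi, enumLimit = 5000) {
    s <- yA + yB
    if (s == 0) return(1)
    pB <- nB / (nA + nB)
    if (s <= enumLimit) {
        x <- 0:s
        if (phi <= 1e-6) {            # Poisson limit: exact binomial
            d <- stats::dbinom(x, s, pB)
        } else {
            rA <- nA / phi; rB <- nB / phi
            ld <- lchoose(x + rB - 1, x) + lchoose(s - x + rA - 1, s - x) -
                lchoose(s + rA + rB - 1, s)
            d <- exp(ld - max(ld))
            d <- d / sum(d)
        }
        pobs <- d[yB + 1]
        return(min(1, sum(d[d <= pobs * (1 + 1e-7)])))
    }
    if (phi <= 1e-6) {
        m <- s * pB; v <- s * pB * (1 - pB)
    } else {
        rA <- nA / phi; rB <- nB / phi; rT <- rA + rB
        m <- s * rB / rT
        v <- s * rA * rB * (rT + s) / (rT^2 * (rT + 1))
    }
    if (v <= 0) return(1)
    z <- (abs(yB - m) - 0.5) / sqrt(v)
    min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}

#' Differential expression of one time point against 0 h
#'
#' Negative-binomial conditional exact test on library-adjusted counts.
#' Counts are rescaled to the \emph{median} effective library size (library
#' size x TMM factor) and rounded; the per-gene dispersion is a pooled
#' method-of-moments estimate across all time groups, shrunk toward the
#' all-gene median with prior weight 20 and floored at that common value
#' (one-sided moderation keeps the extreme tail calibrated when per-gene
#' estimates are noisy). The two-sided p-value comes from
#' the conditional distribution of the post-wounding group total given the
#' overall total (enumerated exactly when the total is <= \code{enumLimit},
#' normal approximation beyond); FDR is Benjamini-Hochberg across all genes
#' within the contrast.
#'
#' @param x Count matrix or \code{SummarizedExperiment} (assay
#'   \code{counts}).
#' @param time_h The post-wounding time to contrast against 0 h.
#' @param factors TMM factors (computed with
#'   \code{\link{normalizeLibraries}} when \code{NULL}).
#' @param colData data.frame with \code{time_h} per sample (for a bare
#'   matrix).
#' @param dispersion Optional fixed dispersion (overrides estimation; used
#'   mainly for calibration checks).
#' @param enumLimit Largest group total enumerated exactly.
#' @return data.frame: \code{gene_id}, \code{time_h}, \code{logFC} (log2,
#'   pseudo-count 0.5 on normalized means), \code{p_value}, \code{fdr},
#'   \code{untestable}.
#' @export
testDE <- function(x, time_h, factors = NULL, colData = NULL,
                   dispersion = NULL, enumLimit = 5000) {
    cm <- .countsAndMeta(x, colData)
    counts <- cm$counts; meta <- cm$meta
    if (!time_h %in% meta$time_h || time_h == 0)
        stop("time_h must be a non-zero time present in the metadata")
    if (is.null(factors)) factors <- normalizeLibraries(counts)
    eff <- colSums(counts) * factors
    common <- stats::median(eff)
    adj <- sweep(counts, 2, common / eff, `*`)
    phi <- if (is.null(dispersion)) .estimateDispersion(adj, meta)
           else rep(dispersion, nrow(counts))
    adjInt <- round(adj)

    colsA <- which(meta$time_h == 0)
    colsB <- which(meta$time_h == time_h)
    if (length(colsA) < 2L || length(colsB) < 2L)
        stop("need >= 2 replicates in each group")
    yA <- rowSums(adjInt[, colsA, drop = FALSE])
    yB <- rowSums(adjInt[, colsB, drop = FALSE])
    mA <- rowMeans(adj[, colsA, drop = FALSE])
    mB <- rowMeans(adj[, colsB, drop = FALSE])

    p <- vapply(seq_len(nrow(counts)), function(i)
        .condPValue(yA[i], yB[i], length(colsA), length(colsB), phi[i],
                    enumLimit), 0)
    untestable <- (yA + yB) == 0
    data.frame(
        gene_id = rownames(counts), time_h = time_h,
        logFC = ifelse(untestable, 0, log2((mB + 0.5) / (mA + 0.5))),
        p_value = p, fdr = stats::p.adjust(p, "BH"),
        untestable = untestable, row.names = NULL,
        stringsAsFactors = FALSE)
}

#' Run the 0 h contrast for every post-wounding time
#'
#' @inheritParams testDE
#' @param times Times to contrast (default: every non-zero time present).
#' @return Row-bound \code{\link{testDE}} results across contrasts.
#' @export
testDEAllTimes <- function(x, factors = NULL, colData = NULL, times = NULL,
                           dispersion = NULL, enumLimit = 5000) {
    cm <- .countsAndMeta(x, colData)
    if (is.null(times)) times <- sort(setdiff(unique(cm$meta$time_h), 0))
    if (is.null(factors)) factors <- normalizeLibraries(cm$counts)
    do.call(rbind, lapply(times, function(t)
        testDE(cm$counts, t, factors = factors, colData = cm$meta,
               dispersion = dispersion, enumLimit = enumLimit)))
}

#' Wound-responsive gene sets
#'
#' Induced genes show log2FC > log2(\code{fcThreshold}) with FDR <
#' \code{fdrThreshold} at one or more time points; repressed genes the
#' mirror image. A gene passing both directions (at different times) is
#' placed in both sets and flagged with a warning.
#'
#' @param de Differential-expression table covering >= 1 contrast
#'   (\code{\link{testDEAllTimes}}).
#' @param fcThreshold Fold-change cut (default 1.5).
#' @param fdrThreshold FDR cut (default 0.001).
#' @return list with character vectors \code{induced}, \code{repressed} and
#'   \code{both}.
#' @export
callWoundResponsive <- function(de, fcThreshold = 1.5,
                                fdrThreshold = 0.001) {
    lfc <- log2(fcThreshold)
    up <- de$logFC > lfc & de$fdr < fdrThreshold
    dn <- de$logFC < -lfc & de$fdr < fdrThreshold
    induced <- sort(unique(de$gene_id[up]))
    repressed <- sort(unique(de$gene_id[dn]))
    both <- intersect(induced, repressed)
    if (length(both))
        warning(length(both),
                " gene(s) pass both directions at different times; ",
                "listed in both sets")
    list(induced = induced, repressed = repressed, both = both)
}

#' Order K-means clusters from earliest to latest induction
#'
#' Each centroid (a mean-centred log-expression time profile) is scored by
#' the earliest time at which it reaches 50\% of its maximum positive
#' deviation; exact ties are broken by the centroid-weighted mean time
#' (sum t * max(c(t),0) / sum max(c(t),0)), then by original cluster index.
#' A centroid with no positive deviation is scored last and flagged with a
#' warning.
#'
#' @param centroids Numeric matrix, clusters x times.
#' @param times Numeric time points (h) matching the columns.
#' @return Integer permutation \code{perm} such that \code{perm[old]} is the
#'   new label (1 = earliest); timing scores attached as
#'   \code{attr(,"score")}.
#' @export
orderClusters <- function(centroids, times) {
    k <- nrow(centroids)
    score <- tiebreak <- numeric(k)
    for (j in seq_len(k)) {
        cc <- centroids[j, ]
        pos <- pmax(cc, 0)
        if (max(pos) <= 0) {
            score[j] <- Inf; tiebreak[j] <- Inf
            warning("cluster ", j, " has no positive deviation; scored last")
        } else {
            score[j] <- times[which(cc >= 0.5 * max(pos))[1]]
            tiebreak[j] <- sum(times * pos) / sum(pos)
        }
    }
    ord <- order(score, tiebreak, seq_len(k))
    perm <- integer(k)
    perm[ord] <- seq_len(k)
    attr(perm, "score") <- score
    perm
}

#' K-means induction-timing clusters of wound-induced genes
#'
#' Profiles are per-gene log2(normalized count + 1), averaged over
#' replicates per time and mean-centred; K-means (Euclidean, best of
#' \code{nStarts} random starts by within-cluster SS) partitions them into
#' \code{k} clusters, relabelled with \code{\link{orderClusters}} so that
#' cluster 1 is the most rapidly induced.
#'
#' @inheritParams testDE
#' @param induced Character vector of induced gene ids (must have >= k).
#' @param k Number of clusters (default 8).
#' @param nStarts Random starts (default 50).
#' @param seed Seed for the K-means initialisation.
#' @return list: \code{labels} (named integer, 1 = earliest), \code{centroids}
#'   (k x times, rows in label order), \code{score} (per-label timing score),
#'   \code{profiles} (the clustered matrix).
#' @export
clusterInduced <- function(x, induced, factors = NULL, colData = NULL,
                           k = 8, nStarts = 50, seed = 1) {
    cm <- .countsAndMeta(x, colData)
    counts <- cm$counts; meta <- cm$meta
    if (length(induced) < k)
        stop("only ", length(induced), " induced genes for k = ", k,
             "; use a smaller k")
    if (is.null(factors)) factors <- normalizeLibraries(counts)
    eff <- colSums(counts) * factors
    common <- stats::median(eff)
    norm <- sweep(counts[induced, , drop = FALSE], 2, common / eff, `*`)
    times <- sort(unique(meta$time_h))
    prof <- vapply(times, function(t)
        rowMeans(log2(norm[, meta$time_h == t, drop = FALSE] + 1)),
        numeric(length(induced)))
    colnames(prof) <- times
    prof <- prof - rowMeans(prof)
    set.seed(seed)
    km <- stats::kmeans(prof, centers = k, nstart = nStarts, iter.max = 100)
    perm <- orderClusters(km$centers, times)
    labels <- stats::setNames(perm[km$cluster], induced)
    centroids <- km$centers[order(perm), , drop = FALSE]
    rownames(centroids) <- seq_len(k)
    list(labels = labels, centroids = centroids,
         score = attr(perm, "score")[order(perm)], profiles = prof)
}
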