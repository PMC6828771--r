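## Timing-integration analyses: how pre-wound marking and post-wound mark
## dynamics relate to the order and speed of transcriptional induction.

#' Rank-LOESS curve of induction timing over pre-wound mark level
#'
#' Genes are ranked by pre-wound enrichment level (ties broken by input
#' order); the response is the numeric induction-timing cluster label
#' (1 = earliest). A tricube-weighted local linear fit (degree 1, the given
#' span) is evaluated at every rank; the Spearman correlation between level
#' and label accompanies the curve. Being rank-based, the smoothed curve is
#' invariant to any strictly monotone transform of the levels.
#'
#' @param levels Named numeric vector of pre-wound levels for one mark.
#' @param labels Named integer cluster labels over the same genes.
#' @param span LOESS span as a fraction of points in (0, 1] (default 0.3).
#' @return list: \code{curve} (data.frame gene_id, rank, level, label,
#'   smoothed), \code{rho} (Spearman; 0 and flagged when a variable is
#'   constant), \code{flat}.
#' @export
rankLoessTiming <- function(levels, labels, span = 0.3) {
    if (span <= 0 || span > 1) stop("span must be in (0, 1]")
    genes <- intersect(names(levels), names(labels))
    if (length(genes) < length(labels))
        stop("levels missing for some clustered genes")
    x <- levels[genes]; y <- as.numeric(labels[genes])
    rk <- rank(x, ties.method = "first")
    flat <- stats::sd(y) == 0 || stats::sd(x) == 0
    rho <- if (flat) 0 else stats::cor(x, y, method = "spearman")
    fit <- stats::loess(y ~ rk, span = span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    sm <- stats::predict(fit, newdata = data.frame(rk = sort(rk)))
    ord <- order(rk)
    list(curve = data.frame(gene_id = genes[ord], rank = rk[ord],
                            level = x[ord], label = y[ord], smoothed = sm,
                            row.names = NULL, stringsAsFactors = FALSE),
         rho = rho, flat = flat)
}

#' PCA of pre-wound mark ranks, induction timing and baseline expression
#'
#' Variables per induced gene: the rank of each mark's pre-wound level,
#' the timing-cluster label (numeric, 1 = earliest) and the rank of 0 h
#' expression. Standardized (correlation-matrix) PCA; constant variables
#' are dropped with a warning; PC1's sign is fixed so the first variable
#' loads non-negatively.
#'
#' @param levelRanks Numeric matrix genes x marks of pre-wound level ranks
#'   (or raw levels; ranks are taken internally).
#' @param clusterLabel Named numeric vector of timing labels.
#' @param exprRank Named numeric vector of 0 h expression ranks.
#' @return list: \code{loadings} (variables x PCs), \code{varExplained}
#'   (fractions), \code{scores}.
#' @export
timingPCA <- function(levelRanks, clusterLabel, exprRank) {
    genes <- rownames(levelRanks)
    X <- cbind(apply(levelRanks, 2, rank),
               timing = as.numeric(clusterLabel[genes]),
               expression_0h = as.numeric(exprRank[genes]))
    if (anyNA(X)) stop("incomplete variable matrix over the induced genes")
    keep <- apply(X, 2, stats::sd) > 0
    if (any(!keep))
        warning("dropping constant variable(s): ",
                paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
    if (pr$rotation[1, 1] < 0) {
        pr$rotation[, 1] <- -pr$rotation[, 1]
        pr$x[, 1] <- -pr$x[, 1]
    }
    list(loadings = pr$rotation,
         varExplained = pr$sdev^2 / sum(pr$sdev^2), scores = pr$x)
}

#' Acetylation-centred epigenetic categories of induced genes
#'
#' Groups induced genes by their H3K9/14ac status: \code{preac_no_gain}
#' (pre-wound acetylated, no post-wound gain), \code{preac_plus_gain},
#' \code{gain_only}, \code{no_ac}; the independent \code{me3_gain} flag
#' records a post-wound H3K4me3 gain.
#'
#' @param state \code{\linkS4class{MarkStateTable}} (pre-wound marked
#'   status).
#' @param changes data.frame from \code{\link{firstChangeTimes}}.
#' @param genes Genes to classify (default: all genes in \code{state}).
#' @param maxGainTime Latest time counted as a post-wound gain (default 6).
#' @param acMark,me3Mark Mark names.
#' @return data.frame gene_id, category, me3_gain.
#' @export
classifyAcCategory <- function(state, changes, genes = NULL,
                               maxGainTime = 6, acMark = "H3K9K14ac",
                               me3Mark = "H3K4me3") {
    if (is.null(genes)) genes <- geneIds(state)
    miss <- setdiff(genes, geneIds(state))
    if (length(miss))
        stop("gene(s) missing from the state table: ",
             paste(utils::head(miss, 5), collapse = ", "))
    gt <- function(mark) {
        sub <- changes[changes$mark == mark, , drop = FALSE]
        v <- stats::setNames(sub$first_gain_time, sub$gene_id)[genes]
        v[is.na(v)] <- Inf
        v
    }
    preac <- stats::setNames(isMarked(state)[, acMark], geneIds(state))[genes]
    acGain <- gt(acMark) <= maxGainTime
    me3Gain <- gt(me3Mark) <= maxGainTime
    category <- ifelse(preac & !acGain, "preac_no_gain",
                ifelse(preac & acGain, "preac_plus_gain",
                ifelse(acGain, "gain_only", "no_ac")))
    data.frame(gene_id = genes, category = category, me3_gain = me3Gain,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Acetylation/H3K4me3 precedence classification
#'
#' Per gene, compares the first H3K9/14ac gain time with the first H3K4me3
#' gain time: \code{ac_first} (both finite, ac earlier), \code{me3_first},
#' \code{simultaneous}, \code{only_ac}, \code{only_me3}, \code{neither}.
#' Single-gainers are kept separate (strict reading); the inclusive tallies
#' (\code{ac_first + only_ac}, etc.) are also returned so either convention
#' is recoverable.
#'
#' @param changes data.frame from \code{\link{firstChangeTimes}}.
#' @param genes Genes to classify (default: all in \code{changes}).
#' @param acMark,me3Mark Mark names.
#' @return list: \code{calls} (data.frame gene_id, t_gain_ac, t_gain_me3,
#'   category), \code{counts} (named vector over the six categories),
#'   \code{countsInclusive} (ac_first/me3_first including single-gainers).
#' @export
precedenceCounts <- function(changes, genes = NULL, acMark = "H3K9K14ac",
                             me3Mark = "H3K4me3") {
    if (is.null(genes)) genes <- sort(unique(changes$gene_id))
    gt <- function(mark) {
        sub <- changes[changes$mark == mark, , drop = FALSE]
        v <- stats::setNames(sub$first_gain_time, sub$gene_id)[genes]
        v[is.na(v)] <- Inf
        v
    }
    tAc <- gt(acMark); tMe <- gt(me3Mark)
    category <- ifelse(is.finite(tAc) & is.finite(tMe) & tAc < tMe,
                       "ac_first",
                ifelse(is.finite(tAc) & is.finite(tMe) & tMe < tAc,
                       "me3_first",
                ifelse(is.finite(tAc) & is.finite(tMe), "simultaneous",
                ifelse(is.finite(tAc), "only_ac",
                ifelse(is.finite(tMe), "only_me3", "neither")))))
    lev <- c("ac_first", "me3_first", "simultaneous", "only_ac",
             "only_me3", "neither")
    counts <- table(factor(category, levels = lev))
    list(calls = data.frame(gene_id = genes, t_gain_ac = tAc,
                            t_gain_me3 = tMe, category = category,
                            row.names = NULL, stringsAsFactors = FALSE),
         counts = stats::setNames(as.integer(counts), lev),
         countsInclusive = c(
             ac_first = unname(counts["ac_first"] + counts["only_ac"]),
             me3_first = unname(counts["me3_first"] + counts["only_me3"])))
}

#' Mean temporal mark and expression profiles per gene group
#'
#' Arithmetic mean and SD of relative enrichment per (group, mark, time),
#' with the matching mean log2 expression trajectory when provided. Empty
#' groups are omitted with a warning.
#'
#' @param levels Array genes x marks x times (relative enrichment).
#' @param groups Named character/factor vector, gene -> group.
#' @param expression Optional matrix genes x times of log2 normalized
#'   expression.
#' @return list: \code{marks} (data.frame group, mark, time_h, mean, sd,
#'   n), \code{expression} (data.frame group, time_h, mean, sd, n) or NULL.
#' @export
temporalProfiles <- function(levels, groups, expression = NULL) {
    groups <- groups[!is.na(groups)]
    gnames <- sort(unique(as.character(groups)))
    genes <- dimnames(levels)[[1]]
    out <- list(); eout <- list()
    for (g in gnames) {
        ids <- intersect(names(groups)[groups == g], genes)
        if (!length(ids)) {
            warning("empty group '", g, "' omitted")
            next
        }
        for (m in dimnames(levels)[[2]]) for (tc in dimnames(levels)[[3]]) {
            v <- levels[ids, m, tc]
            out[[length(out) + 1L]] <- data.frame(
                group = g, mark = m, time_h = as.numeric(tc),
                mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
                n = length(v), stringsAsFactors = FALSE)
        }
        if (!is.null(expression)) {
            ids2 <- intersect(ids, rownames(expression))
            for (tc in colnames(expression)) {
                v <- expression[ids2, tc]
                eout[[length(eout) + 1L]] <- data.frame(
                    group = g, time_h = as.numeric(tc), mean = mean(v),
                    sd = if (length(v) > 1) stats::sd(v) else 0,
                    n = length(v), stringsAsFactors = FALSE)
            }
        }
    }
    list(marks = do.call(rbind, out),
         expression = if (length(eout)) do.call(rbind, eout) else NULL)
}

#' Pearson correlation of marking change and expression change
#'
#' Per (mark, time): Pearson r between the rescaled M value and the
#' transcriptional log2 fold change over all genes shared by the two
#' tables.
#'
#' @param marking data.frame from \code{\link{differentialMarking}}.
#' @param de data.frame from \code{\link{testDEAllTimes}}.
#' @param minGenes Minimum paired genes per contrast (default 10).
#' @return data.frame mark, time_h, r, n (r is NA and flagged when either
#'   variable has zero variance).
#' @export
markingExpressionCorrelation <- function(marking, de, minGenes = 10) {
    out <- list()
    for (m in unique(marking$mark)) {
        for (t in sort(unique(marking$time_h))) {
            mm <- marking[marking$mark == m & marking$time_h == t, ]
            dd <- de[de$time_h == t & !de$untestable, ]
            ids <- intersect(mm$gene_id, dd$gene_id)
            if (length(ids) < minGenes) next
            x <- mm$M_rescaled[match(ids, mm$gene_id)]
            y <- dd$logFC[match(ids, dd$gene_id)]
            r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
                warning("zero variance for ", m, " at ", t, " h")
                NA_real_
            } else stats::cor(x, y)
            out[[length(out) + 1L]] <- data.frame(
                mark = m, time_h = t, r = r, n = length(ids),
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Format a count pair as the reported percentage
#'
#' 100 * numerator / denominator, rendered to one decimal place below 10
#' and to the nearest integer (half away from zero) otherwise — the
#' reporting convention used for headline fractions.
#'
#' @param numerator,denominator Non-negative counts, numerator <=
#'   denominator, denominator > 0.
#' @return Character percentage, e.g. \code{"17\%"} or \code{"3.2\%"}; the
#'   unrounded value is attached as \code{attr(,"value")}.
#' @export
#' @examples
#' reportFraction(961, 5777)  # "17%"
#' reportFraction(116, 3665)  # "3.2%"
reportFraction <- function(numerator, denominator) {
    if (denominator <= 0) stop("denominator must be > 0")
    if (numerator < 0 || numerator > denominator)
        stop("need 0 <= numerator <= denominator")
    v <- 100 * numerator / denominator
    out <- if (v < 10) sprintf("%.1f%%", v)
           else sprintf("%d%%", as.integer(floor(v + 0.5)))
    attr(out, "value") <- v
    out
}
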