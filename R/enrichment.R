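## Representation factors with exact hypergeometric tails, applied to marks,
## co-marks, categories-within-clusters and generic term sets.

.stars <- function(p) {
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
        ifelse(p < 0.05, "*", "")))
}

#' Representation factor with two one-sided hypergeometric tails
#'
#' RF = (k/n) / (K/N): the observed frequency of a category in the query
#' set over its frequency in the universe. \code{p_over} = P[X >= k] and
#' \code{p_under} = P[X <= k] for X ~ Hypergeometric(N, K, n) (exact tail
#' sums). Stars annotate the tail matching the direction of RF (over when
#' RF > 1, under when RF < 1).
#'
#' @param k Overlap count (query genes in the category).
#' @param n Query-set size.
#' @param K Category size in the universe.
#' @param N Universe size.
#' @param category Optional category label.
#' @return One-row data.frame: category, k, n, K, N,
#'   representation_factor, p_over, p_under, stars.
#' @export
#' @examples
#' representationFactor(4, 8, 5, 20)  # RF = 2, p_over = 7280/125970
representationFactor <- function(k, n, K, N, category = NA_character_) {
    v <- c(k = k, n = n, K = K, N = N)
    if (any(v != round(v))) stop("k, n, K, N must be integers")
    if (k < 0 || k > n) stop("need 0 <= k <= n (k=", k, ", n=", n, ")")
    if (k > K) stop("need k <= K (k=", k, ", K=", K, ")")
    if (n > N) stop("need n <= N (n=", n, ", N=", N, ")")
    if (K > N) stop("need K <= N (K=", K, ", N=", N, ")")
    rf <- if (n == 0) NA_real_ else (k / n) / (K / N)
    pOver <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    pUnder <- stats::phyper(k, K, N - K, n)
    p <- if (!is.na(rf) && rf < 1) pUnder else pOver
    data.frame(category = category, k = k, n = n, K = K, N = N,
               representation_factor = rf, p_over = pOver,
               p_under = pUnder, stars = .stars(p),
               stringsAsFactors = FALSE)
}

#' Per-mark enrichment of a gene set
#'
#' For each mark: k = query genes marked, K = marked genes in the universe,
#' n = query size, N = universe size. Also reports the percentage of each
#' mark's genes that fall in the query (100 k / K, the "induced among
#' marked" figure).
#'
#' @param state A \code{\linkS4class{MarkStateTable}} (or logical gene x
#'   mark matrix).
#' @param query Character vector of gene ids (must be within the universe).
#' @param universe Character vector of gene ids.
#' @return data.frame, one row per mark, with the
#'   \code{\link{representationFactor}} columns plus \code{pct_of_marked}.
#' @export
markEnrichment <- function(state, query, universe) {
    marked <- if (is(state, "MarkStateTable")) isMarked(state) else state
    off <- setdiff(query, universe)
    if (length(off))
        stop("query gene(s) not in universe: ",
             paste(utils::head(off, 5), collapse = ", "))
    out <- do.call(rbind, lapply(colnames(marked), function(m) {
        mg <- rownames(marked)[marked[, m]]
        mg <- intersect(mg, universe)
        r <- representationFactor(length(intersect(query, mg)),
                                  length(query), length(mg),
                                  length(universe), category = m)
        r$pct_of_marked <- if (length(mg)) 100 * r$k / r$K else NA_real_
        r
    }))
    rownames(out) <- NULL
    out
}

#' Co-marking enrichment among marked genes
#'
#' Compares the frequency of each mark pair (both marks present) in the
#' marked subset of the query against its frequency among all marked genes
#' (the universe is the genes bearing at least one mark, per the co-marking
#' analysis convention).
#'
#' @param state \code{\linkS4class{MarkStateTable}} or logical matrix.
#' @param query Character vector of gene ids.
#' @param universe Optional explicit universe; default: all genes with
#'   >= 1 mark.
#' @return data.frame, one row per unordered mark pair.
#' @export
comarkEnrichment <- function(state, query, universe = NULL) {
    marked <- if (is(state, "MarkStateTable")) isMarked(state) else state
    if (is.null(universe))
        universe <- rownames(marked)[rowSums(marked) > 0]
    if (!length(universe)) stop("empty marked universe")
    queryM <- intersect(query, universe)
    prs <- utils::combn(colnames(marked), 2)
    out <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
        m1 <- prs[1, j]; m2 <- prs[2, j]
        co <- rownames(marked)[marked[, m1] & marked[, m2]]
        co <- intersect(co, universe)
        representationFactor(length(intersect(queryM, co)), length(queryM),
                             length(co), length(universe),
                             category = paste(m1, m2, sep = "+"))
    }))
    rownames(out) <- NULL
    out
}

#' Category enrichment within timing clusters
#'
#' For each (cluster, category): k = genes of the category in the cluster,
#' n = cluster size, K = category size, N = all clustered genes. RF is the
#' spie-chart wedge radius (RF = 1 is the reference circle).
#'
#' @param categories Named character vector, gene -> category.
#' @param clusters Named integer/character vector, gene -> cluster label.
#' @return data.frame, one row per cluster x category.
#' @export
clusterCategoryEnrichment <- function(categories, clusters) {
    genes <- intersect(names(categories), names(clusters))
    miss <- setdiff(names(clusters), names(categories))
    if (length(miss))
        stop("clustered gene(s) without category: ",
             paste(utils::head(miss, 5), collapse = ", "))
    cat <- categories[genes]; clu <- clusters[genes]
    N <- length(genes)
    out <- list()
    for (cl in sort(unique(clu))) for (g in sort(unique(cat))) {
        inC <- genes[clu == cl]
        inG <- genes[cat == g]
        r <- representationFactor(length(intersect(inC, inG)), length(inC),
                                  length(inG), N,
                                  category = paste0("cluster", cl, ":", g))
        r$cluster <- cl; r$group <- g
        out[[length(out) + 1L]] <- r
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Compare enrichment-level distributions of two gene sets
#'
#' Two-sided Wilcoxon rank-sum test with tie correction; the exact
#' distribution is used for small samples (total <= 20 and no ties),
#' normal approximation otherwise.
#'
#' @param levels Named numeric vector of levels (e.g. one mark's pre-wound
#'   enrichment).
#' @param setA,setB Disjoint gene-id vectors (>= 3 each).
#' @return list: \code{statistic} (rank-sum W), \code{p_value},
#'   \code{exact}.
#' @export
compareLevelDistributions <- function(levels, setA, setB) {
    if (length(intersect(setA, setB)))
        stop("gene sets must be disjoint")
    if (length(setA) < 3 || length(setB) < 3)
        stop("both sets need >= 3 genes")
    xa <- levels[setA]; xb <- levels[setB]
    if (anyNA(xa) || anyNA(xb)) stop("missing levels for some genes")
    exact <- (length(xa) + length(xb)) <= 20 &&
        !anyDuplicated(c(xa, xb))
    wt <- stats::wilcox.test(xa, xb, exact = exact, correct = TRUE)
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         exact = exact)
}

#' Hypergeometric term (e.g. GO) over-representation
#'
#' Per term: k = query genes annotated, K = universe genes annotated, with
#' the over-representation tail P[X >= k]; BH correction across terms.
#' Terms with k = 0 are reported with p = 1.
#'
#' @param annotation data.frame with columns \code{gene} and \code{term}
#'   (a gene may carry any number of terms).
#' @param query Character vector of gene ids.
#' @param universe Character vector of gene ids.
#' @return data.frame per term: term, k, n, K, N, representation_factor,
#'   p_over, fdr; ordered by p_over.
#' @export
termEnrichment <- function(annotation, query, universe) {
    off <- setdiff(query, universe)
    if (length(off))
        stop("query gene(s) not in universe: ",
             paste(utils::head(off, 5), collapse = ", "))
    ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
    terms <- sort(unique(ann$term))
    n <- length(query); N <- length(universe)
    out <- do.call(rbind, lapply(terms, function(tm) {
        tg <- unique(ann$gene[ann$term == tm])
        k <- length(intersect(query, tg)); K <- length(tg)
        data.frame(term = tm, k = k, n = n, K = K, N = N,
                   representation_factor =
                       if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_,
                   p_over = stats::phyper(k - 1, K, N - K, n,
                                          lower.tail = FALSE),
                   stringsAsFactors = FALSE)
    }))
    out$fdr <- stats::p.adjust(out$p_over, "BH")
    out <- out[order(out$p_over, out$term), , drop = FALSE]
    rownames(out) <- NULL
    out
}
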