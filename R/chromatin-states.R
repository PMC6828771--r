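## H3-normalized enrichment levels and the pre-wound marking-state table.

#' H3-normalized enrichment levels for all genes/marks/times
#'
#' For each (gene, mark, time): replicate depths are averaged first, then a
#' pseudo-depth of 0.5 is added to both the mark and the H3 average before
#' taking their ratio. A missing H3 row for any (gene, time) with mark
#' coverage is an error.
#'
#' @param coverage Long coverage table (\code{gene_id}, \code{track},
#'   \code{time_h}, \code{replicate}, \code{mean_depth}); \code{track} is a
#'   mark name or \code{"H3"}.
#' @param marks Marks to extract (default: all non-H3 tracks present).
#' @param times Times to extract (default: all present).
#' @param pseudoDepth Pseudo-depth added to numerator and denominator
#'   (default 0.5).
#' @param perReplicate If \code{TRUE}, compute the pseudo-counted ratio per
#'   replicate and average the ratios instead (alternative convention).
#' @return Numeric array genes x marks x times of relative enrichment.
#' @export
enrichmentLevels <- function(coverage, marks = NULL, times = NULL,
                             pseudoDepth = 0.5, perReplicate = FALSE) {
    if (is.null(marks)) marks <- setdiff(unique(coverage$track), "H3")
    if (is.null(times)) times <- sort(unique(coverage$time_h))
    genes <- unique(coverage$gene_id)
    gi <- match(coverage$gene_id, genes)
    ti <- match(coverage$time_h, times)

    meanDepth <- function(track) {
        sel <- coverage$track == track & !is.na(ti)
        key <- (ti[sel] - 1L) * length(genes) + gi[sel]
        sums <- rowsum(coverage$mean_depth[sel], key)
        cnts <- rowsum(rep(1, sum(sel)), key)
        out <- matrix(NA_real_, length(genes), length(times),
                      dimnames = list(genes, times))
        out[as.integer(rownames(sums))] <- sums / cnts
        out
    }
    h3 <- meanDepth("H3")
    lev <- array(NA_real_, c(length(genes), length(marks), length(times)),
                 dimnames = list(genes, marks, times))
    for (m in marks) {
        md <- meanDepth(m)
        bad <- which(!is.na(md) & is.na(h3), arr.ind = TRUE)
        if (nrow(bad))
            stop("missing H3 coverage for gene ", genes[bad[1, 1]],
                 " at time ", times[bad[1, 2]], " h")
        if (perReplicate) {
            # average of per-replicate pseudo-counted ratios
            selM <- coverage$track == m
            selH <- coverage$track == "H3"
            keyOf <- function(sel) paste(coverage$gene_id[sel],
                                         coverage$time_h[sel],
                                         coverage$replicate[sel])
            hm <- stats::setNames(coverage$mean_depth[selH], keyOf(selH))
            rat <- (coverage$mean_depth[selM] + pseudoDepth) /
                (hm[keyOf(selM)] + pseudoDepth)
            agg <- rowsum(cbind(rat, 1),
                          paste(coverage$gene_id[selM],
                                coverage$time_h[selM]))
            vals <- agg[, 1] / agg[, 2]
            kk <- strsplit(rownames(agg), " ")
            lev[cbind(match(vapply(kk, `[`, "", 1L), genes), match(m, marks),
                      match(as.numeric(vapply(kk, `[`, "", 2L)), times))] <-
                vals
        } else {
            lev[, m, ] <- (md + pseudoDepth) / (h3 + pseudoDepth)
        }
    }
    if (anyNA(lev))
        stop("missing mark coverage for some gene/time; coverage table ",
             "must be complete over genes x tracks x times")
    lev
}

#' Relative enrichment of one gene/mark/time
#'
#' Scalar convenience wrapper around \code{\link{enrichmentLevels}}.
#'
#' @inheritParams enrichmentLevels
#' @param gene,mark,time_h The cell to extract.
#' @return The mark/H3 ratio (pseudo-counted).
#' @export
#' @examples
#' cov <- data.frame(gene_id = "g1", track = c("H3", "H3", "m", "m"),
#'                   time_h = 0, replicate = c(1, 2, 1, 2),
#'                   mean_depth = c(20, 20, 10, 20))
#' relativeEnrichment(cov, "g1", "m", 0)  # 15.5 / 20.5
relativeEnrichment <- function(coverage, gene, mark, time_h,
                               pseudoDepth = 0.5, perReplicate = FALSE) {
    sub <- coverage[coverage$gene_id == gene &
                    coverage$time_h == time_h &
                    coverage$track %in% c(mark, "H3"), , drop = FALSE]
    if (!any(sub$track == "H3"))
        stop("missing H3 coverage for gene ", gene, " at ", time_h, " h")
    if (!any(sub$track == mark))
        stop("missing ", mark, " coverage for gene ", gene, " at ",
             time_h, " h")
    lev <- enrichmentLevels(sub, marks = mark, times = time_h,
                            pseudoDepth = pseudoDepth,
                            perReplicate = perReplicate)
    unname(lev[gene, mark, 1])
}

#' Build the per-gene marking-state table
#'
#' Marking calls intersect the two replicates' peak assignments per mark at
#' the reference time (a gene is marked only with a qualifying peak in both
#' replicates); levels are H3-normalized enrichment at every ChIP time.
#'
#' @param peaks Nested list \code{mark -> "t<time>" -> replicate} of peak
#'   \code{GRanges} (as from \code{\link{simulateChip}}, or assembled from
#'   \code{\link{readPeaks}} calls).
#' @param coverage Long coverage table (see
#'   \code{\link{enrichmentLevels}}).
#' @param genes \code{GRanges} gene models with \code{gene_id}.
#' @param time_h Reference time for marking calls (default 0, the pre-wound
#'   state).
#' @param promoterBp Promoter extension for the analysis window.
#' @param maxDistanceBp Maximal peak-window distance for a marking call.
#' @param minNegLog10Q Peaks below this -log10(q) are ignored.
#' @return A \code{\linkS4class{MarkStateTable}}.
#' @export
buildStateTable <- function(peaks, coverage, genes, time_h = 0,
                            promoterBp = 1000, maxDistanceBp = 0,
                            minNegLog10Q = 3) {
    marks <- names(peaks)
    ids <- genes$gene_id
    marked <- buildStateTableMarks(peaks, genes, time_h, promoterBp,
                                   maxDistanceBp, minNegLog10Q)
    lev <- enrichmentLevels(coverage, marks = marks)
    lev <- lev[ids, , , drop = FALSE]
    new("MarkStateTable", genes = ids, marks = marks,
        times = as.numeric(dimnames(lev)[[3]]), marked = marked,
        levels = lev, markedTime = time_h)
}

#' Replicate-intersected marking calls at one time point
#'
#' Same call logic as \code{\link{buildStateTable}} but returning only the
#' logical gene x mark matrix for an arbitrary time (used for post-wound
#' marked status and anchor selection).
#'
#' @inheritParams buildStateTable
#' @return Logical matrix genes x marks.
#' @export
markedAtTime <- function(peaks, genes, time_h, promoterBp = 1000,
                         maxDistanceBp = 0, minNegLog10Q = 3) {
    buildStateTableMarks(peaks, genes, time_h, promoterBp,
                         maxDistanceBp, minNegLog10Q)
}

## internal: marking matrix only (no coverage requirement)
buildStateTableMarks <- function(peaks, genes, time_h, promoterBp = 1000,
                                 maxDistanceBp = 0, minNegLog10Q = 3) {
    marks <- names(peaks)
    windows <- analysisWindow(genes, promoterBp)
    tkey <- paste0("t", time_h)
    ids <- genes$gene_id
    marked <- matrix(FALSE, length(ids), length(marks),
                     dimnames = list(ids, marks))
    for (m in marks) {
        reps <- peaks[[m]][[tkey]]
        if (is.null(reps) || length(reps) < 2L)
            stop("missing peak replicate(s) for (", m, ", ", time_h,
                 " h): need 2, found ", length(reps))
        assigns <- lapply(reps[1:2], function(pk) {
            pk <- pk[pk$neg_log10_q >= minNegLog10Q]
            assignPeaksToGenes(pk, windows)
        })
        mg <- markedGenes(assigns[[1]], assigns[[2]], maxDistanceBp)
        marked[, m] <- ids %in% mg
    }
    marked
}

#' Exact combination counts over a boolean feature table
#'
#' Partitions genes by the exact subset of features they bear (the Venn /
#' upset accounting): every one of the 2^m subsets is reported, counts sum
#' to the number of genes.
#'
#' @param boolTable Logical matrix genes x features (<= 8 features).
#' @return data.frame \code{combination} (feature names joined by
#'   \code{"+"}; \code{"(none)"} for the empty set) and \code{count},
#'   ordered by subset size then feature order.
#' @export
combinationTable <- function(boolTable) {
    boolTable <- as.matrix(boolTable)
    m <- ncol(boolTable)
    if (m > 8L) stop("more than 8 features (", m, "): 2^m explosion guard")
    feats <- colnames(boolTable)
    if (is.null(feats)) feats <- paste0("F", seq_len(m))
    masks <- 0:(2^m - 1)
    bit <- function(mask) which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    labels <- vapply(masks, function(k) {
        s <- bit(k)
        if (!length(s)) "(none)" else paste(feats[s], collapse = "+")
    }, "")
    geneMask <- as.integer(boolTable %*% 2^(seq_len(m) - 1))
    counts <- tabulate(geneMask + 1L, nbins = 2^m)
    out <- data.frame(combination = labels, count = counts,
                      stringsAsFactors = FALSE)
    out <- out[order(vapply(masks, function(k) length(bit(k)), 0L), masks), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write a marking-state table as TSV
#'
#' @param state A \code{\linkS4class{MarkStateTable}}.
#' @param path Output path.
#' @export
writeStateTable <- function(state, path) {
    lev <- markLevels(state)
    rows <- do.call(rbind, lapply(markNames(state), function(m) {
        df <- data.frame(gene_id = geneIds(state), mark = m,
                         marked = isMarked(state)[, m],
                         stringsAsFactors = FALSE)
        for (t in timePoints(state))
            df[[sprintf("level_t%g", t)]] <- lev[, m, as.character(t)]
        df
    }))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
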