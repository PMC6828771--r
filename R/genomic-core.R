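#' Histone marks analysed by the pipeline
#'
#' The five histone H3 modifications profiled around wounding: the two
#' acetylation marks (H3K9/14ac, here spelled \code{"H3K9K14ac"}, and
#' H3K27ac), the initiation and elongation methylation marks (H3K4me3,
#' H3K36me3) and the Polycomb repressive mark (H3K27me3).
#'
#' @return Character vector of mark names.
#' @export
#' @examples
#' woundMarks()
woundMarks <- function() {
    c("H3K9K14ac", "H3K27ac", "H3K4me3", "H3K36me3", "H3K27me3")
}

.checkGeneModels <- function(gr, gene_id) {
    if (anyDuplicated(gene_id))
        stop("duplicate gene_id: ",
             paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
    str <- as.character(GenomicRanges::strand(gr))
    if (any(str == "*"))
        stop("gene(s) without strand (+/-): ",
             paste(gene_id[str == "*"], collapse = ", "))
    invisible(gr)
}

#' Read gene models from BED6 or GFF3
#'
#' Gene bodies are returned as a \link[GenomicRanges]{GRanges} (1-based,
#' closed intervals, the Bioconductor convention; BED's 0-based half-open
#' coordinates are converted on read). Input order is preserved and the
#' \code{gene_id} becomes the names of the object.
#'
#' @param path Path to a BED6 file or a GFF3 file with \code{gene} features.
#' @param format \code{"auto"} (by extension), \code{"bed"} or \code{"gff3"}.
#' @return \code{GRanges} with metadata column \code{gene_id}; strands are
#'   \code{+} or \code{-} (a \code{.} strand on a gene is an error, as is a
#'   duplicated \code{gene_id}).
#' @export
readGeneModels <- function(path, format = c("auto", "bed", "gff3")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto") {
        format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
                  else "bed"
    }
    if (format == "gff3") {
        gr <- rtracklayer::import(path, format = "gff3")
        gr <- gr[gr$type == "gene"]
        if (length(gr) == 0L) stop("no 'gene' features in ", path)
        ids <- if (!is.null(gr$ID)) as.character(gr$ID)
               else as.character(gr$gene_id)
        if (anyNA(ids)) stop("gene feature without ID attribute in ", path)
        out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                      IRanges::ranges(gr),
                                      strand = GenomicRanges::strand(gr))
    } else {
        lines <- readLines(path)
        lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                       !startsWith(lines, "track")]
        fields <- strsplit(lines, "\t", fixed = TRUE)
        bad <- which(lengths(fields) < 6L)
        if (length(bad))
            stop("line ", bad[1L], ": expected >= 6 tab-separated BED columns")
        start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
        end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
        bad <- which(is.na(start0) | is.na(end0))
        if (length(bad))
            stop("line ", bad[1L], ": non-numeric BED coordinates")
        bad <- which(start0 < 0 | end0 <= start0)
        if (length(bad))
            stop("line ", bad[1L], ": require 0 <= start < end")
        ids <- vapply(fields, `[`, "", 4L)
        out <- GenomicRanges::GRanges(
            vapply(fields, `[`, "", 1L),
            IRanges::IRanges(start = start0 + 1, end = end0),
            strand = vapply(fields, `[`, "", 6L))
    }
    out$gene_id <- ids
    names(out) <- ids
    .checkGeneModels(out, ids)
    out
}

#' Write gene models as BED6
#'
#' Inverse of \code{\link{readGeneModels}} for BED input: coordinates are
#' converted back to 0-based half-open, so a read/write round trip reproduces
#' the file's coordinates and strands exactly.
#'
#' @param genes \code{GRanges} with \code{gene_id} metadata.
#' @param path Output path.
#' @export
writeGeneModels <- function(genes, path) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(genes)),
        start = GenomicRanges::start(genes) - 1L,
        end = GenomicRanges::end(genes),
        name = genes$gene_id,
        score = 0L,
        strand = as.character(GenomicRanges::strand(genes)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read ChIP-seq peak calls (ENCODE narrowPeak / broadPeak)
#'
#' Peaks below the significance threshold are dropped (the analysis considers
#' only peaks with Q < 0.001, i.e. -log10(q) >= 3, by default); the number
#' dropped is reported with a message.
#'
#' @param path narrowPeak (10 columns) or broadPeak (9 columns) file; the
#'   -log10 q-value is column 9 in both.
#' @param mark Mark name recorded on every peak.
#' @param time_h Hours after wounding.
#' @param replicate Replicate index (>= 1).
#' @param minNegLog10Q Retain peaks with \code{neg_log10_q >= minNegLog10Q}.
#' @return \code{GRanges} with metadata \code{mark}, \code{time_h},
#'   \code{replicate}, \code{neg_log10_q}.
#' @export
readPeaks <- function(path, mark, time_h, replicate, minNegLog10Q = 3) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- tryCatch(
        utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE),
        error = function(e) stop("cannot parse ", path, ": ",
                                 conditionMessage(e)))
    if (ncol(tab) < 9L)
        stop(path, ": expected >= 9 columns (narrowPeak/broadPeak), found ",
             ncol(tab))
    if (any(tab[[2L]] < 0) || any(tab[[3L]] <= tab[[2L]]))
        stop(path, ": invalid peak coordinates (need 0 <= start < end)")
    q <- as.numeric(tab[[9L]])
    if (anyNA(q)) stop(path, ": non-numeric qValue column")
    keep <- q >= minNegLog10Q
    if (any(!keep))
        message(sum(!keep), " peak(s) below -log10(q) ", minNegLog10Q,
                " dropped from ", basename(path))
    tab <- tab[keep, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
        tab[[1L]], IRanges::IRanges(start = tab[[2L]] + 1, end = tab[[3L]]))
    gr$name <- as.character(tab[[4L]])
    gr$mark <- mark
    gr$time_h <- time_h
    gr$replicate <- as.integer(replicate)
    gr$neg_log10_q <- q[keep]
    gr
}

#' Strand-aware analysis window (promoter + gene body)
#'
#' Extends each gene body upstream by \code{promoterBp} on the strand-aware
#' side (5' end), clamped at the chromosome start. Read depth for marks and
#' H3 is averaged over this window.
#'
#' @param genes \code{GRanges} gene bodies with strand \code{+}/\code{-}.
#' @param promoterBp Promoter length in bp (default 1000).
#' @return \code{GRanges} of windows, same names/order as \code{genes}.
#' @export
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 7000), "+")
#' analysisWindow(g)  # 4001-7000
analysisWindow <- function(genes, promoterBp = 1000) {
    if (promoterBp < 0) stop("promoterBp must be >= 0")
    str <- as.character(GenomicRanges::strand(genes))
    if (any(str == "*")) stop("genes must be stranded (+/-)")
    win <- genes
    plus <- str == "+"
    GenomicRanges::start(win)[plus] <-
        pmax(1L, GenomicRanges::start(genes)[plus] - as.integer(promoterBp))
    GenomicRanges::end(win)[!plus] <-
        GenomicRanges::end(genes)[!plus] + as.integer(promoterBp)
    win
}

#' Assign peaks to their closest gene window
#'
#' Reproduces BEDTools \code{closest} semantics: each peak is assigned to the
#' gene whose analysis window is nearest (distance 0 when overlapping,
#' otherwise the gap in bp); on exact distance ties the peak is assigned to
#' every tied gene. Peaks on chromosomes absent from the gene set are
#' returned unassigned (\code{NA}), not an error.
#'
#' @param peaks \code{GRanges} of peaks.
#' @param windows \code{GRanges} of gene analysis windows with
#'   \code{gene_id} metadata (see \code{\link{analysisWindow}}).
#' @return data.frame with one row per (peak, assigned gene):
#'   \code{peak} (index into \code{peaks}), \code{peak_name} (if present),
#'   \code{gene_id}, \code{distance_bp}. Unassigned peaks have \code{NA}
#'   gene_id/distance.
#' @export
assignPeaksToGenes <- function(peaks, windows) {
    if (length(windows) == 0L) stop("empty gene window set")
    near <- GenomicRanges::distanceToNearest(peaks, windows,
                                             ignore.strand = TRUE)
    dStar <- rep(NA_real_, length(peaks))
    dStar[S4Vectors::queryHits(near)] <- S4Vectors::mcols(near)$distance
    ## recover every window at the minimal distance (ties on either side;
    ## distanceToNearest alone does not report cross-side ties)
    maxD <- max(c(0, dStar), na.rm = TRUE)
    fo <- GenomicRanges::findOverlaps(peaks, windows, maxgap = maxD,
                                      ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(fo)
    si <- S4Vectors::subjectHits(fo)
    d <- GenomicRanges::distance(peaks[qi], windows[si],
                                 ignore.strand = TRUE)
    keep <- !is.na(dStar[qi]) & d == dStar[qi]
    qi <- qi[keep]; si <- si[keep]
    out <- data.frame(
        peak = qi,
        gene_id = windows$gene_id[si],
        distance_bp = dStar[qi],
        stringsAsFactors = FALSE)
    missing <- setdiff(seq_along(peaks), qi)
    if (length(missing))
        out <- rbind(out, data.frame(peak = missing, gene_id = NA_character_,
                                     distance_bp = NA_real_))
    out <- out[order(out$peak, out$gene_id), , drop = FALSE]
    if (!is.null(peaks$name))
        out <- cbind(out[1L], peak_name = peaks$name[out$peak],
                     out[-1L])
    rownames(out) <- NULL
    out
}

#' Genes with replicate-consistent peaks
#'
#' A gene counts as marked only when it has at least one assigned peak within
#' \code{maxDistanceBp} of its analysis window in \emph{both} replicates
#' (only genes associated with a peak in both replicates are considered).
#'
#' @param assignRep1,assignRep2 Assignment tables from
#'   \code{\link{assignPeaksToGenes}}, one per replicate.
#' @param maxDistanceBp Maximal peak-to-window distance (default 0 =
#'   overlap required).
#' @return Character vector of gene ids (sorted).
#' @export
markedGenes <- function(assignRep1, assignRep2, maxDistanceBp = 0) {
    hit <- function(a) {
        ok <- !is.na(a$gene_id) & a$distance_bp <= maxDistanceBp
        unique(a$gene_id[ok])
    }
    sort(intersect(hit(assignRep1), hit(assignRep2)))
}

#' Write a peak-to-gene assignment table as TSV
#'
#' @param assignments data.frame from \code{\link{assignPeaksToGenes}}.
#' @param path Output path.
#' @export
writeAssignments <- function(assignments, path) {
    utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
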