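# Small in-code fixtures shared across test files.

writeBedFixture <- function(lines, path = tempfile(fileext = ".bed")) {
    writeLines(lines, path)
    path
}

writePeakFixture <- function(df, path = tempfile(fileext = ".narrowPeak")) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    path
}

# long coverage rows for one gene/track/time across replicates
covRows <- function(gene, track, time, depths) {
    data.frame(gene_id = gene, track = track, time_h = time,
               replicate = seq_along(depths), mean_depth = depths,
               stringsAsFactors = FALSE)
}

# 1-based closed gap distance between two intervals (independent oracle)
gapDistance <- function(s1, e1, s2, e2) {
    max(0L, max(s1, s2) - min(e1, e2) - 1L)
}

grWindows <- function(starts, ends, ids, strand = "+") {
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = starts, end = ends), strand = strand)
    gr$gene_id <- ids
    names(gr) <- ids
    gr
}

# shared default-conditions simulation + pipeline run, computed once
.accCache <- new.env(parent = emptyenv())
acceptanceRun <- function() {
    if (!is.null(.accCache$res)) return(.accCache$res)
    cfg <- woundSimConfig(seed = 101L)
    dir <- file.path(tempdir(), "woundchrom-acc-sim")
    out <- file.path(tempdir(), "woundchrom-acc-out")
    sim <- suppressMessages(simulateWoundDataset(cfg, dir))
    pc <- pipelineConfig(dir, out, seed = 101L)
    res <- suppressWarnings(suppressMessages(runPipeline(pc, quiet = TRUE)))
    .accCache$res <- list(cfg = cfg, dir = dir, out = out,
                          truth = sim$truth, run = res)
    .accCache$res
}
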