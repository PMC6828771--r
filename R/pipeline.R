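## End-to-end orchestration over a file-backed dataset, and the
## treatment-versus-control re-use of the same stages.

#' Pipeline configuration
#'
#' Collects every threshold of the analysis with the published defaults:
#' FC > 1.5 and FDR < 0.001 for wound-responsive genes, |M'| > 0.15 for
#' marking changes, peak Q < 0.001 (-log10 q >= 3), 1 kb promoter windows,
#' k = 8 timing clusters.
#'
#' @param inputDir Directory with \code{genes.bed}, \code{counts.tsv},
#'   \code{coverage.tsv} and \code{peaks_<mark>_t<time>_rep<k>.narrowPeak}
#'   files (the layout \code{\link{simulateWoundDataset}} writes).
#' @param outputDir Output directory for the result bundle.
#' @param fcThreshold,fdrThreshold Wound-responsive cuts.
#' @param mThreshold Differential-marking M-value cut.
#' @param minNegLog10Q Peak significance filter.
#' @param promoterBp Analysis-window promoter length (bp).
#' @param maxDistanceBp Peak-to-window distance cap for marking calls.
#' @param k Number of timing clusters.
#' @param loessSpan Span of the rank-LOESS timing fit.
#' @param seed Seed for the clustering initialisation.
#' @return A \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(inputDir, outputDir, fcThreshold = 1.5,
                           fdrThreshold = 0.001, mThreshold = 0.15,
                           minNegLog10Q = 3, promoterBp = 1000,
                           maxDistanceBp = 0, k = 8, loessSpan = 0.3,
                           seed = 1) {
    stopifnot(fcThreshold > 1, fdrThreshold > 0, fdrThreshold < 1,
              mThreshold > 0, promoterBp >= 0, k >= 2)
    structure(list(inputDir = inputDir, outputDir = outputDir,
                   fcThreshold = fcThreshold, fdrThreshold = fdrThreshold,
                   mThreshold = mThreshold, minNegLog10Q = minNegLog10Q,
                   promoterBp = promoterBp, maxDistanceBp = maxDistanceBp,
                   k = k, loessSpan = loessSpan, seed = seed),
              class = "PipelineConfig")
}

.readPeakDir <- function(dir, minNegLog10Q) {
    files <- list.files(dir, pattern = "^peaks_.*\\.narrowPeak$")
    if (!length(files)) stop("no peaks_*.narrowPeak files in ", dir)
    m <- regmatches(files,
        regexec("^peaks_(.+)_t([0-9.]+)_rep([0-9]+)\\.narrowPeak$", files))
    if (any(lengths(m) != 4L))
        stop("unparseable peak file name(s): ",
             paste(files[lengths(m) != 4L], collapse = ", "))
    peaks <- list()
    for (i in seq_along(files)) {
        mark <- m[[i]][2]; t <- as.numeric(m[[i]][3])
        r <- as.integer(m[[i]][4])
        pk <- readPeaks(file.path(dir, files[i]), mark, t, r,
                        minNegLog10Q = minNegLog10Q)
        peaks[[mark]][[paste0("t", t)]][[r]] <- pk
    }
    peaks
}

.writeTsv <- function(df, dir, name, written) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(written, path)
}

.writeLines2 <- function(x, dir, name, written) {
    path <- file.path(dir, name)
    writeLines(x, path)
    c(written, path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: gene/peak/coverage input parsing; TMM + exact-test
#' differential expression of every time against 0 h; wound-responsive set
#' calls; timing clustering; the pre-wound marking-state table;
#' MA-rescaled differential marking; enrichment statistics (per-mark,
#' co-marking, categories within clusters); and the timing-integration
#' analyses (rank-LOESS, PCA, precedence, temporal profiles, mark/expression
#' correlations). Writes one TSV per result plus a \code{manifest.json}
#' recording the configuration, per-stage row counts and output checksums;
#' re-running with identical inputs and config reproduces the bundle
#' byte-identically. Any stage error aborts with the stage name and removes
#' partial outputs.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list of the in-memory stage results (\code{de},
#'   \code{responsive}, \code{clusters}, \code{state}, \code{marking},
#'   \code{enrichment}, \code{precedence}, \code{manifest}, ...).
#' @export
runPipeline <- function(config, quiet = FALSE) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    written <- character()
    say <- function(...) if (!quiet) message(...)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            unlink(written)
            stop("stage '", name, "': ", conditionMessage(e),
                 call. = FALSE)
        })
    }

    inputs <- stage("read_inputs", {
        genes <- readGeneModels(file.path(config$inputDir, "genes.bed"))
        se <- readCounts(file.path(config$inputDir, "counts.tsv"))
        coverage <- readCoverage(file.path(config$inputDir, "coverage.tsv"))
        peaks <- .readPeakDir(config$inputDir, config$minNegLog10Q)
        list(genes = genes, se = se, coverage = coverage, peaks = peaks)
    })
    say("read_inputs: ", length(inputs$genes), " genes, ",
        ncol(inputs$se), " RNA samples, ", nrow(inputs$coverage),
        " coverage rows")

    expr <- stage("expression", {
        factors <- normalizeLibraries(inputs$se)
        de <- testDEAllTimes(inputs$se, factors = factors)
        resp <- callWoundResponsive(de, config$fcThreshold,
                                    config$fdrThreshold)
        clusters <- clusterInduced(inputs$se, resp$induced,
                                   factors = factors, k = config$k,
                                   seed = config$seed)
        list(factors = factors, de = de, resp = resp, clusters = clusters)
    })
    say("expression: ", length(expr$resp$induced), " induced, ",
        length(expr$resp$repressed), " repressed")

    chrom <- stage("chromatin_states", {
        state <- buildStateTable(inputs$peaks, inputs$coverage,
                                 inputs$genes,
                                 promoterBp = config$promoterBp,
                                 maxDistanceBp = config$maxDistanceBp,
                                 minNegLog10Q = config$minNegLog10Q)
        chipTimes <- timePoints(state)
        markedByTime <- lapply(stats::setNames(chipTimes,
                                               paste0("t", chipTimes)),
            function(t) markedAtTime(inputs$peaks, inputs$genes, t,
                                     config$promoterBp,
                                     config$maxDistanceBp,
                                     config$minNegLog10Q))
        list(state = state, markedByTime = markedByTime)
    })
    say("chromatin_states: ", sum(isMarked(chrom$state)),
        " gene-mark pre-wound calls")

    marking <- stage("differential_marking", {
        mk <- differentialMarking(markLevels(chrom$state),
                                  chrom$markedByTime,
                                  threshold = config$mThreshold)
        list(calls = mk, changes = firstChangeTimes(mk))
    })
    say("differential_marking: ", sum(marking$calls$call != "none"),
        " gain/loss calls")

    enr <- stage("enrichment", {
        universe <- geneIds(chrom$state)
        induced <- intersect(expr$resp$induced, universe)
        repressed <- intersect(expr$resp$repressed, universe)
        me <- rbind(cbind(set = "induced",
                          markEnrichment(chrom$state, induced, universe)),
                    cbind(set = "repressed",
                          markEnrichment(chrom$state, repressed, universe)))
        co <- cbind(set = "induced",
                    comarkEnrichment(chrom$state, induced))
        acCat <- classifyAcCategory(chrom$state, marking$changes,
                                    genes = induced)
        catVec <- stats::setNames(acCat$category, acCat$gene_id)
        labs <- expr$clusters$labels[names(catVec)]
        ce <- clusterCategoryEnrichment(catVec, labs[!is.na(labs)])
        list(marks = me, comarks = co, acCat = acCat, clusterCat = ce)
    })
    say("enrichment: ", nrow(enr$marks), " mark rows, ",
        nrow(enr$clusterCat), " cluster-category rows")

    dyn <- stage("dynamics", {
        lev <- markLevels(chrom$state)
        induced <- names(expr$clusters$labels)
        loess <- lapply(markNames(chrom$state), function(m) {
            lv <- stats::setNames(lev[induced, m, "0"], induced)
            rankLoessTiming(lv, expr$clusters$labels,
                            span = config$loessSpan)
        })
        names(loess) <- markNames(chrom$state)
        counts <- SummarizedExperiment::assay(inputs$se, "counts")
        meta <- as.data.frame(SummarizedExperiment::colData(inputs$se))
        eff <- colSums(counts) * expr$factors
        norm <- sweep(counts, 2, stats::median(eff) / eff, `*`)
        rtimes <- sort(unique(meta$time_h))
        exprMat <- vapply(rtimes, function(t)
            rowMeans(log2(norm[, meta$time_h == t, drop = FALSE] + 1)),
            numeric(nrow(norm)))
        colnames(exprMat) <- rtimes
        pca <- timingPCA(lev[induced, , "0"], expr$clusters$labels,
                         rank(exprMat[induced, "0"]))
        prec <- precedenceCounts(marking$changes, genes = induced)
        groups <- stats::setNames(enr$acCat$category, enr$acCat$gene_id)
        prof <- temporalProfiles(lev[induced, , , drop = FALSE], groups,
                                 exprMat[induced, , drop = FALSE])
        corr <- markingExpressionCorrelation(marking$calls, expr$de)
        list(loess = loess, pca = pca, prec = prec, prof = prof,
             corr = corr, exprMat = exprMat)
    })
    say("dynamics: precedence ",
        paste(names(dyn$prec$counts), dyn$prec$counts, collapse = ", "))

    manifest <- stage("write_outputs", {
        od <- config$outputDir
        written <- .writeTsv(expr$de, od, "de_results.tsv", written)
        written <- .writeLines2(expr$resp$induced, od, "induced.txt",
                                 written)
        written <- .writeLines2(expr$resp$repressed, od, "repressed.txt",
                                 written)
        written <- .writeTsv(data.frame(
            gene_id = names(expr$clusters$labels),
            cluster = unname(expr$clusters$labels)), od, "clusters.tsv",
            written)
        writeStateTable(chrom$state, file.path(od, "state_table.tsv"))
        written <- c(written, file.path(od, "state_table.tsv"))
        written <- .writeTsv(marking$calls, od, "marking_changes.tsv",
                              written)
        written <- .writeTsv(rbind(
            cbind(analysis = "mark", enr$marks[setdiff(names(enr$marks),
                                                       "pct_of_marked")]),
            cbind(analysis = "comark", enr$comarks)), od,
            "enrichment.tsv", written)
        written <- .writeTsv(enr$clusterCat, od,
                              "cluster_category_enrichment.tsv", written)
        written <- .writeTsv(enr$acCat, od, "ac_categories.tsv", written)
        written <- .writeTsv(dyn$prec$calls, od, "precedence.tsv", written)
        written <- .writeTsv(data.frame(
            category = names(dyn$prec$counts),
            count = unname(dyn$prec$counts)), od, "precedence_counts.tsv",
            written)
        rho <- data.frame(mark = names(dyn$loess),
                          rho = vapply(dyn$loess, `[[`, 0, "rho"))
        written <- .writeTsv(rho, od, "loess_rho.tsv", written)
        curves <- do.call(rbind, lapply(names(dyn$loess), function(m)
            cbind(mark = m, dyn$loess[[m]]$curve)))
        written <- .writeTsv(curves, od, "loess_curves.tsv", written)
        written <- .writeTsv(data.frame(
            variable = rownames(dyn$pca$loadings),
            dyn$pca$loadings), od, "pca_loadings.tsv", written)
        written <- .writeTsv(data.frame(
            pc = seq_along(dyn$pca$varExplained),
            var_explained = dyn$pca$varExplained), od,
            "pca_variance.tsv", written)
        written <- .writeTsv(dyn$corr, od, "correlations.tsv", written)
        written <- .writeTsv(dyn$prof$marks, od, "profiles.tsv", written)

        files <- sort(basename(written))
        manifest <- list(
            config = unclass(config),
            stages = list(
                genes = length(inputs$genes),
                rna_samples = ncol(inputs$se),
                induced = length(expr$resp$induced),
                repressed = length(expr$resp$repressed),
                marking_calls = sum(marking$calls$call != "none"),
                precedence = as.list(dyn$prec$counts)),
            outputs = as.list(tools::md5sum(file.path(od, files))))
        names(manifest$outputs) <- files
        jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE)
        manifest
    })
    say("pipeline complete: ", length(manifest$outputs), " output files")
    invisible(list(inputs = inputs, factors = expr$factors, de = expr$de,
                   responsive = expr$resp, clusters = expr$clusters,
                   state = chrom$state, markedByTime = chrom$markedByTime,
                   marking = marking$calls, changes = marking$changes,
                   enrichment = enr, dynamics = dyn, manifest = manifest))
}

#' Differential expression between two arms at matched times
#'
#' Same conditional NB exact test as \code{\link{testDE}}, contrasting
#' treated against control samples at each shared time point; the
#' dispersion is pooled across every arm x time group.
#'
#' @param controlSE,treatedSE \code{SummarizedExperiment}s with counts and
#'   \code{time_h} colData over the same genes.
#' @param times Times to contrast (default: all shared).
#' @param enumLimit See \code{\link{testDE}}.
#' @return data.frame as \code{\link{testDE}} (positive logFC = higher in
#'   the treated arm), one block per time.
#' @export
treatmentDE <- function(controlSE, treatedSE, times = NULL,
                        enumLimit = 5000) {
    cc <- .countsAndMeta(controlSE); tt <- .countsAndMeta(treatedSE)
    if (!identical(rownames(cc$counts), rownames(tt$counts)))
        stop("arms must cover the same genes in the same order")
    shared <- intersect(unique(cc$meta$time_h), unique(tt$meta$time_h))
    if (is.null(times)) times <- sort(shared)
    missing <- setdiff(times, shared)
    if (length(missing))
        stop("time(s) missing from one arm: ",
             paste(missing, collapse = ", "))
    counts <- cbind(cc$counts, tt$counts)
    arm <- rep(c("control", "treated"),
               c(ncol(cc$counts), ncol(tt$counts)))
    timev <- c(cc$meta$time_h, tt$meta$time_h)
    factors <- normalizeLibraries(counts)
    eff <- colSums(counts) * factors
    common <- stats::median(eff)
    adj <- sweep(counts, 2, common / eff, `*`)
    phi <- .estimateDispersion(adj, data.frame(
        time_h = paste(arm, timev)))   # pooled over arm x time groups
    adjInt <- round(adj)
    do.call(rbind, lapply(times, function(t) {
        colsA <- which(arm == "control" & timev == t)
        colsB <- which(arm == "treated" & timev == t)
        if (length(colsA) < 2L || length(colsB) < 2L)
            stop("need >= 2 replicates per arm at ", t, " h")
        yA <- rowSums(adjInt[, colsA, drop = FALSE])
        yB <- rowSums(adjInt[, colsB, drop = FALSE])
        mA <- rowMeans(adj[, colsA, drop = FALSE])
        mB <- rowMeans(adj[, colsB, drop = FALSE])
        p <- vapply(seq_len(nrow(counts)), function(i)
            .condPValue(yA[i], yB[i], length(colsA), length(colsB),
                        phi[i], enumLimit), 0)
        untestable <- (yA + yB) == 0
        data.frame(gene_id = rownames(counts), time_h = t,
                   logFC = ifelse(untestable, 0,
                                  log2((mB + 0.5) / (mA + 0.5))),
                   p_value = p, fdr = stats::p.adjust(p, "BH"),
                   untestable = untestable, row.names = NULL,
                   stringsAsFactors = FALSE)
    }))
}

#' Treatment-versus-control contrast mode
#'
#' Re-uses every stage on a treated arm against a control arm: per-time
#' DE contrasts (treated vs control), per-time marking contrasts (M values
#' of treated over control levels, rescaled on genes marked in both arms),
#' and the triple-overlap report — wound-induced (control arm, each time
#' vs 0 h) x treatment-down-regulated x treatment-decreased acetylation —
#' with representation factors.
#'
#' @param controlDir,treatedDir Input directories (layout as
#'   \code{\link{runPipeline}}).
#' @param outputDir Output directory.
#' @param config A \code{\link{pipelineConfig}} supplying thresholds (its
#'   inputDir/outputDir fields are ignored here); defaults used when NULL.
#' @param acMark Acetylation mark for the decreased-ac set.
#' @return Invisibly: list with \code{de} (treated vs control),
#'   \code{marking}, \code{sets} (induced, down, acDecreased), \code{venn}
#'   (overlap counts and representation factors), \code{manifest}.
#' @export
runTreatmentContrast <- function(controlDir, treatedDir, outputDir,
                                 config = NULL, acMark = "H3K9K14ac") {
    if (is.null(config))
        config <- pipelineConfig(controlDir, outputDir)
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    genes <- readGeneModels(file.path(controlDir, "genes.bed"))
    seC <- readCounts(file.path(controlDir, "counts.tsv"))
    seT <- readCounts(file.path(treatedDir, "counts.tsv"))
    covC <- readCoverage(file.path(controlDir, "coverage.tsv"))
    covT <- readCoverage(file.path(treatedDir, "coverage.tsv"))
    pkC <- .readPeakDir(controlDir, config$minNegLog10Q)
    pkT <- .readPeakDir(treatedDir, config$minNegLog10Q)

    ## wound-induced genes from the control arm (each time vs 0 h)
    deWound <- testDEAllTimes(seC)
    induced <- callWoundResponsive(deWound, config$fcThreshold,
                                   config$fdrThreshold)$induced

    de <- treatmentDE(seC, seT)
    lfc <- log2(config$fcThreshold)
    down <- sort(unique(de$gene_id[de$logFC < -lfc &
                                   de$fdr < config$fdrThreshold]))

    levC <- enrichmentLevels(covC)
    levT <- enrichmentLevels(covT)
    chipTimes <- intersect(as.numeric(dimnames(levC)[[3]]),
                           as.numeric(dimnames(levT)[[3]]))
    if (!length(chipTimes)) stop("no shared ChIP times between arms")
    marks <- dimnames(levC)[[2]]
    mk <- list()
    for (t in chipTimes) {
        mC <- markedAtTime(pkC, genes, t, config$promoterBp,
                           config$maxDistanceBp, config$minNegLog10Q)
        mT <- markedAtTime(pkT, genes, t, config$promoterBp,
                           config$maxDistanceBp, config$minNegLog10Q)
        for (m in marks) {
            ma <- maTransform(levT[, m, as.character(t)],
                              levC[, m, as.character(t)])
            rs <- rescaleMA(ma$M, ma$A, mC[, m] & mT[, m])
            mk[[paste(m, t)]] <- data.frame(
                gene_id = dimnames(levC)[[1]], mark = m, time_h = t,
                M = ma$M, A = ma$A, M_rescaled = rs$M_rescaled,
                call = callMarkingChanges(rs$M_rescaled,
                                          config$mThreshold),
                stringsAsFactors = FALSE)
        }
    }
    marking <- do.call(rbind, mk)
    rownames(marking) <- NULL
    acDec <- sort(unique(marking$gene_id[marking$mark == acMark &
                                         marking$call == "loss"]))

    universe <- genes$gene_id
    indDown <- intersect(induced, down)
    triple <- intersect(indDown, acDec)
    venn <- rbind(
        representationFactor(length(indDown), length(induced),
                             length(down), length(universe),
                             category = "induced_x_down"),
        representationFactor(length(triple), length(indDown),
                             length(acDec), length(universe),
                             category = "induced_x_down_x_acDecreased"))

    utils::write.table(de, file.path(outputDir, "treatment_de.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(marking,
                       file.path(outputDir, "treatment_marking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(venn, file.path(outputDir, "treatment_venn.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
        thresholds = list(fc = config$fcThreshold,
                          fdr = config$fdrThreshold,
                          m = config$mThreshold),
        sets = list(induced = length(induced), down = length(down),
                    ac_decreased = length(acDec),
                    induced_x_down = length(indDown),
                    triple = length(triple)))
    jsonlite::write_json(manifest,
                         file.path(outputDir, "treatment_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(de = de, marking = marking,
                   sets = list(induced = induced, down = down,
                               acDecreased = acDec),
                   venn = venn, manifest = manifest))
}
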