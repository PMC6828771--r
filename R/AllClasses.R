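#' @import methods
NULL

.WC_CLASSES <- c("rapid_preacetylated", "slow_gain_ac_then_me3",
                 "prc2_bivalent_induced", "prc2_only_silent",
                 "repressed_lose_ac", "stable")

#' Configuration for the synthetic wound time-course generator
#'
#' Holds every knob of the planted-truth simulator: design (gene number,
#' sampling times, replicates), class mixture, and noise model. The defaults
#' are the study conditions the whole test battery runs under; see the
#' methods vignette for their rationale.
#'
#' @slot nGenes Number of genes (default 2000).
#' @slot rnaTimes RNA-seq sampling times in hours (default 0,1,3,6,12).
#' @slot chipTimes ChIP-seq sampling times in hours (default 0,1,3,6).
#' @slot nRnaReps RNA-seq replicates per time (default 3).
#' @slot nChipReps ChIP-seq replicates per time (default 2).
#' @slot classProportions Named fractions over the six gene classes; must
#'   sum to 1.
#' @slot nbDispersion Negative-binomial dispersion phi of the counts
#'   (default 0.1).
#' @slot baselineMeanLogSd SD (natural log) of the per-gene baseline
#'   expression mean around its class centre (default 0.5).
#' @slot markRatioMarked,markRatioUnmarked Mark/H3 coverage ratio for
#'   marked (2.5) and unmarked (0.4) genes.
#' @slot gainFold Multiplicative ratio change planted at a gain (or its
#'   inverse at a loss); default 2.
#' @slot peakDropoutProb Per-replicate probability that a genuine peak is
#'   not emitted (default 0.05).
#' @slot noiseSdLog SD (natural log) of the multiplicative coverage noise
#'   (default 0.05).
#' @slot seed Integer seed; the generator is fully deterministic given it.
#' @export
setClass("WoundSimConfig",
    representation(nGenes = "integer", rnaTimes = "numeric",
                   chipTimes = "numeric", nRnaReps = "integer",
                   nChipReps = "integer", classProportions = "numeric",
                   nbDispersion = "numeric", baselineMeanLogSd = "numeric",
                   markRatioMarked = "numeric", markRatioUnmarked = "numeric",
                   gainFold = "numeric", peakDropoutProb = "numeric",
                   noiseSdLog = "numeric", seed = "integer"))

setValidity("WoundSimConfig", function(object) {
    msg <- character()
    p <- object@classProportions
    if (!setequal(names(p), .WC_CLASSES))
        msg <- c(msg, paste("classProportions must be named over:",
                            paste(.WC_CLASSES, collapse = ", ")))
    if (abs(sum(p) - 1) > 1e-9)
        msg <- c(msg, sprintf("class proportions sum to %.12f, not 1", sum(p)))
    if (any(p < 0)) msg <- c(msg, "negative class proportion")
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
    if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be > 0")
    if (object@peakDropoutProb < 0 || object@peakDropoutProb > 1)
        msg <- c(msg, "peakDropoutProb must be in [0,1]")
    if (object@markRatioMarked <= 0 || object@markRatioUnmarked <= 0)
        msg <- c(msg, "mark ratios must be > 0")
    if (object@gainFold <= 1) msg <- c(msg, "gainFold must be > 1")
    if (object@noiseSdLog < 0) msg <- c(msg, "noiseSdLog must be >= 0")
    if (!0 %in% object@rnaTimes || !0 %in% object@chipTimes)
        msg <- c(msg, "time vectors must include 0 h")
    if (length(msg)) msg else TRUE
})

#' @describeIn WoundSimConfig-class Constructor with the default study
#'   conditions.
#' @param nGenes,rnaTimes,chipTimes,nRnaReps,nChipReps,classProportions
#'   See slots.
#' @param nbDispersion,baselineMeanLogSd,markRatioMarked,markRatioUnmarked
#'   See slots.
#' @param gainFold,peakDropoutProb,noiseSdLog,seed See slots.
#' @return A validated \code{WoundSimConfig}.
#' @export
#' @examples
#' woundSimConfig(nGenes = 200, seed = 7)
woundSimConfig <- function(nGenes = 2000,
                           rnaTimes = c(0, 1, 3, 6, 12),
                           chipTimes = c(0, 1, 3, 6),
                           nRnaReps = 3, nChipReps = 2,
                           classProportions = c(
                               rapid_preacetylated = 0.10,
                               slow_gain_ac_then_me3 = 0.15,
                               prc2_bivalent_induced = 0.05,
                               prc2_only_silent = 0.15,
                               repressed_lose_ac = 0.15,
                               stable = 0.40),
                           nbDispersion = 0.1,
                           baselineMeanLogSd = 0.5,
                           markRatioMarked = 2.5,
                           markRatioUnmarked = 0.4,
                           gainFold = 2.0,
                           peakDropoutProb = 0.05,
                           noiseSdLog = 0.05,
                           seed = 1L) {
    new("WoundSimConfig", nGenes = as.integer(nGenes), rnaTimes = rnaTimes,
        chipTimes = chipTimes, nRnaReps = as.integer(nRnaReps),
        nChipReps = as.integer(nChipReps),
        classProportions = classProportions[.WC_CLASSES],
        nbDispersion = nbDispersion, baselineMeanLogSd = baselineMeanLogSd,
        markRatioMarked = markRatioMarked,
        markRatioUnmarked = markRatioUnmarked, gainFold = gainFold,
        peakDropoutProb = peakDropoutProb, noiseSdLog = noiseSdLog,
        seed = as.integer(seed))
}

setMethod("show", "WoundSimConfig", function(object) {
    cat("WoundSimConfig:", object@nGenes, "genes, seed", object@seed, "\n")
    cat("  RNA times (h):", paste(object@rnaTimes, collapse = ","),
        "x", object@nRnaReps, "reps;  ChIP times (h):",
        paste(object@chipTimes, collapse = ","), "x", object@nChipReps,
        "reps\n")
    cat("  classes:",
        paste(sprintf("%s=%.2f", names(object@classProportions),
                      object@classProportions), collapse = " "), "\n")
    cat(sprintf("  phi=%.3g, ratios %0.2g/%0.2g, gainFold=%g, dropout=%g, noiseSdLog=%g\n",
        object@nbDispersion, object@markRatioMarked, object@markRatioUnmarked,
        object@gainFold, object@peakDropoutProb, object@noiseSdLog))
})

#' Per-gene marking state and H3-normalized enrichment levels
#'
#' The central chromatin-state container: a boolean replicate-intersected
#' marking call per gene x mark (at the reference time, normally 0 h) and
#' the mark/H3 relative enrichment level per gene x mark x time.
#'
#' @slot genes Character gene ids.
#' @slot marks Character mark names.
#' @slot times Numeric ChIP times (h).
#' @slot marked Logical matrix, genes x marks.
#' @slot levels Numeric array, genes x marks x times (mark/H3 ratios,
#'   pseudo-counted, finite, >= 0).
#' @slot markedTime Time (h) at which the marking calls were made.
#' @export
setClass("MarkStateTable",
    representation(genes = "character", marks = "character",
                   times = "numeric", marked = "matrix", levels = "array",
                   markedTime = "numeric"))

setValidity("MarkStateTable", function(object) {
    msg <- character()
    d <- dim(object@levels)
    if (!identical(d, c(length(object@genes), length(object@marks),
                        length(object@times))))
        msg <- c(msg, "levels array dimensions do not match genes/marks/times")
    if (!identical(dim(object@marked),
                   c(length(object@genes), length(object@marks))))
        msg <- c(msg, "marked matrix dimensions do not match genes/marks")
    if (!is.logical(object@marked)) msg <- c(msg, "marked must be logical")
    if (any(!is.finite(object@levels)) || any(object@levels < 0))
        msg <- c(msg, "levels must be finite and >= 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "MarkStateTable", function(object) {
    cat("MarkStateTable:", length(object@genes), "genes x",
        length(object@marks), "marks, levels at",
        paste(object@times, collapse = ","), "h\n")
    cat("  marked (replicate-intersected peaks at", object@markedTime, "h):\n")
    print(colSums(object@marked))
})

#' @rdname MarkStateTable-class
#' @param x A \code{MarkStateTable}.
#' @export
setGeneric("isMarked", function(x) standardGeneric("isMarked"))
#' @rdname MarkStateTable-class
#' @export
setMethod("isMarked", "MarkStateTable", function(x) x@marked)

#' @rdname MarkStateTable-class
#' @export
setGeneric("markLevels", function(x) standardGeneric("markLevels"))
#' @rdname MarkStateTable-class
#' @export
setMethod("markLevels", "MarkStateTable", function(x) x@levels)

#' @rdname MarkStateTable-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname MarkStateTable-class
#' @export
setMethod("geneIds", "MarkStateTable", function(x) x@genes)

#' @rdname MarkStateTable-class
#' @export
setGeneric("markNames", function(x) standardGeneric("markNames"))
#' @rdname MarkStateTable-class
#' @export
setMethod("markNames", "MarkStateTable", function(x) x@marks)

#' @rdname MarkStateTable-class
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))
#' @rdname MarkStateTable-class
#' @export
setMethod("timePoints", "MarkStateTable", function(x) x@times)
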