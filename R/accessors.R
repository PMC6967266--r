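#' @name CohortExperiment-accessors
#' @title Accessors for CohortExperiment objects
#' @param x a [CohortExperiment-class].
#' @description \code{cohortId} and \code{platformTag} return the cohort
#'   identity; \code{exprs} the log2 genes x samples matrix;
#'   \code{classLabels} the per-sample tumor/normal factor;
#'   \code{samplePairing} the partner-id vector (all \code{NA} when the
#'   design is unpaired); \code{isPaired} whether any pairing is present.
NULL

#' @rdname CohortExperiment-accessors
#' @export
setGeneric("cohortId", function(x) standardGeneric("cohortId"))
#' @rdname CohortExperiment-accessors
#' @export
setMethod("cohortId", "CohortExperiment", function(x) x@cohortId)

#' @rdname CohortExperiment-accessors
#' @export
setGeneric("platformTag", function(x) standardGeneric("platformTag"))
#' @rdname CohortExperiment-accessors
#' @export
setMethod("platformTag", "CohortExperiment", function(x) x@platformTag)

#' @rdname CohortExperiment-accessors
#' @export
setGeneric("exprs", function(x) standardGeneric("exprs"))
#' @rdname CohortExperiment-accessors
#' @export
setMethod("exprs", "CohortExperiment",
          function(x) SummarizedExperiment::assay(x, "exprs"))

#' @rdname CohortExperiment-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname CohortExperiment-accessors
#' @export
setMethod("classLabels", "CohortExperiment", function(x)
  factor(as.character(x$label), levels = c("normal", "tumor", "unknown")))

#' @rdname CohortExperiment-accessors
#' @export
setGeneric("samplePairing", function(x) standardGeneric("samplePairing"))
#' @rdname CohortExperiment-accessors
#' @export
setMethod("samplePairing", "CohortExperiment", function(x) {
  p <- x$pairId
  if (is.null(p)) p <- rep(NA_character_, ncol(x))
  names(p) <- colnames(x)
  p
})

#' @rdname CohortExperiment-accessors
#' @export
setGeneric("isPaired", function(x) standardGeneric("isPaired"))
#' @rdname CohortExperiment-accessors
#' @export
setMethod("isPaired", "CohortExperiment",
          function(x) any(!is.na(samplePairing(x))))

setMethod("show", "CohortExperiment", function(object) {
  lab <- table(as.character(object$label))
  cat("CohortExperiment '", object@cohortId, "' (",
      object@platformTag, ")\n", sep = "")
  cat(" ", nrow(object), "genes x", ncol(object), "samples;",
      paste(names(lab), lab, sep = "=", collapse = ", "),
      if (isPaired(object)) "; paired design" else "", "\n")
})

setMethod("show", "StumpModel", function(object) {
  cat("StumpModel: gene", object@gene,
      if (object@direction == "up") "> " else "< ",
      format(object@threshold, digits = 4), "=> tumor",
      if (object@degenerate) "(degenerate: constant gene)" else "", "\n")
})

setMethod("show", "PanelModel", function(object) {
  cat("PanelModel [", object@family, "] on panel: ",
      paste(object@features, collapse = ", "), "\n",
      "  10-fold CV AUROC ", sprintf("%.3f", object@cvAurocMean),
      " (sd ", sprintf("%.3f", object@cvAurocSd), "), trained on '",
      object@trainCohort, "'\n", sep = "")
})

setMethod("show", "SimulationSpec", function(object) {
  cat("SimulationSpec:", object@nCohorts, "cohorts x (",
      object@nTumor, "tumor +", object@nNormal, "normal ),",
      object@nGenes, "genes;", length(object@plantedUp), "up +",
      length(object@plantedDown), "down planted at effect",
      object@effectSize, "with consistency", object@consistency, "\n")
})

#' @rdname CohortExperiment-accessors
#' @export
setGeneric("modelFeatures", function(x) standardGeneric("modelFeatures"))
#' @rdname CohortExperiment-accessors
#' @export
setMethod("modelFeatures", "PanelModel", function(x) x@features)
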