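#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' CohortExperiment: one cohort of log-scale expression with class labels
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a single
#' cohort's genes x samples log2 expression matrix (assay \code{"exprs"}),
#' per-sample tumor/normal labels and optional tumor-normal pairing in
#' \code{colData}, and the cohort / platform identity in \code{metadata}.
#'
#' @slot cohortId single string identifying the cohort (e.g. an accession).
#' @slot platformTag free-text profiling platform description.
#'
#' @details Validity requires: unique, non-empty gene and sample identifiers;
#' all expression values finite; labels in \code{tumor}, \code{normal},
#' \code{unknown}; and, when pairing is present, mutual partners carrying
#' opposite tumor/normal labels.
#'
#' @seealso [CohortExperiment()] for the user constructor,
#'   [classLabels()], [samplePairing()], [exprs()].
#' @export
setClass("CohortExperiment",
  contains = "SummarizedExperiment",
  slots = c(cohortId = "character", platformTag = "character")
)

.validCohortExperiment <- function(object) {
  msg <- character()
  if (length(object@cohortId) != 1L || !nzchar(object@cohortId))
    msg <- c(msg, "cohortId must be a single non-empty string")
  m <- SummarizedExperiment::assay(object, "exprs")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    msg <- c(msg, "sample ids must be present and unique")
  if (!all(is.finite(m)))
    msg <- c(msg, "expression values must all be finite")
  lab <- object$label
  if (is.null(lab)) {
    msg <- c(msg, "colData must contain a 'label' column")
  } else if (!all(as.character(lab) %in% c("tumor", "normal", "unknown"))) {
    msg <- c(msg, "labels must be 'tumor', 'normal' or 'unknown'")
  }
  pid <- object$pairId
  if (!is.null(pid)) {
    has <- !is.na(pid)
    if (any(has)) {
      ids <- colnames(m)
      bad <- has & !(pid %in% ids)
      if (any(bad)) {
        msg <- c(msg, "pairing refers to unknown sample ids")
      } else {
        idx <- match(pid[has], ids)
        back <- pid[idx]
        if (any(is.na(back)) || !all(back == ids[has]))
          msg <- c(msg, "pairing must be mutual")
        else if (!all(as.character(lab[has]) != as.character(lab[idx])))
          msg <- c(msg, "paired samples must carry opposite labels")
      }
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("CohortExperiment", .validCohortExperiment)

#' Construct a CohortExperiment
#'
#' @param values numeric genes x samples matrix on log2 scale, with gene
#'   rownames and sample colnames.
#' @param labels character/factor of per-sample classes (\code{"tumor"},
#'   \code{"normal"}, \code{"unknown"}), recycled named or positional.
#' @param cohortId single string naming the cohort.
#' @param platformTag free-text platform tag (default \code{"unknown"}).
#' @param pairing optional character vector (or NA) of partner sample ids for
#'   paired tumor/normal designs; partners must be mutual with opposite labels.
#' @return A [CohortExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ce <- CohortExperiment(m, c("tumor", "tumor", "normal", "normal"), "demo")
#' classLabels(ce)
#' @export
CohortExperiment <- function(values, labels, cohortId,
                             platformTag = "unknown", pairing = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  labels <- as.character(labels)
  if (length(labels) != ncol(values))
    stop("need one label per sample in cohort '", cohortId, "'")
  cd <- S4Vectors::DataFrame(label = labels, row.names = colnames(values))
  if (!is.null(pairing)) cd$pairId <- as.character(pairing)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd
  )
  new("CohortExperiment", se, cohortId = as.character(cohortId),
      platformTag = as.character(platformTag))
}

#' Multi-cohort simulation specification
#'
#' Parameters of the synthetic multi-cohort generator. The planted up/down
#' gene sets are disjoint subsets of \code{gene1 ... gene<nGenes>}; each
#' planted gene carries its log2 effect in a \code{consistency} fraction of
#' cohorts (chosen deterministically from \code{seed}), emulating genes
#' differentially expressed in "most but not all" cohorts.
#'
#' @slot nCohorts number of cohorts.
#' @slot nTumor,nNormal per-cohort class sizes.
#' @slot nGenes number of genes.
#' @slot plantedUp,plantedDown disjoint planted gene-id sets.
#' @slot effectSize mean log2 tumor shift of planted genes (>= 0).
#' @slot consistency fraction of cohorts carrying each planted effect, in [0,1].
#' @slot platformShiftSd sd of cohort x gene platform location offsets.
#' @slot noiseSd residual sd on the log2 scale.
#' @slot pairedFraction fraction of cohorts generated as paired designs.
#' @slot seed integer master seed; all randomness flows from it.
#' @seealso [simulationSpec()], [simulateCohort()], [simulateCohorts()]
#' @export
setClass("SimulationSpec", slots = c(
  nCohorts = "integer", nTumor = "integer", nNormal = "integer",
  nGenes = "integer", plantedUp = "character", plantedDown = "character",
  effectSize = "numeric", consistency = "numeric",
  platformShiftSd = "numeric", noiseSd = "numeric",
  pairedFraction = "numeric", seed = "integer"
))

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (object@nCohorts < 1L) msg <- c(msg, "nCohorts must be >= 1")
  if (object@nTumor < 2L || object@nNormal < 2L)
    msg <- c(msg, "need >= 2 samples per class")
  if (length(intersect(object@plantedUp, object@plantedDown)))
    msg <- c(msg, "plantedUp and plantedDown must be disjoint")
  if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
  if (object@consistency < 0 || object@consistency > 1)
    msg <- c(msg, "consistency must lie in [0, 1]")
  if (object@noiseSd < 0 || object@platformShiftSd < 0)
    msg <- c(msg, "standard deviations must be >= 0")
  if (object@pairedFraction < 0 || object@pairedFraction > 1)
    msg <- c(msg, "pairedFraction must lie in [0, 1]")
  genes <- paste0("gene", seq_len(object@nGenes))
  if (!all(c(object@plantedUp, object@plantedDown) %in% genes))
    msg <- c(msg, "planted genes must be within gene1..gene<nGenes>")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationSpec-class constructor with the package's default
#'   study conditions: 10 cohorts of 40 tumor / 40 normal samples, 1,000
#'   genes, 10 up- and 10 down-regulated planted genes at effect size 3 with
#'   consistency 0.9, unit noise and platform-shift sd, 30 percent paired
#'   cohorts.
#' @param nCohorts,nTumor,nNormal,nGenes,plantedUp,plantedDown,effectSize,consistency,platformShiftSd,noiseSd,pairedFraction,seed
#'   see slots.
#' @export
simulationSpec <- function(nCohorts = 10, nTumor = 40, nNormal = 40,
                           nGenes = 1000,
                           plantedUp = paste0("gene", 1:10),
                           plantedDown = paste0("gene", 11:20),
                           effectSize = 3, consistency = 0.9,
                           platformShiftSd = 1, noiseSd = 1,
                           pairedFraction = 0.3, seed = 1L) {
  new("SimulationSpec", nCohorts = as.integer(nCohorts),
      nTumor = as.integer(nTumor), nNormal = as.integer(nNormal),
      nGenes = as.integer(nGenes), plantedUp = as.character(plantedUp),
      plantedDown = as.character(plantedDown),
      effectSize = as.numeric(effectSize),
      consistency = as.numeric(consistency),
      platformShiftSd = as.numeric(platformShiftSd),
      noiseSd = as.numeric(noiseSd),
      pairedFraction = as.numeric(pairedFraction), seed = as.integer(seed))
}

#' Survival simulation specification
#'
#' Event times are exponential with hazard
#' \code{baselineHazard * exp(sum(logHr * centered expression))}; censoring is
#' independent exponential calibrated to \code{censorRate} plus an
#' administrative cap at \code{maxFollowup}.
#'
#' @slot nPatients number of patients (drawn from the tumor samples).
#' @slot baselineHazard baseline event rate per time unit (> 0).
#' @slot logHr named numeric: per-gene log hazard ratio per log2 unit.
#' @slot censorRate target fraction censored, in [0, 1).
#' @slot maxFollowup administrative censoring time (may be \code{Inf}).
#' @slot seed integer seed.
#' @seealso [survivalSimSpec()], [simulateSurvival()]
#' @export
setClass("SurvivalSimSpec", slots = c(
  nPatients = "integer", baselineHazard = "numeric", logHr = "numeric",
  censorRate = "numeric", maxFollowup = "numeric", seed = "integer"
))

setValidity("SurvivalSimSpec", function(object) {
  msg <- character()
  if (object@baselineHazard <= 0) msg <- c(msg, "baselineHazard must be > 0")
  if (object@censorRate < 0 || object@censorRate >= 1)
    msg <- c(msg, "censorRate must lie in [0, 1)")
  if (object@maxFollowup <= 0) msg <- c(msg, "maxFollowup must be > 0")
  if (length(object@logHr) && is.null(names(object@logHr)))
    msg <- c(msg, "logHr must be a named (gene) vector")
  if (length(msg)) msg else TRUE
})

#' @describeIn SurvivalSimSpec-class constructor.
#' @param nPatients,baselineHazard,logHr,censorRate,maxFollowup,seed see slots.
#' @export
survivalSimSpec <- function(nPatients = 500, baselineHazard = 0.1,
                            logHr = numeric(), censorRate = 0.3,
                            maxFollowup = Inf, seed = 1L) {
  new("SurvivalSimSpec", nPatients = as.integer(nPatients),
      baselineHazard = as.numeric(baselineHazard),
      logHr = if (length(logHr)) unlist(logHr) else setNames(numeric(), character()),
      censorRate = as.numeric(censorRate),
      maxFollowup = as.numeric(maxFollowup), seed = as.integer(seed))
}

#' Single-gene threshold classifier (decision stump)
#'
#' @slot gene gene id the stump reads.
#' @slot threshold finite log2-scale decision threshold.
#' @slot direction \code{"up"} (expression strictly above the threshold is
#'   called cancer) or \code{"down"} (strictly below is cancer); samples
#'   exactly at the threshold fall on the normal side.
#' @slot degenerate TRUE when the gene was constant on the training data and
#'   the stump simply predicts the majority class.
#' @seealso [fitStump()], [predictStump()]
#' @export
setClass("StumpModel", slots = c(
  gene = "character", threshold = "numeric", direction = "character",
  degenerate = "logical"
))

setValidity("StumpModel", function(object) {
  msg <- character()
  if (!is.finite(object@threshold)) msg <- c(msg, "threshold must be finite")
  if (!object@direction %in% c("up", "down"))
    msg <- c(msg, "direction must be 'up' or 'down'")
  if (length(msg)) msg else TRUE
})

#' Trained multi-gene diagnosis model
#'
#' Bundle of a fitted classifier, its feature panel, family, tuned
#' parameters, cross-validation score and seed, as produced by
#' [trainModels()].
#'
#' @slot family one of \code{extra_trees}, \code{naive_bayes}, \code{knn},
#'   \code{random_forest}, \code{logistic_regression}, \code{svc_rbf}.
#' @slot features gene panel the model reads, in order.
#' @slot fit the underlying fitted object (family-specific).
#' @slot params tuned hyper-parameters selected by the AUROC grid search.
#' @slot cvAurocMean,cvAurocSd mean and sd of 10-fold CV AUROC.
#' @slot seed seed used for fold assignment and stochastic learners.
#' @slot trainCohort id of the training cohort.
#' @export
setClass("PanelModel", slots = c(
  family = "character", features = "character", fit = "ANY",
  params = "list", cvAurocMean = "numeric", cvAurocSd = "numeric",
  seed = "integer", trainCohort = "character"
))
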