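# Multi-cohort simulator. All randomness flows from SimulationSpec@seed:
# cross-cohort structure (gene baselines, which cohorts carry each planted
# effect) is drawn from the master seed, per-cohort noise from a derived
# child seed, so simulateCohort(spec, i) is reproducible in isolation.

.simTruth <- function(spec) {
  genes <- paste0("gene", seq_len(spec@nGenes))
  planted <- c(spec@plantedUp, spec@plantedDown)
  withSeed(spec@seed, {
    mu <- stats::runif(spec@nGenes, 4, 12)
    names(mu) <- genes
    nCarry <- round(spec@consistency * spec@nCohorts)
    carriers <- matrix(FALSE, length(planted), spec@nCohorts,
                       dimnames = list(planted, NULL))
    for (g in planted)
      carriers[g, sample.int(spec@nCohorts, nCarry)] <- TRUE
  })
  nPaired <- round(spec@pairedFraction * spec@nCohorts)
  list(genes = genes, baselines = mu, carriers = carriers,
       plantedUp = spec@plantedUp, plantedDown = spec@plantedDown,
       pairedCohorts = seq_len(spec@nCohorts) <= nPaired)
}

.simCohort <- function(spec, i, truth) {
  if (i < 1L || i > spec@nCohorts)
    stop("cohort_index must lie in 1..", spec@nCohorts)
  genes <- truth$genes
  nT <- spec@nTumor; nN <- spec@nNormal
  paired <- truth$pairedCohorts[i]
  cid <- sprintf("SIM%03d", i)
  effect <- setNames(numeric(length(genes)), genes)
  up <- rownames(truth$carriers)[truth$carriers[, i]]
  effect[intersect(up, spec@plantedUp)] <- spec@effectSize
  effect[intersect(up, spec@plantedDown)] <- -spec@effectSize
  withSeed(childSeed(spec@seed, i), {
    shift <- stats::rnorm(length(genes), 0, spec@platformShiftSd)
    base <- truth$baselines + shift
    tum <- base + effect +
      matrix(stats::rnorm(length(genes) * nT, 0, spec@noiseSd), length(genes))
    nor <- base +
      matrix(stats::rnorm(length(genes) * nN, 0, spec@noiseSd), length(genes))
    pairing <- NULL
    if (paired) {
      np <- min(nT, nN)
      b <- stats::rnorm(np, 0, spec@noiseSd)  # shared patient intercept
      tum[, seq_len(np)] <- sweep(tum[, seq_len(np), drop = FALSE], 2, b, `+`)
      nor[, seq_len(np)] <- sweep(nor[, seq_len(np), drop = FALSE], 2, b, `+`)
    }
  })
  m <- cbind(tum, nor)
  rownames(m) <- genes
  colnames(m) <- c(sprintf("%s_t%02d", cid, seq_len(nT)),
                   sprintf("%s_n%02d", cid, seq_len(nN)))
  labels <- c(rep("tumor", nT), rep("normal", nN))
  if (paired) {
    np <- min(nT, nN)
    pairing <- rep(NA_character_, nT + nN)
    pairing[seq_len(np)] <- sprintf("%s_n%02d", cid, seq_len(np))
    pairing[nT + seq_len(np)] <- sprintf("%s_t%02d", cid, seq_len(np))
  }
  CohortExperiment(m, labels, cid,
                   platformTag = if (paired) "sim-paired" else "sim-unpaired",
                   pairing = if (paired) pairing else NULL)
}

#' Simulate one cohort of log2 expression with planted effects
#'
#' Background expression for gene g is Normal(mu_g + platform offset,
#' noiseSd) in both classes, with mu_g ~ Uniform(4, 12) shared across
#' cohorts; planted up (down) genes add +effectSize (-effectSize) to the
#' tumor mean in the consistency-fraction of cohorts that carry the effect.
#' Paired cohorts add a per-patient intercept (sd = noiseSd) shared by the
#' tumor and normal sample of each patient.
#'
#' @param spec a [SimulationSpec-class].
#' @param cohortIndex which cohort to generate, in \code{1..nCohorts}.
#' @return A [CohortExperiment-class]; reproducible given (seed, cohortIndex).
#' @seealso [simulateCohorts()] for all cohorts plus the ground-truth ledger.
#' @export
simulateCohort <- function(spec, cohortIndex) {
  .simCohort(spec, as.integer(cohortIndex), .simTruth(spec))
}

#' Simulate all cohorts of a study plus the ground-truth ledger
#'
#' @param spec a [SimulationSpec-class].
#' @return list with \code{cohorts} (list of [CohortExperiment-class]) and
#'   \code{truth}: planted up/down gene sets, the planted-gene x cohort
#'   carrier matrix, per-gene baselines and the paired-cohort flags —
#'   sufficient to score recovery at every downstream stage.
#' @examples
#' sim <- simulateCohorts(simulationSpec(nCohorts = 2, nGenes = 50,
#'                                       plantedUp = "gene1",
#'                                       plantedDown = "gene2", seed = 7))
#' sim$cohorts[[1]]
#' @export
simulateCohorts <- function(spec) {
  truth <- .simTruth(spec)
  cohorts <- lapply(seq_len(spec@nCohorts), function(i)
    .simCohort(spec, i, truth))
  names(cohorts) <- vapply(cohorts, cohortId, character(1))
  list(cohorts = cohorts, truth = truth)
}

#' Simulate a survival table driven by planted prognostic genes
#'
#' Event times are exponential with per-patient hazard
#' \code{baselineHazard * exp(sum(logHr * centered log2 expression))}.
#' Censoring is independent: exponential with rate
#' \code{baselineHazard * censorRate / (1 - censorRate)} (calibrated to the
#' target censoring fraction under the null), capped at \code{maxFollowup}.
#' Age, gender and ordinal stage (1-4) covariates are generated independently
#' of survival so they act as nulls in downstream models.
#'
#' @param spec a [SurvivalSimSpec-class]; every gene named in \code{logHr}
#'   must exist in \code{expr}.
#' @param expr a [CohortExperiment-class] whose tumor samples provide the
#'   expression covariates (resampled with replacement to \code{nPatients}).
#' @param genes expression columns to attach to the table; defaults to the
#'   prognostic genes.
#' @param endpoint endpoint tag (OS, DSS, DFS, PFS or RFS).
#' @return data.frame with patient_id, time, event (1 = observed), endpoint,
#'   age, gender, stage and one column per requested gene.
#' @export
simulateSurvival <- function(spec, expr, genes = names(spec@logHr),
                             endpoint = c("OS", "DSS", "DFS", "PFS", "RFS")) {
  endpoint <- match.arg(endpoint)
  bad <- setdiff(names(spec@logHr), rownames(expr))
  if (length(bad))
    stop("prognostic gene(s) absent from expression data: ",
         paste(bad, collapse = ", "))
  tum <- which(as.character(classLabels(expr)) == "tumor")
  if (!length(tum)) tum <- seq_len(ncol(expr))
  m <- exprs(expr)
  withSeed(spec@seed, {
    idx <- if (spec@nPatients == length(tum)) tum
           else tum[sample.int(length(tum), spec@nPatients, replace = TRUE)]
    lp <- numeric(spec@nPatients)
    for (g in names(spec@logHr)) {
      v <- m[g, idx]
      lp <- lp + spec@logHr[[g]] * (v - mean(v))
    }
    haz <- spec@baselineHazard * exp(lp)
    tEvent <- stats::rexp(spec@nPatients, rate = haz)
    tCens <- if (spec@censorRate > 0)
      stats::rexp(spec@nPatients,
                  rate = spec@baselineHazard *
                    spec@censorRate / (1 - spec@censorRate))
    else rep(Inf, spec@nPatients)
    tCens <- pmin(tCens, spec@maxFollowup)
    age <- round(stats::rnorm(spec@nPatients, 60, 10))
    gender <- sample(c("M", "F"), spec@nPatients, replace = TRUE)
    stage <- sample(1:4, spec@nPatients, replace = TRUE,
                    prob = c(0.3, 0.3, 0.25, 0.15))
  })
  out <- data.frame(
    patient_id = sprintf("pt%04d", seq_len(spec@nPatients)),
    time = pmin(tEvent, tCens),
    event = as.integer(tEvent <= tCens),
    endpoint = endpoint, age = age, gender = gender, stage = stage,
    stringsAsFactors = FALSE
  )
  for (g in genes) out[[g]] <- as.numeric(m[g, idx])
  out
}
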