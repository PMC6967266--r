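#' Assemble a pipeline run configuration
#'
#' Collects the cohorts and every tunable threshold of the end-to-end
#' analysis. All defaults follow the package's reference workflow: per-gene
#' per-cohort tests at Bonferroni-adjusted alpha 0.01, core genes at >= 80
#' percent of cohorts, top-10 then top-5 shortlist, wrapper reduction to a
#' 3-gene panel, all six model families.
#'
#' @param discovery list of [CohortExperiment-class] cohorts used for DEG
#'   discovery (never for model training).
#' @param training single [CohortExperiment-class] used to rank genes and
#'   train models.
#' @param validation list of held-out [CohortExperiment-class] cohorts;
#'   read only by the evaluation stage.
#' @param survTables optional named list of survival data.frames (see
#'   [survivalScreen()]) for the prognostic stage.
#' @param alpha per-cohort family-wise significance level.
#' @param minSigFrac core-gene cohort fraction (inclusive).
#' @param k10,k5 shortlist sizes. @param panelSize final panel size.
#' @param families model families to train. @param wrapperFamily family used
#'   during wrapper reduction.
#' @param seed master seed. @param outdir optional directory for TSV/JSON
#'   artifacts.
#' @return config list (class \code{hcc_config}).
#' @export
pipelineConfig <- function(discovery, training, validation = list(),
                           survTables = list(), alpha = 0.01,
                           minSigFrac = 0.80, k10 = 10, k5 = 5,
                           panelSize = 3, families = PANEL_FAMILIES,
                           wrapperFamily = "logistic_regression",
                           seed = 1L, outdir = NULL) {
  cfg <- list(discovery = discovery, training = training,
              validation = validation, survTables = survTables,
              alpha = alpha, minSigFrac = minSigFrac, k10 = k10, k5 = k5,
              panelSize = panelSize, families = families,
              wrapperFamily = wrapperFamily, seed = as.integer(seed),
              outdir = outdir)
  class(cfg) <- "hcc_config"
  cfg
}

#' Read a pipeline configuration from a YAML manifest
#'
#' The manifest lists cohort files by role. Each cohort entry needs
#' \code{expr} and \code{labels} paths and may add \code{pairing},
#' \code{probe_map}, \code{id} and \code{platform}; scalar fields mirror
#' the [pipelineConfig()] arguments.
#'
#' @param path YAML file path.
#' @return config list as from [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  loadOne <- function(e) readCohort(
    e$expr, e$labels,
    cohortId = if (!is.null(e$id)) e$id else sub("\\.[^.]+$", "", basename(e$expr)),
    platformTag = if (!is.null(e$platform)) e$platform else "unknown",
    pairingFile = e$pairing, probeMapFile = e$probe_map)
  if (length(y$training) != 1 && !is.list(y$training))
    stop("config must name exactly one training cohort")
  args <- list(
    discovery = lapply(y$discovery, loadOne),
    training = loadOne(y$training),
    validation = lapply(y$validation, loadOne)
  )
  for (nm in c("alpha", "minSigFrac", "k10", "k5", "panelSize", "families",
               "wrapperFamily", "seed", "outdir"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(pipelineConfig, args)
}

.validateConfig <- function(cfg) {
  if (!length(cfg$discovery))
    stop("config error: at least one discovery cohort is required")
  if (!is(cfg$training, "CohortExperiment"))
    stop("config error: exactly one training CohortExperiment is required")
  ids <- c(vapply(cfg$discovery, cohortId, character(1)),
           cohortId(cfg$training),
           vapply(cfg$validation, cohortId, character(1)))
  if (anyDuplicated(ids))
    stop("config error: cohort roles must be disjoint (duplicated id: ",
         ids[duplicated(ids)][1], ")")
  invisible(TRUE)
}

.cfgHash <- function(cfg) {
  scalars <- cfg[c("alpha", "minSigFrac", "k10", "k5", "panelSize",
                   "families", "wrapperFamily", "seed")]
  txt <- jsonlite::toJSON(scalars, auto_unbox = TRUE)
  raw <- utf8ToInt(as.character(txt))
  sprintf("%08x", sum(raw * seq_along(raw)) %% 4294967291)
}

.writeTsv <- function(df, outdir, name) {
  if (is.null(outdir)) return(invisible(NULL))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  utils::write.table(df, file.path(outdir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes, in order: per-discovery-cohort differential expression on the
#' common-gene intersection; cross-cohort consensus and core-gene selection;
#' single-gene stump ranking on the training cohort; two-stage shortlist;
#' wrapper reduction to the final panel; grid-searched model training; and
#' evaluation on each held-out validation cohort (validation data are not
#' touched by any earlier stage). If survival tables are supplied, panel
#' genes are screened prognostically. Every artifact carries the config
#' hash and seed; a rerun with the same config is byte-identical.
#'
#' @param cfg a [pipelineConfig()] list.
#' @return report list: config_hash, seed, consensus, core_genes, ranking,
#'   shortlist, wrapper (with audit log), panel, models, evaluation,
#'   survival, log (per-stage timings).
#' @export
runPipeline <- function(cfg) {
  .validateConfig(cfg)
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  common <- stage("intersect",
                  intersectCommonGenes(c(cfg$discovery, list(cfg$training))))
  degs <- stage("diffexp", lapply(cfg$discovery, function(d)
    callDEGs(d[common, ], alpha = cfg$alpha)))
  consensus <- stage("consensus", summarizeConsensus(degs))
  core <- stage("core_genes", selectCoreGenes(consensus, cfg$minSigFrac))
  if (!length(core)) stop("pipeline stage 'core_genes' produced no genes")

  ranking <- stage("rank", rankGenes(cfg$training, core))
  k10 <- min(cfg$k10, nrow(ranking)); k5 <- min(cfg$k5, k10)
  shortlist <- stage("shortlist",
                     shortlistGenes(ranking, cfg$training, k10, k5,
                                    seed = cfg$seed))
  wrap <- stage("wrapper",
                wrapperReduce(shortlist, cfg$training,
                              family = cfg$wrapperFamily,
                              targetSize = min(cfg$panelSize, k5),
                              seed = cfg$seed))
  panel <- wrap$features
  models <- stage("train",
                  trainModels(cfg$training, panel, cfg$families,
                              seed = cfg$seed))

  evaluation <- NULL
  if (length(cfg$validation)) {
    evaluation <- stage("evaluate", do.call(rbind, unlist(
      lapply(cfg$validation, function(v)
        lapply(names(models), function(fam) {
          met <- evaluateExternal(models[[fam]], v, seed = cfg$seed)
          data.frame(cohort = cohortId(v), family = fam,
                     sens_pct = met$sens_pct, spec_pct = met$spec_pct,
                     acc_pct = met$acc_pct, mcc = met$mcc,
                     auroc = met$auroc, auroc_ci_low = met$auroc_ci[1],
                     auroc_ci_high = met$auroc_ci[2],
                     stringsAsFactors = FALSE)
        })), recursive = FALSE)))
  }

  survres <- NULL
  if (length(cfg$survTables)) {
    survres <- stage("survival", do.call(rbind, lapply(
      names(cfg$survTables), function(nm) {
        st <- cfg$survTables[[nm]]
        res <- survivalScreen(st, intersect(panel, colnames(st)))
        cbind(cohort = nm, res, stringsAsFactors = FALSE)
      })))
  }

  hash <- .cfgHash(cfg)
  stamp <- function(df) {
    df$config_hash <- hash; df$seed <- cfg$seed; df
  }
  if (!is.null(cfg$outdir)) {
    .writeTsv(stamp(consensus), cfg$outdir, "consensus.tsv")
    .writeTsv(stamp(ranking), cfg$outdir, "ranking.tsv")
    if (!is.null(evaluation))
      .writeTsv(stamp(evaluation), cfg$outdir, "evaluation.tsv")
    if (!is.null(survres))
      .writeTsv(stamp(survres), cfg$outdir, "survival.tsv")
    writeLines(as.character(jsonlite::toJSON(
      list(config_hash = hash, seed = cfg$seed, panel = panel,
           core_genes = core, shortlist = shortlist),
      auto_unbox = TRUE, pretty = TRUE)),
      file.path(cfg$outdir, "run.json"))
  }
  list(config_hash = hash, seed = cfg$seed, consensus = consensus,
       core_genes = core, ranking = ranking, shortlist = shortlist,
       wrapper = wrap, panel = panel, models = models,
       evaluation = evaluation, survival = survres, log = log)
}
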