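#' Consensus tally for one gene across cohorts
#'
#' Counts, over the per-cohort differential-expression records of a single
#' gene, how many cohorts call it up- vs down-regulated (by the sign of the
#' tumor - normal mean difference, significant or not) and in how many it is
#' significant; percentages are reported to two decimals (half-up). The
#' consensus regulation is the majority direction over all cohorts, ties
#' broken by the majority among significant cohorts only.
#'
#' @param records data.frame of [callDEGs()] rows for one gene, one row per
#'   cohort.
#' @return one-row data.frame with gene, n_up, n_down, n_sig, n_nonsig,
#'   up_pct, down_pct, sig_pct, regulation and a \code{conflict} flag set
#'   when the all-cohort majority disagrees with the significant-only
#'   majority.
#' @export
summarizeGene <- function(records) {
  if (nrow(records) < 1) stop("need at least one cohort record")
  if (length(unique(records$gene)) != 1)
    stop("records mix gene ids: ", paste(unique(records$gene), collapse = ", "))
  n <- nrow(records)
  nUp <- sum(records$direction == "up")
  nDown <- n - nUp
  nSig <- sum(records$significant)
  sigUp <- sum(records$significant & records$direction == "up")
  sigDown <- nSig - sigUp
  reg <- if (nUp > nDown) "up"
         else if (nDown > nUp) "down"
         else if (sigUp >= sigDown) "up" else "down"
  regSig <- if (sigUp > sigDown) "up" else if (sigDown > sigUp) "down" else reg
  data.frame(
    gene = records$gene[1], n_up = nUp, n_down = nDown,
    n_sig = nSig, n_nonsig = n - nSig,
    up_pct = roundHalfUp(nUp / n * 100, 2),
    down_pct = roundHalfUp(nDown / n * 100, 2),
    sig_pct = roundHalfUp(nSig / n * 100, 2),
    regulation = reg, conflict = reg != regSig,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Cross-cohort consensus summary of differential expression
#'
#' Aggregates per-cohort DEG tables into one consensus row per gene. Genes
#' absent from any cohort are excluded first (the analysis is restricted to
#' the common-gene intersection).
#'
#' @param degTables list of [callDEGs()] outputs, one per cohort.
#' @return data.frame in the shape of [summarizeGene()], one row per common
#'   gene, sorted by gene id; cohort ordering does not affect the result.
#' @export
summarizeConsensus <- function(degTables) {
  if (!length(degTables)) stop("need at least one cohort DEG table")
  common <- sort(Reduce(intersect, lapply(degTables, `[[`, "gene")))
  if (!length(common)) stop("no gene shared by all cohort DEG tables")
  up <- sig <- sigUp <- setNames(integer(length(common)), common)
  for (tab in degTables) {
    tab <- tab[match(common, tab$gene), ]
    isUp <- tab$direction == "up"
    up <- up + isUp
    sig <- sig + tab$significant
    sigUp <- sigUp + (tab$significant & isUp)
  }
  n <- length(degTables)
  nDown <- n - up
  sigDown <- sig - sigUp
  reg <- ifelse(up > nDown, "up",
         ifelse(nDown > up, "down",
         ifelse(sigUp >= sigDown, "up", "down")))
  regSig <- ifelse(sigUp > sigDown, "up",
            ifelse(sigDown > sigUp, "down", reg))
  data.frame(
    gene = common, n_up = as.integer(up), n_down = as.integer(nDown),
    n_sig = as.integer(sig), n_nonsig = as.integer(n - sig),
    up_pct = roundHalfUp(up / n * 100, 2),
    down_pct = roundHalfUp(nDown / n * 100, 2),
    sig_pct = roundHalfUp(sig / n * 100, 2),
    regulation = reg, conflict = reg != regSig,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Select core genes significant in at least a fraction of cohorts
#'
#' The "core gene" rule: keep genes whose significant-cohort percentage
#' meets the threshold (inclusive — "at least 80 percent"), ordered by
#' significance percentage descending, ties by gene id.
#'
#' @param summaries a [summarizeConsensus()] data.frame.
#' @param minSigFrac minimum fraction of cohorts in which the gene must be
#'   significant (default 0.80).
#' @return character vector of selected gene ids.
#' @export
selectCoreGenes <- function(summaries, minSigFrac = 0.80) {
  frac <- summaries$n_sig / (summaries$n_sig + summaries$n_nonsig)
  keep <- frac >= minSigFrac - 1e-12
  sel <- summaries[keep, , drop = FALSE]
  sel$gene[order(-sel$sig_pct, sel$gene)]
}
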