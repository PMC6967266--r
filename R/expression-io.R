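#' Average probe-level rows into gene-level expression
#'
#' Microarray platforms measure most genes with several probes; for a
#' gene-level matrix every mapped gene row is the arithmetic mean of its
#' probe rows. Unmapped probes are dropped; gene rows are returned in
#' lexicographic order.
#'
#' @param values numeric probes x samples matrix with probe-id rownames.
#' @param probeToGene named character vector mapping probe id to gene symbol
#'   (probes absent from the map, or mapping to \code{NA}/empty, are dropped).
#' @param cohortId,platformTag,labels,pairing passed to [CohortExperiment()].
#' @return A [CohortExperiment-class] with one row per mapped gene.
#' @examples
#' m <- matrix(c(4, 6, 1, 2, 3, 5), 3, 2,
#'             dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
#' map <- c(p1 = "GENEA", p2 = "GENEA", p3 = "GENEB")
#' exprs(aggregateProbes(m, map, "demo", labels = c("tumor", "normal")))
#' @export
aggregateProbes <- function(values, probeToGene, cohortId,
                            platformTag = "unknown", labels = NULL,
                            pairing = NULL) {
  values <- as.matrix(values)
  if (nrow(values) == 0L) stop("empty probe matrix for cohort '", cohortId, "'")
  if (is.null(rownames(values))) stop("probe matrix must have probe-id rownames")
  if (!all(is.finite(values))) stop("probe values must be finite")
  genes <- probeToGene[rownames(values)]
  keep <- !is.na(genes) & nzchar(genes)
  if (!any(keep))
    stop("no probe of cohort '", cohortId, "' maps to a gene symbol")
  values <- values[keep, , drop = FALSE]
  genes <- as.character(genes[keep])
  agg <- rowsum(values, group = genes, reorder = TRUE)
  counts <- as.vector(table(genes)[rownames(agg)])
  agg <- agg / counts
  if (is.null(labels)) labels <- rep("unknown", ncol(agg))
  CohortExperiment(agg, labels, cohortId, platformTag, pairing)
}

#' Zero-safe log2 transform of non-negative expression values
#'
#' Applies \code{log2(x + 1)} elementwise, the standard zero-safe transform
#' for FPKM-scale RNA-seq values.
#'
#' @param values non-negative numeric matrix or vector.
#' @return object of the same shape on log2 scale.
#' @examples
#' log2Transform(c(0, 1, 7))  # 0, 1, 3
#' @export
log2Transform <- function(values) {
  if (any(values < 0, na.rm = TRUE))
    stop("log2Transform requires non-negative input")
  log2(values + 1)
}

#' Quantile-normalize the samples of an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution given
#' by the row-wise mean of the column-sorted input; ties within a column
#' receive the mean of the reference quantiles they span. Applied per cohort,
#' never jointly across cohorts.
#'
#' @param values numeric genes x samples matrix (or a
#'   [CohortExperiment-class], normalized in place).
#' @return same type as the input, with identical per-column sorted values.
#' @details Delegates to \code{limma::normalizeQuantiles(ties = TRUE)}.
#'   A single-column matrix is returned unchanged with a warning, since a
#'   lone sample defines its own reference distribution.
#' @export
quantileNormalize <- function(values) {
  if (is(values, "CohortExperiment")) {
    m <- quantileNormalize(exprs(values))
    SummarizedExperiment::assay(values, "exprs") <- m
    return(values)
  }
  values <- as.matrix(values)
  if (ncol(values) < 2L) {
    warning("quantile normalization skipped: fewer than 2 samples")
    return(values)
  }
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Genes present in every cohort
#'
#' @param datasets list of [CohortExperiment-class] objects (or of character
#'   gene-id vectors).
#' @return sorted character vector of the common gene ids.
#' @export
intersectCommonGenes <- function(datasets) {
  if (length(datasets) == 0L) stop("need at least one dataset")
  sets <- lapply(datasets, function(d)
    if (is(d, "CohortExperiment")) rownames(d) else as.character(d))
  common <- Reduce(intersect, sets)
  if (length(common) == 0L) {
    counts <- vapply(sets, length, integer(1))
    ids <- vapply(seq_along(datasets), function(i) {
      d <- datasets[[i]]
      if (is(d, "CohortExperiment")) cohortId(d) else as.character(i)
    }, character(1))
    stop("no gene is shared by all cohorts (per-cohort gene counts: ",
         paste(ids, counts, sep = "=", collapse = ", "), ")")
  }
  sort(common)
}

#' Read one cohort from delimited text files
#'
#' Expression files are TSV/CSV with the gene (or probe) id in the first
#' column and one column per sample; the labels file has two columns
#' (sample_id, class), the optional pairing file two columns
#' (sample_id, partner_id), and the optional probe map two columns
#' (probe_id, gene_symbol) triggering probe aggregation.
#'
#' @param exprFile path to the expression matrix.
#' @param labelsFile path to the two-column labels table.
#' @param cohortId cohort identifier; defaults to the expression file name.
#' @param platformTag free-text platform tag.
#' @param pairingFile optional path to the pairing table.
#' @param probeMapFile optional path to the probe-to-gene map.
#' @return A [CohortExperiment-class].
#' @export
readCohort <- function(exprFile, labelsFile,
                       cohortId = sub("\\.[^.]+$", "", basename(exprFile)),
                       platformTag = "unknown",
                       pairingFile = NULL, probeMapFile = NULL) {
  dt <- data.table::fread(exprFile, header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- ids
  lab <- data.table::fread(labelsFile, header = TRUE, data.table = FALSE)
  labels <- setNames(as.character(lab[[2]]), as.character(lab[[1]]))
  missing <- setdiff(colnames(m), names(labels))
  if (length(missing))
    stop("labels missing for samples: ", paste(missing, collapse = ", "))
  labels <- labels[colnames(m)]
  pairing <- NULL
  if (!is.null(pairingFile)) {
    pr <- data.table::fread(pairingFile, header = TRUE, data.table = FALSE)
    pairing <- setNames(rep(NA_character_, ncol(m)), colnames(m))
    pairing[as.character(pr[[1]])] <- as.character(pr[[2]])
  }
  if (!is.null(probeMapFile)) {
    pm <- data.table::fread(probeMapFile, header = TRUE, data.table = FALSE)
    map <- setNames(as.character(pm[[2]]), as.character(pm[[1]]))
    return(aggregateProbes(m, map, cohortId, platformTag, labels, pairing))
  }
  CohortExperiment(m, labels, cohortId, platformTag, pairing)
}
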