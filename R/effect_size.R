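#' Detect the scale of an expression matrix
#'
#' Microarray series are deposited either as linear intensities or already
#' log2-transformed. The heuristic used throughout the pipeline calls a
#' matrix `log2` when all values lie in `[-10, 30]` (log2 intensities of
#' real arrays rarely leave `[0, 16]`) and `linear` otherwise.
#'
#' @param study An [expression_study()].
#' @return `"log2"` or `"linear"`.
#' @export
detect_scale <- function(study) {
  v <- study$values
  megax_check(length(v) > 0L, "empty expression matrix",
              "megax_validation_error")
  if (all(is.na(v)))
    megax_stop("all-NA expression matrix", "megax_validation_error")
  rng <- range(v, na.rm = TRUE)
  if (rng[2L] <= 30 && rng[1L] >= -10) "log2" else "linear"
}

#' Transform a linear-scale study to log2
#'
#' Applies `log2(x + 1)`; the pseudo-count keeps zero intensities finite
#' and is recorded as part of the canonical preprocessing so results are
#' reproducible bit for bit.
#'
#' @param study An [expression_study()] with `scale == "linear"`.
#' @return The study with transformed values and `scale == "log2"`.
#' @export
to_log2 <- function(study) {
  megax_check(identical(study$scale, "linear"),
              "study is not on the linear scale", "megax_validation_error")
  if (any(study$values <= -1, na.rm = TRUE))
    megax_stop("values <= -1 cannot be log2(x + 1) transformed",
               "megax_validation_error")
  study$values <- log2(study$values + 1)
  study$scale <- "log2"
  study
}

#' Collapse duplicate gene symbols
#'
#' Array platforms carry several probes per gene; rows sharing a symbol are
#' collapsed to the single row with the highest mean expression, ties going
#' to the first occurrence.
#'
#' @param study An [expression_study()].
#' @return The study with one row per gene symbol.
#' @export
collapse_duplicates <- function(study) {
  if (!anyDuplicated(study$genes)) return(study)
  means <- rowMeans(study$values, na.rm = TRUE)
  keep <- vapply(split(seq_along(study$genes), study$genes)[
    unique(study$genes)], function(idx) idx[which.max(means[idx])],
    integer(1L))
  keep <- sort(unname(keep))
  study$values <- study$values[keep, , drop = FALSE]
  study$genes <- study$genes[keep]
  study
}

#' @noRd
group_stats <- function(values, sel) {
  x <- values[, sel, drop = FALSE]
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  s2 <- rowSums((x - m)^2, na.rm = TRUE) / pmax(n - 1L, 1L)
  list(n = n, mean = m, var = s2)
}

#' Per-study log2 fold-change effects
#'
#' For each gene the effect size is the log2 fold change
#' `LFC = mean(case) - mean(control)` on log2-scale values, with the Welch
#' two-sample standard error `sqrt(s2_case/n_case + s2_control/n_control)`
#' (`s2` the unbiased sample variance). Genes with any missing value in the
#' study are excluded from that study's effects (reported via `message()`),
#' as are genes where either group has fewer than 2 usable samples.
#' Effects where both group variances are zero are kept with `se = 0` and
#' flagged `degenerate`.
#'
#' @param study An [expression_study()] on the log2 scale (see
#'   [to_log2()]).
#' @param genes Gene symbols to compute effects for; default all genes.
#' @return A `data.frame` with columns `study_id`, `gene`, `lfc`, `se`,
#'   `n_control`, `n_case`, `degenerate`.
#' @export
compute_study_effects <- function(study, genes = NULL) {
  megax_check(identical(study$scale, "log2"),
              "effects are defined on the log2 scale; call to_log2() first",
              "megax_validation_error")
  if (is.null(genes)) genes <- unique(study$genes)
  missing_genes <- setdiff(genes, study$genes)
  megax_check(length(missing_genes) == 0L,
              sprintf("gene(s) not in study %s: %s", study$metadata$study_id,
                      paste(missing_genes, collapse = ", ")),
              "megax_validation_error")
  study <- collapse_duplicates(study)
  idx <- match(genes, study$genes)
  values <- study$values[idx, , drop = FALSE]
  has_na <- rowSums(is.na(values)) > 0L
  if (any(has_na)) {
    message(sprintf("study %s: excluding %d gene(s) with missing values: %s",
                    study$metadata$study_id, sum(has_na),
                    paste(genes[has_na], collapse = ", ")))
    values <- values[!has_na, , drop = FALSE]
    genes <- genes[!has_na]
  }
  ctl <- group_stats(values, study$group == "control")
  cas <- group_stats(values, study$group == "case")
  megax_check(all(ctl$n >= 2L) && all(cas$n >= 2L),
              sprintf("study %s: a group has fewer than 2 usable samples",
                      study$metadata$study_id),
              "megax_degenerate_effect")
  se <- sqrt(cas$var / cas$n + ctl$var / ctl$n)
  data.frame(study_id = study$metadata$study_id, gene = genes,
             lfc = cas$mean - ctl$mean, se = se,
             n_control = as.integer(ctl$n), n_case = as.integer(cas$n),
             degenerate = se == 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @param gene A single gene symbol.
#' @rdname compute_study_effects
#' @export
compute_study_effect <- function(study, gene) {
  megax_check(length(gene) == 1L, "gene must be a single symbol",
              "megax_validation_error")
  compute_study_effects(study, genes = gene)
}

#' Effect tables for a whole study collection
#'
#' Convenience wrapper: transforms linear-scale studies with [to_log2()],
#' collapses duplicate symbols and row-binds [compute_study_effects()]
#' across studies.
#'
#' @param studies A list of [expression_study()] objects.
#' @param genes Genes of interest (default: genes present in the first
#'   study).
#' @return A combined effect `data.frame`.
#' @export
compute_collection_effects <- function(studies, genes = NULL) {
  megax_check(length(studies) > 0L, "no studies supplied",
              "megax_validation_error")
  if (is.null(genes)) genes <- unique(studies[[1L]]$genes)
  do.call(rbind, lapply(studies, function(s) {
    if (identical(s$scale, "linear")) s <- to_log2(s)
    compute_study_effects(s, genes = genes)
  }))
}
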