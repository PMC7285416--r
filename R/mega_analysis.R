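#' @noRd
check_effects <- function(effects, min_k = 2L) {
  megax_check(is.data.frame(effects) &&
                all(c("lfc", "se") %in% names(effects)),
              "effects must be a data.frame with columns lfc and se",
              "megax_validation_error")
  megax_check(nrow(effects) >= min_k,
              sprintf("at least %d studies are required (got %d)",
                      min_k, nrow(effects)),
              "megax_insufficient_studies")
  megax_check(all(is.finite(effects$lfc)), "non-finite lfc",
              "megax_validation_error")
  megax_check(all(effects$se > 0), "all standard errors must be > 0",
              "megax_validation_error")
  if ("gene" %in% names(effects))
    megax_check(length(unique(effects$gene)) == 1L,
                "effects mix several genes; pool one gene at a time",
                "megax_validation_error")
  invisible(effects)
}

#' Cochran's Q, I-squared and DerSimonian-Laird tau-squared
#'
#' Heterogeneity of a set of per-study effects for one gene. With fixed
#' (inverse-variance) weights `w_i = 1/se_i^2` and the fixed-effects pooled
#' estimate `m`, Cochran's statistic is `Q = sum(w_i (lfc_i - m)^2)` on
#' `df = k - 1` degrees of freedom. `I2 = 100 * max(0, (Q - df)/Q)` is the
#' percentage of total variation attributable to between-study
#' heterogeneity (0 when `Q = 0`), and the DerSimonian-Laird moment
#' estimator of the between-study variance is
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`, so `tau2 = 0`
#' exactly when `Q <= df`.
#'
#' @param effects Effect `data.frame` for a single gene with columns `lfc`
#'   and `se` (at least 2 studies, all `se > 0`).
#' @return An object of class `heterogeneity_stats`: list with `Q`, `df`,
#'   `ISq_pct`, `p_Q` (upper-tail chi-square p of `Q`), `tau2`.
#' @export
heterogeneity <- function(effects) {
  check_effects(effects)
  w <- 1 / effects$se^2
  m <- sum(w * effects$lfc) / sum(w)
  Q <- sum(w * (effects$lfc - m)^2)
  df <- nrow(effects) - 1L
  structure(list(
    Q = Q, df = df,
    ISq_pct = if (Q > 0) 100 * max(0, (Q - df) / Q) else 0,
    p_Q = stats::pchisq(Q, df, lower.tail = FALSE),
    tau2 = max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))),
    class = "heterogeneity_stats")
}

#' @export
print.heterogeneity_stats <- function(x, ...) {
  cat(sprintf("Q = %.4g on df = %d (p = %.3g), I2 = %.2f%%, tau2 = %.4g\n",
              x$Q, x$df, x$p_Q, x$ISq_pct, x$tau2))
  invisible(x)
}

#' Inverse-variance pooling of study effects
#'
#' Fixed-effects weights are `1/se_i^2`; random-effects weights are
#' `1/(se_i^2 + tau2)` with `tau2` the DerSimonian-Laird estimate from
#' [heterogeneity()]. The pooled effect is the weighted mean, its standard
#' error `1/sqrt(sum(w))`, the 95% CI `pooled +/- 1.959964 se`, and the
#' p-value the two-sided normal (z) test of `pooled/se`. Reported weights
#' are normalized to a maximum of 1, the convention used in forest plots
#' of this pipeline.
#'
#' @param effects Effect `data.frame` for one gene (columns `lfc`, `se`,
#'   optionally `study_id`, `gene`).
#' @param model `"fixed"` or `"random"`.
#' @return An object of class `mega_result`.
#' @seealso [mega_analyze()] for heterogeneity-driven model selection.
#' @export
pool_effects <- function(effects, model = c("fixed", "random")) {
  model <- match.arg(model)
  check_effects(effects)
  het <- heterogeneity(effects)
  w <- if (model == "fixed") 1 / effects$se^2
       else 1 / (effects$se^2 + het$tau2)
  pooled <- sum(w * effects$lfc) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- pooled / se
  ids <- if ("study_id" %in% names(effects)) effects$study_id
         else sprintf("study_%d", seq_len(nrow(effects)))
  study_data <- data.frame(
    study_id = ids, lfc = effects$lfc, se = effects$se,
    ci_low = effects$lfc - Z95 * effects$se,
    ci_high = effects$lfc + Z95 * effects$se,
    weight = w / max(w), stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    gene = if ("gene" %in% names(effects)) effects$gene[1L] else NA_character_,
    model = model, k_studies = nrow(effects),
    pooled_lfc = pooled, se = se,
    ci95 = c(pooled - Z95 * se, pooled + Z95 * se),
    p_value = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
    het = het,
    weights = stats::setNames(study_data$weight, ids),
    studies_used = ids,
    study_data = study_data),
    class = "mega_result")
}

#' @export
print.mega_result <- function(x, ...) {
  cat(sprintf("<mega_result> %s: %s-effects pooling of %d studies\n",
              if (is.na(x$gene)) "(gene?)" else x$gene, x$model,
              x$k_studies))
  cat(sprintf("  pooled LFC %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$pooled_lfc, x$se, x$ci95[1L], x$ci95[2L], x$p_value))
  cat("  "); print(x$het)
  invisible(x)
}

#' Mega-analysis with heterogeneity-driven model selection
#'
#' Computes [heterogeneity()] and selects the fixed-effects model when
#' Cochran's `Q` does not exceed its degrees of freedom (equivalently the
#' truncated `I2` is 0, so the DerSimonian-Laird `tau2` is 0), otherwise
#' the random-effects model; then pools with [pool_effects()].
#'
#' @inheritParams pool_effects
#' @return A `mega_result` whose `model` records the selected model.
#' @export
mega_analyze <- function(effects) {
  het <- heterogeneity(effects)
  pool_effects(effects, model = if (het$Q <= het$df) "fixed" else "random")
}

#' Select the top datasets by absolute effect size
#'
#' The "top datasets" for a gene are the `floor(k * fraction)` studies with
#' the largest absolute effect size `|lfc|`; ranking is stable, so studies
#' tied for the last slot are resolved in favour of earlier input rows.
#' Selected studies are returned in their original input order. At least 2
#' studies must survive the cut.
#'
#' @inheritParams pool_effects
#' @param fraction Proportion of studies to retain, in `(0, 1]`
#'   (default 0.5).
#' @return The retained subset of `effects`.
#' @export
select_top_datasets <- function(effects, fraction = 0.5) {
  megax_check(is.numeric(fraction) && length(fraction) == 1L &&
                fraction > 0 && fraction <= 1,
              "fraction must be in (0, 1]", "megax_validation_error")
  check_effects(effects)
  k <- nrow(effects)
  m <- floor(k * fraction)
  megax_check(m >= 2L,
              sprintf("top-%g%% of %d studies leaves %d < 2 studies",
                      100 * fraction, k, m),
              "megax_insufficient_studies")
  idx <- order(-abs(effects$lfc))[seq_len(m)]  # stable: ties keep input order
  effects[sort(idx), , drop = FALSE]
}

#' Partial mega-analysis over the top datasets
#'
#' Runs [mega_analyze()] on the [select_top_datasets()] subset: for each
#' gene, only the `fraction` of studies with the largest `|lfc|` enter the
#' pooling. Note this conditions on the observed effect sizes, so under the
#' null it inflates `|pooled_lfc|` by construction; see the methods
#' vignette for the selection-bias property.
#'
#' @inheritParams select_top_datasets
#' @return A `mega_result`; `studies_used` records the retained studies.
#' @export
partial_mega_analyze <- function(effects, fraction = 0.5) {
  mega_analyze(select_top_datasets(effects, fraction))
}

#' Mega- and partial mega-analysis for every gene in an effect table
#'
#' @param effects Effect `data.frame` with a `gene` column covering one or
#'   more genes.
#' @param fraction Top fraction for the partial analysis (0.5 by default).
#' @return A named list (per gene) of lists with elements `full` and
#'   `partial`, each a `mega_result`.
#' @export
mega_analyze_genes <- function(effects, fraction = 0.5) {
  megax_check("gene" %in% names(effects), "effects needs a gene column",
              "megax_validation_error")
  genes <- unique(effects$gene)
  out <- lapply(genes, function(g) {
    e <- effects[effects$gene == g, , drop = FALSE]
    list(full = mega_analyze(e),
         partial = partial_mega_analyze(e, fraction))
  })
  stats::setNames(out, genes)
}
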