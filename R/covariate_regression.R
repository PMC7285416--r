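#' Regress study-level effects on study covariates
#'
#' Ordinary least squares of the per-study log2 fold change of one gene on
#' study-level factors, to flag influences such as sample size, country of
#' origin or study age on the reported effect. Numeric factors enter
#' as-is; categorical factors are coded with treatment contrasts and are
#' tested jointly (partial F test), so every declared factor gets exactly
#' one p-value. `n_total` (control + case samples) is derived
#' automatically when requested.
#'
#' With about a dozen studies a multi-level factor such as country nearly
#' saturates the design: the fit warns when fewer than 3 residual degrees
#' of freedom remain and refuses to fit with none, and a rank-deficient
#' design is an error naming the aliased terms rather than a silently
#' dropped column.
#'
#' @param effects Effect `data.frame` for one gene (column `study_id`
#'   linking into `studies`).
#' @param studies Study-metadata `data.frame` (see [read_study_table()]).
#' @param factors Character vector of factor names: metadata columns
#'   and/or `"n_total"`.
#' @param weighted If `TRUE`, weight observations by `1/se^2`
#'   (inverse-variance weighted least squares); default unweighted.
#' @return An object of class `mlr_result`: list with `gene`, `factor_p`
#'   (named per-factor p-values), `coefficients`, `n_studies`, `r2` and
#'   the underlying `lm` fit.
#' @export
fit_mlr <- function(effects, studies, factors, weighted = FALSE) {
  check_effects(effects)
  megax_check(length(factors) > 0L, "no factors declared",
              "megax_validation_error")
  megax_check(all(effects$study_id %in% studies$study_id),
              "every effect's study_id must appear in the study table",
              "megax_validation_error")
  dat <- merge(effects, studies, by = "study_id", sort = FALSE,
               suffixes = c("", ".meta"))
  dat$n_total <- dat$n_control + dat$n_case
  missing <- setdiff(factors, names(dat))
  megax_check(length(missing) == 0L,
              sprintf("unknown factor(s): %s",
                      paste(missing, collapse = ", ")),
              "megax_validation_error")
  for (f in factors)
    if (is.character(dat[[f]])) dat[[f]] <- factor(dat[[f]])

  form <- stats::reformulate(factors, response = "lfc")
  n_par <- sum(vapply(factors, function(f)
    if (is.factor(dat[[f]])) nlevels(dat[[f]]) - 1L else 1L,
    integer(1L))) + 1L
  megax_check(nrow(dat) >= n_par + 1L,
              sprintf("%d studies cannot identify %d parameters",
                      nrow(dat), n_par),
              "megax_insufficient_studies")

  fit <- if (weighted) stats::lm(form, data = dat, weights = 1 / dat$se^2)
         else stats::lm(form, data = dat)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased) > 0L)
    megax_stop(sprintf("design is rank deficient; aliased term(s): %s",
                       paste(aliased, collapse = ", ")),
               "megax_multicollinearity_error")
  rdf <- stats::df.residual(fit)
  megax_check(rdf > 0L, "no residual degrees of freedom left",
              "megax_insufficient_studies")
  if (rdf < 3L)
    warning(sprintf("only %d residual df: factor tests are fragile", rdf),
            call. = FALSE)

  ## one p per declared factor: marginal F tests (equal to the coefficient
  ## t test for single-column factors)
  dr <- stats::drop1(fit, scope = form, test = "F")
  factor_p <- stats::setNames(dr[factors, "Pr(>F)"], factors)
  structure(list(
    gene = if ("gene" %in% names(effects)) effects$gene[1L] else NA_character_,
    factor_p = factor_p,
    coefficients = stats::coef(fit),
    n_studies = nrow(dat),
    r2 = summary(fit)$r.squared,
    fit = fit),
    class = "mlr_result")
}

#' @export
print.mlr_result <- function(x, ...) {
  cat(sprintf("<mlr_result> %s: OLS of lfc on %d studies, R2 = %.3f\n",
              if (is.na(x$gene)) "(gene?)" else x$gene, x$n_studies, x$r2))
  for (f in names(x$factor_p))
    cat(sprintf("  %-18s p = %.4g\n", f, x$factor_p[[f]]))
  invisible(x)
}
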