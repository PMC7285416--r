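#' Ground truth for the multi-study simulator
#'
#' Defines the generative model used by [simulate_collection()] and
#' [simulate_effect_table()]. For gene `g` in study `s` the study-level
#' effect is `delta_gs = delta_g + covariate shifts for s + N(0, tau2)`;
#' control samples are `N(mu_g, base_noise_sd^2)` and case samples
#' `N(mu_g + delta_gs, base_noise_sd^2)`, all on the log2 scale, with the
#' per-gene baseline `mu_g` drawn once from `baseline_range`.
#'
#' @param gene_truth Named numeric vector: true log2 fold change `delta`
#'   per gene.
#' @param tau2 Between-study variance of the study-level effect
#'   (non-negative).
#' @param covariate_effects Named list of additive shifts on `delta`. An
#'   element named after a numeric metadata column (e.g.
#'   `study_age_years`) is a slope; an element named after a categorical
#'   column (e.g. `country`) is a named vector of per-level shifts
#'   (levels not listed shift by 0).
#' @param base_noise_sd Per-sample residual SD on the log2 scale
#'   (default 1, a typical residual spread for array intensities).
#' @param baseline_range Range the per-gene baseline `mu_g` is drawn from
#'   (default `c(4, 10)`, the mid-range of log2 array intensities).
#' @param seed Integer seed; every draw derives from it.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(gene_truth, tau2 = 0,
                             covariate_effects = list(),
                             base_noise_sd = 1,
                             baseline_range = c(4, 10),
                             seed = 1L) {
  megax_check(is.numeric(gene_truth) && length(gene_truth) > 0L &&
                !is.null(names(gene_truth)),
              "gene_truth must be a named numeric vector",
              "megax_validation_error")
  megax_check(is.numeric(tau2) && tau2 >= 0, "tau2 must be >= 0",
              "megax_validation_error")
  megax_check(is.numeric(base_noise_sd) && base_noise_sd > 0,
              "base_noise_sd must be > 0", "megax_validation_error")
  structure(list(gene_truth = gene_truth, tau2 = tau2,
                 covariate_effects = covariate_effects,
                 base_noise_sd = base_noise_sd,
                 baseline_range = baseline_range,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

#' @noRd
covariate_shift <- function(truth, meta) {
  shift <- 0
  for (cov in names(truth$covariate_effects)) {
    megax_check(cov %in% names(meta),
                sprintf("covariate '%s' not in study metadata", cov),
                "megax_validation_error")
    eff <- truth$covariate_effects[[cov]]
    val <- meta[[cov]]
    shift <- shift + if (is.null(names(eff))) eff * as.numeric(val)
                     else if (as.character(val) %in% names(eff))
                       eff[[as.character(val)]]
                     else 0
  }
  shift
}

## deterministic per-study substream so a study can be regenerated alone
study_seed <- function(seed, i, stream = 0L) {
  as.integer((as.numeric(seed) + 1000003 * i + 29 * stream) %% 2147483629)
}

#' Simulate a multi-study expression collection
#'
#' Draws genes-by-samples log2 expression matrices for every study in a
#' metadata table under the generative model of [simulation_truth()].
#' Reproducible: the per-gene baselines derive from `truth$seed` and each
#' study from a substream keyed by `(seed, study index)`, so the same truth
#' always yields the same collection.
#'
#' @param truth A [simulation_truth()].
#' @param studies Study-metadata `data.frame` (see [read_study_table()]),
#'   non-empty.
#' @return A list of [expression_study()] objects, one per metadata row.
#' @export
simulate_collection <- function(truth, studies) {
  megax_check(inherits(truth, "simulation_truth"),
              "truth must be a simulation_truth", "megax_validation_error")
  megax_check(is.data.frame(studies) && nrow(studies) >= 1L,
              "studies must be a non-empty metadata table",
              "megax_validation_error")
  genes <- names(truth$gene_truth)
  G <- length(genes)
  set.seed(study_seed(truth$seed, 0L))
  mu <- stats::runif(G, truth$baseline_range[1L], truth$baseline_range[2L])
  lapply(seq_len(nrow(studies)), function(i) {
    meta <- studies[i, , drop = FALSE]
    set.seed(study_seed(truth$seed, i))
    delta <- truth$gene_truth + covariate_shift(truth, meta) +
      stats::rnorm(G, 0, sqrt(truth$tau2))
    nc <- meta$n_control; nk <- meta$n_case
    ctl <- matrix(stats::rnorm(G * nc, mu, truth$base_noise_sd),
                  nrow = G)
    cas <- matrix(stats::rnorm(G * nk, mu + delta, truth$base_noise_sd),
                  nrow = G)
    values <- cbind(ctl, cas)
    dimnames(values) <- list(genes, sprintf("%s_%s%d", meta$study_id,
                                            rep(c("C", "T"), c(nc, nk)),
                                            c(seq_len(nc), seq_len(nk))))
    expression_study(meta, values,
                     rep(c("control", "case"), c(nc, nk)),
                     scale = "log2")
  })
}

#' Simulate per-study effect tables directly
#'
#' Effect-level shortcut for testing the pooling stages without drawing
#' sample-level matrices: for each study the reported standard error is
#' `SE = base_noise_sd * sqrt(1/n_control + 1/n_case)` and the observed
#' effect is drawn from `N(delta + shifts, tau2 + SE^2)` — the marginal
#' distribution of the matrix-level LFC under [simulate_collection()].
#'
#' @inheritParams simulate_collection
#' @return An effect `data.frame` (columns `study_id`, `gene`, `lfc`,
#'   `se`, `n_control`, `n_case`).
#' @export
simulate_effect_table <- function(truth, studies) {
  megax_check(inherits(truth, "simulation_truth"),
              "truth must be a simulation_truth", "megax_validation_error")
  megax_check(is.data.frame(studies) && nrow(studies) >= 1L,
              "studies must be a non-empty metadata table",
              "megax_validation_error")
  genes <- names(truth$gene_truth)
  G <- length(genes)
  do.call(rbind, lapply(seq_len(nrow(studies)), function(i) {
    meta <- studies[i, , drop = FALSE]
    se <- truth$base_noise_sd * sqrt(1 / meta$n_control + 1 / meta$n_case)
    set.seed(study_seed(truth$seed, i, stream = 1L))
    lfc <- stats::rnorm(G, truth$gene_truth + covariate_shift(truth, meta),
                        sqrt(truth$tau2 + se^2))
    data.frame(study_id = meta$study_id, gene = genes, lfc = lfc,
               se = se, n_control = meta$n_control, n_case = meta$n_case,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Default simulated study table
#'
#' A convenience metadata table mirroring the shape of the packaged LSCC
#' collection: `k` studies with the given group sizes, spread over
#' countries and study ages.
#'
#' @param k Number of studies.
#' @param n_control,n_case Per-study group sizes (recycled to length `k`).
#' @param countries Country labels to cycle through.
#' @return A study-metadata `data.frame`.
#' @export
simulated_study_table <- function(k = 11L, n_control = 30L, n_case = 30L,
                                  countries = c("A", "B", "C", "D")) {
  n_control <- rep_len(n_control, k)
  n_case <- rep_len(n_case, k)
  do.call(rbind, lapply(seq_len(k), function(i) {
    study_metadata(sprintf("SIM%03d", i), n_control[i], n_case[i],
                   country = countries[(i - 1L) %% length(countries) + 1L],
                   study_age_years = 2 + (i - 1L))
  }))
}
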