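# Shared fixtures and independent oracles for the megax test suite.

## a 2-gene, 4-sample toy study (control means 1 and 4, case means 4 and 4)
toy_study <- function() {
  values <- matrix(c(0, 2, 3, 5,
                     4, 4, 4, 4), nrow = 2, byrow = TRUE,
                   dimnames = list(c("G1", "G2"),
                                   c("s1", "s2", "s3", "s4")))
  expression_study(study_metadata("TOY1", 2, 2), values,
                   c("control", "control", "case", "case"))
}

toy_study_file <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("sample_id\ts1\ts2\ts3\ts4",
               "group\tcontrol\tcontrol\tcase\tcase",
               "G1\t0\t2\t3\t5",
               "G2\t4\t4\t4\t4"), path)
  path
}

## study table with the group sizes of the packaged LSCC collection but
## simulated IDs, for Monte-Carlo work at realistic sizes
lscc_like_table <- function(k = 11) {
  simulated_study_table(
    k = k,
    n_control = c(9, 8, 14, 27, 59, 65, 5, 30, 28, 5, 7)[seq_len(k)],
    n_case = c(9, 69, 61, 14, 12, 27, 35, 48, 34, 14, 17)[seq_len(k)])
}

## brute-force inverse-variance pooling oracle (independent of pool_effects)
oracle_pool <- function(lfc, se, tau2 = 0) {
  w <- 1 / (se^2 + tau2)
  est <- sum(w * lfc) / sum(w)
  list(est = est, se = sqrt(1 / sum(w)))
}

## exhaustive hypergeometric upper-tail oracle: enumerate every possible
## n-gene query from an N-gene universe and count overlaps >= k with a
## fixed K-gene set
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

## hand step-up BH oracle
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}
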