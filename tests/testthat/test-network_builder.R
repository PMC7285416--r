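diag_rel <- read_relation_table(lscc_fixture("diagnostic_relations"))
prog_rel <- read_relation_table(lscc_fixture("prognostic_relations"))

test_that("the diagnostic fixture yields the published marker partition", {
  net <- build_diagnostic_network(diag_rel, "PPARG", "LSCC")
  expect_equal(length(net$positive_markers) + length(net$negative_markers),
               12L)
  expect_setequal(net$positive_markers,
                  c("XIAP", "UBE2D1", "SKP2", "ACKR3", "MI21", "HOXA10",
                    "STAT1", "PDPN"))
  expect_setequal(net$negative_markers,
                  c("MIR223", "ANGPT1", "CYP2A6", "FOXA2"))
  expect_length(intersect(net$positive_markers, net$negative_markers), 0L)
  ## every marker carries exactly one driver and one disease edge
  for (g in c(net$positive_markers, net$negative_markers)) {
    e <- net$edges[net$edges$target == g, ]
    expect_setequal(e$source, c("PPARG", "LSCC"))
  }
  expect_true(all(net$consistency == "untested"))  # no mega supplied
})

test_that("consistency labels follow the pooled expression direction", {
  mega <- list(XIAP = 0.8, UBE2D1 = -0.5, MIR223 = -0.3, ANGPT1 = 1e-12)
  net <- build_diagnostic_network(diag_rel, "PPARG", "LSCC", mega = mega)
  expect_equal(unname(net$consistency["XIAP"]), "consistent")
  expect_equal(unname(net$consistency["UBE2D1"]), "inconsistent")
  expect_equal(unname(net$consistency["MIR223"]), "consistent")
  expect_equal(unname(net$consistency["ANGPT1"]), "untested")  # |lfc| ~ 0
  expect_equal(unname(net$consistency["SKP2"]), "untested")
  kept <- consistent_markers(net)
  expect_false("UBE2D1" %in% kept)
  expect_true(all(c("XIAP", "MIR223", "ANGPT1", "SKP2") %in% kept))
})

test_that("flipping every polarity swaps the marker lists exactly", {
  flipped <- transform(diag_rel, polarity = -polarity)
  a <- build_diagnostic_network(diag_rel, "PPARG", "LSCC")
  b <- build_diagnostic_network(flipped, "PPARG", "LSCC")
  expect_setequal(b$positive_markers, a$negative_markers)
  expect_setequal(b$negative_markers, a$positive_markers)
})

test_that("network assembly is order independent and validates polarity", {
  set.seed(8)
  shuffled <- diag_rel[sample(nrow(diag_rel)), ]
  a <- build_diagnostic_network(diag_rel, "PPARG", "LSCC")
  b <- build_diagnostic_network(shuffled, "PPARG", "LSCC")
  expect_equal(a$positive_markers, b$positive_markers)
  expect_equal(a$negative_markers, b$negative_markers)
  conflict <- rbind(diag_rel,
                    data.frame(source = "PPARG", target = "XIAP",
                               polarity = 1L, relation_kind = "regulation",
                               provenance = "x"))
  expect_error(build_diagnostic_network(conflict, "PPARG", "LSCC"),
               "XIAP", class = "megax_validation_error")
  empty <- build_diagnostic_network(diag_rel[0, ], "PPARG", "LSCC")
  expect_length(empty$positive_markers, 0L)
  expect_length(empty$negative_markers, 0L)
})

test_that("the prognostic fixture yields the published regulator chain", {
  chain <- build_prognostic_network(prog_rel, "PPARG", "LSCC")
  expect_setequal(chain$promoters, c("TNF", "NOS2", "ACE"))
  expect_equal(chain$inhibitors, "STK11")
  expect_length(intersect(chain$promoters, chain$inhibitors), 0L)
})

test_that("prognostic chains annotate but never filter on expression", {
  ## promoters down in disease (moving with the driver) are retained
  mega <- list(TNF = -0.4, NOS2 = -0.2, ACE = -0.1, STK11 = 0.05)
  chain <- build_prognostic_network(prog_rel, "PPARG", "LSCC", mega = mega)
  expect_setequal(chain$promoters, c("TNF", "NOS2", "ACE"))
  expect_equal(unname(chain$expression_direction["TNF"]), -1L)
  expect_equal(unname(chain$expression_direction["STK11"]), 1L)
  ## co-directional edges produce no chain members
  codir <- transform(prog_rel,
                     polarity = ifelse(relation_kind == "regulation",
                                       abs(polarity), polarity))
  codir$polarity[codir$source == "STK11"] <- 1L
  chain2 <- build_prognostic_network(codir, "PPARG", "LSCC")
  expect_length(chain2$promoters, 0L)
})
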