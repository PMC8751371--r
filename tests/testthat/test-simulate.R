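test_that("preset constructor validates its parameters", {
  expect_error(subtype_preset("X", 10, c(Signature.1 = 0.5), 0.1),
               "sum to 1")
  expect_error(subtype_preset("X", 10, c(Signature.1 = 1), 1.5), "msi")
  p <- subtype_preset("X", 10, c(Signature.1 = 1), 0.01,
                      segment_profile = c(gain = 2L))
  expect_equal(unname(p$segment_profile["gain"]), 2L)
  expect_equal(unname(p$segment_profile["lst_pair"]), 0L)
})

test_that("simulated samples are reproducible and carry planted truth", {
  p <- default_presets()$`CN-low`
  a <- simulate_sample(p, seed = 42)
  b <- simulate_sample(p, seed = 42)
  expect_equal(as.data.frame(a$variants), as.data.frame(b$variants))
  expect_equal(as.data.frame(a$segments), as.data.frame(b$segments))
  truth <- attr(a, "planted")
  expect_equal(truth$label, "CN-low")
  expect_equal(truth$seed, 42)
  expect_equal(nrow(validate_profile(a)), 0)
  # global RNG stream is untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(simulate_sample(p, seed = 9)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("a zero-mutation preset yields an empty variant table and TMB 0", {
  p <- subtype_preset("empty", 0, c(Signature.1 = 1), 0)
  prof <- simulate_sample(p, seed = 1)
  expect_equal(nrow(prof$variants), 0)
  expect_equal(compute_tmb(prof$variants, prof$callable_mb), 0)
})

test_that("each default preset satisfies its defining metric bounds", {
  presets <- default_presets()
  for (s in 1:5) {
    b <- compute_burden(simulate_sample(presets$POLE, seed = s))
    expect_gt(b$tmb, 600); expect_lt(b$msi_score, 3)
    b <- compute_burden(simulate_sample(presets$MMRd, seed = s))
    expect_gt(b$tmb, 20); expect_gte(b$msi_score, 3)
    b <- compute_burden(simulate_sample(presets$`CN-high`, seed = s))
    expect_lte(b$tmb, 10); expect_gt(b$pct_cna, 25)
    expect_gt(b$n_cna_segments, 15)
    b <- compute_burden(simulate_sample(presets$`CN-low`, seed = s))
    expect_lte(b$pct_cna, 25)
  }
})

test_that("simulated catalogs match the mixture spectrum (chi-square GOF)", {
  catref <- default_signature_catalog()
  mix <- c(Signature.1 = 0.5, Signature.2 = 0.25, Signature.3 = 0.25)
  cat <- simulate_catalog(mix, 3000, catref, seed = 1)
  expect_equal(sum(cat), 3000)
  expected <- as.numeric(catref$signatures[, names(mix)] %*% mix) * 3000
  keep <- expected > 5
  gof <- suppressWarnings(
    stats::chisq.test(as.integer(cat)[keep], p = expected[keep] /
                        sum(expected[keep])))
  expect_gt(gof$p.value, 0.01)
  expect_equal(sum(simulate_catalog(mix, 0, catref, seed = 1)), 0)
  expect_error(simulate_catalog(c(Signature.1 = 1.2, Signature.2 = -0.2),
                                100, catref), "nonnegative")
})

test_that("whole-genome duplication doubles planted copy numbers", {
  p <- subtype_preset("wgd", 10, c(Signature.1 = 1), 0.01,
                      segment_profile = c(gain = 1L), wgd = TRUE)
  prof <- simulate_sample(p, seed = 2)
  states <- unique(prof$segments[, c("total_cn", "minor_cn")])
  expect_true(all(states$total_cn %in% c(4L, 6L)))
  expect_true(all(states$minor_cn %in% c(2L)))
})

test_that("clone-tree specs enforce the prevalence sum rule before sampling", {
  expect_error(clone_tree_spec(
    data.frame(id = 1:3, parent = c(NA, 1, 1), n_private = c(10, 10, 10)),
    matrix(c(1, 0.7, 0.6), nrow = 1, dimnames = list("S", 1:3))),
    "sum rule")
  expect_error(clone_tree_spec(
    data.frame(id = 1:2, parent = c(NA, NA), n_private = c(10, 10)),
    matrix(c(1, 0.5), nrow = 1, dimnames = list("S", 1:2))),
    "one root")
})

test_that("single-clone trees give fully shared panels", {
  tree <- clone_tree_spec(
    data.frame(id = 1, parent = NA, n_private = 80),
    matrix(c(1, 1, 1), nrow = 3, dimnames = list(c("P", "A", "B"), 1)))
  sim <- simulate_lineage_panel(tree, samples = data.frame(
    sample_id = c("P", "A", "B"), role = c("primary", "pdx", "pdx"),
    lineage = c(NA, "A", "B"), passage = c(NA, 0, 0), purity = 1),
    depth = 200, seed = 1)
  panel <- build_panel(sim$samples)
  expect_equal(names(euler_regions(panel)), "A&B&P")
})

test_that("volume simulation honors noiseless growth-rate settings", {
  s <- simulate_volume_series(n_per_arm = 4, growth_rate_vehicle = 0.08,
                              growth_rate_drug = 0.08, noise_sd = 0,
                              days = seq(0, 28, 7), seed = 1)
  r <- summarize_response(s)
  expect_equal(r$tgi_percent, 0, tolerance = 1e-9)
  s2 <- simulate_volume_series(n_per_arm = 4, growth_rate_vehicle = 0.08,
                               growth_rate_drug = 0, noise_sd = 0,
                               days = seq(0, 28, 7), seed = 1)
  r2 <- summarize_response(s2)
  expect_equal(r2$mean_rel_change_drug, 0, tolerance = 1e-9)
  expect_equal(r2$category, "SD")
  expect_error(simulate_volume_series(noise_sd = -1), "noise_sd")
})
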