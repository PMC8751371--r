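catref <- default_signature_catalog()

test_that("catalog construction maps contexts to channels on the pyrimidine strand", {
  v <- somatic_variants(chrom = c("1", "1"), pos = c(100, 200),
                        ref = c("C", "G"), alt = c("A", "T"),
                        vclass = "SNP", context3 = c("ACA", "TGT"),
                        vaf = c(0.5, 0.5), depth = c(80L, 80L))
  cat <- build_catalog(v)
  # G>T at TGT reverse-complements to C>A at ACA: both land in one channel
  expect_equal(unname(cat["A[C>A]A"]), 2L)
  expect_equal(sum(cat), 2L)
  expect_equal(sum(build_catalog(somatic_variants())), 0L)
})

test_that("inconsistent contexts are skipped with a warning; indels ignored", {
  v <- somatic_variants(chrom = c("1", "1", "1"), pos = c(1, 2, 3),
                        ref = c("C", "C", "A"), alt = c("T", "T", "-"),
                        vclass = c("SNP", "SNP", "DEL"),
                        context3 = c("ACA", "ATA", NA),  # ATA middle != C
                        vaf = rep(0.5, 3), depth = rep(80L, 3))
  expect_warning(cat <- build_catalog(v), "skipped")
  expect_equal(sum(cat), 1L)
  expect_equal(attr(cat, "n_skipped"), 1L)
})

test_that("refit recovers an identity mixture and respects the cutoff", {
  e <- refit_exposures(simulate_catalog(c(Signature.10 = 1), 1000, catref,
                                        seed = 1), catref)
  expect_gte(e$weights["Signature.10"], 0.95)
  expect_true(all(e$weights >= e$cutoff_used))
  expect_equal(sum(e$weights), 1, tolerance = 1e-6)
  expect_error(refit_exposures(structure(integer(96),
                                         class = "mutation_catalog96")),
               "empty spectrum")
})

test_that("refit weights are scale invariant in catalog counts", {
  cat1 <- simulate_catalog(c(Signature.1 = 0.6, Signature.2 = 0.4), 2000,
                           catref, seed = 5)
  cat5 <- structure(as.integer(cat1) * 5L, names = names(cat1),
                    class = "mutation_catalog96")
  e1 <- refit_exposures(cat1, catref)
  e5 <- refit_exposures(cat5, catref)
  expect_equal(e1$weights, e5$weights, tolerance = 1e-9)
  expect_equal(e5$n_snvs, 5L * e1$n_snvs)
})

test_that("reconstruction error never exceeds the best single signature", {
  for (s in 1:5) {
    mix <- c(Signature.1 = 0.5, Signature.13 = 0.3, Signature.5 = 0.2)
    cat <- simulate_catalog(mix, 4000, catref, seed = s)
    e <- refit_exposures(cat, catref)
    m <- as.numeric(cat) / sum(cat)
    best_single <- min(apply(catref$signatures, 2,
                             function(col) sum((m - col) ^ 2)))
    expect_lte(e$residual_sse, best_single + 1e-12)
  }
})

test_that("refit matches exhaustive simplex grid search on small catalogs", {
  for (case in list(c(Signature.1 = 0.55, Signature.2 = 0.45),
                    c(Signature.1 = 0.4, Signature.2 = 0.35,
                      Signature.13 = 0.25))) {
    sub <- signature_catalog(catref$signatures[, names(case), drop = FALSE])
    cat <- simulate_catalog(case, 5000, catref, seed = 11)
    e <- refit_exposures(cat, sub, cutoff = 0.15)
    m <- as.numeric(cat) / sum(cat)
    grid <- grid_refit(m, sub$signatures)
    expect_lte(e$residual_sse, grid$sse + 1e-6)
    expect_equal(unname(e$weights[names(case)]), grid$w, tolerance = 0.011)
  }
})

test_that("mixture recovery stays within 0.05 mean absolute error over seeds", {
  errs <- c()
  for (s in 1:20) {
    mix <- if (s %% 2 == 0)
      c(Signature.1 = 0.4, Signature.2 = 0.35, Signature.13 = 0.25)
    else c(Signature.6 = 0.7, Signature.10 = 0.3)
    e <- refit_exposures(simulate_catalog(mix, 5000, catref, seed = s), catref)
    w <- e$weights[names(mix)]
    w[is.na(w)] <- 0
    errs <- c(errs, abs(w - mix))
  }
  expect_lt(mean(errs), 0.05)
})

test_that("dominant etiology follows the 30% rule", {
  fake <- function(w) structure(list(weights = w, residual_sse = 0,
                                     n_snvs = 100L, cutoff_used = 0.15),
                                class = "exposure_estimate")
  expect_equal(dominant_etiology(fake(c(Signature.10 = 0.8,
                                        Signature.1 = 0.2)), catref), "POLE")
  expect_equal(dominant_etiology(fake(c(Signature.1 = 0.25, Signature.2 = 0.25,
                                        Signature.5 = 0.25,
                                        Signature.13 = 0.25)), catref), "none")
  expect_equal(dominant_etiology(fake(c(Signature.2 = 0.45, Signature.1 = 0.3,
                                        Signature.5 = 0.25)), catref), "APOBEC")
  expect_equal(dominant_etiology(fake(c(Signature.3 = 0.5,
                                        Signature.1 = 0.5)), catref), "HRD")
})

test_that("bundled signature file matches the generator and is normalized", {
  m <- catref$signatures
  expect_equal(dim(m), c(96L, 30L))
  expect_equal(unname(colSums(m)), rep(1, 30), tolerance = 1e-9)
  expect_equal(m, make_synthetic_signatures(), tolerance = 1e-6,
               ignore_attr = TRUE)
})
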