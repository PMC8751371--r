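clonal_variants <- function(n, vaf, depth = 100, chrom = "1") {
  somatic_variants(chrom = rep(chrom, n), pos = seq_len(n) * 1000,
                   ref = rep("C", n), alt = rep("T", n), vclass = "SNP",
                   context3 = rep("ACA", n), vaf = vaf, depth = rep(depth, n))
}

test_that("purity is twice the VAF mode, clamped at 1", {
  expect_equal(estimate_purity(clonal_variants(200, rep(0.5, 200))), 1.0,
               tolerance = 0.01)  # density-grid resolution
  # bimodal: clonal majority at 0.4, subclone at 0.1 -> purity 0.8
  v <- clonal_variants(300, c(rep(0.4, 220), rep(0.1, 80)))
  expect_equal(estimate_purity(v), 0.8, tolerance = 0.02)
  expect_error(estimate_purity(clonal_variants(10, rep(0.4, 10))),
               "insufficient variants")
  # depth filter removes low-coverage variants
  low <- clonal_variants(100, rep(0.4, 100), depth = 10)
  expect_error(estimate_purity(low), "insufficient variants")
})

test_that("purity recovery from binomial sampling hits the planted value", {
  set.seed(11)
  for (true_p in c(0.83, 0.45)) {
    vaf <- pmax(1, rbinom(500, 100, true_p / 2)) / 100
    est <- estimate_purity(clonal_variants(500, vaf))
    expect_equal(est, true_p, tolerance = 0.05)
  }
})

test_that("copy-neutral filter restricts purity estimation when segments given", {
  v <- rbind(as.data.frame(clonal_variants(100, rep(0.25, 100), chrom = "1")),
             as.data.frame(clonal_variants(100, rep(0.48, 100), chrom = "2")))
  v$pos <- rep(seq_len(100) * 1000, 2)
  class(v) <- c("somatic_variants", "data.frame")
  # chrom 1 is tetraploid, chrom 2 diploid: only chrom 2 counts
  seg <- allelic_segments(c("1", "2"), c(1, 1), c(100e6, 100e6),
                          c(4, 2), c(2, 1))
  expect_equal(estimate_purity(v, seg), 0.96, tolerance = 0.02)
})

test_that("cellular prevalence follows the closed form and clamps", {
  expect_equal(cellular_prevalence(0.5, 1, 2), 1.0)
  expect_equal(cellular_prevalence(0.25, 1, 2), 0.5)
  expect_equal(cellular_prevalence(0.415, 0.83, 2), 1.0)  # clamped from 1.0
  expect_equal(cellular_prevalence(0.1, 0.5, 2), 0.4)
  # monotone in vaf; equals 2*vaf at purity 1 on diploid
  vafs <- seq(0.05, 0.45, by = 0.05)
  cps <- cellular_prevalence(vafs, 1, 2)
  expect_true(all(diff(cps) > 0))
  expect_equal(cps, 2 * vafs)
  expect_error(cellular_prevalence(0.2, 0, 2), "purity")
  expect_error(cellular_prevalence(0.2, 1, 0), "local_total_cn")
})

test_that("panel presence follows the detection rule and Euler set arithmetic", {
  mk <- function(id, ids_present, vaf = 0.4, depth = 100) {
    n <- length(ids_present)
    v <- somatic_variants(chrom = rep("1", n), pos = seq_len(n),
                          ref = rep("C", n), alt = rep("T", n),
                          vclass = "SNP", context3 = rep("ACA", n),
                          vaf = rep(vaf, n), depth = rep(depth, n),
                          id = ids_present)
    sample_profile(id, "primary", callable_mb = 30, variants = v)
  }
  panel <- build_panel(list(mk("P", c("A", "B", "C")), mk("L", c("A", "D"))))
  er <- euler_regions(panel)
  expect_equal(unname(er["L&P"]), 1L)
  expect_equal(unname(er["P"]), 2L)
  expect_equal(unname(er["L"]), 1L)
  expect_equal(sum(er), length(panel$mutation_universe))

  # identical samples collapse to a single shared region
  panel2 <- build_panel(list(mk("X", c("A", "B")), mk("Y", c("A", "B"))))
  expect_equal(length(euler_regions(panel2)), 1)

  # sub-threshold VAF calls are not "present"
  panel3 <- build_panel(list(mk("P", c("A", "B")), mk("L", "A", vaf = 0.01)))
  expect_false(panel3$presence["L", "A"])
  expect_error(build_panel(list(mk("P", "A"))), "at least 2")
})

test_that("Euler counts equal planted clone sizes on simulated panels", {
  sim <- make_three_clone_panel(3)
  panel <- build_panel(sim$samples)
  er <- euler_regions(panel)
  truth <- table(sim$truth$clone)
  # truncal clone (1): all samples; clone 2: lineage A only; clone 3: P and B
  expect_equal(unname(er["A&B&P"]), unname(truth["1"]))
  expect_equal(unname(er["A"]), unname(truth["2"]))
  expect_equal(unname(er["B&P"]), unname(truth["3"]))
  expect_equal(sum(er), nrow(sim$truth))
})

test_that("a lineage sharing a third of its substitutions is reproduced", {
  tree <- clone_tree_spec(
    data.frame(id = 1:2, parent = c(NA, 1), n_private = c(200, 400)),
    matrix(c(1, 1, 0, 1), nrow = 2, dimnames = list(c("P", "A"), 1:2)))
  shared <- vapply(1:5, function(s) {
    sim <- simulate_lineage_panel(tree, samples = data.frame(
      sample_id = c("P", "A"), role = c("primary", "pdx"),
      lineage = c(NA, "A"), passage = c(NA, 0), purity = 1),
      depth = 100, seed = s)
    pres <- build_panel(sim$samples)$presence
    sum(pres["A", ] & pres["P", ]) / sum(pres["A", ])
  }, 1)
  expect_true(all(abs(shared - 1 / 3) < 0.05))
})

test_that("prevalence clustering finds planted clone structure", {
  sim <- make_three_clone_panel(1)
  panel <- build_panel(sim$samples)
  cl <- cluster_prevalences(panel)
  expect_equal(cl$k, 3L)
  top <- top_clusters(cl)
  expect_equal(nrow(top), 3)
  expect_equal(sum(cl$clusters$fraction), 1)
  # largest cluster is the lineage-A private clone (300 of 550)
  expect_equal(top$n_members[1], unname(table(sim$truth$clone)["2"]))
  expect_error(cluster_prevalences(build_panel(sim$samples[1:2]), k_max = 2),
               NA)  # two samples alone are fine
})

test_that("single-clone panels collapse to one cluster under the variance floor", {
  tree <- clone_tree_spec(
    data.frame(id = 1, parent = NA, n_private = 60),
    matrix(c(1, 1), nrow = 2, dimnames = list(c("P", "A"), 1)))
  sim <- simulate_lineage_panel(tree, samples = data.frame(
    sample_id = c("P", "A"), role = c("primary", "pdx"),
    lineage = c(NA, "A"), passage = c(NA, 0), purity = 1),
    depth = 2000, seed = 2)
  cl <- cluster_prevalences(build_panel(sim$samples), variance_floor = 0.01)
  expect_equal(cl$k, 1L)
  expect_equal(cl$clusters$fraction, 1)
  expect_error(cluster_prevalences(
    build_panel(sim$samples), min_fraction = 0.05, k_max = 2,
    variance_floor = 0.01) , NA)
})

test_that("clone-tree inference honors the sum rule and recovers planted topology", {
  sim <- make_three_clone_panel(1)
  cl <- cluster_prevalences(build_panel(sim$samples))
  trees <- infer_clone_tree(cl)
  expect_gte(length(trees), 1)
  for (tr in trees) expect_true(validate_clone_tree(tr, cl))
  # planted topology: truncal root with both subclones as children
  root_id <- trees[[1]]$root
  root_prev <- cl$clusters[cl$clusters$cluster_id == root_id, cl$sample_ids]
  expect_true(all(root_prev > 0.9))  # truncal clone everywhere
  kids <- sort(trees[[1]]$edges$child[trees[[1]]$edges$parent == root_id])
  expect_equal(kids, setdiff(cl$clusters$cluster_id, root_id))
})

test_that("branching violating the sum rule is rejected in favor of a chain", {
  fake <- structure(list(
    clusters = data.frame(cluster_id = 1:3, n_members = c(50, 30, 20),
                          fraction = c(0.5, 0.3, 0.2), minor = FALSE,
                          S1 = c(1.0, 0.7, 0.6)),
    sample_ids = "S1", min_fraction = 0.05, k = 3L),
    class = "clone_clusters")
  trees <- infer_clone_tree(fake, tolerance = 0.05)
  # 0.7 + 0.6 > 1.0 + tol: clusters 2 and 3 can never be siblings under 1
  for (tr in trees) {
    sib <- tr$edges$parent[tr$edges$child == 2] ==
      tr$edges$parent[tr$edges$child == 3]
    expect_false(sib && tr$edges$parent[tr$edges$child == 2] == 1)
  }
  expect_gte(length(trees), 1)  # linear chains remain consistent
})

test_that("tree inference fails cleanly when no cluster dominates everywhere", {
  fake <- structure(list(
    clusters = data.frame(cluster_id = 1:2, n_members = c(30, 30),
                          fraction = c(0.5, 0.5), minor = FALSE,
                          S1 = c(1.0, 0.2), S2 = c(0.2, 1.0)),
    sample_ids = c("S1", "S2"), min_fraction = 0.05, k = 2L),
    class = "clone_clusters")
  expect_error(infer_clone_tree(fake), "no valid root")
})
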