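g1 <- mini_genome(1, 100e6, 0.5)   # centromere midpoint at 50 Mb
g2 <- mini_genome(2, 100e6, 0.5)

seg1 <- function(...) {
  df <- rbind(...)
  allelic_segments(rep("1", nrow(df)), df[, 1], df[, 2], df[, 3], df[, 4])
}

test_that("HRD-LOH counts >15 Mb non-whole-chromosome LOH", {
  dip <- seg1(c(1, 100e6, 2, 1))
  expect_equal(compute_hrd_loh(dip, g1), 0L)
  # one 20 Mb qualifying LOH plus one 10 Mb too-short LOH
  s <- seg1(c(1, 20e6, 2, 1), c(20e6 + 1, 40e6, 2, 0),
            c(40e6 + 1, 60e6, 2, 1), c(60e6 + 1, 70e6, 1, 0),
            c(70e6 + 1, 100e6, 2, 1))
  expect_equal(compute_hrd_loh(s, g1), 1L)
  # whole-chromosome LOH is excluded
  whole <- seg1(c(1, 100e6, 1, 0))
  expect_equal(compute_hrd_loh(whole, g1), 0L)
  # split whole-chromosome LOH still excluded after run merging
  split <- seg1(c(1, 60e6, 1, 0), c(60e6 + 1, 100e6, 2, 0))
  expect_equal(compute_hrd_loh(split, g1), 0L)
})

test_that("LST smoothing removes small interruptions and counts transitions", {
  # single-state arm
  expect_equal(compute_lst(seg1(c(1, 100e6, 2, 1)), g1), 0L)
  # A(30) | B(2) | A(25): 2 Mb interruption smoothed away, flanks merge
  s <- seg1(c(1, 30e6, 2, 1), c(30e6 + 1, 32e6, 3, 1),
            c(32e6 + 1, 50e6, 2, 1), c(50e6 + 1, 100e6, 2, 1))
  expect_equal(compute_lst(s, g1), 0L)
  # A(20) | B(18) | C(12) on one arm: two qualifying transitions
  s2 <- seg1(c(1, 20e6, 2, 1), c(20e6 + 1, 38e6, 3, 1),
             c(38e6 + 1, 50e6, 1, 0), c(50e6 + 1, 100e6, 2, 1))
  expect_equal(compute_lst(s2, g1), 2L)
  # transitions straddling the centromere midpoint: both arm pieces of the
  # altered block fall under 10 Mb, so neither arm records a transition
  s3 <- seg1(c(1, 45e6, 2, 1), c(45e6 + 1, 58e6, 3, 1),
             c(58e6 + 1, 100e6, 2, 1))
  expect_equal(compute_lst(s3, g1), 0L)
})

test_that("NtAI counts telomeric imbalance runs not crossing the centromere", {
  expect_equal(compute_ntai(seg1(c(1, 100e6, 2, 1)), g1), 0L)
  # AI from the tip to 10 Mb, centromere at 50 Mb
  s <- seg1(c(1, 10e6, 3, 1), c(10e6 + 1, 100e6, 2, 1))
  expect_equal(compute_ntai(s, g1), 1L)
  # AI spanning the whole chromosome crosses the centromere
  expect_equal(compute_ntai(seg1(c(1, 100e6, 3, 1)), g1), 0L)
  # interstitial AI does not touch an end
  s2 <- seg1(c(1, 20e6, 2, 1), c(20e6 + 1, 40e6, 3, 1),
             c(40e6 + 1, 100e6, 2, 1))
  expect_equal(compute_ntai(s2, g1), 0L)
  # both arms imbalanced but split by a balanced centromeric block: 2 runs
  s3 <- seg1(c(1, 45e6, 3, 1), c(45e6 + 1, 55e6, 2, 1),
             c(55e6 + 1, 100e6, 1, 0))
  expect_equal(compute_ntai(s3, g1), 2L)
})

test_that("scar components match the pixel oracle on random segment sets", {
  set.seed(402)
  for (i in 1:200) {
    s <- random_segment_set(2, 100)
    expect_equal(compute_hrd_loh(s, g2), oracle_hrd_loh(s, g2),
                 info = paste("hrd_loh case", i))
    expect_equal(compute_ntai(s, g2), oracle_ntai(s, g2),
                 info = paste("ntai case", i))
    expect_equal(compute_lst(s, g2), oracle_lst(s, g2),
                 info = paste("lst case", i))
  }
})

test_that("components are invariant to same-state splits and segment order", {
  set.seed(77)
  for (i in 1:20) {
    s <- random_segment_set(2, 100)
    df <- as.data.frame(s)
    # split the widest segment in two
    w <- which.max(df$end_bp - df$start_bp)
    mid <- floor((df$start_bp[w] + df$end_bp[w]) / 2)
    extra <- df[w, ]; extra$start_bp <- mid + 1
    df$end_bp[w] <- mid
    df <- rbind(df, extra)
    df <- df[sample(nrow(df)), ]
    s2 <- allelic_segments(df$chrom, df$start_bp, df$end_bp, df$total_cn,
                           df$minor_cn)
    expect_equal(score_hrd(s2, g2)[c("ntai", "lst", "hrd_loh")],
                 score_hrd(s, g2)[c("ntai", "lst", "hrd_loh")])
  }
})

test_that("adding one qualifying LOH segment raises the sum by exactly one", {
  base <- allelic_segments(c("1", "2"), c(1, 1), c(100e6, 100e6),
                           c(2, 2), c(1, 1))
  before <- score_hrd(base, g2)
  # interior 42 Mb LOH with sub-10 Mb balanced flanks on the p arm: it
  # qualifies for HRD-LOH but creates no telomeric-AI run and no LST pair
  with_loh <- allelic_segments(c("1", "1", "1", "2"),
                               c(1, 4e6 + 1, 46e6 + 1, 1),
                               c(4e6, 46e6, 100e6, 100e6),
                               c(2, 2, 2, 2), c(1, 0, 1, 1))
  after <- score_hrd(with_loh, g2)
  expect_equal(after$hrd_loh, before$hrd_loh + 1L)
  expect_equal(after$sum, before$sum + 1L)
})

test_that("HRD call applies the threshold of 42 and evidence is assembled", {
  dip <- allelic_segments("1", 1, 100e6, 2, 1)
  sc <- score_hrd(dip, g1)
  expect_equal(sc$sum, 0L)
  expect_false(sc$hrd_call)

  prof <- sample_profile(
    "s1", "primary", callable_mb = 30,
    variants = somatic_variants(chrom = "17", pos = 41244936, ref = "G",
                                alt = "T", vclass = "SNP", context3 = "TGT",
                                vaf = 0.6, depth = 90, gene = "BRCA1",
                                protein_change = "p.Glu23fs"),
    segments = dip)
  exp0 <- structure(list(weights = c(Signature.3 = 0.25, Signature.1 = 0.75),
                         residual_sse = 0, n_snvs = 100L, cutoff_used = 0.15),
                    class = "exposure_estimate")
  ev <- summarize_hrd_evidence(prof, exp0, genome = g1)
  expect_equal(ev$sig3_fraction, 0.25)
  expect_equal(nrow(ev$hr_gene_hits), 1)
  expect_equal(ev$hr_gene_hits$gene, "BRCA1")
  expect_equal(ev$hr_gene_hits$class, "HR")
  expect_true(is.na(ev$hrdetect_probability))

  none <- sample_profile("s2", "primary", callable_mb = 30, segments = dip)
  ev2 <- summarize_hrd_evidence(none,
                                structure(list(weights = c(Signature.1 = 1),
                                               residual_sse = 0, n_snvs = 10L,
                                               cutoff_used = 0.15),
                                          class = "exposure_estimate"),
                                genome = g1)
  expect_equal(nrow(ev2$hr_gene_hits), 0)
  expect_equal(ev2$sig3_fraction, 0)
})
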