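#' Subtype preset constructor
#'
#' A preset bundles the generative parameters for one molecular subtype:
#' expected somatic SNV count, signature mixture, microsatellite
#' instability fraction, planted copy-number events and driver mutations.
#'
#' @param label subtype label: POLE, MMRd, CN-low or CN-high
#' @param n_mutations expected somatic SNV count (Poisson mean)
#' @param signature_mix named fractions over bundled signatures, sum 1
#' @param msi_unstable_frac fraction of panel sites unstable
#' @param segment_profile named integer counts of planted events over
#'   {gain, loss, loh_large, loh_small, telomeric_ai, lst_pair}; gain and
#'   loss are realized as whole-arm events (the dominant mode of
#'   copy-number change in HR-proficient aneuploid tumors), the others as
#'   sub-arm events
#' @param driver_genes data.frame(gene, protein_change, vclass) injected
#'   as labelled variants
#' @param wgd whole-genome duplication: doubles all copy numbers
#' @param msi_panel_size microsatellite panel size, default 1000 sites
#' @return list of class `subtype_preset`
#' @export
subtype_preset <- function(label, n_mutations, signature_mix,
                           msi_unstable_frac,
                           segment_profile = c(gain = 0L, loss = 0L,
                                               loh_large = 0L, loh_small = 0L,
                                               telomeric_ai = 0L, lst_pair = 0L),
                           driver_genes = NULL, wgd = FALSE,
                           msi_panel_size = 1000L) {
  if (abs(sum(signature_mix) - 1) > 1e-9)
    stop("signature_mix must sum to 1")
  if (any(signature_mix < 0)) stop("signature_mix weights must be nonnegative")
  if (msi_unstable_frac < 0 || msi_unstable_frac > 1)
    stop("msi_unstable_frac must lie in [0,1]")
  prof <- c(gain = 0L, loss = 0L, loh_large = 0L, loh_small = 0L,
            telomeric_ai = 0L, lst_pair = 0L)
  prof[names(segment_profile)] <- as.integer(segment_profile)
  structure(list(label = label, n_mutations = n_mutations,
                 signature_mix = signature_mix,
                 msi_unstable_frac = msi_unstable_frac,
                 segment_profile = prof, driver_genes = driver_genes,
                 wgd = wgd, msi_panel_size = as.integer(msi_panel_size)),
            class = "subtype_preset")
}

#' Default presets for the four molecular subtypes
#'
#' Parameter choices place each preset firmly on its side of every
#' classification bound: the POLE preset is ultramutated (expected TMB
#' 650/Mb at 30 callable Mb) and microsatellite-stable; the MMRd preset is
#' hypermutated (expected TMB 40/Mb) with 10% unstable sites; the CN-high
#' preset is mutation-quiet (expected TMB 5/Mb) with 18 whole-arm events
#' plus sub-arm scar events chosen to stay HR-proficient (HRD sum well
#' under 42); the CN-low preset is quiet on every axis.
#'
#' @return named list of four `subtype_preset` objects
#' @export
default_presets <- function() {
  list(
    POLE = subtype_preset(
      "POLE", n_mutations = 19500,
      signature_mix = c(Signature.10 = 0.8, Signature.1 = 0.2),
      msi_unstable_frac = 0.005,
      driver_genes = data.frame(gene = c("POLE", "PTEN"),
                                protein_change = c("p.Pro286Arg", "p.Arg130Gly"),
                                vclass = c("SNP", "SNP"),
                                stringsAsFactors = FALSE)),
    MMRd = subtype_preset(
      "MMRd", n_mutations = 1200,
      signature_mix = c(Signature.6 = 0.6, Signature.1 = 0.4),
      msi_unstable_frac = 0.10,
      driver_genes = data.frame(
        gene = c("PTEN", "ARID1A", "RPL22", "MSH6"),
        protein_change = c("p.Arg130Gly", "p.Gly1848fs", "p.Lys15fs",
                           "p.Thr1219Ile"),
        vclass = c("SNP", "DEL", "DEL", "SNP"),
        stringsAsFactors = FALSE)),
    `CN-low` = subtype_preset(
      "CN-low", n_mutations = 120,
      signature_mix = c(Signature.1 = 0.7, Signature.5 = 0.3),
      msi_unstable_frac = 0.005,
      segment_profile = c(gain = 1L, loss = 1L),
      driver_genes = data.frame(gene = c("PTEN", "PIK3CA"),
                                protein_change = c("p.Arg233*", "p.His1047Arg"),
                                vclass = c("SNP", "SNP"),
                                stringsAsFactors = FALSE)),
    `CN-high` = subtype_preset(
      "CN-high", n_mutations = 150,
      signature_mix = c(Signature.1 = 0.25, Signature.2 = 0.25,
                        Signature.5 = 0.25, Signature.13 = 0.25),
      msi_unstable_frac = 0.005,
      segment_profile = c(gain = 14L, loss = 4L, loh_large = 1L,
                          loh_small = 1L, telomeric_ai = 2L, lst_pair = 2L),
      driver_genes = data.frame(gene = "TP53",
                                protein_change = "p.Arg273His",
                                vclass = "SNP",
                                stringsAsFactors = FALSE)))
}

#' Chromosome-arm table for a genome
#' @param genome a `genome_build`
#' @return data.frame(arm_id, chrom, arm, start_bp, end_bp, length_bp)
#' @keywords internal
arm_table <- function(genome) {
  ch <- genome$chromosomes
  mids <- centromere_midpoint(genome)
  p <- data.frame(arm_id = paste0(ch$name, "_p"), chrom = ch$name, arm = "p",
                  start_bp = 1, end_bp = as.numeric(mids[ch$name]),
                  stringsAsFactors = FALSE)
  q <- data.frame(arm_id = paste0(ch$name, "_q"), chrom = ch$name, arm = "q",
                  start_bp = as.numeric(mids[ch$name]) + 1,
                  end_bp = ch$length_bp, stringsAsFactors = FALSE)
  out <- rbind(p, q)
  out$length_bp <- out$end_bp - out$start_bp + 1
  out[order(-out$length_bp), ]
}

#' Simulate one sample profile from a subtype preset
#'
#' Draws the somatic SNV count from Poisson(`n_mutations`), assigns each
#' SNV a 96-channel identity from the preset's signature mixture under
#' uniform trinucleotide opportunity, places positions uniformly on the
#' autosomes, and samples VAFs as Binomial(depth, purity/2)/depth for
#' clonal heterozygous diploid variants (alt counts of zero are floored
#' at one read: an uncalled variant would not be in a somatic table).
#' The microsatellite summary is Binomial(panel size, unstable fraction).
#' Copy-number events are planted on distinct chromosome arms over a
#' diploid (2,1) background; whole-genome duplication doubles all copy
#' numbers. Driver variants are injected with the preset's labels.
#'
#' The planted truth (true mixture, event table, purity, seed) is
#' attached as attribute `planted`.
#'
#' @param preset a `subtype_preset`
#' @param genome a `genome_build`
#' @param callable_mb callable size in Mb, default 30 (exome-like)
#' @param purity simulated tumor purity, default 0.8
#' @param depth mean sequencing depth, default 80 (must be >= 30)
#' @param seed integer seed
#' @param sample_id sample identifier
#' @param role,lineage,passage sample metadata
#' @return a `sample_profile`
#' @export
simulate_sample <- function(preset, genome = default_genome(),
                            callable_mb = 30, purity = 0.8, depth = 80,
                            seed = 1, sample_id = paste0(preset$label, "_s", seed),
                            role = "pdx", lineage = "A",
                            passage = if (role == "pdx") 0L else NA_integer_) {
  if (depth < 30) stop("depth must be at least 30")
  if (purity <= 0 || purity > 1) stop("purity must lie in (0,1]")
  rng <- local_rng(seed)
  catref <- default_signature_catalog()
  miss <- setdiff(names(preset$signature_mix), colnames(catref$signatures))
  if (length(miss) > 0) stop("unknown signature(s) in mix: ",
                             paste(miss, collapse = ", "))

  n <- stats::rpois(1, preset$n_mutations)
  variants <- draw_snvs(n, preset$signature_mix, catref, genome, purity, depth)
  if (!is.null(preset$driver_genes) && nrow(preset$driver_genes) > 0)
    variants <- rbind_variants(variants,
                               draw_drivers(preset$driver_genes, genome,
                                            purity, depth))
  ms <- microsat_result(preset$msi_panel_size,
                        stats::rbinom(1, preset$msi_panel_size,
                                      preset$msi_unstable_frac))
  seg <- plant_segments(preset$segment_profile, genome, preset$wgd)
  profile <- sample_profile(sample_id = sample_id, role = role,
                            lineage = if (role == "pdx") lineage else NA_character_,
                            passage = passage, purity = purity,
                            callable_mb = callable_mb,
                            variants = variants, segments = seg$segments,
                            ms_result = ms)
  attr(profile, "planted") <- list(
    label = preset$label, n_snv_drawn = n,
    signature_mix = preset$signature_mix,
    msi_unstable_frac = preset$msi_unstable_frac,
    purity = purity, depth = depth, seed = seed,
    events = seg$events)
  rng()
  profile
}

#' Draw SNVs with channel identities from a signature mixture
#' @keywords internal
draw_snvs <- function(n, signature_mix, catref, genome, purity, depth) {
  if (n == 0) return(somatic_variants())
  spectrum <- as.numeric(catref$signatures[, names(signature_mix), drop = FALSE] %*%
                           signature_mix)
  ch <- sbs96_channels()
  idx <- sample.int(96, n, replace = TRUE, prob = spectrum)
  lab <- ch[idx]
  ref <- substr(lab, 3, 3)
  alt <- substr(lab, 5, 5)
  ctx <- paste0(substr(lab, 1, 1), ref, substr(lab, 7, 7))
  pos <- random_positions(n, genome)
  alt_count <- pmax(1L, stats::rbinom(n, depth, purity / 2))
  somatic_variants(chrom = pos$chrom, pos = pos$pos, ref = ref, alt = alt,
                   vclass = "SNP", context3 = ctx,
                   vaf = alt_count / depth, depth = depth)
}

#' Uniform random genomic positions
#' @keywords internal
random_positions <- function(n, genome) {
  ch <- genome$chromosomes
  ci <- sample.int(nrow(ch), n, replace = TRUE,
                   prob = ch$length_bp / sum(ch$length_bp))
  list(chrom = ch$name[ci],
       pos = floor(stats::runif(n, 1, ch$length_bp[ci] + 1)))
}

#' Inject labelled driver variants
#' @keywords internal
draw_drivers <- function(drivers, genome, purity, depth) {
  n <- nrow(drivers)
  pos <- random_positions(n, genome)
  ref <- alt <- ctx <- character(n)
  for (i in seq_len(n)) {
    if (drivers$vclass[i] == "SNP") {
      ref[i] <- "C"; alt[i] <- "T"; ctx[i] <- "ACA"
    } else if (drivers$vclass[i] == "DEL") {
      ref[i] <- "A"; alt[i] <- "-"; ctx[i] <- NA_character_
    } else {
      ref[i] <- "-"; alt[i] <- "A"; ctx[i] <- NA_character_
    }
  }
  alt_count <- pmax(1L, stats::rbinom(n, depth, purity / 2))
  somatic_variants(chrom = pos$chrom, pos = pos$pos, ref = ref, alt = alt,
                   vclass = drivers$vclass, context3 = ctx,
                   vaf = alt_count / depth, depth = depth,
                   gene = drivers$gene,
                   protein_change = drivers$protein_change)
}

rbind_variants <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  class(out) <- c("somatic_variants", "data.frame")
  out
}

#' Plant copy-number events on a diploid background
#'
#' Whole-arm gains (3,1) and losses (1,0) occupy one randomly chosen arm
#' each, at most one arm-level event per chromosome so telomeric runs
#' never fuse across the centromere. Sub-arm events (copy-neutral LOH
#' blocks, terminal allelic-imbalance segments, state-transition pairs)
#' are placed with >= 12 Mb diploid flanks inside arms not already used.
#'
#' @keywords internal
plant_segments <- function(profile, genome, wgd = FALSE) {
  arms <- arm_table(genome)
  events <- list()
  used_chrom_armlevel <- character()
  used_arms <- character()

  take_arm <- function(min_len, avoid_armlevel_chrom = FALSE) {
    ok <- arms$length_bp >= min_len & !(arms$arm_id %in% used_arms)
    if (avoid_armlevel_chrom)
      ok <- ok & !(arms$chrom %in% used_chrom_armlevel)
    cand <- which(ok)
    if (length(cand) == 0) stop("no arm left for planted event")
    pick <- cand[sample.int(length(cand), 1)]
    used_arms <<- c(used_arms, arms$arm_id[pick])
    arms[pick, ]
  }
  add_event <- function(kind, chrom, start, end, total, minor)
    events[[length(events) + 1]] <<- data.frame(
      kind = kind, chrom = chrom, start_bp = start, end_bp = end,
      total_cn = total, minor_cn = minor, stringsAsFactors = FALSE)

  for (k in seq_len(profile["gain"] + profile["loss"])) {
    is_gain <- k <= profile["gain"]
    a <- take_arm(40e6, avoid_armlevel_chrom = TRUE)
    used_chrom_armlevel <- c(used_chrom_armlevel, a$chrom)
    if (is_gain) add_event("gain", a$chrom, a$start_bp, a$end_bp, 3L, 1L)
    else add_event("loss", a$chrom, a$start_bp, a$end_bp, 1L, 0L)
  }
  interior <- function(kind, size, total, minor) {
    a <- take_arm(size + 26e6)
    start <- a$start_bp + 13e6
    add_event(kind, a$chrom, start, start + size - 1, total, minor)
  }
  for (k in seq_len(profile["loh_large"])) interior("loh_large", 20e6, 2L, 0L)
  for (k in seq_len(profile["loh_small"])) interior("loh_small", 8e6, 2L, 0L)
  for (k in seq_len(profile["telomeric_ai"])) {
    a <- take_arm(30e6)
    if (a$arm == "p") add_event("telomeric_ai", a$chrom, 1, 10e6, 3L, 1L)
    else add_event("telomeric_ai", a$chrom, a$end_bp - 10e6 + 1, a$end_bp, 3L, 1L)
  }
  for (k in seq_len(profile["lst_pair"])) {
    a <- take_arm(24e6 + 26e6)
    start <- a$start_bp + 13e6
    add_event("lst_pair", a$chrom, start, start + 12e6 - 1, 3L, 1L)
    add_event("lst_pair", a$chrom, start + 12e6, start + 24e6 - 1, 1L, 0L)
  }

  ev <- if (length(events) == 0)
    data.frame(kind = character(), chrom = character(), start_bp = numeric(),
               end_bp = numeric(), total_cn = integer(), minor_cn = integer(),
               stringsAsFactors = FALSE)
  else do.call(rbind, events)

  # fill the remainder of every chromosome with the diploid background
  segs <- list()
  for (i in seq_len(nrow(genome$chromosomes))) {
    cname <- genome$chromosomes$name[i]
    clen <- genome$chromosomes$length_bp[i]
    e <- ev[ev$chrom == cname, , drop = FALSE]
    e <- e[order(e$start_bp), , drop = FALSE]
    cursor <- 1
    for (j in seq_len(nrow(e))) {
      if (e$start_bp[j] > cursor)
        segs[[length(segs) + 1]] <- data.frame(
          chrom = cname, start_bp = cursor, end_bp = e$start_bp[j] - 1,
          total_cn = 2L, minor_cn = 1L, stringsAsFactors = FALSE)
      segs[[length(segs) + 1]] <- e[j, c("chrom", "start_bp", "end_bp",
                                         "total_cn", "minor_cn")]
      cursor <- e$end_bp[j] + 1
    }
    if (cursor <= clen)
      segs[[length(segs) + 1]] <- data.frame(
        chrom = cname, start_bp = cursor, end_bp = clen,
        total_cn = 2L, minor_cn = 1L, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, segs)
  if (wgd) {
    df$total_cn <- df$total_cn * 2L
    df$minor_cn <- df$minor_cn * 2L
  }
  list(segments = allelic_segments(df$chrom, df$start_bp, df$end_bp,
                                   df$total_cn, df$minor_cn),
       events = ev)
}

#' Simulate a 96-channel catalog from a signature mixture
#'
#' Multinomial draw of `n_snvs` channel assignments from the mixture
#' spectrum (the mixture-weighted sum of signature profiles).
#'
#' @param signature_mix named nonnegative weights summing to 1
#' @param n_snvs number of SNVs to draw
#' @param catalog_ref a `signature_catalog`
#' @param seed integer seed
#' @return a `mutation_catalog96` count vector
#' @export
simulate_catalog <- function(signature_mix, n_snvs,
                             catalog_ref = default_signature_catalog(),
                             seed = 1) {
  if (any(signature_mix < 0)) stop("signature_mix weights must be nonnegative")
  if (abs(sum(signature_mix) - 1) > 1e-9) stop("signature_mix must sum to 1")
  rng <- local_rng(seed)
  spectrum <- as.numeric(
    catalog_ref$signatures[, names(signature_mix), drop = FALSE] %*%
      signature_mix)
  counts <- if (n_snvs == 0) integer(96)
            else as.integer(stats::rmultinom(1, n_snvs, spectrum))
  rng()
  structure(stats::setNames(counts, sbs96_channels()),
            class = "mutation_catalog96", n_skipped = 0L)
}

#' Clone tree specification for panel simulation
#'
#' @param clones data.frame(id, parent, n_private); parent NA for the root
#' @param prevalence numeric matrix, samples in rows (rownames = sample
#'   ids), clones in columns; cellular prevalence in [0,1]
#' @return list of class `clone_tree_spec`
#' @export
clone_tree_spec <- function(clones, prevalence) {
  if (sum(is.na(clones$parent)) != 1) stop("exactly one root clone required")
  if (!all(stats::na.omit(clones$parent) %in% clones$id))
    stop("unknown parent clone")
  if (is.null(rownames(prevalence)) || is.null(colnames(prevalence)))
    stop("prevalence needs sample rownames and clone colnames")
  if (!setequal(colnames(prevalence), clones$id))
    stop("prevalence columns must match clone ids")
  if (any(prevalence < 0 | prevalence > 1))
    stop("prevalences must lie in [0,1]")
  root <- clones$id[is.na(clones$parent)]
  for (s in rownames(prevalence)) {
    for (cid in clones$id) {
      kids <- clones$id[!is.na(clones$parent) & clones$parent == cid]
      if (length(kids) > 0 &&
          sum(prevalence[s, kids]) > prevalence[s, cid] + 1e-9)
        stop("sum rule violated for clone ", cid, " in sample ", s)
    }
  }
  structure(list(clones = clones, prevalence = prevalence, root = root),
            class = "clone_tree_spec")
}

#' Simulate a matched primary + PDX lineage panel from a clone tree
#'
#' Each clone receives its private mutations; in every sample a
#' mutation's expected VAF is
#' `purity * prevalence * multiplicity / (purity * total_cn + (1 - purity) * 2)`
#' with multiplicity 1 on a diploid background, and the observed alt
#' count is binomial at the given depth. Mutations with zero sampled alt
#' reads are absent from that sample's variant table, which is how
#' lineage-private clones produce disjoint catalogs.
#'
#' @param tree a `clone_tree_spec`
#' @param samples data.frame(sample_id, role, lineage, passage, purity);
#'   default: one primary plus one PDX per prevalence row
#' @param depth sequencing depth, default 100
#' @param seed integer seed
#' @param genome a `genome_build`
#' @param signature_mix channel mixture for mutation identities
#' @param callable_mb callable size per sample
#' @return list of class `lineage_panel_sim`: `samples` (named profiles)
#'   and `truth` (mutation-to-clone assignment)
#' @export
simulate_lineage_panel <- function(tree, samples = NULL, depth = 100, seed = 1,
                                   genome = default_genome(),
                                   signature_mix = c(Signature.1 = 1),
                                   callable_mb = 30) {
  rng <- local_rng(seed)
  catref <- default_signature_catalog()
  ids <- rownames(tree$prevalence)
  if (is.null(samples)) {
    samples <- data.frame(sample_id = ids,
                          role = ifelse(seq_along(ids) == 1, "primary", "pdx"),
                          lineage = ifelse(seq_along(ids) == 1, NA, LETTERS[pmax(1, seq_along(ids) - 1)]),
                          passage = ifelse(seq_along(ids) == 1, NA, 0L),
                          purity = 1, stringsAsFactors = FALSE)
  }
  stopifnot(setequal(samples$sample_id, ids))

  # planted mutation set: one block per clone
  muts <- list()
  for (i in seq_len(nrow(tree$clones))) {
    cl <- tree$clones[i, ]
    if (cl$n_private == 0) next
    v <- draw_snvs(cl$n_private, signature_mix, catref, genome,
                   purity = 1, depth = depth)
    v$clone <- cl$id
    muts[[length(muts) + 1]] <- v
  }
  allmut <- do.call(rbind, lapply(muts, as.data.frame))
  allmut$id <- make.unique(allmut$id)

  profiles <- list()
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    purity <- s$purity
    prev <- tree$prevalence[s$sample_id, allmut$clone]
    vaf_true <- purity * prev * 1 / (purity * 2 + (1 - purity) * 2)
    alt <- stats::rbinom(nrow(allmut), depth, vaf_true)
    keep <- alt >= 1
    v <- allmut[keep, , drop = FALSE]
    v$vaf <- alt[keep] / depth
    v$depth <- depth
    v$clone <- NULL
    class(v) <- c("somatic_variants", "data.frame")
    profiles[[s$sample_id]] <- sample_profile(
      sample_id = s$sample_id, role = s$role,
      lineage = if (is.na(s$lineage)) NA_character_ else s$lineage,
      passage = suppressWarnings(as.integer(s$passage)),
      purity = purity, callable_mb = callable_mb, variants = v)
  }
  rng()
  structure(list(samples = profiles,
                 truth = data.frame(id = allmut$id, clone = allmut$clone,
                                    stringsAsFactors = FALSE),
                 tree = tree, depth = depth, seed = seed),
            class = "lineage_panel_sim")
}

#' Simulate two-arm tumor-volume series
#'
#' Exponential growth `V(t) = V0 * exp(r * t)` with lognormal measurement
#' noise; baseline volumes drawn uniformly from `v0_range`.
#'
#' @param n_per_arm animals per arm
#' @param growth_rate_vehicle,growth_rate_drug per-day growth rates
#' @param noise_sd lognormal noise SD (0 = noiseless)
#' @param days measurement days (first day is baseline)
#' @param seed integer seed
#' @param v0_range baseline-volume window in mm3, default c(150, 250)
#' @return list of `therapy_series`
#' @export
simulate_volume_series <- function(n_per_arm = 8,
                                   growth_rate_vehicle = 0.08,
                                   growth_rate_drug = 0.02,
                                   noise_sd = 0.1,
                                   days = seq(0, 28, by = 4), seed = 1,
                                   v0_range = c(150, 250)) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (length(days) == 0) stop("days must be nonempty")
  rng <- local_rng(seed)
  out <- list()
  # baseline volumes are drawn once and shared across arms (enrolment
  # matched on baseline), so arm contrasts reflect growth rates only
  v0 <- stats::runif(n_per_arm, v0_range[1], v0_range[2])
  for (arm in c("vehicle", "drug")) {
    r <- if (arm == "vehicle") growth_rate_vehicle else growth_rate_drug
    for (i in seq_len(n_per_arm)) {
      vol <- v0[i] * exp(r * days) *
        exp(stats::rnorm(length(days), 0, noise_sd))
      id <- sprintf("%s_%02d", arm, i)
      out[[id]] <- therapy_series(id, arm, days, vol)
    }
  }
  rng()
  out
}

#' Run body with a locally seeded RNG, restoring global state afterwards
#' @param seed integer seed
#' @return function restoring the previous RNG state
#' @keywords internal
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}
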