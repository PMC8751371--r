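# Independent pixel-level oracles for the scar metrics: chromosomes are
# discretized into 1 Mb bins and runs are found with rle(), so the
# arithmetic shares nothing with the segment-merging implementation.
# All oracle fixtures use Mb-aligned segment bounds.

MB <- 1e6

# state matrix per Mb bin: list(total=..., minor=...) over n bins
pixelate <- function(segments, chrom, n_bins) {
  total <- rep(NA_integer_, n_bins)
  minor <- rep(NA_integer_, n_bins)
  s <- segments[segments$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(s))) {
    b0 <- (s$start_bp[i] - 1) / MB + 1
    b1 <- s$end_bp[i] / MB
    total[b0:b1] <- s$total_cn[i]
    minor[b0:b1] <- s$minor_cn[i]
  }
  list(total = total, minor = minor)
}

oracle_hrd_loh <- function(segments, genome) {
  count <- 0L
  for (i in seq_len(nrow(genome$chromosomes))) {
    cc <- genome$chromosomes$name[i]
    nb <- genome$chromosomes$length_bp[i] / MB
    px <- pixelate(segments, cc, nb)
    loh <- !is.na(px$minor) & px$minor == 0 & px$total >= 1
    r <- rle(loh)
    lens <- r$lengths[r$values]
    count <- count + sum(lens > 15 & lens < 0.9 * nb)
  }
  count
}

oracle_ntai <- function(segments, genome) {
  mids <- (genome$chromosomes$centromere_start_bp +
             genome$chromosomes$centromere_end_bp) %/% 2
  count <- 0L
  for (i in seq_len(nrow(genome$chromosomes))) {
    cc <- genome$chromosomes$name[i]
    nb <- genome$chromosomes$length_bp[i] / MB
    px <- pixelate(segments, cc, nb)
    covered <- which(!is.na(px$total))
    if (length(covered) == 0) next
    ai <- !is.na(px$total) & (px$minor != px$total - px$minor)
    r <- rle(ai)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    mid_bin <- mids[i] / MB  # midpoint sits at the end of this bin
    for (k in which(r$values)) {
      telomeric <- starts[k] == min(covered) || ends[k] == max(covered)
      crosses <- starts[k] <= mid_bin && ends[k] > mid_bin
      if (telomeric && !crosses) count <- count + 1L
    }
  }
  count
}

oracle_lst <- function(segments, genome) {
  mids <- (genome$chromosomes$centromere_start_bp +
             genome$chromosomes$centromere_end_bp) %/% 2
  count <- 0L
  for (i in seq_len(nrow(genome$chromosomes))) {
    cc <- genome$chromosomes$name[i]
    nb <- genome$chromosomes$length_bp[i] / MB
    px <- pixelate(segments, cc, nb)
    mid_bin <- mids[i] / MB
    for (arm_bins in list(seq_len(mid_bin), seq(mid_bin + 1, nb))) {
      st <- paste(px$total[arm_bins], px$minor[arm_bins])
      st[is.na(px$total[arm_bins])] <- NA
      r <- rle(st)
      keep <- !is.na(r$values) & r$lengths >= 3
      runs <- data.frame(state = r$values[keep], len = r$lengths[keep],
                         stringsAsFactors = FALSE)
      if (nrow(runs) < 2) next
      # merge neighbours sharing a state after small-run removal
      j <- 1
      while (j < nrow(runs)) {
        if (runs$state[j] == runs$state[j + 1]) {
          runs$len[j] <- runs$len[j] + runs$len[j + 1]
          runs <- runs[-(j + 1), , drop = FALSE]
        } else j <- j + 1
      }
      if (nrow(runs) >= 2)
        count <- count + sum(runs$len[-nrow(runs)] >= 10 & runs$len[-1] >= 10)
    }
  }
  count
}

# random Mb-aligned segment set on a mini genome; states include balanced,
# imbalanced, LOH and homozygous-deletion configurations
random_segment_set <- function(n_chrom = 2, n_bins = 100) {
  states <- list(c(2L, 1L), c(2L, 0L), c(1L, 0L), c(3L, 1L), c(3L, 0L),
                 c(4L, 2L), c(4L, 1L), c(0L, 0L), c(4L, 0L))
  rows <- list()
  for (cc in as.character(seq_len(n_chrom))) {
    cuts <- sort(sample(1:(n_bins - 1), sample(2:8, 1)))
    bounds <- c(0, cuts, n_bins)
    for (j in seq_len(length(bounds) - 1)) {
      st <- states[[sample(length(states), 1)]]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = cc, start_bp = bounds[j] * MB + 1,
        end_bp = bounds[j + 1] * MB,
        total_cn = st[1], minor_cn = st[2], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  allelic_segments(df$chrom, df$start_bp, df$end_bp, df$total_cn, df$minor_cn)
}

# exhaustive grid refit over the weight simplex (step 0.01) for <= 3 signatures
grid_refit <- function(spectrum, S) {
  k <- ncol(S)
  best <- list(sse = Inf, w = NULL)
  grid <- seq(0, 1, by = 0.01)
  if (k == 2) {
    for (w1 in grid) {
      w <- c(w1, 1 - w1)
      sse <- sum((spectrum - as.numeric(S %*% w)) ^ 2)
      if (sse < best$sse) best <- list(sse = sse, w = w)
    }
  } else {
    for (w1 in grid) for (w2 in seq(0, 1 - w1, by = 0.01)) {
      w <- c(w1, w2, 1 - w1 - w2)
      sse <- sum((spectrum - as.numeric(S %*% w)) ^ 2)
      if (sse < best$sse) best <- list(sse = sse, w = w)
    }
  }
  best
}

# three-clone branching panel used by clustering and tree tests
make_three_clone_panel <- function(seed, n_truncal = 150, n_a = 300, n_b = 100) {
  tree <- clone_tree_spec(
    data.frame(id = 1:3, parent = c(NA, 1, 1),
               n_private = c(n_truncal, n_a, n_b)),
    matrix(c(1, 1, 1, 0, 1, 0, 0.6, 0, 0.9), nrow = 3,
           dimnames = list(c("P", "A", "B"), 1:3)))
  simulate_lineage_panel(tree, samples = data.frame(
    sample_id = c("P", "A", "B"), role = c("primary", "pdx", "pdx"),
    lineage = c(NA, "A", "B"), passage = c(NA, 0, 0), purity = 1),
    depth = 100, seed = seed)
}
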