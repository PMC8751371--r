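#' Tumor mutation burden
#'
#' Somatic mutations per callable megabase. All variant classes count
#' (SNVs, MNVs and indels); the denominator is the sample's callable
#' region size, an explicit input because exome and genome assays differ.
#'
#' @param variants a `somatic_variants` table
#' @param callable_mb callable region size in Mb (> 0)
#' @return mutations per Mb
#' @examples
#' # 3000 variants over 30 Mb -> 100 mutations/Mb
#' @export
compute_tmb <- function(variants, callable_mb) {
  if (callable_mb <= 0) stop("callable_mb must be positive")
  nrow(variants) / callable_mb
}

#' Microsatellite instability score
#'
#' Percent of assessed microsatellite sites called somatically unstable.
#' Samples at or above 3% are conventionally MSI-high.
#'
#' @param ms a `microsat_result`
#' @return percentage in [0, 100]
#' @export
compute_msi_score <- function(ms) {
  if (ms$n_assessed <= 0) stop("n_assessed must be positive")
  100 * ms$n_unstable / ms$n_assessed
}

#' Copy-number alteration burden
#'
#' A segment is altered when its allele-specific state differs from the
#' heterozygous diploid baseline (total 2, minor 1). Adjacent same-state
#' altered segments are merged before counting, so the segment count does
#' not depend on how the input was split. The percentage is taken over the
#' segmented genome only: regions without copy-number calls do not enter
#' the denominator.
#'
#' @param segments an `allelic_segments` table
#' @param genome a `genome_build` (used for validation context only)
#' @return list with `pct_cna` (percent of segmented bp altered) and
#'   `n_cna_segments` (merged altered-segment count)
#' @export
compute_cna_burden <- function(segments, genome = default_genome()) {
  if (nrow(segments) == 0) {
    warning("no segments supplied; CNA burden undefined, returning zeros")
    return(list(pct_cna = 0, n_cna_segments = 0L))
  }
  runs <- merge_same_state(segments)
  width <- runs$end_bp - runs$start_bp + 1
  altered <- !(runs$total_cn == 2L & runs$minor_cn == 1L)
  list(pct_cna = 100 * sum(width[altered]) / sum(width),
       n_cna_segments = sum(altered))
}

#' Merge contiguous same-state segments
#'
#' Two segments merge when they are on the same chromosome, share the
#' (total_cn, minor_cn) state, and are contiguous (next start == previous
#' end + 1). Used by the burden and scar metrics so results are invariant
#' to splitting a segment into same-state pieces.
#'
#' @param segments an `allelic_segments` table (non-overlapping)
#' @return data.frame of merged runs, sorted by (chrom, start)
#' @keywords internal
merge_same_state <- function(segments) {
  df <- as.data.frame(segments)
  df <- df[order(df$chrom, df$start_bp), , drop = FALSE]
  if (nrow(df) <= 1) return(df)
  new_run <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                 df$start_bp[-1] != df$end_bp[-nrow(df)] + 1 |
                 df$total_cn[-1] != df$total_cn[-nrow(df)] |
                 df$minor_cn[-1] != df$minor_cn[-nrow(df)])
  grp <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(df, grp), function(s)
    data.frame(chrom = s$chrom[1], start_bp = min(s$start_bp),
               end_bp = max(s$end_bp), total_cn = s$total_cn[1],
               minor_cn = s$minor_cn[1], stringsAsFactors = FALSE)))
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Burden summary for one sample
#' @param profile a `sample_profile`
#' @param genome a `genome_build`
#' @return list of class `burden_summary`: tmb, msi_score, pct_cna,
#'   n_cna_segments
#' @export
compute_burden <- function(profile, genome = default_genome()) {
  cna <- if (nrow(profile$segments) == 0)
    list(pct_cna = 0, n_cna_segments = 0L)
  else compute_cna_burden(profile$segments, genome)
  structure(list(tmb = compute_tmb(profile$variants, profile$callable_mb),
                 msi_score = compute_msi_score(profile$ms_result),
                 pct_cna = cna$pct_cna,
                 n_cna_segments = cna$n_cna_segments),
            class = "burden_summary")
}
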