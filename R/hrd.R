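#' HRD-LOH scar component
#'
#' Counts loss-of-heterozygosity regions longer than 15 Mb that do not
#' span (essentially) a whole chromosome. LOH means minor copy number 0
#' with at least one copy retained; contiguous LOH segments are merged
#' into runs first, and a run covering at least `whole_chrom_frac` of its
#' chromosome is excluded as a whole-chromosome event.
#'
#' @param segments an `allelic_segments` table
#' @param genome a `genome_build`
#' @param min_len_bp qualifying run length, default 15 Mb (exclusive bound)
#' @param whole_chrom_frac whole-chromosome exclusion fraction, default 0.9
#' @return integer count
#' @export
compute_hrd_loh <- function(segments, genome = default_genome(),
                            min_len_bp = 15e6, whole_chrom_frac = 0.9) {
  if (nrow(segments) == 0) return(0L)
  chrlen <- stats::setNames(genome$chromosomes$length_bp, genome$chromosomes$name)
  runs <- state_runs(segments, function(s) s$minor_cn == 0L & s$total_cn >= 1L)
  if (nrow(runs) == 0) return(0L)
  len <- runs$end_bp - runs$start_bp + 1
  keep <- len > min_len_bp & len < whole_chrom_frac * chrlen[runs$chrom]
  sum(keep)
}

#' Large-scale state transitions (LST)
#'
#' Per chromosome arm (segments split at the centromere midpoint):
#' segments shorter than the smoothing window (3 Mb) are discarded and
#' flanking same-state segments merged; every remaining adjacent pair
#' with different allele-specific state in which both members are at
#' least 10 Mb long counts as one transition.
#'
#' @param segments an `allelic_segments` table
#' @param genome a `genome_build`
#' @param smooth_bp smoothing window, default 3 Mb
#' @param min_seg_bp minimum flanking segment size, default 10 Mb
#' @return integer count
#' @export
compute_lst <- function(segments, genome = default_genome(),
                        smooth_bp = 3e6, min_seg_bp = 10e6) {
  if (nrow(segments) == 0) return(0L)
  mids <- centromere_midpoint(genome)
  arms <- split_at_centromere(segments, mids)
  total <- 0L
  for (key in unique(arms$arm_id)) {
    s <- arms[arms$arm_id == key, , drop = FALSE]
    s <- merge_same_state(allelic_segments(s$chrom, s$start_bp, s$end_bp,
                                           s$total_cn, s$minor_cn))
    s$width <- s$end_bp - s$start_bp + 1
    s <- s[s$width >= smooth_bp, , drop = FALSE]
    if (nrow(s) < 2) next
    # after discarding small segments, merge neighbours that share a state
    grp <- cumsum(c(TRUE, s$total_cn[-1] != s$total_cn[-nrow(s)] |
                            s$minor_cn[-1] != s$minor_cn[-nrow(s)]))
    w <- tapply(s$width, grp, sum)
    if (length(w) < 2) next
    total <- total + sum(w[-length(w)] >= min_seg_bp & w[-1] >= min_seg_bp)
  }
  as.integer(total)
}

#' Telomeric allelic imbalance (NtAI)
#'
#' Allelic imbalance means the two allele copy numbers differ
#' (minor != total - minor). Contiguous imbalanced segments are merged
#' into runs; a run counts when it touches a chromosome end (the first or
#' last segmented base of that chromosome) without crossing the
#' centromere midpoint. A run spanning the whole chromosome touches both
#' ends, crosses the centromere, and therefore contributes nothing.
#'
#' @param segments an `allelic_segments` table
#' @param genome a `genome_build`
#' @return integer count
#' @export
compute_ntai <- function(segments, genome = default_genome()) {
  if (nrow(segments) == 0) return(0L)
  mids <- centromere_midpoint(genome)
  runs <- state_runs(segments, function(s) s$minor_cn != s$total_cn - s$minor_cn)
  if (nrow(runs) == 0) return(0L)
  ends <- do.call(rbind, lapply(split(as.data.frame(segments), segments$chrom),
    function(s) data.frame(chrom = s$chrom[1], first = min(s$start_bp),
                           last = max(s$end_bp), stringsAsFactors = FALSE)))
  runs <- merge(runs, ends, by = "chrom")
  telomeric <- runs$start_bp == runs$first | runs$end_bp == runs$last
  crosses <- runs$start_bp < mids[runs$chrom] & runs$end_bp > mids[runs$chrom]
  sum(telomeric & !crosses)
}

#' Merge contiguous segments satisfying a state predicate into runs
#' @param segments an `allelic_segments` table
#' @param predicate function(data.frame) -> logical per row
#' @return data.frame of runs (chrom, start_bp, end_bp)
#' @keywords internal
state_runs <- function(segments, predicate) {
  df <- as.data.frame(segments)
  df <- df[order(df$chrom, df$start_bp), , drop = FALSE]
  df <- df[predicate(df), , drop = FALSE]
  if (nrow(df) == 0)
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), stringsAsFactors = FALSE))
  new_run <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                 df$start_bp[-1] != df$end_bp[-nrow(df)] + 1)
  grp <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(df, grp), function(s)
    data.frame(chrom = s$chrom[1], start_bp = min(s$start_bp),
               end_bp = max(s$end_bp), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Split segments at centromere midpoints into arm-labelled pieces
#' @param segments an `allelic_segments` table
#' @param mids named centromere midpoints
#' @return data.frame with an `arm_id` column (chrom_p / chrom_q)
#' @keywords internal
split_at_centromere <- function(segments, mids) {
  df <- as.data.frame(segments)
  pieces <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    mid <- mids[r$chrom]
    if (is.na(mid) || r$end_bp <= mid || r$start_bp > mid) {
      arm <- if (!is.na(mid) && r$end_bp <= mid) "p" else "q"
      cbind(r, arm_id = paste0(r$chrom, "_", arm))
    } else {
      rbind(cbind(transform(r, end_bp = mid), arm_id = paste0(r$chrom, "_p")),
            cbind(transform(r, start_bp = mid + 1), arm_id = paste0(r$chrom, "_q")))
    }
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' HRD genomic-scar score
#'
#' Sum of the three scar components (NtAI + LST + HRD-LOH) with the
#' conventional positivity threshold of 42 established in breast and
#' ovarian cancer.
#'
#' @param segments an `allelic_segments` table
#' @param genome a `genome_build`
#' @param threshold positivity threshold on the sum, default 42
#' @return list of class `hrd_score`: ntai, lst, hrd_loh, sum, hrd_call
#' @export
score_hrd <- function(segments, genome = default_genome(), threshold = 42) {
  ntai <- compute_ntai(segments, genome)
  lst <- compute_lst(segments, genome)
  loh <- compute_hrd_loh(segments, genome)
  structure(list(ntai = as.integer(ntai), lst = as.integer(lst),
                 hrd_loh = as.integer(loh),
                 sum = as.integer(ntai + lst + loh),
                 hrd_call = (ntai + lst + loh) >= threshold,
                 threshold = threshold),
            class = "hrd_score")
}

#' @export
print.hrd_score <- function(x, ...) {
  cat(sprintf("<hrd_score> NtAI %d + LST %d + HRD-LOH %d = %d (threshold %s: %s)\n",
              x$ntai, x$lst, x$hrd_loh, x$sum, x$threshold,
              if (x$hrd_call) "HRD" else "HR-proficient"))
  invisible(x)
}

#' Default homologous-recombination gene panel
#'
#' Core HR genes, plus PTEN and ARID1A which are flagged separately
#' because their PARP-inhibitor relevance is preclinical rather than
#' HR-pathway membership.
#' @return data.frame with columns gene, class
#' @export
default_hr_gene_panel <- function() {
  data.frame(
    gene = c("BRCA1", "BRCA2", "PALB2", "RAD51C", "RAD51D", "BRIP1", "ATM",
             "CHEK2", "MRE11A", "NBN", "RAD51B", "PTEN", "ARID1A"),
    class = c(rep("HR", 11), "associated", "associated"),
    stringsAsFactors = FALSE)
}

#' Combined HRD evidence for one sample
#'
#' Assembles the three lines of genomic HRD evidence that are computable
#' from a somatic profile: the scar score, the Signature-3 exposure
#' fraction, and somatic hits in an HR gene panel. The weighted
#' classifier probability used by WGS-based HRD predictors needs trained
#' weights and structural-variant signatures and is reported as NA.
#'
#' @param profile a `sample_profile`
#' @param exposure an `exposure_estimate` for the same sample
#' @param hr_gene_panel data.frame(gene, class), default [default_hr_gene_panel()]
#' @param genome a `genome_build`
#' @param threshold HRD-sum threshold, default 42
#' @return list of class `hrd_evidence`
#' @export
summarize_hrd_evidence <- function(profile, exposure,
                                   hr_gene_panel = default_hr_gene_panel(),
                                   genome = default_genome(), threshold = 42) {
  hits <- profile$variants[!is.na(profile$variants$gene) &
                             profile$variants$gene %in% hr_gene_panel$gene, ,
                           drop = FALSE]
  hits <- data.frame(gene = hits$gene, protein_change = hits$protein_change,
                     id = hits$id,
                     class = hr_gene_panel$class[match(hits$gene,
                                                       hr_gene_panel$gene)],
                     stringsAsFactors = FALSE)
  structure(list(hrd_score = score_hrd(profile$segments, genome, threshold),
                 sig3_fraction = sig3_fraction(exposure),
                 hr_gene_hits = hits,
                 hrdetect_probability = NA_real_),
            class = "hrd_evidence")
}
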