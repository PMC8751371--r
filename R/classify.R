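#' Default thresholds for subtype classification and downstream rules
#'
#' All tunable thresholds in one named list: the MSI cut-off (3%), the
#' hypermutation bound for MMRd (TMB > 20), the CN-high bounds
#' (TMB <= 10, >25% genome altered, >15 segments), the TMB floor guarding
#' the POLE call (100), the POLE exonuclease-domain codon window
#' (268-471), the signature minimum-contribution (0.15) and dominance
#' (0.30) cut-offs, the HRD-sum threshold (42), and the heterogeneity
#' detection/clustering defaults. Round-trips through YAML unchanged.
#'
#' @return named list of class `run_config`
#' @export
default_config <- function() {
  structure(list(
    msi_cut = 3, tmb_mmrd = 20, tmb_cnhigh = 10,
    pct_cna_cnhigh = 25, n_seg_cnhigh = 15,
    pole_tmb_min = 100, pole_domain = c(268L, 471L),
    sig_cutoff = 0.15, dominance = 0.30,
    hrd_threshold = 42,
    detect_vaf = 0.05, detect_depth = 10,
    cluster_min_fraction = 0.05, k_max = 8L,
    variance_floor = 0.001, kmeans_restarts = 10L, kmeans_seed = 20L,
    tree_tolerance = 0.05,
    genome = "hg19_autosomes"), class = "run_config")
}

#' Read / write a run configuration (YAML)
#' @param path YAML file
#' @return a `run_config`
#' @export
read_config <- function(path) {
  cfg <- utils::modifyList(unclass(default_config()), yaml::read_yaml(path))
  cfg$pole_domain <- as.integer(cfg$pole_domain)
  structure(cfg, class = "run_config")
}

#' @rdname read_config
#' @param config a `run_config`
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Detect POLE exonuclease-domain mutations
#'
#' The POLE-ultramutated subtype is defined by missense mutations inside
#' the exonuclease domain (codon window 268-471 by default). POLE coding
#' variants outside the window (such as p.Tyr956His) are reported as
#' `other` and never trigger the POLE call on their own.
#'
#' @param variants a `somatic_variants` table with gene/protein_change
#' @param domain codon window, default c(268, 471)
#' @return list(exo = logical, other = logical)
#' @export
detect_pole_exonuclease <- function(variants, domain = c(268L, 471L)) {
  pole <- variants[!is.na(variants$gene) & variants$gene == "POLE", ,
                   drop = FALSE]
  if (nrow(pole) == 0) return(list(exo = FALSE, other = FALSE))
  codons <- vapply(pole$protein_change, parse_hgvsp_codon, numeric(1))
  bad <- is.na(codons)
  if (any(bad))
    warning(sum(bad), " POLE variant(s) with unparseable protein change ",
            "counted as non-exonuclease")
  exo <- !bad & codons >= domain[1] & codons <= domain[2] &
    hgvsp_class(pole$protein_change) == "missense"
  list(exo = any(exo), other = any(!exo))
}

#' Extract the (first) codon number from an HGVS-p string
#' @param p protein change such as "p.Pro286Arg" or "p.G12D"
#' @return codon number or NA
#' @keywords internal
parse_hgvsp_codon <- function(p) {
  if (is.na(p)) return(NA_real_)
  m <- regmatches(p, regexpr("[0-9]+", p))
  if (length(m) == 0) NA_real_ else as.numeric(m)
}

#' Crude protein-consequence class from HGVS-p
#' @param p character vector of protein changes
#' @return one of missense/nonsense/frameshift/splice/other per element
#' @keywords internal
hgvsp_class <- function(p) {
  out <- rep("other", length(p))
  out[grepl("fs", p)] <- "frameshift"
  out[grepl("\\*$|Ter$", p) & !grepl("fs", p)] <- "nonsense"
  out[grepl("splice", p, ignore.case = TRUE)] <- "splice"
  miss <- grepl("^p\\.([A-Z][a-z]{2}|[A-Z])[0-9]+([A-Z][a-z]{2}|[A-Z])$", p) &
    !grepl("fs|\\*|Ter", p)
  out[miss] <- "missense"
  out[is.na(p)] <- NA_character_
  out
}

#' Four-way molecular subtype classification
#'
#' Decision procedure over the five classification axes (driver
#' mutations, TMB, MSI score, copy-number burden, dominant signature),
#' with fixed precedence:
#' \enumerate{
#'   \item POLE: exonuclease-domain mutation and TMB above `pole_tmb_min`;
#'   \item MMRd: MSI score >= `msi_cut` and TMB > `tmb_mmrd`;
#'   \item CN-high: pct_cna > `pct_cna_cnhigh`, segments > `n_seg_cnhigh`
#'     and TMB <= `tmb_cnhigh`;
#'   \item CN-low: everything else.
#' }
#' The precedence mirrors how a hypermutated sample carrying a
#' non-exonuclease POLE variant is still called MMRd. TP53 status is
#' reported as evidence only — the CN-high group is typically but not
#' universally TP53-mutant — and MMRd does not require a detected MMR-gene
#' mutation (the deficiency can be epigenetic).
#'
#' @param burden a `burden_summary`
#' @param exposure an `exposure_estimate` (or NULL: etiology reported as none)
#' @param variants a `somatic_variants` table
#' @param config a `run_config`
#' @param catalog_ref a `signature_catalog` for etiology lookup
#' @return list of class `subtype_call`: label, evidence, thresholds_used
#' @export
classify_subtype <- function(burden, exposure, variants,
                             config = default_config(),
                             catalog_ref = default_signature_catalog()) {
  for (metric in c("tmb", "msi_score", "pct_cna", "n_cna_segments"))
    if (is.null(burden[[metric]]) || is.na(burden[[metric]]))
      stop("missing metric: ", metric)
  pole <- detect_pole_exonuclease(variants, config$pole_domain)
  dom <- if (is.null(exposure)) "none"
         else dominant_etiology(exposure, catalog_ref, config$dominance)
  mmr_genes <- c("MLH1", "MSH2", "MSH6", "PMS2")
  evidence <- list(
    tmb = burden$tmb, msi_score = burden$msi_score,
    pct_cna = burden$pct_cna, n_cna_segments = burden$n_cna_segments,
    dominant_etiology = dom,
    pole_exonuclease_mut = pole$exo, pole_other_mut = pole$other,
    tp53_mut = any(!is.na(variants$gene) & variants$gene == "TP53"),
    mmr_gene_hits = unique(variants$gene[!is.na(variants$gene) &
                                           variants$gene %in% mmr_genes]))
  label <-
    if (pole$exo && burden$tmb > config$pole_tmb_min) "POLE"
    else if (burden$msi_score >= config$msi_cut && burden$tmb > config$tmb_mmrd) "MMRd"
    else if (burden$pct_cna > config$pct_cna_cnhigh &&
             burden$n_cna_segments > config$n_seg_cnhigh &&
             burden$tmb <= config$tmb_cnhigh) "CN-high"
    else "CN-low"
  structure(list(label = label, evidence = evidence,
                 thresholds_used = config[c("msi_cut", "tmb_mmrd", "tmb_cnhigh",
                                            "pct_cna_cnhigh", "n_seg_cnhigh",
                                            "pole_tmb_min", "pole_domain",
                                            "dominance")]),
            class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  e <- x$evidence
  cat(sprintf(paste0("<subtype_call> %s (TMB %.1f/Mb, MSI %.1f%%, CNA %.1f%% ",
                     "in %d segments, etiology %s)\n"),
              x$label, e$tmb, e$msi_score, e$pct_cna, e$n_cna_segments,
              e$dominant_etiology))
  invisible(x)
}

#' Default driver-gene panel for evidence annotation
#' @return character vector of gene symbols
#' @export
default_driver_panel <- function() {
  c("TP53", "POLE", "PTEN", "ARID1A", "PIK3CA", "KRAS", "RPL22",
    "MSH2", "MSH6", "MLH1", "PMS2")
}

#' Annotate driver-panel hits
#'
#' Filters the variant table to a gene panel and attaches a crude
#' protein-consequence class parsed from the HGVS-p annotation.
#'
#' @param variants a `somatic_variants` table
#' @param gene_panel character vector of gene symbols
#' @return data.frame(gene, protein_change, id, class)
#' @export
annotate_drivers <- function(variants, gene_panel = default_driver_panel()) {
  hits <- variants[!is.na(variants$gene) & variants$gene %in% gene_panel, ,
                   drop = FALSE]
  data.frame(gene = hits$gene, protein_change = hits$protein_change,
             id = hits$id, class = hgvsp_class(hits$protein_change),
             stringsAsFactors = FALSE)
}
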