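#' Build the 96-channel mutation catalog from somatic variants
#'
#' Only SNPs with a trinucleotide context contribute. Purine-reference
#' calls are reverse-complemented onto the pyrimidine strand, the field
#' convention for SBS96 catalogs. Variants whose context middle base
#' disagrees with the reference allele are skipped with a warning and the
#' skip count is attached as an attribute.
#'
#' @param variants a `somatic_variants` table
#' @return named integer vector of 96 channel counts
#'   (class `mutation_catalog96`, attribute `n_skipped`)
#' @export
build_catalog <- function(variants) {
  ch <- sbs96_channels()
  counts <- stats::setNames(integer(length(ch)), ch)
  skipped <- 0L
  snv <- variants[variants$vclass == "SNP" & !is.na(variants$context3), ,
                  drop = FALSE]
  if (nrow(snv) > 0) {
    ref <- snv$ref; alt <- snv$alt; ctx <- toupper(snv$context3)
    pur <- ref %in% c("A", "G")
    ref[pur] <- revcomp(ref[pur])
    alt[pur] <- revcomp(alt[pur])
    ctx[pur] <- revcomp(ctx[pur])
    ok <- substr(ctx, 2, 2) == ref & nchar(ctx) == 3
    skipped <- sum(!ok)
    if (skipped > 0)
      warning(skipped, " variant(s) skipped: context inconsistent with ref allele")
    lab <- paste0(substr(ctx[ok], 1, 1), "[", ref[ok], ">", alt[ok], "]",
                  substr(ctx[ok], 3, 3))
    tab <- table(factor(lab, levels = ch))
    counts <- stats::setNames(as.integer(tab), ch)
  }
  structure(counts, class = "mutation_catalog96", n_skipped = skipped)
}

#' Reverse-complement a DNA string vector
#' @param x character vector of A/C/G/T strings
#' @return reverse complements
#' @export
revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL),
                function(s) paste(rev(s), collapse = ""), ""))
}

#' Refit signature exposures onto a mutation catalog
#'
#' Three-stage refit in the style of iterative signature attribution tools:
#' \enumerate{
#'   \item Forward selection on the normalized 96-spectrum: each round
#'     scores every candidate signature by one-dimensional line search
#'     (the current reconstruction is scaled by \eqn{1-a} and the
#'     candidate enters with weight \eqn{a}), admits the candidate giving
#'     the largest drop in sum-of-squared error, and refits the admitted
#'     set jointly by nonnegative least squares before the next round;
#'     selection stops when the relative SSE improvement falls below
#'     `rel_tol`.
#'   \item Signatures whose weight falls below `cutoff` (default 15%, the
#'     minimum-contribution rule) are dropped.
#'   \item Joint nonnegative least squares restricted to the survivors;
#'     weights renormalized to sum to one.
#' }
#' Ties in forward selection break by signature name order, so the refit is
#' deterministic.
#'
#' @param catalog `mutation_catalog96` counts (sum must be positive)
#' @param catalog_ref a `signature_catalog` (default: bundled synthetic)
#' @param cutoff minimum retained contribution, default 0.15
#' @param rel_tol forward-selection stopping rule on relative SSE improvement
#' @return list of class `exposure_estimate`: `weights` (named, sum 1),
#'   `residual_sse`, `n_snvs`, `cutoff_used`
#' @export
refit_exposures <- function(catalog, catalog_ref = default_signature_catalog(),
                            cutoff = 0.15, rel_tol = 1e-3) {
  m <- as.numeric(catalog)
  n_snvs <- sum(m)
  if (n_snvs <= 0) stop("empty spectrum: catalog has no mutations")
  m <- m / n_snvs
  S <- catalog_ref$signatures
  sse <- function(recon) sum((m - recon) ^ 2)

  support <- character()
  w <- stats::setNames(numeric(ncol(S)), colnames(S))
  recon <- numeric(96)
  cur <- sse(recon)
  repeat {
    best <- list(sse = cur, j = NA)
    for (j in setdiff(colnames(S), support)) {
      f <- function(a) sse((1 - a) * recon + a * S[, j])
      opt <- stats::optimize(f, c(0, 1), tol = 1e-4)
      if (opt$objective < best$sse - 1e-12) best <- list(sse = opt$objective,
                                                         j = j)
    }
    if (is.na(best$j) || (cur - best$sse) < rel_tol * cur) break
    support <- c(support, best$j)
    fit <- pracma::lsqnonneg(S[, support, drop = FALSE], m)
    w[] <- 0
    w[support] <- fit$x
    recon <- as.numeric(S[, support, drop = FALSE] %*% fit$x)
    cur <- sse(recon)
    if (cur <= 1e-12 || length(support) == ncol(S)) break
  }
  if (sum(w) > 0) w <- w / sum(w)

  keep <- names(w)[w >= cutoff]
  if (length(keep) == 0) keep <- names(which.max(w))
  fit <- pracma::lsqnonneg(S[, keep, drop = FALSE], m)
  wk <- fit$x
  if (sum(wk) <= 0) wk <- rep(1 / length(keep), length(keep))
  wk <- wk / sum(wk)
  names(wk) <- keep
  wk <- wk[wk >= cutoff]
  wk <- wk / sum(wk)
  wk <- wk[order(names(wk))]
  recon <- as.numeric(S[, names(wk), drop = FALSE] %*% wk)
  structure(list(weights = wk, residual_sse = sse(recon),
                 n_snvs = as.integer(round(n_snvs)), cutoff_used = cutoff),
            class = "exposure_estimate")
}

#' @export
print.exposure_estimate <- function(x, ...) {
  cat("<exposure_estimate> n =", x$n_snvs, "SNVs, SSE =",
      signif(x$residual_sse, 3), "\n")
  for (nm in names(sort(x$weights, decreasing = TRUE)))
    cat(sprintf("  %-14s %5.1f%%\n", nm, 100 * x$weights[nm]))
  invisible(x)
}

#' Dominant mutational-process etiology
#'
#' A sample has a dominant signature when its largest single exposure
#' reaches the dominance threshold (default 30% of somatic mutations
#' attributed to one signature); otherwise no etiology is reported.
#'
#' @param exposure an `exposure_estimate`
#' @param catalog_ref a `signature_catalog` supplying etiology labels
#' @param threshold dominance threshold, default 0.30
#' @return etiology label, or "none"
#' @export
dominant_etiology <- function(exposure,
                              catalog_ref = default_signature_catalog(),
                              threshold = 0.30) {
  if (length(exposure$weights) == 0) return("none")
  top <- which.max(exposure$weights)
  if (exposure$weights[top] < threshold) return("none")
  et <- catalog_ref$etiology[names(exposure$weights)[top]]
  if (is.na(et)) "other" else unname(et)
}

#' Signature-3 (HRD) fraction of an exposure estimate
#' @param exposure an `exposure_estimate`
#' @return Signature.3 weight, 0 when not retained
#' @export
sig3_fraction <- function(exposure) {
  w <- exposure$weights["Signature.3"]
  if (is.na(w)) 0 else unname(w)
}
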