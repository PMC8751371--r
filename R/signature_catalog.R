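#' The 96 single-base-substitution channels
#'
#' Canonical ordering: six pyrimidine substitution classes (C>A, C>G, C>T,
#' T>A, T>C, T>G), each crossed with the 16 flanking-base contexts in
#' lexicographic order. Labels use the conventional `5'[ref>alt]3'` form.
#'
#' @return character vector of 96 channel labels
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(bases, bases, function(f5, f3)
      paste0(f5, "[", s, "]", f3))))))
}

#' Synthetic 30-signature SBS96 reference catalog
#'
#' A deterministic stand-in reference of 30 single-base-substitution
#' signatures. It is synthetic: the channel profiles are constructed, not
#' measured, but the signatures carrying a named etiology reproduce the
#' qualitative shape associated with that process (CpG-focused C>T for the
#' ageing clock, TpC-focused C>T/C>G for APOBEC, a near-flat profile for
#' the HR-deficiency signature, TpCpT C>A enrichment for polymerase-epsilon
#' proofreading loss, and so on); the remaining signatures are sparse,
#' mutually distinct filler spectra. Columns sum to 1.
#'
#' The same matrix ships as a TSV at
#' `system.file("extdata", "signatures_sbs96_synthetic.tsv", package = "ecpdx")`.
#'
#' @return 96 x 30 matrix; rownames are channels, colnames Signature.1..30
#' @export
make_synthetic_signatures <- function() {
  ch <- sbs96_channels()
  n <- length(ch)
  sub_of <- substr(ch, 3, 5)
  f5 <- substr(ch, 1, 1)
  f3 <- substr(ch, 7, 7)

  base_profile <- function() rep(0.08 / n, n)
  add <- function(p, sel, mass) {
    sel <- which(sel)
    p[sel] <- p[sel] + mass / length(sel)
    p
  }
  norm <- function(p) p / sum(p)

  sig <- matrix(0, n, 30, dimnames = list(ch, paste0("Signature.", 1:30)))

  # ageing: C>T at NpCpG
  p <- base_profile()
  p <- add(p, sub_of == "C>T" & f3 == "G", 0.60)
  p <- add(p, sub_of == "C>T", 0.22)
  p <- add(p, sub_of == "T>C", 0.10)
  sig[, 1] <- norm(p)

  # APOBEC: C>T at TpCpW
  p <- base_profile()
  p <- add(p, sub_of == "C>T" & f5 == "T" & f3 %in% c("A", "T"), 0.66)
  p <- add(p, sub_of == "C>G" & f5 == "T", 0.12)
  p <- add(p, sub_of == "C>T", 0.14)
  sig[, 2] <- norm(p)

  # HR deficiency: near-flat
  p <- rep(1 / n, n)
  p <- add(p, sub_of %in% c("C>G", "T>A"), 0.06)  # mild tilt, still broad
  sig[, 3] <- norm(p)

  # clock-like, T>C dominated
  p <- base_profile()
  p <- add(p, sub_of == "T>C" & f5 == "A", 0.48)
  p <- add(p, sub_of == "T>C", 0.20)
  p <- add(p, sub_of == "C>T" & f3 != "G", 0.18)
  sig[, 5] <- norm(p)

  # MMR deficiency: C>T with 5' C/G, plus G[T>C]N
  p <- base_profile()
  p <- add(p, sub_of == "C>T" & f5 == "C", 0.40)
  p <- add(p, sub_of == "C>T" & f5 == "G" & f3 != "G", 0.22)
  p <- add(p, sub_of == "T>C" & f5 == "G", 0.22)
  sig[, 6] <- norm(p)

  # POLE proofreading loss: C>A at TpCpT, C>T at TpCpG
  p <- base_profile()
  p <- add(p, ch == "T[C>A]T", 0.50)
  p <- add(p, ch == "T[C>T]G", 0.22)
  p <- add(p, sub_of == "C>A", 0.12)
  sig[, 10] <- norm(p)

  # APOBEC: C>G at TpCpW
  p <- base_profile()
  p <- add(p, sub_of == "C>G" & f5 == "T" & f3 %in% c("A", "T"), 0.66)
  p <- add(p, sub_of == "C>T" & f5 == "T", 0.14)
  sig[, 13] <- norm(p)

  # concurrent POLE + MMR: hybrid peaks
  p <- base_profile()
  p <- add(p, ch == "T[C>A]T", 0.24)
  p <- add(p, sub_of == "C>A" & f5 == "C", 0.22)
  p <- add(p, sub_of == "T>G" & f3 == "T", 0.26)
  p <- add(p, sub_of == "C>T" & f5 == "C", 0.14)
  sig[, 14] <- norm(p)

  # further MMR-associated spectra, mutually distinct
  p <- base_profile()
  p <- add(p, sub_of == "C>T" & f5 == "A" & f3 != "G", 0.52)
  p <- add(p, sub_of == "T>C" & f3 == "C", 0.24)
  sig[, 15] <- norm(p)

  p <- base_profile()
  p <- add(p, sub_of == "C>T" & f5 == "G" & f3 == "T", 0.40)
  p <- add(p, sub_of == "C>A" & f5 == "C" & f3 == "T", 0.30)
  sig[, 20] <- norm(p)

  p <- base_profile()
  p <- add(p, sub_of == "T>C" & f5 == "T", 0.46)
  p <- add(p, sub_of == "T>A" & f5 == "T", 0.24)
  sig[, 26] <- norm(p)

  # filler signatures: sparse deterministic peak sets, no assigned etiology
  filler <- setdiff(1:30, c(1, 2, 3, 5, 6, 10, 13, 14, 15, 20, 26))
  for (k in filler) {
    p <- base_profile()
    peaks <- ((k * 17L + (0:5) * 31L) %% n) + 1L
    w <- 0.92 * (0.55 ^ (0:5))
    w <- w / sum(w) * 0.92
    p[peaks] <- p[peaks] + w
    sig[, k] <- norm(p)
  }
  sig
}

#' Etiology labels for the bundled signatures
#'
#' Maps each signature name to the mutational process class used for
#' dominant-etiology reporting: ageing, APOBEC, HRD, MMR, POLE,
#' POLE+MMR, or other.
#'
#' @return named character vector over Signature.1..30
#' @export
signature_etiologies <- function() {
  et <- stats::setNames(rep("other", 30), paste0("Signature.", 1:30))
  et[c("Signature.1", "Signature.5")] <- "age"
  et[c("Signature.2", "Signature.13")] <- "APOBEC"
  et["Signature.3"] <- "HRD"
  et[c("Signature.6", "Signature.15", "Signature.20", "Signature.26")] <- "MMR"
  et["Signature.10"] <- "POLE"
  et["Signature.14"] <- "POLE+MMR"
  et
}

#' Assemble a signature catalog object
#' @param signatures 96 x K matrix of channel probabilities (columns sum to 1)
#' @param etiology named character vector of process labels per signature
#' @return list of class `signature_catalog`
#' @export
signature_catalog <- function(signatures,
                              etiology = signature_etiologies()[colnames(signatures)]) {
  stopifnot(is.matrix(signatures), nrow(signatures) == 96)
  if (any(signatures < 0)) stop("signature entries must be nonnegative")
  s <- colSums(signatures)
  if (any(abs(s - 1) > 1e-9)) stop("signature columns must sum to 1")
  etiology[is.na(etiology)] <- "other"
  structure(list(signatures = signatures,
                 etiology = stats::setNames(as.character(etiology),
                                            colnames(signatures))),
            class = "signature_catalog")
}

#' Default (bundled synthetic) signature catalog
#' @return a `signature_catalog` with 30 signatures
#' @export
default_signature_catalog <- function() {
  path <- system.file("extdata", "signatures_sbs96_synthetic.tsv",
                      package = "ecpdx")
  if (nzchar(path)) read_signature_catalog(path)
  else signature_catalog(make_synthetic_signatures())
}

#' Read a signature catalog from TSV (96 rows x signatures)
#' @param path TSV with a `channel` column then one column per signature
#' @return a `signature_catalog`
#' @export
read_signature_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"channel" %in% names(df)) stop("signature TSV needs a 'channel' column")
  m <- as.matrix(df[, setdiff(names(df), "channel"), drop = FALSE])
  rownames(m) <- df$channel
  m <- m[match(sbs96_channels(), rownames(m)), , drop = FALSE]
  if (anyNA(m)) stop("signature TSV does not cover all 96 channels")
  s <- colSums(m)
  if (any(abs(s - 1) > 1e-4)) stop("signature columns must sum to ~1")
  m <- sweep(m, 2, s, "/")  # absorb file rounding
  signature_catalog(m)
}

#' Write a signature catalog as TSV
#' @param catalog a `signature_catalog`
#' @param path output path
#' @export
write_signature_catalog <- function(catalog, path) {
  df <- data.frame(channel = rownames(catalog$signatures),
                   signif(catalog$signatures, 7), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
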