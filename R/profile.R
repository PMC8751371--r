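#' Somatic variant table constructor
#'
#' Variants are kept as a plain data.frame, one row per somatic call, with
#' 1-based positions. `context3` is the pyrimidine-normalized trinucleotide
#' context and is required for SNPs only; it feeds the 96-channel catalog.
#'
#' @param chrom chromosome names
#' @param pos 1-based positions
#' @param ref,alt allele strings
#' @param vclass variant class: SNP, DNP, TNP, INS or DEL (inferred from
#'   allele lengths when NULL)
#' @param context3 trinucleotide context for SNPs (NA otherwise)
#' @param vaf variant allele fraction in [0,1]
#' @param depth total read depth
#' @param gene,protein_change optional annotations
#' @param id stable identifier (default `chrom:pos:ref>alt`)
#' @return data.frame of class `somatic_variants`
#' @export
somatic_variants <- function(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             vclass = NULL, context3 = NA_character_,
                             vaf = numeric(), depth = integer(),
                             gene = NA_character_,
                             protein_change = NA_character_, id = NULL) {
  n <- length(chrom)
  if (is.null(vclass)) vclass <- infer_vclass(ref, alt)
  if (is.null(id) && n > 0) id <- paste0(chrom, ":", pos, ":", ref, ">", alt)
  if (is.null(id)) id <- character()
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   vclass = as.character(vclass),
                   context3 = rep_len(as.character(context3), n),
                   vaf = as.numeric(vaf), depth = as.integer(depth),
                   gene = rep_len(as.character(gene), n),
                   protein_change = rep_len(as.character(protein_change), n),
                   id = as.character(id),
                   stringsAsFactors = FALSE)
  class(df) <- c("somatic_variants", "data.frame")
  df
}

#' Infer variant class from allele lengths (MAF-like dialect)
#' @param ref,alt allele strings; "-" denotes the empty allele
#' @return character vector over {SNP, DNP, TNP, INS, DEL}
#' @export
infer_vclass <- function(ref, alt) {
  nr <- ifelse(ref == "-", 0L, nchar(ref))
  na <- ifelse(alt == "-", 0L, nchar(alt))
  out <- rep("SNP", length(ref))
  out[nr == 2 & na == 2] <- "DNP"
  out[nr == 3 & na == 3] <- "TNP"
  out[na > nr] <- "INS"
  out[na < nr] <- "DEL"
  out
}

#' Allele-specific copy-number segment table
#'
#' @param chrom chromosome names
#' @param start_bp,end_bp 1-based inclusive bounds
#' @param total_cn integer total copy number (>= 0)
#' @param minor_cn integer minor-allele copy number, `minor_cn <= total_cn - minor_cn`
#' @return data.frame of class `allelic_segments`, sorted by (chrom, start)
#' @export
allelic_segments <- function(chrom = character(), start_bp = integer(),
                             end_bp = integer(), total_cn = integer(),
                             minor_cn = integer()) {
  df <- data.frame(chrom = as.character(chrom),
                   start_bp = as.numeric(start_bp),
                   end_bp = as.numeric(end_bp),
                   total_cn = as.integer(total_cn),
                   minor_cn = as.integer(minor_cn),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(df$end_bp < df$start_bp)) stop("segment end < start")
    if (any(df$total_cn < 0)) stop("total_cn must be >= 0")
    if (any(df$minor_cn < 0 | df$minor_cn > df$total_cn - df$minor_cn))
      stop("minor_cn must satisfy 0 <= minor_cn <= total_cn - minor_cn")
    df <- df[order(df$chrom, df$start_bp), , drop = FALSE]
    rownames(df) <- NULL
    for (cc in unique(df$chrom)) {
      s <- df[df$chrom == cc, ]
      if (nrow(s) > 1 && any(s$start_bp[-1] <= s$end_bp[-nrow(s)]))
        stop("overlapping segments on chromosome ", cc)
    }
  }
  class(df) <- c("allelic_segments", "data.frame")
  df
}

#' Microsatellite panel summary
#' @param n_assessed number of evaluated microsatellite sites (> 0)
#' @param n_unstable number called somatically unstable
#' @return list of class `microsat_result`
#' @export
microsat_result <- function(n_assessed, n_unstable) {
  if (n_assessed <= 0) stop("n_assessed must be positive")
  if (n_unstable < 0 || n_unstable > n_assessed)
    stop("n_unstable must lie in [0, n_assessed]")
  structure(list(n_assessed = as.integer(n_assessed),
                 n_unstable = as.integer(n_unstable)),
            class = "microsat_result")
}

#' One tumor sample's somatic profile
#'
#' Bundles the somatic variants, allele-specific segments, microsatellite
#' summary and metadata for one sample (a primary tumor or a PDX sample
#' identified by lineage and passage).
#'
#' @param sample_id sample identifier
#' @param role "primary" or "pdx"
#' @param lineage optional lineage label ("A", "B", ...), PDX only
#' @param passage optional transplant generation (0 = F0), PDX only
#' @param purity tumor purity in (0, 1], or NA when unknown
#' @param callable_mb callable region size in Mb (TMB denominator)
#' @param variants a `somatic_variants` table
#' @param segments an `allelic_segments` table
#' @param ms_result a `microsat_result`
#' @return list of class `sample_profile`
#' @export
sample_profile <- function(sample_id, role = c("primary", "pdx"),
                           lineage = NA_character_, passage = NA_integer_,
                           purity = NA_real_, callable_mb,
                           variants = somatic_variants(),
                           segments = allelic_segments(),
                           ms_result = microsat_result(1000, 0)) {
  role <- match.arg(role)
  if (role == "primary" && !is.na(passage))
    stop("passage is only meaningful for PDX samples")
  if (callable_mb <= 0) stop("callable_mb must be positive")
  if (!is.na(purity) && (purity <= 0 || purity > 1))
    stop("purity must lie in (0, 1]")
  structure(list(sample_id = sample_id, role = role, lineage = lineage,
                 passage = if (is.na(passage)) NA_integer_ else as.integer(passage),
                 purity = purity, callable_mb = callable_mb,
                 variants = variants, segments = segments,
                 ms_result = ms_result),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  lab <- if (x$role == "pdx")
    sprintf("pdx F%s(%s)", ifelse(is.na(x$passage), "?", x$passage),
            ifelse(is.na(x$lineage), "?", x$lineage)) else "primary"
  cat(sprintf("<sample_profile> %s [%s]: %d variants, %d segments, MSI %d/%d\n",
              x$sample_id, lab, nrow(x$variants), nrow(x$segments),
              x$ms_result$n_unstable, x$ms_result$n_assessed))
  invisible(x)
}

#' Validate a sample profile against a genome build
#'
#' Structural checks that never raise: every violated invariant is returned
#' as one row of a data.frame (`what`, `where`, `detail`). An empty result
#' means the profile is well formed and all coordinates fall inside the
#' genome.
#'
#' @param profile a `sample_profile`
#' @param genome a `genome_build`
#' @return data.frame with columns what/where/detail (0 rows when clean)
#' @export
validate_profile <- function(profile, genome = default_genome()) {
  v <- list()
  add <- function(what, where, detail)
    v[[length(v) + 1]] <<- data.frame(what = what, where = where,
                                      detail = detail, stringsAsFactors = FALSE)
  len <- stats::setNames(genome$chromosomes$length_bp, genome$chromosomes$name)

  if (profile$callable_mb <= 0)
    add("callable_mb", profile$sample_id, "must be positive")
  if (!is.na(profile$purity) && (profile$purity <= 0 || profile$purity > 1))
    add("purity", profile$sample_id, "must lie in (0,1]")
  if (profile$role == "primary" && !is.na(profile$passage))
    add("passage", profile$sample_id, "present on a primary sample")

  vr <- profile$variants
  if (nrow(vr) > 0) {
    bad <- which(is.na(vr$vaf) | vr$vaf < 0 | vr$vaf > 1)
    for (i in bad) add("vaf", vr$id[i], "outside [0,1]")
    bad <- which(vr$vclass == "SNP" & (is.na(vr$context3) | nchar(vr$context3) != 3))
    for (i in bad) add("context3", vr$id[i], "missing or malformed for SNP")
    bad <- which(vr$vclass != "SNP" & !is.na(vr$context3))
    for (i in bad) add("context3", vr$id[i], "present on non-SNP")
    unknown <- !(vr$chrom %in% names(len))
    for (i in which(unknown)) add("chrom", vr$id[i], "not in genome")
    oob <- which(!unknown & (vr$pos < 1 | vr$pos > len[vr$chrom]))
    for (i in oob) add("pos", vr$id[i], "outside chromosome bounds")
  }

  sg <- profile$segments
  if (nrow(sg) > 0) {
    for (i in seq_len(nrow(sg))) {
      where <- sprintf("%s:%s-%s", sg$chrom[i], sg$start_bp[i], sg$end_bp[i])
      if (sg$end_bp[i] < sg$start_bp[i]) add("segment", where, "end < start")
      if (sg$minor_cn[i] < 0 || sg$minor_cn[i] > sg$total_cn[i] - sg$minor_cn[i])
        add("segment", where, "minor_cn > total_cn - minor_cn")
      if (!(sg$chrom[i] %in% names(len)))
        add("segment", where, "chromosome not in genome")
      else if (sg$start_bp[i] < 1 || sg$end_bp[i] > len[sg$chrom[i]])
        add("segment", where, "outside chromosome bounds")
    }
    for (cc in unique(sg$chrom)) {
      s <- sg[sg$chrom == cc, ]
      s <- s[order(s$start_bp), ]
      if (nrow(s) > 1 && any(s$start_bp[-1] <= s$end_bp[-nrow(s)]))
        add("segment", cc, "overlapping segments")
    }
  }

  ms <- profile$ms_result
  if (ms$n_assessed <= 0) add("ms_result", profile$sample_id, "n_assessed <= 0")
  if (ms$n_unstable < 0 || ms$n_unstable > ms$n_assessed)
    add("ms_result", profile$sample_id, "n_unstable outside [0, n_assessed]")

  if (length(v) == 0)
    return(data.frame(what = character(), where = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Tumor-volume series for one animal
#' @param animal_id animal identifier
#' @param arm "vehicle" or "drug"
#' @param day integer measurement days, strictly increasing
#' @param volume_mm3 positive tumor volumes
#' @return data.frame of class `therapy_series`
#' @export
therapy_series <- function(animal_id, arm = c("vehicle", "drug"), day, volume_mm3) {
  arm <- match.arg(arm)
  if (any(diff(day) <= 0)) stop("days must be strictly increasing")
  if (any(volume_mm3 <= 0)) stop("volumes must be positive")
  df <- data.frame(animal_id = animal_id, arm = arm, day = as.integer(day),
                   volume_mm3 = as.numeric(volume_mm3), stringsAsFactors = FALSE)
  class(df) <- c("therapy_series", "data.frame")
  df
}
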