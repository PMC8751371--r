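#' Read somatic variants from a MAF-like TSV
#'
#' Minimal MAF dialect: columns Chromosome, Start_Position (1-based),
#' Reference_Allele, Tumor_Seq_Allele2 are mandatory; Variant_Type,
#' t_alt_count, t_depth, Hugo_Symbol, HGVSp_Short and Context3 are used
#' when present. VAF is t_alt_count / t_depth unless a VAF column exists.
#' The variant class is inferred from allele lengths when Variant_Type is
#' absent ("-" denotes the empty allele for indels).
#'
#' @param path TSV file with a header row
#' @return a `somatic_variants` table
#' @export
read_variants_maf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  need <- c("Chromosome", "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("MAF file missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(somatic_variants())

  pos <- suppressWarnings(as.integer(df$Start_Position))
  if (anyNA(pos))
    stop("unparseable Start_Position at line ", which(is.na(pos))[1] + 1L)
  pick <- function(col, default) if (col %in% names(df)) df[[col]] else default
  depth <- suppressWarnings(as.integer(pick("t_depth", NA)))
  altc <- suppressWarnings(as.numeric(pick("t_alt_count", NA)))
  vaf <- if ("VAF" %in% names(df)) suppressWarnings(as.numeric(df$VAF))
         else altc / depth
  vclass <- pick("Variant_Type", NA)
  if (all(is.na(vclass)))
    vclass <- infer_vclass(df$Reference_Allele, df$Tumor_Seq_Allele2)
  ctx <- pick("Context3", NA_character_)
  ctx[!is.na(ctx) & ctx == ""] <- NA_character_

  somatic_variants(chrom = df$Chromosome, pos = pos,
                   ref = df$Reference_Allele, alt = df$Tumor_Seq_Allele2,
                   vclass = vclass, context3 = ctx,
                   vaf = vaf, depth = depth,
                   gene = blank_to_na(pick("Hugo_Symbol", NA_character_)),
                   protein_change = blank_to_na(pick("HGVSp_Short", NA_character_)))
}

blank_to_na <- function(x) { x[!is.na(x) & x == ""] <- NA_character_; x }

#' Write somatic variants as MAF-like TSV
#' @param variants a `somatic_variants` table
#' @param path output path
#' @export
write_variants_maf <- function(variants, path) {
  out <- data.frame(
    Hugo_Symbol = ifelse(is.na(variants$gene), "", variants$gene),
    Chromosome = variants$chrom,
    Start_Position = variants$pos,
    Reference_Allele = variants$ref,
    Tumor_Seq_Allele2 = variants$alt,
    Variant_Type = variants$vclass,
    t_alt_count = round(variants$vaf * variants$depth),
    t_depth = variants$depth,
    VAF = variants$vaf,
    HGVSp_Short = ifelse(is.na(variants$protein_change), "", variants$protein_change),
    Context3 = ifelse(is.na(variants$context3), "", variants$context3),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read allele-specific segments from a SEG-like TSV
#'
#' SEG dialect extended with allele-specific columns: chrom, start_bp,
#' end_bp (1-based inclusive), total_cn, minor_cn. Segments are sorted at
#' ingestion; overlapping segments on one chromosome are an error.
#'
#' @param path TSV file
#' @return an `allelic_segments` table
#' @export
read_segments_seg <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "start_bp", "end_bp", "total_cn", "minor_cn")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("SEG file missing column(s): ", paste(miss, collapse = ", "))
  allelic_segments(df$chrom, df$start_bp, df$end_bp, df$total_cn, df$minor_cn)
}

#' Write segments as SEG-like TSV
#' @param segments an `allelic_segments` table
#' @param path output path
#' @export
write_segments_seg <- function(segments, path) {
  utils::write.table(as.data.frame(segments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a microsatellite panel summary (TSV: n_assessed, n_unstable)
#' @param path TSV file with one data row
#' @return a `microsat_result`
#' @export
read_microsat_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  microsat_result(df$n_assessed[1], df$n_unstable[1])
}

#' Write a microsatellite panel summary
#' @param ms a `microsat_result`
#' @param path output path
#' @export
write_microsat_tsv <- function(ms, path) {
  utils::write.table(data.frame(n_assessed = ms$n_assessed,
                                n_unstable = ms$n_unstable),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read tumor-volume series (TSV: animal_id, arm, day, volume_mm3)
#' @param path TSV file
#' @return list of `therapy_series`, one per animal
#' @export
read_volumes_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "arm", "day", "volume_mm3")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("volume file missing column(s): ", paste(miss, collapse = ", "))
  lapply(split(df, df$animal_id), function(a) {
    a <- a[order(a$day), ]
    therapy_series(a$animal_id[1], a$arm[1], a$day, a$volume_mm3)
  })
}

#' Write tumor-volume series
#' @param series list of `therapy_series`
#' @param path output path
#' @export
write_volumes_tsv <- function(series, path) {
  df <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read somatic variants from an uncompressed VCF
#'
#' Thin adapter onto the same `somatic_variants` records the MAF reader
#' produces. Multi-allelic rows are split into one record per ALT allele;
#' left-aligned indel notation is taken as-is. VAF/depth come from AF/DP
#' INFO keys when present.
#'
#' @param path uncompressed VCF file
#' @return a `somatic_variants` table
#' @export
read_variants_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) return(somatic_variants())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- list()
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    if (length(m) == 0) return(NA_real_)
    as.numeric(sub(paste0(".*", key, "="), "", m))
  }
  for (f in fields) {
    if (length(f) < 8) stop("malformed VCF row: ", paste(f, collapse = "\t"))
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    for (alt in alts) {
      ref <- f[4]
      # trim shared leading base for indels to match the MAF dialect
      if (nchar(ref) != nchar(alt) && substr(ref, 1, 1) == substr(alt, 1, 1)) {
        pos <- as.integer(f[2]) + 1L
        ref2 <- if (nchar(ref) > 1) substr(ref, 2, nchar(ref)) else "-"
        alt2 <- if (nchar(alt) > 1) substr(alt, 2, nchar(alt)) else "-"
      } else {
        pos <- as.integer(f[2]); ref2 <- ref; alt2 <- alt
      }
      rows[[length(rows) + 1]] <- data.frame(
        chrom = sub("^chr", "", f[1]), pos = pos, ref = ref2, alt = alt2,
        vaf = info_get(f[8], "AF"), depth = info_get(f[8], "DP"),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  somatic_variants(df$chrom, df$pos, df$ref, df$alt,
                   vaf = df$vaf, depth = df$depth)
}

#' Read a sample sheet
#'
#' TSV columns: sample_id, role, lineage, passage, callable_mb, purity,
#' variants_file, segments_file, microsat_file. File paths are resolved
#' relative to the sheet's directory; referenced files must exist.
#'
#' @param path sample sheet TSV
#' @return data.frame of class `sample_sheet`
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "role", "callable_mb",
            "variants_file", "segments_file", "microsat_file")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet")
  base <- dirname(path)
  for (col in c("variants_file", "segments_file", "microsat_file")) {
    df[[col]] <- ifelse(df[[col]] == "" | is.na(df[[col]]), NA,
                        file.path(base, df[[col]]))
    bad <- !is.na(df[[col]]) & !file.exists(df[[col]])
    if (any(bad)) stop("missing file referenced by sample sheet: ",
                       df[[col]][which(bad)[1]])
  }
  if (!"lineage" %in% names(df)) df$lineage <- NA_character_
  if (!"passage" %in% names(df)) df$passage <- NA_integer_
  if (!"purity" %in% names(df)) df$purity <- NA_real_
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Load the sample profiles referenced by a sample sheet
#' @param sheet a `sample_sheet`
#' @return named list of `sample_profile`
#' @export
load_sample_sheet <- function(sheet) {
  out <- lapply(seq_len(nrow(sheet)), function(i) {
    r <- sheet[i, ]
    sample_profile(
      sample_id = r$sample_id, role = r$role,
      lineage = if (is.na(r$lineage) || r$lineage == "") NA_character_ else r$lineage,
      passage = suppressWarnings(as.integer(r$passage)),
      purity = suppressWarnings(as.numeric(r$purity)),
      callable_mb = r$callable_mb,
      variants = if (is.na(r$variants_file)) somatic_variants()
                 else read_variants_maf(r$variants_file),
      segments = if (is.na(r$segments_file)) allelic_segments()
                 else read_segments_seg(r$segments_file),
      ms_result = if (is.na(r$microsat_file)) microsat_result(1000, 0)
                  else read_microsat_tsv(r$microsat_file))
  })
  stats::setNames(out, sheet$sample_id)
}

#' Write the per-sample report TSV
#'
#' One row per sample with the burden metrics, retained signature
#' exposures (packed as `name:weight` pairs), HRD components and call,
#' and the subtype label with its evidence flags. Column order is fixed
#' and samples are written in sorted sample_id order, so rewriting the
#' same results is byte-identical.
#'
#' @param results list of per-sample result lists as produced by
#'   [characterize_sample()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_report <- function(results, path) {
  cols <- c("sample_id", "subtype", "tmb", "msi_score", "pct_cna",
            "n_cna_segments", "dominant_etiology", "exposures",
            "ntai", "lst", "hrd_loh", "hrd_sum", "hrd_call",
            "sig3_fraction", "pole_exonuclease_mut", "tp53_mut")
  rows <- lapply(results, function(r) {
    ex <- r$exposure
    packed <- if (is.null(ex) || length(ex$weights) == 0) "" else
      paste(sprintf("%s:%.4f", names(ex$weights), ex$weights), collapse = ";")
    data.frame(
      sample_id = r$sample_id,
      subtype = if (is.null(r$subtype)) "" else r$subtype$label,
      tmb = num_or_na(r$burden$tmb), msi_score = num_or_na(r$burden$msi_score),
      pct_cna = num_or_na(r$burden$pct_cna),
      n_cna_segments = num_or_na(r$burden$n_cna_segments),
      dominant_etiology = if (is.null(r$dominant_etiology)) "none"
                          else r$dominant_etiology,
      exposures = packed,
      ntai = num_or_na(r$hrd$ntai), lst = num_or_na(r$hrd$lst),
      hrd_loh = num_or_na(r$hrd$hrd_loh), hrd_sum = num_or_na(r$hrd$sum),
      hrd_call = isTRUE(r$hrd$hrd_call),
      sig3_fraction = num_or_na(r$sig3_fraction),
      pole_exonuclease_mut = isTRUE(r$subtype$evidence$pole_exonuclease_mut),
      tp53_mut = isTRUE(r$subtype$evidence$tp53_mut),
      stringsAsFactors = FALSE)
  })
  df <- if (length(rows) == 0) {
    empty <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
    empty
  } else {
    df <- do.call(rbind, rows)[, cols]
    df[order(df$sample_id), , drop = FALSE]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
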