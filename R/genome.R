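#' Genome builds
#'
#' A genome build is a table of chromosomes with lengths and centromere
#' bounds. Scar metrics (NtAI, LST) need centromere coordinates to split
#' chromosomes into arms and to decide whether an allelic-imbalance run is
#' telomeric. All coordinates in this package are 1-based inclusive, the
#' convention shared by MAF and SEG files.
#'
#' @param chromosomes data.frame with columns `name`, `length_bp`,
#'   `centromere_start_bp`, `centromere_end_bp`.
#' @return An object of class `genome_build`: the validated chromosome table
#'   plus `total_length_bp`.
#' @export
genome_build <- function(chromosomes) {
  stopifnot(is.data.frame(chromosomes))
  need <- c("name", "length_bp", "centromere_start_bp", "centromere_end_bp")
  miss <- setdiff(need, names(chromosomes))
  if (length(miss) > 0)
    stop("genome table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(chromosomes$name))
    stop("duplicate chromosome names in genome table")
  with(chromosomes, {
    if (any(length_bp <= 0)) stop("chromosome length must be positive")
    if (any(centromere_start_bp <= 0 | centromere_end_bp <= centromere_start_bp |
            centromere_end_bp >= length_bp))
      stop("centromere bounds must satisfy 0 < start < end < length")
  })
  structure(
    list(chromosomes = chromosomes,
         total_length_bp = sum(as.numeric(chromosomes$length_bp))),
    class = "genome_build"
  )
}

#' Bundled hg19-like autosome table
#'
#' The 22 human autosomes with GRCh37 lengths and centromere (acen band)
#' bounds. Sex chromosomes are deliberately excluded: burden and scar
#' metrics assume a diploid baseline that does not hold on X/Y.
#'
#' @return A `genome_build` with 22 autosomes.
#' @examples
#' g <- default_genome()
#' nrow(g$chromosomes)  # 22
#' @export
default_genome <- function() {
  genome_build(data.frame(
    name = as.character(1:22),
    length_bp = c(
      249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
      159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
      115169878, 107349540, 102531392,  90354753,  81195210,  78077248,
       59128983,  63025520,  48129895,  51304566),
    centromere_start_bp = c(
      121535434,  92326171,  90504854,  49660117,  46405641,  58830166,
       58054331,  43838887,  47367679,  39254935,  51644205,  34856694,
       16000000,  16000000,  17000000,  35335801,  22263006,  15460898,
       24681782,  26369569,  11288129,  13000000),
    centromere_end_bp = c(
      124535434,  95326171,  93504854,  52660117,  49405641,  61830166,
       61054331,  46838887,  50367679,  42254935,  54644205,  37856694,
       19000000,  19000000,  20000000,  38335801,  25263006,  18460898,
       27681782,  29369569,  14288129,  16000000),
    stringsAsFactors = FALSE
  ))
}

#' Centromere midpoints
#'
#' Single coordinate used to split a chromosome into arms; arm-level scar
#' logic is insensitive to pericentromeric gaps at segment scale.
#' @param genome a `genome_build`
#' @return named numeric vector, one midpoint per chromosome
#' @keywords internal
centromere_midpoint <- function(genome) {
  ch <- genome$chromosomes
  stats::setNames(floor((ch$centromere_start_bp + ch$centromere_end_bp) / 2),
                  ch$name)
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build> ", nrow(x$chromosomes), " chromosomes, ",
      format(x$total_length_bp, big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Small configurable genome for examples and tests
#'
#' @param n_chrom number of chromosomes
#' @param length_bp per-chromosome length
#' @param centromere_frac centromere midpoint as fraction of length
#' @return a `genome_build`
#' @export
mini_genome <- function(n_chrom = 2, length_bp = 100e6, centromere_frac = 0.5) {
  mid <- round(length_bp * centromere_frac)
  genome_build(data.frame(
    name = as.character(seq_len(n_chrom)),
    length_bp = rep(length_bp, n_chrom),
    centromere_start_bp = rep(mid - 1e6, n_chrom),
    centromere_end_bp = rep(mid + 1e6, n_chrom),
    stringsAsFactors = FALSE
  ))
}
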