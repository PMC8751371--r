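#' Summarize a two-arm tumor-volume experiment
#'
#' Per animal the relative volume change is
#' `100 * (V_end - V_0) / V_0`, with V_0 the first measured day and
#' V_end the measurement at `end_day` (or the last prior day, flagged).
#' Tumor growth inhibition is `TGI = 100 * (1 - dT/dC)` over the arm-mean
#' absolute volume gains; it is undefined (NA, with a warning) when the
#' vehicle arm does not grow. The response category applies solid-tumor
#' response thresholds to the drug-arm mean relative change: PR at or
#' below -30%, PD at or above +20%, SD between. Classical RECIST
#' thresholds are defined on diameters; setting `diameter_equivalent`
#' cube-root-transforms volumes before the thresholds are applied.
#'
#' @param series list of `therapy_series` covering both arms
#' @param end_day final study day (default: last day observed)
#' @param diameter_equivalent apply thresholds on cube-root volumes
#' @return list of class `response_summary`
#' @export
summarize_response <- function(series, end_day = NULL,
                               diameter_equivalent = FALSE) {
  df <- do.call(rbind, lapply(series, as.data.frame))
  if (!all(c("vehicle", "drug") %in% df$arm))
    stop("both a vehicle and a drug arm are required")
  if (is.null(end_day)) end_day <- max(df$day)

  per_animal <- do.call(rbind, lapply(split(df, df$animal_id), function(a) {
    a <- a[order(a$day), ]
    eligible <- a[a$day <= end_day, ]
    if (nrow(eligible) == 0)
      stop("animal ", a$animal_id[1], " has no measurement by day ", end_day)
    v0 <- a$volume_mm3[1]
    vend <- eligible$volume_mm3[nrow(eligible)]
    if (diameter_equivalent) { v0 <- v0 ^ (1 / 3); vend <- vend ^ (1 / 3) }
    data.frame(animal_id = a$animal_id[1], arm = a$arm[1],
               v0 = v0, vend = vend,
               rel_change = 100 * (vend - v0) / v0,
               truncated = eligible$day[nrow(eligible)] != end_day,
               stringsAsFactors = FALSE)
  }))

  arm_mean <- function(arm, col) mean(per_animal[per_animal$arm == arm, col])
  dC <- arm_mean("vehicle", "vend") - arm_mean("vehicle", "v0")
  dT <- arm_mean("drug", "vend") - arm_mean("drug", "v0")
  tgi <- if (dC <= 0) {
    warning("vehicle arm not growing on average; TGI undefined")
    NA_real_
  } else 100 * (1 - dT / dC)
  drug_change <- arm_mean("drug", "rel_change")
  category <- if (drug_change <= -30) "PR" else if (drug_change >= 20) "PD" else "SD"
  structure(list(mean_rel_change_vehicle = arm_mean("vehicle", "rel_change"),
                 mean_rel_change_drug = drug_change,
                 tgi_percent = tgi, category = category,
                 per_animal = per_animal, end_day = end_day),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf(paste0("<response_summary> day %d: vehicle %+.1f%%, drug %+.1f%%",
                     " -> TGI %s%%, %s\n"),
              x$end_day, x$mean_rel_change_vehicle, x$mean_rel_change_drug,
              ifelse(is.na(x$tgi_percent), "NA",
                     sprintf("%.1f", x$tgi_percent)), x$category))
  invisible(x)
}

#' Permutation test on final volumes between arms
#'
#' Simple two-sample permutation test on end-of-study volumes (difference
#' of arm means), a deliberately lightweight stand-in for longitudinal
#' mixed-effects treatment modelling.
#'
#' @param series list of `therapy_series`
#' @param end_day final study day (default: last observed)
#' @param n_perm number of permutations, default 10000
#' @param seed RNG seed
#' @return list with observed difference and two-sided p-value
#' @export
permutation_test_volumes <- function(series, end_day = NULL, n_perm = 10000,
                                     seed = 1) {
  df <- do.call(rbind, lapply(series, as.data.frame))
  if (is.null(end_day)) end_day <- max(df$day)
  finals <- do.call(rbind, lapply(split(df, df$animal_id), function(a) {
    a <- a[a$day <= end_day, ]
    a[which.max(a$day), c("arm", "volume_mm3")]
  }))
  obs <- mean(finals$volume_mm3[finals$arm == "drug"]) -
    mean(finals$volume_mm3[finals$arm == "vehicle"])
  rng <- local_rng(seed)
  on.exit(rng())
  n_drug <- sum(finals$arm == "drug")
  perm <- replicate(n_perm, {
    idx <- sample.int(nrow(finals), n_drug)
    mean(finals$volume_mm3[idx]) - mean(finals$volume_mm3[-idx])
  })
  list(observed_diff = obs,
       p_value = (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1))
}
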