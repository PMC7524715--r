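# Synthetic strain-specific qPCR quantification records.

#' Generate synthetic strain quantification records
#'
#' Emulates strain-specific qPCR tracking: product strains are nondetects at
#' baseline (D0) and after washout (D56) and detected during consumption
#' (D14, D28) in Test arms at levels around `level_mean` log10 copies/g, with
#' the 3-bottle arm shifted up by `dose_shift` at consumption visits.
#' Control arms are nondetects throughout.
#'
#' @param config A [synth_config()].
#' @param strains Strain labels.
#' @param level_mean,level_sd Detected level distribution (log10 copies/g);
#'   the default spread matches the interquartile ranges qPCR strain tracking
#'   typically reports (IQR of roughly 0.4-0.8 log10).
#' @param dose_shift Planted 3-bottle minus 1-bottle shift at D14/D28.
#' @param lod Limit of detection (log10 copies/g).
#' @return Data frame of records (see [validate_strain_records()]).
#' @export
gen_strain_quant <- function(config,
                             strains = c("CNCM I-1518", "CNCM I-3689", "CNCM I-3690"),
                             level_mean = 7.4, level_sd = 0.3,
                             dose_shift = 0.4, lod = 3) {
  stopifnot(inherits(config, "synth_config"))
  with_substream(config$seed, "strains", {
    n_arm <- config$n_subjects_per_arm
    subjects <- sprintf("S%03d", seq_len(n_arm * length(config$arms)))
    arm_of <- rep(config$arms, each = n_arm)
    grid <- expand.grid(
      subject_idx = seq_along(subjects), visit = config$visits,
      strain = strains, stringsAsFactors = FALSE
    )
    grid$subject <- subjects[grid$subject_idx]
    grid$arm <- arm_of[grid$subject_idx]
    detected <- arm_is_test(grid$arm) & grid$visit %in% c("D14", "D28")
    level <- stats::rnorm(nrow(grid), level_mean, level_sd) +
      ifelse(arm_dose(grid$arm) == 3, dose_shift, 0)
    level <- pmax(level, lod)
    data.frame(
      subject = grid$subject, arm = grid$arm, visit = grid$visit,
      strain = grid$strain,
      log10_copies_per_g = ifelse(detected, level, NA_real_),
      lod = lod, stringsAsFactors = FALSE
    )
  })
}
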