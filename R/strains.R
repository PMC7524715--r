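#' Strain quantification records: validation
#'
#' qPCR quantification of product strains in feces, one row per subject x
#' visit x strain, in log10 gene copies per gram. Nondetects (below the limit
#' of detection) are recorded as NA in `log10_copies_per_g` and are imputed at
#' the LOD — left-censoring at the assay floor — for both summaries and rank
#' tests.
#'
#' @param records Data frame with columns `subject`, `arm`, `visit`, `strain`,
#'   `log10_copies_per_g` (NA for nondetects), `lod`.
#' @param visits Controlled vocabulary of visit labels.
#' @return The validated data frame with a `value` column (LOD-imputed) and a
#'   logical `detected` column appended.
#' @export
validate_strain_records <- function(records,
                                    visits = c("D0", "D14", "D28", "D56")) {
  needed <- c("subject", "arm", "visit", "strain", "log10_copies_per_g", "lod")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    stop("records must contain columns ", paste(needed, collapse = ", "))
  }
  if (!all(records$visit %in% visits)) {
    stop("unknown visit label(s): ",
         paste(setdiff(unique(records$visit), visits), collapse = ", "))
  }
  if (any(!is.na(records$log10_copies_per_g) &
          records$log10_copies_per_g < records$lod)) {
    stop("detected values below the stated limit of detection")
  }
  records$detected <- !is.na(records$log10_copies_per_g)
  records$value <- ifelse(records$detected, records$log10_copies_per_g, records$lod)
  records
}

#' Median and interquartile range of strain levels
#'
#' Summarizes log10 gene copies/g for one strain at one visit in one arm, with
#' nondetects imputed at the limit of detection. Quartiles use linear
#' interpolation between order statistics (quantile type 7).
#'
#' @param records Strain quantification records (see
#'   [validate_strain_records()]).
#' @param strain,visit,arm Selection labels.
#' @return A list with `median`, `q1`, `q3`, `n`, `n_detected`.
#' @export
summarize_strain_levels <- function(records, strain, visit, arm) {
  records <- validate_strain_records(records)
  sel <- records[records$strain == strain & records$visit == visit &
                   records$arm == arm, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop(sprintf("no records for strain %s, visit %s, arm %s", strain, visit, arm))
  }
  q <- stats::quantile(sel$value, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(
    median = q[2], q1 = q[1], q3 = q[3],
    n = nrow(sel), n_detected = sum(sel$detected)
  )
}

#' Dose comparison of strain levels per strain and visit
#'
#' Two-sided Mann-Whitney test of the 1-bottle vs 3-bottle Test arms for each
#' (strain, visit) pair, with Benjamini-Hochberg adjustment across the whole
#' family of tests performed. Nondetects enter as ties at the limit of
#' detection, preserving the ordering "below every detected value".
#'
#' @param records Strain quantification records.
#' @param strains,visits Labels to test (defaults: all present).
#' @param arm_low,arm_high Arm labels for the low and high dose (defaults
#'   "Test1", "Test3").
#' @return Data frame with one row per (strain, visit): `statistic`, `p`,
#'   `p_adjusted`, group sizes.
#' @export
compare_doses <- function(records, strains = NULL, visits = NULL,
                          arm_low = "Test1", arm_high = "Test3") {
  records <- validate_strain_records(records)
  if (is.null(strains)) strains <- sort(unique(records$strain))
  if (is.null(visits)) visits <- intersect(c("D0", "D14", "D28", "D56"),
                                           unique(records$visit))
  grid <- expand.grid(strain = strains, visit = visits,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$strain[i]; v <- grid$visit[i]
    lo <- records$value[records$strain == s & records$visit == v &
                          records$arm == arm_low]
    hi <- records$value[records$strain == s & records$visit == v &
                          records$arm == arm_high]
    if (length(lo) == 0L || length(hi) == 0L) {
      stop(sprintf("missing dose arm for strain %s at visit %s", s, v))
    }
    tst <- mann_whitney_u(lo, hi)
    data.frame(
      strain = s, visit = v, statistic = tst$statistic, p = tst$p_value,
      n_low = length(lo), n_high = length(hi), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out$p_adjusted <- bh_adjust(out$p)
  out
}
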