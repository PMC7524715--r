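# Genus-level longitudinal screen: per genus, joint (two-part) tests of the
# consumption-period effect and the dose effect, FDR per test family, and
# response classification.

#' Build the ZIBR design matrix from sample metadata
#'
#' Covariates: intercept; `consumption` = 1 for Test-arm samples at
#' consumption-period visits (D14, D28); `dose` = bottles/day x the
#' consumption indicator (0, 1 or 3), so the consumption coefficient is the
#' extrapolated per-period effect and the dose coefficient the per-bottle
#' effect.
#'
#' @param metadata Data frame with columns `sample`, `subject`, `arm`, `dose`
#'   (bottles/day), `visit`.
#' @param consumption_visits Visits during product consumption.
#' @return List with `X` (design matrix), `subject`, `sample`.
#' @export
zibr_design <- function(metadata, consumption_visits = c("D14", "D28")) {
  needed <- c("sample", "subject", "arm", "dose", "visit")
  if (!all(needed %in% names(metadata))) {
    stop("metadata must contain columns ", paste(needed, collapse = ", "))
  }
  is_test <- grepl("^Test", metadata$arm)
  consuming <- is_test & metadata$visit %in% consumption_visits
  X <- cbind(
    intercept = 1,
    consumption = as.numeric(consuming),
    dose = as.numeric(consuming) * metadata$dose
  )
  tab <- table(metadata$subject)
  if (any(tab < 2L)) stop("every subject needs >= 2 observations")
  list(X = X, subject = metadata$subject, sample = metadata$sample)
}

#' Screen genera with the two-part zero-inflated beta model
#'
#' For every genus passing the prevalence floor, fits the full model
#' (intercept + consumption + dose in both parts) and the two reduced models
#' dropping one covariate at a time, forms joint likelihood-ratio p values,
#' and adjusts each test family (consumption across genera; dose across
#' genera) by Benjamini-Hochberg.
#'
#' @param counts Genus count matrix (taxa x samples).
#' @param metadata Sample metadata (see [zibr_design()]).
#' @param prevalence_floor Minimum fraction of samples in which a genus must
#'   be nonzero to be tested (default 0.1); excluded genera are reported, not
#'   silently dropped.
#' @param quad_order Quadrature order for [fit_zibr()].
#' @param alpha FDR level used for classification (default 0.05).
#' @return A list: `results` data frame (genus, p and adjusted p per
#'   covariate, response class), `excluded` character vector of low-prevalence
#'   genera.
#' @export
screen_genera <- function(counts, metadata, prevalence_floor = 0.1,
                          quad_order = 10L, alpha = 0.05) {
  validate_count_table(counts, metadata)
  metadata <- metadata[match(colnames(counts), metadata$sample), ]
  des <- zibr_design(metadata)
  rel <- rel_abund(counts)
  stopifnot(all(rel < 1 | ncol(counts) == 0))
  prevalence <- rowMeans(counts > 0)
  excluded <- rownames(counts)[prevalence < prevalence_floor]
  keep <- setdiff(rownames(counts), excluded)
  if (length(keep) == 0L) stop("no genus passes the prevalence floor")

  test_one <- function(y) {
    c(consumption = zibr_lrt(y, des$X, des$subject, "consumption",
                             quad_order = quad_order)$p,
      dose = zibr_lrt(y, des$X, des$subject, "dose",
                      quad_order = quad_order)$p)
  }
  ps <- t(vapply(keep, function(g) test_one(rel[g, ]), numeric(2)))
  results <- data.frame(
    genus = keep,
    p_consumption = ps[, "consumption"],
    p_dose = ps[, "dose"],
    stringsAsFactors = FALSE
  )
  results$p_consumption_adj <- bh_adjust(results$p_consumption)
  results$p_dose_adj <- bh_adjust(results$p_dose)
  results$class <- classify_responses(results, alpha = alpha)
  list(results = results, excluded = excluded)
}

#' Classify genus responses from adjusted p values
#'
#' A genus is consumption-responsive, dose-responsive, both, or none,
#' according to which adjusted p values fall below `alpha`.
#'
#' @param results Data frame with `p_consumption_adj` and `p_dose_adj`.
#' @param alpha Significance level on the adjusted scale.
#' @return Character vector of labels in
#'   `{"consumption", "dose", "both", "none"}`.
#' @export
classify_responses <- function(results, alpha = 0.05) {
  sc <- results$p_consumption_adj < alpha
  sd_ <- results$p_dose_adj < alpha
  ifelse(sc & sd_, "both",
         ifelse(sc, "consumption",
                ifelse(sd_, "dose", "none")))
}
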