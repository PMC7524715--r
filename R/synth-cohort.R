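# Synthetic longitudinal genus count table with known planted effects.

#' Generate a synthetic cohort count table
#'
#' One sample per subject x visit. Each genus follows the two-part model the
#' screen assumes: presence is Bernoulli on the logit scale with a subject
#' random intercept; conditional abundance is beta-distributed with a
#' logit-linear mean, per-taxon baseline, and a subject random intercept.
#' Planted effects apply only at consumption visits (D14, D28) in Test arms:
#' consumption-responsive taxa receive `consumption_effect_logit` (and
#' `presence_effect` on the presence log-odds), dose-responsive taxa receive
#' `bottles * dose_effect_logit`, both-responsive taxa receive both.
#'
#' Conversion to counts is a single multinomial draw at `library_size_16s`
#' over the modeled genera plus one background component (`genus_other`,
#' ground-truth class `"background"`) that absorbs the remaining community
#' mass. Without it, renormalization would couple every genus to the planted
#' ones and non-responsive genera would no longer be null on the
#' relative-abundance scale.
#'
#' @param config A [synth_config()].
#' @return A list: `counts` (taxa x samples), `metadata` (sample, subject,
#'   arm, dose, visit), `ground_truth` (per-taxon response class and planted
#'   logit effects, plus the subject random intercepts).
#' @export
gen_cohort_counts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_substream(config$seed, "cohort", {
    n_arm <- config$n_subjects_per_arm
    subjects <- sprintf("S%03d", seq_len(n_arm * length(config$arms)))
    arm_of <- rep(config$arms, each = n_arm)
    taxa <- sprintf("genus_%03d", seq_len(config$n_taxa))

    class <- rep("none", config$n_taxa)
    planted <- sample.int(config$n_taxa,
                          config$n_consumption_taxa + config$n_dose_taxa +
                            config$n_both_taxa)
    class[planted[seq_len(config$n_consumption_taxa)]] <- "consumption"
    class[planted[config$n_consumption_taxa + seq_len(config$n_dose_taxa)]] <- "dose"
    class[planted[config$n_consumption_taxa + config$n_dose_taxa +
                    seq_len(config$n_both_taxa)]] <- "both"

    # Per-taxon baselines: mean logits centered so the modeled genera occupy
    # ~30% of the community; headroom keeps the background component positive
    # even when planted effects boost the responsive taxa severalfold, so
    # closure never leaks effects into null genera.
    base_logit <- stats::rnorm(config$n_taxa,
                               stats::qlogis(0.3 / config$n_taxa),
                               config$taxon_logit_sd)
    pres_logit <- stats::qlogis(1 - config$zero_inflation_base)

    b_pres <- stats::rnorm(length(subjects), 0, config$random_intercept_sd_presence)
    b_ab <- stats::rnorm(length(subjects), 0, config$random_intercept_sd_abundance)

    grid <- expand.grid(subject_idx = seq_along(subjects),
                        visit = config$visits, stringsAsFactors = FALSE)
    grid$subject <- subjects[grid$subject_idx]
    grid$arm <- arm_of[grid$subject_idx]
    grid$dose <- arm_dose(grid$arm)
    grid$sample <- paste0(grid$subject, "_", grid$visit)
    consuming <- arm_is_test(grid$arm) & grid$visit %in% c("D14", "D28")

    counts <- matrix(0L, config$n_taxa + 1L, nrow(grid),
                     dimnames = list(c(taxa, "genus_other"), grid$sample))
    eff_cons <- as.numeric(class %in% c("consumption", "both"))
    eff_dose <- as.numeric(class %in% c("dose", "both"))
    for (s in seq_len(nrow(grid))) {
      shift <- if (consuming[s]) {
        eff_cons * config$consumption_effect_logit +
          eff_dose * grid$dose[s] * config$dose_effect_logit
      } else {
        numeric(config$n_taxa)
      }
      # presence response mirrors the taxon's class: consumption-responsive
      # taxa shift at any consumption visit, dose-responsive taxa shift in
      # proportion to bottles/day (scaled so 3 bottles gives the full effect)
      pres_shift <- if (consuming[s]) {
        config$presence_effect *
          pmin(1, eff_cons + eff_dose * grid$dose[s] / 3)
      } else {
        numeric(config$n_taxa)
      }
      i <- grid$subject_idx[s]
      present <- stats::rbinom(config$n_taxa, 1,
                               stats::plogis(pres_logit + pres_shift + b_pres[i]))
      mu <- stats::plogis(base_logit + shift + b_ab[i])
      y <- ifelse(present == 1,
                  stats::rbeta(config$n_taxa, mu * config$beta_precision,
                               (1 - mu) * config$beta_precision),
                  0)
      other <- max(1 - sum(y), 0.01)   # background community mass
      counts[, s] <- stats::rmultinom(1, config$library_size_16s, c(y, other))
    }
    list(
      counts = counts,
      metadata = data.frame(
        sample = grid$sample, subject = grid$subject, arm = grid$arm,
        dose = grid$dose, visit = grid$visit, stringsAsFactors = FALSE
      ),
      ground_truth = list(
        class = stats::setNames(c(class, "background"), c(taxa, "genus_other")),
        consumption_effect = config$consumption_effect_logit,
        dose_effect = config$dose_effect_logit,
        base_logit = stats::setNames(base_logit, taxa)
      )
    )
  })
}

#' Simulate one genus from the two-part model
#'
#' Draws per-observation relative abundances directly from the zero-inflated
#' beta mixed model for a balanced Test/Control design (one Test arm per
#' dose), without the count-conversion step. Used for calibration studies of
#' the fitter: type-I error, power and parameter recovery.
#'
#' @param n_subjects Total subjects, split evenly across `arms`.
#' @param arms Arm labels.
#' @param visits Visit labels.
#' @param presence_logit Baseline presence log-odds.
#' @param base_logit Baseline beta-mean logit.
#' @param consumption_effect,dose_effect,presence_effect Planted effects (see
#'   [gen_cohort_counts()]).
#' @param phi Beta precision.
#' @param sigma_presence,sigma_abundance Random-intercept SDs.
#' @return A list: `y`, `X` (intercept/consumption/dose), `subject`,
#'   `metadata`.
#' @export
sim_zibr_genus <- function(n_subjects = 48L,
                           arms = c("Test1", "Control1", "Test3", "Control3"),
                           visits = c("D0", "D14", "D28", "D56"),
                           presence_logit = 1.0,
                           base_logit = -2.5,
                           consumption_effect = 0,
                           dose_effect = 0,
                           presence_effect = 0,
                           phi = 20,
                           sigma_presence = 0.5,
                           sigma_abundance = 0.5) {
  n_arm <- ceiling(n_subjects / length(arms))
  arm_of <- rep(arms, each = n_arm)[seq_len(n_subjects)]
  subject <- rep(seq_len(n_subjects), each = length(visits))
  visit <- rep(visits, times = n_subjects)
  arm <- arm_of[subject]
  dose <- arm_dose(arm)
  consuming <- arm_is_test(arm) & visit %in% c("D14", "D28")
  X <- cbind(
    intercept = 1,
    consumption = as.numeric(consuming),
    dose = as.numeric(consuming) * dose
  )
  b_pres <- stats::rnorm(n_subjects, 0, sigma_presence)
  b_ab <- stats::rnorm(n_subjects, 0, sigma_abundance)
  eta_pres <- presence_logit + X[, "consumption"] * presence_effect + b_pres[subject]
  eta_mu <- base_logit + X[, "consumption"] * consumption_effect +
    X[, "dose"] * dose_effect + b_ab[subject]
  present <- stats::rbinom(length(subject), 1, stats::plogis(eta_pres))
  mu <- stats::plogis(eta_mu)
  y <- ifelse(present == 1, stats::rbeta(length(subject), mu * phi, (1 - mu) * phi), 0)
  y <- pmin(y, 1 - 1e-12)
  list(
    y = y, X = X, subject = subject,
    metadata = data.frame(subject = subject, arm = arm, dose = dose,
                          visit = visit, stringsAsFactors = FALSE)
  )
}
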