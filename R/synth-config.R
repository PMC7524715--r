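# Synthetic-data configuration: one object drives every generator, and a
# single master seed (with stable per-generator substreams) makes every
# output reproducible bit-for-bit.

#' Configuration for the synthetic trial generators
#'
#' Defaults emulate the trial design the pipeline targets: four parallel arms
#' (Test/Control at 1 or 3 bottles/day) of 24 subjects each, four visits (D0
#' baseline, D14/D28 during consumption, D56 follow-up), genus abundances
#' from a two-part (zero-inflated beta) model with subject random intercepts,
#' a metagenome in which product-strain genes ride at a configurable share of
#' the community, logistic-normal MSP abundances with a known sparse
#' precision graph, and binomial adverse-event counts.
#'
#' @param seed Master seed; every generator derives its own substream from it.
#' @param n_subjects_per_arm Subjects per arm (default 24, as in a 96-subject
#'   1:1:1:1 allocation).
#' @param arms,visits Arm and visit labels (dose in bottles/day is parsed from
#'   the arm label suffix).
#' @param n_taxa Number of genera in the count table.
#' @param library_size_16s,library_size_metagenome Multinomial depths used to
#'   convert abundances to counts.
#' @param zero_inflation_base Baseline probability that a genus is absent from
#'   a sample.
#' @param consumption_effect_logit,dose_effect_logit Planted effects on the
#'   beta-mean logit for responsive taxa: a Test-arm sample at a consumption
#'   visit receives `consumption_effect_logit + bottles * dose_effect_logit`
#'   according to its taxon's response class.
#' @param presence_effect Planted effect on the presence log-odds at
#'   consumption visits for responsive taxa.
#' @param n_consumption_taxa,n_dose_taxa,n_both_taxa Planted counts of
#'   consumption-only, dose-only and both-responsive taxa (defaults 3/3/6).
#' @param beta_precision Precision phi of the conditional beta distribution.
#' @param taxon_logit_sd Spread of per-taxon baseline mean logits.
#' @param random_intercept_sd_presence,random_intercept_sd_abundance Subject
#'   random-intercept SDs for the two parts.
#' @param strain_share Fraction of metagenome mass carried by product strains.
#' @param n_kos Size of the KO universe; `n_marker_kos` of them are universal
#'   single-copy markers and `n_planted_kos` are product-exclusive.
#' @param n_marker_kos Number of universal single-copy marker KOs (default 31).
#' @param n_planted_kos Product-exclusive (truly contributive) KOs.
#' @param n_resident_genomes Resident genomes in the synthetic community.
#' @param resident_ko_prob Probability a resident genome carries a given
#'   non-marker resident KO.
#' @param n_metagenome_samples Samples in the gene count matrix.
#' @param n_msps Nodes of the co-abundance network.
#' @param precision_graph Data frame (`from`, `to`, `pcor`) of nonzero partial
#'   correlations; NULL builds a chain with partial correlation -0.3 whose
#'   first two nodes are the product species.
#' @param n_network_samples Samples drawn from the logistic-normal model.
#' @param library_size_msp Depth for the MSP count matrix.
#' @param ae_risk_test,ae_risk_control Per-arm adverse-event risks.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_subjects_per_arm = 24L,
                         arms = c("Test1", "Control1", "Test3", "Control3"),
                         visits = c("D0", "D14", "D28", "D56"),
                         n_taxa = 50L,
                         library_size_16s = 1e5,
                         library_size_metagenome = 1e6,
                         zero_inflation_base = 0.3,
                         consumption_effect_logit = 1.0,
                         dose_effect_logit = 0.4,
                         presence_effect = 1.0,
                         n_consumption_taxa = 3L,
                         n_dose_taxa = 3L,
                         n_both_taxa = 6L,
                         beta_precision = 200,
                         taxon_logit_sd = 0.6,
                         random_intercept_sd_presence = 0.5,
                         random_intercept_sd_abundance = 0.5,
                         strain_share = 0.05,
                         n_kos = 500L,
                         n_marker_kos = 31L,
                         n_planted_kos = 150L,
                         n_resident_genomes = 30L,
                         resident_ko_prob = 0.3,
                         n_metagenome_samples = 20L,
                         n_msps = 30L,
                         precision_graph = NULL,
                         n_network_samples = 500L,
                         library_size_msp = 1e5,
                         ae_risk_test = 0.5,
                         ae_risk_control = 0.5) {
  cfg <- list(
    seed = check_count(seed, "seed", min = 0L),
    n_subjects_per_arm = check_count(n_subjects_per_arm, "n_subjects_per_arm"),
    arms = arms, visits = visits,
    n_taxa = check_count(n_taxa, "n_taxa"),
    library_size_16s = check_number(library_size_16s, "library_size_16s", min = 1),
    library_size_metagenome = check_number(library_size_metagenome,
                                           "library_size_metagenome", min = 1),
    zero_inflation_base = check_prob(zero_inflation_base, "zero_inflation_base"),
    consumption_effect_logit = check_number(consumption_effect_logit,
                                            "consumption_effect_logit"),
    dose_effect_logit = check_number(dose_effect_logit, "dose_effect_logit"),
    presence_effect = check_number(presence_effect, "presence_effect"),
    n_consumption_taxa = check_count(n_consumption_taxa, "n_consumption_taxa", 0L),
    n_dose_taxa = check_count(n_dose_taxa, "n_dose_taxa", 0L),
    n_both_taxa = check_count(n_both_taxa, "n_both_taxa", 0L),
    beta_precision = check_number(beta_precision, "beta_precision", min = 1e-8),
    taxon_logit_sd = check_number(taxon_logit_sd, "taxon_logit_sd", min = 0),
    random_intercept_sd_presence =
      check_number(random_intercept_sd_presence, "random_intercept_sd_presence", 0),
    random_intercept_sd_abundance =
      check_number(random_intercept_sd_abundance, "random_intercept_sd_abundance", 0),
    strain_share = check_number(strain_share, "strain_share", min = 0),
    n_kos = check_count(n_kos, "n_kos"),
    n_marker_kos = check_count(n_marker_kos, "n_marker_kos"),
    n_planted_kos = check_count(n_planted_kos, "n_planted_kos", 0L),
    n_resident_genomes = check_count(n_resident_genomes, "n_resident_genomes"),
    resident_ko_prob = check_prob(resident_ko_prob, "resident_ko_prob"),
    n_metagenome_samples = check_count(n_metagenome_samples, "n_metagenome_samples"),
    n_msps = check_count(n_msps, "n_msps", min = 3L),
    precision_graph = precision_graph,
    n_network_samples = check_count(n_network_samples, "n_network_samples"),
    library_size_msp = check_number(library_size_msp, "library_size_msp", min = 1),
    ae_risk_test = check_prob(ae_risk_test, "ae_risk_test"),
    ae_risk_control = check_prob(ae_risk_control, "ae_risk_control")
  )
  if (cfg$strain_share >= 1) stop_field("strain_share", "must be < 1")
  if (cfg$n_marker_kos > cfg$n_kos) {
    stop_field("n_marker_kos", "cannot exceed n_kos")
  }
  if (cfg$n_marker_kos + cfg$n_planted_kos > cfg$n_kos) {
    stop_field("n_planted_kos", "markers plus planted KOs exceed the KO universe")
  }
  if (cfg$n_consumption_taxa + cfg$n_dose_taxa + cfg$n_both_taxa > cfg$n_taxa) {
    stop_field("n_taxa", "fewer taxa than planted responsive taxa")
  }
  if (is.null(cfg$precision_graph)) {
    cfg$precision_graph <- data.frame(
      from = seq_len(cfg$n_msps - 1L),
      to = seq_len(cfg$n_msps - 1L) + 1L,
      pcor = -0.3
    )
  } else {
    pg <- cfg$precision_graph
    if (!all(c("from", "to", "pcor") %in% names(pg))) {
      stop_field("precision_graph", "needs columns from, to, pcor")
    }
    if (any(pg$from == pg$to)) stop_field("precision_graph", "self-loops not allowed")
    if (any(pg$from > cfg$n_msps | pg$to > cfg$n_msps | pg$from < 1 | pg$to < 1)) {
      stop_field("precision_graph", "node index out of range")
    }
  }
  structure(cfg, class = "synth_config")
}

# Run `expr` under a dedicated RNG substream and restore the caller's RNG
# state, so generators are pure functions of (config, label).
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  force(expr)
}

arm_dose <- function(arm) as.numeric(sub("^[A-Za-z]+", "", arm))
arm_is_test <- function(arm) grepl("^Test", arm)
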