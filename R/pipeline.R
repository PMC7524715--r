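# Pipeline orchestration: run every stage from one configuration, write
# plain-text outputs, and record a machine-readable run report.

#' Demo run configuration
#'
#' A desk-scale configuration exercising every stage: synthetic inputs are
#' generated, then the safety screen, strain dose comparison, diversity
#' screen, ZIBR screen, functional-contribution scoring and the co-abundance
#' network run in dependency order. Sizes are reduced relative to the
#' full-trial defaults so a complete run takes minutes on one CPU.
#'
#' @param seed Master seed.
#' @param outdir Output directory.
#' @return A `run_config` list.
#' @export
demo_run_config <- function(seed = 1L, outdir = tempfile("strainshare_run_")) {
  list(
    seed = seed,
    outdir = outdir,
    synth = synth_config(
      seed = seed,
      n_subjects_per_arm = 12L, n_taxa = 30L,
      n_kos = 300L, n_planted_kos = 90L, n_resident_genomes = 20L,
      n_metagenome_samples = 10L, library_size_metagenome = 3e5,
      n_msps = 20L, n_network_samples = 200L
    ),
    stages = c("simulate", "safety", "strains", "community", "zibr",
               "contribution", "network"),
    fdr_level = 0.05,
    pseudocount = 1,
    quad_order = 10L,
    prevalence_floor = 0.1,
    stars_threshold = 0.05,
    n_subsamples = 20L
  )
}

#' Load a run configuration from a JSON or YAML document
#'
#' The document mirrors [demo_run_config()]: top-level `seed`, `outdir`,
#' `stages` and per-stage parameters, plus a `synth` block of
#' [synth_config()] arguments.
#'
#' @param path Path to a `.json` or `.yaml`/`.yml` file.
#' @return A `run_config` list ready for [run_pipeline()].
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- demo_run_config(seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
  for (k in setdiff(names(cfg), c("synth"))) base[[k]] <- cfg[[k]]
  if (!is.null(cfg$synth)) {
    args <- cfg$synth
    args$seed <- base$seed
    base$synth <- do.call(synth_config, args)
  }
  base
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order (simulate -> safety / strains / community /
#' zibr -> contribution -> network); a stage failure stops its dependents and
#' is recorded. Outputs are TSV/JSON files under `config$outdir`; the run
#' report lists every produced file with its MD5 checksum, so identical
#' config and seed reproduce identical outputs.
#'
#' @param config A run configuration (see [demo_run_config()]).
#' @return A `run_report` list: per-stage status, output manifest with
#'   checksums, parameter echo, wall time. The report is also written to
#'   `run_report.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  if (!all(c("seed", "outdir", "synth", "stages") %in% names(config))) {
    stop("config must contain seed, outdir, synth, stages")
  }
  t0 <- Sys.time()
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  status <- stats::setNames(rep("pending", length(config$stages)), config$stages)
  outputs <- character(0)
  state <- new.env()

  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    message(sprintf("[%s] running", name))
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      status[[name]] <<- paste("failed:", conditionMessage(res))
      message(sprintf("[%s] FAILED: %s", name, conditionMessage(res)))
    } else {
      status[[name]] <<- "ok"
      outputs <<- c(outputs, res)
    }
  }
  path <- function(...) file.path(config$outdir, ...)

  run_stage("simulate", function() {
    state$cohort <- gen_cohort_counts(config$synth)
    state$strainq <- gen_strain_quant(config$synth)
    state$meta_g <- gen_metagenome(config$synth)
    state$net <- gen_network_data(config$synth)
    state$ae <- gen_ae_table(config$synth)
    state$tree <- with_substream(config$synth$seed, "tree",
                                 ape::rtree(nrow(state$cohort$counts),
                                            tip.label = rownames(state$cohort$counts)))
    ape::write.tree(state$tree, path("genus_tree.nwk"))
    c(
      write_matrix_tsv(state$cohort$counts, path("genus_counts.tsv"), "taxon_id"),
      write_df_tsv(state$cohort$metadata, path("sample_metadata.tsv")),
      write_df_tsv(state$strainq, path("strain_quant.tsv")),
      write_matrix_tsv(state$meta_g$counts, path("gene_counts.tsv"), "gene_id"),
      write_df_tsv(state$meta_g$annotation, path("gene_annotation.tsv")),
      writeLines_path(state$meta_g$markers, path("marker_kos.txt")),
      write_matrix_tsv(state$net$counts, path("msp_counts.tsv"), "msp_id"),
      path("genus_tree.nwk"),
      json_out(list(
        taxon_class = as.list(state$cohort$ground_truth$class),
        contributive_kos = state$meta_g$ground_truth$contributive_kos,
        true_edges = state$net$ground_truth$true_edges
      ), path("ground_truth.json"))
    )
  })

  run_stage("safety", function() {
    rows <- adverse_event_counts()
    tab <- data.frame(label = paste(rows$period, rows$endpoint, rows$dose, sep = "."),
                      rows[, c("events_test", "n_test", "events_control", "n_control")])
    res <- screen_safety_table(tab)
    sim <- state$ae
    sim_rr <- relative_risk_ci(sim$events_test, sim$n_test,
                               sim$events_control, sim$n_control)
    c(write_df_tsv(res, path("safety_rr.tsv")),
      json_out(sim_rr, path("safety_rr_synthetic.json")))
  })

  run_stage("strains", function() {
    if (is.null(state$strainq)) stop("missing upstream output from stage 'simulate'")
    res <- compare_doses(state$strainq)
    sums <- do.call(rbind, lapply(unique(state$strainq$strain), function(s) {
      do.call(rbind, lapply(c("D14", "D28"), function(v) {
        for_arm <- function(a) {
          q <- summarize_strain_levels(state$strainq, s, v, a)
          data.frame(strain = s, visit = v, arm = a, median = q$median,
                     q1 = q$q1, q3 = q$q3, n = q$n, n_detected = q$n_detected)
        }
        rbind(for_arm("Test1"), for_arm("Test3"))
      }))
    }))
    c(write_df_tsv(res, path("strain_dose_tests.tsv")),
      write_df_tsv(sums, path("strain_summaries.tsv")))
  })

  run_stage("community", function() {
    if (is.null(state$cohort)) stop("missing upstream output from stage 'simulate'")
    counts <- state$cohort$counts
    md <- state$cohort$metadata
    grouping <- stats::setNames(md$arm, md$sample)
    alpha <- sapply(c("observed", "shannon", "simpson"),
                    function(m) alpha_diversity(counts, m))
    alpha_tests <- lapply(colnames(alpha), function(m) {
      tst <- group_difference_test(stats::setNames(alpha[, m], colnames(counts)),
                                   grouping)
      data.frame(metric = m, statistic = tst$statistic, p = tst$p_value)
    })
    beta_tests <- lapply(c("bray_curtis", "jsd"), function(m) {
      d <- beta_diversity_matrix(counts, m)
      tst <- group_difference_test(d, grouping)
      data.frame(metric = m, statistic = tst$statistic, p = tst$p_value)
    })
    for (w in c(TRUE, FALSE)) {
      d <- unifrac_distance(counts, state$tree, weighted = w)
      tst <- group_difference_test(d, grouping)
      beta_tests <- c(beta_tests, list(data.frame(
        metric = if (w) "weighted_unifrac" else "unweighted_unifrac",
        statistic = tst$statistic, p = tst$p_value
      )))
    }
    tests <- do.call(rbind, c(alpha_tests, beta_tests))
    c(write_df_tsv(data.frame(sample = colnames(counts), alpha), path("alpha_diversity.tsv")),
      write_df_tsv(tests, path("diversity_tests.tsv")))
  })

  run_stage("zibr", function() {
    if (is.null(state$cohort)) stop("missing upstream output from stage 'simulate'")
    scr <- screen_genera(state$cohort$counts, state$cohort$metadata,
                         prevalence_floor = config$prevalence_floor,
                         quad_order = config$quad_order,
                         alpha = config$fdr_level)
    state$zibr <- scr
    c(write_df_tsv(scr$results, path("zibr_screen.tsv")),
      writeLines_path(scr$excluded, path("zibr_excluded.txt")))
  })

  run_stage("contribution", function() {
    if (is.null(state$meta_g)) stop("missing upstream output from stage 'simulate'")
    agg <- aggregate_to_ko(state$meta_g$counts, state$meta_g$annotation)
    scores <- contribution_scores(agg, pseudocount = config$pseudocount)
    base <- marker_baseline(scores, state$meta_g$markers)
    contrib <- contributive_set(scores, base)
    state$contributive <- contrib
    scores$baseline <- base$baseline
    scores$contributive <- scores$ko %in% contrib
    c(write_df_tsv(scores, path("ko_contribution.tsv")),
      writeLines_path(contrib, path("contributive_kos.txt")))
  })

  run_stage("network", function() {
    if (is.null(state$net)) stop("missing upstream output from stage 'simulate'")
    if (is.null(state$contributive)) {
      stop("missing upstream output from stage 'contribution'")
    }
    net <- build_network(state$net$counts, product_nodes = state$net$product_nodes,
                         stars_threshold = config$stars_threshold,
                         n_subsamples = config$n_subsamples,
                         seed = config$seed)
    dists <- geodesic_distances(net)
    sets <- msp_ko_sets(state$meta_g$annotation)
    resident <- setdiff(net$nodes, net$product_nodes)
    shared <- stats::setNames(rep(0L, length(resident)), resident)
    common <- intersect(resident, names(sets))
    shared[common] <- msp_shared_ko_counts(sets[common], state$contributive)
    assoc <- tryCatch(
      distance_function_association(net, shared),
      error = function(e) list(error = conditionMessage(e))
    )
    c(write_df_tsv(net$edges, path("network_edges.tsv")),
      write_df_tsv(data.frame(node = names(dists), distance = dists),
                   path("network_distances.tsv")),
      json_out(assoc, path("network_association.json")))
  })

  manifest <- data.frame(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)),
    stringsAsFactors = FALSE
  )
  report <- list(
    stages = as.list(status),
    parameters = config[setdiff(names(config), "synth")],
    outputs = manifest,
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(report, file.path(config$outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  class(report) <- "run_report"
  report
}

writeLines_path <- function(x, path) {
  writeLines(as.character(x), path)
  path
}

json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  path
}
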