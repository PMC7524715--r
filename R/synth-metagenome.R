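# Synthetic shotgun metagenome: gene counts with product-strain attribution.

#' Generate a synthetic gene count matrix with strain attribution
#'
#' Builds a community of resident genomes plus product-strain genomes. Every
#' genome carries each of the `n_marker_kos` universal marker KOs exactly once
#' (single copy); product strains additionally carry `n_planted_kos`
#' product-exclusive KOs (the true contributive set); remaining KOs are
#' carried only by residents (each with probability `resident_ko_prob`, at
#' least one carrier each). Genome masses are drawn per sample (residents:
#' Dirichlet scaled to `1 - strain_share`; strains share `strain_share`
#' evenly), each gene inherits its genome's mass, and counts are a
#' multinomial draw of `library_size_metagenome` reads over genes.
#'
#' @param config A [synth_config()].
#' @return A list: `counts` (gene x sample), `annotation` (gene_id, ko_id,
#'   source, msp_id), `markers` (marker KO ids), `ground_truth`
#'   (`contributive_kos`, `strain_share`, genome masses).
#' @export
gen_metagenome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_substream(config$seed, "metagenome", {
    kos <- sprintf("KO%05d", seq_len(config$n_kos))
    markers <- kos[seq_len(config$n_marker_kos)]
    planted <- kos[config$n_marker_kos + seq_len(config$n_planted_kos)]
    resident_kos <- setdiff(kos, c(markers, planted))

    n_res <- config$n_resident_genomes
    strains <- c("L_paracasei", "L_rhamnosus")
    residents <- sprintf("MSP%03d", seq_len(n_res))

    # genome -> KO content
    content <- list()
    for (g in residents) {
      carry <- resident_kos[stats::runif(length(resident_kos)) < config$resident_ko_prob]
      content[[g]] <- c(markers, carry)
    }
    # guarantee every resident KO has a carrier
    orphan <- setdiff(resident_kos, unique(unlist(content)))
    for (k in orphan) {
      g <- sample(residents, 1)
      content[[g]] <- c(content[[g]], k)
    }
    for (g in strains) content[[g]] <- c(markers, planted)

    genomes <- c(residents, strains)
    gene_tab <- do.call(rbind, lapply(genomes, function(g) {
      data.frame(genome = g, ko = content[[g]], stringsAsFactors = FALSE)
    }))
    gene_tab$gene_id <- sprintf("gene_%05d", seq_len(nrow(gene_tab)))
    gene_tab$source <- ifelse(gene_tab$genome %in% strains,
                              "product_strain", "resident")

    n_samp <- config$n_metagenome_samples
    counts <- matrix(0L, nrow(gene_tab), n_samp,
                     dimnames = list(gene_tab$gene_id,
                                     sprintf("sample_%02d", seq_len(n_samp))))
    mass_log <- matrix(0, length(genomes), n_samp,
                       dimnames = list(genomes, colnames(counts)))
    for (s in seq_len(n_samp)) {
      w <- stats::rgamma(n_res, shape = 1)
      res_mass <- (1 - config$strain_share) * w / sum(w)
      strain_mass <- rep(config$strain_share / length(strains), length(strains))
      mass <- stats::setNames(c(res_mass, strain_mass), genomes)
      mass_log[, s] <- mass
      p <- mass[gene_tab$genome]
      counts[, s] <- stats::rmultinom(1, config$library_size_metagenome, p / sum(p))
    }

    annotation <- data.frame(
      gene_id = gene_tab$gene_id,
      ko_id = gene_tab$ko,
      source = gene_tab$source,
      msp_id = ifelse(gene_tab$source == "resident", gene_tab$genome, NA_character_),
      stringsAsFactors = FALSE
    )
    list(
      counts = counts,
      annotation = annotation,
      markers = markers,
      ground_truth = list(
        contributive_kos = planted,
        strain_share = config$strain_share,
        genome_mass = mass_log
      )
    )
  })
}
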