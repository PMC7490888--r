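#' Default pipeline configuration
#'
#' Every analysis threshold is a named key defaulting to the value the
#' pipeline's filters are defined with (length > 200 nt, >= 2 exons,
#' neighbour window < 10 kb, trans |r| > 0.95, DE p < 0.05 with
#' |log2FC| >= 1, pseudocount 1, site score >= 80 with energy <= -7,
#' enrichment adjusted p < 0.05).
#'
#' @param seed Integer seed for the whole run.
#' @param out_dir Output directory.
#' @return Nested list of configuration values.
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = tempfile("cerna_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulation = list(
      n_coding_genes = 60L, n_lncrnas = 30L, n_mirnas = 10L,
      n_true_triads = 5L, n_de_features_per_contrast = 10L,
      de_log2fc_effect = 2, replicates_per_group = 4L,
      nb_dispersion = 0.05, library_size_mean = 5e5,
      antisense_fraction = 0.26),
    thresholds = list(
      lncrna_min_length = 200L, lncrna_min_exons = 2L,
      orf_min = 300L, cov_min = 0.35,
      max_neighbor_dist = 10000L, trans_r_min = 0.95,
      de_alpha = 0.05, de_lfc_min = 1.0, pseudocount = 1.0,
      score_min = 80, energy_max = -7.0, enrich_alpha = 0.05),
    n_random_pairs = 200L,
    n_enrichment_terms = 20L
  )
}

load_pipeline_config <- function(config) {
  if (is.character(config)) {
    check_files_exist(config)
    config <- yaml::read_yaml(config)
  }
  missing <- setdiff(c("seed", "out_dir"), names(config))
  if (length(missing) > 0) {
    stop("missing config keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  defaults <- default_pipeline_config(config$seed, config$out_dir)
  for (sec in c("simulation", "thresholds")) {
    user <- config[[sec]]
    merged <- defaults[[sec]]
    merged[names(user)] <- user
    config[[sec]] <- merged
  }
  for (k in setdiff(names(defaults), names(config))) {
    config[[k]] <- defaults[[k]]
  }
  config
}

#' Run the full ceRNA inference pipeline
#'
#' Orchestrates simulate, identify-lncrna, de, cis-pairs, predict-targets,
#' network and enrich from one configuration (a YAML path or a nested
#' list; see [default_pipeline_config()]), writing each stage's tables
#' under `out_dir` and a JSON run manifest with per-stage record counts.
#' Deterministic under a fixed seed.
#'
#' @param config YAML file path or configuration list with at least `seed`
#'   and `out_dir`.
#' @return The run manifest (list of class `cerna_manifest`): `config_hash`,
#'   `seed`, `stages` (name, outputs, record counts) and `evaluation`
#'   (triad recall/precision against the planted truth).
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  th <- cfg$thresholds
  stages <- list()
  note_stage <- function(name, outputs, n_records) {
    stages[[length(stages) + 1L]] <<- list(
      name = name, outputs = unname(unlist(outputs)), n_records = n_records)
  }

  ## 1. simulate ------------------------------------------------------------
  sim_args <- cfg$simulation
  sim_args$seed <- cfg$seed
  scfg <- do.call(sim_config, sim_args)
  ds <- simulate_cerna_dataset(scfg)
  data_paths <- write_dataset(ds, file.path(out, "data"))
  note_stage("simulate", data_paths,
             c(transcripts = nrow(ds$catalog), mirnas = nrow(ds$mirnas),
               triads = nrow(ds$truth$true_triads)))

  ## 2. identify-lncrna ------------------------------------------------------
  reports <- coding_potential_reports(ds$catalog, orf_min = th$orf_min,
                                      cov_min = th$cov_min)
  lnc_ids <- filter_lncrnas(ds$catalog, reports,
                            min_length = th$lncrna_min_length,
                            min_exons = th$lncrna_min_exons)
  classes <- classify_lncrnas(ds$catalog, lnc_ids)
  summ <- feature_summary(lnc_ids, ds$catalog, reports)
  lnc_dir <- file.path(out, "lncrna")
  dir.create(lnc_dir, showWarnings = FALSE)
  write_tsv(reports, file.path(lnc_dir, "coding_potential.tsv"))
  write_tsv(data.frame(transcript_id = lnc_ids), file.path(lnc_dir,
                                                           "lncrna_ids.tsv"))
  write_tsv(classes, file.path(lnc_dir, "lncrna_classes.tsv"))
  write_tsv(summ$summary, file.path(lnc_dir, "summary.tsv"))
  note_stage("identify-lncrna", file.path(lnc_dir, c(
    "coding_potential.tsv", "lncrna_ids.tsv", "lncrna_classes.tsv",
    "summary.tsv")), c(lncrnas = length(lnc_ids)))

  ## 3. differential expression ----------------------------------------------
  fpkm <- compute_fpkm(ds$counts, ds$lengths)
  contrasts <- sim_contrasts(scfg$groups)
  de_dir <- file.path(out, "de")
  dir.create(de_dir, showWarnings = FALSE)
  utils::write.table(data.frame(feature_id = rownames(fpkm), fpkm,
                                check.names = FALSE),
                     file.path(de_dir, "fpkm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  de_tables <- lapply(contrasts, function(ctr) {
    de <- differential_expression(fpkm, ds$design, ctr,
                                  alpha = th$de_alpha,
                                  lfc_min = th$de_lfc_min,
                                  pseudocount = th$pseudocount)
    write_tsv(de, file.path(de_dir, paste0("de_", ctr, ".tsv")))
    de
  })
  names(de_tables) <- contrasts
  note_stage("de", file.path(de_dir, c("fpkm.tsv",
                                       paste0("de_", contrasts, ".tsv"))),
             c(significant = sum(vapply(de_tables, function(d)
               sum(d$significant), numeric(1)))))

  ## 4. cis pairs -------------------------------------------------------------
  pairs <- find_neighbors(ds$catalog, lnc_ids,
                          max_dist = th$max_neighbor_dist)
  gene_fpkm <- rowsum(fpkm[ds$catalog$transcript_id, , drop = FALSE],
                      ds$catalog$gene_id)
  pairs_r <- pair_correlations(pairs, gene_fpkm)
  coding_genes <- unique(ds$catalog$gene_id[
    ds$catalog$biotype == "protein_coding"])
  n_rand <- min(cfg$n_random_pairs, choose(length(coding_genes), 2))
  rand_null <- random_pair_null(gene_fpkm, coding_genes, n_rand,
                                seed = cfg$seed + 11L)
  cis_dir <- file.path(out, "cis")
  dir.create(cis_dir, showWarnings = FALSE)
  write_tsv(pairs_r, file.path(cis_dir, "neighbor_pairs.tsv"))
  write_tsv(rand_null, file.path(cis_dir, "random_pairs.tsv"))
  cis_cmp <- if (nrow(pairs_r) >= 2L && nrow(rand_null) >= 2L) {
    compare_correlation_distributions(pairs_r$pearson_r,
                                      rand_null$pearson_r)
  } else {
    list(mean_a = NA_real_, mean_b = NA_real_, statistic = NA_real_,
         p_value = NA_real_)
  }
  write_tsv(as.data.frame(cis_cmp), file.path(cis_dir, "comparison.tsv"))
  note_stage("cis-pairs", file.path(cis_dir, c(
    "neighbor_pairs.tsv", "random_pairs.tsv", "comparison.tsv")),
    c(neighbor_pairs = nrow(pairs_r), random_pairs = nrow(rand_null)))

  ## 5. predict targets --------------------------------------------------------
  sites <- predict_targets(ds$mirnas, ds$catalog, lncrna_ids = lnc_ids,
                           score_min = th$score_min,
                           energy_max = th$energy_max)
  tgt_dir <- file.path(out, "targets")
  dir.create(tgt_dir, showWarnings = FALSE)
  write_tsv(sites, file.path(tgt_dir, "sites.tsv"))
  note_stage("predict-targets", file.path(tgt_dir, "sites.tsv"),
             c(sites = nrow(sites)))

  ## 6. networks per contrast ---------------------------------------------------
  mirna_ids <- ds$mirnas$mirna_id
  mrna_ids <- ds$catalog$transcript_id[ds$catalog$biotype == "protein_coding"]
  all_triads <- list()
  for (ctr in contrasts) {
    de <- de_tables[[ctr]]
    de_mir <- de[de$feature_id %in% mirna_ids, ]
    de_mrna <- de[de$feature_id %in% mrna_ids, ]
    de_lnc <- de[de$feature_id %in% lnc_ids, ]
    e_mm <- negative_mirna_mrna_edges(de_mir, de_mrna, sites, ctr)
    e_lm <- negative_lncrna_mirna_edges(de_lnc, de_mir, sites, ctr)
    triads <- assemble_triads(e_mm, e_lm)
    all_triads[[ctr]] <- triads
    net_dir <- file.path(out, paste0("network_", ctr))
    suppressWarnings(export_network(rbind(e_mm, e_lm), triads, net_dir))
    note_stage(paste0("network_", ctr),
               file.path(net_dir, c("network.sif", "node_attributes.tsv",
                                    "triads.tsv")),
               c(edges = nrow(e_mm) + nrow(e_lm), triads = nrow(triads)))
  }
  triads_all <- do.call(rbind, all_triads)
  rownames(triads_all) <- NULL
  write_tsv(triads_all, file.path(out, "triads.tsv"))
  evaluation <- evaluate_triads(triads_all, ds$truth$true_triads)

  ## 7. enrichment ---------------------------------------------------------------
  query <- unique(unlist(lapply(de_tables, function(d)
    d$feature_id[d$significant & d$feature_id %in% mrna_ids])))
  term_map <- generate_term_map(mrna_ids, n_terms = cfg$n_enrichment_terms,
                                planted_genes = query,
                                seed = cfg$seed + 13L)
  write_gmt(term_map, file.path(out, "terms.gmt"))
  enr <- if (length(query) > 0L) {
    enrich(query, mrna_ids, term_map, alpha = th$enrich_alpha)
  } else {
    NULL
  }
  enr_path <- file.path(out, "enrichment.tsv")
  if (!is.null(enr)) write_tsv(enr, enr_path) else
    writeLines("term_id\tk\tK\tn\tN\tp_value\tp_adjusted\tsignificant",
               enr_path)
  note_stage("enrich", c(file.path(out, "terms.gmt"), enr_path),
             c(terms_tested = if (is.null(enr)) 0L else nrow(enr),
               significant = if (is.null(enr)) 0L else sum(enr$significant)))

  ## manifest --------------------------------------------------------------------
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, cfg_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = cfg$seed,
    stages = stages,
    evaluation = evaluation
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(manifest) <- "cerna_manifest"
  manifest
}

#' @export
print.cerna_manifest <- function(x, ...) {
  cat("ceRNA pipeline run (seed", x$seed, "):\n")
  for (s in x$stages) {
    cat(sprintf("  %-22s %s\n", s$name,
                paste(names(s$n_records), s$n_records,
                      sep = "=", collapse = ", ")))
  }
  cat(sprintf("  triad recall %.2f, precision %.2f\n",
              x$evaluation$recall, x$evaluation$precision))
  invisible(x)
}
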