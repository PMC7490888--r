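test_that("config invariants are enforced", {
  expect_error(sim_config(n_true_triads = 50L, n_mirnas = 3L), "pool")
  expect_error(sim_config(de_log2fc_effect = 0.5), "log2FC")
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(n_coding_genes = -1L), "count")
  # zero effect allowed when nothing is planted
  expect_s3_class(sim_config(n_true_triads = 0L, de_log2fc_effect = 0),
                  "sim_config")
})

test_that("zero-count configs yield empty, not failing, outputs", {
  cfg <- sim_config(n_coding_genes = 0L, n_lncrnas = 0L, n_mirnas = 0L,
                    n_true_triads = 0L, de_log2fc_effect = 1)
  expect_equal(nrow(generate_annotation(cfg)), 0L)
  expect_equal(nrow(generate_mirnas(cfg)), 0L)
})

test_that("same config and seed give byte-identical GTF and FASTA", {
  cfg <- sim_config(n_coding_genes = 12L, n_lncrnas = 8L, n_mirnas = 4L,
                    n_true_triads = 2L, seed = 5L)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(simulate_cerna_dataset(cfg), d1)
  write_dataset(simulate_cerna_dataset(cfg), d2)
  for (f in c("annotation.gtf", "transcripts.fa", "mirnas.fa", "counts.tsv",
              "design.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("emitted lncRNAs pass the filter cascade and coding fail it", {
  cfg <- sim_config(n_coding_genes = 50L, n_lncrnas = 20L, n_mirnas = 5L,
                    n_true_triads = 3L, seed = 9L)
  ds <- simulate_cerna_dataset(cfg)
  reports <- coding_potential_reports(ds$catalog)
  recovered <- filter_lncrnas(ds$catalog, reports)
  truth <- ds$catalog$transcript_id[ds$catalog$biotype != "protein_coding"]
  expect_setequal(recovered, truth)
  # structural guarantees behind the exact recovery
  lnc_idx <- match(truth, ds$catalog$transcript_id)
  expect_true(all(ds$catalog$length[lnc_idx] > 200))
  expect_true(all(vapply(ds$catalog$exons[lnc_idx], nrow, integer(1)) >= 2))
  cod_idx <- which(ds$catalog$biotype == "protein_coding")
  cod_rep <- reports[match(ds$catalog$transcript_id[cod_idx],
                           reports$transcript_id), ]
  expect_true(all(cod_rep$longest_orf_nt >= 300))
  expect_true(all(cod_rep$orf_coverage >= 0.35))
})

test_that("hexamer scorer separates coding from noncoding on average", {
  ds <- tiny_dataset()
  reports <- coding_potential_reports(ds$catalog)
  cod <- reports$hexamer_score[
    reports$transcript_id %in%
      ds$catalog$transcript_id[ds$catalog$biotype == "protein_coding"]]
  lnc <- reports$hexamer_score[
    reports$transcript_id %in%
      ds$catalog$transcript_id[ds$catalog$biotype != "protein_coding"]]
  expect_lt(stats::wilcox.test(cod, lnc, alternative = "greater")$p.value,
            1e-6)
})

test_that("miRNA sequences respect length, alphabet and seed uniqueness", {
  cfg <- sim_config(n_mirnas = 10L, seed = 3L)
  mir <- generate_mirnas(cfg)
  lens <- nchar(mir$mature_seq)
  expect_true(all(lens >= 20 & lens <= 24))
  expect_false(any(grepl("[^ACGU]", mir$mature_seq)))
  expect_equal(anyDuplicated(mir$seed), 0L)
  expect_true(all(substr(mir$mature_seq, 1L, 1L) == "U"))
})

test_that("seed complements never occur in non-target transcripts", {
  ds <- tiny_dataset()
  targets <- split(ds$truth$planted_sites$transcript_id,
                   ds$truth$planted_sites$mirna_id)
  for (mi in seq_len(nrow(ds$mirnas))) {
    seed_rc <- rc_str(ds$mirnas$seed[mi])
    allowed <- targets[[ds$mirnas$mirna_id[mi]]]
    for (ti in seq_len(nrow(ds$catalog))) {
      tid <- ds$catalog$transcript_id[ti]
      if (tid %in% allowed) next
      expect_false(grepl(seed_rc, ds$catalog$sequence[ti], fixed = TRUE),
                   info = paste(ds$mirnas$mirna_id[mi], tid))
    }
  }
})

test_that("planting writes exactly two perfect sites per triad", {
  cfg <- sim_config(n_coding_genes = 15L, n_lncrnas = 8L, n_mirnas = 4L,
                    n_true_triads = 1L, seed = 21L)
  mir <- generate_mirnas(cfg)
  catalog <- generate_annotation(cfg, avoid_kmers = vapply(
    mir$seed, rc_str, character(1), USE.NAMES = FALSE))
  planted <- plant_triads_and_sites(catalog, mir, cfg)
  tt <- planted$truth$true_triads
  expect_equal(nrow(tt), 1L)
  expect_equal(nrow(planted$truth$planted_sites), 2L)
  site_seq <- rc_str(mir$mature_seq[mir$mirna_id == tt$mirna_id])
  for (tid in c(tt$lncrna_id, tt$mrna_id)) {
    seq <- planted$catalog$sequence[
      planted$catalog$transcript_id == tid]
    expect_equal(lengths(regmatches(seq, gregexpr(site_seq, seq,
                                                  fixed = TRUE))), 1L,
                 info = tid)
  }
  # mRNA site sits in the 3' UTR
  i <- match(tt$mrna_id, planted$catalog$transcript_id)
  s <- planted$truth$planted_sites$start[
    planted$truth$planted_sites$transcript_id == tt$mrna_id]
  expect_gte(s, planted$catalog$cds_end[i])
})

test_that("zero triads leave sequences unmodified and truth empty", {
  cfg <- sim_config(n_coding_genes = 10L, n_lncrnas = 5L, n_mirnas = 0L,
                    n_true_triads = 0L, seed = 2L)
  catalog <- generate_annotation(cfg)
  mir <- generate_mirnas(cfg)
  planted <- plant_triads_and_sites(catalog, mir, cfg)
  expect_identical(planted$catalog$sequence, catalog$sequence)
  expect_equal(nrow(planted$truth$true_triads), 0L)
  expect_equal(nrow(planted$truth$planted_sites), 0L)
})

test_that("infeasible triad requests error explicitly", {
  cfg <- sim_config(n_coding_genes = 3L, n_lncrnas = 3L, n_mirnas = 3L,
                    n_true_triads = 3L, seed = 2L)
  catalog <- generate_annotation(cfg)
  mir <- generate_mirnas(cfg)[1:2, ]  # fewer miRNAs than triads
  expect_error(plant_triads_and_sites(catalog, mir, cfg), "infeasible")
})

test_that("ground-truth sign invariant holds for every triad", {
  ds <- tiny_dataset()
  tt <- ds$truth$true_triads
  de <- ds$truth$de_features
  eff <- function(fid, ctr) de$log2fc[de$feature_id == fid &
                                        de$contrast == ctr]
  for (i in seq_len(nrow(tt))) {
    e_lnc <- eff(tt$lncrna_id[i], tt$contrast[i])
    e_mrna <- eff(tt$mrna_id[i], tt$contrast[i])
    e_mir <- eff(tt$mirna_id[i], tt$contrast[i])
    expect_equal(sign(e_lnc), sign(e_mrna))
    expect_equal(sign(e_mir), -sign(e_lnc))
    expect_gte(abs(e_mir), 1)
  }
  # and both partners carry a planted site for the shared miRNA
  ps_key <- paste(ds$truth$planted_sites$mirna_id,
                  ds$truth$planted_sites$transcript_id)
  expect_true(all(paste(tt$mirna_id, tt$lncrna_id) %in% ps_key))
  expect_true(all(paste(tt$mirna_id, tt$mrna_id) %in% ps_key))
})

test_that("planted effects shift group means by 2^effect", {
  # Monte-Carlo oracle: many replicates per group, compare group-mean ratio
  cfg <- sim_config(n_coding_genes = 4L, n_lncrnas = 0L, n_mirnas = 0L,
                    n_true_triads = 0L, n_de_features_per_contrast = 0L,
                    de_log2fc_effect = 2, replicates_per_group = 2500L,
                    nb_dispersion = 0.05, seed = 8L)
  catalog <- generate_annotation(cfg)
  truth <- list(de_features = data.frame(
    contrast = "LH_vs_LL", feature_id = catalog$transcript_id[1L],
    log2fc = 2, stringsAsFactors = FALSE))
  mir <- generate_mirnas(cfg)
  cm <- simulate_counts(catalog, mir, truth, cfg)
  hi <- cm$design$sample[cm$design$group == "LH"]
  lo <- cm$design$sample[cm$design$group == "LL"]
  ratio <- mean(cm$counts[1L, hi]) / mean(cm$counts[1L, lo])
  expect_lt(abs(ratio / 4 - 1), 0.02)
  # untouched feature: ratio ~= 1
  ratio0 <- mean(cm$counts[2L, hi]) / mean(cm$counts[2L, lo])
  expect_lt(abs(ratio0 - 1), 0.05)
})

test_that("design table has the required group sizes", {
  ds <- tiny_dataset()
  expect_equal(unname(table(ds$design$group)[c("LH", "LL", "FH", "FL")]),
               rep(4L, 4L), ignore_attr = TRUE)
  bad_cfg <- ds$config
  bad_cfg$nb_dispersion <- -1
  expect_error(simulate_counts(ds$catalog, ds$mirnas, ds$truth, bad_cfg),
               "dispersion")
})

test_that("dataset files are written in the documented formats", {
  ds <- tiny_dataset()
  dir <- tempfile()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  counts <- utils::read.delim(paths[["counts"]], check.names = FALSE)
  expect_equal(counts$feature_id,
               c(ds$catalog$transcript_id, ds$mirnas$mirna_id))
  expect_equal(ncol(counts), 1L + nrow(ds$design))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_setequal(truth$true_triads$mirna_id, ds$truth$true_triads$mirna_id)
})
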