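mk_mirna <- function(seq, id = "miR-x") {
  data.frame(mirna_id = id, mature_seq = seq,
             seed = substr(seq, 2L, 8L), stringsAsFactors = FALSE)
}

test_that("a seed complement in the target is found at the right offset", {
  # seed GGAAUGU (positions 2-8) -> target site ACATTCC
  mir <- mk_mirna("UGGAAUGUAAAGAAGUAUGUAU")
  expect_equal(mir$seed, "GGAAUGU")
  target <- paste0(strrep("C", 30), "ACATTCC", strrep("C", 20))
  sites <- find_seed_sites(mir, target, "t1")
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start, 30L)
  expect_equal(sites$seed_class, "7mer-m8")  # no A opposite position 1
  # with an A after the match it becomes an 8mer
  target8 <- paste0(strrep("C", 30), "ACATTCCA", strrep("C", 20))
  expect_equal(find_seed_sites(mir, target8, "t1")$seed_class, "8mer")
  # no complement anywhere: empty
  expect_equal(nrow(find_seed_sites(mir, strrep("C", 60), "t1")), 0L)
})

test_that("site discovery equals the sliding-window oracle on random pairs", {
  set.seed(77)
  rna <- c("A", "C", "G", "U")
  for (i in 1:50) {
    mir <- mk_mirna(paste(c("U", sample(rna, 21, TRUE)), collapse = ""))
    target <- random_dna_str(300)
    got <- find_seed_sites(mir, target, "t")
    want <- oracle_seed_sites(mir$mature_seq, target)
    expect_equal(got$start, want$start, info = paste("case", i))
    expect_equal(got$seed_class, want$seed_class, info = paste("case", i))
  }
})

test_that("scoring matches hand evaluation on a perfect 22-nt duplex", {
  # 11 GC pairs + 11 AU pairs
  mature <- paste0("U", strrep("G", 5), strrep("C", 6), strrep("A", 6),
                   strrep("U", 4))
  expect_equal(nchar(mature), 22L)
  mir <- mk_mirna(mature)
  site_seq <- rc_str(mature)
  target <- paste0(strrep("C", 40), site_seq, strrep("C", 40))
  sites <- find_seed_sites(mir, target, "t")
  perfect <- sites[sites$start == 40L + 22L - 8L, ]  # seed match position
  expect_equal(nrow(perfect), 1L)
  sc <- score_site(mir, target, perfect)
  expect_equal(sc$align_score, 110)     # 22 Watson-Crick pairs x 5
  expect_equal(sc$energy, -33.0)        # -(2*11 + 1*11)
})

test_that("a seed-only site scores below the perfect duplex", {
  mature <- paste0("U", strrep("G", 5), strrep("C", 6), strrep("A", 6),
                   strrep("U", 4))
  mir <- mk_mirna(mature)
  seed_site <- rc_str(substr(mature, 2L, 8L))
  # mismatching flank (G cannot pair G; avoid accidental complement)
  target <- paste0(strrep("G", 40), seed_site, "A", strrep("G", 20))
  sites <- find_seed_sites(mir, target, "t")
  sc <- score_site(mir, target, sites[1L, ])
  expect_lt(sc$align_score, 110)
  expect_gt(sc$energy, -33)
})

test_that("scores equal an independent per-position tally on random sites", {
  set.seed(31)
  rna <- c("A", "C", "G", "U")
  wc <- c(A = "T", C = "G", G = "C", U = "A")
  n_checked <- 0L
  for (i in 1:80) {
    mature <- paste(c("U", sample(rna, 21, TRUE)), collapse = "")
    mir <- mk_mirna(mature)
    target <- random_dna_str(2000)
    sites <- find_seed_sites(mir, target, "t")
    if (nrow(sites) == 0L) next
    for (si in seq_len(nrow(sites))) {
      got <- score_site(mir, target, sites[si, ])
      # independent tally, positions paired antiparallel from the seed match
      score <- 0; e <- 0
      for (p in 1:22) {
        tpos <- sites$start[si] + 9L - p
        if (tpos < 1 || tpos > nchar(target)) next
        mb <- substr(mature, p, p)
        tb <- substr(target, tpos, tpos)
        if (tb == wc[[mb]]) {
          score <- score + 5
          e <- e + if (mb %in% c("C", "G")) 2 else 1
        } else if ((mb == "G" && tb == "T") || (mb == "U" && tb == "G")) {
          e <- e + 0.5
          score <- score + if (p >= 2 && p <= 8) -3 else 2
        } else {
          score <- score - 3
        }
      }
      expect_equal(got$align_score, max(score, 0))
      expect_equal(got$energy, -e)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 10L)
})

test_that("planted perfect-duplex sites are all recovered at defaults", {
  ds <- tiny_dataset()
  lnc <- ds$catalog$transcript_id[ds$catalog$biotype != "protein_coding"]
  sites <- predict_targets(ds$mirnas, ds$catalog, lncrna_ids = lnc)
  planted_key <- paste(ds$truth$planted_sites$mirna_id,
                       ds$truth$planted_sites$transcript_id)
  got_key <- paste(sites$mirna_id, sites$transcript_id)
  expect_true(all(planted_key %in% got_key))
  # every emitted site satisfies both thresholds
  expect_true(all(sites$align_score >= 80))
  expect_true(all(sites$energy <= -7))
})

test_that("extreme thresholds empty the prediction set", {
  ds <- tiny_dataset()
  sites <- predict_targets(ds$mirnas, ds$catalog, score_min = Inf,
                           energy_max = -Inf)
  expect_equal(nrow(sites), 0L)
})

test_that("predictions are invariant to input ordering", {
  ds <- tiny_dataset()
  lnc <- ds$catalog$transcript_id[ds$catalog$biotype != "protein_coding"]
  a <- predict_targets(ds$mirnas, ds$catalog, lncrna_ids = lnc)
  set.seed(1)
  mir_shuf <- ds$mirnas[sample(nrow(ds$mirnas)), ]
  cat_shuf <- ds$catalog[sample(nrow(ds$catalog)), ]
  class(cat_shuf) <- class(ds$catalog)
  b <- predict_targets(mir_shuf, cat_shuf, lncrna_ids = lnc)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("trans targets use a strict absolute-correlation threshold", {
  set.seed(6)
  x <- rnorm(16)
  z <- rnorm(16)
  z <- residuals(lm(z ~ x))                    # orthogonal to x
  y <- 0.95 * scale(x)[, 1] + sqrt(1 - 0.95^2) * scale(z)[, 1]
  lx <- matrix(x, nrow = 1, dimnames = list("lnc1", paste0("s", 1:16)))
  gx <- rbind(gene1 = y, gene2 = -2 * x + 1e-8 * z)
  colnames(gx) <- paste0("s", 1:16)
  r_obs <- cor(x, y)
  # r exactly at the threshold is excluded; just below it is included
  at <- trans_targets(lx, gx, r_min = r_obs)
  expect_false("gene1" %in% at$gene_id)
  below <- trans_targets(lx, gx, r_min = r_obs - 1e-9)
  expect_true("gene1" %in% below$gene_id)
  # perfectly (negatively) proportional gene always emitted at default
  def <- trans_targets(lx, gx)
  expect_true("gene2" %in% def$gene_id)
  expect_lt(def$pearson_r[def$gene_id == "gene2"], -0.99)
})

test_that("trans-target null rate matches the correlation tail mass", {
  set.seed(12)
  n_samp <- 16L
  lx <- matrix(rnorm(30 * n_samp), nrow = 30,
               dimnames = list(paste0("l", 1:30), paste0("s", 1:n_samp)))
  gx <- matrix(rnorm(30 * n_samp), nrow = 30,
               dimnames = list(paste0("g", 1:30), paste0("s", 1:n_samp)))
  r_min <- 0.6
  got <- trans_targets(lx, gx, r_min = r_min)
  frac <- nrow(got) / (30 * 30)
  t_crit <- r_min * sqrt(n_samp - 2) / sqrt(1 - r_min^2)
  expected <- 2 * stats::pt(-t_crit, df = n_samp - 2)
  expect_lt(abs(frac - expected), 0.02)
  # zero-variance features are skipped with a count
  lx0 <- rbind(lx, flat = rep(1, n_samp))
  got0 <- trans_targets(lx0, gx, r_min = 0.6)
  expect_equal(attr(got0, "n_skipped"), 1L)
})
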