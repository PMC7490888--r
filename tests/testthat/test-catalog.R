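test_that("longest_orf handles minimal and degenerate sequences", {
  expect_equal(longest_orf("ATGTAA")$length_nt, 6L)
  expect_equal(longest_orf("CCCCCC")$length_nt, 0L)
  expect_equal(longest_orf("")$length_nt, 0L)
  expect_equal(longest_orf("AUGUAA")$length_nt, 6L)  # RNA accepted
  expect_error(longest_orf("ATGNNN"), "non-ACGTU")
})

test_that("longest_orf equals the exhaustive enumeration oracle", {
  set.seed(101)
  for (i in 1:40) {
    s <- random_dna_str(300)
    expect_equal(longest_orf(s)$length_nt, oracle_longest_orf(s), info = s)
  }
})

test_that("GTF coordinates convert 1-based inclusive to 0-based half-open", {
  gtf <- tempfile(fileext = ".gtf")
  fa <- tempfile(fileext = ".fa")
  writeLines(paste("chr1", "src", "exon", 1L, 100L, ".", "+", ".",
                   'gene_id "g1"; transcript_id "t1"; gene_biotype "unknown";',
                   sep = "\t"), gtf)
  writeLines(c(">t1", strrep("A", 100L)), fa)
  cat <- load_catalog(gtf, fa)
  expect_equal(cat$exons[[1]], cbind(start = 0L, end = 100L))
  expect_equal(cat$length, 100L)
})

test_that("empty GTF yields an empty catalog; missing sequence is named", {
  gtf <- tempfile(fileext = ".gtf")
  fa <- tempfile(fileext = ".fa")
  writeLines(character(0), gtf)
  writeLines(c(">tX", "ACGT"), fa)
  expect_equal(nrow(load_catalog(gtf, fa)), 0L)
  writeLines(paste("chr1", "src", "exon", 1L, 4L, ".", "+", ".",
                   'gene_id "g1"; transcript_id "t9";', sep = "\t"), gtf)
  expect_error(load_catalog(gtf, fa), "t9")
})

test_that("write/load round trip preserves all records", {
  ds <- tiny_dataset()
  catalog <- ds$catalog[1:12, ]
  class(catalog) <- class(ds$catalog)
  gtf <- tempfile(fileext = ".gtf")
  fa <- tempfile(fileext = ".fa")
  write_catalog(catalog, gtf, fa)
  back <- load_catalog(gtf, fa)
  back <- back[match(catalog$transcript_id, back$transcript_id), ]
  expect_equal(back$transcript_id, catalog$transcript_id)
  expect_equal(back$gene_id, catalog$gene_id)
  expect_equal(back$strand, catalog$strand)
  expect_equal(back$biotype, catalog$biotype)
  expect_equal(back$sequence, catalog$sequence)
  expect_equal(unname(back$cds_start), unname(catalog$cds_start))
  expect_equal(unname(back$cds_end), unname(catalog$cds_end))
  for (i in seq_len(nrow(catalog))) {
    expect_equal(unname(back$exons[[i]]), unname(catalog$exons[[i]]))
  }
})

test_that("filter cascade enforces each criterion and is order-independent", {
  mk_rep <- function(id, orf = "noncoding", hex = "noncoding") {
    data.frame(transcript_id = id, longest_orf_nt = 0L, orf_coverage = 0,
               hexamer_score = 0, orf_verdict = orf, hexamer_verdict = hex,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    flat_row("len200", 200L),                              # strict > 200
    list(id = "oneexon", gene = "g2", strand = "+", biotype = "unknown",
         exons = cbind(start = 10000L, end = 15000L),
         seq = strrep("C", 5000L)),                        # 1 exon
    list(id = "bioty", gene = "g3", strand = "+", biotype = "protein_coding",
         exons = cbind(start = c(30000L, 31000L), end = c(30500L, 31500L)),
         seq = strrep("C", 1000L)),                        # excluded biotype
    list(id = "codverd", gene = "g4", strand = "+", biotype = "unknown",
         exons = cbind(start = c(50000L, 51000L), end = c(50500L, 51500L)),
         seq = strrep("C", 1000L)),                        # coding verdict
    list(id = "keeper", gene = "g5", strand = "+", biotype = "unknown",
         exons = cbind(start = c(70000L, 71000L), end = c(70500L, 71500L)),
         seq = strrep("C", 1000L)))
  rows[[1]]$exons <- cbind(start = c(0L, 500L), end = c(100L, 600L))
  rows[[1]]$seq <- strrep("C", 200L)
  catalog <- make_catalog(rows)
  reports <- rbind(mk_rep("len200"), mk_rep("oneexon"), mk_rep("bioty"),
                   mk_rep("codverd", orf = "coding"), mk_rep("keeper"))
  expect_equal(filter_lncrnas(catalog, reports), "keeper")

  # order independence: intersecting per-criterion masks in any order
  n_ex <- vapply(catalog$exons, nrow, integer(1))
  masks <- list(
    catalog$length > 200,
    n_ex >= 2,
    !(catalog$biotype %in% c("protein_coding", "miRNA", "tRNA", "snoRNA",
                             "rRNA", "pseudogene")),
    reports$orf_verdict == "noncoding" &
      reports$hexamer_verdict == "noncoding")
  for (perm in list(1:4, 4:1, c(2, 4, 1, 3), c(3, 1, 4, 2))) {
    keep <- Reduce(`&`, masks[perm])
    expect_equal(catalog$transcript_id[keep], "keeper")
  }
})

test_that("missing coding-potential report is an error", {
  catalog <- make_catalog(list(flat_row("t1", 300L)))
  expect_error(filter_lncrnas(catalog, data.frame(transcript_id = "other",
                                                  orf_verdict = "noncoding",
                                                  hexamer_verdict = "noncoding")),
               "report")
})

test_that("antisense/intergenic classification follows the overlap rule", {
  catalog <- make_catalog(list(
    list(id = "lnc1", gene = "gl1", strand = "-", biotype = "unknown",
         exons = cbind(start = c(100L, 250L), end = c(200L, 400L)),
         seq = strrep("A", 250L)),
    list(id = "cod1", gene = "gc1", strand = "+", biotype = "protein_coding",
         exons = cbind(start = 300L, end = 600L), seq = strrep("A", 300L)),
    list(id = "lnc2", gene = "gl2", strand = "-", biotype = "unknown",
         exons = cbind(start = c(5000L, 5500L), end = c(5200L, 5800L)),
         seq = strrep("A", 500L))))
  cls <- classify_lncrnas(catalog, c("lnc1", "lnc2"))
  expect_equal(cls$class[cls$transcript_id == "lnc1"], "antisense")
  expect_equal(cls$class[cls$transcript_id == "lnc2"], "intergenic")
})

test_that("same-strand overlap with a coding exon is not antisense", {
  catalog <- make_catalog(list(
    list(id = "lnc1", gene = "gl1", strand = "+", biotype = "unknown",
         exons = cbind(start = c(100L, 250L), end = c(200L, 400L)),
         seq = strrep("A", 250L)),
    list(id = "cod1", gene = "gc1", strand = "+", biotype = "protein_coding",
         exons = cbind(start = 300L, end = 600L), seq = strrep("A", 300L))))
  expect_equal(classify_lncrnas(catalog, "lnc1")$class, "intergenic")
})

test_that("classes partition the lncRNA set on synthetic data", {
  ds <- tiny_dataset()
  truth_lnc <- ds$catalog$transcript_id[ds$catalog$biotype != "protein_coding"]
  cls <- classify_lncrnas(ds$catalog, truth_lnc)
  expect_setequal(cls$transcript_id, truth_lnc)
  expect_true(all(cls$class %in% c("antisense", "intergenic")))
  # generator placed round(0.26 * 20) = 5 antisense lncRNAs
  expect_equal(sum(cls$class == "antisense"), 5L)
})

test_that("feature_summary matches direct recomputation", {
  catalog <- make_catalog(list(flat_row("a", 300L)))
  s <- feature_summary("a", catalog)
  expect_equal(s$summary$mean_length, 300)
  catalog2 <- make_catalog(list(
    list(id = "x", gene = "gx", strand = "+", biotype = "unknown",
         exons = cbind(start = c(0L, 200L), end = c(100L, 300L)),
         seq = strrep("A", 200L)),
    list(id = "y", gene = "gy", strand = "+", biotype = "unknown",
         exons = cbind(start = c(1000L, 1200L, 1400L, 1600L),
                       end = c(1100L, 1300L, 1500L, 1700L)),
         seq = strrep("A", 400L))))
  s2 <- feature_summary(c("x", "y"), catalog2)
  expect_equal(s2$summary$mean_exons, 3.0)
  expect_equal(s2$summary$mean_length, 300)
  expect_error(feature_summary(character(0), catalog2), "empty")

  ds <- tiny_dataset()
  ids <- ds$catalog$transcript_id[ds$catalog$biotype != "protein_coding"]
  s3 <- feature_summary(ids, ds$catalog)
  idx <- match(ids, ds$catalog$transcript_id)
  expect_equal(s3$summary$mean_length, mean(ds$catalog$length[idx]))
  expect_equal(s3$summary$mean_exons,
               mean(vapply(ds$catalog$exons[idx], nrow, integer(1))))
})

test_that("catalog invariants reject inconsistent records", {
  bad <- list(id = "t1", gene = "g1", strand = "+", biotype = "unknown",
              exons = cbind(start = 0L, end = 100L), seq = strrep("A", 99L))
  expect_error(make_catalog(list(bad)), "disagree")
})
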