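# Shared fixtures, built in code. tiny_dataset() is memoised per test run.

tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cerna_dataset(sim_config(
        n_coding_genes = 40L, n_lncrnas = 20L, n_mirnas = 8L,
        n_true_triads = 4L, n_de_features_per_contrast = 6L, seed = 42L))
    }
    cache
  }
})

# Hand-built catalog from compact row specs:
# list(id, gene, strand, biotype, exons (matrix), seq, cds = c(s, e) or NULL)
make_catalog <- function(rows, chrom = "chr1") {
  df <- do.call(rbind, lapply(rows, function(r) {
    d <- data.frame(
      transcript_id = r$id, gene_id = r$gene, chrom = chrom,
      strand = r$strand, biotype = r$biotype, sequence = r$seq,
      length = nchar(r$seq),
      cds_start = if (is.null(r$cds)) NA_integer_ else r$cds[1L],
      cds_end = if (is.null(r$cds)) NA_integer_ else r$cds[2L],
      stringsAsFactors = FALSE)
    d$exons <- list(r$exons)
    d
  }))
  df <- df[c("transcript_id", "gene_id", "chrom", "strand", "biotype",
             "exons", "sequence", "length", "cds_start", "cds_end")]
  transcript_catalog(df)
}

# Single-exon transcript row of given length (plain-A sequence by default)
flat_row <- function(id, len, start = 0L, strand = "+",
                     biotype = "unknown", gene = paste0("g_", id),
                     seq = strrep("A", len)) {
  list(id = id, gene = gene, strand = strand, biotype = biotype,
       exons = cbind(start = start, end = start + len), seq = seq)
}

# Large featureless catalog for count-simulation experiments (sequence
# content never inspected downstream of counts)
make_flat_catalog <- function(n, len = 1000L) {
  make_catalog(lapply(seq_len(n), function(i) {
    flat_row(sprintf("F%04d", i), len, start = (i - 1L) * (len + 1000L))
  }))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent brute-force oracles -------------------------------------------

# Longest ATG->stop ORF by exhaustive (frame, start, stop) enumeration
oracle_longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  for (i in seq_len(max(n - 5L, 0L))) {
    if (substr(seq, i, i + 2L) != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      if (substr(seq, j, j + 2L) %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, j + 2L - i + 1L)
        break
      }
      j <- j + 3L
    }
  }
  best
}

rc_str <- function(x) {
  x <- chartr("U", "T", toupper(x))
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# All seed sites by sliding-window comparison (no string search shortcuts)
oracle_seed_sites <- function(mature, target) {
  mature <- chartr("U", "T", toupper(mature))
  target <- toupper(target)
  seed7 <- rc_str(substr(mature, 2L, 8L))
  seed6 <- rc_str(substr(mature, 2L, 7L))
  m8 <- substr(seed7, 1L, 1L)
  n <- nchar(target)
  out <- list()
  for (s in seq_len(n - 6L)) {
    if (substr(target, s, s + 6L) == seed7) {
      a1 <- if (s + 7L <= n) substr(target, s + 7L, s + 7L) else ""
      out[[length(out) + 1L]] <- data.frame(
        start = s - 1L, seed_class = if (a1 == "A") "8mer" else "7mer-m8")
    }
  }
  for (s in seq_len(max(n - 5L, 0L))) {
    if (substr(target, s, s + 5L) == seed6 &&
        s + 6L <= n && substr(target, s + 6L, s + 6L) == "A" &&
        !(s >= 2L && substr(target, s - 1L, s - 1L) == m8)) {
      out[[length(out) + 1L]] <- data.frame(start = s - 1L,
                                            seed_class = "7mer-A1")
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), seed_class = character(0)))
  }
  d <- do.call(rbind, out)
  d[order(d$start), , drop = FALSE]
}

# Quadratic all-vs-all neighbour enumeration over gene spans
oracle_neighbors <- function(spans, max_dist = 10000L) {
  out <- list()
  n <- nrow(spans)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (spans$chrom[i] != spans$chrom[j]) next
      a <- if (spans$start[i] <= spans$start[j]) i else j
      b <- if (spans$start[i] <= spans$start[j]) j else i
      gap <- max(0L, spans$start[b] - spans$end[a])
      if (gap >= max_dist) next
      lnc_a <- spans$is_lncrna[a] && !spans$is_coding[a]
      lnc_b <- spans$is_lncrna[b] && !spans$is_coding[b]
      if (lnc_a && lnc_b) next
      if (!(spans$is_coding[a] || lnc_a) || !(spans$is_coding[b] || lnc_b))
        next
      cls <- if (!lnc_a && !lnc_b) "coding-coding" else "lncRNA-coding"
      out[[length(out) + 1L]] <- data.frame(
        feature_a = spans$gene_id[a], feature_b = spans$gene_id[b],
        pair_class = cls, distance = gap, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(feature_a = character(0), feature_b = character(0),
                      pair_class = character(0), distance = integer(0)))
  }
  do.call(rbind, out)
}

# Mann-Whitney U by exhaustive pair counting (ties get half weight)
oracle_u_stat <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) {
    u <- u + (xi > yi) + 0.5 * (xi == yi)
  }
  u
}

# Hypergeometric upper tail by direct enumeration of the pmf
oracle_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Triad assembly by brute-force triple loop over the two edge lists
oracle_triads <- function(lm_edges, mm_edges) {
  out <- list()
  for (i in seq_len(nrow(lm_edges))) {
    for (j in seq_len(nrow(mm_edges))) {
      if (lm_edges$source_id[i] != mm_edges$source_id[j]) next
      out[[length(out) + 1L]] <- data.frame(
        lncrna_id = lm_edges$target_id[i],
        mirna_id = lm_edges$source_id[i],
        mrna_id = mm_edges$target_id[j], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(lncrna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0)))
  }
  unique(do.call(rbind, out))
}

pair_key <- function(df) {
  sort(paste(df$feature_a, df$feature_b, df$pair_class, df$distance))
}
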