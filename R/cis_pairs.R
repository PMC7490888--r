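#' Gene spans of a catalog
#'
#' One row per gene: chromosome, strand and the union span of the gene's
#' transcripts (0-based half-open), plus whether the gene is protein-coding
#' and whether any of its transcripts is in `lncrna_ids`.
#'
#' @param catalog A [transcript_catalog()].
#' @param lncrna_ids Transcript ids called lncRNA.
#' @return data.frame: `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `is_coding`, `is_lncrna`.
#' @export
gene_spans <- function(catalog, lncrna_ids = character(0)) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  spans <- lapply(split(seq_len(nrow(catalog)), catalog$gene_id), function(ix) {
    exmat <- do.call(rbind, catalog$exons[ix])
    data.frame(
      gene_id = catalog$gene_id[ix[1L]],
      chrom = catalog$chrom[ix[1L]],
      strand = catalog$strand[ix[1L]],
      start = min(exmat[, 1L]),
      end = max(exmat[, 2L]),
      is_coding = any(catalog$biotype[ix] == "protein_coding"),
      is_lncrna = any(catalog$transcript_id[ix] %in% lncrna_ids),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, spans)
  rownames(out) <- NULL
  out
}

#' Find neighbouring gene pairs within a distance window
#'
#' Emits lncRNA-coding and coding-coding gene pairs on the same chromosome
#' whose gene-span gap is strictly below `max_dist` (distance 0 for
#' overlapping spans). Orientation is classified for every pair.
#'
#' @param catalog A [transcript_catalog()].
#' @param lncrna_ids Transcript ids called lncRNA.
#' @param max_dist Neighbour window in nt (strict `<`; default 10 kb).
#' @return data.frame: `feature_a`, `feature_b` (gene ids, a left of b),
#'   `pair_class` (`"coding-coding"` or `"lncRNA-coding"`), `distance`,
#'   `orientation` (`"divergent"`, `"convergent"`, `"tandem"`).
#' @export
find_neighbors <- function(catalog, lncrna_ids, max_dist = 10000L) {
  spans <- gene_spans(catalog, lncrna_ids)
  spans <- spans[spans$is_coding | spans$is_lncrna, , drop = FALSE]
  out <- list()
  for (chr in unique(spans$chrom)) {
    s <- spans[spans$chrom == chr, , drop = FALSE]
    s <- s[order(s$start, s$end), , drop = FALSE]
    n <- nrow(s)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        gap <- max(0L, s$start[j] - s$end[i])
        # spans are start-sorted: once the gap from i's end exceeds the
        # window for a j, later j can still overlap? no - starts only grow,
        # so gap is non-decreasing in j and we can stop.
        if (gap >= max_dist) break
        cls <- pair_class(s$is_lncrna[i] && !s$is_coding[i],
                          s$is_lncrna[j] && !s$is_coding[j])
        if (is.na(cls)) next
        out[[length(out) + 1L]] <- data.frame(
          feature_a = s$gene_id[i], feature_b = s$gene_id[j],
          pair_class = cls, distance = gap,
          orientation = orientation_of(s$start[i], s$end[i], s$strand[i],
                                       s$start[j], s$end[j], s$strand[j]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(feature_a = character(0), feature_b = character(0),
                      pair_class = character(0), distance = integer(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

pair_class <- function(a_is_lnc, b_is_lnc) {
  if (!a_is_lnc && !b_is_lnc) return("coding-coding")
  if (xor(a_is_lnc, b_is_lnc)) return("lncRNA-coding")
  NA_character_  # lncRNA-lncRNA pairs are not collected
}

# Orientation from 5'-end positions: order the two features by 5' end; the
# pair is divergent iff the 5'-earlier feature transcribes leftward (-) and
# the later rightward (+), convergent for the reverse, tandem on one strand.
orientation_of <- function(start_a, end_a, strand_a,
                           start_b, end_b, strand_b) {
  if (strand_a == strand_b) return("tandem")
  p5_a <- if (strand_a == "+") start_a else end_a - 1L
  p5_b <- if (strand_b == "+") start_b else end_b - 1L
  left_strand <- if (p5_a <= p5_b) strand_a else strand_b
  if (left_strand == "-") "divergent" else "convergent"
}

#' Classify the orientation of a gene pair
#'
#' @param pair One row (or a data.frame) with `feature_a`, `feature_b`.
#' @param catalog A [transcript_catalog()].
#' @return Character vector of orientations (see [find_neighbors()]).
#' @export
classify_orientation <- function(pair, catalog) {
  spans <- gene_spans(catalog)
  vapply(seq_len(nrow(pair)), function(i) {
    a <- spans[spans$gene_id == pair$feature_a[i], ]
    b <- spans[spans$gene_id == pair$feature_b[i], ]
    orientation_of(a$start, a$end, a$strand, b$start, b$end, b$strand)
  }, character(1))
}

#' Pearson correlation of expression for gene pairs
#'
#' Pearson r across all samples. Pairs where either feature has zero
#' variance are dropped; the number dropped is attached as attribute
#' `"n_dropped"`.
#'
#' @param pairs data.frame with `feature_a`, `feature_b` present among the
#'   rownames of `expr`.
#' @param expr Abundance matrix (features x samples, >= 3 samples).
#' @return `pairs` with a `pearson_r` column.
#' @export
pair_correlations <- function(pairs, expr) {
  if (ncol(expr) < 3L) stop("need at least 3 samples", call. = FALSE)
  missing <- setdiff(unique(c(pairs$feature_a, pairs$feature_b)),
                     rownames(expr))
  if (length(missing) > 0) {
    stop("pair features absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    x <- expr[pairs$feature_a[i], ]
    y <- expr[pairs$feature_b[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  pairs$pearson_r <- r
  out <- pairs[!is.na(r), , drop = FALSE]
  attr(out, "n_dropped") <- sum(is.na(r))
  out
}

#' Random coding-pair correlation null
#'
#' Draws `n_pairs` distinct unordered coding-coding gene pairs uniformly at
#' random (seeded) and computes their expression correlations; the empirical
#' null against which neighbour-pair correlations are compared.
#'
#' @param expr Abundance matrix.
#' @param coding_ids Feature ids eligible for pairing (>= 2).
#' @param n_pairs Number of random pairs.
#' @param seed Integer seed.
#' @return data.frame like [pair_correlations()] output with
#'   `pair_class = "random"`.
#' @export
random_pair_null <- function(expr, coding_ids, n_pairs, seed = 1L) {
  if (n_pairs == 0L) {
    return(data.frame(feature_a = character(0), feature_b = character(0),
                      pair_class = character(0), pearson_r = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (length(coding_ids) < 2L) stop("need >= 2 coding features", call. = FALSE)
  n_avail <- choose(length(coding_ids), 2)
  if (n_pairs > n_avail) {
    stop("n_pairs exceeds the number of distinct pairs", call. = FALSE)
  }
  with_seed(seed, {
    picks <- sample.int(n_avail, n_pairs)
    idx <- pair_index_to_ij(picks, length(coding_ids))
    pairs <- data.frame(feature_a = coding_ids[idx[, 1L]],
                        feature_b = coding_ids[idx[, 2L]],
                        pair_class = "random", stringsAsFactors = FALSE)
    pair_correlations(pairs, expr)
  })
}

# Map linear indices 1..choose(n,2) to (i < j) pairs, row-major over i.
pair_index_to_ij <- function(k, n) {
  i <- findInterval(k - 1L, cumsum(c(0, (n - 1):1))[-1], left.open = FALSE) + 1L
  offset <- cumsum(c(0, (n - 1):1))[i]
  j <- i + (k - offset)
  cbind(i, j)
}

#' Compare two correlation distributions
#'
#' Two-sided Mann-Whitney U test (normal approximation with ties handled)
#' plus group means; used to contrast neighbour-pair correlations with the
#' random-pair null.
#'
#' @param r_a,r_b Numeric vectors of correlations (each length >= 2).
#' @return List: `mean_a`, `mean_b`, `statistic` (U for the first group),
#'   `p_value`.
#' @export
compare_correlation_distributions <- function(r_a, r_b) {
  if (length(r_a) < 2L || length(r_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(r_a, r_b, exact = FALSE))
  list(mean_a = mean(r_a), mean_b = mean(r_b),
       statistic = unname(wt$statistic), p_value = wt$p.value)
}
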