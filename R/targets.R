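#' Find candidate miRNA seed-match sites on a target sequence
#'
#' Scans the target (5' to 3', DNA or RNA) for Watson-Crick
#' reverse-complement matches to the miRNA seed (mature-sequence positions
#' 2-8; no G:U pairing within the seed) and classifies each site:
#' \describe{
#'   \item{8mer}{seed match through position 8 plus target A opposite
#'     miRNA position 1.}
#'   \item{7mer-m8}{seed match through position 8, no A opposite
#'     position 1.}
#'   \item{7mer-A1}{match to positions 2-7 plus target A opposite
#'     position 1, with position 8 unpaired.}
#' }
#'
#' @param mirna One-row data.frame (or list) with `mirna_id`, `mature_seq`.
#' @param target_seq Target nucleotide string.
#' @param target_id Optional target identifier carried into the result.
#' @return data.frame: `mirna_id`, `transcript_id`, `start` (0-based
#'   position of the seed-match 5' end on the target), `seed_class`.
#' @export
find_seed_sites <- function(mirna, target_seq, target_id = NA_character_) {
  mature <- dna(mirna$mature_seq)
  target <- dna(target_seq)
  seed8_rc <- revcomp(substr(mature, 2L, 8L))   # 7 nt, matches m2-m8
  seed7_rc <- revcomp(substr(mature, 2L, 7L))   # 6 nt, matches m2-m7
  n <- nchar(target)
  res <- list()
  add <- function(start0, cls) {
    res[[length(res) + 1L]] <<- data.frame(
      mirna_id = mirna$mirna_id, transcript_id = target_id,
      start = start0, seed_class = cls, stringsAsFactors = FALSE)
  }
  for (s in str_find_all(seed8_rc, target)) {
    a1 <- if (s + 7L <= n) substr(target, s + 7L, s + 7L) else ""
    add(s - 1L, if (a1 == "A") "8mer" else "7mer-m8")
  }
  # 7mer-A1: m2-m7 match + A, with the m8-complement position mismatching
  # (otherwise the site is already reported above).
  m8_rc <- substr(seed8_rc, 1L, 1L)
  for (s in str_find_all(seed7_rc, target)) {
    if (s + 6L > n) next
    if (substr(target, s + 6L, s + 6L) != "A") next
    if (s >= 2L && substr(target, s - 1L, s - 1L) == m8_rc) next
    add(s - 1L, "7mer-A1")
  }
  if (length(res) == 0L) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), seed_class = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(out$start), , drop = FALSE]
}

# Pair category of one miRNA base against one target base (both DNA-coded,
# miRNA base given as its mature-sequence letter).
pair_type <- function(mir_base, tgt_base) {
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  if (tgt_base == wc[[mir_base]]) {
    if (mir_base %in% c("C", "G")) "GC" else "AU"
  } else if ((mir_base == "G" && tgt_base == "T") ||
             (mir_base == "T" && tgt_base == "G")) {
    "GU"
  } else {
    "mismatch"
  }
}

#' Score a candidate miRNA site
#'
#' Ungapped complementarity of the full mature miRNA against the target
#' window implied by the site: +5 per Watson-Crick pair, +2 per G:U wobble
#' outside the seed (positions 2-8 allow no wobble credit), -3 per
#' mismatch; the total is floored at 0. The pseudo-energy is
#' `-(2*GC + 1*AU + 0.5*GU)` over paired positions (kcal/mol-like scale,
#' more negative = more stable). Windows truncated by the sequence ends are
#' scored over the available overlap.
#'
#' @param mirna One-row data.frame/list with `mature_seq`.
#' @param target_seq Target nucleotide string.
#' @param site One row from [find_seed_sites()] (uses `start`).
#' @return List: `align_score`, `energy`.
#' @export
score_site <- function(mirna, target_seq, site) {
  mature <- dna(mirna$mature_seq)
  target <- dna(target_seq)
  m <- nchar(mature)
  n <- nchar(target)
  # seed match occupies target[start+1 .. start+7] (1-based), pairing
  # m8..m2; miRNA position i pairs target position start + 9 - i.
  s1 <- site$start + 1L
  score <- 0
  n_gc <- 0L
  n_au <- 0L
  n_gu <- 0L
  for (i in seq_len(m)) {
    tpos <- s1 + 8L - i
    if (tpos < 1L || tpos > n) next
    pt <- pair_type(substr(mature, i, i), substr(target, tpos, tpos))
    in_seed <- i >= 2L && i <= 8L
    if (pt == "GC" || pt == "AU") {
      score <- score + 5
      if (pt == "GC") n_gc <- n_gc + 1L else n_au <- n_au + 1L
    } else if (pt == "GU") {
      n_gu <- n_gu + 1L
      score <- score + if (in_seed) -3 else 2
    } else {
      score <- score - 3
    }
  }
  list(align_score = max(score, 0),
       energy = -(2 * n_gc + 1 * n_au + 0.5 * n_gu))
}

#' Predict miRNA response elements across a catalog
#'
#' Runs seed-site discovery and scoring for every miRNA against every
#' lncRNA (whole sequence) and every mRNA (annotated 3' UTR when present,
#' else whole transcript), keeping sites with `align_score >= score_min`
#' and `energy <= energy_max`. Output order is deterministic and invariant
#' to input ordering.
#'
#' @param mirnas miRNA data.frame (`mirna_id`, `mature_seq`).
#' @param catalog A [transcript_catalog()].
#' @param lncrna_ids Transcript ids to search over their full length;
#'   defaults to all non-protein-coding transcripts.
#' @param score_min Minimum alignment score (inclusive).
#' @param energy_max Maximum (least negative) pseudo-energy (inclusive).
#' @return data.frame: `mirna_id`, `transcript_id`, `start` (0-based on the
#'   full transcript), `seed_class`, `align_score`, `energy`.
#' @export
predict_targets <- function(mirnas, catalog, lncrna_ids = NULL,
                            score_min = 80, energy_max = -7.0) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  if (is.null(lncrna_ids)) {
    lncrna_ids <- catalog$transcript_id[catalog$biotype != "protein_coding"]
  }
  out <- list()
  for (mi in seq_len(nrow(mirnas))) {
    mir <- mirnas[mi, ]
    for (ti in seq_len(nrow(catalog))) {
      tid <- catalog$transcript_id[ti]
      is_coding <- catalog$biotype[ti] == "protein_coding"
      if (!is_coding && !(tid %in% lncrna_ids)) next
      seq <- catalog$sequence[ti]
      offset <- 0L
      if (is_coding && !is.na(catalog$cds_end[ti])) {
        offset <- catalog$cds_end[ti]
        seq <- substr(seq, offset + 1L, catalog$length[ti])
      }
      sites <- find_seed_sites(mir, seq, target_id = tid)
      if (nrow(sites) == 0L) next
      for (si in seq_len(nrow(sites))) {
        sc <- score_site(mir, seq, sites[si, ])
        if (sc$align_score >= score_min && sc$energy <= energy_max) {
          row <- sites[si, ]
          row$start <- row$start + offset
          row$align_score <- sc$align_score
          row$energy <- sc$energy
          out[[length(out) + 1L]] <- row
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), seed_class = character(0),
                      align_score = numeric(0), energy = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$mirna_id, res$transcript_id, res$start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Trans-acting lncRNA targets by expression correlation
#'
#' All lncRNA-gene cross pairs whose absolute Pearson correlation across
#' the shared samples strictly exceeds `r_min`. Zero-variance features are
#' skipped; their count is attached as attribute `"n_skipped"`.
#'
#' @param lncrna_expr,gene_expr Abundance matrices sharing columns
#'   (>= 3 samples).
#' @param r_min Absolute-correlation threshold (strict `>`).
#' @return data.frame: `lncrna_id`, `gene_id`, `pearson_r`.
#' @export
trans_targets <- function(lncrna_expr, gene_expr, r_min = 0.95) {
  shared <- intersect(colnames(lncrna_expr), colnames(gene_expr))
  if (length(shared) < 3L) stop("need >= 3 shared samples", call. = FALSE)
  lx <- lncrna_expr[, shared, drop = FALSE]
  gx <- gene_expr[, shared, drop = FALSE]
  var_l <- apply(lx, 1L, stats::sd) > 0
  var_g <- apply(gx, 1L, stats::sd) > 0
  n_skipped <- sum(!var_l) + sum(!var_g)
  lx <- lx[var_l, , drop = FALSE]
  gx <- gx[var_g, , drop = FALSE]
  out <- data.frame(lncrna_id = character(0), gene_id = character(0),
                    pearson_r = numeric(0), stringsAsFactors = FALSE)
  if (nrow(lx) > 0L && nrow(gx) > 0L) {
    cc <- stats::cor(t(lx), t(gx))
    hits <- which(abs(cc) > r_min, arr.ind = TRUE)
    if (nrow(hits) > 0L) {
      out <- data.frame(lncrna_id = rownames(lx)[hits[, 1L]],
                        gene_id = rownames(gx)[hits[, 2L]],
                        pearson_r = cc[hits],
                        stringsAsFactors = FALSE)
      out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "n_skipped") <- n_skipped
  out
}
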