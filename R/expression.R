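#' FPKM normalisation
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `FPKM = count * 1e9 / (length * sample_total)`, with the sample total the
#' column sum of the raw count matrix. Scale-invariant to uniform count
#' scaling.
#'
#' @param counts Non-negative numeric matrix, features x samples, with
#'   rownames and colnames.
#' @param lengths Named vector of feature lengths in nt (> 0), covering
#'   every row of `counts`.
#' @return Numeric matrix of FPKM values with unit attribute `"FPKM"`.
#' @export
compute_fpkm <- function(counts, lengths) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  len <- lengths[rownames(counts)]
  if (anyNA(len)) {
    stop("missing length for features: ",
         paste(rownames(counts)[is.na(len)], collapse = ", "), call. = FALSE)
  }
  if (any(len <= 0)) stop("feature lengths must be positive", call. = FALSE)
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop("zero-total sample(s): ",
         paste(colnames(counts)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  fpkm <- sweep(counts * 1e9 / len, 2L, totals, "/")
  attr(fpkm, "unit") <- "FPKM"
  fpkm
}

#' Threshold-based differential expression
#'
#' Per feature: log2 fold change from group means of the abundance matrix
#' (`log2((mean_H + pseudocount) / (mean_L + pseudocount))`, H over L) and a
#' Welch two-sample t-test on `log2(x + pseudocount)`. A feature is called
#' significant iff `p < alpha` and `|log2fc| >= lfc_min` (the fold-change
#' bound is inclusive). No multiple-testing correction is applied to these
#' calls. When both groups have zero variance, p is 1 for equal means and 0
#' otherwise.
#'
#' @param expr Abundance matrix (FPKM), features x samples.
#' @param design data.frame with columns `sample`, `group` covering the
#'   matrix columns.
#' @param contrast Length-2 character vector `c(high_group, low_group)`, or
#'   a string like `"LH_vs_LL"`.
#' @param alpha P-value threshold (strict `<`).
#' @param lfc_min Absolute log2 fold-change threshold (inclusive `>=`).
#' @param pseudocount Added before log/ratio computation.
#' @return data.frame: `feature_id`, `contrast`, `log2fc`, `p_value`,
#'   `direction` (`"up"`/`"down"` relative to the high group), `significant`.
#' @export
differential_expression <- function(expr, design, contrast,
                                    alpha = 0.05, lfc_min = 1.0,
                                    pseudocount = 1.0) {
  stopifnot(is.matrix(expr))
  if (length(contrast) == 1L) contrast <- contrast_groups(contrast)
  stopifnot(length(contrast) == 2L)
  g_hi <- design$sample[design$group == contrast[1L]]
  g_lo <- design$sample[design$group == contrast[2L]]
  g_hi <- intersect(g_hi, colnames(expr))
  g_lo <- intersect(g_lo, colnames(expr))
  if (length(g_hi) < 2L || length(g_lo) < 2L) {
    stop("each contrast group needs at least 2 samples", call. = FALSE)
  }
  hi <- expr[, g_hi, drop = FALSE]
  lo <- expr[, g_lo, drop = FALSE]
  log2fc <- log2((rowMeans(hi) + pseudocount) /
                   (rowMeans(lo) + pseudocount))
  lhi <- log2(hi + pseudocount)
  llo <- log2(lo + pseudocount)
  p <- vapply(seq_len(nrow(expr)), function(i) {
    welch_p(lhi[i, ], llo[i, ])
  }, numeric(1))
  data.frame(
    feature_id = rownames(expr),
    contrast = paste0(contrast[1L], "_vs_", contrast[2L]),
    log2fc = unname(log2fc),
    p_value = p,
    direction = ifelse(log2fc >= 0, "up", "down"),
    significant = p < alpha & abs(log2fc) >= lfc_min,
    stringsAsFactors = FALSE
  )
}

# Welch t-test p-value with the degenerate zero-variance branch made
# explicit (stats::t.test errors on constant data).
welch_p <- function(x, y) {
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Group presence sets and Venn regions
#'
#' A feature is present in a group iff its mean abundance in that group
#' exceeds `min_expr` (strict). Returns the per-group feature sets, the
#' intersection across all groups, and the size of every Venn region
#' (named by the `&`-joined group combination).
#'
#' @param expr Abundance matrix, features x samples.
#' @param design data.frame with `sample`, `group`.
#' @param min_expr Presence threshold (strict `>`).
#' @return List with `sets` (named list of feature vectors),
#'   `intersection` (features present in every group) and `region_sizes`
#'   (named integer vector over non-empty group combinations).
#' @export
group_presence_sets <- function(expr, design, min_expr = 0) {
  groups <- unique(design$group)
  sets <- lapply(groups, function(g) {
    cols <- intersect(design$sample[design$group == g], colnames(expr))
    rownames(expr)[rowMeans(expr[, cols, drop = FALSE]) > min_expr]
  })
  names(sets) <- groups
  membership <- vapply(sets, function(s) rownames(expr) %in% s,
                       logical(nrow(expr)))
  if (nrow(expr) == 1L) membership <- matrix(membership, nrow = 1L,
                                             dimnames = list(NULL, groups))
  key <- apply(membership, 1L, function(m) paste(groups[m], collapse = "&"))
  key <- key[key != ""]
  region_sizes <- if (length(key) > 0) table(key) else
    table(factor(character(0)))
  list(sets = sets,
       intersection = Reduce(intersect, sets),
       region_sizes = stats::setNames(as.integer(region_sizes),
                                      names(region_sizes)))
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((Ct_target,test - Ct_ref,test) - (Ct_target,calib - Ct_ref,calib))`:
#' expression of a target gene in a test sample relative to a calibrator
#' sample, each normalised to a reference gene.
#'
#' @param ct_target_test,ct_ref_test Ct values in the test sample.
#' @param ct_target_calib,ct_ref_calib Ct values in the calibrator sample.
#' @return Relative expression (1 when ddCt is 0).
#' @export
delta_delta_ct <- function(ct_target_test, ct_ref_test,
                           ct_target_calib, ct_ref_calib) {
  vals <- c(ct_target_test, ct_ref_test, ct_target_calib, ct_ref_calib)
  if (any(!is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_test - ct_ref_test) -
    (ct_target_calib - ct_ref_calib)
  2^(-ddct)
}
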