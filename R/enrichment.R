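#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the over-representation
#' p-value for observing `k` annotated genes in a query of size `n` when
#' `K` of the `N` background genes carry the annotation. Evaluated via the
#' numerically stable (log-space) distribution function.
#'
#' @param k Hits in the query.
#' @param K Annotated genes in the background.
#' @param n Query size.
#' @param N Background size.
#' @return The upper-tail probability (1 when `k` is 0).
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 0 || k > min(K, n) || K > N || n > N) {
    stop("invalid hypergeometric parameters: need 0 <= k <= min(K, n) ",
         "and K, n <= N", call. = FALSE)
  }
  if (k == 0) return(1.0)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input order is preserved and
#' every adjusted value dominates its raw value.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param method Adjustment method (`"BH"` default, `"bonferroni"`
#'   available).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = method)
}

#' Term over-representation analysis
#'
#' Hypergeometric upper-tail test of each term's genes against a query
#' list, with multiplicity correction across all tested terms. Terms with
#' no query hit are reported with p = 1. Significance is called at
#' adjusted p < `alpha`.
#'
#' @param query_genes Genes of interest (must all be in the background).
#' @param background_genes The gene universe.
#' @param term_map Named list mapping term id to a character vector of
#'   genes (e.g. from [read_gmt()] or [generate_term_map()]); genes outside
#'   the background are ignored, terms with no background gene are dropped.
#' @param alpha Significance threshold on adjusted p (strict `<`).
#' @param method Correction method passed to [bh_adjust()].
#' @return data.frame sorted by p: `term_id`, `k` (query hits), `K` (term
#'   size in background), `n` (query size), `N` (background size),
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
enrich <- function(query_genes, background_genes, term_map, alpha = 0.05,
                   method = "BH") {
  query_genes <- unique(query_genes)
  background_genes <- unique(background_genes)
  off <- setdiff(query_genes, background_genes)
  if (length(off) > 0) {
    stop("query genes outside the background: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  if (length(term_map) == 0L) stop("empty term map", call. = FALSE)
  N <- length(background_genes)
  n <- length(query_genes)
  rows <- lapply(names(term_map), function(term) {
    genes <- intersect(unique(term_map[[term]]), background_genes)
    K <- length(genes)
    if (K == 0L) return(NULL)
    k <- length(intersect(genes, query_genes))
    data.frame(term_id = term, k = k, K = K, n = n, N = N,
               p_value = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no term has background genes", call. = FALSE)
  out$p_adjusted <- bh_adjust(out$p_value, method = method)
  out$significant <- out$p_adjusted < alpha
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GMT-style term-to-gene file
#'
#' Tab-separated: term id, description, then one gene per remaining field.
#'
#' @param path GMT file path.
#' @return Named list of gene vectors; descriptions in attribute
#'   `"descriptions"`.
#' @export
read_gmt <- function(path) {
  check_files_exist(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tm <- lapply(parts, function(p) p[-(1:2)])
  names(tm) <- vapply(parts, `[`, character(1), 1L)
  attr(tm, "descriptions") <- vapply(parts, `[`, character(1), 2L)
  tm
}

#' Write a term map as GMT
#'
#' @param term_map Named list of gene vectors.
#' @param path Output path.
#' @param descriptions Optional descriptions (recycled `"NA"`).
#' @return Invisibly, the path.
#' @export
write_gmt <- function(term_map, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("NA", length(term_map))
  lines <- vapply(seq_along(term_map), function(i) {
    paste(c(names(term_map)[i], descriptions[i], term_map[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
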