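#' Negative miRNA-mRNA edges
#'
#' An edge is drawn between a differentially expressed miRNA and a
#' differentially expressed mRNA of the same contrast iff (1) the mRNA
#' carries a predicted site for the miRNA and (2) their regulation
#' directions are opposite.
#'
#' @param de_mirnas,de_mrnas Differential-expression tables
#'   ([differential_expression()] output); only rows with
#'   `significant == TRUE` are used.
#' @param sites Predicted sites ([predict_targets()] output).
#' @param contrast Contrast name (e.g. `"LH_vs_LL"`).
#' @return data.frame of class `cerna_edges`: `source_id` (miRNA),
#'   `target_id`, `edge_type`, `mirna_direction`, `partner_direction`,
#'   `contrast`, `n_sites`.
#' @export
negative_mirna_mrna_edges <- function(de_mirnas, de_mrnas, sites, contrast) {
  build_negative_edges(de_mirnas, de_mrnas, sites, contrast, "miRNA-mRNA")
}

#' Negative lncRNA-miRNA edges
#'
#' As [negative_mirna_mrna_edges()] with lncRNA partners: the lncRNA must
#' carry a predicted site for the miRNA and the two must move in opposite
#' directions in the contrast.
#'
#' @param de_lncrnas,de_mirnas Differential-expression tables.
#' @param sites Predicted sites.
#' @param contrast Contrast name.
#' @return data.frame of class `cerna_edges` (source is the miRNA, target
#'   the lncRNA, `edge_type = "lncRNA-miRNA"`).
#' @export
negative_lncrna_mirna_edges <- function(de_lncrnas, de_mirnas, sites,
                                        contrast) {
  build_negative_edges(de_mirnas, de_lncrnas, sites, contrast,
                       "lncRNA-miRNA")
}

build_negative_edges <- function(de_mirnas, de_partners, sites, contrast,
                                 edge_type) {
  mir <- de_mirnas[de_mirnas$significant & de_mirnas$contrast == contrast, ,
                   drop = FALSE]
  par <- de_partners[de_partners$significant &
                       de_partners$contrast == contrast, , drop = FALSE]
  out <- list()
  if (nrow(mir) > 0L && nrow(par) > 0L && nrow(sites) > 0L) {
    site_key <- paste(sites$mirna_id, sites$transcript_id)
    for (i in seq_len(nrow(mir))) {
      for (j in seq_len(nrow(par))) {
        if (mir$direction[i] == par$direction[j]) next
        k <- paste(mir$feature_id[i], par$feature_id[j])
        ns <- sum(site_key == k)
        if (ns == 0L) next
        out[[length(out) + 1L]] <- data.frame(
          source_id = mir$feature_id[i], target_id = par$feature_id[j],
          edge_type = edge_type, mirna_direction = mir$direction[i],
          partner_direction = par$direction[j], contrast = contrast,
          n_sites = ns, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(source_id = character(0), target_id = character(0),
               edge_type = character(0), mirna_direction = character(0),
               partner_direction = character(0), contrast = character(0),
               n_sites = integer(0), stringsAsFactors = FALSE)
  class(res) <- c("cerna_edges", "data.frame")
  res
}

#' Assemble ceRNA triads from the two negative edge sets
#'
#' One triad per (lncRNA, miRNA, mRNA) combination in which a
#' lncRNA-miRNA edge and a miRNA-mRNA edge share the miRNA. By
#' construction of the negative edges, the lncRNA and mRNA share a
#' regulation direction opposite to the miRNA, and both carry a predicted
#' site for the shared miRNA. Both edge sets must come from the same
#' contrast.
#'
#' @param mirna_mrna_edges Output of [negative_mirna_mrna_edges()].
#' @param lncrna_mirna_edges Output of [negative_lncrna_mirna_edges()].
#' @return data.frame: `lncrna_id`, `mirna_id`, `mrna_id`, `contrast`,
#'   `mirna_direction`, `partner_direction` (deduplicated).
#' @export
assemble_triads <- function(mirna_mrna_edges, lncrna_mirna_edges) {
  ctrs <- unique(c(mirna_mrna_edges$contrast, lncrna_mirna_edges$contrast))
  if (length(ctrs) > 1L) {
    stop("edge sets mix contrasts: ", paste(ctrs, collapse = ", "),
         call. = FALSE)
  }
  empty <- data.frame(lncrna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), contrast = character(0),
                      mirna_direction = character(0),
                      partner_direction = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(mirna_mrna_edges) == 0L || nrow(lncrna_mirna_edges) == 0L) {
    return(empty)
  }
  merged <- merge(
    data.frame(mirna_id = lncrna_mirna_edges$source_id,
               lncrna_id = lncrna_mirna_edges$target_id,
               mirna_direction = lncrna_mirna_edges$mirna_direction,
               partner_direction = lncrna_mirna_edges$partner_direction,
               stringsAsFactors = FALSE),
    data.frame(mirna_id = mirna_mrna_edges$source_id,
               mrna_id = mirna_mrna_edges$target_id,
               stringsAsFactors = FALSE),
    by = "mirna_id")
  merged$contrast <- rep(ctrs, length.out = nrow(merged))
  out <- unique(merged[c("lncrna_id", "mirna_id", "mrna_id", "contrast",
                         "mirna_direction", "partner_direction")])
  out <- out[order(out$lncrna_id, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a ceRNA network as SIF plus node attributes
#'
#' Writes a Cytoscape-compatible SIF edge list
#' (`source<TAB>interaction<TAB>target`), a node-attribute TSV (`node`,
#' `type`, `direction`) and a triads TSV. An empty graph produces empty
#' files with a warning.
#'
#' @param edges Combined `cerna_edges` (rbind of both edge sets).
#' @param triads Triads from [assemble_triads()].
#' @param dir Output directory.
#' @return Invisibly, a list with written paths and `n_nodes`/`n_edges`.
#' @export
export_network <- function(edges, triads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sif_path <- file.path(dir, "network.sif")
  attr_path <- file.path(dir, "node_attributes.tsv")
  triad_path <- file.path(dir, "triads.tsv")
  if (nrow(edges) == 0L) {
    warning("exporting an empty network", call. = FALSE)
    writeLines(character(0), sif_path)
    write_tsv(data.frame(node = character(0), type = character(0),
                         direction = character(0)), attr_path)
    write_tsv(triads, triad_path)
    return(invisible(list(sif = sif_path, attributes = attr_path,
                          triads = triad_path, n_nodes = 0L, n_edges = 0L)))
  }
  writeLines(paste(edges$source_id, edges$edge_type, edges$target_id,
                   sep = "\t"), sif_path)
  nodes <- rbind(
    data.frame(node = edges$source_id, type = "miRNA",
               direction = edges$mirna_direction, stringsAsFactors = FALSE),
    data.frame(node = edges$target_id,
               type = ifelse(edges$edge_type == "miRNA-mRNA",
                             "mRNA", "lncRNA"),
               direction = edges$partner_direction, stringsAsFactors = FALSE))
  nodes <- unique(nodes)
  nodes <- nodes[order(nodes$node), , drop = FALSE]
  write_tsv(nodes, attr_path)
  write_tsv(triads, triad_path)
  jsonlite::write_json(
    list(nodes = nodes, edges = as.data.frame(edges)),
    file.path(dir, "network.json"), dataframe = "columns", digits = NA)
  invisible(list(sif = sif_path, attributes = attr_path, triads = triad_path,
                 json = file.path(dir, "network.json"),
                 n_nodes = nrow(nodes), n_edges = nrow(edges)))
}

#' Read a SIF edge list
#'
#' @param path SIF file (`source<TAB>interaction<TAB>target`).
#' @return data.frame: `source_id`, `edge_type`, `target_id`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(source_id = character(0), edge_type = character(0),
                      target_id = character(0), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(source_id = parts[, 1L], edge_type = parts[, 2L],
             target_id = parts[, 3L], stringsAsFactors = FALSE)
}

#' Evaluate recovered triads against planted truth
#'
#' @param triads Recovered triads (any data.frame with `lncrna_id`,
#'   `mirna_id`, `mrna_id`).
#' @param true_triads Planted triads (same columns).
#' @return List: `recall`, `precision`, `n_recovered`, `n_true`.
#' @export
evaluate_triads <- function(triads, true_triads) {
  key <- function(d) paste(d$lncrna_id, d$mirna_id, d$mrna_id)
  got <- unique(key(triads))
  want <- unique(key(true_triads))
  tp <- length(intersect(got, want))
  list(recall = if (length(want) == 0L) NA_real_ else tp / length(want),
       precision = if (length(got) == 0L) NA_real_ else tp / length(got),
       n_recovered = length(got), n_true = length(want))
}
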