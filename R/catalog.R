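#' Transcript catalogs
#'
#' A `transcript_catalog` is a data.frame with one row per transcript and
#' columns:
#' \describe{
#'   \item{transcript_id, gene_id, chrom, strand}{identifiers; strand
#'     `"+"` or `"-"`.}
#'   \item{biotype}{declared biotype (`"protein_coding"`, `"unknown"`, ...).}
#'   \item{exons}{list column; per transcript an integer matrix with columns
#'     `start`, `end` holding 0-based half-open genomic exon intervals,
#'     sorted and non-overlapping.}
#'   \item{sequence}{spliced transcript sequence (DNA, 5' to 3').}
#'   \item{length}{spliced length; equals both the exon-length sum and
#'     `nchar(sequence)`.}
#'   \item{cds_start, cds_end}{0-based half-open CDS span in transcript
#'     coordinates (`NA` for transcripts without an annotated CDS); the
#'     3' UTR is `[cds_end, length)`.}
#' }
#'
#' @param df data.frame with the columns above.
#' @return The validated catalog, classed `transcript_catalog`.
#' @export
transcript_catalog <- function(df) {
  needed <- c("transcript_id", "gene_id", "chrom", "strand", "biotype",
              "exons", "sequence", "length", "cds_start", "cds_end")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("catalog lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("transcript_catalog", "data.frame")
  validate_catalog(df)
  df
}

validate_catalog <- function(catalog) {
  if (nrow(catalog) == 0L) return(invisible(TRUE))
  stopifnot(all(catalog$strand %in% c("+", "-")))
  for (i in seq_len(nrow(catalog))) {
    ex <- catalog$exons[[i]]
    stopifnot(is.matrix(ex), ncol(ex) == 2L)
    if (nrow(ex) > 1L) {
      stopifnot(all(diff(ex[, 1L]) > 0), all(ex[-1L, 1L] >= ex[-nrow(ex), 2L]))
    }
    stopifnot(all(ex[, 2L] > ex[, 1L]))
    len <- sum(ex[, 2L] - ex[, 1L])
    if (len != catalog$length[i] || len != nchar(catalog$sequence[i])) {
      stop("transcript ", catalog$transcript_id[i],
           ": exon lengths, length field and sequence length disagree",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.transcript_catalog <- function(x, ...) {
  cat("transcript_catalog:", nrow(x), "transcripts on",
      length(unique(x$chrom)), "chromosome(s);",
      sum(x$biotype == "protein_coding"), "declared protein-coding\n")
  invisible(x)
}

#' Load a transcript catalog from GTF + transcript FASTA
#'
#' GTF coordinates (1-based, inclusive) are converted to the 0-based
#' half-open convention used internally. Every transcript in the GTF must
#' have a sequence in the FASTA; CDS features, when present, are mapped to
#' transcript coordinates so the 3' UTR is recoverable.
#'
#' @param gtf_path Path to a GTF with `exon` (and optionally `CDS`) features
#'   carrying `transcript_id`, `gene_id` and `gene_biotype` attributes.
#' @param fasta_path Path to a FASTA of spliced transcript sequences named
#'   by `transcript_id`.
#' @return A [transcript_catalog()].
#' @export
load_catalog <- function(gtf_path, fasta_path) {
  check_files_exist(gtf_path, fasta_path)
  raw <- readLines(gtf_path)
  if (length(raw[nzchar(raw) & !startsWith(raw, "#")]) == 0L) {
    return(transcript_catalog(empty_catalog_df()))
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  seq_map <- stats::setNames(as.character(seqs),
                             sub("\\s.*$", "", names(seqs)))
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) {
    return(transcript_catalog(empty_catalog_df()))
  }
  cds <- gr[gr$type == "CDS"]
  tx_ids <- unique(ex$transcript_id)
  rows <- lapply(tx_ids, function(tid) {
    e <- ex[ex$transcript_id == tid]
    strand <- as.character(GenomicRanges::strand(e))[1L]
    m <- cbind(start = GenomicRanges::start(e) - 1L,
               end = GenomicRanges::end(e))
    m <- m[order(m[, 1L]), , drop = FALSE]
    if (!(tid %in% names(seq_map))) {
      stop("no FASTA sequence for transcript ", tid, call. = FALSE)
    }
    seq <- seq_map[[tid]]
    biotype <- if (!is.null(e$gene_biotype)) e$gene_biotype[1L] else "unknown"
    if (is.na(biotype)) biotype <- "unknown"
    cds_tx <- c(NA_integer_, NA_integer_)
    ctx <- cds[cds$transcript_id == tid]
    if (length(ctx) > 0L) {
      gmin <- min(GenomicRanges::start(ctx)) - 1L
      gmax <- max(GenomicRanges::end(ctx))
      cds_tx <- cds_span_to_tx(gmin, gmax, m, strand)
    }
    data.frame(
      transcript_id = tid,
      gene_id = e$gene_id[1L],
      chrom = as.character(GenomicRanges::seqnames(e))[1L],
      strand = strand,
      biotype = biotype,
      sequence = seq,
      length = sum(m[, 2L] - m[, 1L]),
      cds_start = cds_tx[1L],
      cds_end = cds_tx[2L],
      stringsAsFactors = FALSE
    ) -> row
    row$exons <- list(m)
    row
  })
  df <- do.call(rbind, rows)
  df <- df[c("transcript_id", "gene_id", "chrom", "strand", "biotype",
             "exons", "sequence", "length", "cds_start", "cds_end")]
  rownames(df) <- NULL
  transcript_catalog(df)
}

empty_catalog_df <- function() {
  data.frame(
    transcript_id = character(0), gene_id = character(0),
    chrom = character(0), strand = character(0), biotype = character(0),
    exons = I(list()), sequence = character(0), length = integer(0),
    cds_start = integer(0), cds_end = integer(0),
    stringsAsFactors = FALSE
  )
}

# Map a genomic base (0-based) to its transcript coordinate given sorted
# 0-based half-open exons and strand.
genomic_to_tx <- function(gpos, exons, strand) {
  widths <- exons[, 2L] - exons[, 1L]
  hit <- which(gpos >= exons[, 1L] & gpos < exons[, 2L])
  if (length(hit) != 1L) stop("position not exonic", call. = FALSE)
  plus_coord <- sum(widths[seq_len(hit - 1L)]) + (gpos - exons[hit, 1L])
  if (strand == "+") plus_coord else sum(widths) - 1L - plus_coord
}

# Genomic CDS span [gmin, gmax) -> transcript-relative half-open span.
cds_span_to_tx <- function(gmin, gmax, exons, strand) {
  a <- genomic_to_tx(gmin, exons, strand)
  b <- genomic_to_tx(gmax - 1L, exons, strand)
  c(min(a, b), max(a, b) + 1L)
}

# Transcript-relative half-open interval -> list of genomic intervals
# (0-based half-open), used when writing CDS features back to GTF.
tx_to_genomic <- function(tstart, tend, exons, strand) {
  widths <- exons[, 2L] - exons[, 1L]
  total <- sum(widths)
  if (strand == "-") {
    tmp <- total - tend
    tend <- total - tstart
    tstart <- tmp
  }
  out <- list()
  cum <- 0L
  for (i in seq_len(nrow(exons))) {
    lo <- max(tstart, cum)
    hi <- min(tend, cum + widths[i])
    if (hi > lo) {
      out[[length(out) + 1L]] <- c(exons[i, 1L] + (lo - cum),
                                   exons[i, 1L] + (hi - cum))
    }
    cum <- cum + widths[i]
  }
  out
}

#' Write a transcript catalog as GTF and FASTA
#'
#' Emits 1-based inclusive GTF `transcript`, `exon` and (for transcripts with
#' a CDS) `CDS` features with `transcript_id`, `gene_id` and `gene_biotype`
#' attributes, plus the spliced transcript sequences as FASTA.
#'
#' @param catalog A [transcript_catalog()].
#' @param gtf_path,fasta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_catalog <- function(catalog, gtf_path, fasta_path) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  lines <- character(0)
  for (i in seq_len(nrow(catalog))) {
    tid <- catalog$transcript_id[i]
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
      catalog$gene_id[i], tid, catalog$biotype[i])
    ex <- catalog$exons[[i]]
    span <- c(min(ex[, 1L]), max(ex[, 2L]))
    mk <- function(type, s0, e0) {
      paste(catalog$chrom[i], "cernaforge", type, s0 + 1L, e0, ".",
            catalog$strand[i], ".", attrs, sep = "\t")
    }
    lines <- c(lines, mk("transcript", span[1L], span[2L]))
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, mk("exon", ex[j, 1L], ex[j, 2L]))
    }
    if (!is.na(catalog$cds_start[i])) {
      for (iv in tx_to_genomic(catalog$cds_start[i], catalog$cds_end[i],
                               ex, catalog$strand[i])) {
        lines <- c(lines, mk("CDS", iv[1L], iv[2L]))
      }
    }
  }
  writeLines(lines, gtf_path)
  write_fasta(stats::setNames(catalog$sequence, catalog$transcript_id),
              fasta_path)
  invisible(c(gtf_path, fasta_path))
}

#' Write named sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(dna(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' lncRNA filter cascade
#'
#' Keeps a transcript iff all four criteria hold: spliced length strictly
#' greater than `min_length`; at least `min_exons` exons; declared biotype
#' not in the excluded set (known coding and structural RNA classes); and a
#' unanimous noncoding verdict from all coding-potential scorers (a
#' transcript called coding by any scorer is discarded).
#'
#' @param catalog A [transcript_catalog()].
#' @param reports Per-transcript reports from [coding_potential_reports()].
#' @param min_length Length threshold (strict `>`; default 200 nt).
#' @param min_exons Minimum exon count (default 2).
#' @param excluded_biotypes Biotypes rejected outright.
#' @return Character vector of transcript ids passing the cascade.
#' @export
filter_lncrnas <- function(catalog, reports,
                           min_length = 200L, min_exons = 2L,
                           excluded_biotypes = c("protein_coding", "miRNA",
                                                 "tRNA", "snoRNA", "rRNA",
                                                 "pseudogene")) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  if (!all(catalog$transcript_id %in% reports$transcript_id)) {
    stop("a coding-potential report is required for every transcript",
         call. = FALSE)
  }
  rep_idx <- match(catalog$transcript_id, reports$transcript_id)
  n_exons <- vapply(catalog$exons, nrow, integer(1))
  keep <- catalog$length > min_length &
    n_exons >= min_exons &
    !(catalog$biotype %in% excluded_biotypes) &
    reports$orf_verdict[rep_idx] == "noncoding" &
    reports$hexamer_verdict[rep_idx] == "noncoding"
  catalog$transcript_id[keep]
}

#' Classify lncRNAs as antisense or intergenic
#'
#' A lncRNA is antisense iff at least one of its exonic bases overlaps an
#' exon of a declared protein-coding transcript on the opposite strand of
#' the same chromosome; otherwise it is intergenic.
#'
#' @param catalog A [transcript_catalog()].
#' @param lncrna_ids Transcript ids that passed [filter_lncrnas()].
#' @return data.frame with `transcript_id` and `class`
#'   (`"antisense"`/`"intergenic"`).
#' @export
classify_lncrnas <- function(catalog, lncrna_ids) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  coding <- catalog[catalog$biotype == "protein_coding", , drop = FALSE]
  coding_gr <- exons_granges(coding)
  cls <- vapply(lncrna_ids, function(tid) {
    i <- match(tid, catalog$transcript_id)
    ex <- catalog$exons[[i]]
    gr <- GenomicRanges::GRanges(
      seqnames = catalog$chrom[i],
      ranges = IRanges::IRanges(start = ex[, 1L] + 1L, end = ex[, 2L]),
      strand = flip_strand(catalog$strand[i]))
    if (length(coding_gr) > 0 &&
        sum(GenomicRanges::countOverlaps(gr, coding_gr)) > 0) {
      "antisense"
    } else {
      "intergenic"
    }
  }, character(1), USE.NAMES = FALSE)
  data.frame(transcript_id = lncrna_ids, class = cls,
             stringsAsFactors = FALSE)
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# All exons of a catalog subset as a stranded GRanges (1-based).
exons_granges <- function(catalog) {
  if (nrow(catalog) == 0L) return(GenomicRanges::GRanges())
  parts <- lapply(seq_len(nrow(catalog)), function(i) {
    ex <- catalog$exons[[i]]
    GenomicRanges::GRanges(
      seqnames = catalog$chrom[i],
      ranges = IRanges::IRanges(start = ex[, 1L] + 1L, end = ex[, 2L]),
      strand = catalog$strand[i])
  })
  do.call(c, parts)
}

#' Genomic-feature summary of a transcript set
#'
#' @param ids Transcript ids to summarise (nonempty).
#' @param catalog A [transcript_catalog()].
#' @param reports Optional [coding_potential_reports()] output; when given,
#'   ORF lengths are included.
#' @return A list with `summary` (one-row data.frame: `n`, `mean_length`,
#'   `median_length`, `mean_exons`, `mean_orf_nt`) and `features` (one row
#'   per transcript for external plotting).
#' @export
feature_summary <- function(ids, catalog, reports = NULL) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  if (length(ids) == 0L) stop("empty feature set", call. = FALSE)
  idx <- match(ids, catalog$transcript_id)
  if (anyNA(idx)) {
    stop("ids absent from catalog: ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  lens <- catalog$length[idx]
  exn <- vapply(catalog$exons[idx], nrow, integer(1))
  orf <- if (!is.null(reports)) {
    reports$longest_orf_nt[match(ids, reports$transcript_id)]
  } else {
    rep(NA_integer_, length(ids))
  }
  feats <- data.frame(transcript_id = ids, length = lens, n_exons = exn,
                      orf_nt = orf, stringsAsFactors = FALSE)
  list(
    summary = data.frame(
      n = length(ids),
      mean_length = mean(lens),
      median_length = stats::median(lens),
      mean_exons = mean(exn),
      mean_orf_nt = if (all(is.na(orf))) NA_real_ else mean(orf)
    ),
    features = feats
  )
}
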