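#' Longest open reading frame of a transcript sequence
#'
#' Scans the three forward frames of the (already stranded, spliced)
#' transcript sequence for the longest ATG-to-stop open reading frame.
#' The reported length is in nucleotides and includes the stop codon.
#' RNA input (U) is accepted and treated as T.
#'
#' @param sequence A single nucleotide string (A/C/G/T/U, case-insensitive).
#' @return A list with `length_nt` (0 if the sequence contains no complete
#'   ORF), `frame` (0, 1 or 2; `NA` if none) and `start` (0-based position of
#'   the A of the start codon; `NA` if none).
#' @examples
#' longest_orf("ATGTAA")$length_nt  # 6
#' longest_orf("CCCCCC")$length_nt  # 0
#' @export
longest_orf <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- dna(sequence)
  if (nchar(seq) > 0 && grepl("[^ACGT]", seq)) {
    stop("sequence contains non-ACGTU characters", call. = FALSE)
  }
  stops <- c("TAA", "TAG", "TGA")
  best <- list(length_nt = 0L, frame = NA_integer_, start = NA_integer_)
  n <- nchar(seq)
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3L
    if (n_codons < 2L) next
    starts1 <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(seq, starts1, starts1 + 2L)
    atg_idx <- which(codons == "ATG")
    stop_idx <- which(codons %in% stops)
    if (length(atg_idx) == 0L || length(stop_idx) == 0L) next
    for (a in atg_idx) {
      s <- stop_idx[stop_idx > a]
      if (length(s) == 0L) next
      len <- (s[1L] - a + 1L) * 3L
      if (len > best$length_nt) {
        best <- list(length_nt = len, frame = frame,
                     start = starts1[a] - 1L)
      }
    }
  }
  best
}

#' Train an in-frame hexamer usage table from a coding sequence set
#'
#' Builds the log-ratio table used by the hexamer coding-potential scorer:
#' log of in-frame hexamer frequency in the coding sequences (hexamers read
#' in the frame of each sequence's longest ORF) over the same statistic for
#' per-sequence shuffled versions of those sequences. Frequencies use a
#' pseudocount of 1 on each of the 4096 hexamers. Deterministic: the shuffle
#' is driven by `shuffle_seed` only.
#'
#' @param sequences Character vector of coding transcript sequences.
#' @param shuffle_seed Integer seed for the background shuffle.
#' @return Named numeric vector of length 4096 (log-ratios), class
#'   `hexamer_table`.
#' @export
train_hexamer_table <- function(sequences, shuffle_seed = 0L) {
  stopifnot(is.character(sequences))
  shuffled <- with_seed(shuffle_seed, {
    vapply(sequences, function(s) {
      paste(sample(strsplit(dna(s), "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  tab <- log(hexamer_freqs(sequences)) - log(hexamer_freqs(shuffled))
  structure(tab, class = "hexamer_table")
}

# In-frame hexamer relative frequencies (pseudocount 1) over a sequence set.
# Frame per sequence = frame of its longest ORF, restricted to the ORF span;
# sequences without an ORF contribute frame-0 hexamers over their whole length.
hexamer_freqs <- function(sequences) {
  all_hex <- all_hexamers()
  counts <- stats::setNames(rep(1, 4096), all_hex)  # pseudocount
  for (s in sequences) {
    s <- dna(s)
    hx <- inframe_hexamers(s)
    if (length(hx) == 0L) next
    t0 <- table(hx)
    counts[names(t0)] <- counts[names(t0)] + as.vector(t0)
  }
  counts / sum(counts)
}

all_hexamers <- function() {
  g <- expand.grid(rep(list(DNA_BASES), 6), stringsAsFactors = FALSE)
  # column 1 varies fastest; order is irrelevant as the table is named
  do.call(paste0, g)
}

# Hexamers stepped by codon (3 nt) in the reading frame of the longest ORF.
inframe_hexamers <- function(seq) {
  orf <- longest_orf(seq)
  if (orf$length_nt >= 6L) {
    region <- substr(seq, orf$start + 1L, orf$start + orf$length_nt)
  } else {
    region <- seq
  }
  n <- nchar(region)
  if (n < 6L) return(character(0))
  starts <- seq.int(1L, n - 5L, by = 3L)
  hx <- substring(region, starts, starts + 5L)
  hx[!grepl("[^ACGT]", hx)]
}

#' Hexamer log-ratio score of one sequence
#'
#' Mean in-frame hexamer log-ratio under a trained [train_hexamer_table()]
#' table. Positive scores indicate coding-like hexamer usage. Sequences
#' shorter than 6 nt score 0.
#'
#' @param sequence Nucleotide string.
#' @param hexamer_table A `hexamer_table` from [train_hexamer_table()].
#' @return Numeric scalar.
#' @export
hexamer_score <- function(sequence, hexamer_table) {
  stopifnot(inherits(hexamer_table, "hexamer_table"))
  hx <- inframe_hexamers(dna(sequence))
  if (length(hx) == 0L) return(0)
  mean(unclass(hexamer_table)[hx])
}

#' Coding-potential report for a transcript
#'
#' Runs the two internal coding-potential scorers and reports both verdicts.
#' The ORF scorer votes coding iff the longest ORF is at least `orf_min` nt
#' long AND covers at least `cov_min` of the transcript. The hexamer scorer
#' votes coding iff the mean in-frame hexamer log-ratio is positive.
#' Sequences shorter than 6 nt get hexamer score 0 and a noncoding verdict.
#'
#' @param sequence Transcript sequence (nucleotide string).
#' @param hexamer_table Trained table from [train_hexamer_table()].
#' @param transcript_id Optional identifier carried into the report.
#' @param orf_min Minimum ORF length (nt) for a coding ORF verdict.
#' @param cov_min Minimum ORF coverage (fraction of transcript length).
#' @return A one-row data.frame: `transcript_id`, `longest_orf_nt`,
#'   `orf_coverage`, `hexamer_score`, `orf_verdict`, `hexamer_verdict`
#'   (each verdict `"coding"` or `"noncoding"`).
#' @export
coding_potential <- function(sequence, hexamer_table,
                             transcript_id = NA_character_,
                             orf_min = 300L, cov_min = 0.35) {
  len <- nchar(sequence)
  orf <- longest_orf(sequence)
  coverage <- if (len > 0) orf$length_nt / len else 0
  hs <- hexamer_score(sequence, hexamer_table)
  data.frame(
    transcript_id = transcript_id,
    longest_orf_nt = orf$length_nt,
    orf_coverage = coverage,
    hexamer_score = hs,
    orf_verdict = if (orf$length_nt >= orf_min && coverage >= cov_min)
      "coding" else "noncoding",
    hexamer_verdict = if (hs > 0) "coding" else "noncoding",
    stringsAsFactors = FALSE
  )
}

#' Coding-potential reports for every transcript in a catalog
#'
#' @param catalog A `transcript_catalog` (see [load_catalog()]).
#' @param hexamer_table Trained table; defaults to training on the catalog's
#'   declared protein-coding transcripts.
#' @inheritParams coding_potential
#' @return data.frame with one row per transcript.
#' @export
coding_potential_reports <- function(catalog, hexamer_table = NULL,
                                     orf_min = 300L, cov_min = 0.35) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  if (is.null(hexamer_table)) {
    coding_seqs <- catalog$sequence[catalog$biotype == "protein_coding"]
    if (length(coding_seqs) == 0L) {
      stop("no declared protein-coding transcripts to train the hexamer ",
           "table on; pass hexamer_table explicitly", call. = FALSE)
    }
    hexamer_table <- train_hexamer_table(coding_seqs)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(catalog)), function(i) {
    coding_potential(catalog$sequence[i], hexamer_table,
                     transcript_id = catalog$transcript_id[i],
                     orf_min = orf_min, cov_min = cov_min)
  }))
  rownames(out) <- NULL
  out
}
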