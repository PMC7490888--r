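#' Simulation configuration
#'
#' Holds every knob of the synthetic ceRNA study generator. Defaults emulate
#' the study design the pipeline is built for: four fertility groups
#' (luteal/follicular phase crossed with high/low fecundity) with four
#' biological replicates each, overdispersed RNA-seq counts, and planted
#' differential-expression effects that clear the |log2 fold change| >= 1
#' calling threshold.
#'
#' @param n_coding_genes Number of protein-coding genes (one transcript each).
#' @param n_lncrnas Number of lncRNAs (one transcript each).
#' @param n_mirnas Number of mature miRNAs.
#' @param n_true_triads Number of planted ceRNA triads
#'   (lncRNA, miRNA, mRNA); must not exceed any of the three pools.
#' @param n_de_features_per_contrast Extra (non-triad) features given a
#'   differential-expression effect in each contrast.
#' @param de_log2fc_effect Planted effect size in log2 units; must be >= 1 so
#'   planted effects clear the fold-change threshold.
#' @param replicates_per_group Biological replicates per group.
#' @param groups Group labels; the first two and last two form the two
#'   high-vs-low contrasts.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0.
#' @param library_size_mean Expected per-sample total count.
#' @param antisense_fraction Fraction of lncRNAs placed antisense to a
#'   coding gene; the rest are intergenic.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_coding_genes = 60L,
                       n_lncrnas = 30L,
                       n_mirnas = 10L,
                       n_true_triads = 5L,
                       n_de_features_per_contrast = 10L,
                       de_log2fc_effect = 2,
                       replicates_per_group = 4L,
                       groups = c("LH", "LL", "FH", "FL"),
                       nb_dispersion = 0.05,
                       library_size_mean = 5e5,
                       antisense_fraction = 0.26,
                       seed = 1L) {
  cfg <- list(
    n_coding_genes = as.integer(n_coding_genes),
    n_lncrnas = as.integer(n_lncrnas),
    n_mirnas = as.integer(n_mirnas),
    n_true_triads = as.integer(n_true_triads),
    n_de_features_per_contrast = as.integer(n_de_features_per_contrast),
    de_log2fc_effect = de_log2fc_effect,
    replicates_per_group = as.integer(replicates_per_group),
    groups = groups,
    nb_dispersion = nb_dispersion,
    library_size_mean = library_size_mean,
    antisense_fraction = antisense_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_coding_genes", "n_lncrnas", "n_mirnas", "n_true_triads",
              "n_de_features_per_contrast", "replicates_per_group")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) {
      stop(f, " must be a non-negative count", call. = FALSE)
    }
  }
  if (cfg$n_true_triads > 0 && cfg$de_log2fc_effect < 1) {
    stop("de_log2fc_effect must be >= 1 so planted effects clear the ",
         "|log2FC| >= 1 threshold", call. = FALSE)
  }
  if (cfg$n_true_triads > min(cfg$n_lncrnas, cfg$n_mirnas,
                              cfg$n_coding_genes)) {
    stop("n_true_triads exceeds the smallest feature pool", call. = FALSE)
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (length(cfg$groups) < 2L) stop("need at least two groups", call. = FALSE)
  invisible(TRUE)
}

#' Contrasts implied by a group vector
#'
#' Groups are paired in order: (1st vs 2nd), (3rd vs 4th), ... with the first
#' member of each pair the "high" group of its contrast.
#' @param groups Character vector of group labels.
#' @return Character vector of contrast names like `"LH_vs_LL"`.
#' @export
sim_contrasts <- function(groups = c("LH", "LL", "FH", "FL")) {
  n <- length(groups) %/% 2L
  vapply(seq_len(n), function(i) {
    paste0(groups[2L * i - 1L], "_vs_", groups[2L * i])
  }, character(1))
}

#' @keywords internal
#' @noRd
contrast_groups <- function(contrast) strsplit(contrast, "_vs_")[[1]]

## ---------------------------------------------------------------------------
## Sequence construction

# Biased sense-codon weights: a fixed subset of codons is strongly favoured so
# coding ORFs have a distinctive in-frame hexamer signature that the hexamer
# scorer can learn.
coding_codon_pool <- function() {
  bases <- DNA_BASES
  codons <- as.vector(outer(as.vector(outer(bases, bases, paste0)),
                            bases, paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  favoured <- c("GCC", "GAG", "AAG", "CTG", "GAC", "GGC", "ATC", "CAG",
                "GTG", "TTC", "AGC", "ACC", "CCC", "TAC", "AAC", "GAA",
                "CGG", "TGC", "CAC", "TCC")
  weights <- ifelse(codons %in% favoured, 8, 1)
  list(codons = codons, weights = weights / sum(weights))
}

random_coding_sequence <- function(pool) {
  n_codons <- sample(110:300, 1L)
  cds <- paste0("ATG",
                paste(sample(pool$codons, n_codons, replace = TRUE,
                             prob = pool$weights), collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1L))
  utr5 <- random_dna(sample(20:120, 1L))
  utr3 <- random_dna(sample(80:300, 1L))
  list(seq = paste0(utr5, cds, utr3),
       cds_start = nchar(utr5),
       cds_end = nchar(utr5) + nchar(cds))
}

# Position lists (1-based starts) of any of `kmers` in `seq`.
kmer_hits <- function(seq, kmers) {
  out <- lapply(kmers, function(k) str_find_all(k, seq))
  data.frame(kmer = rep(kmers, lengths(out)), start = unlist(out),
             stringsAsFactors = FALSE)
}

# Remove every occurrence of `kmers` from `seq` by single-base mutation while
# `check_fn(seq)` stays TRUE and `protected` (1-based positions) are untouched.
scrub_kmers <- function(seq, kmers, check_fn = function(s) TRUE,
                        protected = integer(0), max_iter = 500L) {
  if (length(kmers) == 0L) return(seq)
  live_hits <- function(s) {
    h <- kmer_hits(s, kmers)
    if (nrow(h) == 0L) return(h)
    keep <- vapply(seq_len(nrow(h)), function(i) {
      pos <- h$start[i]:(h$start[i] + nchar(h$kmer[i]) - 1L)
      any(!(pos %in% protected))  # fully-protected hits are allowed
    }, logical(1))
    h[keep, , drop = FALSE]
  }
  for (iter in seq_len(max_iter)) {
    hits <- live_hits(seq)
    if (nrow(hits) == 0L) return(seq)
    fixed <- FALSE
    for (i in seq_len(nrow(hits))) {
      pos_range <- hits$start[i]:(hits$start[i] + nchar(hits$kmer[i]) - 1L)
      pos_range <- setdiff(pos_range, protected)
      for (pos in pos_range) {
        cur <- substr(seq, pos, pos)
        for (alt in setdiff(DNA_BASES, cur)) {
          cand <- seq
          substr(cand, pos, pos) <- alt
          if (nrow(live_hits(cand)) < nrow(hits) && check_fn(cand)) {
            seq <- cand
            fixed <- TRUE
            break
          }
        }
        if (fixed) break
      }
      if (fixed) break
    }
    if (!fixed) {
      stop("could not scrub seed k-mers from a sequence", call. = FALSE)
    }
  }
  stop("k-mer scrub did not converge", call. = FALSE)
}

coding_ok <- function(seq) {
  orf <- longest_orf(seq)
  orf$length_nt >= 300L && orf$length_nt / nchar(seq) >= 0.35
}

lncrna_orf_ok <- function(seq) longest_orf(seq)$length_nt < 300L

# Random exon widths summing to `total`, each >= min_width.
split_exons <- function(total, n_exons, min_width = 30L) {
  if (n_exons == 1L) return(total)
  slack <- total - n_exons * min_width
  cuts <- as.vector(stats::rmultinom(1L, slack, rep(1 / n_exons, n_exons)))
  cuts + min_width
}

## ---------------------------------------------------------------------------
## Operations

#' Generate a synthetic transcript annotation
#'
#' Builds a seeded catalog of protein-coding transcripts and lncRNAs with
#' exon structure on both strands of one synthetic chromosome. Coding
#' transcripts carry an ORF of at least 300 nt (ORF coverage >= 0.35) built
#' from a biased codon model; lncRNAs have at least two exons, length
#' over 200 nt, no ORF reaching 300 nt, and a non-positive hexamer score
#' against the run's own coding set (enforced by rejection sampling, so
#' downstream lncRNA recovery is exact by construction). A configurable
#' fraction of lncRNAs is placed antisense to a coding gene (exonic overlap
#' on the opposite strand); the rest are intergenic. Some neighbouring gene
#' pairs are placed under 10 kb apart, including divergent pairs.
#'
#' @param config A [sim_config()].
#' @param avoid_kmers DNA k-mers (e.g. miRNA seed-site sequences) that must
#'   not occur in any generated transcript.
#' @return A [transcript_catalog()] (empty for zero-count configs).
#' @export
generate_annotation <- function(config, avoid_kmers = character(0)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_coding_genes == 0L && config$n_lncrnas == 0L) {
    return(transcript_catalog(empty_catalog_df()))
  }
  with_seed(config$seed, {
    pool <- coding_codon_pool()
    n_cod <- config$n_coding_genes
    n_lnc <- config$n_lncrnas
    n_anti <- min(round(config$antisense_fraction * n_lnc), n_cod)
    if (n_cod == 0L) n_anti <- 0L
    n_inter <- n_lnc - n_anti

    ## -- sequences ---------------------------------------------------------
    coding <- lapply(seq_len(n_cod), function(i) {
      cs <- random_coding_sequence(pool)
      cs$seq <- scrub_kmers(cs$seq, avoid_kmers, coding_ok)
      cs
    })
    hx_table <- if (n_cod > 0L) {
      train_hexamer_table(vapply(coding, `[[`, character(1), "seq"))
    } else {
      NULL
    }
    lnc_seq_ok <- function(s) {
      lncrna_orf_ok(s) && (is.null(hx_table) || hexamer_score(s, hx_table) <= 0)
    }
    lnc_seqs <- vapply(seq_len(n_lnc), function(i) {
      for (try in 1:200) {
        s <- random_dna(sample(400:2500, 1L))
        s <- tryCatch(scrub_kmers(s, avoid_kmers, lncrna_orf_ok),
                      error = function(e) NULL)
        if (!is.null(s) && lnc_seq_ok(s)) return(s)
      }
      stop("could not generate a compliant lncRNA sequence", call. = FALSE)
    }, character(1))

    ## -- genomic layout ----------------------------------------------------
    slots <- c(rep("coding", n_cod), rep("lnc", n_inter))
    slots <- sample(slots)
    cursor <- 1000L
    rows <- list()
    cod_i <- 0L
    lnc_i <- 0L
    for (slot in slots) {
      gap <- if (stats::runif(1) < 0.35) sample(300:7000, 1L) else
        sample(12000:25000, 1L)
      cursor <- cursor + gap
      strand <- sample(c("+", "-"), 1L)
      if (slot == "coding") {
        cod_i <- cod_i + 1L
        cs <- coding[[cod_i]]
        len <- nchar(cs$seq)
        n_ex <- sample(1:4, 1L)
        widths <- split_exons(len, n_ex)
        starts <- cursor + c(0L, cumsum(widths[-n_ex] +
                                          sample(100:1500, max(n_ex - 1L, 1L),
                                                 replace = TRUE)[seq_len(max(n_ex - 1L, 0L))]))
        ex <- cbind(start = as.integer(starts),
                    end = as.integer(starts + widths))
        id <- sprintf("TCOD%04d", cod_i)
        rows[[length(rows) + 1L]] <- list(
          transcript_id = id, gene_id = sprintf("GCOD%04d", cod_i),
          chrom = "chr1", strand = strand, biotype = "protein_coding",
          exons = ex, sequence = cs$seq, length = len,
          cds_start = cs$cds_start, cds_end = cs$cds_end)
        cursor <- max(ex[, 2L])
      } else {
        lnc_i <- lnc_i + 1L
        s <- lnc_seqs[lnc_i]
        len <- nchar(s)
        n_ex <- sample(2:4, 1L)
        widths <- split_exons(len, n_ex)
        starts <- cursor + c(0L, cumsum(widths[-n_ex] +
                                          sample(100:1500, n_ex - 1L,
                                                 replace = TRUE)))
        ex <- cbind(start = as.integer(starts),
                    end = as.integer(starts + widths))
        id <- sprintf("TLNC%04d", lnc_i)
        rows[[length(rows) + 1L]] <- list(
          transcript_id = id, gene_id = sprintf("GLNC%04d", lnc_i),
          chrom = "chr1", strand = strand, biotype = "unknown",
          exons = ex, sequence = s, length = len,
          cds_start = NA_integer_, cds_end = NA_integer_)
        cursor <- max(ex[, 2L])
      }
    }

    ## -- antisense lncRNAs over random coding hosts ------------------------
    if (n_anti > 0L) {
      host_idx <- sample(which(vapply(rows, function(r)
        r$biotype == "protein_coding", logical(1))), n_anti)
      for (k in seq_len(n_anti)) {
        lnc_i <- lnc_i + 1L
        host <- rows[[host_idx[k]]]
        s <- lnc_seqs[lnc_i]
        len <- nchar(s)
        n_ex <- sample(2:3, 1L)
        widths <- split_exons(len, n_ex)
        hx <- host$exons[1L, ]
        st <- hx[["start"]] + sample(0:max(0L, hx[["end"]] - hx[["start"]] - 40L), 1L)
        starts <- st + c(0L, cumsum(widths[-n_ex] +
                                      sample(50:200, n_ex - 1L,
                                             replace = TRUE)))
        ex <- cbind(start = as.integer(starts),
                    end = as.integer(starts + widths))
        rows[[length(rows) + 1L]] <- list(
          transcript_id = sprintf("TLNC%04d", lnc_i),
          gene_id = sprintf("GLNC%04d", lnc_i),
          chrom = "chr1", strand = flip_strand(host$strand),
          biotype = "unknown", exons = ex, sequence = s, length = len,
          cds_start = NA_integer_, cds_end = NA_integer_)
      }
    }

    ## -- guarantee at least one close divergent coding pair ----------------
    rows <- ensure_divergent_pair(rows)

    df <- do.call(rbind, lapply(rows, function(r) {
      d <- data.frame(transcript_id = r$transcript_id, gene_id = r$gene_id,
                      chrom = r$chrom, strand = r$strand,
                      biotype = r$biotype, sequence = r$sequence,
                      length = r$length, cds_start = r$cds_start,
                      cds_end = r$cds_end, stringsAsFactors = FALSE)
      d$exons <- list(r$exons)
      d
    }))
    df <- df[c("transcript_id", "gene_id", "chrom", "strand", "biotype",
               "exons", "sequence", "length", "cds_start", "cds_end")]
    rownames(df) <- NULL
    transcript_catalog(df)
  })
}

# If no coding-coding pair closer than 10 kb is divergent, flip strands of
# the closest such pair to divergent orientation (left gene -, right gene +).
ensure_divergent_pair <- function(rows) {
  cod <- which(vapply(rows, function(r) r$biotype == "protein_coding",
                      logical(1)))
  if (length(cod) < 2L) return(rows)
  spans <- t(vapply(cod, function(i) {
    c(min(rows[[i]]$exons[, 1L]), max(rows[[i]]$exons[, 2L]))
  }, numeric(2)))
  ord <- cod[order(spans[, 1L])]
  spans <- spans[order(spans[, 1L]), , drop = FALSE]
  gaps <- spans[-1L, 1L] - spans[-nrow(spans), 2L]
  close <- which(gaps > 0 & gaps < 10000)
  if (length(close) == 0L) return(rows)
  has_div <- any(vapply(close, function(j) {
    rows[[ord[j]]]$strand == "-" && rows[[ord[j + 1L]]]$strand == "+"
  }, logical(1)))
  if (!has_div) {
    j <- close[which.min(gaps[close])]
    rows[[ord[j]]]$strand <- "-"
    rows[[ord[j + 1L]]]$strand <- "+"
  }
  rows
}

#' Generate a synthetic mature miRNA set
#'
#' Mature sequences are 20-24 nt (mode 22 nt) over the RNA alphabet with
#' position 1 fixed to U (so a perfectly complementary target shows the
#' canonical A opposite position 1). Seeds (nucleotides 2-8) are unique
#' across the set, and no miRNA's full-length reverse complement contains
#' another miRNA's seed site, so planted perfect-duplex sites can never
#' create cross-miRNA seed matches.
#'
#' @param config A [sim_config()].
#' @return data.frame with `mirna_id`, `mature_seq` (RNA), `seed` (RNA,
#'   positions 2-8).
#' @export
generate_mirnas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_mirnas
  if (n == 0L) {
    return(data.frame(mirna_id = character(0), mature_seq = character(0),
                      seed = character(0), stringsAsFactors = FALSE))
  }
  with_seed(config$seed + 1L, {
    rna <- c("A", "C", "G", "U")
    lens <- sample(20:24, n, replace = TRUE,
                   prob = c(0.1, 0.2, 0.4, 0.2, 0.1))
    seqs <- character(0)
    seed_rcs <- character(0)  # DNA reverse complements of accepted seeds
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:500) {
        cand <- paste0("U", paste(sample(rna, lens[i] - 1L, replace = TRUE),
                                  collapse = ""))
        seed <- substr(cand, 2L, 8L)
        seed_rc <- revcomp(seed)
        mature_rc <- revcomp(cand)
        clash <- seed %in% substr(seqs, 2L, 8L) ||
          any(vapply(seed_rcs, grepl, logical(1), x = mature_rc,
                     fixed = TRUE)) ||
          any(vapply(seqs, function(s) grepl(seed_rc, revcomp(s),
                                             fixed = TRUE), logical(1)))
        if (!clash) {
          seqs <- c(seqs, cand)
          seed_rcs <- c(seed_rcs, seed_rc)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not draw a compatible miRNA set", call. = FALSE)
    }
    data.frame(mirna_id = sprintf("miR-%03d", seq_len(n)),
               mature_seq = seqs,
               seed = substr(seqs, 2L, 8L),
               stringsAsFactors = FALSE)
  })
}

#' Plant ceRNA triads, MRE sites and differential-expression effects
#'
#' For each true triad (lncRNA, miRNA, mRNA) a full-length
#' perfect-complement site for the shared miRNA (8mer seed class) is written
#' into the lncRNA sequence and into the mRNA 3' UTR. Triad members receive
#' signed log2 effects in the triad's contrast, the miRNA with sign opposite
#' to its two partners; additional non-triad features receive effects of
#' random sign. Triads alternate between the design's contrasts. Sequence
#' edits preserve each class's coding-potential constraints, and junction
#' artefacts (accidental seed matches created by the insertions) are
#' scrubbed.
#'
#' @param catalog A [transcript_catalog()] from [generate_annotation()].
#' @param mirnas miRNA set from [generate_mirnas()].
#' @param config A [sim_config()].
#' @param hexamer_table Optional trained table used to re-check lncRNA
#'   hexamer scores after editing (defaults to training on the catalog's
#'   coding set).
#' @return A list with `catalog` (edited sequences) and `truth`, the ground
#'   truth: `true_triads` (lncrna_id, mirna_id, mrna_id, contrast, sign),
#'   `de_features` (contrast, feature_id, log2fc) and `planted_sites`
#'   (mirna_id, transcript_id, start, 0-based).
#' @export
plant_triads_and_sites <- function(catalog, mirnas, config,
                                   hexamer_table = NULL) {
  stopifnot(inherits(catalog, "transcript_catalog"),
            inherits(config, "sim_config"))
  n_triads <- config$n_true_triads
  empty_truth <- list(
    true_triads = data.frame(lncrna_id = character(0), mirna_id = character(0),
                             mrna_id = character(0), contrast = character(0),
                             sign = numeric(0), stringsAsFactors = FALSE),
    de_features = data.frame(contrast = character(0), feature_id = character(0),
                             log2fc = numeric(0), stringsAsFactors = FALSE),
    planted_sites = data.frame(mirna_id = character(0),
                               transcript_id = character(0),
                               start = integer(0), stringsAsFactors = FALSE))
  lnc_ids <- catalog$transcript_id[catalog$biotype != "protein_coding"]
  mrna_ids <- catalog$transcript_id[catalog$biotype == "protein_coding"]
  if (n_triads > 0 &&
      (length(lnc_ids) < n_triads || length(mrna_ids) < n_triads ||
       nrow(mirnas) < n_triads)) {
    stop("n_true_triads infeasible for this catalog/miRNA set",
         call. = FALSE)
  }
  contrasts <- sim_contrasts(config$groups)
  if (is.null(hexamer_table) && length(mrna_ids) > 0L) {
    hexamer_table <- train_hexamer_table(
      catalog$sequence[catalog$biotype == "protein_coding"])
  }

  with_seed(config$seed + 2L, {
    truth <- empty_truth
    seed_rc <- revcomp(mirnas$seed)
    protected <- stats::setNames(vector("list", nrow(catalog)),
                                 catalog$transcript_id)
    if (n_triads > 0L) {
      tri_lnc <- sample(lnc_ids, n_triads)
      tri_mir <- sample(mirnas$mirna_id, n_triads)
      tri_mrna <- sample(mrna_ids, n_triads)
      tri_contrast <- contrasts[((seq_len(n_triads) - 1L) %%
                                   length(contrasts)) + 1L]
      tri_sign <- sample(c(-1, 1), n_triads, replace = TRUE)
      sites <- list()
      for (t in seq_len(n_triads)) {
        mir <- mirnas[mirnas$mirna_id == tri_mir[t], ]
        site_seq <- revcomp(mir$mature_seq)  # DNA, written 5'->3' on target
        for (tid in c(tri_lnc[t], tri_mrna[t])) {
          i <- match(tid, catalog$transcript_id)
          is_coding <- catalog$biotype[i] == "protein_coding"
          check_fn <- if (is_coding) coding_ok else function(s) {
            lncrna_orf_ok(s) &&
              (is.null(hexamer_table) || hexamer_score(s, hexamer_table) <= 0)
          }
          pos <- plant_site(catalog$sequence[i], site_seq, check_fn,
                            window = if (is_coding)
                              c(catalog$cds_end[i] + 1L, catalog$length[i])
                            else c(1L, catalog$length[i]),
                            protected = unlist(protected[[tid]]))
          catalog$sequence[i] <- pos$seq
          protected[[tid]] <- c(protected[[tid]],
                                list(pos$start:(pos$start + nchar(site_seq) - 1L)))
          sites[[length(sites) + 1L]] <- data.frame(
            mirna_id = tri_mir[t], transcript_id = tid,
            start = pos$start - 1L, stringsAsFactors = FALSE)
        }
      }
      truth$true_triads <- data.frame(
        lncrna_id = tri_lnc, mirna_id = tri_mir, mrna_id = tri_mrna,
        contrast = tri_contrast, sign = tri_sign, stringsAsFactors = FALSE)
      truth$planted_sites <- do.call(rbind, sites)
    }

    ## scrub junction-created seed matches (planted windows stay intact)
    target_of <- split(truth$planted_sites$transcript_id,
                       truth$planted_sites$mirna_id)
    for (i in seq_len(nrow(catalog))) {
      tid <- catalog$transcript_id[i]
      bad_kmers <- seed_rc[!vapply(mirnas$mirna_id, function(m)
        tid %in% target_of[[m]], logical(1))]
      is_coding <- catalog$biotype[i] == "protein_coding"
      check_fn <- if (is_coding) coding_ok else lncrna_orf_ok
      catalog$sequence[i] <- scrub_kmers(
        catalog$sequence[i], bad_kmers, check_fn,
        protected = unlist(protected[[tid]]))
    }
    catalog$length <- nchar(catalog$sequence)  # unchanged, but re-assert
    validate_catalog(catalog)

    ## planted effects
    de <- list()
    if (n_triads > 0L) {
      eff <- config$de_log2fc_effect
      tt <- truth$true_triads
      de[[1L]] <- data.frame(
        contrast = rep(tt$contrast, 3L),
        feature_id = c(tt$lncrna_id, tt$mrna_id, tt$mirna_id),
        log2fc = c(tt$sign * eff, tt$sign * eff, -tt$sign * eff),
        stringsAsFactors = FALSE)
    }
    triad_members <- unique(c(truth$true_triads$lncrna_id,
                              truth$true_triads$mrna_id,
                              truth$true_triads$mirna_id))
    pool <- setdiff(catalog$transcript_id, triad_members)
    for (ctr in contrasts) {
      n_extra <- min(config$n_de_features_per_contrast, length(pool))
      if (n_extra > 0L) {
        picks <- sample(pool, n_extra)
        de[[length(de) + 1L]] <- data.frame(
          contrast = ctr, feature_id = picks,
          log2fc = sample(c(-1, 1), n_extra, replace = TRUE) *
            config$de_log2fc_effect,
          stringsAsFactors = FALSE)
      }
    }
    if (length(de) > 0L) truth$de_features <- do.call(rbind, de)
    rownames(truth$de_features) <- NULL
    list(catalog = catalog, truth = truth)
  })
}

# Insert `site` into `seq` at a random admissible position within `window`
# (1-based inclusive transcript positions), avoiding `protected` positions,
# such that `check_fn` still holds. Returns list(seq, start) (1-based).
plant_site <- function(seq, site, check_fn, window, protected = integer(0)) {
  k <- nchar(site)
  lo <- window[1L]
  hi <- window[2L] - k + 1L
  if (hi < lo) stop("target region too short to plant a site", call. = FALSE)
  starts <- sample(lo:hi)
  for (st in starts) {
    if (length(protected) > 0 &&
        any((st:(st + k - 1L)) %in% protected)) next
    cand <- seq
    substr(cand, st, st + k - 1L) <- site
    if (check_fn(cand)) return(list(seq = cand, start = st))
  }
  stop("no admissible planting position found", call. = FALSE)
}

#' Simulate a count matrix and design table
#'
#' Draws negative-binomial counts for every transcript and miRNA across the
#' full design (groups x replicates). Baseline means are log-normal, scaled
#' so the expected per-sample total equals `library_size_mean`; features
#' with a planted effect have their mean multiplied by `2^log2fc` in the
#' high (first) group of their contrast, so triad miRNAs shift opposite to
#' their lncRNA/mRNA partners. Deterministic under the config seed.
#'
#' @param catalog A [transcript_catalog()].
#' @param mirnas miRNA set from [generate_mirnas()].
#' @param truth Ground truth from [plant_triads_and_sites()].
#' @param config A [sim_config()].
#' @return A list with `counts` (integer matrix, features x samples),
#'   `design` (data.frame: sample, group) and `lengths` (named feature
#'   lengths in nt, for FPKM).
#' @export
simulate_counts <- function(catalog, mirnas, truth, config) {
  stopifnot(inherits(catalog, "transcript_catalog"),
            inherits(config, "sim_config"))
  if (config$nb_dispersion <= 0) stop("nb_dispersion must be > 0",
                                      call. = FALSE)
  if (nrow(catalog) == 0L && nrow(mirnas) == 0L) {
    stop("cannot simulate counts for an empty catalog", call. = FALSE)
  }
  feature_ids <- c(catalog$transcript_id, mirnas$mirna_id)
  lengths <- c(stats::setNames(catalog$length, catalog$transcript_id),
               stats::setNames(nchar(mirnas$mature_seq), mirnas$mirna_id))
  groups <- config$groups
  reps <- config$replicates_per_group
  samples <- as.vector(vapply(groups, function(g)
    paste0(g, "_", seq_len(reps)), character(reps)))
  design <- data.frame(sample = samples,
                       group = rep(groups, each = reps),
                       stringsAsFactors = FALSE)
  with_seed(config$seed + 3L, {
    n <- length(feature_ids)
    mu0 <- pmax(stats::rlnorm(n, meanlog = log(100), sdlog = 1), 10)
    mu0 <- mu0 * config$library_size_mean / sum(mu0)
    mu <- matrix(mu0, nrow = n, ncol = nrow(design),
                 dimnames = list(feature_ids, design$sample))
    if (nrow(truth$de_features) > 0L) {
      for (r in seq_len(nrow(truth$de_features))) {
        ctr <- contrast_groups(truth$de_features$contrast[r])
        fid <- truth$de_features$feature_id[r]
        hi_samples <- design$sample[design$group == ctr[1L]]
        mu[fid, hi_samples] <- mu[fid, hi_samples] *
          2^truth$de_features$log2fc[r]
      }
    }
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu),
                     size = 1 / config$nb_dispersion),
      nrow = n, dimnames = dimnames(mu))
    list(counts = counts, design = design, lengths = lengths)
  })
}

#' Generate a complete synthetic ceRNA study
#'
#' Convenience wrapper running [generate_mirnas()], [generate_annotation()]
#' (with miRNA seed sites excluded from background sequence),
#' [plant_triads_and_sites()] and [simulate_counts()] in order.
#'
#' @param config A [sim_config()].
#' @return A list of class `cerna_dataset`: `config`, `catalog`, `mirnas`,
#'   `truth`, `counts`, `design`, `lengths`.
#' @export
simulate_cerna_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  mirnas <- generate_mirnas(config)
  avoid <- if (nrow(mirnas) > 0L) revcomp(mirnas$seed) else character(0)
  catalog <- generate_annotation(config, avoid_kmers = avoid)
  planted <- plant_triads_and_sites(catalog, mirnas, config)
  cm <- simulate_counts(planted$catalog, mirnas, planted$truth, config)
  structure(list(config = config, catalog = planted$catalog,
                 mirnas = mirnas, truth = planted$truth,
                 counts = cm$counts, design = cm$design,
                 lengths = cm$lengths),
            class = "cerna_dataset")
}

#' @export
print.cerna_dataset <- function(x, ...) {
  cat("cerna_dataset:", nrow(x$catalog), "transcripts,",
      nrow(x$mirnas), "miRNAs,", nrow(x$truth$true_triads),
      "planted triads,", ncol(x$counts), "samples\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits `annotation.gtf`, `transcripts.fa`, `mirnas.fa`, `counts.tsv`
#' (features x samples), `design.tsv` (sample, group), `lengths.tsv` and
#' `truth.json`.
#'
#' @param dataset A `cerna_dataset` from [simulate_cerna_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cerna_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_catalog(dataset$catalog, p("annotation.gtf"), p("transcripts.fa"))
  writeLines(paste0(">", dataset$mirnas$mirna_id, "\n",
                    dataset$mirnas$mature_seq), p("mirnas.fa"))
  counts_df <- data.frame(feature_id = rownames(dataset$counts),
                          dataset$counts, check.names = FALSE,
                          stringsAsFactors = FALSE)
  write_tsv(counts_df, p("counts.tsv"))
  write_tsv(dataset$design, p("design.tsv"))
  write_tsv(data.frame(feature_id = names(dataset$lengths),
                       length = unname(dataset$lengths)), p("lengths.tsv"))
  jsonlite::write_json(dataset$truth, p("truth.json"), dataframe = "columns",
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  paths <- c(gtf = p("annotation.gtf"), transcripts = p("transcripts.fa"),
             mirnas = p("mirnas.fa"), counts = p("counts.tsv"),
             design = p("design.tsv"), lengths = p("lengths.tsv"),
             truth = p("truth.json"))
  invisible(paths)
}

#' Generate a synthetic term-to-gene map
#'
#' Random gene-set annotation (GMT-like) over a gene universe, optionally
#' with one planted term whose genes are supplied by the caller so
#' enrichment of that set is detectable.
#'
#' @param genes Gene universe.
#' @param n_terms Number of random terms.
#' @param term_size_range Min/max genes per term.
#' @param planted_genes Optional character vector; when given, an extra term
#'   `"TERM_PLANTED"` containing exactly these genes is added.
#' @param seed Integer seed.
#' @return Named list mapping term id to character vector of genes.
#' @export
generate_term_map <- function(genes, n_terms = 20L,
                              term_size_range = c(5L, 25L),
                              planted_genes = NULL, seed = 1L) {
  with_seed(seed, {
    sizes <- sample(term_size_range[1L]:term_size_range[2L], n_terms,
                    replace = TRUE)
    sizes <- pmin(sizes, length(genes))
    tm <- lapply(sizes, function(k) sample(genes, k))
    names(tm) <- sprintf("TERM_%03d", seq_len(n_terms))
    if (!is.null(planted_genes)) tm$TERM_PLANTED <- planted_genes
    tm
  })
}
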