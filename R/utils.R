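## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @keywords internal
#' @noRd
dna <- function(x) toupper(chartr("Uu", "Tt", x))

#' Reverse complement of DNA/RNA strings (returned as DNA)
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", dna(x))
  vapply(strsplit(comp, "", fixed = TRUE), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Run code with a locally-set RNG seed, restoring global RNG state after.
#' All package randomness flows through this; no global state leaks.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Random DNA string of length n under the current RNG stream
#' @keywords internal
#' @noRd
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' All start positions (1-based) of fixed pattern in subject
#' @keywords internal
#' @noRd
str_find_all <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Stop unless all named files exist
#' @keywords internal
#' @noRd
check_files_exist <- function(...) {
  paths <- c(...)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("file not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @keywords internal
#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
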