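#' Read a reference genome from FASTA
#'
#' Reads a FASTA file into the tidy genome representation used throughout the
#' package: one row per contig with the upper-cased sequence and its length.
#' Only the strict nucleotide alphabet `{A, C, G, T, N}` is accepted (after
#' case folding); any other character is a parse error.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `contig`, `sequence`, `length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgTN"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  # read raw (BString) so that e.g. RNA "U" is caught instead of silently
  # translated to "T"
  dss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(dss))
  bad <- stringr::str_detect(seqs, "[^ACGTN]")
  if (any(bad)) {
    abort(paste0(
      "illegal character outside {A,C,G,T,N} in FASTA record(s): ",
      paste(names(dss)[bad], collapse = ", ")
    ))
  }
  # keep only the first word of each header, as aligners do
  nm <- stringr::str_split_fixed(names(dss), "\\s+", 2)[, 1]
  tibble(contig = nm, sequence = unname(seqs), length = unname(nchar(seqs)))
}

#' Write a genome tibble to FASTA
#'
#' @param ref Genome tibble (`contig`, `sequence`, `length`).
#' @param path Output path.
#' @param width Line width for wrapped sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path, width = 70L) {
  check_genome(ref)
  dss <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$contig))
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Read TSS/gene annotations from BED
#'
#' Reads a BED6 (or BED3) file of gene bodies or transcription start sites.
#' The transcription start site of each record is its 5' end: `start` for
#' `+` records, `end - 1` for `-` records.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `contig`, `start`, `end`, `name`, `score`,
#'   `strand`, `tss` (0-based TSS coordinate). Coordinates are 0-based
#'   half-open as in BED.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  if (ncol(x) < 3L) abort("malformed BED: fewer than 3 columns")
  x <- x[, seq_len(min(ncol(x), 6L))]
  names(x) <- c("contig", "start", "end", "name", "score", "strand")[seq_len(ncol(x))]
  if (!"name" %in% names(x)) x$name <- paste0("region_", seq_len(nrow(x)))
  if (!"score" %in% names(x)) x$score <- 0
  if (!"strand" %in% names(x)) x$strand <- "."
  x <- as_tibble(x)
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  if (any(x$end <= x$start)) abort("malformed BED: end <= start")
  x$tss <- ifelse(x$strand == "-", x$end - 1L, x$start)
  x
}

#' Write BED6 records
#'
#' @param x Tibble with `contig`, `start`, `end` and optionally `name`,
#'   `score`, `strand` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  out <- tibble(
    contig = x$contig, start = x$start, end = x$end,
    name = x$name %||% paste0("region_", seq_len(nrow(x))),
    score = x$score %||% 0,
    strand = x$strand %||% "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
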