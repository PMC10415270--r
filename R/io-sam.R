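#' Read modified-base alignments from SAM/BAM
#'
#' Loads aligned reads carrying `MM`/`ML` 5mC tags into the tidy alignment
#' representation used by the pileup and accuracy functions: one row per
#' alignment record with the stored sequence, per-base Phred qualities and
#' the decoded per-cytosine modification calls as list-columns.
#'
#' SAM text is converted to BAM on the fly via [Rsamtools::asBam()]; tag
#' decoding itself is done by [decode_mod_tags()].
#'
#' @param path Path to a SAM or BAM file.
#' @param keep_secondary Keep secondary/supplementary records (they are
#'   flagged `primary = FALSE`); by default they are retained in the tibble
#'   and excluded downstream by functions that require one record per read.
#' @return A tibble with columns `read_id`, `flag`, `contig`, `pos` (0-based
#'   leftmost reference coordinate), `strand`, `cigar`, `seq`, `qual`
#'   (list-column of integer Phred scores), `mod_calls` (list-column of
#'   tibbles with `offset`, `prob`), `primary` (logical).
#' @export
read_modbam <- function(path, keep_secondary = TRUE) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam <- if (is_sam) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  } else {
    path
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    tag = c("MM", "ML")
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(x$qname)
  if (n == 0L) {
    return(tibble(
      read_id = character(), flag = integer(), contig = character(),
      pos = integer(), strand = character(), cigar = character(),
      seq = character(), qual = list(), mod_calls = list(), primary = logical()
    ))
  }
  flag <- x$flag
  reverse <- bitwAnd(flag, 16L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  seqs <- as.character(x$seq)
  quals <- lapply(as.character(x$qual), qual_to_int)
  mm <- x$tag$MM %||% rep(NA_character_, n)
  ml <- x$tag$ML %||% rep(list(integer()), n)
  mod_calls <- lapply(seq_len(n), function(i) {
    if (is.na(mm[[i]])) return(empty_mod_calls())
    decode_mod_tags(mm[[i]], ml[[i]] %||% integer(), seqs[[i]], reverse[[i]])
  })
  out <- tibble(
    read_id = x$qname,
    flag = flag,
    contig = as.character(x$rname),
    pos = x$pos - 1L,
    strand = ifelse(reverse, "-", "+"),
    cigar = x$cigar,
    seq = seqs,
    qual = quals,
    mod_calls = mod_calls,
    primary = !secondary
  )
  if (!keep_secondary) out <- dplyr::filter(out, .data$primary)
  out
}

#' Write modified-base alignments as SAM
#'
#' Serialises the tidy alignment tibble back to SAM text with `MM`/`ML` tags
#' (re-encoded with [encode_mod_tags()]), so simulated alignments round-trip
#' through [read_modbam()].
#'
#' @param reads Alignment tibble as returned by [read_modbam()] or
#'   [simulate_ont_reads()].
#' @param ref Genome tibble providing `@SQ` headers.
#' @param path Output path (conventionally `.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, ref, path) {
  check_genome(ref)
  hdr <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", ref$contig, ref$length)
  )
  flags <- if ("flag" %in% names(reads)) reads$flag else
    ifelse(reads$strand == "-", 16L, 0L)
  lines <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    calls <- r$mod_calls[[1]]
    tags <- character()
    if (nrow(calls) > 0L) {
      enc <- encode_mod_tags(calls$offset, calls$prob, r$seq, r$strand == "-")
      tags <- c(
        paste0("MM:Z:", enc$mm),
        paste0("ML:B:C,", paste(enc$ml, collapse = ","))
      )
    } else {
      tags <- c("MM:Z:C+m;", "ML:B:C")
    }
    paste(c(
      r$read_id, flags[[i]], r$contig,
      r$pos + 1L, 60L, r$cigar, "*", 0L, 0L, r$seq, int_to_qual(r$qual[[1]]),
      tags
    ), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read raw reads from FASTQ
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return A tibble with `read_id`, `seq`, and `qual` (list-column of
#'   integer Phred scores).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  dss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- S4Vectors::mcols(dss)$qualities
  tibble(
    read_id = stringr::str_split_fixed(names(dss), "\\s+", 2)[, 1],
    seq = unname(as.character(dss)),
    qual = lapply(as.character(q), qual_to_int)
  )
}

#' Write raw reads to FASTQ
#'
#' @param reads Tibble with `read_id`, `seq`, `qual` (integer list-column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  rec <- vapply(seq_len(nrow(reads)), function(i) {
    paste0(
      "@", reads$read_id[[i]], "\n", reads$seq[[i]], "\n+\n",
      int_to_qual(reads$qual[[i]])
    )
  }, character(1))
  writeLines(rec, path)
  invisible(path)
}
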