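#' Read a bedMethyl site table
#'
#' Reads the 9+2 column bedMethyl dialect (as emitted by modbam2bed-style
#' tools and by [write_bedmethyl()]): BED9 fields followed by valid coverage
#' and percent methylated.
#'
#' @param path Path to a tab-separated bedMethyl file.
#' @return A tibble with columns `contig`, `start`, `end`, `name`, `score`,
#'   `strand`, `coverage`, `pct_methylated`. Coordinates are 0-based
#'   half-open; each record spans a single base.
#' @export
read_bedmethyl <- function(path) {
  if (!file.exists(path)) abort(paste0("bedMethyl file not found: ", path))
  x <- readr::read_tsv(
    path,
    col_names = c("contig", "start", "end", "name", "score", "strand",
                  "thick_start", "thick_end", "rgb", "coverage",
                  "pct_methylated"),
    col_types = readr::cols(
      contig = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), name = readr::col_character(),
      score = readr::col_double(), strand = readr::col_character(),
      thick_start = readr::col_integer(), thick_end = readr::col_integer(),
      rgb = readr::col_character(), coverage = readr::col_integer(),
      pct_methylated = readr::col_double()
    ),
    progress = FALSE
  )
  if (nrow(x) > 0L &&
      (any(x$pct_methylated < 0 | x$pct_methylated > 100) || any(x$coverage < 0))) {
    abort("bedMethyl: percent methylated outside [0,100] or negative coverage")
  }
  dplyr::select(x, "contig", "start", "end", "name", "score", "strand",
                "coverage", "pct_methylated")
}

#' Write a bedMethyl site table
#'
#' Records must already be sorted by `(contig, start)`; sorting is the
#' caller's responsibility so that written files are deterministic.
#' Output round-trips bit-identically through [read_bedmethyl()].
#'
#' @param records Tibble with at least `contig`, `start`, `end`, `strand`,
#'   `coverage`, `pct_methylated`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(records, path) {
  if (nrow(records) > 1L) {
    o <- order(match(records$contig, unique(records$contig)), records$start)
    if (!identical(o, seq_len(nrow(records)))) {
      abort("write_bedmethyl: records must be sorted by (contig, start)")
    }
  }
  out <- tibble(
    contig = records$contig,
    start = records$start,
    end = records$end,
    name = if ("name" %in% names(records)) records$name else "m5C",
    score = if ("score" %in% names(records))
      records$score else pmin(records$coverage, 1000L),
    strand = records$strand,
    thick_start = records$start,
    thick_end = records$end,
    rgb = "0,0,0",
    coverage = records$coverage,
    pct_methylated = records$pct_methylated
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Convert bedMethyl records to a CpG-site count tibble
#'
#' Inverse of [cpg_to_bedmethyl()] up to rounding: recovers modified and
#' canonical call counts from coverage and percent methylated, so external
#' site tables (e.g. WGBS) can flow into [bin_methylation()],
#' [overall_methylation()] and the shared-site correlation.
#'
#' @param records bedMethyl tibble from [read_bedmethyl()].
#' @return A tibble with `contig`, `pos`, `n_modified`, `n_canonical`.
#' @export
bedmethyl_to_sites <- function(records) {
  n_mod <- as.integer(round(records$coverage * records$pct_methylated / 100))
  tibble(
    contig = records$contig,
    pos = records$start,
    n_modified = n_mod,
    n_canonical = records$coverage - n_mod
  )
}

#' Convert collapsed CpG sites to bedMethyl records
#'
#' @param cpgs CpG-site tibble from [collapse_cpg()].
#' @return A bedMethyl-shaped tibble (strand `.`, one record per CpG at the
#'   forward-strand C position), sorted by `(contig, start)`.
#' @export
cpg_to_bedmethyl <- function(cpgs) {
  valid <- cpgs$n_modified + cpgs$n_canonical
  out <- tibble(
    contig = cpgs$contig,
    start = cpgs$pos,
    end = cpgs$pos + 1L,
    name = "m5C",
    score = pmin(as.integer(valid), 1000L),
    strand = ".",
    coverage = as.integer(valid),
    pct_methylated = ifelse(valid > 0, 100 * cpgs$n_modified / valid, NA_real_)
  )
  dplyr::arrange(out, match(.data$contig, unique(.data$contig)), .data$start)
}
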