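#' Regional methylation in fixed-size bins
#'
#' Tiles every contig into `[0, bin)`, `[bin, 2*bin)`, ... windows (the last
#' window truncated at the contig end) and pools CpG counts per window. The
#' regional proportion is the coverage-weighted pooled ratio
#' `100 * sum(n_modified) / sum(n_modified + n_canonical)`, so bin totals
#' aggregate exactly to the genome-wide figure. Bins without any valid call
#' are emitted with `NA` proportion.
#'
#' @param cpgs CpG-site tibble from [collapse_cpg()] (any tibble with
#'   `contig`, `pos`, `n_modified`, `n_canonical` works, e.g. per-strand
#'   sites).
#' @param ref Genome tibble (defines contig lengths and hence the tiling).
#' @param bin_size Window size in bases (default 100 kb).
#' @return A tibble with `contig`, `start`, `end`, `n_modified`, `n_valid`,
#'   `n_sites`, `proportion` (percent).
#' @export
bin_methylation <- function(cpgs, ref, bin_size = 100000L) {
  check_genome(ref)
  if (bin_size <= 0) abort("bin_methylation: bin_size must be positive")
  grid <- bind_rows(lapply(seq_len(nrow(ref)), function(i) {
    starts <- seq(0L, ref$length[[i]] - 1L, by = bin_size)
    tibble(
      contig = ref$contig[[i]],
      start = as.integer(starts),
      end = as.integer(pmin(starts + bin_size, ref$length[[i]]))
    )
  }))
  agg <- cpgs |>
    mutate(
      start = as.integer((.data$pos %/% bin_size) * bin_size),
      valid = .data$n_modified + .data$n_canonical
    ) |>
    group_by(.data$contig, .data$start) |>
    summarise(
      n_modified = sum(.data$n_modified),
      n_valid = sum(.data$valid),
      n_sites = sum(.data$valid > 0),
      .groups = "drop"
    )
  out <- left_join(grid, agg, by = c("contig", "start")) |>
    mutate(
      n_modified = dplyr::coalesce(.data$n_modified, 0L),
      n_valid = dplyr::coalesce(.data$n_valid, 0L),
      n_sites = dplyr::coalesce(.data$n_sites, 0L),
      proportion = ifelse(.data$n_valid > 0,
                          100 * .data$n_modified / .data$n_valid, NA_real_)
    )
  arrange(out, match(.data$contig, unique(.data$contig)), .data$start)
}

#' Promoter methylation
#'
#' Defines the promoter of each gene as the `upstream` bases 5' of its
#' transcription start site — `[TSS - upstream, TSS)` for `+` genes and
#' `(TSS, TSS + upstream]` for `-` genes — clipped to contig bounds, and
#' pools CpG counts over it as in [bin_methylation()]. One record per gene;
#' overlapping promoters are not merged.
#'
#' @param cpgs CpG-site tibble from [collapse_cpg()].
#' @param tss TSS tibble from [read_bed()] (needs `contig`, `strand`,
#'   `tss`, `name`).
#' @param ref Genome tibble.
#' @param upstream Promoter length in bases (default 5 kb).
#' @return A tibble with `name`, `contig`, `start`, `end`, `strand`,
#'   `n_modified`, `n_valid`, `n_sites`, `proportion`.
#' @export
promoter_methylation <- function(cpgs, tss, ref, upstream = 5000L) {
  check_genome(ref)
  stopifnot(all(c("contig", "strand", "tss") %in% names(tss)))
  lens <- setNames(ref$length, ref$contig)
  valid <- tss$contig %in% ref$contig &
    tss$tss >= 0L & tss$tss < lens[tss$contig]
  if (any(!valid)) {
    warn(sprintf("promoter_methylation: skipping %d TSS outside the reference",
                 sum(!valid)))
    tss <- tss[valid, ]
  }
  start <- ifelse(tss$strand == "-", tss$tss + 1L, tss$tss - upstream)
  end <- ifelse(tss$strand == "-", tss$tss + 1L + upstream, tss$tss)
  start <- pmax(start, 0L)
  end <- pmin(end, unname(lens[tss$contig]))
  prom <- tibble(
    name = tss$name %||% paste0("gene_", seq_len(nrow(tss))),
    contig = tss$contig,
    start = as.integer(start),
    end = as.integer(end),
    strand = tss$strand
  )
  pool <- region_pool(cpgs, prom)
  bind_rows(pool)
}

# Pool CpG counts over arbitrary intervals (0-based half-open), one output
# row per interval, via an IRanges overlap join.
region_pool <- function(cpgs, regions) {
  regions$n_modified <- 0L
  regions$n_valid <- 0L
  regions$n_sites <- 0L
  for (ctg in unique(regions$contig)) {
    ri <- which(regions$contig == ctg)
    ci <- which(cpgs$contig == ctg)
    if (length(ci) == 0L) next
    q <- IRanges::IRanges(start = regions$start[ri] + 1L, end = regions$end[ri])
    s <- IRanges::IRanges(start = cpgs$pos[ci] + 1L, width = 1L)
    ov <- IRanges::findOverlaps(s, q)
    if (length(ov) == 0L) next
    hits <- tibble(
      region = ri[S4Vectors::subjectHits(ov)],
      site = ci[S4Vectors::queryHits(ov)]
    )
    agg <- hits |>
      mutate(
        n_mod = cpgs$n_modified[.data$site],
        n_can = cpgs$n_canonical[.data$site]
      ) |>
      group_by(.data$region) |>
      summarise(
        n_modified = sum(.data$n_mod),
        n_valid = sum(.data$n_mod + .data$n_can),
        n_sites = sum(.data$n_mod + .data$n_can > 0),
        .groups = "drop"
      )
    regions$n_modified[agg$region] <- agg$n_modified
    regions$n_valid[agg$region] <- agg$n_valid
    regions$n_sites[agg$region] <- agg$n_sites
  }
  regions$proportion <- ifelse(
    regions$n_valid > 0, 100 * regions$n_modified / regions$n_valid, NA_real_
  )
  regions
}
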