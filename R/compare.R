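#' Genome recovery rate
#'
#' Fraction of reference bases covered by at least one aligned base.
#' Reference-consuming CIGAR ops (`M`, `=`, `X`, `D`) cover; insertions,
#' clips and `N` skips do not.
#'
#' @param reads Alignment tibble (primary mapped records are used).
#' @param ref Genome tibble.
#' @return A fraction in `[0, 1]`.
#' @export
genome_recovery <- function(reads, ref) {
  check_genome(ref)
  use <- !is.na(reads$contig) & (reads$primary %||% rep(TRUE, nrow(reads)))
  reads <- reads[use, , drop = FALSE]
  if (nrow(reads) == 0L) {
    warn("genome_recovery: no mapped reads; recovery is 0")
    return(0)
  }
  covered <- 0
  for (ctg in unique(reads$contig)) {
    rr <- reads[reads$contig == ctg, ]
    rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      rr$cigar, pos = rr$pos + 1L, ops = c("M", "=", "X", "D")
    )
    ir <- IRanges::reduce(unlist(rl))
    covered <- covered + sum(IRanges::width(ir))
  }
  covered / sum(ref$length)
}

#' Sum aligned-base depth per fixed-size bin
#'
#' Companion to [gc_bias_profile()]: computes, per tiling window, the summed
#' per-base read depth (the quantity `samtools bedcov` reports) from aligned
#' reads.
#'
#' @param reads Alignment tibble.
#' @param ref Genome tibble.
#' @param bin_size Window size in bases (default 1 kb).
#' @return A tibble with `contig`, `start`, `end`, `depth` (summed per-base
#'   coverage in the window).
#' @export
bin_depth <- function(reads, ref, bin_size = 1000L) {
  check_genome(ref)
  use <- !is.na(reads$contig) & (reads$primary %||% rep(TRUE, nrow(reads)))
  reads <- reads[use, , drop = FALSE]
  bind_rows(lapply(seq_len(nrow(ref)), function(i) {
    ctg <- ref$contig[[i]]
    len <- ref$length[[i]]
    starts <- seq(0L, len - 1L, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    rr <- reads[reads$contig == ctg, ]
    if (nrow(rr) > 0L) {
      rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        rr$cigar, pos = rr$pos + 1L, ops = c("M", "=", "X", "D")
      )
      cov <- IRanges::coverage(unlist(rl), width = len)
      csum <- c(0, cumsum(as.numeric(cov)))
      depth <- csum[ends + 1L] - csum[starts + 1L]
    } else {
      depth <- rep(0, length(starts))
    }
    tibble(contig = ctg, start = as.integer(starts), end = as.integer(ends),
           depth = depth)
  }))
}

#' Subsample reads
#'
#' Keeps each read independently with probability `proportion` (read-level
#' Bernoulli subsampling, without replacement), deterministically for a
#' given seed. The caller's RNG state is left untouched.
#'
#' @param reads Any tibble of reads (one row per read).
#' @param proportion Keep probability in `(0, 1]`.
#' @param seed Integer seed.
#' @return The kept subset, in input order.
#' @export
subsample_reads <- function(reads, proportion, seed) {
  if (proportion <= 0 || proportion > 1) {
    abort("subsample_reads: proportion must lie in (0, 1]")
  }
  if (proportion == 1) return(reads)
  keep <- with_seed(seed, runif(nrow(reads)) < proportion)
  reads[keep, , drop = FALSE]
}

new_subsample_curve <- function(values, statistic) {
  structure(
    list(values = values, statistic = statistic),
    class = "nmq_subsample_curve"
  )
}

#' @export
print.nmq_subsample_curve <- function(x, ...) {
  cat(sprintf(
    "<subsample curve> statistic: %s; %d proportions x %d replicates\n",
    x$statistic, length(unique(x$values$proportion)),
    max(x$values$replicate)
  ))
  invisible(x)
}

# Replicate seeds are derived deterministically from the base seed and the
# grid position, and recorded in the curve for reproducibility.
curve_seed <- function(base_seed, proportion, replicate) {
  as.integer((base_seed + round(1000 * proportion) * 131L + replicate * 7919L) %% .Machine$integer.max)
}

subsample_curve <- function(reads, proportions, replicates, base_seed,
                            statistic, fn) {
  if (any(proportions <= 0 | proportions > 1)) {
    abort("subsample curve: proportions must lie in (0, 1]")
  }
  grid <- tidyr::expand_grid(
    proportion = proportions, replicate = seq_len(replicates)
  )
  grid$seed <- curve_seed(base_seed, grid$proportion, grid$replicate)
  grid$value <- map2_dbl(grid$proportion, grid$seed, function(p, s) {
    fn(subsample_reads(reads, p, s))
  })
  new_subsample_curve(grid, statistic)
}

#' Genome-recovery saturation curve
#'
#' Subsamples reads over a proportion grid (default 10%..100% in tens),
#' `replicates` times per proportion, and computes the genome recovery rate
#' of each subsample.
#'
#' @param reads Alignment tibble.
#' @param ref Genome tibble.
#' @param proportions Subsampling grid in `(0, 1]`.
#' @param replicates Replicates per proportion (default 10).
#' @param base_seed Base RNG seed; per-replicate seeds are derived from it
#'   and recorded.
#' @return An `nmq_subsample_curve` whose `values` tibble has `proportion`,
#'   `replicate`, `seed`, `value`.
#' @export
recovery_curve <- function(reads, ref, proportions = seq(0.1, 1, by = 0.1),
                           replicates = 10L, base_seed = 1L) {
  subsample_curve(
    reads, proportions, replicates, base_seed, "genome_recovery",
    function(sub) {
      if (nrow(sub) == 0L) return(0)
      genome_recovery(sub, ref)
    }
  )
}

#' Methylation-stability subsampling curve
#'
#' Subsamples reads and computes the overall 5mC percentage of each
#' subsample from its pooled per-read call counts (call-level pooling, so
#' the proportion-1 value equals the full-data overall methylation exactly).
#' Replicates with zero unambiguous calls yield `NA` and are logged with a
#' warning.
#'
#' @inheritParams recovery_curve
#' @param threshold Call-classification policy, see [classify_call()].
#' @return An `nmq_subsample_curve`.
#' @export
methylation_stability_curve <- function(reads,
                                        proportions = seq(0.1, 1, by = 0.1),
                                        replicates = 10L, base_seed = 1L,
                                        threshold = 0.5) {
  counts <- per_read_methylation(reads, threshold)
  curve <- subsample_curve(
    counts, proportions, replicates, base_seed, "overall_methylation",
    function(sub) {
      valid <- sum(sub$n_modified) + sum(sub$n_canonical)
      if (valid == 0) return(NA_real_)
      100 * sum(sub$n_modified) / valid
    }
  )
  if (anyNA(curve$values$value)) {
    warn(sprintf("methylation_stability_curve: %d replicate(s) had no calls",
                 sum(is.na(curve$values$value))))
  }
  curve
}

#' Correlation of regional methylation between two datasets
#'
#' Pearson correlation of regional proportions across regions with data in
#' both datasets. Regions are matched by their coordinates (bins) or their
#' `name` (promoters). With `shared_only = TRUE` the regional proportions
#' are first *recomputed* from only the CpG sites present in both datasets
#' (pass the two site tibbles and the tiling parameters), mirroring the
#' shared-site comparison used when one platform covers fewer sites.
#'
#' @param a,b Region tibbles from [bin_methylation()] /
#'   [promoter_methylation()], or CpG-site tibbles when
#'   `shared_only = TRUE`.
#' @param shared_only Recompute regional proportions on the shared CpG
#'   sites before correlating.
#' @param ref,bin_size Needed when `shared_only = TRUE` to re-tile.
#' @return An object of class `nmq_correlation` with fields `r`, `n`,
#'   `p_value` and the paired tibble `pairs` (`key`, `a`, `b`).
#' @export
region_correlation <- function(a, b, shared_only = FALSE, ref = NULL,
                               bin_size = 100000L) {
  if (shared_only) {
    if (is.null(ref)) abort("region_correlation: shared_only = TRUE needs `ref`")
    shared <- inner_join(
      select(a, "contig", "pos"), select(b, "contig", "pos"),
      by = c("contig", "pos")
    )
    a <- dplyr::semi_join(a, shared, by = c("contig", "pos"))
    b <- dplyr::semi_join(b, shared, by = c("contig", "pos"))
    a <- bin_methylation(a, ref, bin_size)
    b <- bin_methylation(b, ref, bin_size)
  }
  key_a <- region_key(a)
  key_b <- region_key(b)
  pairs <- inner_join(
    tibble(key = key_a, a = a$proportion),
    tibble(key = key_b, b = b$proportion),
    by = "key"
  )
  pairs <- pairs[!is.na(pairs$a) & !is.na(pairs$b), ]
  if (nrow(pairs) < 3L) {
    abort("region_correlation: fewer than 3 complete region pairs")
  }
  if (stats::sd(pairs$a) == 0 || stats::sd(pairs$b) == 0) {
    abort("region_correlation: undefined correlation (zero variance)")
  }
  ct <- stats::cor.test(pairs$a, pairs$b, method = "pearson")
  structure(
    list(r = unname(ct$estimate), n = nrow(pairs), p_value = ct$p.value,
         pairs = pairs, shared_only = shared_only),
    class = "nmq_correlation"
  )
}

region_key <- function(x) {
  if (all(c("contig", "start", "end") %in% names(x))) {
    paste(x$contig, x$start, x$end, sep = ":")
  } else if ("name" %in% names(x)) {
    x$name
  } else {
    abort("region tibble needs contig/start/end or name columns")
  }
}

#' @export
print.nmq_correlation <- function(x, ...) {
  cat(sprintf("<region correlation> r = %.4f over n = %d region pairs%s\n",
              x$r, x$n, if (isTRUE(x$shared_only)) " (shared sites)" else ""))
  invisible(x)
}

#' GC-bias coverage profile
#'
#' Assigns every fixed-size window an integer GC percentage (computed over
#' non-N bases; windows with more than 50% N are dropped), averages window
#' depth per GC level, and normalises the in-range levels by the average
#' depth of all windows whose GC lies within `gc_range` (default 10-60%).
#' A normalised coverage near 1 at every level indicates little or no GC
#' bias.
#'
#' @param ref Genome tibble.
#' @param depth Per-window summed-depth tibble from [bin_depth()] (or a
#'   `samtools bedcov`-style table with `contig`, `start`, `end`, `depth`).
#' @param bin_size Window size in bases; must match the depth tiling.
#' @param gc_range Length-2 integer GC-percent range for normalisation.
#' @return An object of class `nmq_gc_profile`: tibble `levels` with
#'   `gc_pct`, `n_bins`, `mean_depth`, `normalized` (`NA` outside
#'   `gc_range`), plus `grand_mean` and `gc_range`.
#' @export
gc_bias_profile <- function(ref, depth, bin_size = 1000L, gc_range = c(10, 60)) {
  check_genome(ref)
  stopifnot(all(c("contig", "start", "end", "depth") %in% names(depth)))
  widths <- depth$end - depth$start
  if (any(widths > bin_size) || any(widths <= 0)) {
    abort("gc_bias_profile: depth windows do not match bin_size")
  }
  gc <- bind_rows(lapply(seq_len(nrow(ref)), function(i) {
    dss <- Biostrings::DNAString(ref$sequence[[i]])
    len <- ref$length[[i]]
    starts <- seq(0L, len - 1L, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    v <- Biostrings::Views(dss, start = starts + 1L, end = ends)
    freq <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T", "N"))
    acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
    tibble(
      contig = ref$contig[[i]], start = as.integer(starts),
      end = as.integer(ends),
      n_frac = freq[, "N"] / (ends - starts),
      gc_pct = ifelse(acgt > 0,
                      as.integer(round(100 * (freq[, "C"] + freq[, "G"]) / acgt)),
                      NA_integer_)
    )
  }))
  x <- inner_join(gc, depth, by = c("contig", "start", "end"))
  if (nrow(x) != nrow(gc) || nrow(depth) != nrow(gc)) {
    abort("gc_bias_profile: depth windows do not tile the reference at bin_size")
  }
  x <- x[!is.na(x$gc_pct) & x$n_frac <= 0.5, ]
  x$mean_depth_bin <- x$depth / (x$end - x$start)
  levels <- x |>
    group_by(gc_pct = .data$gc_pct) |>
    summarise(n_bins = n(), mean_depth = mean(.data$mean_depth_bin),
              .groups = "drop") |>
    arrange(.data$gc_pct)
  in_range <- x$gc_pct >= gc_range[1] & x$gc_pct <= gc_range[2]
  if (!any(in_range)) abort("gc_bias_profile: no windows within gc_range")
  grand <- mean(x$mean_depth_bin[in_range])
  levels$normalized <- ifelse(
    levels$gc_pct >= gc_range[1] & levels$gc_pct <= gc_range[2],
    levels$mean_depth / grand, NA_real_
  )
  structure(
    list(levels = levels, grand_mean = grand, gc_range = gc_range,
         bin_size = bin_size),
    class = "nmq_gc_profile"
  )
}

#' @export
print.nmq_gc_profile <- function(x, ...) {
  rng <- range(x$levels$normalized, na.rm = TRUE)
  cat(sprintf(
    "<GC-bias profile> %d GC levels; normalized coverage %.3f-%.3f over GC %d-%d%%\n",
    nrow(x$levels), rng[1], rng[2], x$gc_range[1], x$gc_range[2]
  ))
  invisible(x)
}
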