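#' Classify a modification probability
#'
#' Symmetric single-threshold policy by default: probabilities `>= threshold`
#' are modified calls and `< 1 - threshold` canonical; anything in between
#' is ambiguous and discarded from counts. With the default `threshold =
#' 0.5` there is no ambiguous zone and a probability of exactly 0.5
#' classifies as modified. A dual-threshold mode (e.g. `c(0.33, 0.66)`) can
#' be given as a length-2 vector `c(lo, hi)`: `< lo` canonical, `>= hi`
#' modified, otherwise ambiguous.
#'
#' @param prob Probabilities in `[0, 1]`.
#' @param threshold Single threshold `t` (canonical `< 1 - t`, modified
#'   `>= t`) or a `c(lo, hi)` pair.
#' @return Character vector in `c("modified", "canonical", "ambiguous")`.
#' @export
classify_call <- function(prob, threshold = 0.5) {
  if (length(threshold) == 2L) {
    lo <- threshold[1]; hi <- threshold[2]
  } else {
    hi <- threshold; lo <- 1 - threshold
  }
  if (lo > hi) abort("classify_call: lower threshold exceeds upper threshold")
  dplyr::case_when(
    prob >= hi ~ "modified",
    prob < lo ~ "canonical",
    TRUE ~ "ambiguous"
  )
}

#' Pile up modification calls into per-strand sites
#'
#' Projects every read's per-cytosine modification calls through its CIGAR
#' to reference coordinates and accumulates modified/canonical/ambiguous
#' counts per `(contig, position, strand)`. Calls sitting on inserted or
#' soft-clipped bases have no reference position and are dropped. Only
#' primary alignments contribute.
#'
#' @param reads Alignment tibble with `mod_calls` list-column (see
#'   [read_modbam()], [simulate_ont_reads()]).
#' @param ref Genome tibble.
#' @param threshold Call-classification policy, see [classify_call()].
#' @return A tibble with `contig`, `pos` (0-based), `strand`, `n_modified`,
#'   `n_canonical`, `n_ambiguous`, one row per site with at least one
#'   projected call.
#' @export
pileup_sites <- function(reads, ref, threshold = 0.5) {
  check_genome(ref)
  use <- which(!is.na(reads$contig) & (reads$primary %||% rep(TRUE, nrow(reads))))
  cg <- explode_cigars(reads$cigar)
  pieces <- vector("list", length(use))
  for (j in seq_along(use)) {
    i <- use[j]
    calls <- reads$mod_calls[[i]]
    if (is.null(calls) || nrow(calls) == 0L) next
    qmap <- query_to_ref_map(reads$cigar[[i]], reads$pos[[i]],
                             cg = list(op = cg$op[[i]], len = cg$len[[i]]))
    L <- length(qmap)
    stored_idx <- if (reads$strand[[i]] == "-") L - 1L - calls$offset else calls$offset
    if (any(stored_idx < 0L | stored_idx >= L)) {
      abort("pileup_sites: modification call offset outside the read")
    }
    rpos <- qmap[stored_idx + 1L]
    keep <- !is.na(rpos)
    if (!any(keep)) next
    rp <- rpos[keep]
    if (any(rp >= genome_len(ref, reads$contig[[i]]))) {
      abort("pileup_sites: call projects outside the contig (corrupt alignment)")
    }
    pieces[[j]] <- tibble(
      contig = reads$contig[[i]],
      pos = rp,
      strand = reads$strand[[i]],
      class = classify_call(calls$prob[keep], threshold)
    )
  }
  calls <- dplyr::bind_rows(pieces)
  if (nrow(calls) == 0L) {
    return(tibble(
      contig = character(), pos = integer(), strand = character(),
      n_modified = integer(), n_canonical = integer(), n_ambiguous = integer()
    ))
  }
  calls |>
    group_by(.data$contig, .data$pos, .data$strand) |>
    summarise(
      n_modified = sum(.data$class == "modified"),
      n_canonical = sum(.data$class == "canonical"),
      n_ambiguous = sum(.data$class == "ambiguous"),
      .groups = "drop"
    ) |>
    arrange(match(.data$contig, unique(.data$contig)), .data$pos, .data$strand)
}

#' Collapse strand sites into CpG sites
#'
#' A CpG dinucleotide carries methylation information on both strands: the
#' forward-strand C at position `i` and the reverse-strand C (read as G on
#' the forward strand) at `i + 1`. For every reference `CG`, the `+` site at
#' `i` and the `-` site at `i + 1` are pooled into a single CpG site keyed
#' at `i`. Strand sites that do not sit on a reference CG (e.g. non-CpG
#' cytosine calls) are excluded.
#'
#' @param sites Per-strand site tibble from [pileup_sites()].
#' @param ref Genome tibble.
#' @return A tibble with `contig`, `pos` (forward-strand C position),
#'   `n_modified`, `n_canonical`, `n_ambiguous` (pooled over strands),
#'   `fwd_coverage` and `rev_coverage` (valid calls per strand).
#' @export
collapse_cpg <- function(sites, ref) {
  check_genome(ref)
  pieces <- lapply(unique(sites$contig), function(ctg) {
    s <- sites[sites$contig == ctg, ]
    cg <- cpg_positions(genome_seq(ref, ctg))
    fwd <- s[s$strand == "+" & s$pos %in% cg, ]
    rev <- s[s$strand == "-" & (s$pos - 1L) %in% cg, ]
    fwd$site <- fwd$pos
    rev$site <- rev$pos - 1L
    fwd$fwd_valid <- fwd$n_modified + fwd$n_canonical
    rev$rev_valid <- rev$n_modified + rev$n_canonical
    both <- bind_rows(fwd, rev)
    if (nrow(both) == 0L) return(NULL)
    both |>
      group_by(site = .data$site) |>
      summarise(
        n_modified = sum(.data$n_modified),
        n_canonical = sum(.data$n_canonical),
        n_ambiguous = sum(.data$n_ambiguous),
        fwd_coverage = sum(.data$fwd_valid, na.rm = TRUE),
        rev_coverage = sum(.data$rev_valid, na.rm = TRUE),
        .groups = "drop"
      ) |>
      mutate(contig = ctg, .before = 1) |>
      rename(pos = "site")
  })
  out <- bind_rows(pieces)
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble(
      contig = character(), pos = integer(), n_modified = integer(),
      n_canonical = integer(), n_ambiguous = integer(),
      fwd_coverage = integer(), rev_coverage = integer()
    ))
  }
  arrange(out, match(.data$contig, unique(.data$contig)), .data$pos)
}

#' Fraction of reference CpG sites covered on both strands
#'
#' A CpG site counts as covered only when it has at least one valid call on
#' the forward strand *and* one on the reverse strand. The denominator is
#' the total number of CG dinucleotides on the forward strand of the
#' selected contigs.
#'
#' @param cpgs CpG-site tibble from [collapse_cpg()].
#' @param ref Genome tibble.
#' @param contigs Contigs to evaluate (default: all in `ref`).
#' @return A tibble with one row per contig plus an `overall` row:
#'   `contig`, `n_covered`, `n_cpg`, `fraction`.
#' @export
covered_cpg_fraction <- function(cpgs, ref, contigs = ref$contig) {
  check_genome(ref)
  if (length(contigs) == 0L) abort("covered_cpg_fraction: empty contig set")
  per <- lapply(contigs, function(ctg) {
    n_cpg <- length(cpg_positions(genome_seq(ref, ctg)))
    cc <- cpgs[cpgs$contig == ctg, ]
    n_cov <- sum(cc$fwd_coverage >= 1L & cc$rev_coverage >= 1L)
    tibble(contig = ctg, n_covered = n_cov, n_cpg = n_cpg)
  })
  out <- bind_rows(per)
  out <- bind_rows(out, tibble(
    contig = "overall",
    n_covered = sum(out$n_covered),
    n_cpg = sum(out$n_cpg)
  ))
  mutate(out, fraction = .data$n_covered / .data$n_cpg)
}

#' Per-read methylation proportion
#'
#' Fraction of a read's unambiguous modification calls classified modified.
#'
#' @param reads Alignment tibble with `mod_calls`.
#' @param threshold Call-classification policy, see [classify_call()].
#' @return A tibble with `read_id`, `length`, `n_modified`, `n_canonical`,
#'   `methylation` (fraction, `NA` when the read has no unambiguous call).
#' @export
per_read_methylation <- function(reads, threshold = 0.5) {
  counts <- map(reads$mod_calls, function(calls) {
    if (is.null(calls) || nrow(calls) == 0L) {
      return(c(mod = 0L, canon = 0L))
    }
    cl <- classify_call(calls$prob, threshold)
    c(mod = sum(cl == "modified"), canon = sum(cl == "canonical"))
  })
  n_mod <- map_int(counts, "mod")
  n_can <- map_int(counts, "canon")
  valid <- n_mod + n_can
  tibble(
    read_id = reads$read_id,
    length = nchar(reads$seq),
    n_modified = n_mod,
    n_canonical = n_can,
    methylation = ifelse(valid > 0, n_mod / valid, NA_real_)
  )
}

#' Overall methylation percentage
#'
#' Pools modified and valid (modified + canonical) call counts over all
#' sites and returns `100 * modified / valid`. Accepts any tibble carrying
#' `n_modified` and `n_canonical` columns (per-strand sites, collapsed CpG
#' sites, or per-read counts).
#'
#' @param sites Tibble with `n_modified`, `n_canonical`.
#' @return Percentage in `[0, 100]`.
#' @export
overall_methylation <- function(sites) {
  n_mod <- sum(sites$n_modified)
  n_valid <- n_mod + sum(sites$n_canonical)
  if (n_valid == 0) abort("overall_methylation: no valid calls")
  100 * n_mod / n_valid
}
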