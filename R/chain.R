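#' Parse a UCSC chain file
#'
#' Reads assembly-to-assembly block alignments in UCSC chain format. The
#' chain header's `t` fields are the *source* assembly (the one existing
#' records live on) and the `q` fields the *target*, matching how
#' old-to-new "over" chains are oriented. Block arithmetic is validated
#' against the header spans: the sum of `size + dt` over blocks must equal
#' the source span and the sum of `size + dq` the target span.
#'
#' @param path Path to a chain file.
#' @return A tibble with one row per chain: `chain_id`, `score`,
#'   `source_contig`, `source_size`, `source_strand`, `source_start`,
#'   `source_end`, `target_contig`, `target_size`, `target_strand`,
#'   `target_start`, `target_end`, and a `blocks` list-column of tibbles
#'   with `size`, `dt` (source gap) and `dq` (target gap); the last block
#'   of each chain has `dt = dq = 0`.
#' @export
parse_chain <- function(path) {
  if (!file.exists(path)) abort(paste0("chain file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  starts <- grep("^chain\\b", lines)
  if (length(starts) == 0L) abort("no chain records found")
  bounds <- c(starts, length(lines) + 1L)
  chains <- lapply(seq_along(starts), function(i) {
    hdr <- strsplit(stringr::str_trim(lines[starts[i]]), "\\s+")[[1]]
    if (length(hdr) != 13L) {
      abort(paste0("malformed chain header: ", lines[starts[i]]))
    }
    body <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    body <- body[stringr::str_trim(body) != ""]
    parts <- strsplit(stringr::str_trim(body), "\\s+")
    nf <- lengths(parts)
    if (any(!nf %in% c(1L, 3L)) || nf[length(nf)] != 1L ||
        (length(nf) > 1L && any(nf[-length(nf)] != 3L))) {
      abort(paste0("malformed block lines in chain ", hdr[13]))
    }
    blocks <- tibble(
      size = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
      dt = vapply(parts, function(p) if (length(p) == 3L) as.numeric(p[2]) else 0, numeric(1)),
      dq = vapply(parts, function(p) if (length(p) == 3L) as.numeric(p[3]) else 0, numeric(1))
    )
    ch <- tibble(
      chain_id = as.integer(hdr[13]), score = as.numeric(hdr[2]),
      source_contig = hdr[3], source_size = as.integer(hdr[4]),
      source_strand = hdr[5], source_start = as.integer(hdr[6]),
      source_end = as.integer(hdr[7]),
      target_contig = hdr[8], target_size = as.integer(hdr[9]),
      target_strand = hdr[10], target_start = as.integer(hdr[11]),
      target_end = as.integer(hdr[12]),
      blocks = list(blocks)
    )
    validate_chain(ch)
    ch
  })
  dplyr::bind_rows(chains)
}

validate_chain <- function(ch) {
  b <- ch$blocks[[1]]
  if (ch$source_strand != "+") {
    abort(paste0("chain ", ch$chain_id, ": source strand must be '+'"))
  }
  s_span <- sum(b$size + b$dt)
  t_span <- sum(b$size + b$dq)
  if (s_span != ch$source_end - ch$source_start ||
      t_span != ch$target_end - ch$target_start) {
    abort(sprintf(
      "chain %d: block arithmetic does not match header spans (source %g vs %d, target %g vs %d)",
      ch$chain_id, s_span, ch$source_end - ch$source_start,
      t_span, ch$target_end - ch$target_start
    ))
  }
  invisible(ch)
}

#' Write chains in UCSC chain format
#'
#' @param chains Chain tibble as returned by [parse_chain()] or
#'   [simulate_chain()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  out <- unlist(lapply(seq_len(nrow(chains)), function(i) {
    ch <- chains[i, ]
    validate_chain(ch)
    b <- ch$blocks[[1]]
    hdr <- sprintf(
      "chain %s %s %d %s %d %d %s %d %s %d %d %d",
      format(ch$score, scientific = FALSE), ch$source_contig, ch$source_size,
      ch$source_strand, ch$source_start, ch$source_end,
      ch$target_contig, ch$target_size, ch$target_strand,
      ch$target_start, ch$target_end, ch$chain_id
    )
    n <- nrow(b)
    body <- c(
      if (n > 1L) sprintf("%d\t%d\t%d", b$size[-n], b$dt[-n], b$dq[-n]),
      sprintf("%d", b$size[n])
    )
    c(hdr, body, "")
  }))
  writeLines(out, path)
  invisible(path)
}

#' Invert chains (swap source and target assemblies)
#'
#' Only chains whose target strand is `+` can be inverted this way; gap
#' columns are swapped along with the header fields.
#'
#' @param chains Chain tibble.
#' @return The inverted chain tibble.
#' @export
invert_chain <- function(chains) {
  if (any(chains$target_strand != "+")) {
    abort("invert_chain supports only '+' target strands")
  }
  out <- chains
  out$source_contig <- chains$target_contig
  out$source_size <- chains$target_size
  out$source_start <- chains$target_start
  out$source_end <- chains$target_end
  out$target_contig <- chains$source_contig
  out$target_size <- chains$source_size
  out$target_start <- chains$source_start
  out$target_end <- chains$source_end
  out$blocks <- lapply(chains$blocks, function(b) {
    tibble(size = b$size, dt = b$dq, dq = b$dt)
  })
  out
}

# Flatten chains into one row per aligned block with absolute source/target
# block starts (target starts in target-strand coordinates).
chain_block_table <- function(chains) {
  dplyr::bind_rows(lapply(seq_len(nrow(chains)), function(i) {
    ch <- chains[i, ]
    b <- ch$blocks[[1]]
    s_starts <- ch$source_start + cumsum(c(0, head(b$size + b$dt, -1)))
    t_starts <- ch$target_start + cumsum(c(0, head(b$size + b$dq, -1)))
    tibble(
      chain_ord = i, chain_id = ch$chain_id, score = ch$score,
      source_contig = ch$source_contig,
      s_start = s_starts, size = b$size, t_start = t_starts,
      target_contig = ch$target_contig, target_strand = ch$target_strand,
      target_size = ch$target_size
    )
  }))
}

#' Lift per-site records between assemblies through chains
#'
#' Maps single-base records (e.g. bedMethyl sites) from the source assembly
#' to the target assembly by walking chain blocks. A position inside an
#' aligned block maps by offset; positions falling in inter-block gaps or
#' outside every chain are returned unmapped. Where several chains' blocks
#' contain a position, the highest-scoring chain wins (ties broken by file
#' order). When the target strand of the winning chain is `-`, the mapped
#' coordinate is flipped to forward-strand coordinates and the record's
#' strand is inverted.
#'
#' @param records Tibble of single-base records with `contig`, `start`,
#'   `end` (= start + 1) and `strand`; extra columns are carried through.
#' @param chains Chain tibble from [parse_chain()] or [simulate_chain()].
#' @return A list with elements `mapped` (records with target coordinates)
#'   and `unmapped` (input records that did not map);
#'   `nrow(mapped) + nrow(unmapped) == nrow(records)`.
#' @export
liftover_sites <- function(records, chains) {
  stopifnot(all(c("contig", "start", "end") %in% names(records)))
  if (any(records$end - records$start != 1L)) {
    abort("liftover_sites expects single-base records (end == start + 1)")
  }
  if (!"strand" %in% names(records)) records$strand <- "."
  if (nrow(records) == 0L) {
    return(list(mapped = records, unmapped = records))
  }
  bt <- chain_block_table(chains)
  hit_chain <- rep(NA_integer_, nrow(records))  # row index into bt
  for (ctg in unique(records$contig)) {
    ri <- which(records$contig == ctg)
    bi <- which(bt$source_contig == ctg)
    if (length(bi) == 0L) next
    q <- IRanges::IRanges(start = records$start[ri] + 1L, width = 1L)
    s <- IRanges::IRanges(start = bt$s_start[bi] + 1L, width = bt$size[bi])
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0L) next
    cand <- tibble(
      rec = ri[S4Vectors::queryHits(ov)],
      blk = bi[S4Vectors::subjectHits(ov)]
    )
    cand$score <- bt$score[cand$blk]
    cand$ord <- bt$chain_ord[cand$blk]
    cand <- dplyr::arrange(cand, .data$rec, dplyr::desc(.data$score), .data$ord)
    best <- cand[!duplicated(cand$rec), ]
    hit_chain[best$rec] <- best$blk
  }
  is_mapped <- !is.na(hit_chain)
  mapped <- records[is_mapped, , drop = FALSE]
  if (nrow(mapped) > 0L) {
    blk <- bt[hit_chain[is_mapped], ]
    off <- mapped$start - blk$s_start
    t_pos <- blk$t_start + off
    minus <- blk$target_strand == "-"
    fwd <- ifelse(minus, blk$target_size - 1L - t_pos, t_pos)
    mapped$contig <- blk$target_contig
    mapped$start <- as.integer(fwd)
    mapped$end <- mapped$start + 1L
    mapped$strand <- ifelse(
      minus & mapped$strand %in% c("+", "-"),
      ifelse(mapped$strand == "+", "-", "+"),
      mapped$strand
    )
  }
  list(mapped = mapped, unmapped = records[!is_mapped, , drop = FALSE])
}
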