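#' Estimated read accuracy from Phred qualities
#'
#' The estimated accuracy of a read is one minus its mean per-base error
#' probability, `1 - mean(10^(-q_i / 10))`, where `q_i` is the Phred quality
#' of the i-th basecalled base.
#'
#' @param qualities Integer (or numeric) vector of per-base Phred scores.
#' @return A fraction in `[0, 1)`.
#' @examples
#' estimated_accuracy(c(10, 20, 30))
#' @export
estimated_accuracy <- function(qualities) {
  if (length(qualities) == 0L) abort("estimated_accuracy: empty quality vector")
  if (any(qualities < 0)) abort("estimated_accuracy: negative Phred score")
  1 - mean(phred_to_error(qualities))
}

# Read-level quality: the Q-scale twin of estimated accuracy,
# -10*log10(mean error probability).
read_quality <- function(qualities) {
  error_to_phred(mean(phred_to_error(qualities)))
}

#' Tally alignment columns against the reference
#'
#' Classifies every alignment column of a read into match, substitution,
#' insertion or deletion. `M` operations are split into matches and
#' substitutions by base comparison with the reference; `=`/`X` are counted
#' directly; `I` and `D` add inserted/deleted bases; soft/hard clips and `N`
#' skips contribute nothing. Reference `N` positions under an `M` op are
#' excluded from both matches and substitutions.
#'
#' @param read One-row alignment tibble (or list) with `contig`, `pos`,
#'   `cigar`, `seq`.
#' @param ref Genome tibble.
#' @return A tibble with `n_mat`, `n_sub`, `n_ins`, `n_del`, `n_total`
#'   where `n_total = n_mat + n_sub + n_ins + n_del`.
#' @export
tally_alignment <- function(read, ref) {
  check_genome(ref)
  cg <- cigar_ops(read$cigar[[1]])
  tally_core(cg$op, cg$len, read$pos[[1]], read$seq[[1]],
             genome_seq(ref, read$contig[[1]]))
}

tally_core <- function(op_v, len_v, pos, qseq, refseq) {
  span <- sum(len_v[op_v %in% REF_OPS])
  if (pos + span > nchar(refseq)) {
    abort("tally_alignment: aligned span exceeds contig length")
  }
  n_mat <- sum(len_v[op_v == "="])
  n_sub <- sum(len_v[op_v == "X"])
  n_ins <- sum(len_v[op_v == "I"])
  n_del <- sum(len_v[op_v == "D"])
  m <- which(op_v == "M")
  if (length(m) > 0L) {
    # 0-based query/reference offset at the start of every op
    q_start <- cumsum(c(0L, head(len_v * (op_v %in% QUERY_OPS), -1L)))
    r_start <- cumsum(c(0L, head(len_v * (op_v %in% REF_OPS), -1L)))
    qv_all <- strsplit(toupper(qseq), "", fixed = TRUE)[[1]]
    rv_all <- strsplit(substring(refseq, pos + 1L, pos + span),
                       "", fixed = TRUE)[[1]]
    qv <- qv_all[sequence(len_v[m], from = q_start[m] + 1L)]
    rv <- rv_all[sequence(len_v[m], from = r_start[m] + 1L)]
    usable <- rv != "N"
    n_mat <- n_mat + sum(usable & rv == qv)
    n_sub <- n_sub + sum(usable & rv != qv)
  }
  tibble(n_mat = n_mat, n_sub = n_sub, n_ins = n_ins, n_del = n_del,
         n_total = n_mat + n_sub + n_ins + n_del)
}

#' Observed read accuracy from an alignment tally
#'
#' `N(mat) / N(total)` with `N(total) = N(mat) + N(sub) + N(ins) + N(del)`.
#'
#' @param tally Tally tibble from [tally_alignment()].
#' @return A fraction in `[0, 1]`.
#' @export
observed_accuracy <- function(tally) {
  if (tally$n_total[[1]] <= 0) abort("observed_accuracy: empty tally (n_total == 0)")
  tally$n_mat[[1]] / tally$n_total[[1]]
}

#' Per-read accuracy table
#'
#' Computes estimated accuracy (from qualities) for every read and observed
#' accuracy (from the alignment tally) for primary mapped reads; secondary
#' and supplementary records, and unmapped reads, get `NA` observed
#' accuracy.
#'
#' @param reads Alignment tibble (see [read_modbam()]).
#' @param ref Genome tibble.
#' @return A tibble with `read_id`, `length` (query bases), `estimated`,
#'   `observed`.
#' @export
read_accuracy <- function(reads, ref) {
  check_genome(ref)
  est <- map_dbl(reads$qual, estimated_accuracy)
  use <- !is.na(reads$contig) & (reads$primary %||% rep(TRUE, nrow(reads)))
  obs <- rep(NA_real_, nrow(reads))
  cg <- explode_cigars(reads$cigar)
  seqs <- setNames(ref$sequence, ref$contig)
  for (i in which(use)) {
    tally <- tally_core(cg$op[[i]], cg$len[[i]], reads$pos[[i]],
                        reads$seq[[i]], seqs[[reads$contig[[i]]]])
    obs[i] <- observed_accuracy(tally)
  }
  tibble(
    read_id = reads$read_id,
    length = nchar(reads$seq),
    estimated = est,
    observed = obs
  )
}

#' Trim and filter raw reads
#'
#' Applies the standard long-read cleanup: a fixed number of bases is cut
#' from both the head and the tail of every read, then reads are dropped if
#' the trimmed length falls below `min_length` or the read-level quality,
#' `-10 * log10(mean per-base error probability)` of the trimmed read, falls
#' below `min_q`. Reads of at most `2 * trim` bases are discarded as fully
#' trimmed. Qualities are trimmed with the sequence.
#'
#' @param reads Raw-read tibble with `read_id`, `seq`, `qual` (integer
#'   list-column), e.g. from [read_fastq()].
#' @param trim Bases removed from each end (default 50).
#' @param min_length Minimum post-trim length in bases (default 200).
#' @param min_q Minimum read-level quality (default 7).
#' @return The kept, trimmed reads; the attribute `"log"` holds a tibble of
#'   counts by outcome (`kept`, `fully_trimmed`, `too_short`,
#'   `low_quality`).
#' @export
filter_reads <- function(reads, trim = 50L, min_length = 200L, min_q = 7) {
  len <- nchar(reads$seq)
  post <- len - 2L * trim
  status <- rep("kept", nrow(reads))
  status[post <= 0L] <- "fully_trimmed"
  keep_idx <- which(status == "kept")
  seq_t <- substring(reads$seq[keep_idx], trim + 1L, len[keep_idx] - trim)
  qual_t <- lapply(keep_idx, function(i) {
    q <- reads$qual[[i]]
    q[(trim + 1L):(length(q) - trim)]
  })
  short <- nchar(seq_t) < min_length
  status[keep_idx[short]] <- "too_short"
  rq <- vapply(qual_t, read_quality, numeric(1))
  lowq <- !short & rq < min_q
  status[keep_idx[lowq]] <- "low_quality"
  ok <- which(status[keep_idx] == "kept")
  out <- tibble(
    read_id = reads$read_id[keep_idx[ok]],
    seq = seq_t[ok],
    qual = qual_t[ok]
  )
  lv <- c("kept", "fully_trimmed", "too_short", "low_quality")
  attr(out, "log") <- tibble(
    outcome = lv,
    n = as.integer(table(factor(status, levels = lv)))
  )
  out
}

#' Summarise an accuracy distribution
#'
#' Mean, fixed-width histogram over `[0, 1]`, and the histogram mode (the
#' centre of the fullest bin, ties broken toward the lower bin) of a
#' collection of per-read accuracies — the summary behind accuracy density
#' plots and the "modal read accuracy".
#'
#' @param values Accuracies in `[0, 1]` (NAs dropped).
#' @param bin_width Histogram bin width (default 0.005, i.e. half a
#'   percentage point).
#' @return An object of class `nmq_accuracy_summary` with fields `mean`,
#'   `mode`, `n`, `bin_width` and `histogram` (tibble of `bin_center`,
#'   `count`, `density`; densities sum to 1).
#' @export
accuracy_summary <- function(values, bin_width = 0.005) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) abort("accuracy_summary: no values")
  if (any(values < 0 | values > 1)) abort("accuracy_summary: values outside [0, 1]")
  breaks <- seq(0, 1, by = bin_width)
  if (tail(breaks, 1) < 1) breaks <- c(breaks, 1)
  # left-closed bins so a value on a boundary belongs to the upper bin,
  # except 1.0 which stays in the last bin
  idx <- pmin(findInterval(values, breaks, left.open = FALSE), length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  mode_bin <- which.max(counts)  # which.max takes the first (lower) tie
  structure(
    list(
      mean = mean(values),
      mode = centers[mode_bin],
      n = length(values),
      bin_width = bin_width,
      histogram = tibble(
        bin_center = centers,
        count = counts,
        density = counts / sum(counts)
      )
    ),
    class = "nmq_accuracy_summary"
  )
}

#' @export
print.nmq_accuracy_summary <- function(x, ...) {
  cat(sprintf(
    "<accuracy summary> n = %d reads; mean = %.4f; mode = %.4f (bin width %g)\n",
    x$n, x$mean, x$mode, x$bin_width
  ))
  invisible(x)
}

#' Correlation between read length and a per-read metric
#'
#' Pearson product-moment correlation between read length and any per-read
#' fraction (observed accuracy, per-read 5mC proportion, ...), used to check
#' that read length does not drive the metric.
#'
#' @param reads Tibble with a `length` column and the metric column.
#' @param metric Name of the metric column (string).
#' @return A one-row tibble with `r`, `n`, `p_value`.
#' @export
length_metric_correlation <- function(reads, metric) {
  x <- reads$length
  y <- reads[[metric]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("length_metric_correlation: need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("length_metric_correlation: undefined correlation (zero variance)")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), n = length(x), p_value = ct$p.value)
}
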