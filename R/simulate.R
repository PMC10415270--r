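#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' desk-scale stand-in for an ONT whole-genome 5mC run over a toy genome:
#' two 250 kb contigs whose 1 kb windows ramp from 25% to 60% GC, ~10
#' planted CpGs per kb (~5,000 sites), a bimodal Beta-mixture methylome
#' with truth mean 0.782 (hypermethylated bulk plus a hypomethylated
#' minority, the genome-wide level typical of vertebrate tissue), 2,000
#' reads of mean length 5 kb (about 20x coverage), 5% per-base alignment
#' error, and a WGBS-like coverage model whose depth is multiplied by a
#' GC-dependent factor (default: 2x below 35% GC, 0.5x at or above —
#' the short-read amplification bias pattern).
#'
#' @param seed Integer master seed; every generator derives its stream from
#'   it, so an identical config yields byte-identical outputs.
#' @param n_contigs,contig_length Number and length (bases) of contigs.
#' @param gc_window Window size (bases) over which GC targets are enforced.
#' @param gc_range Length-2 fractional GC range of the per-window ramp.
#' @param cpg_per_kb Expected planted CpG dinucleotides per kb (Poisson).
#' @param meth_weights,meth_shape1,meth_shape2 Beta-mixture weights and
#'   shape parameters of the true per-CpG methylation levels.
#' @param n_reads Number of simulated reads.
#' @param read_length_mean,read_length_sdlog,read_length_min Log-normal
#'   read-length model (mean in bases, sdlog, minimum length).
#' @param error_rate Total per-column alignment error rate; split into
#'   substitution/insertion/deletion by `error_split`.
#' @param error_split Length-3 fractions (sub, ins, del) summing to 1.
#' @param fidelity Probability that a modification call falls on the
#'   correct side of 0.5 given the molecule's true state.
#' @param wgbs_depth Mean WGBS site coverage before GC scaling.
#' @param gc_bias_fn Function mapping integer GC percent to a multiplicative
#'   depth factor for the WGBS model.
#' @return A list of class `nmq_sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_contigs = 2L,
                       contig_length = 250000L,
                       gc_window = 1000L,
                       gc_range = c(0.25, 0.60),
                       cpg_per_kb = 10,
                       meth_weights = c(0.848, 0.152),
                       meth_shape1 = c(9, 1),
                       meth_shape2 = c(1, 7),
                       n_reads = 2000L,
                       read_length_mean = 5000,
                       read_length_sdlog = 0.35,
                       read_length_min = 300L,
                       error_rate = 0.05,
                       error_split = c(0.6, 0.2, 0.2),
                       fidelity = 0.95,
                       wgbs_depth = 20,
                       gc_bias_fn = function(gc_pct) ifelse(gc_pct < 35, 2, 0.5)) {
  stopifnot(
    n_contigs > 0, contig_length > 0, gc_window > 0,
    all(gc_range >= 0 & gc_range <= 1),
    cpg_per_kb >= 0, length(meth_weights) == length(meth_shape1),
    length(meth_shape1) == length(meth_shape2),
    abs(sum(meth_weights) - 1) < 1e-9,
    n_reads > 0, error_rate >= 0, error_rate < 1,
    abs(sum(error_split) - 1) < 1e-9,
    fidelity >= 0, fidelity <= 1, wgbs_depth > 0
  )
  structure(
    list(
      seed = as.integer(seed), n_contigs = as.integer(n_contigs),
      contig_length = as.integer(contig_length),
      gc_window = as.integer(gc_window), gc_range = gc_range,
      cpg_per_kb = cpg_per_kb, meth_weights = meth_weights,
      meth_shape1 = meth_shape1, meth_shape2 = meth_shape2,
      n_reads = as.integer(n_reads), read_length_mean = read_length_mean,
      read_length_sdlog = read_length_sdlog,
      read_length_min = as.integer(read_length_min),
      error_rate = error_rate, error_split = error_split,
      fidelity = fidelity, wgbs_depth = wgbs_depth, gc_bias_fn = gc_bias_fn
    ),
    class = "nmq_sim_config"
  )
}

#' Simulate a toy genome
#'
#' Builds each contig window by window with an exact GC base count matching
#' the window's target (a linear ramp over `gc_range`), plants CpG
#' dinucleotides at Poisson(`cpg_per_kb`) density, and removes accidental
#' `CG` dinucleotides by composition-preserving swaps so that the planted
#' sites dominate the CpG landscape. Realised window GC stays within 2
#' percentage points of target.
#'
#' @param config An [sim_config()] object.
#' @return A genome tibble (`contig`, `sequence`, `length`).
#' @export
simulate_genome <- function(config) {
  with_seed(config$seed, {
    seqs <- vapply(seq_len(config$n_contigs), function(ci) {
      simulate_contig(config)
    }, character(1))
  })
  tibble(
    contig = paste0("chrS", seq_len(config$n_contigs)),
    sequence = seqs,
    length = nchar(seqs)
  )
}

simulate_contig <- function(config) {
  w <- config$gc_window
  len <- config$contig_length
  starts <- seq(0L, len - 1L, by = w)
  widths <- pmin(starts + w, len) - starts
  targets <- seq(config$gc_range[1], config$gc_range[2],
                 length.out = length(starts))
  chars <- vector("list", length(starts))
  planted <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    wd <- widths[k]
    g_target <- round(targets[k] * wd)
    n_cpg <- rpois(1L, config$cpg_per_kb * wd / 1000)
    slots <- seq(1L, wd - 2L, by = 2L)  # odd starts: planted CGs can't overlap
    n_cpg <- min(n_cpg, length(slots))
    if (2L * n_cpg > g_target) {
      abort("simulate_genome: infeasible GC/CpG combination (planted CGs exceed the GC budget)")
    }
    cg_at <- sort(sample(slots, n_cpg))
    v <- character(wd)
    v[cg_at + 1L] <- "C"
    v[cg_at + 2L] <- "G"
    free <- which(v == "")
    gc_left <- g_target - 2L * n_cpg
    gc_pos <- sample(free, gc_left)
    v[gc_pos] <- sample(c("C", "G"), gc_left, replace = TRUE)
    rest <- setdiff(free, gc_pos)
    v[rest] <- sample(c("A", "T"), length(rest), replace = TRUE)
    chars[[k]] <- v
    planted[[k]] <- starts[k] + cg_at  # 0-based contig coords
  }
  s <- unlist(chars)
  planted <- unlist(planted)
  s <- remove_accidental_cpg(s, planted, starts, widths)
  paste(s, collapse = "")
}

# Remove CG dinucleotides not in `planted` (0-based starts) by swapping the
# G with an A/T elsewhere in the same window; swaps preserve window base
# composition and cannot create new CGs.
remove_accidental_cpg <- function(s, planted, win_starts, win_widths) {
  n <- length(s)
  is_cg <- which(s[-n] == "C" & s[-1] == "G")  # 1-based index of the C
  acc <- setdiff(is_cg - 1L, planted)          # 0-based starts
  win_of <- findInterval(acc + 1L, win_starts)  # window index of the G
  for (j in seq_along(acc)) {
    gi <- acc[j] + 2L  # 1-based index of the G
    if (s[gi - 1L] != "C" || s[gi] != "G") next  # already fixed by a prior swap
    k <- win_of[j]
    lo <- win_starts[k] + 1L
    hi <- win_starts[k] + win_widths[k]
    cand <- lo:hi
    ok <- cand[s[cand] %in% c("A", "T")]
    ok <- ok[ok > 1L]
    ok <- ok[s[ok - 1L] != "C"]
    if (length(ok) > 0L) {
      tgt <- if (length(ok) == 1L) ok else sample(ok, 1L)
      tmp <- s[tgt]
      s[tgt] <- "G"
      s[gi] <- tmp
    } else {
      s[gi] <- "A"  # rare fallback; drifts window GC by one base
    }
  }
  s
}

#' Simulate a ground-truth methylome
#'
#' Draws a true methylation level `p` for every reference CG dinucleotide
#' from the configured Beta mixture (component sampled by weight, then
#' `Beta(shape1, shape2)` within the component).
#'
#' @param genome Genome tibble from [simulate_genome()].
#' @param config An [sim_config()] object.
#' @return The truth table: a tibble with `contig`, `pos` (0-based
#'   forward-strand C position) and `p` (true methylation level).
#' @export
simulate_methylome <- function(genome, config) {
  check_genome(genome)
  pos <- lapply(genome$sequence, cpg_positions)
  if (sum(lengths(pos)) == 0L) abort("simulate_methylome: genome has no CpG sites")
  with_seed(config$seed + 1L, {
    out <- bind_rows(lapply(seq_len(nrow(genome)), function(i) {
      n <- length(pos[[i]])
      comp <- sample.int(length(config$meth_weights), n, replace = TRUE,
                         prob = config$meth_weights)
      tibble(
        contig = genome$contig[[i]],
        pos = pos[[i]],
        p = rbeta(n, config$meth_shape1[comp], config$meth_shape2[comp])
      )
    }))
  })
  out
}

#' Simulate ONT-like modified-base alignments
#'
#' Places reads uniformly on the genome (strand-balanced), injects
#' substitution/insertion/deletion errors as independent alignment columns
#' at the configured total rate (so the expected observed accuracy is
#' `1 - error_rate`), draws per-base Phred qualities consistent with that
#' rate, and attaches a 5mC modification call to every correctly basecalled
#' cytosine over a reference CpG: the molecule's state is
#' `Bernoulli(p_site)` and the call probability falls uniformly on the
#' correct side of 0.5 with probability `fidelity`, else on the wrong side.
#'
#' @param genome Genome tibble.
#' @param truth Truth table from [simulate_methylome()].
#' @param config An [sim_config()] object.
#' @return An alignment tibble in [read_modbam()] layout (`read_id`, `flag`,
#'   `contig`, `pos`, `strand`, `cigar`, `seq`, `qual`, `mod_calls`,
#'   `primary`).
#' @export
simulate_ont_reads <- function(genome, truth, config) {
  check_genome(genome)
  cpg_by_contig <- split(truth$pos, truth$contig)
  p_by_contig <- split(truth$p, truth$contig)
  e <- config$error_rate
  es <- e * config$error_split[1]
  ei <- e * config$error_split[2]
  ed <- e * config$error_split[3]
  q0 <- if (e > 0) error_to_phred(e) else 30
  bases <- c("A", "C", "G", "T")
  with_seed(config$seed + 2L, {
    rows <- vector("list", config$n_reads)
    for (i in seq_len(config$n_reads)) {
      ctg_i <- sample.int(nrow(genome), 1L, prob = genome$length)
      ctg <- genome$contig[[ctg_i]]
      clen <- genome$length[[ctg_i]]
      L <- 0L
      while (L < config$read_length_min || L > clen) {
        L <- as.integer(round(stats::rlnorm(
          1, log(config$read_length_mean) - config$read_length_sdlog^2 / 2,
          config$read_length_sdlog
        )))
      }
      start <- sample.int(clen - L + 1L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      rc <- strsplit(substring(genome$sequence[[ctg_i]], start + 1L, start + L),
                     "", fixed = TRUE)[[1]]
      # per-reference-column event, conditional on not-insertion
      ev <- sample(c("mat", "sub", "del"), L, replace = TRUE,
                   prob = c(1 - e, es, ed) / (1 - ei))
      ins <- if (ei > 0) rgeom(L, 1 - ei) else integer(L)
      n_cols <- L + sum(ins)
      op <- rep("I", n_cols)
      base_col <- cumsum(ins + 1L)           # column index of each ref base
      op[base_col] <- ifelse(ev == "del", "D", "M")
      qbase <- rep(NA_character_, n_cols)
      qbase[op == "I"] <- sample(bases, sum(ins), replace = TRUE)
      mat_cols <- base_col[ev == "mat"]
      qbase[mat_cols] <- rc[ev == "mat"]
      sub_cols <- base_col[ev == "sub"]
      if (length(sub_cols) > 0L) {
        shift <- sample.int(3L, length(sub_cols), replace = TRUE)
        qbase[sub_cols] <- bases[(match(rc[ev == "sub"], bases) - 1L + shift) %% 4L + 1L]
      }
      is_q <- !is.na(qbase)
      nq <- sum(is_q)
      qidx <- cumsum(is_q) - 1L              # 0-based query index per column
      ref_pos <- start + cumsum(op != "I") - 1L  # ref pos per column (valid for M/D)
      # cigar
      r <- rle(op)
      cigar <- paste0(r$lengths, r$values, collapse = "")
      # qualities
      qual <- pmin(pmax(as.integer(round(rnorm(nq, q0, 3))), 2L), 40L)
      # modification calls at correctly basecalled CpG cytosines
      cpgs <- cpg_by_contig[[ctg]]
      ps <- p_by_contig[[ctg]]
      if (strand == "+") {
        site_cols <- mat_cols[rc[ev == "mat"] == "C" &
                                (ref_pos[mat_cols] %in% cpgs)]
        site_pos <- ref_pos[site_cols]
      } else {
        site_cols <- mat_cols[rc[ev == "mat"] == "G" &
                                ((ref_pos[mat_cols] - 1L) %in% cpgs)]
        site_pos <- ref_pos[site_cols] - 1L
      }
      calls <- empty_mod_calls()
      if (length(site_cols) > 0L) {
        p_i <- ps[match(site_pos, cpgs)]
        state <- rbinom(length(p_i), 1L, p_i)
        correct <- rbinom(length(p_i), 1L, config$fidelity)
        high <- (state == 1L) == (correct == 1L)
        prob <- ifelse(high, runif(length(p_i), 0.5, 1), runif(length(p_i), 0, 0.5))
        qi <- qidx[site_cols]
        offset <- if (strand == "+") qi else nq - 1L - qi
        o <- order(offset)
        calls <- tibble(offset = as.integer(offset[o]), prob = prob[o])
      }
      rows[[i]] <- tibble(
        read_id = sprintf("read_%05d", i),
        flag = if (strand == "-") 16L else 0L,
        contig = ctg, pos = start, strand = strand, cigar = cigar,
        seq = paste(qbase[is_q], collapse = ""),
        qual = list(qual), mod_calls = list(calls), primary = TRUE
      )
    }
  })
  bind_rows(rows)
}

#' Simulate WGBS-like per-site methylation with GC-dependent depth
#'
#' Draws per-CpG coverage `Poisson(wgbs_depth * f(GC))`, where `f` is the
#' configured GC-bias factor of the 1 kb window containing the site, and
#' methylated counts `Binomial(coverage, p)`. Sites drawing zero coverage
#' are omitted, reproducing the CpG recovery gap of amplification-biased
#' short-read data. Also emits a per-window summed-depth table for
#' [gc_bias_profile()], drawn from the same biased rate.
#'
#' @param genome Genome tibble.
#' @param truth Truth table from [simulate_methylome()].
#' @param config An [sim_config()] object.
#' @param bin_size GC window size in bases (default 1 kb).
#' @return A list with `sites` (bedMethyl-shaped tibble: `contig`, `start`,
#'   `end`, `name`, `score`, `strand = "."`, `coverage`, `pct_methylated`,
#'   plus `n_modified`/`n_canonical` for aggregation) and `depth`
#'   (`contig`, `start`, `end`, `depth`).
#' @export
simulate_wgbs_sites <- function(genome, truth, config, bin_size = 1000L) {
  check_genome(genome)
  with_seed(config$seed + 3L, {
    out <- lapply(seq_len(nrow(genome)), function(i) {
      ctg <- genome$contig[[i]]
      len <- genome$length[[i]]
      dss <- Biostrings::DNAString(genome$sequence[[i]])
      starts <- seq(0L, len - 1L, by = bin_size)
      ends <- pmin(starts + bin_size, len)
      v <- Biostrings::Views(dss, start = starts + 1L, end = ends)
      freq <- Biostrings::letterFrequency(v, letters = c("C", "G"))
      gc_pct <- as.integer(round(100 * rowSums(freq) / (ends - starts)))
      fac <- config$gc_bias_fn(gc_pct)
      tt <- truth[truth$contig == ctg, ]
      bin_of <- tt$pos %/% bin_size + 1L
      cov <- rpois(nrow(tt), config$wgbs_depth * fac[bin_of])
      n_meth <- rbinom(nrow(tt), cov, tt$p)
      keep <- cov > 0L
      sites <- tibble(
        contig = ctg, start = tt$pos[keep], end = tt$pos[keep] + 1L,
        name = "m5C", score = pmin(cov[keep], 1000L), strand = ".",
        coverage = cov[keep],
        pct_methylated = 100 * n_meth[keep] / cov[keep],
        n_modified = n_meth[keep],
        n_canonical = cov[keep] - n_meth[keep]
      )
      depth <- tibble(
        contig = ctg, start = as.integer(starts), end = as.integer(ends),
        depth = rpois(length(starts),
                      config$wgbs_depth * fac * (ends - starts))
      )
      list(sites = sites, depth = depth)
    })
  })
  list(
    sites = bind_rows(lapply(out, `[[`, "sites")),
    depth = bind_rows(lapply(out, `[[`, "depth"))
  )
}

#' Simulate a derived assembly and its chains
#'
#' Applies an edit script of insertions and deletions to a genome, producing
#' the edited assembly and the UCSC-style chains that exactly describe the
#' edits (source = input genome, target = edited genome). Deleted source
#' positions become inter-block `dt` gaps and are unmappable by
#' [liftover_sites()]; inserted target bases become `dq` gaps.
#'
#' @param genome Genome tibble (the source assembly).
#' @param edits Tibble with `contig`, `pos` (0-based source coordinate),
#'   `type` (`"ins"` or `"del"`), `length`. Edits must not overlap and must
#'   not touch contig ends.
#' @param seed Seed for the randomly drawn inserted bases.
#' @return A list with `genome` (the edited assembly, contigs suffixed
#'   `"_v2"`) and `chains` (chain tibble, one chain per contig).
#' @export
simulate_chain <- function(genome, edits = NULL, seed = 1L) {
  check_genome(genome)
  if (is.null(edits) || nrow(edits) == 0L) {
    edits <- tibble(contig = character(), pos = integer(),
                    type = character(), length = integer())
  }
  stopifnot(all(edits$type %in% c("ins", "del")), all(edits$length > 0))
  with_seed(seed, {
    per <- lapply(seq_len(nrow(genome)), function(i) {
      ctg <- genome$contig[[i]]
      Ls <- genome$length[[i]]
      ed <- edits[edits$contig == ctg, ]
      ed <- ed[order(ed$pos), ]
      span_end <- ed$pos + ifelse(ed$type == "del", ed$length, 0L)
      if (nrow(ed) > 0L) {
        if (any(ed$pos <= 0L) || any(span_end >= Ls)) {
          abort("simulate_chain: edits must not touch contig ends")
        }
        if (nrow(ed) > 1L && any(ed$pos[-1] < span_end[-nrow(ed)] + 1L)) {
          abort("simulate_chain: overlapping or adjacent edits")
        }
      }
      src <- genome$sequence[[i]]
      blocks <- list(); tgt_parts <- list()
      cursor <- 0L; t_len <- 0L
      for (k in seq_len(nrow(ed))) {
        size <- ed$pos[k] - cursor
        tgt_parts[[length(tgt_parts) + 1L]] <-
          substring(src, cursor + 1L, ed$pos[k])
        if (ed$type[k] == "del") {
          blocks[[length(blocks) + 1L]] <-
            c(size = size, dt = ed$length[k], dq = 0)
          cursor <- ed$pos[k] + ed$length[k]
          t_len <- t_len + size
        } else {
          blocks[[length(blocks) + 1L]] <-
            c(size = size, dt = 0, dq = ed$length[k])
          tgt_parts[[length(tgt_parts) + 1L]] <-
            paste(sample(c("A", "C", "G", "T"), ed$length[k], replace = TRUE),
                  collapse = "")
          cursor <- ed$pos[k]
          t_len <- t_len + size + ed$length[k]
        }
      }
      blocks[[length(blocks) + 1L]] <- c(size = Ls - cursor, dt = 0, dq = 0)
      tgt_parts[[length(tgt_parts) + 1L]] <- substring(src, cursor + 1L, Ls)
      t_len <- t_len + Ls - cursor
      tgt_seq <- paste(unlist(tgt_parts), collapse = "")
      stopifnot(nchar(tgt_seq) == t_len)
      bl <- as_tibble(do.call(rbind, blocks))
      chain <- tibble(
        chain_id = i, score = Ls,
        source_contig = ctg, source_size = Ls, source_strand = "+",
        source_start = 0L, source_end = Ls,
        target_contig = paste0(ctg, "_v2"), target_size = t_len,
        target_strand = "+", target_start = 0L, target_end = t_len,
        blocks = list(bl)
      )
      validate_chain(chain)
      list(seq = tgt_seq, chain = chain)
    })
  })
  list(
    genome = tibble(
      contig = paste0(genome$contig, "_v2"),
      sequence = vapply(per, `[[`, character(1), "seq"),
      length = vapply(per, function(x) nchar(x$seq), integer(1))
    ),
    chains = bind_rows(lapply(per, `[[`, "chain"))
  )
}

#' Simulate a complete study dataset
#'
#' Convenience wrapper running the whole generator: genome, truth methylome,
#' ONT-like alignments, WGBS-like sites/depth, and a random TSS annotation
#' (`n_genes` single-exon gene models with random strands).
#'
#' @param config An [sim_config()] object.
#' @param n_genes Number of random gene models for the TSS table.
#' @return A list of class `nmq_simulation` with elements `config`,
#'   `genome`, `truth`, `reads`, `wgbs` (list of `sites`, `depth`), `tss`.
#' @export
simulate_dataset <- function(config = sim_config(), n_genes = 100L) {
  genome <- simulate_genome(config)
  truth <- simulate_methylome(genome, config)
  reads <- simulate_ont_reads(genome, truth, config)
  wgbs <- simulate_wgbs_sites(genome, truth, config)
  tss <- with_seed(config$seed + 4L, {
    ctg_i <- sample.int(nrow(genome), n_genes, replace = TRUE,
                        prob = genome$length)
    glen <- sample(1000:10000, n_genes, replace = TRUE)
    start <- vapply(seq_len(n_genes), function(j) {
      sample.int(genome$length[[ctg_i[j]]] - glen[j], 1L) - 1L
    }, integer(1))
    out <- tibble(
      contig = genome$contig[ctg_i],
      start = start, end = start + glen,
      name = sprintf("gene_%03d", seq_len(n_genes)),
      score = 0, strand = sample(c("+", "-"), n_genes, replace = TRUE)
    )
    out$tss <- ifelse(out$strand == "-", out$end - 1L, out$start)
    out
  })
  structure(
    list(config = config, genome = genome, truth = truth, reads = reads,
         wgbs = wgbs, tss = tss),
    class = "nmq_simulation"
  )
}

#' @export
print.nmq_simulation <- function(x, ...) {
  cat(sprintf(
    "<synthetic 5mC dataset> %d contig(s), %s bases; %d CpG sites (truth mean %.3f); %d ONT reads; %d WGBS sites\n",
    nrow(x$genome), format(sum(x$genome$length), big.mark = ","),
    nrow(x$truth), mean(x$truth$p), nrow(x$reads), nrow(x$wgbs$sites)
  ))
  invisible(x)
}
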