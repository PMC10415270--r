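small_cfg <- function(...) {
  sim_config(seed = 5L, n_contigs = 1L, contig_length = 20000L,
             n_reads = 150L, read_length_mean = 1500, ...)
}

test_that("simulated genomes hit their per-window GC targets within 2 points", {
  cfg <- small_cfg()
  g <- simulate_genome(cfg)
  expect_equal(g$length, cfg$contig_length)
  expect_false(grepl("[^ACGTN]", g$sequence))
  w <- cfg$gc_window
  targets <- seq(cfg$gc_range[1], cfg$gc_range[2],
                 length.out = cfg$contig_length / w)
  v <- Biostrings::Views(
    Biostrings::DNAString(g$sequence),
    start = seq(1L, cfg$contig_length, by = w), width = w
  )
  gc <- rowSums(Biostrings::letterFrequency(v, c("C", "G"))) / w
  expect_true(all(abs(gc - targets) <= 0.02))
})

test_that("genome generation is deterministic per seed", {
  expect_identical(simulate_genome(small_cfg()), simulate_genome(small_cfg()))
  g1 <- simulate_genome(sim_config(seed = 1L, n_contigs = 1L,
                                   contig_length = 10000L))
  g2 <- simulate_genome(sim_config(seed = 2L, n_contigs = 1L,
                                   contig_length = 10000L))
  expect_false(identical(g1$sequence, g2$sequence))
})

test_that("planted CpG density matches the configuration within Poisson noise", {
  cfg <- small_cfg()
  g <- simulate_genome(cfg)
  n_cg <- length(nanomethqc:::cpg_positions(g$sequence))
  lambda <- cfg$cpg_per_kb * cfg$contig_length / 1000
  expect_lt(abs(n_cg - lambda), 4 * sqrt(lambda))
})

test_that("methylome draws follow the configured Beta mixture", {
  cfg <- small_cfg()
  g <- simulate_genome(cfg)
  # degenerate mixture at p = 1
  cfg1 <- small_cfg(meth_weights = 1, meth_shape1 = 1e9, meth_shape2 = 1e-9)
  t1 <- simulate_methylome(g, cfg1)
  expect_true(all(t1$p > 0.999))

  truth <- simulate_methylome(g, cfg)
  mu <- sum(cfg$meth_weights * cfg$meth_shape1 /
              (cfg$meth_shape1 + cfg$meth_shape2))
  expect_lt(abs(mean(truth$p) - mu), 3 * stats::sd(truth$p) / sqrt(nrow(truth)))

  # two-component mixture is bimodal: both tails outweigh the middle
  h <- table(cut(truth$p, c(0, 0.3, 0.7, 1)))
  expect_gt(h[[1]], h[[2]])
  expect_gt(h[[3]], h[[2]])
})

test_that("simulated reads respect orientation, bounds and call sidedness", {
  cfg <- small_cfg(fidelity = 1)
  g <- simulate_genome(cfg)
  truth <- simulate_methylome(g, cfg)
  truth$p <- rep(1, nrow(truth))  # fully methylated molecule truth
  reads <- simulate_ont_reads(g, truth, cfg)
  expect_equal(nrow(reads), cfg$n_reads)
  # every read stays on the contig
  cglen <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  expect_true(all(reads$pos >= 0 & reads$pos + cglen <= g$length))
  # query-consuming CIGAR length equals sequence and quality length
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(reads$cigar)
  expect_equal(qlen, nchar(reads$seq))
  expect_equal(lengths(reads$qual), nchar(reads$seq))
  # with fidelity 1 and p = 1 every call is on the modified side
  probs <- unlist(lapply(reads$mod_calls, `[[`, "prob"))
  expect_gt(length(probs), 100)
  expect_true(all(probs >= 0.5))
  # strand balance within 3 binomial SE of one half
  n_minus <- sum(reads$strand == "-")
  expect_lt(abs(n_minus - cfg$n_reads / 2), 3 * sqrt(cfg$n_reads * 0.25))
  # every call offset addresses a C in the original-orientation read
  for (i in sample(nrow(reads), 25)) {
    calls <- reads$mod_calls[[i]]
    if (nrow(calls) == 0) next
    original <- if (reads$strand[[i]] == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(reads$seq[[i]])))
    } else {
      reads$seq[[i]]
    }
    expect_true(all(strsplit(original, "")[[1]][calls$offset + 1L] == "C"))
  }
})

test_that("read generation is deterministic and end-to-end recovery holds", {
  cfg <- small_cfg(fidelity = 1)
  g <- simulate_genome(cfg)
  truth <- simulate_methylome(g, cfg)
  r1 <- simulate_ont_reads(g, truth, cfg)
  r2 <- simulate_ont_reads(g, truth, cfg)
  expect_identical(r1, r2)

  # pipeline estimate of genome-wide methylation within 3 SE of the truth mean
  sites <- pileup_sites(r1, g)
  cpgs <- collapse_cpg(sites, g)
  joined <- dplyr::inner_join(cpgs, truth, by = c("contig", "pos"))
  n_i <- joined$n_modified + joined$n_canonical
  est <- 100 * sum(joined$n_modified) / sum(n_i)
  target <- 100 * sum(n_i * joined$p) / sum(n_i)
  se <- 100 * sqrt(sum(n_i * joined$p * (1 - joined$p))) / sum(n_i)
  expect_lt(abs(est - target), 3 * se)
})

test_that("WGBS site tables follow the injected GC-depth model", {
  cfg <- small_cfg()
  g <- simulate_genome(cfg)
  truth <- simulate_methylome(g, cfg)

  # p = 0 everywhere: all percent-methylated are 0
  t0 <- truth; t0$p <- 0
  w0 <- simulate_wgbs_sites(g, t0, cfg)
  expect_true(all(w0$sites$pct_methylated == 0))
  expect_true(all(w0$sites$coverage > 0))  # zero-coverage sites are omitted

  # flat GC-depth function: site coverage independent of window GC
  cfg_flat <- small_cfg(gc_bias_fn = function(gc) rep(1, length(gc)))
  wf <- simulate_wgbs_sites(g, truth, cfg_flat)
  gc <- tidy(gc_bias_profile(g, wf$depth, 1000L))
  fit <- stats::lm(normalized ~ gc_pct, data = gc[!is.na(gc$normalized), ])
  expect_lt(abs(stats::coef(fit)[["gc_pct"]]), 0.002)

  # step bias: the covered-CpG fraction drops in high-GC windows
  wb <- simulate_wgbs_sites(g, truth, small_cfg(wgbs_depth = 1.5))
  bin_gc <- rowSums(Biostrings::letterFrequency(
    Biostrings::Views(Biostrings::DNAString(g$sequence),
                      start = seq(1L, g$length, by = 1000L), width = 1000L),
    c("C", "G")
  )) / 10  # percent
  site_bin <- truth$pos %/% 1000L + 1L
  covered <- truth$pos %in% wb$sites$start
  low <- bin_gc[site_bin] < 35
  expect_gt(mean(covered[low]), mean(covered[!low]))
})

test_that("every simulated artefact round-trips through its reader silently", {
  cfg <- small_cfg()
  sim <- simulate_dataset(cfg, n_genes = 20L)
  dir <- withr::local_tempdir()
  expect_no_warning({
    write_fasta(sim$genome, file.path(dir, "ref.fa"))
    write_sam(head(sim$reads, 50), sim$genome, file.path(dir, "reads.sam"))
    write_fastq(head(sim$reads, 50), file.path(dir, "reads.fastq"))
    write_bed(sim$tss, file.path(dir, "tss.bed"))
    wg <- dplyr::arrange(sim$wgbs$sites,
                         match(contig, unique(contig)), start)
    write_bedmethyl(wg[, c("contig", "start", "end", "name", "score",
                           "strand", "coverage", "pct_methylated")],
                    file.path(dir, "wgbs.bed"))
    ch <- simulate_chain(sim$genome, tibble::tibble(
      contig = sim$genome$contig[[1]], pos = 5000L, type = "del", length = 100L
    ))
    write_chain(ch$chains, file.path(dir, "edits.chain"))
  })
  expect_no_warning({
    expect_equal(read_fasta(file.path(dir, "ref.fa")), sim$genome)
    expect_equal(nrow(read_modbam(file.path(dir, "reads.sam"))), 50L)
    expect_equal(read_fastq(file.path(dir, "reads.fastq"))$seq,
                 head(sim$reads, 50)$seq)
    expect_equal(read_bed(file.path(dir, "tss.bed"))$tss, sim$tss$tss)
    expect_equal(nrow(read_bedmethyl(file.path(dir, "wgbs.bed"))),
                 nrow(sim$wgbs$sites))
    expect_equal(parse_chain(file.path(dir, "edits.chain"))$target_size,
                 ch$chains$target_size)
  })
})

test_that("chain edits delete CpG sites from the liftable set", {
  cfg <- small_cfg()
  g <- simulate_genome(cfg)
  truth <- simulate_methylome(g, cfg)
  # delete a window containing at least one CpG
  victim <- truth$pos[which(truth$pos > 1000)[1]]
  ch <- simulate_chain(g, tibble::tibble(
    contig = g$contig[[1]], pos = victim - 5L, type = "del", length = 20L
  ))
  rec <- tibble::tibble(
    contig = g$contig[[1]], start = truth$pos, end = truth$pos + 1L,
    strand = "."
  )
  lo <- liftover_sites(rec, ch$chains)
  expect_true(victim %in% lo$unmapped$start)
  expect_equal(nrow(lo$mapped) + nrow(lo$unmapped), nrow(rec))
})
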