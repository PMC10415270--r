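# A 20-base genome with CGs at forward positions 2, 8 and 14:
#   pos: 01234567890123456789
#   seq: AACGTACACGTTAACGTTAA
meth_ref <- function() tiny_genome(chr = "AACGTACACGTTAACGTTAA")

test_that("pileup projects calls through the CIGAR and applies the >= threshold", {
  ref <- meth_ref()
  # forward read covering [0,10): C of the CpG at ref 2 is query offset 2
  r1 <- make_read("chr", 0, "10M", "AACGTACACG",
                  mod_offsets = 2L, mod_probs = 0.9)
  s1 <- pileup_sites(r1, ref)
  expect_equal(s1$pos, 2L)
  expect_equal(s1$strand, "+")
  expect_equal(s1$n_modified, 1L)
  expect_equal(s1$n_canonical, 0L)

  # two reads over the same C with p = 0.9 and 0.1: one modified, one canonical
  r2 <- dplyr::bind_rows(
    r1,
    make_read("chr", 0, "10M", "AACGTACACG",
              mod_offsets = 2L, mod_probs = 0.1, read_id = "r2")
  )
  s2 <- pileup_sites(r2, ref)
  expect_equal(s2$n_modified, 1L)
  expect_equal(s2$n_canonical, 1L)

  # p = 0.5 exactly counts as modified (>= rule)
  r3 <- make_read("chr", 0, "10M", "AACGTACACG",
                  mod_offsets = 2L, mod_probs = 0.5)
  expect_equal(pileup_sites(r3, ref)$n_modified, 1L)

  # dual thresholds: mid-probability calls become ambiguous
  s4 <- pileup_sites(r3, ref, threshold = c(0.33, 0.66))
  expect_equal(s4$n_modified, 0L)
  expect_equal(s4$n_ambiguous, 1L)
})

test_that("pileup handles indels, reverse strands and dropped calls", {
  ref <- meth_ref()
  # 2M2D8M: query offset 2 sits at ref position 4 after the deletion;
  # query offsets 0..1 -> ref 0..1, offsets 2.. -> ref 4..
  # ref C of the CpG at 8 is query offset 6
  r <- make_read("chr", 0, "2M2D8M", "AATACACGTT",
                 mod_offsets = 6L, mod_probs = 0.8)
  s <- pileup_sites(r, ref)
  expect_equal(s$pos, 8L)

  # insertion: call on an inserted base has no reference position -> dropped
  r2 <- make_read("chr", 0, "2M3I8M", "AACCCCGTACACG",
                  mod_offsets = c(2L, 3L), mod_probs = c(0.9, 0.9))
  expect_equal(nrow(pileup_sites(r2, ref)), 0L)

  # reverse read over [0,10): stored seq = ref; original read = revcomp.
  # The G of the CpG at ref 3 is stored index 3, original offset 10-1-3 = 6
  r3 <- make_read("chr", 0, "10M", "AACGTACACG", strand = "-",
                  mod_offsets = 6L, mod_probs = 0.95)
  s3 <- pileup_sites(r3, ref)
  expect_equal(s3$pos, 3L)
  expect_equal(s3$strand, "-")
  expect_equal(s3$n_modified, 1L)
})

test_that("CpG collapsing pools the + C with the - G of each reference CG", {
  ref <- tiny_genome(chr = "ACGT")
  sites <- tibble::tibble(
    contig = "chr", pos = c(1L, 2L), strand = c("+", "-"),
    n_modified = c(1L, 0L), n_canonical = c(0L, 1L), n_ambiguous = 0L
  )
  cpg <- collapse_cpg(sites, ref)
  expect_equal(cpg$pos, 1L)
  expect_equal(cpg$n_modified, 1L)
  expect_equal(cpg$n_canonical, 1L)
  expect_equal(cpg$fwd_coverage, 1L)
  expect_equal(cpg$rev_coverage, 1L)

  # only + coverage: rev_coverage is 0
  cpg2 <- collapse_cpg(sites[1, ], ref)
  expect_equal(cpg2$rev_coverage, 0L)

  # a + site over a non-CG cytosine is excluded
  ref3 <- tiny_genome(chr = "ACAT")
  expect_equal(nrow(collapse_cpg(sites[1, ], ref3)), 0L)
})

test_that("collapsing conserves counts at CG positions on synthetic data", {
  sim <- default_sim()
  sites <- default_sites()
  cpgs <- default_cpgs()
  # which strand sites sit on reference CGs
  at_cg <- logical(nrow(sites))
  for (ctg in sim$genome$contig) {
    cg <- nanomethqc:::cpg_positions(sim$genome$sequence[sim$genome$contig == ctg])
    i <- sites$contig == ctg
    at_cg[i] <- (sites$strand[i] == "+" & sites$pos[i] %in% cg) |
      (sites$strand[i] == "-" & (sites$pos[i] - 1L) %in% cg)
  }
  expect_equal(sum(cpgs$n_modified), sum(sites$n_modified[at_cg]))
  expect_equal(sum(cpgs$n_canonical), sum(sites$n_canonical[at_cg]))
  expect_equal(sum(cpgs$fwd_coverage) + sum(cpgs$rev_coverage),
               sum((sites$n_modified + sites$n_canonical)[at_cg]))
  # the simulator only emits CpG calls, so nothing is lost at all
  expect_equal(sum(cpgs$n_modified) + sum(cpgs$n_canonical),
               sum(sites$n_modified) + sum(sites$n_canonical))
})

test_that("covered-CpG fraction requires coverage on both strands", {
  ref <- tiny_genome(chr = "ACGACGACGT")  # CGs at 1, 4, 7
  cpgs <- tibble::tibble(
    contig = "chr", pos = c(1L, 4L, 7L),
    n_modified = c(1L, 2L, 3L), n_canonical = 0L, n_ambiguous = 0L,
    fwd_coverage = c(1L, 3L, 0L), rev_coverage = c(1L, 0L, 2L)
  )
  cov <- covered_cpg_fraction(cpgs, ref)
  expect_equal(cov$fraction[cov$contig == "chr"], 1 / 3)
  expect_equal(cov$n_cpg[cov$contig == "overall"], 3L)
  expect_error(covered_cpg_fraction(cpgs, ref, contigs = character()), "empty")
})

test_that("covered-CpG fraction is monotone under adding reads", {
  sim <- default_sim()
  half <- pileup_sites(head(sim$reads, 1000), sim$genome)
  full_frac <- covered_cpg_fraction(default_cpgs(), sim$genome)
  half_frac <- covered_cpg_fraction(collapse_cpg(half, sim$genome), sim$genome)
  expect_true(all(
    half_frac$fraction <= full_frac$fraction + 1e-12
  ))
})

test_that("bin methylation pools counts per window with truncation at contig end", {
  ref <- tiny_genome(chr = strrep("A", 250))
  cpgs <- tibble::tibble(
    contig = "chr", pos = c(10L, 60L, 120L),
    n_modified = c(3L, 1L, 4L), n_canonical = c(1L, 3L, 0L)
  )
  bins <- bin_methylation(cpgs, ref, bin_size = 100L)
  expect_equal(nrow(bins), 3L)
  expect_equal(bins$end, c(100L, 200L, 250L))
  expect_equal(bins$proportion, c(100 * 4 / 8, 100, NA_real_))
  expect_equal(bins$n_sites, c(2L, 1L, 0L))
})

test_that("pooled bin proportions aggregate exactly to the overall figure", {
  sim <- default_sim()
  cpgs <- default_cpgs()
  bins <- bin_methylation(cpgs, sim$genome)
  pooled <- 100 * sum(bins$n_modified) / sum(bins$n_valid)
  expect_identical(pooled, overall_methylation(cpgs))
})

test_that("promoters are the strand-aware 5' window, clipped to the contig", {
  ref <- tiny_genome(chr = strrep("AC", 4000))  # 8000 bp
  cpgs <- tibble::tibble(
    contig = "chr", pos = c(1500L, 6500L),
    n_modified = c(2L, 1L), n_canonical = c(2L, 0L)
  )
  tss <- tibble::tibble(
    contig = "chr", strand = c("+", "-"), tss = c(6000L, 6000L),
    name = c("plus_gene", "minus_gene")
  )
  prom <- promoter_methylation(cpgs, tss, ref)
  expect_equal(prom$start, c(1000L, 6001L))
  expect_equal(prom$end, c(6000L, 8000L))
  expect_equal(prom$proportion[1], 50)   # the CpG at 1500 with 2/4
  expect_equal(prom$proportion[2], 100)  # the CpG at 6500 with 1/1

  # TSS outside the contig: skipped with a warning
  tss_bad <- tibble::tibble(contig = "chr", strand = "+", tss = 9000L,
                            name = "off_end")
  expect_warning(out <- promoter_methylation(cpgs, tss_bad, ref), "skipping")
  expect_equal(nrow(out), 0L)
})

test_that("per-read methylation is the modified fraction of unambiguous calls", {
  r <- make_read("chr", 0, "5M", "CCCCC",
                 mod_offsets = c(0L, 1L, 2L), mod_probs = c(0.9, 0.9, 0.1))
  expect_equal(per_read_methylation(r)$methylation, 2 / 3)

  r2 <- make_read("chr", 0, "5M", "CCCCC",
                  mod_offsets = c(0L, 1L), mod_probs = c(0.4, 0.6))
  expect_true(is.na(per_read_methylation(r2, threshold = c(0.33, 0.66))$methylation))

  r3 <- make_read("chr", 0, "5M", "CCCCC", mod_offsets = 0L, mod_probs = 0.99)
  expect_equal(per_read_methylation(r3)$methylation, 1)
})

test_that("overall methylation pools counts and rejects empty input", {
  s <- tibble::tibble(n_modified = c(3L, 1L), n_canonical = c(1L, 3L))
  expect_equal(overall_methylation(s), 50)
  s_all <- tibble::tibble(n_modified = 5L, n_canonical = 0L)
  expect_equal(overall_methylation(s_all), 100)
  expect_error(
    overall_methylation(tibble::tibble(n_modified = 0L, n_canonical = 0L)),
    "no valid calls"
  )
})

test_that("site estimates recover the simulated methylome", {
  sim <- default_sim()
  cpgs <- default_cpgs()
  joined <- dplyr::inner_join(cpgs, sim$truth, by = c("contig", "pos"))
  est <- 100 * sum(joined$n_modified) / sum(joined$n_modified + joined$n_canonical)
  # with fidelity f the expected called-modified fraction is f*p + (1-f)*(1-p)
  f <- sim$config$fidelity
  expected <- 100 * sum((f * joined$p + (1 - f) * (1 - joined$p)) *
                          (joined$n_modified + joined$n_canonical)) /
    sum(joined$n_modified + joined$n_canonical)
  n <- sum(joined$n_modified + joined$n_canonical)
  expect_lt(abs(est - expected), 3 * 100 * sqrt(0.25 / n))
})
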