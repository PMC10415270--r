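---
title: "Methods: validating nanopore 5mC methylation profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating nanopore 5mC methylation profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nanomethqc implements the technical-validation layer of whole-genome
5-methylcytosine (5mC) profiling from Oxford Nanopore long reads: read
quality control, methylation pileups from modified-base tags, regional
aggregation, saturation and bias diagnostics, cross-platform comparison,
and assembly liftover. This vignette explains the statistical procedures,
their assumptions, the tunable parameters, and the design decisions behind
them — including what the bundled synthetic-data generator does and does
not emulate.

## Read quality statistics

Two per-read accuracies are computed.

**Estimated accuracy** uses only the basecaller's Phred qualities: with
per-base error probabilities $10^{-q_i/10}$,

$$\mathrm{acc}_{est} = 1 - \frac{1}{N}\sum_{i=1}^{N} 10^{-q_i/10}.$$

It is permutation-invariant in the qualities and monotone in each $q_i$.

**Observed accuracy** uses the alignment. Every alignment column is
classified as match, substitution, insertion or deletion, with

$$N_{total} = N_{mat} + N_{sub} + N_{ins} + N_{del}, \qquad
  \mathrm{acc}_{obs} = N_{mat}/N_{total}.$$

`M` CIGAR operations are split into matches and substitutions by direct
comparison against the reference (`MD` tags are not required; synthetic
and most real alignments carry the reference anyway), `=`/`X` count
directly, and soft/hard clips and `N` skips contribute to no term — the
column identity above has no clip term, so clipped bases are excluded from
$N_{total}$. A reference `N` under an `M` op is uninformative and is
excluded from both $N_{mat}$ and $N_{sub}$. Observed accuracy is computed
on primary alignments only; secondary and supplementary records would
count the same read twice.

**Filtering** mirrors standard long-read cleanup: a fixed trim (default 50
bases) is removed from both ends *first*, then reads are dropped when the
post-trim length falls below 200 bases or the read-level quality falls
below Q7. The read-level quality is defined as
$-10\log_{10}(\text{mean per-base error probability})$ of the trimmed
read — the Q-scale twin of estimated accuracy, which is what common
long-read filters threshold when they speak of a "read quality score".
Reads of at most twice the trim length are discarded as fully trimmed.

**Modal accuracy** is reported as the centre of the fullest histogram bin.
The bin width defaults to 0.005 (half a percentage point); ties break
toward the lower bin so the mode is deterministic. There is no canonical
binning rule for a "modal accuracy", so the width is exposed as a
parameter.

## Methylation calling from modified-base tags

Aligned reads carry `MM`/`ML` tags encoding, per cytosine of the
original-orientation read, a 256-bin quantised probability that the base
is 5mC. Decoding resolves the `C+m` skip counts against the read's
cytosines and converts each byte with the mid-bin rule $(v + 0.5)/256$,
so decoded probabilities lie in $(0, 1)$ and re-encoding is exact
(decode/encode is a bijection on valid tags). For reverse-strand
alignments the stored sequence is the reverse complement of the basecalled
read; skip counts are resolved against the reverse complement and offsets
mapped back through the alignment.

**Pileup.** Each call is projected through the CIGAR to a reference
position; calls on inserted or clipped bases have none and are dropped. A
call with probability $\ge t$ counts as modified and $< 1 - t$ as
canonical; anything between is ambiguous and discarded. The default
$t = 0.5$ has no ambiguous zone, and a probability of exactly 0.5
classifies as modified — a deterministic boundary that matters because the
256-bin quantisation can land calls exactly on 0.5. An optional
dual-threshold mode (e.g. `c(0.33, 0.66)`) emulates tools that discard
mid-probability calls; site-level tallies then carry an `n_ambiguous`
column so nothing is silently lost.

**CpG collapsing.** A CpG dinucleotide is symmetric: the reverse-strand C
at position $i+1$ reports on the same site as the forward C at $i$. Sites
are therefore pooled per reference `CG` — and CpG identity is taken from
the *reference*, not from read sequences, since read errors would
otherwise create phantom sites. Strand sites that do not sit on a
reference CG (non-CpG cytosine calls) are excluded from CpG output.
Collapsing conserves counts: pooled modified/canonical totals equal the
strand-site sums at CG positions.

**Coverage rule.** A CpG site counts as *covered* only with at least one
valid call on each strand. This bidirectional rule is stricter than raw
depth and is the quantity that separates long-read from bisulfite coverage
in practice; the denominator is the total number of forward-strand CG
dinucleotides of the contigs considered.

## Regional aggregation

Contigs are tiled into fixed windows (default 100 kb, last window
truncated); promoters are the 5 kb window 5' of each transcription start
site — $[TSS - 5000, TSS)$ for `+` genes, $(TSS, TSS + 5000]$ for `-`
genes, clipped to contig bounds. Upstream is undefined without strand, so
promoters are strand-aware by construction. One record is emitted per
gene; overlapping promoters are not merged or deduplicated.

The regional proportion is the coverage-weighted pooled ratio
$100 \cdot \sum n_{mod} / \sum (n_{mod} + n_{can})$, not the unweighted
mean of per-site proportions. Pooling is the only choice under which
window totals aggregate *exactly* to the genome-wide figure (a tested
invariant); the unweighted mean over-weights low-coverage sites and breaks
that consistency.

## Saturation, correlation, GC bias, liftover

**Subsampling** keeps each read independently with probability $p$
(read-level Bernoulli, not exact-count draws — the semantics of common
read-sampling toolkits), seeded and with every derived seed recorded in
the returned curve object. The default grid is 10%–100% in steps of ten
with 10 replicates. At $p = 1$ every replicate equals the full-data
statistic exactly. The methylation-stability curve pools call-level counts
over the kept reads, which equals site-level pooling of the same calls.

**Regional correlation** is Pearson's $r$ over regions with data in both
datasets (complete-case). Because a platform that covers fewer CpG sites
sees a different site mixture in each window, a `shared_only` mode first
restricts *both* datasets to the CpG sites present in each, recomputes the
regional proportions from those shared sites only, and then correlates —
recompute-from-shared-sites rather than merely intersecting region lists,
which would leave the compositional difference in place.

**GC bias.** Each 1 kb window gets an integer GC percentage computed over
its non-N bases (windows over 50% N are dropped; gaps would otherwise
produce spurious 0%-GC levels); window depth is averaged per GC level, and
levels inside the 10–60% range — where most of a vertebrate genome lies —
are normalised by the mean depth of all in-range windows. A flat profile
sits at 1 by construction; amplification-biased short-read data shows the
characteristic high coverage at low GC and depletion at high GC.

**Liftover** maps single-base records between assemblies by walking
chain-file blocks: a position inside an aligned block maps by offset,
positions in gaps are returned unmapped (a result, not an error), and
where chains overlap the highest-scoring chain wins, deterministically.
Reverse-strand targets flip both the coordinate and the record's strand.
Chain block arithmetic is validated against the header spans on parse.
The implementation is cross-checked in the test suite against
`rtracklayer::liftOver` and a naive per-position block walk.

## The synthetic-data generator

Every stage above is exercised on generated data with a known ground
truth, so correctness can be asserted against the generating parameters
rather than against fixtures.

* **Genome** — contigs are built window by window with an *exact* GC base
  count per 1 kb window (targets ramp linearly over 25–60% GC, covering
  the normalisation range), CpG dinucleotides planted at
  Poisson(10 per kb), and accidental `CG`s removed by
  composition-preserving swaps so the CpG landscape is controlled.
  Realised window GC stays within 2 percentage points of target.
* **Methylome** — a true level $p_i$ per reference CpG from a Beta
  mixture, by default $0.848\,\mathrm{Beta}(9,1) +
  0.152\,\mathrm{Beta}(1,7)$: a hypermethylated bulk with a
  hypomethylated minority, bimodal with mean 0.782 — the genome-wide 5mC
  level typical of vertebrate tissue.
* **Reads** — 2,000 reads, log-normal lengths of mean 5 kb over a 500 kb
  genome, i.e. about 20x coverage; strands balanced; placement uniform.
  Alignment errors are independent columns at total rate 5% (split
  60/20/20 into substitution/insertion/deletion), so expected observed
  accuracy is $1 - e$ exactly. Methylation is *molecule-level*: each read
  draws its state per site as Bernoulli($p_i$) — the single-molecule
  semantics of nanopore calling — and the call probability falls
  uniformly on the correct side of 0.5 with probability `fidelity`
  (default 0.95), else on the wrong side. Note the identification
  consequence: with fidelity $f$ the expected called-modified fraction is
  $f p + (1-f)(1-p)$, so at the defaults the pipeline estimate sits
  roughly 2.5 points below the truth mean; tests that assert parameter
  recovery use $f = 1$.
* **WGBS-like sites** — per-CpG coverage Poisson with a GC-dependent rate
  multiplier (default step: 2x below 35% GC, 0.5x at or above — the
  amplification-bias pattern), methylated counts Binomial(coverage,
  $p_i$), zero-coverage sites omitted. The same biased rate drives the
  per-window depth table consumed by the GC-bias profile, which must
  recover the injected 4:1 ratio.
* **Chains** — an insertion/deletion edit script applied to the genome
  yields the edited assembly and chains that exactly describe the edits,
  giving liftover tests full ground truth.

Determinism: an identical configuration (including seed) reproduces every
output byte-for-byte; each generator derives an independent stream from
the master seed.

What the generator does **not** emulate: basecaller error motifs
(homopolymer compression, strand-specific biases), non-uniform read
placement, mapping ambiguity and chimeric reads, 5hmC or non-CpG
methylation, bisulfite conversion failure at the read level (WGBS is
simulated at site/coverage level only), or biological covariation between
methylation and GC content. Passing tests therefore demonstrate that the
*computations* are correct under controlled conditions, not that any
particular real dataset is well calibrated.

## Problem sizes and numerical choices

The default toy genome is 2 x 250 kb with ~5,000 CpGs and 2,000 reads;
generation takes well under a minute and the full validation sweep a few
minutes. Where the genome's size interacts with a statistic's stability,
sizes are chosen to keep the statistic meaningful: regional correlations
in the acceptance sweep use 10 kb windows, since a 500 kb genome yields
only five or six 100 kb windows — about a hundred 10 kb regions is the
same order as a chromosome's worth of 100 kb bins on a real genome.
Accuracy-tally acceptance checks run 1,000 short, high-error reads against
a brute-force per-base comparator.

Other fixed choices: coordinates are 0-based half-open everywhere
internally (BED convention on output); probability ties at a threshold
classify as modified; histogram mode ties break toward the lower bin;
written bedMethyl must arrive sorted by (contig, start) so outputs are
deterministic; subsample replicate seeds are derived arithmetically from
the base seed and the grid position and stored in the result.

## Known limitations

* Only `C+m` (5mC) modification tags are decoded; other marks error out
  explicitly rather than being silently ignored.
* Inputs are scanned linearly; there is no indexing or random access.
  This is deliberate — the package targets desk-scale validation, not
  production-scale pileup.
* Liftover handles single-base records (per-site tables); interval
  records would need split-mapping semantics that per-site methylation
  does not require.
* The promoter definition is a fixed upstream window; it does not model
  bidirectional promoters or use annotated CpG islands.
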