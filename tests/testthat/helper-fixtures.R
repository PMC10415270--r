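# Shared fixtures, built once per test run and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default study-condition dataset (the generator's defaults).
default_sim <- function() {
  memo("default_sim", function() simulate_dataset(sim_config(seed = 42L)))
}

# Per-strand pileup and collapsed CpG sites of the default dataset.
default_sites <- function() {
  memo("default_sites", function() {
    sim <- default_sim()
    pileup_sites(sim$reads, sim$genome)
  })
}

default_cpgs <- function() {
  memo("default_cpgs", function() {
    sim <- default_sim()
    collapse_cpg(default_sites(), sim$genome)
  })
}

# A small genome tibble from literal contig sequences.
tiny_genome <- function(...) {
  seqs <- c(...)
  tibble::tibble(
    contig = names(seqs),
    sequence = unname(toupper(seqs)),
    length = unname(nchar(seqs))
  )
}

# One aligned read row in the package's alignment-tibble layout.
make_read <- function(contig, pos, cigar, seq, strand = "+",
                      qual = rep(30L, nchar(seq)),
                      mod_offsets = integer(), mod_probs = double(),
                      read_id = "r1", primary = TRUE) {
  tibble::tibble(
    read_id = read_id,
    flag = if (strand == "-") 16L else 0L,
    contig = contig, pos = as.integer(pos), strand = strand, cigar = cigar,
    seq = toupper(seq), qual = list(as.integer(qual)),
    mod_calls = list(tibble::tibble(offset = as.integer(mod_offsets),
                                    prob = as.double(mod_probs))),
    primary = primary
  )
}

# Independent brute-force alignment comparator: walks the CIGAR column by
# column, comparing one base at a time. Deliberately naive; used as the
# oracle for tally_alignment / observed_accuracy.
brute_force_tally <- function(cigar, pos, seq, refseq) {
  op <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  len <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  qv <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  rv <- strsplit(toupper(refseq), "", fixed = TRUE)[[1]]
  qi <- 0L; ri <- pos
  mat <- 0L; sub <- 0L; ins <- 0L; del <- 0L
  for (k in seq_along(op)) {
    for (j in seq_len(len[k])) {
      if (op[k] %in% c("M", "=", "X")) {
        rb <- rv[ri + 1L]; qb <- qv[qi + 1L]
        if (op[k] == "=" || (op[k] == "M" && rb != "N" && rb == qb)) {
          mat <- mat + 1L
        } else if (op[k] == "X" || (op[k] == "M" && rb != "N")) {
          sub <- sub + 1L
        }
        qi <- qi + 1L; ri <- ri + 1L
      } else if (op[k] == "I") {
        ins <- ins + 1L; qi <- qi + 1L
      } else if (op[k] == "D") {
        del <- del + 1L; ri <- ri + 1L
      } else if (op[k] == "S") {
        qi <- qi + 1L
      } else if (op[k] == "N") {
        ri <- ri + 1L
      }
    }
  }
  c(mat = mat, sub = sub, ins = ins, del = del)
}
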