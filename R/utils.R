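# Internal helpers shared across modules.

# Phred integer -> error probability and back.
phred_to_error <- function(q) 10^(-q / 10)
error_to_phred <- function(p) -10 * log10(p)

# Run `code` with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Validate a genome tibble (contig, sequence, length) as produced by
# read_fasta()/simulate_genome().
check_genome <- function(ref) {
  stopifnot(is.data.frame(ref), all(c("contig", "sequence", "length") %in% names(ref)))
  if (any(nchar(ref$sequence) != ref$length)) {
    abort("genome tibble is inconsistent: sequence length differs from declared length")
  }
  invisible(ref)
}

genome_seq <- function(ref, contig) {
  i <- match(contig, ref$contig)
  if (is.na(i)) abort(paste0("contig not found in reference: ", contig))
  ref$sequence[[i]]
}

genome_len <- function(ref, contig) {
  i <- match(contig, ref$contig)
  if (is.na(i)) abort(paste0("contig not found in reference: ", contig))
  ref$length[[i]]
}

# Reverse-complement of an ACGTN string.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# 0-based positions (of the first base) of CG dinucleotides on the forward
# strand of one contig sequence.
cpg_positions <- function(sequence) {
  m <- Biostrings::matchPattern("CG", Biostrings::DNAString(sequence))
  BiocGenerics::start(m) - 1L
}

# Split a CIGAR string into parallel op / length vectors.
cigar_ops <- function(cigar) {
  list(
    op  = GenomicAlignments::explodeCigarOps(cigar)[[1]],
    len = GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  )
}

# Vectorised version over many CIGARs (one S4 dispatch for the whole batch).
explode_cigars <- function(cigars) {
  list(
    op  = GenomicAlignments::explodeCigarOps(cigars),
    len = GenomicAlignments::explodeCigarOpLengths(cigars)
  )
}

QUERY_OPS <- c("M", "=", "X", "I", "S")
REF_OPS   <- c("M", "=", "X", "D", "N")

# Map each stored-orientation query index (0-based) to its 0-based reference
# position, or NA where the base is inserted/clipped. `pos` is the 0-based
# leftmost reference coordinate of the alignment. A pre-exploded op/len list
# can be passed to avoid repeated CIGAR parsing.
query_to_ref_map <- function(cigar, pos, cg = NULL) {
  if (is.null(cg)) cg <- cigar_ops(cigar)
  qlen <- sum(cg$len[cg$op %in% QUERY_OPS])
  out <- rep(NA_integer_, qlen)
  qi <- 0L   # query cursor, 0-based
  ri <- pos  # reference cursor, 0-based
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; l <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      out[(qi + 1L):(qi + l)] <- ri + 0L:(l - 1L)
      qi <- qi + l; ri <- ri + l
    } else if (op %in% c("I", "S")) {
      qi <- qi + l
    } else if (op %in% c("D", "N")) {
      ri <- ri + l
    }
    # H consumes neither
  }
  out
}

# Phred+33 string <-> integer vector.
qual_to_int <- function(qual_string) {
  utf8ToInt(qual_string) - 33L
}
int_to_qual <- function(q) {
  intToUtf8(q + 33L)
}

empty_mod_calls <- function() {
  tibble(offset = integer(), prob = double())
}
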