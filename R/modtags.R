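#' Decode MM/ML base-modification tags into per-cytosine calls
#'
#' Resolves a `C+m` skip-count tag against the read sequence and converts the
#' 256-bin quantised `ML` values into modification probabilities using the
#' mid-bin rule `(ml + 0.5) / 256`.
#'
#' The `MM` skip counts index cytosines in the read's *original* (basecalled)
#' orientation. For a reverse-strand alignment the stored sequence is the
#' reverse complement of the original read, so counting is performed on the
#' reverse complement of `sequence`; returned offsets are always 0-based
#' indices into the original-orientation read.
#'
#' @param mm_text `MM` tag string, e.g. `"C+m,0,2,1;"`. Both the plain and
#'   the explicit-skip (`C+m?`/`C+m.`) spellings are accepted.
#' @param ml_values Integer vector of `ML` values in `0:255`, one per skip
#'   count in `mm_text`.
#' @param sequence Stored (alignment-orientation) read sequence.
#' @param reverse Logical; `TRUE` for a reverse-strand alignment.
#' @return A tibble with columns `offset` (0-based index into the
#'   original-orientation read, always a `C` there) and `prob` (probability
#'   the base is 5-methylcytosine).
#' @examples
#' decode_mod_tags("C+m,0,1;", c(230L, 10L), "CACAC", reverse = FALSE)
#' @export
decode_mod_tags <- function(mm_text, ml_values, sequence, reverse = FALSE) {
  skips <- parse_mm_skips(mm_text)
  ml_values <- as.integer(ml_values)
  if (length(ml_values) != length(skips)) {
    abort(sprintf(
      "MM/ML length mismatch: %d skip counts but %d ML values",
      length(skips), length(ml_values)
    ))
  }
  if (length(skips) == 0L) return(empty_mod_calls())
  if (any(ml_values < 0L | ml_values > 255L)) {
    abort("ML values must lie in 0:255")
  }
  original <- if (reverse) revcomp(sequence) else toupper(sequence)
  c_offsets <- which(strsplit(original, "", fixed = TRUE)[[1]] == "C") - 1L
  idx <- cumsum(skips + 1L)  # 1-based index into the read's C's
  if (length(c_offsets) < max(idx)) {
    abort(sprintf(
      "MM skip counts exhaust the read's cytosines (%d C's, need %d)",
      length(c_offsets), max(idx)
    ))
  }
  tibble(offset = c_offsets[idx], prob = (ml_values + 0.5) / 256)
}

#' Encode per-cytosine calls back into MM/ML tags
#'
#' Inverse of [decode_mod_tags()]: given call offsets (original-orientation,
#' 0-based, each addressing a `C`) and probabilities, emits the `C+m`
#' skip-count string and the quantised `ML` byte values
#' `floor(prob * 256)` clipped to `0:255`.
#'
#' @param offsets Integer vector of 0-based original-orientation offsets.
#' @param probs Modification probabilities in `[0, 1]`.
#' @inheritParams decode_mod_tags
#' @return A list with elements `mm` (tag string) and `ml` (integer vector).
#' @export
encode_mod_tags <- function(offsets, probs, sequence, reverse = FALSE) {
  original <- if (reverse) revcomp(sequence) else toupper(sequence)
  c_offsets <- which(strsplit(original, "", fixed = TRUE)[[1]] == "C") - 1L
  ord <- order(offsets)
  offsets <- as.integer(offsets)[ord]
  probs <- probs[ord]
  idx <- match(offsets, c_offsets)
  if (anyNA(idx)) {
    abort("encode_mod_tags: an offset does not address a C in the original-orientation read")
  }
  skips <- diff(c(0L, idx)) - 1L
  ml <- pmin(pmax(as.integer(floor(probs * 256)), 0L), 255L)
  mm <- if (length(skips) == 0L) "C+m;" else
    paste0("C+m,", paste(skips, collapse = ","), ";")
  list(mm = mm, ml = ml)
}

# Parse the skip counts out of a single C+m MM item. Accepts an optional
# trailing '?' or '.' flag after the modification code.
parse_mm_skips <- function(mm_text) {
  mm_text <- stringr::str_trim(mm_text)
  m <- stringr::str_match(mm_text, "^C\\+m[.?]?((,-?\\d+)*);?$")
  if (is.na(m[1, 1])) {
    abort(paste0("unsupported or malformed MM tag (only C+m is handled): ", mm_text))
  }
  body <- m[1, 2]
  if (body == "") return(integer())
  skips <- as.integer(strsplit(sub("^,", "", body), ",", fixed = TRUE)[[1]])
  if (any(skips < 0L)) abort("negative MM skip count")
  skips
}
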