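# Alphabet shared by the aligner: 20 standard residues plus ambiguity
# codes. U (selenocysteine) and O (pyrrolysine) are accepted in input and
# scored as X, since standard substitution matrices do not cover them.
aa_alphabet <- function() c("A","R","N","D","C","Q","E","G","H","I","L","K",
                            "M","F","P","S","T","W","Y","V","B","Z","X","*")

# BLOSUM62 restricted to the aligner alphabet, as a plain integer matrix.
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      ab <- aa_alphabet()
      cache <<- e$BLOSUM62[ab, ab]
      storage.mode(cache) <<- "integer"
    }
    cache
  }
})

encode_aa <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  chars[chars %in% c("U", "O")] <- "X"
  idx <- match(chars, aa_alphabet())
  if (anyNA(idx))
    stop("sequence contains characters outside the amino-acid alphabet: ",
         paste(unique(chars[is.na(idx)]), collapse = ""))
  idx - 1L  # 0-based for C++
}

#' Local pairwise alignment with identity and coverage
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps (open 11,
#' extend 1; a gap of length L costs `gap_open + (L-1) * gap_extend`).
#' Identity is the number of identical aligned columns divided by the total
#' number of alignment columns, gap columns included in the denominator.
#' Coverage of each sequence is the aligned envelope length divided by the
#' sequence length. Results are symmetric: swapping the inputs swaps the
#' coverages and preserves score and identity.
#'
#' A diagonal band can restrict the dynamic program for long sequences
#' (`band = "auto"` uses half-width `max(200, 0.1 * max(len))`, widened by
#' the length difference so the corner-to-corner diagonal stays inside the
#' band). `band = NULL` runs the full quadratic dynamic program.
#'
#' @param a,b Amino-acid strings (standard residues plus X, B, Z; U and O
#'   are scored as X).
#' @param gap_open,gap_extend Positive gap penalties (matrix units).
#' @param band `NULL` (full DP), `"auto"`, or an integer half-width.
#' @return A list with `query_id`/`target_id`-free alignment metrics:
#'   `score`, `identity`, `coverage_query`, `coverage_target`, and the
#'   1-based aligned envelopes `query_range`, `target_range` (`NA` when no
#'   positive-scoring alignment exists, in which case identity and
#'   coverages are 0).
#' @export
align_pair <- function(a, b, gap_open = 11, gap_extend = 1, band = NULL) {
  ea <- encode_aa(a)
  eb <- encode_aa(b)
  m <- length(ea); n <- length(eb)
  if (is.null(band)) {
    lo <- -m; hi <- n
  } else {
    d <- if (identical(band, "auto"))
      max(200L, ceiling(0.1 * max(m, n))) else as.integer(band)
    lo <- min(0L, n - m) - d
    hi <- max(0L, n - m) + d
    lo <- max(lo, -m); hi <- min(hi, n)
  }
  r <- .sw_align_cpp(ea, eb, blosum62_matrix(), as.integer(gap_open),
                     as.integer(gap_extend), as.integer(lo), as.integer(hi))
  if (r$columns == 0) {
    return(list(score = 0, identity = 0,
                coverage_query = 0, coverage_target = 0,
                query_range = c(NA_integer_, NA_integer_),
                target_range = c(NA_integer_, NA_integer_)))
  }
  list(score = r$score,
       identity = r$identical / r$columns,
       coverage_query = (r$a_end - r$a_start + 1) / m,
       coverage_target = (r$b_end - r$b_start + 1) / n,
       query_range = c(r$a_start, r$a_end),
       target_range = c(r$b_start, r$b_end))
}
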