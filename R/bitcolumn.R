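#' Bitvector representation of a DP column
#'
#' A column of the alignment matrix is stored as a positive bitvector
#' \code{vp}, a negative bitvector \code{vn} and the scalar score
#' \code{s_before} just above the column's top row.  Bit \code{j} records
#' the score step from row \code{j-1} into row \code{j} (\code{+1} when
#' \code{vp} is set, \code{-1} when \code{vn} is set, \code{0} otherwise),
#' so the score at row \code{j} is
#' \code{s_before + popcount(vp[1..j]) - popcount(vn[1..j])}.  This encoding
#' is valid because vertically adjacent cells of the alignment matrix never
#' differ by more than one (the vertical property), which holds for graphs
#' just as for sequences.
#'
#' In whole-column mode a column covers all \code{m} query rows and
#' \code{s_before = 0}; in sliced mode it covers one \code{w}-row slice and
#' \code{s_before} carries the converged score from the slice above.
#'
#' @param vp,vn Integer/logical vectors of 0/1 bits, equal length, disjoint.
#' @param s_before Integer score above the top row (default 0).
#' @return An object of class \code{"bit_column"} with fields \code{vp},
#'   \code{vn}, \code{s_before}, \code{s_end}, \code{k}.
#' @examples
#' col <- bit_column(c(0, 1, 1), c(0, 0, 0))
#' decode_scores(col)
#' @export
bit_column <- function(vp, vn, s_before = 0L) {
  vp <- as.integer(vp); vn <- as.integer(vn)
  if (length(vp) != length(vn)) stop("vp and vn must have the same width")
  if (!all(vp %in% 0:1) || !all(vn %in% 0:1)) stop("vp/vn must be 0/1 bits")
  if (any(vp & vn)) stop("vp AND vn must be empty")
  structure(list(vp = vp, vn = vn,
                 s_before = as.integer(s_before),
                 s_end = as.integer(s_before + sum(vp) - sum(vn)),
                 k = length(vp)),
            class = "bit_column")
}

#' @export
print.bit_column <- function(x, ...) {
  cat(sprintf("<bit_column> k=%d s_before=%d s_end=%d\n", x$k, x$s_before, x$s_end))
  cat("  scores:", paste(decode_scores(x), collapse = " "), "\n")
  invisible(x)
}

#' Decode the scores of a bit column
#'
#' @param col A \code{\link{bit_column}}.
#' @return Integer vector of length \code{k}; the last element equals
#'   \code{col$s_end}.
#' @export
decode_scores <- function(col) {
  stopifnot(inherits(col, "bit_column"))
  col$s_before + cumsum(col$vp - col$vn)
}

#' Encode a score sequence as a bit column
#'
#' The inverse of \code{\link{decode_scores}}.  Requires the vertical
#' property: consecutive scores (and the step from \code{s_before} to the
#' first score) must differ by at most one.  An encode failure on scores
#' produced by the alignment pipeline would falsify the vertical property
#' and is treated as an internal error.
#'
#' @param scores Integer score vector.
#' @param s_before Score above the top row.
#' @return A \code{\link{bit_column}} with \code{decode_scores(.) == scores}.
#' @export
encode_scores <- function(scores, s_before = 0L) {
  steps <- diff(c(as.integer(s_before), as.integer(scores)))
  if (any(abs(steps) > 1L))
    stop("vertical property violated: adjacent scores differ by more than 1")
  bit_column(as.integer(steps == 1L), as.integer(steps == -1L), s_before)
}

#' Reference column merge (decode, minimum, encode)
#'
#' Computes the elementwise minimum of two columns by decoding both,
#' taking row-wise minima and re-encoding.  The minimum of two sequences
#' with the vertical property again has the vertical property, so the
#' encode cannot fail.  This transparent path is the authority against
#' which the bit-parallel merge is checked.
#'
#' @param a,b \code{\link{bit_column}}s of the same width.
#' @return A \code{\link{bit_column}} decoding to \code{pmin(decode(a),
#'   decode(b))}, with \code{s_before = min(a$s_before, b$s_before)}.
#' @export
merge_reference <- function(a, b) {
  stopifnot(inherits(a, "bit_column"), inherits(b, "bit_column"))
  if (a$k != b$k) stop("width mismatch")
  encode_scores(pmin(decode_scores(a), decode_scores(b)),
                min(a$s_before, b$s_before))
}

#' Bit-parallel column merge
#'
#' Merges two columns to their elementwise minimum working directly on the
#' bitvectors: the running score difference between the columns is tracked
#' in parallel chunks of \code{log2(k) + 2} rows, producing difference
#' masks (rows where A is above B and vice versa), from which a picking
#' mask selects output bits per row, with step corrections where the picked
#' source switches.  Decodes identically to \code{\link{merge_reference}};
#' the number of rows per chunk is attached as attribute
#' \code{"chunk_rows"}.
#'
#' @param a,b \code{\link{bit_column}}s of the same width.
#' @param word_size Machine word size in bits (2..64); columns wider than
#'   \code{word_size} are processed word by word with exact difference
#'   carries.
#' @return A \code{\link{bit_column}}; attribute \code{"chunk_rows"} gives
#'   the chunk granularity used.
#' @export
merge_bitparallel <- function(a, b, word_size = 64L) {
  stopifnot(inherits(a, "bit_column"), inherits(b, "bit_column"))
  if (a$k != b$k) stop("width mismatch")
  r <- cpp_merge_bitparallel(a$vp, a$vn, a$s_before,
                             b$vp, b$vn, b$s_before, as.integer(word_size))
  out <- bit_column(r$vp, r$vn, r$s_before)
  attr(out, "chunk_rows") <- r$chunk_rows
  out
}

#' Minimum changed score between two columns
#'
#' \code{changed_min(old, new)} is the minimum score of \code{new} over the
#' rows where \code{new} is strictly smaller than \code{old}, or \code{Inf}
#' when no row improved.  It is the priority with which a node is re-queued
#' in the cyclic alignment algorithm: only cells that improved can
#' propagate scores onward.  The fast path computes the difference mask
#' bit-parallel and inspects only local minima of the new column (a row
#' whose incoming step is not +1 and whose outgoing step is not -1);
#' the brute-force path decodes both columns.
#'
#' @param old,new \code{\link{bit_column}}s of the same width and the same
#'   \code{s_before}.
#' @param method \code{"fast"} (bit-parallel) or \code{"brute"} (decoded).
#' @param word_size Machine word size for the fast path.
#' @return A score, or \code{Inf}.
#' @export
changed_min <- function(old, new, method = c("fast", "brute"), word_size = 64L) {
  method <- match.arg(method)
  stopifnot(inherits(old, "bit_column"), inherits(new, "bit_column"))
  if (old$k != new$k) stop("width mismatch")
  if (old$s_before != new$s_before)
    stop("changed_min requires a common s_before baseline")
  if (method == "brute") {
    so <- decode_scores(old); sn <- decode_scores(new)
    i <- sn < so
    return(if (any(i)) as.double(min(sn[i])) else Inf)
  }
  cpp_changed_min(old$vp, old$vn, new$vp, new$vn,
                  old$s_before, as.integer(word_size))
}

#' Myers block step along one graph edge
#'
#' Computes the column of an edge's destination node from the source
#' node's column and the destination label's match mask, exactly as in
#' Myers' bitvector algorithm for sequence alignment (edlib-style block
#' formulation with a horizontal carry).  \code{hin} is the horizontal
#' score delta entering at the boundary row above the slice:
#' 0 for the top slice (virtual all-zero row) and the clamped difference of
#' the nodes' \code{s_before} values for deeper slices.  The decoded output
#' equals the direct evaluation of the alignment recurrence restricted to a
#' single predecessor column plus the vertical continuation from the
#' boundary row.
#'
#' @param col Source node's \code{\link{bit_column}}.
#' @param mask 0/1 match mask of the destination label against the slice's
#'   query rows (bit j set iff the query character of row j equals the
#'   destination node's label).
#' @param hin Horizontal carry-in at the boundary row (-1, 0 or +1).
#' @param word_size Machine word size in bits.
#' @return The destination candidate as a \code{\link{bit_column}} with
#'   \code{s_before = col$s_before + hin}.
#' @export
myers_step <- function(col, mask, hin = 0L, word_size = 64L) {
  stopifnot(inherits(col, "bit_column"))
  mask <- as.integer(mask)
  if (length(mask) != col$k) stop("width mismatch")
  if (!hin %in% -1:1) stop("hin must be -1, 0 or +1")
  r <- cpp_myers_step(col$vp, col$vn, mask, as.integer(hin),
                      as.integer(word_size))
  bit_column(r$vp, r$vn, col$s_before + as.integer(hin))
}

#' Pattern match masks
#'
#' For a pattern \code{s} of length m, the mask of character c has bit i
#' set iff \code{s[i] == c}.  The masks of the alphabet characters
#' partition the m positions (their OR is all-ones, and they are pairwise
#' disjoint); positions holding N (lenient policy) belong to no mask, so N
#' never matches.  Masks are stored as plain 0/1 vectors at the R level and
#' packed into \code{ceiling(m / word_size)} machine words inside the
#' kernels.
#'
#' @param s Pattern string.
#' @param alphabet Character vector of alphabet symbols.
#' @param word_size Word size recorded for downstream packing.
#' @return An object of class \code{"pattern_masks"}: list with \code{m},
#'   \code{word_size} and \code{masks} (named list of 0/1 integer vectors).
#' @examples
#' pattern_masks("ACA")$masks$A  # bits 1 and 3
#' @export
pattern_masks <- function(s, alphabet = DNA_BASES, word_size = 64L) {
  x <- chars(s)
  if (length(x) == 0L) stop("empty pattern")
  x <- apply_alphabet_policy(x, "iupac_to_n")
  if (!all(x %in% c(alphabet, "N"))) stop("pattern character outside alphabet")
  masks <- lapply(alphabet, function(c) as.integer(x == c))
  names(masks) <- alphabet
  structure(list(m = length(x), word_size = as.integer(word_size),
                 masks = masks, pattern = paste(x, collapse = "")),
            class = "pattern_masks")
}

#' Shift-And state transition
#'
#' One automaton step: \code{((state << 1) + 1) AND mask}, with carry
#' propagation across machine words.  The \code{+ 1} term lets a new match
#' start at every step, so no separate seeding of start states is needed.
#'
#' @param state 0/1 integer vector of m bits (bit i set iff some path into
#'   the current node spells the pattern prefix of length i).
#' @param mask The pattern mask of the character being consumed.
#' @param word_size Machine word size in bits (2..64).
#' @return The next state as a 0/1 integer vector.
#' @export
nfa_step <- function(state, mask, word_size = 64L) {
  state <- as.integer(state); mask <- as.integer(mask)
  if (length(state) != length(mask)) stop("width mismatch")
  cpp_nfa_step(state, mask, as.integer(word_size))
}
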