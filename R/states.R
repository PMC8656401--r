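#' Encode binary activation patterns as state codes
#'
#' A brain state is the joint on/off pattern of the `n` channels (ROIs) at one
#' timepoint. Patterns are encoded as integers in `[0, 2^n)`: the channel at
#' position `i` of the ROI ordering (1-based) contributes `2^(i-1)` when
#' active, so `encode_state(c(1, 0, 1))` is `5`.
#'
#' @param bits A 0/1 vector of length `n`, or a matrix with `n` columns
#'   (one row per timepoint).
#' @return An integer code (or vector of codes, one per row).
#' @seealso [decode_state()]
#' @examples
#' encode_state(c(1, 0, 1))
#' decode_state(5, n = 3)
#' @export
encode_state <- function(bits) {
  if (is.matrix(bits)) {
    n <- check_n(ncol(bits))
    if (!all(bits %in% c(0, 1))) abort("`bits` must contain only 0 and 1.")
    return(as.integer(drop(bits %*% 2^(seq_len(n) - 1))))
  }
  n <- check_n(length(bits))
  if (!all(bits %in% c(0, 1))) abort("`bits` must contain only 0 and 1.")
  as.integer(sum(bits * 2^(seq_len(n) - 1)))
}

#' @rdname encode_state
#' @param code Integer state code(s) in `[0, 2^n)`.
#' @param n Number of channels.
#' @return For `decode_state`, a 0/1 integer vector (or matrix with one row
#'   per code).
#' @export
decode_state <- function(code, n) {
  n <- check_n(n)
  if (any(code < 0) || any(code >= 2^n)) {
    abort(sprintf("state codes must lie in [0, %d) for n = %d.", 2^n, n))
  }
  bits <- outer(as.integer(code), 2^(seq_len(n) - 1), function(c, w) bitwAnd(c, as.integer(w)) > 0)
  storage.mode(bits) <- "integer"
  if (length(code) == 1L) drop(bits) else bits
}

# All 2^n states as a 2^n x n 0/1 matrix; row k is state code k-1.
state_matrix <- function(n) {
  n <- check_n(n)
  decode_state(0:(2^n - 1), n)
}

# 2^n x n matrix of single-flip neighbours: entry [s+1, i] = code of s with bit i flipped.
neighbor_matrix <- function(n) {
  n <- check_n(n)
  outer(0:(2^n - 1), as.integer(2^(seq_len(n) - 1)), bitwXor)
}

# Hamming distance between state codes (vectorized over `code`).
hamming_to <- function(code, ref, n) {
  x <- bitwXor(as.integer(code), as.integer(ref))
  bits <- outer(x, 2^(seq_len(n) - 1), function(c, w) bitwAnd(c, as.integer(w)) > 0)
  as.integer(rowSums(bits))
}
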