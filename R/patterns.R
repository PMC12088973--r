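#' Encode and decode 6-bit binary patterns
#'
#' Each binarized record is a 6-bit pattern; patterns are referred to by
#' their decimal index with the *first* feature as the most significant
#' bit, so `c(0,1,0,1,1,1)` is pattern 16 + 4 + 2 + 1 = 23.
#'
#' @param bits A vector of 6 bits (0/1), or an n x 6 matrix of such rows.
#' @param index Integer vector of pattern indices in 0..63.
#' @return `pattern_index()` returns an integer vector of indices;
#'   `pattern_bits()` returns an n x 6 matrix of 0/1 bits;
#'   `all_patterns()` returns the full 64 x 6 pattern matrix in index order.
#' @examples
#' pattern_index(c(0, 1, 0, 1, 1, 1))  # 23
#' pattern_bits(23)
#' @export
pattern_index <- function(bits) {
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1)
  bits <- as.matrix(bits)
  if (ncol(bits) != 6L)
    stop("a binary pattern must have exactly 6 bits, got ", ncol(bits))
  if (anyNA(bits) || !all(bits == 0 | bits == 1))
    stop("pattern bits must be 0 or 1")
  as.integer(bits %*% 2^(5:0))
}

#' @rdname pattern_index
#' @export
pattern_bits <- function(index) {
  index <- as.integer(index)
  if (anyNA(index) || any(index < 0L | index > 63L))
    stop("pattern index must be in 0..63")
  m <- t(vapply(index, function(i) (i %/% 2^(5:0)) %% 2, numeric(6)))
  storage.mode(m) <- "integer"
  m
}

#' @rdname pattern_index
#' @export
all_patterns <- function() pattern_bits(0:63)

# Hamming-1 neighbourhood of every pattern: 64 x 6 matrix of 0-based indices,
# row i+1 holds the six patterns differing from pattern i in exactly one bit.
pattern_neighbors <- function() {
  outer(0:63, 2^(5:0), bitwXor)
}
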