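#' Stacked matrices
#'
#' A stacked matrix is an ordinary numeric matrix partitioned into
#' `block_count` vertically stacked blocks of equal height, one per channel.
#' Multi-way EMG data (channels x users x motions x repetitions) is flattened
#' into this two-dimensional form so standard matrix algebra applies, with
#' the stacked transpose handling the per-channel block structure.
#'
#' @param data Numeric matrix whose row count is divisible by `block_count`.
#' @param block_count Number of blocks `C >= 1`.
#' @return An object of class `stacked_matrix` with fields `data`,
#'   `block_count` and `block_rows` (= `nrow(data) / block_count`).
#' @export
stacked_matrix <- function(data, block_count = 1L) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  block_count <- as.integer(block_count)
  if (block_count < 1L) stop("block_count must be >= 1", call. = FALSE)
  if (nrow(data) %% block_count != 0L) {
    stop(sprintf("row count %d not divisible by block count %d",
                 nrow(data), block_count), call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("stacked matrix entries must be finite", call. = FALSE)
  }
  structure(
    list(data = data, block_count = block_count,
         block_rows = nrow(data) %/% block_count),
    class = "stacked_matrix"
  )
}

as_stacked <- function(x, block_count = 1L) {
  if (inherits(x, "stacked_matrix")) x else stacked_matrix(x, block_count)
}

#' @export
print.stacked_matrix <- function(x, ...) {
  cat(sprintf("<stacked_matrix> %d x %d, %d block(s) of %d row(s)\n",
              nrow(x$data), ncol(x$data), x$block_count, x$block_rows))
  invisible(x)
}

#' Extract one block of a stacked matrix
#' @param x A [stacked_matrix()].
#' @param c Block (channel) index.
#' @return Plain numeric matrix, the `c`-th block.
#' @export
stacked_block <- function(x, c) {
  stopifnot(inherits(x, "stacked_matrix"))
  c <- as.integer(c)
  if (c < 1L || c > x$block_count) stop("block index out of range", call. = FALSE)
  rows <- ((c - 1L) * x$block_rows + 1L):(c * x$block_rows)
  x$data[rows, , drop = FALSE]
}

#' Stacked transpose
#'
#' Transposes each of the `C` blocks of a stacked matrix independently and
#' restacks them in the same block order: an `(R*C) x K` stacked matrix maps
#' to a `(K*C) x R` stacked matrix. With `C = 1` this is the ordinary
#' transpose; applying it twice gives back the original matrix.
#'
#' @param x A [stacked_matrix()] (or plain matrix, treated as one block).
#' @return A [stacked_matrix()] with the same block count.
#' @export
stacked_transpose <- function(x) {
  x <- as_stacked(x)
  C <- x$block_count
  R <- x$block_rows
  K <- ncol(x$data)
  out <- matrix(0, nrow = K * C, ncol = R)
  for (c in seq_len(C)) {
    out[((c - 1L) * K + 1L):(c * K), ] <- t(stacked_block(x, c))
  }
  stacked_matrix(out, C)
}
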