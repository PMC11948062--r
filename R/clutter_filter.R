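#' Clutter filter parameters
#'
#' Block length and number of removed singular components for the
#' spatiotemporal SVD clutter filter. Defaults follow the clinical protocol:
#' clips are split into blocks of 200 frames and the 5 largest of the 200
#' singular components are removed (a 5/200 eigenvalue threshold).
#'
#' @param block_length Frames per block (default 200).
#' @param n_remove Number of lowest-order (largest) singular components
#'   zeroed per block (default 5); must satisfy `1 <= n_remove < block_length`.
#' @param n_remove_high Optional count of highest-order (smallest, noise)
#'   components also zeroed; default 0 (off).
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(block_length = 200L, n_remove = 5L,
                          n_remove_high = 0L) {
  block_length <- as.integer(block_length)
  n_remove <- as.integer(n_remove)
  if (n_remove < 1L || n_remove >= block_length) {
    stop("need 1 <= n_remove < block_length")
  }
  if (n_remove_high < 0L) stop("`n_remove_high` must be >= 0")
  structure(list(block_length = block_length, n_remove = n_remove,
                 n_remove_high = as.integer(n_remove_high)),
            class = "filter_params")
}

#' Split a clip into consecutive filtering blocks
#'
#' Non-overlapping blocks of `block_length` frames in order. A final
#' remainder shorter than `block_length` is kept only if it still has at
#' least `2 * n_remove` frames (enough temporal samples to estimate and
#' remove the clutter subspace); otherwise it is dropped.
#'
#' @param stack A [frame_stack()].
#' @param params A [filter_params()].
#' @return List of `frame_stack` blocks; concatenating them reproduces the
#'   corresponding input frames exactly.
#' @export
split_blocks <- function(stack, params = filter_params()) {
  stopifnot(inherits(stack, "frame_stack"), inherits(params, "filter_params"))
  nf <- n_frames(stack)
  bl <- params$block_length
  n_full <- nf %/% bl
  rem <- nf - n_full * bl
  starts <- seq_len(n_full) * bl - bl + 1L
  lens <- rep(bl, n_full)
  if (rem >= 2L * params$n_remove) {
    starts <- c(starts, n_full * bl + 1L)
    lens <- c(lens, rem)
  }
  mapply(function(s, l) {
    frame_stack(stack$frames[s:(s + l - 1L), , , drop = FALSE], stack$meta)
  }, starts, lens, SIMPLIFY = FALSE)
}

## Casorati matrix: pixels x frames
casorati <- function(block) {
  d <- dim(block$frames)
  matrix(aperm(block$frames, c(2, 3, 1)), d[2] * d[3], d[1])
}

uncasorati <- function(X, d) {
  aperm(array(X, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
}

#' SVD clutter filtering of one block
#'
#' The block is reshaped to its Casorati matrix (pixels x frames) and the
#' `n_remove` largest singular components -- the coherent, quasi-static
#' tissue echo -- are subtracted. Before the final magnitude step the filter
#' is linear, and its output is exactly orthogonal (in the Casorati inner
#' product) to the removed subspace.
#'
#' @param block A [frame_stack()] with at least `n_remove + 1` frames.
#' @param params A [filter_params()].
#' @param magnitude Take the absolute value after reconstruction (default
#'   TRUE; downstream detection needs nonnegative intensity). Set FALSE for
#'   the raw linear residual.
#' @return A `frame_stack` of filtered frames, same geometry as the input.
#' @export
svd_filter_block <- function(block, params = filter_params(),
                             magnitude = TRUE) {
  stopifnot(inherits(block, "frame_stack"), inherits(params, "filter_params"))
  nf <- n_frames(block)
  k <- params$n_remove
  if (nf < k + 1L) {
    stop(sprintf("block has %d frames; need at least n_remove + 1 = %d",
                 nf, k + 1L))
  }
  X <- casorati(block)
  sv <- svd(X, nu = k, nv = k)
  low <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
  Y <- X - low
  kh <- params$n_remove_high
  if (kh > 0L) {
    r <- length(sv$d)
    hi <- seq.int(r - kh + 1L, r)
    svh <- svd(X)
    Y <- Y - svh$u[, hi, drop = FALSE] %*%
      (svh$d[hi] * t(svh$v[, hi, drop = FALSE]))
  }
  if (magnitude) Y <- abs(Y)
  frame_stack(uncasorati(Y, dim(block$frames)), block$meta)
}

#' Filter a whole clip block by block
#'
#' Splits the clip with [split_blocks()] and filters each block with
#' [svd_filter_block()]. Frames in a dropped remainder block do not appear in
#' the output.
#'
#' @inheritParams svd_filter_block
#' @param stack A [frame_stack()].
#' @return A filtered `frame_stack` (possibly fewer frames than the input).
#' @export
svd_filter <- function(stack, params = filter_params(), magnitude = TRUE) {
  blocks <- split_blocks(stack, params)
  if (!length(blocks)) stop("no block has enough frames to filter")
  filt <- lapply(blocks, svd_filter_block, params = params,
                 magnitude = magnitude)
  frames <- do.call(abind1, lapply(filt, `[[`, "frames"))
  frame_stack(frames, stack$meta)
}

## bind 3-D arrays along the first (time) dimension
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(0, dim = c(sum(vapply(arrs, function(a) dim(a)[1], 0)),
                          d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
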