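# Internal raster helpers shared by the generator, the pyramid and the models.
# Rasters are stored as base-R numeric matrices (grayscale) or H x W x C arrays
# with values in [0, 1]; masks are integer 0/1 matrices.

# Block mean with ceil()-sized output: ragged border blocks average over the
# pixels that exist.  This is the anti-aliased "area" downsampling used between
# pyramid levels.
block_mean <- function(m, f) {
  stopifnot(is.matrix(m), f >= 1)
  if (f == 1) return(m)
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- rep(seq_len(ceiling(nr / f)), each = f, length.out = nr)
  ci <- rep(seq_len(ceiling(nc / f)), each = f, length.out = nc)
  s <- rowsum(m, ri, reorder = FALSE)
  s <- t(rowsum(t(s), ci, reorder = FALSE))
  s / (tabulate(ri) %o% tabulate(ci))
}

block_mean_image <- function(img, f) {
  if (is.matrix(img)) return(block_mean(img, f))
  out <- NULL
  for (ch in seq_len(dim(img)[3])) {
    d <- block_mean(img[, , ch], f)
    if (is.null(out)) out <- array(0, c(dim(d), dim(img)[3]))
    out[, , ch] <- d
  }
  out
}

# Separable bilinear interpolation matrix for resizing a length n_in axis to
# n_out samples, using half-pixel sample centers (each output sample sits at
# the center of its footprint in input coordinates).  Dense n_out x n_in with
# at most two nonzero weights per row; resizing is then two BLAS products.
interp_matrix <- function(n_in, n_out) {
  pos <- (seq_len(n_out) - 0.5) * (n_in / n_out) + 0.5
  lo <- floor(pos)
  w <- pos - lo
  lo <- pmin(pmax(lo, 1), n_in)
  hi <- pmin(lo + 1, n_in)
  w[pos < 1] <- 0
  w[pos > n_in] <- 1
  w[hi == lo] <- 0
  M <- matrix(0, n_out, n_in)
  M[cbind(seq_len(n_out), lo)] <- 1 - w
  M[cbind(seq_len(n_out), hi)] <- M[cbind(seq_len(n_out), hi)] + w
  M
}

bilinear_resize <- function(m, out_h, out_w) {
  (interp_matrix(nrow(m), out_h) %*% m) %*% t(interp_matrix(ncol(m), out_w))
}

# Adjoint of bilinear_resize, used in backpropagation: scatters a gradient on
# the fine grid back to the coarse grid.
bilinear_resize_t <- function(g, in_h, in_w) {
  crossprod(interp_matrix(in_h, nrow(g)), g) %*% interp_matrix(in_w, ncol(g))
}

# Snap values in [0, 1] to the 256-level grid of 8-bit image data.
quantize8 <- function(x) round(x * 255) / 255

as_binary_mask <- function(m, arg = "mask") {
  if (!is.matrix(m)) abort(sprintf("`%s` must be a matrix.", arg))
  u <- unique(as.vector(m))
  if (!all(u %in% c(0, 1))) {
    abort(sprintf("`%s` must be binary (0/1); found other values.", arg))
  }
  storage.mode(m) <- "integer"
  m
}

check_number <- function(x, arg, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", arg,
                  format(min), format(max)))
  }
  x
}
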