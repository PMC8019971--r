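# 3D Gaussian pre-smoothing of multi-echo volumes. Separable convolution
# with a normalized sampled Gaussian kernel and mirror ('reflect', edge
# value repeated) boundary handling, applied independently to each echo.

gauss_kernel_1d <- function(sd) {
  r <- max(1L, ceiling(4 * sd))
  k <- exp(-((-r):r)^2 / (2 * sd^2))
  k / sum(k)
}

# n x n convolution matrix with reflect boundaries: row i holds the kernel
# centred at i with out-of-range taps folded back in
conv_matrix_reflect <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  reflect <- function(j) {
    # scipy-style 'reflect': (d c b a | a b c d | d c b a), period 2n
    j <- (j - 1L) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- reflect(i + (-r):r)
    for (t in seq_along(js)) C[i, js[t]] <- C[i, js[t]] + kernel[t]
  }
  C
}

smooth_volume_3d <- function(vol, sd) {
  d <- dim(vol)
  kern <- gauss_kernel_1d(sd)
  for (ax in 1:3) {
    C <- conv_matrix_reflect(d[ax], kern)
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vol, perm)
    dv <- dim(v)
    v <- C %*% matrix(v, nrow = dv[1])
    dim(v) <- dv
    vol <- aperm(v, order(perm))
  }
  vol
}

#' Smooth a 4D multi-echo volume with a 3D Gaussian kernel
#'
#' Each echo volume (4th axis) is convolved independently with a normalized
#' 3D Gaussian of standard deviation `sd` voxels, using reflected boundaries.
#' `sd = 0` returns the input unchanged.
#'
#' @param vol4d 4D numeric array, echo axis last.
#' @param sd Kernel standard deviation in voxels (>= 0).
#' @return Smoothed 4D array of the same shape.
#' @export
smooth_multiecho <- function(vol4d, sd = 1.5) {
  if (!is.array(vol4d) || length(dim(vol4d)) != 4L) {
    stop("`vol4d` must be a 4D array (x, y, z, echo)", call. = FALSE)
  }
  if (!is.numeric(sd) || sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (sd == 0) return(vol4d)
  out <- vol4d
  for (e in seq_len(dim(vol4d)[4])) {
    out[, , , e] <- smooth_volume_3d(vol4d[, , , e, drop = TRUE], sd)
  }
  out
}
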