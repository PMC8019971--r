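# Independent oracles used across the suite. Each re-derives a quantity by a
# route different from the implementation under test.

# Brute-force isochromat (Bloch) simulation of a CPMG train. Spins are
# equally spaced across one crusher dephasing cycle per half echo spacing;
# rotations and relaxation are applied per half interval, refocusing pulses
# rotate about y. T1 regrowth is neglected, matching the forward model.
isochromat_decay <- function(t2, t1, flip_angle, acq, n_spins = 2001) {
  tau <- acq$echo_spacing
  ne <- acq$n_echoes
  th <- 2 * pi * (seq_len(n_spins) - 0.5) / n_spins
  E2 <- exp(-tau / 2 / t2)
  E1 <- exp(-tau / 2 / t1)
  a <- flip_angle * pi / 180
  ca <- cos(a)
  sa <- sin(a)
  ct <- cos(th)
  st <- sin(th)
  Mx <- rep(0, n_spins)
  My <- rep(-1, n_spins)   # after ideal 90x excitation
  Mz <- rep(0, n_spins)
  out <- numeric(ne)
  half <- function() {
    mx <- ct * Mx - st * My
    my <- st * Mx + ct * My
    Mx <<- mx * E2
    My <<- my * E2
    Mz <<- Mz * E1
  }
  for (e in seq_len(ne)) {
    half()
    mx <- ca * Mx + sa * Mz
    Mz <- -sa * Mx + ca * Mz
    Mx <- mx
    half()
    out[e] <- Mod(complex(real = mean(Mx), imaginary = mean(My)))
  }
  out
}

# Direct (non-separable) 3D Gaussian convolution with scipy-style 'reflect'
# boundaries, by explicit summation over the kernel support.
direct_gauss_smooth3d <- function(vol, sd) {
  d <- dim(vol)
  r <- max(1L, ceiling(4 * sd))
  off <- (-r):r
  k1 <- exp(-off^2 / (2 * sd^2))
  k1 <- k1 / sum(k1)
  reflect <- function(j, n) {
    j <- (j - 1L) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (a in seq_along(off)) for (b in seq_along(off)) for (cc in seq_along(off)) {
      acc <- acc + k1[a] * k1[b] * k1[cc] *
        vol[reflect(i + off[a], d[1]),
            reflect(j + off[b], d[2]),
            reflect(k + off[cc], d[3])]
    }
    out[i, j, k] <- acc
  }
  out
}

# Exhaustive active-set search for non-negative least squares: the global
# optimum's support is some subset of columns whose unconstrained LS solution
# is non-negative, so enumerating all subsets up to `max_support` bounds the
# objective from above (and equals the optimum whenever the optimal support
# is within reach).
enum_nnls_objective <- function(A, y, max_support = 4L) {
  n <- ncol(A)
  best <- sum(y^2)   # empty support
  for (k in seq_len(max_support)) {
    sets <- utils::combn(n, k)
    for (c_i in seq_len(ncol(sets))) {
      S <- sets[, c_i]
      As <- A[, S, drop = FALSE]
      z <- tryCatch(qr.solve(As, y), error = function(e) NULL)
      if (is.null(z) || any(!is.finite(z)) || any(z < 0)) next
      obj <- sum((As %*% z - y)^2)
      if (obj < best) best <- obj
    }
  }
  best
}

# KKT certificate for min ||Ax - y||^2 s.t. x >= 0: at the global optimum the
# gradient g = A'(Ax - y) satisfies g >= 0 and g[x > 0] = 0 (within tol).
nnls_kkt_ok <- function(A, y, x, tol = 1e-8) {
  g <- drop(crossprod(A, A %*% x - y))
  scale <- max(1, max(abs(crossprod(A, y))))
  all(g >= -tol * scale) && all(abs(g[x > tol]) <= tol * scale)
}

# Adjusted Fisher-Pearson standardized third moment, by the hand formula.
skewness_hand <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  m <- mean(x)
  n / ((n - 1) * (n - 2)) * sum(((x - m) / s)^3)
}

# Dice coefficient of two logical arrays.
dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
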