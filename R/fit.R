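# Voxelwise T2 spectrum inversion: non-negative least squares on the EPG
# decay basis, minimum-curvature (second-difference) regularization with
# discrepancy-principle weight selection, and refocusing flip-angle search.

#' Fit configuration for the T2 spectrum inversion
#'
#' @param grid T2 grid from [t2_grid()].
#' @param regularization `"min_curvature"` (second-difference penalty on the
#'   spectrum, weight chosen by the discrepancy principle) or `"none"`.
#' @param misfit_inflation Discrepancy factor: the regularization weight is
#'   the largest value whose data misfit (residual 2-norm) does not exceed
#'   `misfit_inflation` times the unregularized misfit. Must be >= 1.
#' @param flip_range Refocusing flip-angle search range in degrees, within
#'   \[90, 180\].
#' @param flip_step Coarse search step in degrees; the minimizer is refined by
#'   quadratic interpolation through the best node and its neighbours.
#' @param flip_search_t2_min Smallest T2 (ms) of the basis used during the
#'   flip-angle search. Spectral components with T2 well below the first echo
#'   time are invisible to the data except through the earliest echoes, where
#'   they alias refocusing-angle error; excluding them (default 15 ms, about
#'   1.5 times the default echo spacing) makes the misfit-versus-angle curve
#'   identifiable. The final spectrum is always fitted on the full grid.
#' @param geometric_t2 If `TRUE`, compartment weighted T2 is the
#'   amplitude-weighted geometric mean instead of the arithmetic mean.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(grid = t2_grid(),
                       regularization = c("min_curvature", "none"),
                       misfit_inflation = 1.02,
                       flip_range = c(120, 180),
                       flip_step = 1,
                       flip_search_t2_min = 15,
                       geometric_t2 = FALSE) {
  regularization <- match.arg(regularization)
  if (misfit_inflation < 1) stop("`misfit_inflation` must be >= 1", call. = FALSE)
  if (length(flip_range) != 2L || flip_range[1] >= flip_range[2] ||
      flip_range[1] < 90 || flip_range[2] > 180) {
    stop("`flip_range` must be an increasing pair within [90, 180]", call. = FALSE)
  }
  if (flip_step <= 0) stop("`flip_step` must be > 0", call. = FALSE)
  structure(
    list(
      grid = grid, regularization = regularization,
      misfit_inflation = misfit_inflation,
      flip_range = flip_range, flip_step = flip_step,
      flip_search_t2_min = flip_search_t2_min,
      geometric_t2 = isTRUE(geometric_t2)
    ),
    class = "fit_config"
  )
}

check_signal <- function(y, n_expected = NULL) {
  if (!is.numeric(y)) stop("signal must be numeric", call. = FALSE)
  if (anyNA(y) || any(!is.finite(y))) {
    stop("signal contains NA/NaN/Inf values", call. = FALSE)
  }
  if (!is.null(n_expected) && length(y) != n_expected) {
    stop(sprintf("signal length %d does not match basis rows %d",
                 length(y), n_expected), call. = FALSE)
  }
  invisible(y)
}

#' Non-negative least-squares spectrum fit
#'
#' Solves `min ||A x - y||_2` subject to `x >= 0`, where `A` is the decay
#' basis. The problem is convex; the active-set solver returns its global
#' optimum.
#'
#' @param y Measured echo magnitudes (length = basis rows).
#' @param basis A [build_basis()] object.
#' @return List with `amplitudes` (non-negative, one per grid node) and
#'   `residual_norm` (achieved misfit, 2-norm).
#' @examples
#' acq <- acq_params()
#' b <- build_basis(t2_grid(40, 10, 500), 180, acq)
#' fit <- nnls_fit(b$matrix[, 20] * 3, b)
#' which.max(fit$amplitudes)
#' @export
nnls_fit <- function(y, basis) {
  stopifnot(inherits(basis, "decay_basis"))
  check_signal(y, nrow(basis$matrix))
  if (all(y == 0)) {
    return(list(amplitudes = numeric(ncol(basis$matrix)), residual_norm = 0))
  }
  sol <- nnls_solve(basis$matrix, as.numeric(y))
  list(amplitudes = as.numeric(sol$x), residual_norm = sol$rnorm)
}

# Second-difference (curvature) operator on an n-node grid. The spectrum is
# taken to vanish outside the grid (zero padding), so the operator carries
# two boundary rows at each end: without them a linear ramp running into a
# grid edge has zero curvature, and unobservable ultra-short-T2 mass can
# accumulate there unpenalized. D and D'D cached per n.
.d2_cache <- new.env(parent = emptyenv())
second_diff_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.d2_cache[[key]])) return(.d2_cache[[key]])
  stopifnot(n >= 3L)
  D <- matrix(0, n + 2L, n)
  D[1L, 1L] <- 1
  D[2L, 1:2] <- c(-2, 1)
  for (r in 3:n) D[r, (r - 2L):r] <- c(1, -2, 1)
  D[n + 1L, (n - 1L):n] <- c(1, -2)
  D[n + 2L, n] <- 1
  .d2_cache[[key]] <- D
  D
}

second_diff_gram <- function(n) {
  key <- paste0("gram", n)
  if (!is.null(.d2_cache[[key]])) return(.d2_cache[[key]])
  D <- second_diff_matrix(n)
  .d2_cache[[key]] <- crossprod(D)
  .d2_cache[[key]]
}

new_t2_spectrum <- function(amplitudes, grid, flip_angle, residual_norm, mu,
                            flip_fitted = FALSE, flat_misfit = FALSE) {
  structure(
    list(
      amplitudes = amplitudes, grid = grid, flip_angle = flip_angle,
      residual_norm = residual_norm, mu = mu,
      flip_fitted = flip_fitted, flat_misfit = flat_misfit
    ),
    class = "t2_spectrum"
  )
}

#' Minimum-curvature regularized spectrum fit
#'
#' Solves `min ||A x - y||^2 + mu ||D2 x||^2` with `x >= 0`, where `D2` is the
#' second-difference operator on the log-T2 grid, implemented by row
#' augmentation of the basis with `sqrt(mu) * D2` and of the data with zeros.
#' `mu` is chosen by the discrepancy principle: bracketing by doubling, then
#' bisection in `log(mu)`, for the largest `mu` whose data misfit stays within
#' `misfit_inflation` times the unregularized misfit.
#'
#' @inheritParams nnls_fit
#' @param cfg A [fit_config()].
#' @return An object of class `t2_spectrum`: `amplitudes`, `grid`,
#'   `flip_angle`, `residual_norm` (data misfit at the chosen weight), `mu`.
#' @export
regularized_fit <- function(y, basis, cfg = fit_config(grid = basis$grid)) {
  stopifnot(inherits(basis, "decay_basis"), inherits(cfg, "fit_config"))
  check_signal(y, nrow(basis$matrix))
  base <- nnls_fit(y, basis)
  if (cfg$regularization == "none" || all(y == 0)) {
    return(new_t2_spectrum(base$amplitudes, basis$grid, basis$flip_angle,
                           base$residual_norm, 0))
  }
  A <- basis$matrix
  n <- ncol(A)
  # normal-equation pieces: G(mu) = A'A + mu D'D, f = A'y
  G0 <- if (is.null(basis$gram)) crossprod(A) else basis$gram
  DtD <- second_diff_gram(n)
  f <- drop(crossprod(A, y))

  data_misfit <- function(x) sqrt(sum((A %*% x - y)^2))
  warm <- which(base$amplitudes > 0)
  solve_mu <- function(mu) {
    x <- as.numeric(nnls_gram(G0 + mu * DtD, f, warm_support = warm))
    warm <<- which(x > 0)   # seed the next weight's active set
    list(x = x, misfit = data_misfit(x))
  }

  target <- cfg$misfit_inflation * base$residual_norm
  best <- list(mu = 0, x = base$amplitudes, misfit = base$residual_norm)

  # bracket the discrepancy weight: walk down to a feasible mu if needed,
  # then double until the data misfit exceeds the target
  mu_hi <- 1e-3
  hi_fit <- solve_mu(mu_hi)
  n_expand <- 0L
  while (hi_fit$misfit > target && mu_hi > 1e-9 && n_expand < 60L) {
    mu_hi <- mu_hi / 8
    hi_fit <- solve_mu(mu_hi)
    n_expand <- n_expand + 1L
  }
  while (hi_fit$misfit <= target && n_expand < 60L) {
    best <- list(mu = mu_hi, x = hi_fit$x, misfit = hi_fit$misfit)
    mu_hi <- mu_hi * 8
    hi_fit <- solve_mu(mu_hi)
    n_expand <- n_expand + 1L
  }
  if (n_expand >= 60L) {
    warning("discrepancy bracketing failed within 60 expansions; using mu = 0",
            call. = FALSE)
    return(new_t2_spectrum(base$amplitudes, basis$grid, basis$flip_angle,
                           base$residual_norm, 0))
  }
  if (best$mu > 0) {
    # bisect in log(mu) between the last feasible and first infeasible weight
    lo <- best$mu
    hi <- mu_hi
    for (i in seq_len(8L)) {
      mid <- sqrt(lo * hi)
      fm <- solve_mu(mid)
      if (fm$misfit <= target) {
        best <- list(mu = mid, x = fm$x, misfit = fm$misfit)
        lo <- mid
      } else {
        hi <- mid
      }
    }
  }
  new_t2_spectrum(best$x, basis$grid, basis$flip_angle, best$misfit, best$mu)
}

# coarse-grid NNLS misfits over candidate flip angles, evaluated on the
# observable part of the T2 grid. Works on the cached Gram matrices and
# warm-starts each angle's active set from the previous one.
flip_misfits <- function(y, angles, cfg, acq) {
  search_grid <- cfg$grid[cfg$grid >= cfg$flip_search_t2_min]
  if (length(search_grid) < 3L) search_grid <- cfg$grid
  # the misfit-versus-angle profile converges quickly with grid density;
  # 64 log-spaced nodes are ample for locating its minimum
  if (length(search_grid) > 64L) {
    search_grid <- search_grid[unique(round(seq(1, length(search_grid),
                                                length.out = 64L)))]
  }
  yty <- sum(y^2)
  warm <- integer(0)
  vapply(angles, function(a) {
    b <- build_basis(search_grid, a, acq)
    f <- drop(crossprod(b$matrix, y))
    x <- as.numeric(nnls_gram(b$gram, f, warm_support = warm))
    warm <<- which(x > 0)
    sqrt(max(0, yty - 2 * sum(f * x) + sum(x * (b$gram %*% x))))
  }, numeric(1))
}

#' Fit a T2 spectrum with refocusing flip-angle estimation
#'
#' Evaluates the unregularized NNLS misfit over a coarse flip-angle grid,
#' refines the minimizer by quadratic interpolation through the best node and
#' its neighbours, and runs the regularized fit at the refined angle. The
#' angle is estimated on the unregularized fit so the curvature penalty does
#' not bias it. Equal-misfit ties resolve to the largest angle; a voxel whose
#' misfit is flat across all angles (pure noise) is assigned 180 degrees and
#' flagged via `flat_misfit`.
#'
#' @param y Measured echo magnitudes.
#' @param cfg A [fit_config()].
#' @param acq An [acq_params()].
#' @return A `t2_spectrum` with the fitted `flip_angle`.
#' @export
fit_flip_angle <- function(y, cfg = fit_config(), acq = acq_params()) {
  stopifnot(inherits(cfg, "fit_config"))
  check_signal(y, acq$n_echoes)
  if (all(y == 0)) stop("signal is identically zero", call. = FALSE)

  angles <- seq(cfg$flip_range[1], cfg$flip_range[2], by = cfg$flip_step)
  if (angles[length(angles)] < cfg$flip_range[2]) {
    angles <- c(angles, cfg$flip_range[2])
  }
  m <- flip_misfits(y, angles, cfg, acq)

  rng <- max(m) - min(m)
  flat <- rng <= 1e-12 * max(max(m), 1e-300)
  if (flat) {
    best_angle <- 180
  } else {
    tol <- 1e-12 * max(m)
    i <- max(which(m <= min(m) + tol))   # tie -> largest angle
    if (i > 1L && i < length(angles)) {
      denom <- m[i - 1L] - 2 * m[i] + m[i + 1L]
      delta <- if (denom > 0) 0.5 * (m[i - 1L] - m[i + 1L]) / denom else 0
      delta <- max(-1, min(1, delta))
      best_angle <- angles[i] + delta * cfg$flip_step
    } else {
      best_angle <- angles[i]
    }
    best_angle <- min(max(best_angle, cfg$flip_range[1]), cfg$flip_range[2])
    best_angle <- round(best_angle, 1)   # keep the basis cache bounded
  }

  basis <- build_basis(cfg$grid, best_angle, acq)
  spec <- regularized_fit(y, basis, cfg)
  spec$flip_fitted <- TRUE
  spec$flat_misfit <- flat
  spec
}

#' Fit one echo train end to end
#'
#' Convenience wrapper: flip-angle estimation followed by the regularized
#' spectrum fit.
#'
#' @inheritParams fit_flip_angle
#' @return A `t2_spectrum`.
#' @export
fit_echo_train <- function(y, acq = acq_params(), cfg = fit_config()) {
  fit_flip_angle(y, cfg, acq)
}

#' @export
print.t2_spectrum <- function(x, ...) {
  tot <- sum(x$amplitudes)
  cat(sprintf(
    "<t2_spectrum> %d nodes, flip %.1f deg%s, mu %.3g, misfit %.4g, total amplitude %.4g\n",
    length(x$amplitudes), x$flip_angle,
    if (isTRUE(x$flip_fitted)) " (fitted)" else "",
    x$mu, x$residual_norm, tot
  ))
  invisible(x)
}

#' Tidy a fitted T2 spectrum
#'
#' @param x A `t2_spectrum`.
#' @param ... Unused.
#' @return A tibble with columns `t2` (ms), `amplitude`, and `compartment`
#'   under the default pool bounds.
#' @importFrom generics tidy
#' @method tidy t2_spectrum
#' @export
tidy.t2_spectrum <- function(x, ...) {
  tibble::tibble(
    t2 = x$grid,
    amplitude = x$amplitudes,
    compartment = compartment_labels(x$grid, compartment_bounds())
  )
}

#' One-row summary of a fitted T2 spectrum
#'
#' @param x A `t2_spectrum`.
#' @param bounds Compartment bounds, see [compartment_bounds()].
#' @param geometric_t2 Use geometric instead of arithmetic weighted T2.
#' @param ... Unused.
#' @return A one-row tibble: fitted flip angle, regularization weight,
#'   residual norm, pool fractions and weighted T2s.
#' @importFrom generics glance
#' @method glance t2_spectrum
#' @export
glance.t2_spectrum <- function(x, bounds = compartment_bounds(),
                               geometric_t2 = FALSE, ...) {
  parts <- partition_spectrum(x, bounds = bounds, geometric_t2 = geometric_t2)
  dplyr::bind_cols(
    tibble::tibble(
      flip_angle = x$flip_angle,
      mu = x$mu,
      residual_norm = x$residual_norm
    ),
    parts
  )
}

#' Fit many voxels stored in a long table
#'
#' Tidy batch interface: one echo train per voxel, stacked in long format.
#' Rows must be ordered by echo within voxel (or carry an `echo` column to
#' sort by).
#'
#' @param data Data frame with columns `voxel` (id), `signal`, and optionally
#'   `echo` (1-based echo index used for ordering).
#' @param acq An [acq_params()].
#' @param cfg A [fit_config()].
#' @param bounds Compartment bounds for the per-voxel summary.
#' @return A tibble with one row per voxel: `voxel` plus the [glance()]
#'   columns of its fitted spectrum.
#' @examples
#' \donttest{
#' acq <- acq_params()
#' tr <- phantom_voxels(3, tissue_model(), flip = 170, snr = 200,
#'                      acq = acq, seed = 1)
#' fit_voxels(tr, acq)
#' }
#' @export
fit_voxels <- function(data, acq = acq_params(), cfg = fit_config(),
                       bounds = compartment_bounds()) {
  stopifnot(is.data.frame(data), all(c("voxel", "signal") %in% names(data)))
  if ("echo" %in% names(data)) {
    data <- dplyr::arrange(data, .data$voxel, .data$echo)
  }
  split_idx <- split(seq_len(nrow(data)), data$voxel)
  rows <- purrr::map(names(split_idx), function(v) {
    y <- data$signal[split_idx[[v]]]
    spec <- fit_flip_angle(y, cfg, acq)
    dplyr::bind_cols(tibble::tibble(voxel = v),
                     glance(spec, bounds = bounds,
                            geometric_t2 = cfg$geometric_t2))
  })
  out <- dplyr::bind_rows(rows)
  # restore original voxel ordering and type where possible
  first_seen <- unique(as.character(data$voxel))
  out <- out[match(first_seen, out$voxel), , drop = FALSE]
  if (is.numeric(data$voxel)) out$voxel <- as.numeric(out$voxel)
  tibble::as_tibble(out)
}
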