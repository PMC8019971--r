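# Extended phase graph (EPG) forward model for CPMG echo trains.
#
# When the refocusing pulses deviate from 180 deg, part of the transverse
# magnetization is stored as longitudinal configuration states and returns
# at later echoes as stimulated-echo contributions. The EPG recursion tracks
# configuration states F(k) (transverse, dephasing order k) and Z(k)
# (longitudinal) through the train: relaxation over each half echo-spacing,
# a crusher-gradient dephasing shift of one order per half interval, and
# mixing by each refocusing pulse (rotation about the y axis, CPMG phase).
# T1 regrowth of Z states within the train is neglected (trains here end at
# 320 ms << TR).

# Vectorized over a vector of T2 values: returns an n_echoes x length(t2)
# matrix of echo magnitudes for unit initial magnetization.
epg_decay_matrix <- function(t2, t1, flip_angle, acq) {
  stopifnot(inherits(acq, "acq_params"))
  if (any(!is.finite(t2)) || any(t2 <= 0)) {
    stop("`t2` must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(t1) || t1 <= 0) stop("`t1` must be > 0", call. = FALSE)
  if (!is.finite(flip_angle) || flip_angle < 90 || flip_angle > 180) {
    stop("`flip_angle` must lie in [90, 180] degrees", call. = FALSE)
  }

  epg_cpmg(as.numeric(t2), t1, flip_angle, acq$n_echoes, acq$echo_spacing)
}

#' Echo amplitudes of a single T2 species under imperfect refocusing
#'
#' Computes the magnitude of the transverse magnetization at each echo of a
#' CPMG train via the extended phase graph recursion. At `flip_angle = 180`
#' this reduces exactly to mono-exponential decay `exp(-TE/t2)`; at smaller
#' angles stimulated-echo pathways redistribute signal along the train.
#'
#' @param t2 Transverse relaxation time in ms (> 0).
#' @param t1 Longitudinal relaxation time in ms (>= t2 physically; defaults
#'   to the acquisition's assumed T1).
#' @param flip_angle Refocusing flip angle in degrees, in \[90, 180\].
#' @param acq An [acq_params()] object.
#' @return Numeric vector of `acq$n_echoes` non-negative echo amplitudes for
#'   unit initial magnetization.
#' @examples
#' acq <- acq_params()
#' e <- epg_decay(100, flip_angle = 180, acq = acq)
#' all.equal(e, exp(-echo_times(acq) / 100))
#' @export
epg_decay <- function(t2, t1 = acq$t1, flip_angle, acq = acq_params()) {
  if (length(t2) != 1L) stop("`t2` must be a single value", call. = FALSE)
  drop(epg_decay_matrix(t2, t1, flip_angle, acq))
}

# cache of decay bases keyed by (flip, grid, acquisition)
.basis_cache <- new.env(parent = emptyenv())

basis_key <- function(grid, flip_angle, acq) {
  paste(
    format(flip_angle, digits = 12), acq$n_echoes, acq$echo_spacing, acq$t1,
    length(grid), format(grid[1], digits = 12),
    format(grid[length(grid)], digits = 12), format(sum(grid), digits = 15),
    sep = "|"
  )
}

#' Build a multi-exponential decay basis
#'
#' Evaluates [epg_decay()] on every node of a T2 grid at a common refocusing
#' flip angle, yielding the forward-model matrix `A` (echoes x T2 nodes) of
#' the spectral inversion. Columns are not normalized: the fitted spectrum
#' amplitude absorbs proton density. Bases are cached per (flip angle, grid,
#' acquisition) since the flip-angle search re-uses them across voxels.
#'
#' @param grid Numeric T2 grid from [t2_grid()] (ms, strictly increasing).
#' @param flip_angle Refocusing flip angle in degrees.
#' @param acq An [acq_params()] object.
#' @param cache Reuse/populate the in-memory basis cache.
#' @return An object of class `decay_basis` with elements `matrix`,
#'   `flip_angle`, `grid`, `acq`.
#' @examples
#' b <- build_basis(t2_grid(10, 20, 200), 180, acq_params())
#' dim(b$matrix)
#' @export
build_basis <- function(grid, flip_angle, acq = acq_params(), cache = TRUE) {
  if (!is.numeric(grid) || length(grid) < 1L || any(diff(grid) <= 0)) {
    stop("`grid` must be a strictly increasing numeric vector", call. = FALSE)
  }
  key <- basis_key(grid, flip_angle, acq)
  if (cache && !is.null(.basis_cache[[key]])) return(.basis_cache[[key]])
  A <- epg_decay_matrix(grid, acq$t1, flip_angle, acq)
  out <- structure(
    list(matrix = A, gram = crossprod(A), flip_angle = flip_angle,
         grid = grid, acq = acq),
    class = "decay_basis"
  )
  if (cache) {
    if (length(ls(.basis_cache)) > 1200L) {
      rm(list = ls(.basis_cache), envir = .basis_cache)
    }
    .basis_cache[[key]] <- out
  }
  out
}

#' @export
print.decay_basis <- function(x, ...) {
  cat(sprintf(
    "<decay_basis> %d echoes x %d T2 nodes, flip %.2f deg, T2 %g..%g ms\n",
    nrow(x$matrix), ncol(x$matrix), x$flip_angle, min(x$grid), max(x$grid)
  ))
  invisible(x)
}

#' Export a decay basis to a delimited text file
#'
#' Writes the basis matrix with echo times as row names and grid T2 values as
#' column names, for external inspection.
#'
#' @param basis A `decay_basis`.
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
dump_basis <- function(basis, path) {
  stopifnot(inherits(basis, "decay_basis"))
  m <- basis$matrix
  dimnames(m) <- list(
    sprintf("TE%g", echo_times(basis$acq)),
    sprintf("T2_%.6g", basis$grid)
  )
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
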