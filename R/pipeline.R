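# Volumetric pipeline: smooth each echo volume, fit every in-mask voxel,
# assemble the quantitative map set.

#' Pipeline configuration
#'
#' @param smoothing_sd Standard deviation (voxels) of the 3D Gaussian applied
#'   to each echo volume before fitting; 0 disables smoothing.
#' @param acq An [acq_params()].
#' @param fit A [fit_config()].
#' @param bounds A [compartment_bounds()].
#' @param signal_floor_factor Voxels whose first-echo magnitude falls below
#'   `signal_floor_factor` times the estimated background noise are skipped
#'   (NaN in all maps). Background noise is the Rayleigh-corrected mean
#'   first-echo magnitude outside the mask; with no out-of-mask voxels the
#'   floor is 0 and nothing is skipped.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(smoothing_sd = 1.5, acq = acq_params(),
                            fit = fit_config(), bounds = compartment_bounds(),
                            signal_floor_factor = 5) {
  if (smoothing_sd < 0) stop("`smoothing_sd` must be >= 0", call. = FALSE)
  structure(
    list(
      smoothing_sd = smoothing_sd, acq = acq, fit = fit, bounds = bounds,
      signal_floor_factor = signal_floor_factor
    ),
    class = "pipeline_config"
  )
}

map_names <- c("myelin_fraction", "iew_fraction", "csf_fraction",
               "myelin_t2", "iew_t2", "csf_t2", "flip_angle", "residual_norm")

#' Assemble per-voxel summaries into a quantitative map set
#'
#' Writes per-voxel compartment summaries into congruent 3D volumes; voxels
#' outside the mask (or skipped) are NaN in every map.
#'
#' @param summaries Data frame with a `voxel` column of linear voxel indices
#'   and the [glance()] columns (`flip_angle`, `mu`, `residual_norm`, pool
#'   fractions and weighted T2s).
#' @param dim Integer triple: volume shape.
#' @param voxel_size Voxel edge lengths in mm (scalar or length-3).
#' @param config Optional `pipeline_config` recorded for provenance.
#' @return An object of class `t2_map_set`: named list `maps` of eight 3D
#'   arrays (three fractions, three weighted T2s, flip angle, residual norm),
#'   plus `voxel_size`, `dim` and `config`.
#' @export
assemble_maps <- function(summaries, dim, voxel_size = 2.5, config = NULL) {
  dim <- as.integer(dim)
  if (length(dim) != 3L) stop("`dim` must have length 3", call. = FALSE)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  idx <- as.integer(summaries$voxel)
  if (any(idx < 1L | idx > prod(dim))) {
    stop("voxel indices outside the volume", call. = FALSE)
  }
  maps <- lapply(map_names, function(nm) {
    v <- array(NaN, dim)
    v[idx] <- summaries[[nm]]
    v
  })
  names(maps) <- map_names
  structure(
    list(maps = maps, voxel_size = voxel_size, dim = dim, config = config),
    class = "t2_map_set"
  )
}

#' @export
print.t2_map_set <- function(x, ...) {
  nfit <- sum(is.finite(x$maps$iew_fraction))
  cat(sprintf("<t2_map_set> %s volume, %d fitted voxels, voxel %s mm\n",
              paste(x$dim, collapse = "x"), nfit,
              paste(x$voxel_size, collapse = "x")))
  invisible(x)
}

#' @method as_tibble t2_map_set
#' @export
as_tibble.t2_map_set <- function(x, ...) {
  idx <- which(is.finite(x$maps$iew_fraction) | is.finite(x$maps$flip_angle))
  ij <- arrayInd(idx, x$dim)
  out <- tibble::tibble(voxel = idx, i = ij[, 1], j = ij[, 2], k = ij[, 3])
  for (nm in map_names) out[[nm]] <- x$maps[[nm]][idx]
  out
}

read_volume <- function(x, what = "input") {
  if (is.character(x)) {
    if (!file.exists(x)) stop(sprintf("%s file not found: %s", what, x),
                              call. = FALSE)
    img <- RNifti::readNifti(x)
    return(list(data = as.array(img), pixdim = RNifti::pixdim(img)))
  }
  list(data = as.array(x), pixdim = NULL)
}

#' Run the full volumetric T2 analysis
#'
#' Smooths each echo volume with a 3D Gaussian, fits every in-mask voxel
#' (flip-angle estimation + regularized NNLS inversion), partitions each
#' spectrum into the three water pools and assembles the quantitative maps.
#' The computation is deterministic for fixed inputs and configuration.
#'
#' @param echoes 4D array (x, y, z, echo) or path to a 4D NIfTI file.
#' @param mask 3D logical/0-1 array or NIfTI path; `NULL` fits every voxel.
#' @param config A [pipeline_config()].
#' @param voxel_size Voxel size in mm (overridden by the NIfTI header when
#'   reading from file).
#' @return A `t2_map_set`; its `log` element records voxel counts and the
#'   distributions of fitted flip angles and regularization weights.
#' @export
run_pipeline <- function(echoes, mask = NULL, config = pipeline_config(),
                         voxel_size = 2.5) {
  stopifnot(inherits(config, "pipeline_config"))
  ev <- read_volume(echoes, "multi-echo")
  data <- ev$data
  if (length(dim(data)) != 4L) {
    stop("multi-echo input must be 4D (x, y, z, echo)", call. = FALSE)
  }
  if (!is.null(ev$pixdim)) voxel_size <- ev$pixdim[1:3]
  if (dim(data)[4] != config$acq$n_echoes) {
    stop(sprintf("echo count %d does not match acquisition n_echoes %d",
                 dim(data)[4], config$acq$n_echoes), call. = FALSE)
  }
  d3 <- dim(data)[1:3]
  if (is.null(mask)) {
    mask_arr <- array(TRUE, d3)
  } else {
    mask_arr <- read_volume(mask, "mask")$data > 0
    if (!identical(as.integer(dim(mask_arr)), as.integer(d3))) {
      stop("mask shape does not match the echo volumes", call. = FALSE)
    }
  }

  # background noise estimate from out-of-mask first-echo magnitudes; only
  # trusted when the out-of-mask region really is dark (air), not masked-out
  # tissue
  floor_val <- 0
  first_echo <- data[, , , 1, drop = TRUE]
  bg <- first_echo[!mask_arr]
  if (length(bg) >= 50) {
    in_level <- stats::median(first_echo[mask_arr])
    if (is.finite(in_level) && mean(bg) < 0.2 * in_level) {
      sigma_bg <- mean(bg) / sqrt(pi / 2)   # Rayleigh mean -> sigma
      floor_val <- config$signal_floor_factor * sigma_bg
    }
  }

  if (config$smoothing_sd > 0) {
    data <- smooth_multiecho(data, config$smoothing_sd)
  }

  idx <- which(mask_arr)
  ne <- config$acq$n_echoes
  flat <- matrix(data, nrow = prod(d3), ncol = ne)

  n_skipped <- 0L
  rows <- vector("list", length(idx))
  for (q in seq_along(idx)) {
    y <- flat[idx[q], ]
    if (!all(is.finite(y)) || y[1] < floor_val || all(y == 0)) {
      n_skipped <- n_skipped + 1L
      next
    }
    spec <- fit_flip_angle(y, config$fit, config$acq)
    g <- glance(spec, bounds = config$bounds,
                geometric_t2 = config$fit$geometric_t2)
    g$voxel <- idx[q]
    g$mu <- spec$mu
    rows[[q]] <- g
  }
  summaries <- dplyr::bind_rows(rows)
  if (nrow(summaries) == 0L) stop("no voxel could be fitted", call. = FALSE)

  ms <- assemble_maps(summaries, d3, voxel_size, config)
  ms$log <- list(
    n_mask = length(idx),
    n_fitted = nrow(summaries),
    n_skipped = n_skipped,
    signal_floor = floor_val,
    flip_angle = stats::quantile(summaries$flip_angle, c(0, .25, .5, .75, 1)),
    mu = stats::quantile(summaries$mu, c(0, .25, .5, .75, 1))
  )
  ms
}

#' Write a map set to NIfTI files with a JSON provenance sidecar
#'
#' @param mapset A `t2_map_set`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_map_set <- function(mapset, dir) {
  stopifnot(inherits(mapset, "t2_map_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(mapset$maps)) {
    arr <- mapset$maps[[nm]] * 1
    attr(arr, "pixdim") <- mapset$voxel_size
    RNifti::writeNifti(arr, file.path(dir, paste0(nm, ".nii.gz")),
                       datatype = "float")
  }
  cfg <- mapset$config
  side <- list(
    maps = names(mapset$maps),
    dim = mapset$dim,
    voxel_size_mm = mapset$voxel_size,
    smoothing_sd = if (!is.null(cfg)) cfg$smoothing_sd else NA,
    grid = if (!is.null(cfg)) {
      list(n = length(cfg$fit$grid), min = min(cfg$fit$grid),
           max = max(cfg$fit$grid))
    } else NULL,
    bounds = if (!is.null(cfg)) unclass(cfg$bounds) else NULL,
    misfit_inflation = if (!is.null(cfg)) cfg$fit$misfit_inflation else NA,
    flip_range = if (!is.null(cfg)) cfg$fit$flip_range else NA
  )
  jsonlite::write_json(side, file.path(dir, "maps.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
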