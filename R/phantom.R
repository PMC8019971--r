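# Synthetic multi-echo phantoms with known compartmental ground truth.
# The default phantom emulates the statistical structure the analysis
# assumes: three-pool white-matter tissue, a spherical lesion whose
# intra/extracellular-water T2 is elevated by 30 ms, a FLAIR-positive core
# strictly inside the lesion (so the lesion's outer shell is the
# T2/FLAIR mismatch), a spatially varying refocusing flip angle, and Rician
# magnitude noise.

#' Three-pool tissue model
#'
#' Pool fractions must sum to 1. Defaults are a white-matter-like model:
#' myelin water 0.12 at 20 ms, intra/extracellular water 0.80 at 80 ms,
#' fluid 0.08 at 1000 ms.
#'
#' @param myelin_fraction,iew_fraction,csf_fraction Pool signal fractions.
#' @param myelin_t2,iew_t2,csf_t2 Pool T2 times, ms.
#' @param proton_density Overall signal scale of the voxel.
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(myelin_fraction = 0.12, myelin_t2 = 20,
                         iew_fraction = 0.80, iew_t2 = 80,
                         csf_fraction = 0.08, csf_t2 = 1000,
                         proton_density = 1) {
  fr <- c(myelin_fraction, iew_fraction, csf_fraction)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("pool fractions must be non-negative and sum to 1", call. = FALSE)
  }
  structure(
    list(fractions = fr, t2 = c(myelin_t2, iew_t2, csf_t2),
         proton_density = proton_density),
    class = "tissue_model"
  )
}

#' Lesion tissue model
#'
#' White-matter model with reduced myelin water and the
#' intra/extracellular-water T2 elevated by `iew_elevation` ms above the
#' 80 ms baseline (default +30 ms, i.e. 110 ms, inside the 70-140 ms band
#' where pathological IEw peaks are observed).
#'
#' @param iew_elevation Elevation of the IEw T2 over the 80 ms baseline, ms.
#' @return A `tissue_model`.
#' @export
lesion_model <- function(iew_elevation = 30) {
  tissue_model(myelin_fraction = 0.06, myelin_t2 = 20,
               iew_fraction = 0.86, iew_t2 = 80 + iew_elevation,
               csf_fraction = 0.08, csf_t2 = 1000)
}

#' Noiseless echo train of a multi-pool voxel
#'
#' Superposition of the pools' extended-phase-graph decays, weighted by
#' fraction times proton density.
#'
#' @param model A [tissue_model()].
#' @param flip Refocusing flip angle, degrees.
#' @param acq An [acq_params()].
#' @return Numeric vector of noiseless echo magnitudes.
#' @export
voxel_signal <- function(model, flip = 180, acq = acq_params()) {
  stopifnot(inherits(model, "tissue_model"))
  active <- model$fractions > 0
  A <- epg_decay_matrix(model$t2[active], acq$t1, flip, acq)
  drop(A %*% (model$fractions[active] * model$proton_density))
}

#' Add Rician noise to magnitude signals
#'
#' Each sample `s` is replaced by `sqrt((s + g1)^2 + g2^2)` with independent
#' `g1, g2 ~ N(0, sigma^2)` and `sigma = ref / snr`. This is the magnitude
#' noise model of single-coil MRI: Rayleigh-distributed where the signal is
#' zero, approximately Gaussian at high signal-to-noise ratio.
#'
#' @param signal Numeric vector/array of noiseless magnitudes.
#' @param snr First-echo signal-to-noise ratio; `Inf` returns the input.
#' @param ref Reference amplitude defining sigma (defaults to the first
#'   element of `signal`).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Noisy magnitudes, same shape as `signal`.
#' @export
add_rician_noise <- function(signal, snr, ref = signal[1], seed = NULL) {
  if (!is.numeric(snr) || length(snr) != 1L || snr <= 0) {
    stop("`snr` must be a positive scalar", call. = FALSE)
  }
  if (is.infinite(snr)) return(signal)
  sigma <- ref / snr
  if (!is.finite(sigma) || sigma <= 0) {
    stop("invalid noise level: `ref`/`snr` must be positive", call. = FALSE)
  }
  draw <- function() {
    n <- length(signal)
    g1 <- stats::rnorm(n, 0, sigma)
    g2 <- stats::rnorm(n, 0, sigma)
    out <- sqrt((signal + g1)^2 + g2^2)
    attributes(out) <- attributes(signal)
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Phantom specification
#'
#' Geometry and tissue models of the synthetic multi-echo phantom. All
#' geometric units are voxels; centers may be fractional. The FLAIR-positive
#' core must be strictly inside the lesion, leaving a mismatch shell.
#'
#' @param shape Volume shape in voxels.
#' @param voxel_size Isotropic voxel size in mm.
#' @param tissue Background [tissue_model()].
#' @param lesion Lesion [tissue_model()] (default: IEw T2 elevated by 30 ms).
#' @param lesion_center,lesion_radius Sphere defining the lesion.
#' @param flair_radius Radius of the FLAIR-positive core (< `lesion_radius`);
#'   the GTV mask equals this core, mirroring FLAIR-based tumor contouring.
#' @param ctv_radius Radius of the clinical target volume sphere around the
#'   lesion center (> `lesion_radius`).
#' @param contralateral_center,contralateral_radius Healthy reference ROI.
#' @param flip_field Refocusing flip angle at the first and last x index;
#'   linear in between (equal values give a constant field).
#' @param snr First-echo signal-to-noise ratio (`Inf` for noiseless).
#' @param seed Integer seed for the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(24L, 24L, 12L), voxel_size = 2.5,
                         tissue = tissue_model(), lesion = lesion_model(),
                         lesion_center = c(8, 12, 6.5), lesion_radius = 5,
                         flair_radius = 3, ctv_radius = 8,
                         contralateral_center = c(17, 12, 6.5),
                         contralateral_radius = 4,
                         flip_field = c(180, 160), snr = 200, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("`shape` must be three positive integers", call. = FALSE)
  }
  if (flair_radius > lesion_radius) {
    stop("FLAIR core must be contained in the lesion", call. = FALSE)
  }
  if (any(lesion_center - lesion_radius < 0.5) ||
      any(lesion_center + lesion_radius > shape + 0.5)) {
    stop("lesion sphere must lie inside the volume", call. = FALSE)
  }
  if (!(snr > 0)) stop("`snr` must be > 0 (possibly Inf)", call. = FALSE)
  structure(
    list(
      shape = shape, voxel_size = voxel_size, tissue = tissue,
      lesion = lesion, lesion_center = lesion_center,
      lesion_radius = lesion_radius, flair_radius = flair_radius,
      ctv_radius = ctv_radius, contralateral_center = contralateral_center,
      contralateral_radius = contralateral_radius,
      flip_field = flip_field, snr = snr, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

sphere_mask <- function(shape, center, radius) {
  if (radius <= 0) return(array(FALSE, shape))
  i <- slice.index(array(0, shape), 1)
  j <- slice.index(array(0, shape), 2)
  k <- slice.index(array(0, shape), 3)
  (i - center[1])^2 + (j - center[2])^2 + (k - center[3])^2 <= radius^2
}

#' Generate a synthetic multi-echo phantom
#'
#' Builds the 4D multi-echo volume (noiseless superposition of pool decays at
#' the local flip angle, then Rician noise), the per-voxel truth maps and the
#' analysis masks. Deterministic for a fixed spec (including its seed). The
#' noise sigma is the volume-average noiseless tissue first-echo amplitude
#' divided by `snr`.
#'
#' @param spec A [phantom_spec()].
#' @param acq An [acq_params()].
#' @return List of class `t2_phantom`: `echoes` (4D array), `truth` (list of
#'   3D arrays: `iew_t2`, `myelin_fraction`, `iew_fraction`, `csf_fraction`,
#'   `flip_angle`), `masks` (list of logical arrays: `lesion`, `flair`,
#'   `gtv`, `ctv`, `contralateral`, `brain`), `sigma`, `spec`, `acq`.
#' @export
make_phantom <- function(spec = phantom_spec(), acq = acq_params()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$shape
  ne <- acq$n_echoes

  lesion <- sphere_mask(shp, spec$lesion_center, spec$lesion_radius)
  flair <- sphere_mask(shp, spec$lesion_center, spec$flair_radius)
  ctv <- sphere_mask(shp, spec$lesion_center, spec$ctv_radius)
  contra <- sphere_mask(shp, spec$contralateral_center,
                        spec$contralateral_radius)
  brain <- array(TRUE, shp)

  # flip angle linear along x
  fa_x <- if (shp[1] == 1L) {
    mean(spec$flip_field)
  } else {
    seq(spec$flip_field[1], spec$flip_field[2], length.out = shp[1])
  }
  flip_vol <- array(fa_x[slice.index(array(0L, shp), 1)], shp)

  # noiseless signal: unique (region, x-index) combinations
  echoes <- array(0, c(shp, ne))
  flat <- matrix(0, prod(shp), ne)
  region <- ifelse(lesion, 2L, 1L)
  models <- list(spec$tissue, spec$lesion)
  xi <- as.vector(slice.index(array(0L, shp), 1))
  for (r in 1:2) {
    for (x in unique(xi)) {
      sel <- region == r & xi == x
      if (!any(sel)) next
      sig <- voxel_signal(models[[r]], flip = fa_x[x], acq = acq)
      flat[sel, ] <- matrix(sig, sum(sel), ne, byrow = TRUE)
    }
  }

  tissue_first <- flat[region == 1L, 1]
  sigma_ref <- mean(tissue_first)
  noisy <- if (is.infinite(spec$snr)) {
    flat
  } else {
    withr::with_seed(spec$seed, {
      g1 <- matrix(stats::rnorm(length(flat), 0, sigma_ref / spec$snr),
                   nrow(flat))
      g2 <- matrix(stats::rnorm(length(flat), 0, sigma_ref / spec$snr),
                   nrow(flat))
      sqrt((flat + g1)^2 + g2^2)
    })
  }
  echoes <- array(noisy, c(shp, ne))

  truth <- list(
    iew_t2 = array(ifelse(lesion, spec$lesion$t2[2], spec$tissue$t2[2]), shp),
    myelin_fraction = array(ifelse(lesion, spec$lesion$fractions[1],
                                   spec$tissue$fractions[1]), shp),
    iew_fraction = array(ifelse(lesion, spec$lesion$fractions[2],
                                spec$tissue$fractions[2]), shp),
    csf_fraction = array(ifelse(lesion, spec$lesion$fractions[3],
                                spec$tissue$fractions[3]), shp),
    flip_angle = flip_vol
  )
  structure(
    list(
      echoes = echoes, truth = truth,
      masks = list(lesion = lesion, flair = flair, gtv = flair, ctv = ctv,
                   contralateral = contra, brain = brain),
      sigma = if (is.infinite(spec$snr)) 0 else sigma_ref / spec$snr,
      spec = spec, acq = acq
    ),
    class = "t2_phantom"
  )
}

#' @export
print.t2_phantom <- function(x, ...) {
  cat(sprintf(
    "<t2_phantom> %s x %d echoes, lesion %d voxels (FLAIR core %d), SNR %s\n",
    paste(dim(x$echoes)[1:3], collapse = "x"), dim(x$echoes)[4],
    sum(x$masks$lesion), sum(x$masks$flair),
    format(x$spec$snr)
  ))
  invisible(x)
}

#' Write a phantom to NIfTI files
#'
#' @param phantom A [make_phantom()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "t2_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vx <- phantom$spec$voxel_size
  wr <- function(arr, name) {
    arr <- arr * 1
    attr(arr, "pixdim") <- rep(vx, min(3L, length(dim(arr))))
    RNifti::writeNifti(arr, file.path(dir, paste0(name, ".nii.gz")),
                       datatype = "float")
  }
  wr(phantom$echoes, "echoes")
  for (nm in names(phantom$truth)) wr(phantom$truth[[nm]], paste0("truth_", nm))
  for (nm in names(phantom$masks)) wr(phantom$masks[[nm]], paste0("mask_", nm))
  invisible(dir)
}

#' Simulate independent voxels of one tissue model as a long table
#'
#' Generates `n` noisy echo trains from a single tissue model at a common
#' flip angle, stacked in the long format accepted by [fit_voxels()].
#'
#' @param n Number of voxels.
#' @param model A [tissue_model()].
#' @param flip Refocusing flip angle, degrees.
#' @param snr First-echo signal-to-noise ratio.
#' @param acq An [acq_params()].
#' @param seed Integer seed.
#' @return Tibble with columns `voxel`, `echo`, `te`, `signal`.
#' @export
phantom_voxels <- function(n, model = tissue_model(), flip = 180, snr = 200,
                           acq = acq_params(), seed = 1L) {
  sig <- voxel_signal(model, flip = flip, acq = acq)
  ne <- acq$n_echoes
  noisy <- withr::with_seed(as.integer(seed), {
    if (is.infinite(snr)) {
      matrix(sig, n, ne, byrow = TRUE)
    } else {
      sigma <- sig[1] / snr
      s <- matrix(sig, n, ne, byrow = TRUE)
      g1 <- matrix(stats::rnorm(n * ne, 0, sigma), n)
      g2 <- matrix(stats::rnorm(n * ne, 0, sigma), n)
      sqrt((s + g1)^2 + g2^2)
    }
  })
  tibble::tibble(
    voxel = rep(seq_len(n), each = ne),
    echo = rep(seq_len(ne), n),
    te = rep(echo_times(acq), n),
    signal = as.vector(t(noisy))
  )
}
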