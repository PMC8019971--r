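test_that("smoothing with sd 0 or constant input is the identity", {
  v <- array(stats::rnorm(5 * 4 * 3 * 2), c(5, 4, 3, 2))
  expect_identical(smooth_multiecho(v, 0), v)
  cv <- array(7, c(6, 6, 6, 3))
  expect_equal(smooth_multiecho(cv, 1.5), cv, tolerance = 1e-12)
  expect_error(smooth_multiecho(array(0, c(4, 4, 4)), 1), "4D")
})

test_that("separable smoothing matches a direct convolution oracle", {
  v <- array(0, c(9, 9, 9))
  v[5, 5, 5] <- 1
  v[2, 7, 3] <- -0.5         # off-center mass to exercise reflection
  ref <- direct_gauss_smooth3d(v, 1.5)
  got <- smooth_multiecho(array(v, c(9, 9, 9, 1)), 1.5)[, , , 1]
  expect_equal(got, ref, tolerance = 1e-12)
  # kernel normalization conserves the total for interior-supported mass
  w <- array(0, c(15, 15, 15))
  w[8, 8, 8] <- 2
  sm <- smooth_multiecho(array(w, c(dim(w), 1)), 1.5)[, , , 1]
  expect_equal(sum(sm), 2, tolerance = 1e-9)
})

test_that("a uniform noiseless volume reproduces the single-voxel fit everywhere", {
  acq <- acq_params()
  spec <- phantom_spec(
    shape = c(4, 4, 2), lesion_center = c(2, 2, 1.5), lesion_radius = 0.4,
    flair_radius = 0.2, ctv_radius = 1, contralateral_center = c(3, 3, 1.5),
    contralateral_radius = 0.5, flip_field = c(165, 165), snr = Inf
  )
  ph <- make_phantom(spec, acq)
  expect_equal(sum(ph$masks$lesion), 0)   # sub-voxel lesion: uniform tissue
  cfg <- pipeline_config(smoothing_sd = 0, acq = acq)
  ms <- run_pipeline(ph$echoes, mask = NULL, config = cfg)
  single <- glance(fit_echo_train(ph$echoes[1, 1, 1, ], acq))
  expect_equal(max(abs(ms$maps$iew_t2 - single$iew_t2)), 0, tolerance = 1e-9)
  expect_equal(max(abs(ms$maps$myelin_fraction - single$myelin_fraction)), 0,
               tolerance = 1e-9)
  expect_equal(unique(as.vector(ms$maps$flip_angle)), single$flip_angle)
})

test_that("the pipeline is deterministic and honors the mask", {
  acq <- acq_params()
  spec <- phantom_spec(
    shape = c(4, 3, 2), lesion_center = c(2, 2, 1.5), lesion_radius = 0.4,
    flair_radius = 0.2, ctv_radius = 1, contralateral_center = c(3, 2, 1.5),
    contralateral_radius = 0.5, flip_field = c(170, 160), snr = 150, seed = 4
  )
  ph <- make_phantom(spec, acq)
  mask <- array(TRUE, spec$shape)
  mask[1, 1, 1] <- FALSE
  cfg <- pipeline_config(smoothing_sd = 0, acq = acq)
  a <- run_pipeline(ph$echoes, mask, cfg)
  b <- run_pipeline(ph$echoes, mask, cfg)
  expect_identical(a$maps, b$maps)
  expect_true(is.nan(a$maps$iew_t2[1, 1, 1]))
  expect_true(all(is.finite(a$maps$iew_t2[which(mask)])))
  expect_equal(a$log$n_fitted, sum(mask))
})

test_that("shape and configuration mismatches are rejected", {
  acq <- acq_params(n_echoes = 4)
  v <- array(1, c(3, 3, 2, 4))
  cfg <- pipeline_config(acq = acq, smoothing_sd = 0)
  expect_error(run_pipeline(array(1, c(3, 3, 2)), config = cfg), "4D")
  expect_error(run_pipeline(v, mask = array(TRUE, c(2, 3, 2)), config = cfg),
               "mask shape")
  expect_error(
    run_pipeline(array(1, c(3, 3, 2, 5)), config = cfg),
    "echo count"
  )
  expect_error(run_pipeline("no/such/file.nii.gz", config = cfg), "not found")
})

test_that("lesion-tissue contrast in the IEw T2 map matches the built-in truth", {
  acq <- acq_params()
  spec <- phantom_spec(
    shape = c(10, 10, 6), lesion_center = c(4, 5, 3.5), lesion_radius = 2.2,
    flair_radius = 1.2, ctv_radius = 3.5, contralateral_center = c(8, 5, 3.5),
    contralateral_radius = 1.5, flip_field = c(170, 170), snr = Inf
  )
  ph <- make_phantom(spec, acq)
  # fit a slab through the lesion center and a far tissue corner
  mask <- array(FALSE, spec$shape)
  mask[, 5, 4] <- TRUE
  cfg <- pipeline_config(smoothing_sd = 0, acq = acq)
  ms <- run_pipeline(ph$echoes, mask, cfg)
  lesion_vals <- ms$maps$iew_t2[mask & ph$masks$lesion]
  tissue_vals <- ms$maps$iew_t2[mask & !ph$masks$lesion]
  expect_gte(length(lesion_vals), 3)
  contrast <- mean(lesion_vals) - mean(tissue_vals)
  expect_equal(contrast, 30, tolerance = 3)
})

test_that("map sets round-trip through NIfTI with a provenance sidecar", {
  summ <- tibble::tibble(
    voxel = 1:8,
    myelin_fraction = runif(8), iew_fraction = runif(8),
    csf_fraction = runif(8), myelin_t2 = runif(8, 10, 39),
    iew_t2 = runif(8, 45, 240), csf_t2 = runif(8, 300, 2000),
    flip_angle = runif(8, 120, 180), residual_norm = runif(8),
    mu = runif(8)
  )
  ms <- assemble_maps(summ, dim = c(2, 2, 2), voxel_size = 2.5,
                      config = pipeline_config())
  dir <- file.path(tempdir(), "maps-roundtrip")
  write_map_set(ms, dir)
  img <- RNifti::readNifti(file.path(dir, "iew_t2.nii.gz"))
  expect_equal(as.array(img), ms$maps$iew_t2, tolerance = 1e-6,
               ignore_attr = TRUE)
  side <- jsonlite::read_json(file.path(dir, "maps.json"))
  expect_equal(side$smoothing_sd, 1.5)
  expect_equal(side$grid$n, 200)
  unlink(dir, recursive = TRUE)
})
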