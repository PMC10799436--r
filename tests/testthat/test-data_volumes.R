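test_that("min-max normalization maps to [0,1], preserves order, is idempotent", {
  v <- volume(array(c(0, 0.5, 1, 0, 0.5, 1, 0, 1), c(2, 2, 2)))
  expect_equal(normalize_minmax(v)$data, v$data)

  v2 <- volume(array(c(2, 4, 6, 2, 4, 6, 2, 6), c(2, 2, 2)))
  n2 <- normalize_minmax(v2)
  expect_equal(sort(unique(as.numeric(n2$data))), c(0, 0.5, 1))

  set.seed(3)
  for (i in 1:5) {
    a <- array(rnorm(27, sd = 10), c(3, 3, 3))
    n <- normalize_minmax(volume(a))$data
    expect_gte(min(n), 0); expect_lte(max(n), 1)
    expect_equal(order(a), order(n))                     # monotone transform
    expect_equal(normalize_minmax(volume(n))$data, n, tolerance = 1e-6)
  }

  expect_error(normalize_minmax(volume(array(5, c(2, 2, 2)))), "degenerate")
})

test_that("NIfTI round trip preserves data and affine; defaults and errors", {
  set.seed(11)
  aff <- diag(4); aff[1, 1] <- 2; aff[1:3, 4] <- c(-5, 3, 1.5)
  v <- volume(array(runif(8^3), c(8, 8, 8)), aff)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f)
  expect_equal(r$data, v$data)
  expect_equal(r$affine, v$affine)

  # file with no stored transform -> identity affine
  f2 <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(runif(27), c(3, 3, 3))), f2)
  expect_equal(read_volume(f2)$affine, diag(4))

  # 2D image -> dimensionality error; unreadable path -> error naming the path
  f3 <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(matrix(runif(16), 4)), f3)
  expect_error(read_volume(f3), "3D")
  expect_error(read_volume("/nonexistent/vol.nii"), "nonexistent")
})

test_that("block-mean down-sampling matches the hand-computed oracle", {
  expect_equal(downsample_volume(volume(array(0.7, c(8, 8, 8))),
                                 c(4, 4, 4))$data,
               array(0.7, c(4, 4, 4)))
  v <- volume(array(runif(64), c(4, 4, 4)))
  expect_equal(downsample_volume(v, c(4, 4, 4))$data, v$data)

  # 4^3 -> 2^3: every output voxel is the mean of its 2x2x2 source block
  set.seed(4)
  a <- array(rnorm(64), c(4, 4, 4))
  got <- downsample_volume(volume(a), c(2, 2, 2))$data
  want <- array(0, c(2, 2, 2))
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    want[i, j, k] <- mean(a[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
                            (2 * k - 1):(2 * k)])
  expect_equal(got, want)
  expect_true(min(got) >= min(a) && max(got) <= max(a))

  expect_error(downsample_volume(v, c(8, 8, 8)), "upsampling")
})

test_that("cohort generation is a pure function of the seed", {
  cfg <- synthetic_config(n_ad = 3, n_cn = 4, grid = 12, seed = 42)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_equal(sum(vapply(c1, `[[`, character(1), "label") == "AD"), 3)
  expect_equal(sum(vapply(c1, `[[`, character(1), "label") == "CN"), 4)
  for (s in c1) {
    expect_equal(range(s$smri$data), c(0, 1))
    expect_equal(dim(s$smri$data), dim(s$pet$data))
  }
  c3 <- generate_cohort(synthetic_config(n_ad = 3, n_cn = 4, grid = 12,
                                         seed = 43))
  expect_false(identical(c1[[1]]$smri$data, c3[[1]]$smri$data))
})

test_that("planted lesion depresses AD intensities; null cohort has none", {
  grid <- 16L
  cfg <- synthetic_config(n_ad = 10, n_cn = 10, grid = grid,
                          effect_size = 0.5, noise_sd = 0.02, seed = 7)
  coh <- generate_cohort(cfg)
  ax <- seq_len(grid)
  d2 <- outer(outer((ax - cfg$lesion_center[1])^2,
                    (ax - cfg$lesion_center[2])^2, `+`),
              (ax - cfg$lesion_center[3])^2, `+`)
  mask <- d2 <= cfg$lesion_radius^2
  lesion_mean <- function(s) mean(s$smri$data[mask])
  labs <- vapply(coh, `[[`, character(1), "label")
  gap <- mean(vapply(coh[labs == "CN"], lesion_mean, numeric(1))) -
    mean(vapply(coh[labs == "AD"], lesion_mean, numeric(1)))
  expect_gte(gap, cfg$effect_size / 2)

  cfg0 <- synthetic_config(n_ad = 10, n_cn = 10, grid = grid,
                           effect_size = 0, noise_sd = 0.02, seed = 7)
  coh0 <- generate_cohort(cfg0)
  gap0 <- mean(vapply(coh0[labs == "CN"], lesion_mean, numeric(1))) -
    mean(vapply(coh0[labs == "AD"], lesion_mean, numeric(1)))
  expect_lt(abs(gap0), 0.05)
})

test_that("config validation: defaults mirror the study cohort; bad lesions rejected", {
  cfg <- synthetic_config()
  expect_equal(cfg$n_ad, 88L)
  expect_equal(cfg$n_cn, 122L)
  expect_equal(cfg$grid, 64L)
  expect_error(synthetic_config(grid = 16, lesion_center = c(2, 8, 8),
                                lesion_radius = 4), "outside the grid")
  expect_error(synthetic_config(effect_size = 1.2), "effect_size")
})

test_that("cohort manifest round trip preserves subjects", {
  coh <- generate_cohort(synthetic_config(n_ad = 2, n_cn = 1, grid = 8,
                                          seed = 9))
  dir <- file.path(tempdir(), "coh_rt")
  manifest <- write_cohort(coh, dir)
  back <- read_cohort(manifest)
  expect_equal(length(back), 3)
  expect_equal(back[[1]]$subject_id, coh[[1]]$subject_id)
  expect_equal(back[[2]]$label, coh[[2]]$label)
  expect_equal(back[[3]]$smri$data, coh[[3]]$smri$data, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
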