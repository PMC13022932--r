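# Deterministic preprocessing: RAS, isotropic resampling, crop/pad,
# normalisation, the hook chain and the cache.

random_affine_vol <- function(dims = c(10, 12, 14), spacing = c(1, 1, 1)) {
  vol <- array(rnorm(prod(dims)), dim = dims)
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- c(-4, 7, 2)
  list(vol = vol, aff = aff)
}

test_that("to_ras is the identity on RAS volumes and idempotent otherwise", {
  x <- random_affine_vol()
  r <- to_ras(x$vol, x$aff)
  expect_identical(r$data, x$vol)
  expect_equal(r$affine, x$aff)

  # LPS: first two axes flipped
  lps <- x$aff
  lps[1, 1] <- -1; lps[2, 2] <- -1
  r1 <- to_ras(x$vol, lps)
  expect_equal(r1$data[1, 1, 1], x$vol[dim(x$vol)[1], dim(x$vol)[2], 1])
  r2 <- to_ras(r1$data, r1$affine)
  expect_identical(r2$data, r1$data)
  expect_equal(r2$affine, r1$affine)
  expect_error(to_ras(x$vol, matrix(0, 4, 4)), class = "fedbids_input_error")
})

test_that("to_ras preserves world coordinates of every voxel", {
  set.seed(5)
  dims <- c(9, 11, 13)
  vol <- array(rnorm(prod(dims)), dim = dims)
  # permuted + flipped orientation (axial swap with a flip)
  aff <- matrix(0, 4, 4)
  aff[1, 2] <- 1.2; aff[2, 1] <- -0.9; aff[3, 3] <- 1.1; aff[4, 4] <- 1
  aff[1:3, 4] <- c(3, -2, 5)
  r <- to_ras(vol, aff)
  # agreement against RNifti's orientation machinery as an independent oracle
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(1.2, 0.9, 1.1)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::orientation(img) <- "RAS"
  expect_equal(unclass(as.array(img)), r$data, ignore_attr = TRUE)
  for (i in 1:10) {
    new_idx <- vapply(dim(r$data), function(d) sample(d, 1), numeric(1))
    old_h <- solve(aff) %*% (r$affine %*% c(new_idx - 1, 1))
    old_idx <- round(old_h[1:3]) + 1
    expect_equal(r$data[new_idx[1], new_idx[2], new_idx[3]],
                 vol[old_idx[1], old_idx[2], old_idx[3]])
  }
})

test_that("resampling 140^3 at 1.0 mm gives 100^3 at 1.4 mm", {
  vol <- array(rnorm(140^3), dim = c(140, 140, 140))
  aff <- diag(c(1, 1, 1, 1))
  r <- resample_isotropic(vol, aff, 1.4)
  expect_equal(dim(r$data), c(100L, 100L, 100L))
  expect_equal(sqrt(colSums(r$affine[1:3, 1:3]^2)), rep(1.4, 3))
})

test_that("resampling at the native spacing is the identity", {
  x <- random_affine_vol(c(12, 14, 16), spacing = c(1.4, 1.4, 1.4))
  r <- resample_isotropic(x$vol, x$aff, 1.4)
  expect_equal(dim(r$data), dim(x$vol))
  expect_equal(r$data, x$vol, tolerance = 1e-6)
  expect_equal(r$affine, x$aff, tolerance = 1e-9)
})

test_that("interpolation preserves constant volumes", {
  vol <- array(3.7, dim = c(20, 22, 24))
  aff <- diag(c(0.9, 1.1, 1.3, 1))
  r <- resample_isotropic(vol, aff, 1.4)
  expect_true(all(abs(r$data - 3.7) < 1e-12))
})

test_that("crop_or_pad centres, pads trailing-heavy, and is idempotent", {
  big <- array(seq_len(40^3), dim = c(40, 40, 40))
  cp <- crop_or_pad(big, 30)
  expect_equal(dim(cp), c(30L, 30L, 30L))
  expect_identical(cp, big[6:35, 6:35, 6:35])

  small <- array(seq_len(10^3) + 0, dim = c(10, 10, 10))
  pd <- crop_or_pad(small, 16)
  expect_equal(dim(pd), c(16L, 16L, 16L))
  expect_identical(pd[4:13, 4:13, 4:13], small)
  expect_true(all(pd[1:3, , ] == 0) && all(pd[14:16, , ] == 0))

  # odd difference: the extra voxel goes to the trailing side
  odd <- array(1, dim = c(11, 11, 11))
  po <- crop_or_pad(odd, 14)
  expect_true(all(po[1, , ] == 0))           # 1 leading zero slab
  expect_true(all(po[13:14, , ] == 0))        # 2 trailing zero slabs
  co <- crop_or_pad(array(seq_len(11^3), dim = c(11, 11, 11)), 10)
  expect_identical(co, array(seq_len(11^3), dim = c(11, 11, 11))[1:10, 1:10, 1:10])

  same <- crop_or_pad(small, 10)
  expect_identical(same, small)
  expect_identical(crop_or_pad(crop_or_pad(big, 30), 30),
                   crop_or_pad(big, 30))
})

test_that("intensity normalisation modes behave as documented", {
  v <- array(rnorm(6^3, 10, 5), dim = c(6, 6, 6))
  mm <- normalize_intensity(v, "minmax")
  expect_equal(range(mm), c(0, 1))
  zs <- normalize_intensity(v, "zscore")
  expect_lt(abs(mean(zs)), 1e-6)
  expect_equal(sd(as.vector(zs)), 1)
  expect_identical(normalize_intensity(v, "none"), v)
  expect_error(normalize_intensity(array(1, dim = c(3, 3, 3)), "minmax"),
               class = "fedbids_input_error")
})

test_that("the pipeline emits the window shape whatever the input", {
  for (shape in list(c(36, 20, 28), c(16, 16, 16))) {
    cfg <- phantom_config(volume_shape = pmax(shape, 16))
    v <- phantom_volume(50, cfg, 1)
    f <- tempfile(fileext = ".nii.gz")
    write_volume(v$data, v$affine, f)
    out <- preprocess_pipeline(f, preprocess_config(target_spacing = 1.0,
                                                    window = 24L))
    expect_equal(dim(out), c(1L, 24L, 24L, 24L))
  }
})

test_that("the cache returns identical arrays without recomputation", {
  d <- make_phantom_dataset(n = 1, seed = 12)
  f <- d$records$image_paths[[1]][1]
  cdir <- tempfile("cache")
  cfg <- preprocess_config(target_spacing = 1.0, window = 32L,
                           cache_dir = cdir)
  a <- preprocess_pipeline(f, cfg)
  expect_length(list.files(cdir), 1)
  cached <- list.files(cdir, full.names = TRUE)
  mt0 <- file.mtime(cached)
  b <- preprocess_pipeline(f, cfg)
  expect_identical(a, b)
  expect_identical(file.mtime(cached), mt0)
  # a different configuration is a different cache entry
  c2 <- preprocess_pipeline(f, preprocess_config(target_spacing = 1.0,
                                                 window = 30L,
                                                 cache_dir = cdir))
  expect_length(list.files(cdir), 2)
})

test_that("external hooks run in order and failures carry the hook name", {
  d <- make_phantom_dataset(n = 1, seed = 13)
  f <- d$records$image_paths[[1]][1]
  # a hook that passes the image through untouched
  ok <- preprocess_config(target_spacing = 1.0, window = 32L,
                          external_hooks = list(skull_strip = "cp {in} {out}"))
  out <- preprocess_pipeline(f, ok)
  plain <- preprocess_pipeline(f, preprocess_config(target_spacing = 1.0,
                                                    window = 32L))
  expect_equal(out, plain, tolerance = 1e-6)
  bad <- preprocess_config(target_spacing = 1.0, window = 32L,
                           external_hooks = list(
                             bias_correct = "/no/such/tool {in} {out}"))
  err <- tryCatch(preprocess_pipeline(f, bad), error = identity)
  expect_s3_class(err, "fedbids_pipeline_error")
  expect_match(conditionMessage(err), "bias_correct")
  expect_error(preprocess_config(external_hooks = list(warp = "x")),
               class = "fedbids_input_error")
})
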