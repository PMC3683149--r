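test_that("phantom generation is deterministic with a contained brain", {
  p1 <- make_phantom(shape = c(48, 48, 48), seed = 3)
  p2 <- make_phantom(shape = c(48, 48, 48), seed = 3)
  expect_identical(p1$volume$data, p2$volume$data)
  p3 <- make_phantom(shape = c(48, 48, 48), seed = 4)
  expect_false(identical(p1$volume$data, p3$volume$data))

  # brain mask strictly inside the grid with >= 2-voxel background margin
  idx <- which(p1$brain_mask$data, arr.ind = TRUE)
  expect_true(all(idx >= 3))
  expect_true(all(t(idx) <= dim(p1$brain_mask$data) - 2))
  expect_gt(p1$mean_tissue, 0)
})

test_that("phantom similarity behaves sensibly under rotation", {
  ph <- small_phantom()
  fg <- foreground_mask(ph$volume)
  expect_equal(nmi(joint_histogram(ph$volume, ph$volume, fg)), 2.0)
  rot <- resample(ph$volume, rotation_transform(c(0, 0, 90)), ph$volume)
  expect_lt(nmi(joint_histogram(rot, ph$volume, fg)), 1.5)
})

test_that("lesions stay inside the brain and match sphere volume", {
  ph <- small_phantom()
  ctr <- colMeans(voxel_world_coords(ph$volume, ph$brain_mask))

  # radius 0: unchanged image, empty mask
  l0 <- add_lesion(ph$volume, ph$brain_mask, ctr, 0, 1.5, ph$mean_tissue)
  expect_identical(l0$volume$data, ph$volume$data)
  expect_identical(sum(l0$lesion_mask$data), 0L)

  # sphere fully inside the brain: voxel count within 5% of 4/3 pi r^3
  r <- 12
  l1 <- add_lesion(ph$volume, ph$brain_mask, ctr, r, 1.5, ph$mean_tissue)
  vox_vol <- prod(voxel_spacing(ph$volume))
  expected <- 4 / 3 * pi * r^3 / vox_vol
  expect_lt(abs(sum(l1$lesion_mask$data) - expected) / expected, 0.05)
  expect_true(all(l1$volume$data[l1$lesion_mask$data] ==
                    1.5 * ph$mean_tissue))

  # sphere reaching outside the brain: changed voxels strictly within it
  edge <- ctr + c(30, 0, 0)
  idx <- which(ph$brain_mask$data, arr.ind = TRUE) - 1
  w <- voxel_to_world(ph$volume, idx)
  edge <- w[which.max(w[, 1]), ] # brain voxel at the +x boundary
  l2 <- add_lesion(ph$volume, ph$brain_mask, edge, 15, 1.8,
                   ph$mean_tissue)
  expect_true(all(ph$brain_mask$data[l2$lesion_mask$data]))

  expect_error(add_lesion(ph$volume, ph$brain_mask, c(1000, 0, 0), 5, 1.5,
                          ph$mean_tissue), "inside the brain")
})

test_that("Rician noise follows its closed-form moments", {
  d <- c(24, 24, 24)
  v <- image_volume(array(0, d))
  v$data[1] <- 100 # pin the maximum so sigma = fraction * 100
  expect_identical(add_rician_noise(v, 0)$data, v$data)

  frac <- 0.05
  sigma <- frac * 100
  noisy <- add_rician_noise(v, frac, seed = 9)
  bg <- noisy$data[-1]
  # Rayleigh floor: mean sigma * sqrt(pi/2), sd sigma * sqrt(2 - pi/2)
  se <- sigma * sqrt(2 - pi / 2) / sqrt(length(bg))
  expect_lt(abs(mean(bg) - sigma * sqrt(pi / 2)), 3 * se)

  # high-SNR voxels: E[R] = x + sigma^2/(2x) - sigma^4/(8x^3) + O(x^-5)
  # (the Rician mean expansion; sqrt(x^2 + 2 sigma^2) is the root of the
  # second moment and overshoots the mean by sigma^2/(2x))
  vh <- image_volume(array(100, d))
  nh <- add_rician_noise(vh, frac, seed = 10)
  seh <- sigma / sqrt(length(nh$data))
  exact <- 100 + sigma^2 / 200 - sigma^4 / (8 * 100^3)
  expect_lt(abs(mean(nh$data) - exact), 3 * seh)
})

test_that("random 9-dof transforms sample their ranges uniformly", {
  t0 <- random_affine_9dof(0, 0, 0, seed = 1)
  expect_equal(t0$matrix, diag(4))

  set.seed(2)
  draws <- t(replicate(1000, {
    tr <- random_affine_9dof(7, 30, 0.025, center = c(0, 0, 0))
    s <- det(tr$matrix[1:3, 1:3])
    c(tr$matrix[1:3, 4], s)
  }))
  expect_true(all(abs(draws[, 1:3]) <= 7))
  # empirical translation means near 0 within 4 standard errors
  se <- 7 / sqrt(3) / sqrt(1000)
  expect_true(all(abs(colMeans(draws[, 1:3])) < 4 * se))
  # determinant equals the product of scales: within (1 +/- 0.025)^3
  expect_true(all(draws[, 4] > 0.975^3 - 1e-9 &
                    draws[, 4] < 1.025^3 + 1e-9))

  # determinism via explicit seed
  a <- random_affine_9dof(5, 10, 0.02, seed = 42)
  b <- random_affine_9dof(5, 10, 0.02, seed = 42)
  expect_identical(a$matrix, b$matrix)
})

test_that("cohorts honour their construction contracts", {
  cfg <- simulation_config(cohort_size = 3, shape = c(32, 32, 32),
                           seed = 5)
  va <- build_cohort("vA", cfg)
  expect_length(va$volumes, 3)
  # vA ground truth is the identity
  for (t in va$gt_transforms) expect_equal(t$matrix, diag(4))
  # lesion voxels never outside the brain
  for (lm in va$lesion_masks)
    expect_true(all(va$brain_mask$data[lm$data]))

  vp <- build_cohort("vP", cfg)
  expect_null(vp$lesions)
  for (t in vp$gt_transforms) expect_false(identical(t$matrix, diag(4)))

  vap <- build_cohort("vAP", cfg)
  # vAP volume i is the vA volume i resampled under the vP transform i
  i <- 2
  expected <- resample(va$volumes[[i]], vap$gt_transforms[[i]],
                       va$reference)
  expect_equal(vap$volumes[[i]]$data, expected$data, tolerance = 1e-10)
  # vAP transforms match the vP transforms at the same index
  expect_equal(vap$gt_transforms[[i]]$matrix, vp$gt_transforms[[i]]$matrix)

  # same seed: identical cohort
  va2 <- build_cohort("vA", cfg)
  expect_identical(va$volumes[[1]]$data, va2$volumes[[1]]$data)
})

test_that("distance to reference tracks lesion size and displacement", {
  cfg <- simulation_config(cohort_size = 12, shape = c(48, 48, 48),
                           seed = 8)
  va <- build_cohort("vA", cfg)
  roi <- foreground_mask(va$reference)
  d_va <- vapply(va$volumes, function(v)
    inverse_nmi_distance(v, va$reference, roi), numeric(1))
  radii <- va$lesions$radius[match(names(va$volumes), va$lesions$id)]
  expect_gt(cor(d_va, radii, method = "spearman"), 0.5)

  vp <- build_cohort("vP", cfg)
  d_vp <- vapply(vp$volumes, function(v)
    inverse_nmi_distance(v, vp$reference, roi), numeric(1))
  disp <- vapply(names(vp$volumes), function(id)
    rde(vp$gt_transforms[[id]], vp$brain_mask), numeric(1))
  expect_gt(cor(d_vp, disp, method = "spearman"), 0.5)
})

test_that("cohorts round-trip through disk", {
  cfg <- simulation_config(cohort_size = 2, shape = c(24, 24, 24),
                           seed = 13)
  co <- build_cohort("vA", cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  manifest <- readLines(file.path(dir, "manifest.txt"))
  expect_length(manifest, 2)
  v <- read_volume(manifest[1])
  expect_equal(v$data, co$volumes[[1]]$data, tolerance = 1e-5)
  expect_equal(v$affine, co$volumes[[1]]$affine, tolerance = 1e-5)
  t <- read_transform(file.path(dir, "img_01_gt.mat"))
  expect_equal(t$matrix, co$gt_transforms[[1]]$matrix, tolerance = 1e-12)
})
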