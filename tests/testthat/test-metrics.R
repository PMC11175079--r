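grid32 <- pixel_grid(32, 0.2)

img_at <- function(px_values) eit_image(px_values, grid32)

# binary image with ones at the given (row, col) pixels
mask_at <- function(...) {
  coords <- list(...)
  v <- numeric(grid32$M)
  for (rc in coords) {
    v[grid32$index[rc[1], rc[2]]] <- 1
  }
  eit_image(v, grid32)
}

test_that("relative error follows the norm-ratio definition", {
  set.seed(4)
  t_ <- img_at(rnorm(grid32$M))
  expect_equal(relative_error(t_, t_), 0)
  expect_equal(relative_error(img_at(numeric(grid32$M)), t_), 1)
  a <- numeric(grid32$M); a[1] <- 1
  b <- numeric(grid32$M); b[2] <- 1
  expect_equal(relative_error(img_at(b), img_at(a)), sqrt(2))
  expect_error(relative_error(t_, img_at(numeric(grid32$M))),
               class = "eitlf_error_zero_truth")
})

test_that("anomaly extraction applies the quarter-amplitude rule", {
  v <- numeric(grid32$M)
  blob <- grid32$index[15:17, 15:17]
  v[blob] <- 1
  v[grid32$index[5, 5]] <- 0.2 # below quarter amplitude
  m <- extract_anomaly_object(img_at(v))
  expect_setequal(which(as.numeric(m) == 1), as.integer(blob))
  expect_warning(m0 <- extract_anomaly_object(img_at(numeric(grid32$M))), "empty")
  expect_true(all(as.numeric(m0) == 0))
  # the mask can only cover nonzero pixels
  set.seed(8)
  v2 <- pmax(rnorm(grid32$M), 0)
  m2 <- extract_anomaly_object(img_at(v2))
  expect_true(all(v2[as.numeric(m2) == 1] > 0))
})

test_that("size error compares anomaly pixel counts", {
  t_ <- mask_at(c(10, 10), c(10, 11))
  expect_equal(size_error(t_, t_), 0)
  r4 <- mask_at(c(10, 10), c(10, 11), c(11, 10), c(11, 11))
  expect_equal(size_error(r4, t_), 1.0)
  expect_equal(size_error(img_at(numeric(grid32$M)), t_), 1.0)
  expect_error(size_error(t_, img_at(numeric(grid32$M))),
               class = "eitlf_error_empty_mask")
  # intensity rescaling of the underlying image cannot change SE
  v <- numeric(grid32$M); v[grid32$index[20, 20]] <- 2
  expect_equal(size_error(extract_anomaly_object(img_at(v)),
                          extract_anomaly_object(img_at(5 * v))), 0)
})

test_that("position error is the centroid distance, with a percent form", {
  a <- mask_at(c(10, 10))
  b <- mask_at(c(14, 13))    # rows differ by 4, cols by 3
  expect_equal(position_error(a, a), 0)
  expect_equal(position_error(a, b), 5)
  expect_equal(position_error(a, b, normalized = TRUE), 100 * 5 / 32)
  expect_error(position_error(a, img_at(numeric(grid32$M))),
               class = "eitlf_error_empty_mask")
})

test_that("position error obeys the triangle inequality", {
  a <- mask_at(c(8, 16)); b <- mask_at(c(20, 7)); c_ <- mask_at(c(13, 28))
  expect_lte(position_error(a, c_),
             position_error(a, b) + position_error(b, c_) + 1e-12)
})

test_that("metrics are invariant under a joint quarter-turn", {
  set.seed(6)
  v <- pmax(rnorm(grid32$M), 0)
  t_ <- pmax(rnorm(grid32$M), 0)
  rot_px <- vapply(seq_len(grid32$M), function(j) {
    tgt <- c(-grid32$centers[j, 2], grid32$centers[j, 1])
    which.min((grid32$centers[, 1] - tgt[1])^2 + (grid32$centers[, 2] - tgt[2])^2)
  }, integer(1))
  vr <- numeric(grid32$M); vr[rot_px] <- v
  tr <- numeric(grid32$M); tr[rot_px] <- t_
  expect_equal(relative_error(img_at(v), img_at(t_)),
               relative_error(img_at(vr), img_at(tr)))
  ma <- as.numeric(extract_anomaly_object(img_at(v)))
  mt <- as.numeric(extract_anomaly_object(img_at(t_)))
  mar <- numeric(grid32$M); mar[rot_px] <- ma
  mtr <- numeric(grid32$M); mtr[rot_px] <- mt
  expect_equal(size_error(img_at(mar), img_at(mtr)),
               size_error(img_at(ma), img_at(mt)))
  expect_equal(position_error(img_at(mar), img_at(mtr)),
               position_error(img_at(ma), img_at(mt)), tolerance = 1e-9)
})

test_that("evaluate_reconstruction uses the layer-2 component for layered results", {
  sys <- small_system()
  sim <- simulate_case(sys, 3)
  lam <- 1e-3 * sum(unclass(sys$S)^2) / ncol(sys$S)
  r <- run_lf(sim$dU, sys$S, reg_config(lambda = lam), p = sim$p_true)
  ev <- evaluate_reconstruction(r, sim$truth, sim$truth_anomaly)
  ev2 <- evaluate_reconstruction(r$image, sim$truth, sim$truth_anomaly,
                                 anomaly_component = r$layer2)
  expect_identical(ev$se, ev2$se)
  expect_identical(ev$pe_px, ev2$pe_px)
  expect_true(all(c("re", "se", "pe_px", "pe_pct") %in% names(ev)))
  expect_gte(ev$re, 0)
})
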