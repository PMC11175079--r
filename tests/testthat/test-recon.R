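test_that("tikhonov approaches the data in the identity limit and shrinks for large lambda", {
  set.seed(1)
  dU <- rnorm(8)
  x_small <- tikhonov(diag(8), dU, reg_config(lambda = 1e-12))
  expect_equal(as.numeric(x_small), dU, tolerance = 1e-9)
  lam <- 1e6
  x_big <- tikhonov(diag(8), dU, reg_config(lambda = lam))
  expect_lte(sqrt(sum(x_big^2)), sqrt(sum(dU^2)) / lam)
})

test_that("tikhonov matches a dense normal-equations solve", {
  for (seed in 1:5) {
    S <- rmat(12, 8, seed = seed)
    set.seed(seed + 100)
    dU <- rnorm(12)
    lam <- 0.05
    x <- tikhonov(S, dU, reg_config(lambda = lam))
    x_ref <- solve(t(S) %*% S + lam * diag(8), t(S) %*% dU)[, 1]
    expect_equal(as.numeric(x), x_ref, tolerance = 1e-8)
  }
})

test_that("tikhonov validates dimensions and conditioning", {
  expect_error(tikhonov(rmat(5, 3, 1), rnorm(4), reg_config(lambda = 1)),
               class = "eitlf_error_dimension")
  expect_error(reg_config(lambda = -1), "positive")
})

test_that("L-curve selection returns a candidate at the curvature corner", {
  # ill-posed system (geometric singular-value decay) with small noise:
  # the L-curve has a genuine corner near lambda ~ 2e-6, so with
  # over/under-regularizing extremes the middle candidate is selected
  set.seed(12)
  n <- 30; m <- 20
  U <- qr.Q(qr(matrix(rnorm(n * n), n)))[, 1:m]
  V <- qr.Q(qr(matrix(rnorm(m * m), m)))
  S <- U %*% diag(0.6^(0:(m - 1))) %*% t(V)
  dU <- S %*% rnorm(m) + 1e-3 * rnorm(n)
  expect_identical(select_lambda_lcurve(S, dU, c(1e-9, 1e-6, 10)), 1e-6)
  # the selected lambda is always one of the candidates
  cand2 <- 10^seq(-8, 1, length.out = 10)
  expect_true(select_lambda_lcurve(S, dU, cand2) %in% cand2)
  # all-equal candidates collapse to that value
  expect_identical(select_lambda_lcurve(S, dU, c(2, 2, 2)), 2)
  # a monotone, cornerless curve falls back to the median with a warning
  expect_warning(
    med <- select_lambda_lcurve(diag(3), c(1, 1, 1), c(0.1, 1, 10)),
    "corner")
  expect_identical(med, 1)
})

test_that("layer-1 extraction applies the quarter-amplitude rule", {
  expect_equal(extract_layer1(c(0.1, 0.2, 0.8, 1.0)), c(0, 0, 1, 1))
  expect_warning(out <- extract_layer1(c(0, 0, 0)), "empty")
  expect_equal(out, c(0, 0, 0))
  expect_equal(extract_layer1(c(-1.0, 0.3, 1.0)), c(0, 1, 1))
  expect_equal(extract_layer1(c(-1.0, 0.3, 1.0), polarity = "absolute"),
               c(1, 1, 1))
})

test_that("the scale operator averages the low-sensitivity range", {
  expect_equal(scale_operator(c(5, 5, 0.4, 0.2), c(1, 1, 0.2, 0.2)), 0.3)
  expect_equal(scale_operator(c(2, 2, 0.1, 0.1), c(2, 2, 0.1, 0.1)), 0.1)
  # uniform |dUa| leaves the set empty; falls back to all indices
  expect_warning(v <- scale_operator(c(1, 2, 3), c(1, 1, 1)), "low-sensitivity")
  expect_equal(v, 2)
})

test_that("layer-1 voltage reproduces an exactly representable layer", {
  pr_n <- 20
  S <- normalize_sensitivity(rmat(pr_n, 9, seed = 5, positive = TRUE))
  l1 <- c(1, 0, 1, 1, 0, 0, 1, 0, 1)
  dU <- 3.7 * as.numeric(unclass(S) %*% l1) # S l1 = dU / 3.7 exactly
  # the flat |dU| profile empties the low-sensitivity set; the fallback
  # (all indices) still recovers the exact scale
  suppressWarnings(out <- layer1_voltage(S, l1, dU))
  expect_equal(as.numeric(out$dU1), dU, tolerance = 1e-12)
  expect_equal(out$a, 3.7, tolerance = 1e-12)
})

test_that("layer-1 voltage matches a direct re-evaluation on random systems", {
  for (seed in 1:5) {
    S <- normalize_sensitivity(rmat(20, 9, seed = seed, positive = TRUE))
    set.seed(seed + 50)
    l1 <- as.numeric(runif(9) > 0.5)
    if (sum(l1) == 0) l1[1] <- 1
    dU <- rnorm(20)
    out <- layer1_voltage(S, l1, dU)
    # independent evaluation of the same definition
    idx <- which(abs(dU) < mean(abs(dU)) / 2)
    v <- as.numeric(unclass(S) %*% l1)
    a_ref <- mean(abs(dU[idx])) / mean(abs(v[idx]))
    expect_equal(out$a, a_ref, tolerance = 1e-12)
    expect_equal(as.numeric(out$dU1), a_ref * v, tolerance = 1e-12)
    # scale postcondition: both sides have equal low-sensitivity scale
    expect_equal(mean(abs(as.numeric(out$dU1)[idx])), mean(abs(dU[idx])),
                 tolerance = 1e-9)
  }
  expect_error(layer1_voltage(rmat(5, 3, 1), c(0, 0, 0), rnorm(5)), "at least one")
  expect_error(layer1_voltage(rmat(5, 3, 1), c(0.5, 0, 1), rnorm(5)), "binary")
})

test_that("layer voltages conserve the total change exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    dU <- rnorm(30)
    dU1 <- rnorm(30)
    expect_identical(layer2_voltage(dU, dU1), dU - dU1)
  }
  expect_equal(layer2_voltage(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(layer2_voltage(c(1, 2), c(0, 0)), c(1, 2))
})

test_that("the quarter-amplitude filter keeps magnitudes and zeroes the rest", {
  expect_equal(filter_flf(c(0.1, 0.3, 1.0)), c(0, 0.3, 1.0))
  expect_equal(filter_flf(c(0.5, 0.5, 0.5)), c(0.5, 0.5, 0.5))
  expect_equal(filter_flf(c(0, 0, 0)), c(0, 0, 0))
  set.seed(2)
  v <- rnorm(50)
  expect_lte(sum(filter_flf(v) != 0), sum(v != 0))
})

test_that("the proportional filter keeps exactly floor(p*M) pixels", {
  expect_equal(filter_plf(c(3, 1, 2, 0), 0.5), c(3, 0, 2, 0))
  expect_equal(filter_plf(c(3, 1, 2, 0), 0.999), c(3, 1, 2, 0))
  # ties at the cut keep the lowest pixel index
  expect_equal(filter_plf(c(2, 2, 2, 0), 0.5), c(2, 2, 0, 0))
  expect_error(filter_plf(c(1, 2, 3), 0.1),
               class = "eitlf_error_empty_selection")
  set.seed(9)
  v <- rnorm(101)
  for (p in c(0.1, 0.37, 0.8)) {
    expect_identical(sum(filter_plf(v, p) != 0), as.integer(floor(p * 101)))
  }
})

test_that("fusion weights invert the mean-change identity", {
  expect_equal(fusion_weights(c(1, 1, 1, 1), c(1, 1, 1, 1), n1 = 2, n2 = 1)$delta_sigma1, 2)
  for (seed in 1:5) {
    S <- normalize_sensitivity(rmat(20, 9, seed = seed, positive = TRUE))
    set.seed(seed + 10)
    alpha <- runif(1, 0.5, 2)
    w <- as.numeric(runif(9) > 0.4)
    if (sum(w) == 0) w[3] <- 1
    dU <- alpha * as.numeric(unclass(S) %*% w) # positive data: abs = signed
    rec <- fusion_weights(dU, dU, n1 = sum(w), n2 = sum(w))
    expect_equal(rec$delta_sigma1, alpha, tolerance = 1e-9)
    rec_s <- fusion_weights(dU, dU, n1 = sum(w), n2 = sum(w), mean_mode = "signed")
    expect_equal(rec_s$delta_sigma1, alpha, tolerance = 1e-9)
  }
  expect_error(fusion_weights(1:4, 1:4, n1 = 0, n2 = 1),
               class = "eitlf_error_weights")
})

test_that("layer fusion is linear and respects disjoint supports", {
  l1 <- c(1, 1, 0, 0)
  l2 <- c(0, 0, 0.5, 1)
  expect_equal(fuse_layers(l1, l2, 2, 0), 2 * l1)
  expect_equal(fuse_layers(l1, l2, 1, 1), l1 + l2)
  expect_equal(fuse_layers(l1, l2, 3 * 2, 3 * 5),
               3 * fuse_layers(l1, l2, 2, 5))
})

test_that("the full layered pipeline honours its contracts", {
  sys <- small_system()
  sim <- simulate_case(sys, 3)
  lam <- 1e-3 * sum(unclass(sys$S)^2) / ncol(sys$S)
  r_flf <- run_lf(sim$dU, sys$S, reg_config(lambda = lam))
  r_plf <- run_lf(sim$dU, sys$S, reg_config(lambda = lam), p = sim$p_true)

  # voltage conservation is exact in every run
  for (r in list(r_flf, r_plf)) {
    expect_identical(as.numeric(r$dU2), as.numeric(sim$dU) - as.numeric(r$dU1))
    expect_equal(as.numeric(r$dU1) + as.numeric(r$dU2), as.numeric(sim$dU),
                 tolerance = 1e-12)
    expect_true(all(as.numeric(r$layer1) %in% c(0, 1)))
    expect_identical(r$n1, sum(as.numeric(r$layer1)))
  }
  # PLF keeps exactly floor(p*M) layer-2 pixels
  expect_identical(sum(as.numeric(r_plf$layer2) != 0),
                   as.integer(floor(sim$p_true * sys$grid$M)))
  expect_identical(r_flf$method, "flf")
  expect_identical(r_plf$method, "plf")

  # a supplied contour bypasses step 2 exactly
  contour <- rasterize(sim$spec, sys$grid, "delta")
  contour <- eit_image(as.numeric(as.numeric(contour) > 0), sys$grid)
  r_ctr <- run_lf(sim$dU, sys$S, reg_config(lambda = lam), contour = contour)
  expect_equal(as.numeric(r_ctr$layer1), as.numeric(contour))
})

test_that("a two-phase scene leaves layer 2 with little energy", {
  sys <- small_system()
  spec <- phantom_spec(0.17, list(
    phantom_object(c(-0.094, 0), c(0.076, 0.116), 0.27),
    phantom_object(c(0.094, 0), c(0.076, 0.116), 0.27)))
  sim <- simulate_case(sys, spec)
  lam <- 1e-3 * sum(unclass(sys$S)^2) / ncol(sys$S)
  # signed weights on the column-normalized matrix (the idealized layered
  # model): with no anomaly the layer-2 residual has near-zero signed mean,
  # so the fused image is dominated by layer 1
  lam_n <- 1e-3 * sum(unclass(sys$S_norm)^2) / ncol(sys$S_norm)
  r_s <- run_lf(sim$dU, sys$S_norm, reg_config(lambda = lam_n),
                mean_mode = "signed")
  energy <- function(w, img) sqrt(sum((w * as.numeric(img))^2))
  expect_lt(energy(r_s$delta_sigma2, r_s$layer2),
            0.2 * energy(r_s$delta_sigma1, r_s$layer1))
  # absolute weights trade that suppression for sign stability, but layer 1
  # still dominates
  r_a <- run_lf(sim$dU, sys$S, reg_config(lambda = lam))
  expect_lt(energy(r_a$delta_sigma2, r_a$layer2),
            energy(r_a$delta_sigma1, r_a$layer1))
})

test_that("tidy and glance summarise layered results", {
  sys <- small_system()
  sim <- simulate_case(sys, 2)
  r <- run_lf(sim$dU, sys$S, reg_config(lambda = 1e-3 * sum(unclass(sys$S)^2) / ncol(sys$S)),
              p = sim$p_true)
  td <- tidy(r)
  expect_identical(nrow(td), sys$grid$M)
  expect_true(all(c("initial", "layer1", "layer2", "fused") %in% names(td)))
  gl <- glance(r)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$method, "plf")
  expect_identical(gl$p, sim$p_true)
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
  expect_s3_class(ggplot2::autoplot(r$image), "ggplot")
})
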