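test_that("rasterization handles empty, centered, and two-lung scenes", {
  g <- pixel_grid(32, 0.2)
  expect_true(all(as.numeric(rasterize(phantom_spec(0.17), g)) == 0))

  # centred circle of radius R/2: nonzero count matches the pixel count
  # whose centres fall inside the circle (area-fraction estimate +-5%)
  spec <- phantom_spec(0.17, list(
    phantom_object(c(0, 0), radius = 0.1, conductivity = 1.17)))
  img <- rasterize(spec, g)
  n_nonzero <- sum(as.numeric(img) != 0)
  expected <- pi * 16^2 / 4 * (g$M / (pi * 16^2))
  expect_lt(abs(n_nonzero - expected) / expected, 0.05)

  # two separated lungs form two 4-connected components
  lungs <- phantom_spec(0.17, list(
    phantom_object(c(-0.094, 0), c(0.076, 0.116), 0.27),
    phantom_object(c(0.094, 0), c(0.076, 0.116), 0.27)))
  mimg <- as.matrix(rasterize(lungs, g)) != 0
  lab <- label_components(mimg)
  expect_identical(max(lab), 2L)
})

test_that("objects crossing the domain boundary are rejected", {
  g <- pixel_grid(32, 0.2)
  spec <- phantom_spec(0.17, list(
    phantom_object(c(0.15, 0), radius = 0.1, conductivity = 0.5)))
  expect_error(rasterize(spec, g), class = "eitlf_error_geometry")
})

test_that("mesh painting applies the innermost-object rule", {
  m <- disk_mesh(0.2, n_rings = 8)
  expect_true(all(apply_phantom(phantom_spec(0.17), m)$sigma == 0.17))

  lung <- phantom_object(c(0.094, 0), c(0.076, 0.116), 0.27)
  an <- phantom_object(c(0.094, 0), radius = 0.03, conductivity = 0.6,
                       role = "anomaly")
  m1 <- apply_phantom(phantom_spec(0.17, list(lung, an)), m)
  m2 <- apply_phantom(phantom_spec(0.17, list(an, lung)), m)
  expect_identical(m1$sigma, m2$sigma) # listing order cannot matter
  expect_setequal(unique(m1$sigma), c(0.17, 0.27, 0.6))
  # anomaly elements sit inside the lung region
  inside_an <- (m$centroids[, 1] - 0.094)^2 + m$centroids[, 2]^2 < 0.025^2
  expect_true(all(m1$sigma[inside_an] == 0.6))
})

test_that("lung cases have two lungs, one contained anomaly, and the cited contrast", {
  for (cid in 1:6) {
    spec <- lung_case(cid)
    roles <- vapply(spec$objects, function(o) o$role, character(1))
    expect_identical(sum(roles == "object"), 2L)
    expect_identical(sum(roles == "anomaly"), 1L)
    sig <- vapply(spec$objects, function(o) o$conductivity, numeric(1))
    ratio <- sig[roles == "anomaly"] / unique(sig[roles == "object"])
    expect_gt(ratio, 1.6)
    expect_lt(ratio, 3.3)
  }
  expect_error(lung_case(7), class = "eitlf_error_case_id")
})

test_that("rasterized truth and painted mesh agree", {
  g <- pixel_grid(32, 0.2)
  mesh <- disk_mesh(0.2, n_rings = 24)
  W <- pixel_weights(mesh, g)
  # area-averaged reference: conductivity sampled on a 5x5 subgrid per pixel
  sub <- seq(-0.4, 0.4, length.out = 5) * g$pixel_size
  offs <- expand.grid(dx = sub, dy = sub)
  for (cid in c(1, 4)) {
    spec <- lung_case(cid)
    mesh_c <- apply_phantom(spec, mesh)
    # pixel-average the mesh conductivity through the overlap weights
    px_from_mesh <- as.numeric(Matrix::crossprod(W, mesh_c$sigma * mesh$areas) /
                                 Matrix::crossprod(W, mesh$areas))
    ref <- rowMeans(sapply(seq_len(nrow(offs)), function(k) {
      eitlf:::phantom_sigma_at(spec, g$centers[, 1] + offs$dx[k],
                               g$centers[, 2] + offs$dy[k])
    }))
    expect_gt(cor(px_from_mesh, ref), 0.99)
    # the point-sampled raster agrees slightly less tightly (partial-volume
    # pixels at the object edges)
    expect_gt(cor(px_from_mesh, as.numeric(rasterize(spec, g, "sigma"))), 0.97)
  }
})

test_that("noise is reproducible, disablable, and signal-independent", {
  fw <- small_forward()
  expect_identical(add_noise(fw$u0, noise_spec(NULL)), fw$u0)
  n1 <- add_noise(fw$u0, noise_spec(40, seed = 11))
  n2 <- add_noise(fw$u0, noise_spec(40, seed = 11))
  expect_identical(as.numeric(n1), as.numeric(n2))
  expect_false(identical(as.numeric(n1),
                         as.numeric(add_noise(fw$u0, noise_spec(40, seed = 12)))))
  # two frames of equal power receive identically distributed noise
  f1 <- new_frame2(rep(2e-3, 208), fw$pr)
  f2 <- new_frame2(c(rep(0, 207), sqrt(208) * 2e-3), fw$pr)
  e1 <- as.numeric(add_noise(f1, noise_spec(40, 5))) - as.numeric(f1)
  e2 <- as.numeric(add_noise(f2, noise_spec(40, 5))) - as.numeric(f2)
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("zero-power frames cannot receive finite-SNR noise", {
  fw <- small_forward()
  z <- new_frame2(rep(0, 208), fw$pr)
  expect_error(add_noise(z, noise_spec(40)), class = "eitlf_error_zero_power")
})

test_that("generated noise hits the nominal SNR on average", {
  fw <- small_forward()
  u <- as.numeric(fw$u0)
  pu <- mean(u^2)
  snrs <- vapply(seq_len(1000), function(s) {
    e <- as.numeric(add_noise(fw$u0, noise_spec(40, seed = s))) - u
    10 * log10(pu / mean(e^2))
  }, numeric(1))
  expect_lt(abs(mean(snrs) - 40), 0.5)
})

test_that("phantom JSON round-trips", {
  spec <- lung_case(3)
  path <- withr::local_tempfile(fileext = ".json")
  write_phantom_json(spec, path)
  spec2 <- read_phantom_json(path)
  expect_equal(spec2$background, spec$background)
  expect_equal(length(spec2$objects), length(spec$objects))
  g <- pixel_grid(32, 0.2)
  expect_equal(as.numeric(rasterize(spec2, g)), as.numeric(rasterize(spec, g)))
})
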