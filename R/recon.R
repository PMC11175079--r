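#' Regularization configuration
#'
#' @param lambda Regularization parameter (> 0), or `NULL` to use the default
#'   `1e-3 * trace(S'S) / M` when `mode = "fixed"`.
#' @param mode `"fixed"` or `"lcurve"` (pick `lambda` from `candidates` by
#'   the L-curve corner criterion before reconstructing).
#' @param candidates Candidate lambdas for `mode = "lcurve"`; defaults to a
#'   logarithmic grid scaled by `trace(S'S) / M` at solve time.
#' @param L Regularization matrix; `NULL` means the identity.
#' @return An object of class `reg_config`.
#' @export
reg_config <- function(lambda = NULL, mode = c("fixed", "lcurve"),
                       candidates = NULL, L = NULL) {
  mode <- match.arg(mode)
  if (!is.null(lambda) && lambda <= 0) abort("`lambda` must be positive.")
  structure(list(lambda = lambda, mode = mode, candidates = candidates, L = L),
            class = "reg_config")
}

default_lambda <- function(S) 1e-3 * sum(S^2) / ncol(S)

# resolve the lambda actually used for a given system
resolve_lambda <- function(S, dU, cfg) {
  if (!is.null(cfg$lambda)) return(cfg$lambda)
  if (cfg$mode == "lcurve") {
    cand <- cfg$candidates %||% (10^seq(-5, 1, length.out = 25) * sum(S^2) / ncol(S))
    select_lambda_lcurve(S, dU, cand, L = cfg$L)
  } else {
    default_lambda(S)
  }
}

#' One-step Tikhonov reconstruction
#'
#' Solves the linearized difference-imaging problem by the closed form
#' `(S'S + lambda L'L)^{-1} S' dU` with `L` the identity by default.
#'
#' @param S Sensitivity matrix (`eit_sensitivity` or plain `N x M` matrix).
#' @param dU Voltage-change frame (length N).
#' @param cfg A [reg_config()] or a bare numeric lambda.
#' @return The reconstructed pixel image: an `eit_image` when `S` carries a
#'   grid attribute, otherwise a plain numeric vector. The lambda used is
#'   attached as attribute `lambda`.
#' @examples
#' S <- matrix(rnorm(60), 12, 5)
#' x <- tikhonov(S, rnorm(12), reg_config(lambda = 0.1))
#' @export
tikhonov <- function(S, dU, cfg = reg_config()) {
  if (is.numeric(cfg) && length(cfg) == 1L) cfg <- reg_config(lambda = cfg)
  stopifnot(inherits(cfg, "reg_config"))
  dU <- as.numeric(dU)
  if (nrow(S) != length(dU)) {
    abort("S and dU have inconsistent dimensions.",
          class = "eitlf_error_dimension")
  }
  lambda <- resolve_lambda(S, dU, cfg)
  x <- tikhonov_solve(S, dU, lambda, cfg$L)
  g <- attr(S, "grid")
  out <- if (!is.null(g)) eit_image(x, g) else x
  attr(out, "lambda") <- lambda
  out
}

# Cholesky-factored Tikhonov solver: factor (S'S + lambda L'L) once and
# return a function of dU, so repeated solves (steps 1 and 5 of the layered
# pipeline, batch studies) reuse the factorization.
tik_solver <- function(S, lambda, L = NULL) {
  Sm <- unclass(S)
  A <- crossprod(Sm)
  P <- if (is.null(L)) diag(ncol(Sm)) else crossprod(L)
  A <- A + lambda * P
  R <- tryCatch(chol(A), error = function(e) {
    abort(sprintf(
      "normal equations not positive definite (condition estimate %.3g); increase lambda.",
      kappa(A)), class = "eitlf_error_conditioning")
  })
  Rt <- t(R)
  function(dU) {
    backsolve(R, forwardsolve(Rt, crossprod(Sm, as.numeric(dU))))[, 1L]
  }
}

tikhonov_solve <- function(S, dU, lambda, L = NULL) {
  tik_solver(S, lambda, L)(dU)
}

#' Select lambda by the L-curve corner
#'
#' Computes the Tikhonov solution for each candidate lambda, forms the
#' L-curve (log residual norm vs log solution norm), and returns the
#' candidate with the largest Menger curvature. A degenerate (monotone,
#' cornerless) curve falls back to the median candidate with a warning.
#'
#' @param S Sensitivity matrix.
#' @param dU Voltage-change frame.
#' @param candidates At least 3 positive lambdas, sorted increasing.
#' @param L Optional regularization matrix.
#' @return The selected lambda (always one of `candidates`).
#' @export
select_lambda_lcurve <- function(S, dU, candidates, L = NULL) {
  candidates <- as.numeric(candidates)
  if (length(candidates) < 3L) abort("need at least 3 candidate lambdas.")
  if (any(candidates <= 0)) abort("candidates must be positive.")
  if (is.unsorted(candidates)) abort("candidates must be sorted increasing.")
  if (max(candidates) - min(candidates) <= 0) return(candidates[1L])
  dU <- as.numeric(dU)
  pts <- vapply(candidates, function(lam) {
    x <- tikhonov_solve(S, dU, lam, L)
    c(log(sqrt(sum((unclass(S) %*% x - dU)^2)) + 1e-300),
      log(sqrt(sum(x^2)) + 1e-300))
  }, numeric(2))
  k <- length(candidates)
  curv <- rep(NA_real_, k)
  for (i in 2:(k - 1)) {
    curv[i] <- menger_curvature(pts[, i - 1L], pts[, i], pts[, i + 1L])
  }
  if (all(!is.finite(curv[2:(k - 1)])) || max(curv, na.rm = TRUE) <= 0) {
    warn("L-curve has no corner; falling back to the median candidate.")
    return(candidates[ceiling(k / 2)])
  }
  candidates[which.max(curv)]
}

# signed curvature of the circle through three points (positive = convex
# corner of the L-curve traversed from small to large lambda)
menger_curvature <- function(p1, p2, p3) {
  cross <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  d12 <- sqrt(sum((p2 - p1)^2)); d23 <- sqrt(sum((p3 - p2)^2))
  d13 <- sqrt(sum((p3 - p1)^2))
  if (d12 * d23 * d13 == 0) return(NA_real_)
  2 * cross / (d12 * d23 * d13)
}

#' Extract the main-object layer from a pre-image
#'
#' Thresholds a reconstruction at one quarter of its maximum amplitude: the
#' binary Layer-1 image contains every pixel at or above `max/4`. For
#' positive-contrast scenes (the usual lungs-in-thorax setting) the signed
#' values are thresholded; `polarity = "absolute"` thresholds magnitudes
#' instead.
#'
#' @param dsigma Pixel image (`eit_image` or numeric).
#' @param polarity `"signed"` (default) or `"absolute"`.
#' @return A binary image of the same class as the input.
#' @export
extract_layer1 <- function(dsigma, polarity = c("signed", "absolute")) {
  polarity <- match.arg(polarity)
  v <- as.numeric(dsigma)
  if (polarity == "absolute") v <- abs(v)
  mx <- max(v)
  out <- if (all(v == 0)) {
    warn("all-zero pre-image: Layer 1 is empty.")
    v
  } else {
    as.numeric(v >= mx / 4)
  }
  rebuild_like(out, dsigma)
}

rebuild_like <- function(values, template) {
  g <- attr(template, "grid")
  if (!is.null(g)) eit_image(values, g) else values
}

#' Low-sensitivity scale operator
#'
#' Measures the scale of a voltage-change set over the low-sensitivity range
#' of a reference change: the index set where `|dUa|` falls below half its
#' mean absolute value, i.e. the measurements least affected by small local
#' conductivity changes. Returns the mean absolute value of `dUb` over that
#' set. An empty set (e.g. `|dUa|` constant) falls back to all indices with
#' a warning.
#'
#' @param dUb Observed voltage-change set (numeric).
#' @param dUa Reference voltage-change set defining the low-sensitivity
#'   index set (numeric, same length).
#' @return A scalar (volts).
#' @examples
#' scale_operator(c(5, 5, 0.4, 0.2), c(1, 1, 0.2, 0.2)) # 0.3
#' @export
scale_operator <- function(dUb, dUa) {
  dUb <- as.numeric(dUb); dUa <- as.numeric(dUa)
  if (length(dUb) != length(dUa)) abort("dUb and dUa must have equal length.")
  mean(abs(dUb)[low_sensitivity_set(dUa)])
}

low_sensitivity_set <- function(dUa) {
  idx <- which(abs(dUa) < mean(abs(dUa)) / 2)
  if (length(idx) == 0L) {
    warn("empty low-sensitivity set; using all measurements.")
    idx <- seq_along(dUa)
  }
  idx
}

#' Estimate the Layer-1 voltage change and its scale factor
#'
#' The binary Layer-1 image is only known up to an unknown conductivity
#' scale `a`. Because small local anomalies barely move the low-sensitivity
#' measurements, the scale of the total change and of the Layer-1 prediction
#' must agree there, giving `a = L(dU, dU) / L(S l1, dU)` and
#' `dU1 = a * S %*% l1`. Both scale evaluations use the low-sensitivity
#' index set induced by the total change `dU`.
#'
#' @param S Sensitivity matrix (column-normalized in the layered pipeline).
#' @param layer1 Binary Layer-1 image, not all zero.
#' @param dU Total voltage-change frame.
#' @return A list with `dU1` (same class as `dU`) and the scalar `a`.
#' @export
layer1_voltage <- function(S, layer1, dU) {
  l1 <- as.numeric(layer1)
  if (!all(l1 %in% c(0, 1))) abort("`layer1` must be binary.")
  if (sum(l1) == 0) abort("`layer1` must contain at least one pixel.")
  v <- as.numeric(unclass(S) %*% l1)
  idx <- low_sensitivity_set(as.numeric(dU))
  denom <- mean(abs(v)[idx])
  if (denom <= 1e-14 * (mean(abs(v)) + 1e-300)) {
    abort("Layer-1 scale undefined: predicted change vanishes on the low-sensitivity set.",
          class = "eitlf_error_scale")
  }
  a <- mean(abs(as.numeric(dU))[idx]) / denom
  dU1 <- a * v
  if (inherits(dU, "eit_frame")) {
    dU1 <- new_frame(dU1, attr(dU, "protocol"), role = "difference")
  }
  list(dU1 = dU1, a = a)
}

#' Layer-2 voltage change
#'
#' The anomaly layer's voltage contribution is what remains of the total
#' change after removing the Layer-1 estimate: `dU2 = dU - dU1`, exactly.
#'
#' @param dU Total voltage-change frame.
#' @param dU1 Layer-1 voltage change.
#' @return `dU - dU1`, same class as `dU`.
#' @export
layer2_voltage <- function(dU, dU1) {
  if (length(dU) != length(dU1)) abort("frames must have equal length.")
  out <- as.numeric(dU) - as.numeric(dU1)
  if (inherits(dU, "eit_frame")) {
    out <- new_frame(out, attr(dU, "protocol"), role = "difference")
  }
  out
}

#' Quarter-amplitude filter (filter-based variant)
#'
#' Zeroes every pixel below one quarter of the image maximum; surviving
#' pixels keep their values. Used to sharpen the Layer-2 reconstruction when
#' no anomaly-area prior is available.
#'
#' @param dsigma2 Pixel image.
#' @return Filtered image, same class as the input.
#' @export
filter_flf <- function(dsigma2) {
  v <- as.numeric(dsigma2)
  if (!all(v == 0)) v[v < max(v) / 4] <- 0
  rebuild_like(v, dsigma2)
}

#' Proportional filter (prior-based variant)
#'
#' Keeps the `t = floor(p * M)` largest pixel values (the anomaly is assumed
#' to occupy a known fraction `p` of the image) and zeroes the rest. Ties at
#' the cut-off keep the lowest pixel index.
#'
#' @param dsigma2 Pixel image of length M.
#' @param p Anomaly area proportion, in (0, 1) and large enough that
#'   `floor(p * M) >= 1`.
#' @return Filtered image, same class as the input.
#' @export
filter_plf <- function(dsigma2, p) {
  v <- as.numeric(dsigma2)
  M <- length(v)
  if (p <= 0 || p >= 1) abort("`p` must be in (0, 1).")
  t_keep <- floor(p * M)
  if (t_keep < 1L) {
    abort("`p` selects no pixels (floor(p*M) = 0).",
          class = "eitlf_error_empty_selection")
  }
  ord <- order(-v, seq_along(v))
  out <- numeric(M)
  keep <- ord[seq_len(t_keep)]
  out[keep] <- v[keep]
  rebuild_like(out, dsigma2)
}

#' Fusion weights from layer voltage changes
#'
#' With a column-normalized sensitivity matrix, a uniform conductivity
#' change `alpha` over `n` working pixels produces a voltage change of mean
#' `alpha * n / N`. Inverting this for each layer gives the fusion weights
#' `delta_sigma = N * mean(dU_layer) / n_layer`.
#'
#' @param dU1,dU2 Layer voltage-change frames (length N).
#' @param n1,n2 Working-pixel counts of the two layers (>= 1).
#' @param N Number of measurements; defaults to `length(dU1)`.
#' @param mean_mode `"absolute"` (default) uses the mean of absolute
#'   values, `"signed"` the plain arithmetic mean. Under the idealized
#'   layered model (all-positive uniform change, unit column sums) the two
#'   coincide; on real data the signed mean of the small layer-2 residual
#'   is unstable in sign, so the absolute mean is the robust default.
#' @return A list with `delta_sigma1` and `delta_sigma2`.
#' @export
fusion_weights <- function(dU1, dU2, n1, n2, N = length(dU1),
                           mean_mode = c("absolute", "signed")) {
  mean_mode <- match.arg(mean_mode)
  if (n1 < 1 || n2 < 1) {
    abort("working-pixel counts must be at least 1.",
          class = "eitlf_error_weights")
  }
  mfun <- if (mean_mode == "signed") {
    function(z) mean(as.numeric(z))
  } else {
    function(z) mean(abs(as.numeric(z)))
  }
  list(delta_sigma1 = N * mfun(dU1) / n1,
       delta_sigma2 = N * mfun(dU2) / n2)
}

#' Fuse the layer images
#'
#' @param layer1 Binary Layer-1 image.
#' @param layer2 Filtered (and normalized) Layer-2 image.
#' @param delta_sigma1,delta_sigma2 Fusion weights.
#' @return `delta_sigma1 * layer1 + delta_sigma2 * layer2`.
#' @export
fuse_layers <- function(layer1, layer2, delta_sigma1, delta_sigma2) {
  if (length(layer1) != length(layer2)) abort("layers must share the grid.")
  rebuild_like(delta_sigma1 * as.numeric(layer1) +
                 delta_sigma2 * as.numeric(layer2), layer1)
}

#' Layered fusion reconstruction
#'
#' Runs the full layered fusion pipeline for multi-conductivity difference
#' imaging: (1) a one-step Tikhonov pre-image, (2) quarter-amplitude
#' extraction of the binary main-object layer (or a user-supplied contour),
#' (3) estimation of the Layer-1 voltage change via the low-sensitivity
#' scale factor, (4) subtraction to get the Layer-2 voltage change, (5)
#' Tikhonov reconstruction of Layer 2 sharpened by the proportional filter
#' when the anomaly-area prior `p` is given (PLF) or the quarter-amplitude
#' filter otherwise (FLF), and (6) fusion of the layers with weights derived
#' from the layer voltage means.
#'
#' @param dU Voltage-change frame (length N).
#' @param S Sensitivity matrix, used as given for every step: pass the raw
#'   (physical) Jacobian for voltage-faithful layer modelling, or a
#'   column-normalized matrix for the idealized layered model under which
#'   the fusion-weight identity is exact.
#' @param cfg A [reg_config()]; one lambda is resolved once and shared by
#'   steps 1 and 5.
#' @param p Optional anomaly area proportion in (0, 1); selects the PLF
#'   variant.
#' @param contour Optional known binary Layer-1 image that bypasses step 2.
#' @param polarity Passed to [extract_layer1()].
#' @param mean_mode Passed to [fusion_weights()].
#' @return An object of class `lf_result` holding the fused image (`image`),
#'   all intermediates (`initial`, `layer1`, `layer2`, `layer2_raw`, `dU1`,
#'   `dU2`), the scale factor `a`, weights `delta_sigma1`/`delta_sigma2`,
#'   counts `n1`/`n2`, the `lambda` used and the `method` label
#'   (`"flf"`/`"plf"`).
#' @export
run_lf <- function(dU, S, cfg = reg_config(), p = NULL, contour = NULL,
                   polarity = c("signed", "absolute"),
                   mean_mode = c("absolute", "signed")) {
  polarity <- match.arg(polarity)
  mean_mode <- match.arg(mean_mode)
  if (is.numeric(cfg) && length(cfg) == 1L) cfg <- reg_config(lambda = cfg)
  Sn <- S
  if (nrow(Sn) != length(dU)) {
    abort("S and dU have inconsistent dimensions.",
          class = "eitlf_error_dimension")
  }
  step <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("layered fusion failed at %s: %s", label,
                    conditionMessage(e)),
            class = "eitlf_error_step", parent = e)
    })
  }
  lambda <- resolve_lambda(Sn, dU, cfg)
  solver <- step("factorization", tik_solver(Sn, lambda, cfg$L))
  g <- attr(Sn, "grid")
  as_img <- function(x) if (!is.null(g)) eit_image(x, g) else x

  initial <- step("step 1 (pre-image)", as_img(solver(dU)))
  layer1 <- if (!is.null(contour)) {
    if (!all(as.numeric(contour) %in% c(0, 1))) {
      abort("`contour` must be a binary image.")
    }
    rebuild_like(as.numeric(contour), initial)
  } else {
    step("step 2 (layer-1 extraction)", extract_layer1(initial, polarity))
  }
  n1 <- sum(as.numeric(layer1))
  l1v <- step("step 3 (layer-1 voltage)", layer1_voltage(Sn, layer1, dU))
  dU2 <- step("step 4 (layer-2 voltage)", layer2_voltage(dU, l1v$dU1))
  ds2 <- step("step 5 (layer-2 image)", as_img(solver(dU2)))
  ds2f <- step("step 5 (filter)",
               if (!is.null(p)) filter_plf(ds2, p) else filter_flf(ds2))
  # max-normalize the filtered layer before counting working pixels
  mx <- max(as.numeric(ds2f))
  ds2n <- if (mx > 0) rebuild_like(as.numeric(ds2f) / mx, ds2f) else ds2f
  n2 <- max(1, ceiling(sum(as.numeric(ds2n))))
  w <- step("step 6 (weights)",
            fusion_weights(l1v$dU1, dU2, n1, n2, N = length(dU),
                           mean_mode = mean_mode))
  fused <- step("step 6 (fusion)",
                fuse_layers(layer1, ds2n, w$delta_sigma1, w$delta_sigma2))
  structure(
    list(image = fused, initial = initial, layer1 = layer1,
         layer2 = ds2n, layer2_raw = ds2, dU1 = l1v$dU1, dU2 = dU2,
         a = l1v$a, delta_sigma1 = w$delta_sigma1,
         delta_sigma2 = w$delta_sigma2, n1 = n1, n2 = n2,
         lambda = lambda, method = if (!is.null(p)) "plf" else "flf",
         p = p),
    class = "lf_result"
  )
}

#' @export
print.lf_result <- function(x, ...) {
  cat(sprintf(
    "<lf_result %s> a = %.4g, weights (%.4g, %.4g), n1 = %d, n2 = %d, lambda = %.3g\n",
    toupper(x$method), x$a, x$delta_sigma1, x$delta_sigma2,
    as.integer(x$n1), as.integer(x$n2), x$lambda))
  invisible(x)
}
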