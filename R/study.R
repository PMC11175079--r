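#' Configuration of a simulation study
#'
#' Collects every tunable parameter of the lung-anomaly simulation study in
#' one named list, with the standard setup as defaults: 16 electrodes of
#' 1 cm width on a 20 cm radius circular domain, 5 mA adjacent drive, 32x32
#' pixel images, lung/anomaly conductivities 0.27 / 0.6 S/m, and noise
#' levels 30-80 dB SNR.
#'
#' @param n_electrodes Electrode count.
#' @param radius Domain radius (m).
#' @param electrode_width Electrode arc width (m).
#' @param contact_impedance Contact impedance (Ohm m^2).
#' @param current Drive current (A).
#' @param n_rings Mesh density for the forward/sensitivity mesh.
#' @param image_size Pixel image side length.
#' @param background,lung,anomaly Conductivities (S/m).
#' @param geometry Phantom geometry, see [lung_geometry()].
#' @param cases Case ids to run (subset of 1..6).
#' @param snr_db Noise levels in dB; `NULL` entries mean noise-free.
#' @param seeds Integer seeds, one run per seed at each case x SNR.
#' @param methods Reconstruction methods: subset of "tk", "flf", "plf".
#' @param lambda Fixed regularization parameter, or `NULL` to select it once
#'   by the L-curve on the first noise-free case.
#' @param use_true_p If `TRUE` (default) the PLF prior `p` is the true
#'   anomaly proportion collected from each phantom.
#' @return A named list of class `study_config`.
#' @export
study_config <- function(n_electrodes = 16L, radius = 0.20,
                         electrode_width = 0.01, contact_impedance = 1e-5,
                         current = 5e-3, n_rings = 24L, image_size = 32L,
                         background = 0.17, lung = 0.27, anomaly = 0.6,
                         geometry = lung_geometry(), cases = 1:6,
                         snr_db = c(30, 40, 50, 60, 70, 80),
                         seeds = 1L, methods = c("tk", "flf", "plf"),
                         lambda = NULL, use_true_p = TRUE) {
  stopifnot(all(cases %in% 1:6), length(seeds) >= 1L)
  methods <- match.arg(methods, c("tk", "flf", "plf"), several.ok = TRUE)
  structure(
    list(n_electrodes = as.integer(n_electrodes), radius = radius,
         electrode_width = electrode_width,
         contact_impedance = contact_impedance, current = current,
         n_rings = as.integer(n_rings), image_size = as.integer(image_size),
         background = background, lung = lung, anomaly = anomaly,
         geometry = geometry, cases = as.integer(cases), snr_db = snr_db,
         seeds = as.integer(seeds), methods = methods, lambda = lambda,
         use_true_p = use_true_p),
    class = "study_config"
  )
}

#' Assemble the shared study system
#'
#' Builds everything the study reuses across cases: electrode array,
#' protocol, mesh at the reference (background) conductivity, pixel grid,
#' element-to-pixel weights, the reference frame, and the raw and
#' column-normalized sensitivity matrices at the reference state.
#'
#' @param config A [study_config()].
#' @return A list of class `study_system`.
#' @export
study_system <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  el <- electrode_array(config$n_electrodes, config$radius,
                        config$electrode_width, config$contact_impedance)
  pr <- adjacent_protocol(el, config$current)
  grid <- pixel_grid(config$image_size, config$radius)
  mesh <- disk_mesh(config$radius, config$n_rings, sigma = config$background)
  W <- pixel_weights(mesh, grid)
  S <- compute_sensitivity(mesh, el, pr, grid, weights = W)
  structure(
    list(config = config, electrodes = el, protocol = pr, grid = grid,
         mesh = mesh, weights = W, S = S,
         S_norm = normalize_sensitivity(S),
         U0 = solve_forward(mesh, el, pr)),
    class = "study_system"
  )
}

#' Simulate one phantom case
#'
#' Solves the forward problem for a lung case, forms the voltage-change
#' frame against the homogeneous reference, optionally adds noise, and
#' collects the ground truth.
#'
#' @param sys A [study_system()].
#' @param case_id Case id (1..6) or a [phantom_spec()].
#' @param snr_db SNR in dB or `NULL` for noise-free data.
#' @param seed Noise seed.
#' @return A list with the phantom `spec`, clean and noisy voltage changes
#'   (`dU_clean`, `dU`), ground-truth images (`truth`, `truth_anomaly`) and
#'   the true anomaly proportion `p_true`.
#' @export
simulate_case <- function(sys, case_id, snr_db = NULL, seed = 1L) {
  stopifnot(inherits(sys, "study_system"))
  cfg <- sys$config
  spec <- if (inherits(case_id, "phantom_spec")) case_id else {
    lung_case(case_id, radius = cfg$radius, background = cfg$background,
              lung = cfg$lung, anomaly = cfg$anomaly,
              geometry = cfg$geometry)
  }
  mesh_c <- apply_phantom(spec, sys$mesh)
  u <- solve_forward(mesh_c, sys$electrodes, sys$protocol)
  dU_clean <- new_frame(as.numeric(u) - as.numeric(sys$U0), sys$protocol,
                        role = "difference")
  dU <- add_noise(dU_clean, noise_spec(snr_db, seed))
  truth <- rasterize(spec, sys$grid, "delta")
  truth_anomaly <- rasterize(spec, sys$grid, "anomaly")
  list(spec = spec, dU_clean = dU_clean, dU = dU, truth = truth,
       truth_anomaly = truth_anomaly,
       p_true = sum(as.numeric(truth_anomaly)) / sys$grid$M)
}

# Resolve the study-wide lambdas, one per sensitivity matrix, selected in
# advance by the L-curve on the first requested case (noise-free) and then
# used uniformly: `tk` for the column-normalized baseline, `lf` for the
# layered chain on the raw Jacobian. A fixed config$lambda is interpreted
# as a dimensionless scale on 1e-3 * trace(S'S)/M for each matrix.
study_lambda <- function(sys, cases = sys$config$cases) {
  scale_of <- function(S) 1e-3 * sum(S^2) / ncol(S)
  if (!is.null(sys$config$lambda)) {
    # a user-fixed lambda refers to the normalized system; carry it to the
    # raw system through the trace ratio so both are equally regularized
    return(list(tk = sys$config$lambda,
                lf = sys$config$lambda * scale_of(unclass(sys$S)) /
                  scale_of(sys$S_norm)))
  }
  sim <- simulate_case(sys, cases[1L])
  pick <- function(S) {
    cand <- 10^seq(-5, 1, length.out = 25) * sum(S^2) / ncol(S)
    select_lambda_lcurve(S, sim$dU, cand)
  }
  list(tk = pick(sys$S_norm), lf = pick(unclass(sys$S)))
}

#' Reconstruct one frame with the study methods
#'
#' @param sys A [study_system()].
#' @param dU Voltage-change frame.
#' @param lambda A list with elements `tk` (lambda for the normalized
#'   one-step baseline) and `lf` (lambda for the layered chain on the raw
#'   Jacobian), as returned by the internal study selector; a single number
#'   is used for both.
#' @param methods Subset of `"tk"`, `"flf"`, `"plf"`.
#' @param p Anomaly-area prior for PLF (required if "plf" requested).
#' @return A named list: for `"tk"` an `eit_image`, for the layered methods
#'   the full `lf_result`.
#' @export
reconstruct_frame <- function(sys, dU, lambda, methods = c("tk", "flf", "plf"),
                              p = NULL) {
  methods <- match.arg(methods, c("tk", "flf", "plf"), several.ok = TRUE)
  if (!is.list(lambda)) lambda <- list(tk = lambda, lf = lambda)
  out <- list()
  if ("tk" %in% methods) {
    out$tk <- tikhonov(sys$S_norm, dU, reg_config(lambda = lambda$tk))
  }
  if ("flf" %in% methods) {
    out$flf <- run_lf(dU, sys$S, reg_config(lambda = lambda$lf))
  }
  if ("plf" %in% methods) {
    if (is.null(p)) {
      abort("PLF requires the anomaly-area proportion `p`.",
            class = "eitlf_error_missing_p")
    }
    out$plf <- run_lf(dU, sys$S, reg_config(lambda = lambda$lf), p = p)
  }
  out
}

method_image <- function(res) if (inherits(res, "lf_result")) res$image else res

#' Run the full simulation study
#'
#' For every case x noise level x seed x method, simulates the data,
#' reconstructs, and evaluates the image quality metrics. This reproduces
#' the structure of the simulation comparison: one-step Tikhonov (TK)
#' against the layered fusion variants (FLF without prior, PLF with the
#' true anomaly proportion).
#'
#' @param config A [study_config()].
#' @param sys Optional prebuilt [study_system()] (rebuilt from `config`
#'   otherwise).
#' @param keep_images If `TRUE`, attach the reconstructed images as a
#'   list-column.
#' @return A tibble with columns `case`, `snr_db` (NA = noise-free), `seed`,
#'   `method`, the metrics `re`, `se`, `pe_px`, `pe_pct`, mask sizes, and
#'   the lambda used.
#' @export
run_study <- function(config = study_config(), sys = NULL,
                      keep_images = FALSE) {
  sys <- sys %||% study_system(config)
  cfg <- config
  lambda <- study_lambda(sys)
  noise_levels <- c(list(NULL), as.list(cfg$snr_db))
  rows <- list()
  for (case_id in cfg$cases) {
    sim0 <- simulate_case(sys, case_id)
    for (nl in noise_levels) {
      seeds <- if (is.null(nl)) cfg$seeds[1L] else cfg$seeds
      for (seed in seeds) {
        sim <- sim0
        sim$dU <- add_noise(sim0$dU_clean, noise_spec(nl, seed))
        p <- if (cfg$use_true_p) sim$p_true else NULL
        recs <- reconstruct_frame(sys, sim$dU, lambda,
                                  methods = cfg$methods, p = p)
        for (meth in names(recs)) {
          ev <- evaluate_reconstruction(recs[[meth]],
                                        sim$truth, sim$truth_anomaly)
          row <- dplyr::bind_cols(
            tibble(case = case_id,
                   snr_db = if (is.null(nl)) NA_real_ else nl,
                   seed = seed, method = meth),
            ev,
            tibble(lambda_tk = lambda$tk, lambda_lf = lambda$lf)
          )
          if (keep_images) row$image <- list(method_image(recs[[meth]]))
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Summarise a study table per method and noise level
#'
#' @param results Tibble from [run_study()].
#' @return Means of the metrics over cases and seeds, grouped by method and
#'   SNR.
#' @export
summarise_study <- function(results) {
  results |>
    dplyr::group_by(.data$method, .data$snr_db) |>
    dplyr::summarise(re = mean(.data$re), se = mean(.data$se),
                     pe_px = mean(.data$pe_px), pe_pct = mean(.data$pe_pct),
                     n = dplyr::n(), .groups = "drop")
}
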