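#' Write a measurement frame to CSV
#'
#' One row per measurement with the injection and measurement electrode
#' pairs and the voltage, so a frame file is self-describing.
#'
#' @param frame An `eit_frame`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_frame_csv <- function(frame, path) {
  stopifnot(inherits(frame, "eit_frame"))
  df <- as.data.frame(as_tibble(frame))
  df$injection_pair <- paste0(df$inj_a, "-", df$inj_b)
  df$measurement_pair <- paste0(df$meas_a, "-", df$meas_b)
  write.csv(df[, c("index", "injection_pair", "measurement_pair", "volts")],
            path, row.names = FALSE)
  invisible(path)
}

#' Read a measurement frame from CSV
#'
#' @param path File written by [write_frame_csv()].
#' @param protocol The `eit_protocol` the frame belongs to.
#' @param role Frame role.
#' @return An `eit_frame`.
#' @export
read_frame_csv <- function(path, protocol,
                           role = c("difference", "reference", "measured")) {
  df <- read.csv(path)
  new_frame(df$volts[order(df$index)], protocol, role = match.arg(role))
}

#' Write a pixel image as a CSV matrix
#'
#' @param image An `eit_image`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_image_csv <- function(image, path) {
  utils::write.table(as.matrix(image), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a pixel image from a CSV matrix
#'
#' @param path File written by [write_image_csv()].
#' @param grid The matching [pixel_grid()].
#' @return An `eit_image`.
#' @export
read_image_csv <- function(path, grid) {
  m <- as.matrix(read.csv(path, header = FALSE))
  if (!all(dim(m) == c(grid$n, grid$n))) {
    abort("image file dimensions do not match the grid.")
  }
  eit_image(m[cbind(grid$rows, grid$cols)], grid)
}

#' Serialize a phantom specification to JSON
#'
#' @param spec A [phantom_spec()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_phantom_json <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  payload <- list(
    background = spec$background,
    label = spec$label,
    objects = lapply(spec$objects, function(o) {
      list(center = o$center, semi_axes = o$semi_axes,
           conductivity = o$conductivity, role = o$role)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom specification from JSON
#'
#' @param path File written by [write_phantom_json()].
#' @return A [phantom_spec()].
#' @export
read_phantom_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  objs <- lapply(p$objects, function(o) {
    phantom_object(unlist(o$center), unlist(o$semi_axes),
                   o$conductivity, role = o$role)
  })
  phantom_spec(p$background, objs, label = p$label)
}

#' Simulate study data to disk
#'
#' For every requested case and noise setting (noise-free plus each SNR),
#' writes the reference frame, the measured voltage-change frame, the
#' ground-truth images, and the phantom description; the sensitivity matrix
#' and support mask are written once. File layout (under `out_dir`):
#' `sensitivity.csv`, `mask.csv`, `reference.csv`, and per case/noise
#' `case<k>_snr<db|free>_seed<s>_dU.csv`, plus per case
#' `case<k>_truth.csv`, `case<k>_anomaly.csv`, `case<k>_phantom.json`.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @param sys Optional prebuilt [study_system()].
#' @return Invisibly, a tibble listing the written measurement files.
#' @export
cmd_simulate <- function(config = study_config(), out_dir, sys = NULL) {
  sys <- sys %||% study_system(config)
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(unclass(sys$S), file.path(out_dir, "sensitivity.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(1 * sys$grid$mask, file.path(out_dir, "mask.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  write_frame_csv(sys$U0, file.path(out_dir, "reference.csv"))
  rows <- list()
  noise_levels <- c(list(NULL), as.list(cfg$snr_db))
  for (case_id in cfg$cases) {
    sim0 <- simulate_case(sys, case_id)
    write_image_csv(sim0$truth, file.path(out_dir, sprintf("case%d_truth.csv", case_id)))
    write_image_csv(sim0$truth_anomaly,
                    file.path(out_dir, sprintf("case%d_anomaly.csv", case_id)))
    write_phantom_json(sim0$spec,
                       file.path(out_dir, sprintf("case%d_phantom.json", case_id)))
    for (nl in noise_levels) {
      seeds <- if (is.null(nl)) cfg$seeds[1L] else cfg$seeds
      for (seed in seeds) {
        dU <- add_noise(sim0$dU_clean, noise_spec(nl, seed))
        tag <- if (is.null(nl)) "free" else sprintf("%g", nl)
        f <- file.path(out_dir, sprintf("case%d_snr%s_seed%d_dU.csv",
                                        case_id, tag, seed))
        write_frame_csv(dU, f)
        rows[[length(rows) + 1L]] <- tibble(
          case = case_id, snr_db = if (is.null(nl)) NA_real_ else nl,
          seed = seed, file = f, p_true = sim0$p_true)
      }
    }
  }
  index <- dplyr::bind_rows(rows)
  write.csv(as.data.frame(index), file.path(out_dir, "index.csv"),
            row.names = FALSE)
  invisible(index)
}

#' Reconstruct simulated study data from disk
#'
#' Reads the frames listed in `index.csv` under `in_dir` (as written by
#' [cmd_simulate()]) and writes one reconstructed image per method and
#' frame: `case<k>_snr<db>_seed<s>_<method>.csv`.
#'
#' @param config The [study_config()] used for the simulation.
#' @param in_dir Directory produced by [cmd_simulate()].
#' @param out_dir Output directory (default `in_dir`).
#' @param sys Optional prebuilt [study_system()].
#' @return Invisibly, the tibble of written reconstruction files.
#' @export
cmd_reconstruct <- function(config = study_config(), in_dir,
                            out_dir = in_dir, sys = NULL) {
  idx_path <- file.path(in_dir, "index.csv")
  if (!file.exists(idx_path)) {
    abort(sprintf("no simulation index at '%s'; run cmd_simulate() first.", idx_path),
          class = "eitlf_error_missing_input")
  }
  sys <- sys %||% study_system(config)
  cfg <- config
  if ("plf" %in% cfg$methods && !cfg$use_true_p) {
    abort("PLF requested but no anomaly-proportion prior is configured.",
          class = "eitlf_error_missing_p")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  index <- read.csv(idx_path)
  lambda <- study_lambda(sys)
  rows <- list()
  for (i in seq_len(nrow(index))) {
    dU <- read_frame_csv(index$file[i], sys$protocol)
    p <- if (cfg$use_true_p) index$p_true[i] else NULL
    recs <- reconstruct_frame(sys, dU, lambda, methods = cfg$methods, p = p)
    for (meth in names(recs)) {
      f <- sub("_dU\\.csv$", sprintf("_%s.csv", meth), basename(index$file[i]))
      f <- file.path(out_dir, f)
      write_image_csv(method_image(recs[[meth]]), f)
      if (inherits(recs[[meth]], "lf_result")) {
        f2 <- sub("\\.csv$", "_layer2.csv", f)
        write_image_csv(recs[[meth]]$layer2, f2)
      }
      rows[[length(rows) + 1L]] <- tibble(
        case = index$case[i], snr_db = index$snr_db[i], seed = index$seed[i],
        method = meth, file = f)
    }
  }
  out <- dplyr::bind_rows(rows)
  write.csv(as.data.frame(out), file.path(out_dir, "recon_index.csv"),
            row.names = FALSE)
  invisible(out)
}

#' Evaluate reconstructed study data from disk
#'
#' Scores every reconstruction listed in `recon_index.csv` against the
#' stored ground truth and writes a metric table
#' (`case, method, snr_db, seed, re, se, pe_px, pe_pct`) plus per-case
#' best-method flags to `metrics.csv`.
#'
#' @param config The [study_config()] used before.
#' @param in_dir Directory holding simulation and reconstruction outputs.
#' @param sys Optional prebuilt [study_system()].
#' @return The metric tibble.
#' @export
cmd_evaluate <- function(config = study_config(), in_dir, sys = NULL) {
  ridx_path <- file.path(in_dir, "recon_index.csv")
  if (!file.exists(ridx_path)) {
    abort(sprintf("no reconstruction index at '%s'; run cmd_reconstruct() first.",
                  ridx_path),
          class = "eitlf_error_missing_input")
  }
  sys <- sys %||% study_system(config)
  ridx <- read.csv(ridx_path)
  rows <- list()
  for (i in seq_len(nrow(ridx))) {
    recon <- read_image_csv(ridx$file[i], sys$grid)
    truth <- read_image_csv(file.path(in_dir, sprintf("case%d_truth.csv", ridx$case[i])),
                            sys$grid)
    truth_an <- read_image_csv(file.path(in_dir, sprintf("case%d_anomaly.csv", ridx$case[i])),
                               sys$grid)
    l2_path <- sub("\\.csv$", "_layer2.csv", ridx$file[i])
    comp <- if (file.exists(l2_path)) read_image_csv(l2_path, sys$grid) else NULL
    ev <- evaluate_reconstruction(recon, truth, truth_an,
                                  anomaly_component = comp)
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble(case = ridx$case[i], snr_db = ridx$snr_db[i],
             seed = ridx$seed[i], method = ridx$method[i]), ev)
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$case, .data$snr_db, .data$seed) |>
    dplyr::mutate(best_method = .data$method[which.min(.data$re)]) |>
    dplyr::ungroup()
  write.csv(as.data.frame(out), file.path(in_dir, "metrics.csv"),
            row.names = FALSE)
  out
}
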