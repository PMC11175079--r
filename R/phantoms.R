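#' Phantom specification
#'
#' Describes a synthetic conductivity scene: a uniform background plus a list
#' of elliptical or circular objects, each with its own conductivity.
#' Objects with `role = "anomaly"` model local lesions and must be
#' geometrically contained in one of the main objects; at any point the
#' innermost object wins (anomaly over parent, parent over background),
#' independent of listing order.
#'
#' @param background Background conductivity in S/m.
#' @param objects A list of objects created with [phantom_object()].
#' @param label Optional case label.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(background, objects = list(), label = NULL) {
  if (background <= 0) abort("background conductivity must be positive.")
  for (ob in objects) stopifnot(inherits(ob, "phantom_object"))
  spec <- structure(list(background = background, objects = objects,
                         label = label),
                    class = "phantom_spec")
  validate_phantom(spec)
}

#' Elliptical or circular phantom object
#'
#' @param center Numeric length-2 centre (metres).
#' @param semi_axes Numeric length-2 semi-axes (metres); give one value (or
#'   `radius`) for a circle.
#' @param conductivity Conductivity in S/m (positive).
#' @param role `"object"` for a main object, `"anomaly"` for a lesion nested
#'   inside a main object.
#' @param radius Convenience alias for a circle's radius.
#' @return An object of class `phantom_object`.
#' @export
phantom_object <- function(center, semi_axes = NULL, conductivity,
                           role = c("object", "anomaly"), radius = NULL) {
  role <- match.arg(role)
  if (!is.null(radius)) semi_axes <- c(radius, radius)
  if (length(semi_axes) == 1L) semi_axes <- rep(semi_axes, 2L)
  stopifnot(length(center) == 2L, length(semi_axes) == 2L)
  if (any(semi_axes <= 0)) abort("semi-axes must be positive.")
  if (conductivity <= 0) abort("object conductivity must be positive.")
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 conductivity = conductivity, role = role),
            class = "phantom_object")
}

# strict ellipse membership at points (x, y)
in_object <- function(ob, x, y) {
  ((x - ob$center[1L]) / ob$semi_axes[1L])^2 +
    ((y - ob$center[2L]) / ob$semi_axes[2L])^2 < 1
}

# is ellipse `inner` contained in ellipse `outer`? (boundary sampling)
contained_in <- function(inner, outer, n = 256L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  x <- inner$center[1L] + inner$semi_axes[1L] * cos(th)
  y <- inner$center[2L] + inner$semi_axes[2L] * sin(th)
  all(((x - outer$center[1L]) / outer$semi_axes[1L])^2 +
        ((y - outer$center[2L]) / outer$semi_axes[2L])^2 <= 1 + 1e-9)
}

validate_phantom <- function(spec) {
  mains <- Filter(function(o) o$role == "object", spec$objects)
  for (ob in spec$objects) {
    if (ob$role == "anomaly") {
      if (!any(vapply(mains, function(p) contained_in(ob, p), logical(1)))) {
        abort("an anomaly object is not contained in any main object.",
              class = "eitlf_error_geometry")
      }
    }
  }
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec%s> background %g S/m, %d object(s)\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$background, length(x$objects)))
  invisible(x)
}

# conductivity at points (x, y): innermost containing object wins.
# Anomalies are evaluated after main objects regardless of listing order.
phantom_sigma_at <- function(spec, x, y) {
  sig <- rep(spec$background, length(x))
  ord <- order(vapply(spec$objects, function(o) o$role == "anomaly", logical(1)))
  for (ob in spec$objects[ord]) {
    inside <- in_object(ob, x, y)
    sig[inside] <- ob$conductivity
  }
  sig
}

#' Rasterize a phantom to the pixel grid
#'
#' Evaluates the conductivity change (relative to the background) at every
#' supported pixel centre, producing the ground-truth image used by the
#' quality metrics.
#'
#' @param spec A [phantom_spec()].
#' @param grid A [pixel_grid()].
#' @param what `"delta"` (default) for the change relative to background,
#'   `"sigma"` for absolute conductivity, or `"anomaly"` for a binary mask of
#'   the anomaly objects only.
#' @return An `eit_image`.
#' @export
rasterize <- function(spec, grid, what = c("delta", "sigma", "anomaly")) {
  what <- match.arg(what)
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "pixel_grid"))
  disk <- phantom_object(c(0, 0), rep(grid$radius, 2L), conductivity = 1)
  for (ob in spec$objects) {
    if (!contained_in(ob, disk)) {
      abort("phantom object extends outside the circular domain.",
            class = "eitlf_error_geometry")
    }
  }
  x <- grid$centers[, 1L]
  y <- grid$centers[, 2L]
  vals <- switch(
    what,
    delta = phantom_sigma_at(spec, x, y) - spec$background,
    sigma = phantom_sigma_at(spec, x, y),
    anomaly = {
      an <- rep(FALSE, grid$M)
      for (ob in spec$objects) {
        if (ob$role == "anomaly") an <- an | in_object(ob, x, y)
      }
      as.numeric(an)
    }
  )
  eit_image(vals, grid)
}

#' Paint a phantom onto a mesh
#'
#' Assigns each mesh element the conductivity of the innermost phantom
#' object containing its centroid (anomaly over parent over background).
#'
#' @param spec A [phantom_spec()].
#' @param mesh An `eit_mesh`.
#' @return The mesh with updated element conductivities.
#' @export
apply_phantom <- function(spec, mesh) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(mesh, "eit_mesh"))
  set_conductivity(mesh, phantom_sigma_at(spec, mesh$centroids[, 1L],
                                          mesh$centroids[, 2L]))
}

#' Geometry defaults for the lung-like simulation cases
#'
#' The six simulation scenarios share two elliptical "lungs" symmetric about
#' the vertical axis and place one circular anomaly (lesion) in the right
#' lung, at three sizes and two positions. The exact figures are package
#' defaults chosen to look like a simplified transverse chest section; all
#' values are fractions of the domain radius and can be overridden.
#'
#' @param lung_center_x Lung centre offset from the axis (fraction of R).
#' @param lung_semi_axes Lung semi-axes (fraction of R).
#' @param anomaly_radii Three anomaly radii (fraction of R), cases 1-3 use
#'   these at the central position, cases 4-6 at the offset position.
#' @param anomaly_center Central anomaly position (fraction of R, right lung).
#' @param anomaly_center_alt Offset (upper-inner) anomaly position.
#' @return A named list of geometry parameters.
#' @export
lung_geometry <- function(lung_center_x = 0.47,
                          lung_semi_axes = c(0.38, 0.58),
                          anomaly_radii = c(0.10, 0.15, 0.20),
                          anomaly_center = c(0.47, 0),
                          anomaly_center_alt = c(0.35, 0.25)) {
  list(lung_center_x = lung_center_x, lung_semi_axes = lung_semi_axes,
       anomaly_radii = anomaly_radii, anomaly_center = anomaly_center,
       anomaly_center_alt = anomaly_center_alt)
}

#' Lung-like simulation phantoms
#'
#' Builds one of the six lung-with-lesion scenarios: two elliptical lungs at
#' 0.27 S/m (deflated lung at 100 kHz) in a 0.17 S/m background, with a
#' single circular anomaly at 0.6 S/m inside the right lung — a conductivity
#' contrast of 0.6/0.27 = 2.2, inside the 1.6-3.3 range reported for lung
#' tumour tissue. Cases 1-3 vary the anomaly radius at the lung centre;
#' cases 4-6 use the same radii at an upper-inner position.
#'
#' @param case_id Integer 1..6.
#' @param radius Domain radius in metres.
#' @param background Background (reference) conductivity in S/m.
#' @param lung Lung conductivity in S/m.
#' @param anomaly Anomaly conductivity in S/m.
#' @param geometry Geometry parameters from [lung_geometry()].
#' @return A [phantom_spec()].
#' @examples
#' lung_case(1)
#' @export
lung_case <- function(case_id, radius = 0.20, background = 0.17,
                      lung = 0.27, anomaly = 0.6,
                      geometry = lung_geometry()) {
  case_id <- as.integer(case_id)
  if (is.na(case_id) || case_id < 1L || case_id > 6L) {
    abort("`case_id` must be in 1..6.", class = "eitlf_error_case_id")
  }
  gme <- geometry
  lungs <- list(
    phantom_object(c(-gme$lung_center_x, 0) * radius,
                   gme$lung_semi_axes * radius, lung),
    phantom_object(c(gme$lung_center_x, 0) * radius,
                   gme$lung_semi_axes * radius, lung)
  )
  r_an <- gme$anomaly_radii[((case_id - 1L) %% 3L) + 1L]
  ctr <- if (case_id <= 3L) gme$anomaly_center else gme$anomaly_center_alt
  an <- phantom_object(ctr * radius, conductivity = anomaly, role = "anomaly",
                       radius = r_an * radius)
  phantom_spec(background, c(lungs, list(an)),
               label = sprintf("case%d", case_id))
}

#' Noise specification
#'
#' @param snr_db Signal-to-noise ratio in dB, or `NULL` to disable noise.
#' @param seed Integer seed making the draw reproducible.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(snr_db = NULL, seed = 1L) {
  if (!is.null(snr_db) && !is.finite(snr_db)) {
    abort("`snr_db` must be finite or NULL.")
  }
  structure(list(snr_db = snr_db, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' Adds signal-independent zero-mean Gaussian noise to a measurement frame.
#' The noise power is set from the frame's own mean-square power `Pu` so
#' that `SNR = 10 log10(Pu / Pnoise)` equals the nominal value. For
#' difference imaging the frame should be the voltage-change set.
#'
#' @param frame An `eit_frame` (or plain numeric vector).
#' @param noise A [noise_spec()]; with `snr_db = NULL` the frame is returned
#'   unchanged.
#' @return The noisy frame, same class as the input.
#' @export
add_noise <- function(frame, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (is.null(noise$snr_db)) return(frame)
  pu <- mean(as.numeric(frame)^2)
  if (pu <= 0) {
    abort("cannot set an SNR for a zero-power frame.",
          class = "eitlf_error_zero_power")
  }
  sd_n <- sqrt(pu * 10^(-noise$snr_db / 10))
  e <- with_local_seed(noise$seed, rnorm(length(frame), sd = sd_n))
  out <- as.numeric(frame) + e
  if (inherits(frame, "eit_frame")) {
    attributes(out) <- attributes(frame)
  }
  out
}

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
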