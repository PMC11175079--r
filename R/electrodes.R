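#' Ring electrode array on a circular boundary
#'
#' Describes `n` electrodes of equal arc width spread evenly around a circular
#' domain, the standard layout for 2D thoracic EIT. Electrode 1 is centred at
#' angle 0 (positive x axis) and indices run counter-clockwise.
#'
#' @param n Number of electrodes (at least 4).
#' @param radius Domain radius in metres.
#' @param width Electrode arc width in metres (measured along the boundary).
#' @param contact_impedance Effective contact impedance in Ohm m^2, recycled to
#'   one value per electrode. Used by the complete electrode model.
#' @return An object of class `eit_electrodes`.
#' @examples
#' el <- electrode_array(16)
#' el$angles[1:4]
#' @export
electrode_array <- function(n = 16L, radius = 0.20, width = 0.01,
                            contact_impedance = 1e-5) {
  n <- as.integer(n)
  if (is.na(n) || n < 4L) {
    abort("`n` must be an integer >= 4 (need at least one measurement pair per injection).",
          class = "eitlf_error_electrode_count")
  }
  if (radius <= 0) abort("`radius` must be positive.")
  if (width <= 0 || n * width >= 2 * pi * radius) {
    abort("electrode arcs must be positive and non-overlapping on the boundary.")
  }
  z <- rep_len(as.numeric(contact_impedance), n)
  if (any(z <= 0)) abort("contact impedances must be positive.")
  structure(
    list(n = n, radius = radius, width = width,
         angles = 2 * pi * (seq_len(n) - 1L) / n,
         contact_impedance = z),
    class = "eit_electrodes"
  )
}

#' Number of measurements in one adjacent-protocol frame
#'
#' With adjacent current injection and adjacent voltage measurement, each of
#' the `n_electrodes` injections allows `n_electrodes - 3` voltage pairs (all
#' adjacent pairs not touching a driven electrode), giving
#' `n_electrodes * (n_electrodes - 3)` values per frame.
#'
#' @param n_electrodes Electrode count, at least 4.
#' @return Integer frame length.
#' @examples
#' measurement_count(16) # 208
#' @export
measurement_count <- function(n_electrodes) {
  n <- as.integer(n_electrodes)
  if (any(is.na(n)) || any(n < 4L)) {
    abort("`n_electrodes` must be >= 4.", class = "eitlf_error_electrode_count")
  }
  n * (n - 3L)
}

#' Adjacent stimulation/measurement protocol
#'
#' Enumerates the full adjacent protocol: injections cycle through all
#' adjacent electrode pairs starting at (1,2); for each injection, voltages
#' are read on every adjacent pair that shares no electrode with the
#' injection, in ascending index order.
#'
#' @param electrodes An [electrode_array()].
#' @param current Excitation current amplitude in amperes.
#' @return An object of class `eit_protocol` with integer matrices
#'   `injections` (n x 2) and `measurements` (N x 2), the row-aligned
#'   `injection_of` index, and `n_measurements`.
#' @examples
#' pr <- adjacent_protocol(electrode_array(16), current = 5e-3)
#' pr$n_measurements # 208
#' @export
adjacent_protocol <- function(electrodes, current = 5e-3) {
  stopifnot(inherits(electrodes, "eit_electrodes"))
  if (current <= 0) abort("`current` must be positive.")
  n <- electrodes$n
  nxt <- function(i) (i %% n) + 1L
  inj <- cbind(seq_len(n), nxt(seq_len(n)))
  meas <- vector("list", n)
  for (d in seq_len(n)) {
    active <- c(inj[d, 1L], inj[d, 2L])
    keep <- vapply(seq_len(n), function(j) {
      !any(c(j, nxt(j)) %in% active)
    }, logical(1))
    meas[[d]] <- cbind(which(keep), nxt(which(keep)))
  }
  measurements <- do.call(rbind, meas)
  injection_of <- rep(seq_len(n), each = n - 3L)
  stopifnot(nrow(measurements) == measurement_count(n))
  structure(
    list(n_electrodes = n,
         injections = inj,
         measurements = measurements,
         injection_of = injection_of,
         current = current,
         n_measurements = nrow(measurements)),
    class = "eit_protocol"
  )
}

#' @export
print.eit_protocol <- function(x, ...) {
  cat(sprintf("<eit_protocol> %d electrodes, adjacent drive/measure, %d measurements, I = %g A\n",
              x$n_electrodes, x$n_measurements, x$current))
  invisible(x)
}

#' @export
print.eit_electrodes <- function(x, ...) {
  cat(sprintf("<eit_electrodes> %d electrodes, R = %g m, width = %g m\n",
              x$n, x$radius, x$width))
  invisible(x)
}

# Measurement frame: a plain numeric vector tagged with its protocol and role
# (reference / measured / difference), so downstream code can check lengths.
new_frame <- function(values, protocol, role = c("difference", "reference", "measured")) {
  role <- match.arg(role)
  if (length(values) != protocol$n_measurements) {
    abort("frame length does not match the protocol.")
  }
  structure(as.numeric(values), protocol = protocol, role = role,
            class = "eit_frame")
}

#' @export
print.eit_frame <- function(x, ...) {
  cat(sprintf("<eit_frame role=%s> %d voltages, range [%.3g, %.3g] V\n",
              attr(x, "role"), length(x), min(x), max(x)))
  invisible(x)
}

#' Tidy a measurement frame
#'
#' @param x An `eit_frame`.
#' @param ... Unused.
#' @return A tibble with one row per measurement: index, injection and
#'   measurement electrode pairs, and the voltage in volts.
#' @method as_tibble eit_frame
#' @export
as_tibble.eit_frame <- function(x, ...) {
  pr <- attr(x, "protocol")
  tibble(
    index = seq_along(x),
    inj_a = pr$injections[pr$injection_of, 1L],
    inj_b = pr$injections[pr$injection_of, 2L],
    meas_a = pr$measurements[, 1L],
    meas_b = pr$measurements[, 2L],
    volts = as.numeric(x)
  )
}
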