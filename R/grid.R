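#' Square pixel grid with circular support
#'
#' Defines the raster on which images are reconstructed: an `n x n` grid of
#' square pixels covering the bounding box of the circular domain. Only the
#' `M` pixels whose centre lies strictly inside the disk are part of the
#' image support; everything outside is held at zero. Pixel (row 1, col 1)
#' is the top-left corner; x runs to the right and y upward in physical
#' coordinates.
#'
#' @param n Side length in pixels (default 32).
#' @param radius Domain radius in metres.
#' @return An object of class `pixel_grid` with fields `n`, `radius`, `mask`
#'   (n x n logical, row-major), `M` (supported pixel count), `index` (n x n
#'   integer map into the support, NA outside), `centers` (M x 2 physical
#'   coordinates), `rows`, `cols` (pixel coordinates of the support) and
#'   `pixel_size` (metres).
#' @examples
#' g <- pixel_grid()
#' g$M
#' @export
pixel_grid <- function(n = 32L, radius = 0.20) {
  n <- as.integer(n)
  stopifnot(n >= 4L, radius > 0)
  h <- 2 * radius / n
  # column j centre x, row i centre y (row 1 at the top)
  xs <- -radius + (seq_len(n) - 0.5) * h
  ys <- radius - (seq_len(n) - 0.5) * h
  cx <- matrix(rep(xs, each = n), nrow = n)          # [i, j] = xs[j]
  cy <- matrix(rep(ys, times = n), nrow = n)         # [i, j] = ys[i]
  mask <- (cx^2 + cy^2) < radius^2
  idx <- matrix(NA_integer_, n, n)
  # row-major ordering of the support: sweep rows top to bottom
  ord <- which(t(mask))                               # row-major positions
  rows <- ((ord - 1L) %/% n) + 1L
  cols <- ((ord - 1L) %% n) + 1L
  M <- length(ord)
  idx[cbind(rows, cols)] <- seq_len(M)
  structure(
    list(n = n, radius = radius, mask = mask, M = M, index = idx,
         centers = cbind(xs[cols], ys[rows]), rows = rows, cols = cols,
         pixel_size = h),
    class = "pixel_grid"
  )
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid> %dx%d, %d supported pixels, pixel %.3g m\n",
              x$n, x$n, x$M, x$pixel_size))
  invisible(x)
}

#' Pixel image on a circular support
#'
#' A length-`M` numeric vector of per-pixel values (typically a conductivity
#' change in S/m) tied to a [pixel_grid()].
#'
#' @param values Numeric vector of length `grid$M`.
#' @param grid A `pixel_grid`.
#' @return An object of class `eit_image`.
#' @export
eit_image <- function(values, grid) {
  stopifnot(inherits(grid, "pixel_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$M) abort("image length must equal grid$M.")
  if (any(!is.finite(values))) abort("image values must be finite.")
  structure(values, grid = grid, class = "eit_image")
}

#' @export
print.eit_image <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<eit_image> %dx%d grid (%d px), range [%.3g, %.3g]\n",
              g$n, g$n, g$M, min(x), max(x)))
  invisible(x)
}

#' Expand a pixel image to a full square matrix
#'
#' @param x An `eit_image`.
#' @param ... Unused.
#' @param fill Value used outside the circular support.
#' @return An `n x n` matrix (row 1 = top of the image).
#' @export
as.matrix.eit_image <- function(x, ..., fill = 0) {
  g <- attr(x, "grid")
  out <- matrix(fill, g$n, g$n)
  out[cbind(g$rows, g$cols)] <- as.numeric(x)
  out
}

#' Tidy a pixel image into long form
#'
#' @param x An `eit_image`.
#' @param ... Unused.
#' @return A tibble with pixel index, row, col, physical x/y (metres) and
#'   value.
#' @method as_tibble eit_image
#' @export
as_tibble.eit_image <- function(x, ...) {
  g <- attr(x, "grid")
  tibble(pixel = seq_len(g$M), row = g$rows, col = g$cols,
         x = g$centers[, 1L], y = g$centers[, 2L],
         value = as.numeric(x))
}

#' Plot a pixel image
#'
#' @param object An `eit_image`.
#' @param ... Unused.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @method autoplot eit_image
#' @export
autoplot.eit_image <- function(object, ..., title = NULL) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * sigma)) +
    ggplot2::labs(title = title, x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
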