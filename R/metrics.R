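#' Relative image error
#'
#' `RE = ||recon - truth||_2 / ||truth||_2`, the overall error of a
#' reconstruction against the ground-truth conductivity change.
#'
#' @param recon,truth Pixel images on the same grid.
#' @return Non-negative scalar.
#' @export
relative_error <- function(recon, truth) {
  r <- as.numeric(recon); t_ <- as.numeric(truth)
  if (length(r) != length(t_)) abort("images must share the grid.")
  nt <- sqrt(sum(t_^2))
  if (nt == 0) {
    abort("relative error undefined for a zero ground truth.",
          class = "eitlf_error_zero_truth")
  }
  sqrt(sum((r - t_)^2)) / nt
}

#' Extract the observed anomaly object
#'
#' Applies the quarter-amplitude rule to a reconstructed image: the anomaly
#' object mask contains every pixel at or above one quarter of the image
#' maximum. In a fused layered reconstruction the anomaly sits above the
#' main-object level, so this isolates it; applied to a one-step
#' reconstruction of a multi-conductivity scene the mask typically merges
#' anomaly and main objects, which is what makes the one-step size error
#' large.
#'
#' @param image Pixel image.
#' @return A binary image (same class as the input). All-zero (or
#'   non-positive) images yield an empty mask with a warning.
#' @export
extract_anomaly_object <- function(image) {
  v <- as.numeric(image)
  mx <- max(v)
  if (mx <= 0) {
    warn("no positive values: anomaly mask is empty.")
    return(rebuild_like(numeric(length(v)), image))
  }
  rebuild_like(as.numeric(v >= mx / 4), image)
}

#' Size error of the anomaly object
#'
#' `SE = |m_rec - m_true| / m_true` where the `m` are anomaly pixel counts.
#'
#' @param recon_mask Binary mask of the reconstructed anomaly object.
#' @param truth_mask Binary mask of the true anomaly (non-empty).
#' @return Non-negative scalar (1 = 100% size error).
#' @export
size_error <- function(recon_mask, truth_mask) {
  mo_true <- sum(as.numeric(truth_mask) != 0)
  if (mo_true == 0) {
    abort("size error undefined for an empty truth mask.",
          class = "eitlf_error_empty_mask")
  }
  mo_rec <- sum(as.numeric(recon_mask) != 0)
  abs(mo_rec - mo_true) / mo_true
}

# centre of gravity of a mask in pixel coordinates (col = x, row = y),
# weighted by |image| over the mask when an image is supplied
mask_centroid <- function(mask, image = NULL) {
  g <- attr(mask, "grid")
  m <- as.numeric(mask) != 0
  if (!any(m)) {
    abort("centroid undefined for an empty mask.",
          class = "eitlf_error_empty_mask")
  }
  w <- if (is.null(image)) rep(1, sum(m)) else abs(as.numeric(image))[m]
  if (sum(w) == 0) w <- rep(1, length(w))
  if (is.null(g)) abort("mask must carry a pixel grid.")
  c(col = sum(g$cols[m] * w) / sum(w), row = sum(g$rows[m] * w) / sum(w))
}

#' Position error of the anomaly object
#'
#' Euclidean distance, in pixels, between the centres of gravity of the
#' reconstructed and true anomaly objects. When intensity images are given
#' the centroids are weighted by the image amplitude over each mask. The
#' normalized form divides by the image side length and reports percent.
#'
#' @param recon_mask,truth_mask Non-empty binary masks on the same grid.
#' @param recon_image,truth_image Optional intensity images for weighting.
#' @param normalized If `TRUE` return percent of the image side instead of
#'   pixels.
#' @return Non-negative scalar (pixels, or % of image width).
#' @export
position_error <- function(recon_mask, truth_mask, recon_image = NULL,
                           truth_image = NULL, normalized = FALSE) {
  c1 <- mask_centroid(recon_mask, recon_image)
  c2 <- mask_centroid(truth_mask, truth_image)
  d <- sqrt(sum((c1 - c2)^2))
  if (normalized) 100 * d / attr(recon_mask, "grid")$n else d
}

#' Evaluate a reconstruction against the ground truth
#'
#' Computes the three standard image quality metrics in one call: relative
#' error over the whole image, and size/position error of the anomaly
#' object extracted by the quarter-amplitude rule.
#'
#' @param recon Reconstructed pixel image (`eit_image`), or an `lf_result`.
#' @param truth Ground-truth conductivity-change image.
#' @param truth_anomaly Binary mask of the true anomaly object.
#' @param anomaly_component Image from which the anomaly object is
#'   extracted. Defaults to the reconstruction itself; for a layered result
#'   the anomaly layer (`layer2`) is used, since there the local anomaly is
#'   represented as its own component rather than riding on top of the main
#'   objects.
#' @param normalize_re If `TRUE` (default) both images are scaled to unit
#'   maximum before the relative error, since one-step regularized
#'   difference images recover the conductivity change only up to an
#'   overall amplitude.
#' @return A one-row tibble: `re`, `se`, `pe_px`, `pe_pct`, and the mask
#'   pixel counts `m_rec`, `m_true`.
#' @export
evaluate_reconstruction <- function(recon, truth, truth_anomaly,
                                    anomaly_component = NULL,
                                    normalize_re = TRUE) {
  if (inherits(recon, "lf_result")) {
    anomaly_component <- anomaly_component %||% recon$layer2
    recon <- recon$image
  }
  anomaly_component <- anomaly_component %||% recon
  mask <- extract_anomaly_object(anomaly_component)
  se <- size_error(mask, truth_anomaly)
  pe <- if (sum(as.numeric(mask) != 0) == 0) {
    NA_real_
  } else {
    position_error(mask, truth_anomaly, recon_image = anomaly_component,
                   truth_image = truth)
  }
  g <- attr(recon, "grid")
  unit_max <- function(v) {
    m <- max(abs(as.numeric(v)))
    if (m > 0) as.numeric(v) / m else as.numeric(v)
  }
  re <- if (normalize_re) {
    relative_error(unit_max(recon), unit_max(truth))
  } else {
    relative_error(recon, truth)
  }
  tibble(
    re = re,
    se = se,
    pe_px = pe,
    pe_pct = if (is.na(pe)) NA_real_ else 100 * pe / g$n,
    m_rec = sum(as.numeric(mask) != 0),
    m_true = sum(as.numeric(truth_anomaly) != 0)
  )
}
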