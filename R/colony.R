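#' Register a plate image to the reference by integer translation
#'
#' Exhaustive search over integer pixel shifts within `search_radius`,
#' maximising the normalised cross-correlation (Pearson correlation) of the
#' grayscale versions (grayscale = mean of the three channels) over the
#' overlap region. Ties are broken by the smallest `|dy| + |dx|`, then
#' row-major order. A maximum correlation below 0.2 - or an undefined
#' correlation on degenerate (constant) overlap - sets the
#' `"poor registration"` flag; the best offset is still returned.
#'
#' The convention is `image[y, x] == reference[y - dy, x - dx]`: the
#' returned offset is the translation that the image content has undergone
#' relative to the reference.
#'
#' @param image,reference H x W x 3 numeric arrays of equal dimensions.
#' @param search_radius Maximum absolute shift searched per axis
#'   (default 32 px).
#' @return List with `offset` (`c(dy, dx)`), `correlation`, and `flags`
#'   (character vector, possibly empty).
#' @export
register_to_reference <- function(image, reference, search_radius = 32L) {
  if (!identical(dim(image), dim(reference)))
    stop("image and reference must have identical dimensions", call. = FALSE)
  g_img <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  g_ref <- (reference[, , 1] + reference[, , 2] + reference[, , 3]) / 3
  h <- nrow(g_img); w <- ncol(g_img)
  r <- as.integer(search_radius)

  best <- list(cor = -Inf, dy = 0L, dx = 0L, l1 = Inf)
  for (dy in seq.int(-r, r)) {
    ys <- max(1L, 1L + dy):min(h, h + dy)       # rows of image
    if (length(ys) < 2L) next
    for (dx in seq.int(-r, r)) {
      xs <- max(1L, 1L + dx):min(w, w + dx)
      if (length(xs) < 2L) next
      a <- g_img[ys, xs]
      b <- g_ref[ys - dy, xs - dx]
      sa <- stats::sd(a); sb <- stats::sd(b)
      cc <- if (sa == 0 || sb == 0) NA_real_ else stats::cor(c(a), c(b))
      if (is.na(cc)) cc <- 0
      l1 <- abs(dy) + abs(dx)
      if (cc > best$cor + 1e-12 ||
          (abs(cc - best$cor) <= 1e-12 && l1 < best$l1)) {
        best <- list(cor = cc, dy = dy, dx = dx, l1 = l1)
      }
    }
  }
  flags <- character(0)
  if (best$cor < 0.2) flags <- "poor registration"
  list(offset = c(dy = best$dy, dx = best$dx),
       correlation = best$cor, flags = flags)
}

#' Segment colonies by blue-channel thresholding
#'
#' A pixel is colony iff its blue-channel value is at or above `threshold`
#' (polarity `"bright"`, the default for the blue-bright rendering of
#' trypan-blue-stained colonies) or at or below it (polarity `"dark"`, for
#' stain/background contrast that inverts). The same single fixed threshold
#' should be applied to every image of a batch.
#'
#' @param image H x W x 3 numeric array (0-255).
#' @param threshold Blue-channel threshold in 0-255.
#' @param polarity `"bright"` or `"dark"`.
#' @return Logical H x W matrix (TRUE = colony).
#' @export
segment_colonies <- function(image, threshold, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (threshold < 0 || threshold > 255)
    stop("`threshold` must be in 0-255", call. = FALSE)
  b <- image[, , 3]
  if (polarity == "bright") b >= threshold else b <= threshold
}

#' Colony area fraction inside a (shifted) region of interest
#'
#' Applies the registration offset to the ROI (drawn on the reference) so
#' it follows the image content, then computes the fraction of ROI pixels
#' covered by the colony mask. ROI pixels shifted outside the image bounds
#' are excluded from the denominator.
#'
#' @param mask Logical colony mask from [segment_colonies()].
#' @param roi Logical ROI mask defined on the reference image.
#' @param offset Integer `c(dy, dx)` from [register_to_reference()].
#' @return Area fraction in `[0, 1]`.
#' @export
area_fraction <- function(mask, roi, offset = c(0L, 0L)) {
  if (!identical(dim(mask), dim(roi)))
    stop("mask and roi must have identical dimensions", call. = FALSE)
  roi_eff <- shift_matrix(roi, offset[1], offset[2], fill = NA)
  valid <- !is.na(roi_eff) & roi_eff
  denom <- sum(valid)
  if (denom == 0L) stop("effective ROI is empty after shifting", call. = FALSE)
  sum(mask & valid) / denom
}

#' Quantify a batch of colony plate images
#'
#' Full colony pipeline: register each image to the reference, segment it
#' with the single fixed blue threshold, and compute the ROI area fraction
#' with the ROI following the registration offset.
#'
#' @param images List of H x W x 3 arrays.
#' @param reference Reference image (same dimensions).
#' @param roi Logical ROI mask on the reference.
#' @param threshold Fixed blue-channel threshold applied to every image.
#' @param search_radius Registration search radius in px.
#' @param polarity Segmentation polarity, see [segment_colonies()].
#' @return Data frame of class `colony_result`: one row per image with
#'   `image`, `dy`, `dx`, `correlation`, `threshold_used`, `area_fraction`,
#'   `flags`.
#' @export
quantify_colonies <- function(images, reference, roi, threshold,
                              search_radius = 32L,
                              polarity = "bright") {
  nms <- names(images)
  if (is.null(nms)) nms <- sprintf("img%02d", seq_along(images))
  rows <- lapply(seq_along(images), function(i) {
    reg <- register_to_reference(images[[i]], reference, search_radius)
    m <- segment_colonies(images[[i]], threshold, polarity)
    af <- area_fraction(m, roi, reg$offset)
    data.frame(image = nms[i], dy = reg$offset[["dy"]],
               dx = reg$offset[["dx"]], correlation = reg$correlation,
               threshold_used = threshold, area_fraction = af,
               flags = paste(reg$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("colony_result", "data.frame")
  out
}

#' Test whether a CAF coculture is colony-supporting
#'
#' Two-sided Welch t-test of treated vs control colony area fractions.
#' A coculture is colony-supporting when p < 0.05 AND the treated mean
#' exceeds the control mean; colony-suppressing analogously when the
#' treated mean is lower.
#'
#' @param treated,control Numeric vectors of area fractions, at least 2
#'   values each.
#' @param alpha Significance level (study convention 0.05).
#' @return List with `p_value`, `supporting`, `suppressing`,
#'   `mean_treated`, `mean_control`.
#' @export
#' @examples
#' support_test(c(0.30, 0.31, 0.29), c(0.10, 0.11, 0.09))
support_test <- function(treated, control, alpha = 0.05) {
  if (length(treated) < 2L || length(control) < 2L)
    stop("need at least 2 replicates per group", call. = FALSE)
  mt <- mean(treated); mc <- mean(control)
  if (stats::sd(treated) == 0 && stats::sd(control) == 0) {
    p <- if (isTRUE(all.equal(mt, mc))) 1 else 0
  } else {
    p <- stats::t.test(treated, control, var.equal = FALSE)$p.value
  }
  list(p_value = p,
       supporting = p < alpha && mt > mc,
       suppressing = p < alpha && mt < mc,
       mean_treated = mt, mean_control = mc)
}
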