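#' Generate synthetic colony-forming-assay plate images
#'
#' Renders a reference plate image with colonies as filled blue-bright disks
#' (blue channel = background + contrast margin, emulating trypan-blue
#' staining), a region-of-interest mask, and a set of plate images that are
#' the reference content translated by known integer pixel shifts plus
#' Gaussian pixel noise. The true colony area fraction of each image is
#' computed on its rendered (noise-free) colony mask inside the shifted ROI,
#' not analytically, so overlapping disks and border clipping are accounted
#' for exactly.
#'
#' @param config A [sim_config()] object; settings under `config$colony`.
#' @return A list with elements
#'   * `reference`: H x W x 3 integer array (0-255 RGB);
#'   * `roi`: logical H x W matrix (TRUE = inside the labelled region);
#'   * `images`: list of H x W x 3 integer arrays;
#'   * `truth`: data frame `image`, `dy`, `dx`, `area_fraction`;
#'   * `clean_masks`: list of noise-free colony masks, one per image.
#' @export
gen_colony_images <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cs <- config$colony
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sim_seed(config, "colony"))

  h <- cs$height; w <- cs$width
  n_col <- stats::rpois(1L, cs$n_colonies_lambda)
  centers_y <- stats::runif(n_col, 1, h)
  centers_x <- stats::runif(n_col, 1, w)
  radii <- stats::runif(n_col, cs$radius_range[1], cs$radius_range[2])

  mask_ref <- matrix(FALSE, h, w)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (k in seq_len(n_col)) {
    mask_ref <- mask_ref |
      ((yy - centers_y[k])^2 + (xx - centers_x[k])^2 <= radii[k]^2)
  }

  roi <- (yy - (h + 1) / 2)^2 + (xx - (w + 1) / 2)^2 <=
    (0.4 * min(h, w))^2

  render <- function(mask) {
    bg_b <- cs$background_blue
    col_b <- cs$background_blue + cs$contrast_margin
    r <- matrix(200, h, w); g <- matrix(200, h, w)
    b <- matrix(bg_b, h, w)
    r[mask] <- 90; g[mask] <- 90; b[mask] <- col_b
    array(c(r, g, b), dim = c(h, w, 3L))
  }

  add_noise <- function(img) {
    if (cs$pixel_noise_sd == 0) return(img)
    noisy <- img + array(stats::rnorm(length(img), 0, cs$pixel_noise_sd),
                         dim = dim(img))
    array(pmin(255, pmax(0, round(noisy))), dim = dim(img))
  }

  reference <- add_noise(render(mask_ref))

  n_img <- cs$n_images
  dy <- sample(seq(-cs$shift_max, cs$shift_max), n_img, replace = TRUE)
  dx <- sample(seq(-cs$shift_max, cs$shift_max), n_img, replace = TRUE)
  images <- vector("list", n_img)
  clean_masks <- vector("list", n_img)
  frac <- numeric(n_img)
  for (i in seq_len(n_img)) {
    m_i <- shift_matrix(mask_ref, dy[i], dx[i], fill = FALSE)
    roi_i <- shift_matrix(roi, dy[i], dx[i], fill = NA)
    valid <- !is.na(roi_i) & roi_i
    frac[i] <- sum(m_i & valid) / sum(valid)
    clean <- render(m_i)
    images[[i]] <- add_noise(clean)
    clean_masks[[i]] <- m_i
  }

  list(reference = reference, roi = roi, images = images,
       truth = data.frame(image = sprintf("img%02d", seq_len(n_img)),
                          dy = dy, dx = dx, area_fraction = frac),
       clean_masks = clean_masks)
}

# Translate a matrix by (dy, dx): result[y, x] = m[y - dy, x - dx],
# out-of-range positions take `fill`.
shift_matrix <- function(m, dy, dx, fill = NA) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- seq_len(h); xs <- seq_len(w)
  ys_src <- ys - dy; xs_src <- xs - dx
  keep_y <- ys_src >= 1 & ys_src <= h
  keep_x <- xs_src >= 1 & xs_src <= w
  out[ys[keep_y], xs[keep_x]] <- m[ys_src[keep_y], xs_src[keep_x]]
  out
}
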