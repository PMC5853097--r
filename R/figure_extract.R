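#' Marker template for scatter-plot digitisation
#'
#' A small grayscale patch (the manually selected marker mask) plus a
#' detection threshold on the normalized cross-correlation and a
#' non-maximum-suppression radius. Markers closer together than the
#' suppression radius collapse to a single detection — a documented
#' limitation of template matching on overlapping points.
#'
#' @param patch numeric matrix in [0, 1] (rows = image rows).
#' @param threshold NCC detection threshold in (0, 1).
#' @param suppression_radius suppression radius in pixels; default half
#'   the larger template side.
#' @return object of class `marker_template`.
#' @export
marker_template <- function(patch, threshold = 0.8,
                            suppression_radius = NULL) {
  stopifnot(is.matrix(patch), is.numeric(patch),
            threshold > 0, threshold < 1)
  if (is.null(suppression_radius))
    suppression_radius <- max(dim(patch)) / 2
  structure(list(patch = patch, threshold = threshold,
                 suppression_radius = suppression_radius),
            class = "marker_template")
}

#' @rdname marker_template
#' @param radius disc radius in pixels.
#' @param size patch side length; default `2*radius + 3`.
#' @export
disc_template <- function(radius = 3, size = 2 * radius + 3, ...) {
  ctr <- (size + 1) / 2
  d <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+"))
  marker_template(matrix(as.numeric(d <= radius), size, size), ...)
}

# summed-area table window sums of `m` over th x tw windows
box_sums <- function(m, th, tw) {
  sat <- rbind(0, cbind(0, t(apply(apply(m, 2, cumsum), 1, cumsum))))
  H <- nrow(m); W <- ncol(m)
  ys <- seq_len(H - th + 1); xs <- seq_len(W - tw + 1)
  sat[ys + th, xs + tw, drop = FALSE] - sat[ys, xs + tw, drop = FALSE] -
    sat[ys + th, xs, drop = FALSE] + sat[ys, xs, drop = FALSE]
}

# zero-mean normalized cross-correlation map (valid positions; top-left
# indexed)
ncc_map <- function(image, patch) {
  th <- nrow(patch); tw <- ncol(patch)
  t0 <- patch - mean(patch)
  tnorm <- sqrt(sum(t0^2))
  if (tnorm == 0) stop("flat template: NCC undefined", call. = FALSE)
  H <- nrow(image); W <- ncol(image)
  num <- matrix(0, H - th + 1, W - tw + 1)
  for (i in seq_len(th)) for (j in seq_len(tw)) {
    if (t0[i, j] != 0)
      num <- num + t0[i, j] *
        image[i:(H - th + i), j:(W - tw + j), drop = FALSE]
  }
  s1 <- box_sums(image, th, tw)
  s2 <- box_sums(image^2, th, tw)
  varw <- pmax(s2 - s1^2 / (th * tw), 0)
  den <- sqrt(varw) * tnorm
  out <- num / den
  out[den < .Machine$double.eps^0.5] <- 0
  out
}

# 1-D quadratic sub-pixel offset around a discrete peak
subpixel_offset <- function(l, c, r) {
  den <- l - 2 * c + r
  if (den >= 0) return(0)           # not a strict maximum
  max(-0.5, min(0.5, 0.5 * (l - r) / den))
}

#' Detect marker centers by normalized cross-correlation
#'
#' Computes the zero-mean normalized cross-correlation of the template
#' against the image, keeps local maxima at or above the template's
#' threshold, applies greedy non-maximum suppression within the suppression
#' radius, and refines each surviving peak to sub-pixel precision with a
#' 1-D quadratic fit per axis.
#'
#' @param image numeric grayscale matrix (rows = pixel rows, y increases
#'   downward).
#' @param template a [marker_template()].
#' @return data.frame with columns `x`, `y` (pixel coordinates, 1-based,
#'   sub-pixel) and `score` (NCC at the peak), ordered by decreasing score;
#'   zero rows for a blank image.
#' @export
detect_markers <- function(image, template) {
  stopifnot(is.matrix(image), inherits(template, "marker_template"))
  patch <- template$patch
  if (nrow(patch) > nrow(image) || ncol(patch) > ncol(image))
    stop("template larger than image", call. = FALSE)
  cc <- ncc_map(image, patch)
  H <- nrow(cc); W <- ncol(cc)
  cand <- which(cc >= template$threshold, arr.ind = TRUE)
  if (nrow(cand)) {   # keep only 8-neighbourhood local maxima
    keep <- vapply(seq_len(nrow(cand)), function(k) {
      i <- cand[k, 1]; j <- cand[k, 2]
      nb <- cc[max(1, i - 1):min(H, i + 1), max(1, j - 1):min(W, j + 1)]
      cc[i, j] >= max(nb)
    }, TRUE)
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0)))
  sc <- cc[cand]
  ord <- order(sc, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; sc <- sc[ord]
  kept <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (k == 1 || all((cand[k, 1] - cand[kept, 1])^2 +
                        (cand[k, 2] - cand[kept, 2])^2 >
                        template$suppression_radius^2))
      kept[k] <- TRUE
  }
  cand <- cand[kept, , drop = FALSE]; sc <- sc[kept]
  off_y <- (nrow(patch) - 1) / 2
  off_x <- (ncol(patch) - 1) / 2
  res <- t(vapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    dy <- if (i > 1 && i < H) subpixel_offset(cc[i - 1, j], cc[i, j],
                                              cc[i + 1, j]) else 0
    dx <- if (j > 1 && j < W) subpixel_offset(cc[i, j - 1], cc[i, j],
                                              cc[i, j + 1]) else 0
    c(x = j + dx + off_x, y = i + dy + off_y)
  }, c(x = 0, y = 0)))
  data.frame(x = res[, "x"], y = res[, "y"], score = sc)
}

#' Axis calibration between pixel and data coordinates
#'
#' Two pixel/data anchor pairs per axis define an affine map. Pixel y
#' increases downward while data y usually increases upward; the anchor
#' pairs absorb the inversion (the y slope simply comes out negative).
#'
#' @param x_pixels,x_data two x-axis anchors (pixel, data).
#' @param y_pixels,y_data two y-axis anchors (pixel, data).
#' @return object of class `axis_calibration`.
#' @export
axis_calibration <- function(x_pixels, x_data, y_pixels, y_data) {
  stopifnot(length(x_pixels) == 2, length(x_data) == 2,
            length(y_pixels) == 2, length(y_data) == 2)
  if (x_pixels[1] == x_pixels[2] || y_pixels[1] == y_pixels[2])
    stop("degenerate calibration: anchor pixels coincide", call. = FALSE)
  sx <- diff(x_data) / diff(x_pixels)
  sy <- diff(y_data) / diff(y_pixels)
  if (!all(is.finite(c(sx, sy))) || sx == 0 || sy == 0)
    stop("degenerate calibration: zero or non-finite scale", call. = FALSE)
  structure(list(x_pixels = x_pixels, x_data = x_data,
                 y_pixels = y_pixels, y_data = y_data,
                 sx = sx, sy = sy), class = "axis_calibration")
}

#' Map detected pixel centers to data coordinates (and back)
#'
#' @param centers data.frame with pixel `x`, `y` (as from
#'   [detect_markers()]).
#' @param cal an [axis_calibration()].
#' @return data.frame with data-coordinate `x`, `y`.
#' @export
pixels_to_data <- function(centers, cal) {
  stopifnot(inherits(cal, "axis_calibration"))
  data.frame(
    x = cal$x_data[1] + (centers$x - cal$x_pixels[1]) * cal$sx,
    y = cal$y_data[1] + (centers$y - cal$y_pixels[1]) * cal$sy
  )
}

#' @rdname pixels_to_data
#' @param points data.frame with data-coordinate `x`, `y`.
#' @export
data_to_pixels <- function(points, cal) {
  stopifnot(inherits(cal, "axis_calibration"))
  data.frame(
    x = cal$x_pixels[1] + (points$x - cal$x_data[1]) / cal$sx,
    y = cal$y_pixels[1] + (points$y - cal$y_data[1]) / cal$sy
  )
}

#' Render a synthetic scatter plot raster
#'
#' Paints the marker template at the pixel positions of the given data
#' points on a blank image — the synthetic stand-in used to validate the
#' digitisation round trip without any external figure.
#'
#' @param points data.frame with data-coordinate `x`, `y`.
#' @param cal an [axis_calibration()].
#' @param template a [marker_template()].
#' @param width,height image size in pixels.
#' @return numeric matrix in [0, 1].
#' @export
render_scatter <- function(points, cal, template, width = 400,
                           height = 300) {
  img <- matrix(0, height, width)
  px <- data_to_pixels(points, cal)
  patch <- template$patch
  oy <- (nrow(patch) - 1) / 2; ox <- (ncol(patch) - 1) / 2
  for (k in seq_len(nrow(px))) {
    i0 <- round(px$y[k] - oy); j0 <- round(px$x[k] - ox)
    ii <- i0:(i0 + nrow(patch) - 1); jj <- j0:(j0 + ncol(patch) - 1)
    ok_i <- ii >= 1 & ii <= height; ok_j <- jj >= 1 & jj <= width
    if (any(ok_i) && any(ok_j))
      img[ii[ok_i], jj[ok_j]] <-
        pmax(img[ii[ok_i], jj[ok_j]], patch[ok_i, ok_j, drop = FALSE])
  }
  img
}
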