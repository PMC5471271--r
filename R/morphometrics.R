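#' Construct a binary mask
#'
#' A validated single-object binary mask on a pixel grid.  Pixel centers sit
#' at integer coordinates, origin top-left, row-major; \code{pixel_size}
#' converts pixel units to physical length.
#'
#' @param pixels logical matrix; must contain at least one \code{TRUE}.
#' @param pixel_size physical length per pixel (default 1).
#' @return object of class \code{binary_mask}.
#' @export
binary_mask <- function(pixels, pixel_size = 1) {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  if (!is.logical(pixels)) {
    if (!all(pixels %in% c(0, 1))) stop("'pixels' must be binary")
    pixels <- pixels > 0
  }
  if (!any(pixels)) stop("mask is empty")
  if (pixel_size <= 0) stop("'pixel_size' must be > 0")
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "binary_mask")
}

.as_pixels <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$pixels else binary_mask(mask)$pixels
}
.pixel_size <- function(mask) if (inherits(mask, "binary_mask")) mask$pixel_size else 1

# coerce an image argument (matrix or EBImage Image) to a plain numeric
# matrix in [0, 1]
.as_gray <- function(image) {
  if (inherits(image, "Image")) image <- imageData(image)
  if (length(dim(image)) == 3) image <- image[, , 1]
  if (!is.matrix(image) || !is.numeric(image)) stop("image must be a 2-D numeric matrix")
  if (max(image) > 1) image <- image / ifelse(max(image) > 255, 65535, 255)
  image
}

#' Segment a spheroid from a grayscale image
#'
#' Thresholds the image (Otsu by default, after the imaging-software
#' workflow of applying a threshold and keeping the particle), labels
#' connected components, discards components smaller than \code{min_size},
#' keeps the largest remaining one and optionally fills its holes.
#'
#' @param image 2-D grayscale image (numeric matrix in [0,1], 8/16-bit
#'   values are rescaled) or an \code{EBImage} image.
#' @param threshold \code{"otsu"} or a fixed numeric threshold on the [0,1]
#'   scale.
#' @param min_size minimum component area, pixels^2.
#' @param fill_holes fill interior holes of the kept component.
#' @param pixel_size physical length per pixel, stored in the mask.
#' @return a \code{\link{binary_mask}} of the spheroid.
#' @export
segment_spheroid <- function(image, threshold = "otsu", min_size = 50,
                             fill_holes = TRUE, pixel_size = 1) {
  img <- .as_gray(image)
  if (max(img) - min(img) < 1e-12)
    stop("cannot threshold a constant image")
  thr <- if (identical(threshold, "otsu")) otsu(Image(img)) else {
    if (!is.numeric(threshold)) stop("'threshold' must be \"otsu\" or numeric")
    threshold
  }
  bw <- img > thr
  lab <- imageData(bwlabel(Image(bw * 1)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  if (!length(keep)) stop("empty segmentation: no component of at least ", min_size, " px^2")
  biggest <- keep[which.max(sizes[keep])]
  comp <- lab == biggest
  if (fill_holes) comp <- imageData(fillHull(Image(comp * 1))) > 0
  binary_mask(comp, pixel_size = pixel_size)
}

#' Mask area
#'
#' Foreground pixel count times \code{pixel_size^2}.
#'
#' @param mask a \code{\link{binary_mask}} or logical matrix.
#' @return area in physical units squared.
#' @export
measure_area <- function(mask) {
  sum(.as_pixels(mask)) * .pixel_size(mask)^2
}

# marching-squares iso-contours of a padded binary mask at level 0.5;
# returns a list of closed polygons (x = row coord, y = col coord)
.mask_contours <- function(px) {
  m <- matrix(0, nrow(px) + 2, ncol(px) + 2)
  m[2:(nrow(px) + 1), 2:(ncol(px) + 1)] <- px * 1
  contourLines(x = seq_len(nrow(m)) - 1, y = seq_len(ncol(m)) - 1,
               z = m, levels = 0.5)
}

# Ramer-Douglas-Peucker simplification; returns indices of kept vertices
.rdp <- function(x, y, eps) {
  n <- length(x)
  if (n < 3) return(seq_len(n))
  keep <- logical(n); keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    len <- sqrt(dx^2 + dy^2)
    ids <- (i + 1):(j - 1)
    d <- if (len < 1e-12)
      sqrt((x[ids] - x[i])^2 + (y[ids] - y[i])^2)
    else
      abs(dy * (x[ids] - x[i]) - dx * (y[ids] - y[i])) / len
    k <- ids[which.max(d)]
    if (max(d) > eps) {
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k)), list(c(k, j)))
    }
  }
  which(keep)
}

.polygon_length <- function(x, y) {
  x <- c(x, x[1]); y <- c(y, y[1])
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Sub-pixel boundary perimeter of a mask
#'
#' Extracts the 0.5-level marching-squares contour of the mask and measures
#' the length of its Douglas-Peucker-simplified polygon.  The
#' simplification (tolerance \code{eps}, pixels) straightens the staircase
#' artifacts of rasterized smooth boundaries -- which otherwise bias the raw
#' contour length upward by several percent and depress circularity -- while
#' leaving genuine corners in place.  The longest contour (the outer
#' boundary) is measured.
#'
#' @param mask a \code{\link{binary_mask}} or logical matrix.
#' @param eps simplification tolerance in pixels.
#' @return perimeter in physical units.
#' @export
measure_perimeter <- function(mask, eps = 1.0) {
  px <- .as_pixels(mask)
  cl <- .mask_contours(px)
  lens <- vapply(cl, function(cc) {
    x <- cc$x; y <- cc$y; n <- length(x)
    # start the open simplification at the point farthest from the
    # centroid so the implicit closing edge lies on the hull
    i0 <- which.max((x - mean(x))^2 + (y - mean(y))^2)
    x <- c(x[i0:n], x[seq_len(i0)])
    y <- c(y[i0:n], y[seq_len(i0)])
    id <- .rdp(x, y, eps)
    if (length(id) < 4)   # tiny contour collapsed below a triangle: keep raw
      .polygon_length(cc$x, cc$y)
    else
      .polygon_length(x[id][-length(id)], y[id][-length(id)])
  }, 0)
  max(lens) * .pixel_size(mask)
}

#' Circularity
#'
#' The imaging-software standard shape factor \code{4 * pi * area /
#' perimeter^2}: 1 for a perfect disc, smaller for elongated or irregular
#' outlines.  Values are capped at 1, as rasterized discs can slightly
#' exceed it with sub-pixel perimeter estimators.
#'
#' @param area object area (> 0).
#' @param perimeter object perimeter (> 0), same length unit.
#' @return circularity in (0, 1].
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("'area' and 'perimeter' must be positive")
  pmin(1, 4 * pi * area / perimeter^2)
}

#' Fit the moment-equivalent ellipse of a mask
#'
#' The standard imaging-software "fit ellipse": the ellipse with the same
#' centroid and the same principal second-central-moment directions as the
#' foreground pixels, with its area rescaled to equal the mask area.
#' Orientation is the major-axis angle in [0, pi) measured from the row
#' axis.  A per-pixel variance of 1/12 is added to the diagonal of the
#' pixel-center covariance to account for the pixels' own extent.
#'
#' @param mask a \code{\link{binary_mask}} or logical matrix with >= 5
#'   foreground pixels.
#' @return object of class \code{ellipse_fit} with \code{center} (row, col),
#'   \code{semi_major}, \code{semi_minor} (pixels) and \code{orientation}
#'   (radians); \code{pi * semi_major * semi_minor} equals the pixel count.
#' @export
fit_ellipse <- function(mask) {
  px <- .as_pixels(mask)
  ij <- which(px, arr.ind = TRUE)
  if (nrow(ij) < 5) stop("need >= 5 foreground pixels to fit an ellipse")
  ctr <- colMeans(ij)
  cv0 <- cov(ij) * (nrow(ij) - 1) / nrow(ij)
  if (eigen(cv0, symmetric = TRUE, only.values = TRUE)$values[2] <= 1e-9)
    stop("degenerate pixel set: collinear mask")
  eg <- eigen(cv0 + diag(1 / 12, 2), symmetric = TRUE)
  a0 <- 2 * sqrt(eg$values[1])
  b0 <- 2 * sqrt(eg$values[2])
  s <- sqrt(nrow(ij) / (pi * a0 * b0))   # match ellipse area to mask area
  v <- eg$vectors[, 1]
  ang <- atan2(v[2], v[1]) %% pi
  structure(list(center = unname(ctr), semi_major = a0 * s,
                 semi_minor = b0 * s, orientation = ang),
            class = "ellipse_fit")
}

#' Rasterize an ellipse on a pixel grid
#'
#' Marks every pixel whose center lies inside the ellipse; the same
#' inclusion rule used by the synthetic spheroid generator, so identical
#' parameters give identical rasters.
#'
#' @param ellipse an \code{\link{ellipse_fit}}.
#' @param dim integer (rows, cols) of the target grid.
#' @return logical matrix.
#' @export
rasterize_ellipse <- function(ellipse, dim) {
  stopifnot(inherits(ellipse, "ellipse_fit"))
  dx <- matrix(seq_len(dim[1]) - ellipse$center[1], dim[1], dim[2])
  dy <- matrix(rep(seq_len(dim[2]) - ellipse$center[2], each = dim[1]),
               dim[1], dim[2])
  co <- cos(ellipse$orientation); si <- sin(ellipse$orientation)
  u <- co * dx + si * dy
  v <- -si * dx + co * dy
  (u / ellipse$semi_major)^2 + (v / ellipse$semi_minor)^2 <= 1
}

#' Ellipse symmetric-difference roughness
#'
#' The roughness score of a spheroid: fit an ellipse to the mask and add the
#' area of the spheroid outside the ellipse to the area of the ellipse not
#' covered by the spheroid (the symmetric difference, evaluated on the
#' pixel grid with the ellipse rasterized at mask resolution).  A perfectly
#' elliptical spheroid scores (near) zero; boundary irregularity grows the
#' score.  The normalized form divides by the mask area and is the default
#' for group comparisons since it is size-free.
#'
#' @param mask a \code{\link{binary_mask}} or logical matrix.
#' @param ellipse optional \code{\link{ellipse_fit}}; fitted from the mask
#'   when missing.
#' @return list with \code{roughness_raw} (physical units^2) and
#'   \code{roughness_norm} (dimensionless).
#' @export
roughness <- function(mask, ellipse = NULL) {
  px <- .as_pixels(mask)
  if (is.null(ellipse)) ellipse <- fit_ellipse(px)
  er <- rasterize_ellipse(ellipse, dim(px))
  raw_px <- sum(xor(px, er))
  list(roughness_raw = raw_px * .pixel_size(mask)^2,
       roughness_norm = raw_px / sum(px))
}

#' Full morphometric record of one spheroid
#'
#' Runs the complete shape pipeline: segmentation (when a grayscale image is
#' supplied), area, perimeter, circularity, moment ellipse fit and
#' symmetric-difference roughness.
#'
#' @param x grayscale image, logical matrix or \code{\link{binary_mask}}.
#' @param threshold,min_size,fill_holes segmentation settings, see
#'   \code{\link{segment_spheroid}}.
#' @param pixel_size physical length per pixel.
#' @return one-row data.frame with columns \code{area}, \code{perimeter},
#'   \code{circularity}, \code{ellipse_center_row}, \code{ellipse_center_col},
#'   \code{semi_major}, \code{semi_minor}, \code{orientation},
#'   \code{roughness_raw}, \code{roughness_norm}.
#' @export
morphometrics <- function(x, threshold = "otsu", min_size = 50,
                          fill_holes = TRUE, pixel_size = 1) {
  mask <- if (inherits(x, "binary_mask")) x
  else if (is.matrix(x) && is.logical(x)) binary_mask(x, pixel_size)
  else segment_spheroid(x, threshold = threshold, min_size = min_size,
                        fill_holes = fill_holes, pixel_size = pixel_size)
  a <- measure_area(mask)
  p <- measure_perimeter(mask)
  ell <- fit_ellipse(mask)
  rg <- roughness(mask, ell)
  data.frame(area = a, perimeter = p, circularity = circularity(a, p),
             ellipse_center_row = ell$center[1],
             ellipse_center_col = ell$center[2],
             semi_major = ell$semi_major, semi_minor = ell$semi_minor,
             orientation = ell$orientation,
             roughness_raw = rg$roughness_raw,
             roughness_norm = rg$roughness_norm)
}
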