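#' Quantify scratch-wound closure from cell-free masks
#'
#' Given the cell-free zone at scratch time and at a later time point,
#' computes the newly occupied area (initial free area minus remaining free
#' area) and the closure fraction.  Cells occasionally retract, making the
#' free zone grow; the newly occupied area is then clamped to 0 with a
#' warning.
#'
#' @param mask_free_t0,mask_free_t logical matrices (or
#'   \code{\link{binary_mask}}s) of the cell-free zone, same shape;
#'   \code{TRUE} = cell-free.
#' @param elapsed elapsed time in hours (metadata).
#' @return one-row data.frame with \code{free_area_t0}, \code{free_area_t},
#'   \code{newly_occupied}, \code{closure_fraction}, \code{elapsed_h}.
#' @export
scratch_closure <- function(mask_free_t0, mask_free_t, elapsed = NA_real_) {
  p0 <- if (inherits(mask_free_t0, "binary_mask")) mask_free_t0$pixels else mask_free_t0
  p1 <- if (inherits(mask_free_t, "binary_mask")) mask_free_t$pixels else mask_free_t
  if (!identical(dim(p0), dim(p1))) stop("masks have mismatched shapes")
  a0 <- sum(p0); a1 <- sum(p1)
  if (a0 == 0) stop("empty cell-free zone at t0")
  newly <- a0 - a1
  if (newly < 0) {
    warning("free zone grew between time points; clamping newly occupied area to 0")
    newly <- 0
  }
  data.frame(free_area_t0 = a0, free_area_t = a1, newly_occupied = newly,
             closure_fraction = newly / a0, elapsed_h = elapsed)
}

# local variance of an image via box-filter moments
.local_variance <- function(img, window) {
  k <- matrix(1 / window^2, window, window)
  m1 <- imageData(filter2(Image(img), k, boundary = "replicate"))
  m2 <- imageData(filter2(Image(img^2), k, boundary = "replicate"))
  pmax(m2 - m1^2, 0)
}

#' Segment the cell-free band of a scratch-assay image
#'
#' Cell-covered regions are textured while the scratch zone is optically
#' flat, so the cell-free band is recovered as the largest connected
#' component of low local variance.  The variance threshold defaults to
#' Otsu's threshold on the local-SD image.
#'
#' @param image 2-D grayscale image.
#' @param window box window side for the local-variance filter, pixels.
#' @param variance_threshold fixed threshold on local variance, or
#'   \code{NULL} for the Otsu default.
#' @return a \code{\link{binary_mask}} of the cell-free zone.
#' @export
segment_free_zone <- function(image, window = 15, variance_threshold = NULL) {
  img <- .as_gray(image)
  if (max(img) - min(img) < 1e-12) stop("cannot segment a constant image")
  lv <- .local_variance(img, window)
  thr <- if (is.null(variance_threshold)) otsu(Image(sqrt(lv) / max(sqrt(lv))))^2 * max(lv)
  else variance_threshold
  low <- lv <= thr
  if (!any(low)) stop("no cell-free band found")
  lab <- imageData(bwlabel(Image(low * 1)))
  sizes <- tabulate(lab[lab > 0])
  binary_mask(lab == which.max(sizes))
}

#' Count invading cells on a stained membrane image
#'
#' Thresholds the stained image and counts connected components at least
#' \code{spot_min_area} pixels in size, emulating manual counting of
#' Giemsa-stained cells on a transwell membrane.
#'
#' @param image 2-D grayscale image, stained cells bright.
#' @param spot_min_area minimum spot size, pixels^2.
#' @param threshold \code{"otsu"} or fixed numeric threshold.
#' @return integer cell count.
#' @export
count_invading_cells <- function(image, spot_min_area = 20,
                                 threshold = "otsu") {
  img <- .as_gray(image)
  if (max(img) - min(img) < 1e-12) stop("cannot threshold a constant image")
  thr <- if (identical(threshold, "otsu")) otsu(Image(img)) else threshold
  lab <- imageData(bwlabel(Image((img > thr) * 1)))
  sizes <- tabulate(lab[lab > 0])
  sum(sizes >= spot_min_area)
}

#' Welch two-sample comparison with asterisk annotation
#'
#' Two-sided Welch (unequal-variance) comparison of two groups, reported as
#' the study reports assays: per-group mean and SD, the test statistic and
#' p value, and the conventional annotation (\code{""}, \code{"*"},
#' \code{"**"} for p below 0.05 and 0.01).  Degenerate zero-variance inputs
#' use the conventions p = 1 when both groups are constant and equal, and
#' p = 0 (with a warning) when constant but different.
#'
#' @param a,b numeric vectors, each of length >= 2, finite.
#' @param label_a,label_b group labels for the report.
#' @return object of class \code{assay_summary}: list with \code{groups}
#'   (data.frame of n / mean / sd), \code{statistic}, \code{df},
#'   \code{p_value}, \code{annotation}.
#' @export
compare_groups <- function(a, b, label_a = "A", label_b = "B") {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  if (!all(is.finite(c(a, b)))) stop("values must be finite")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      stat <- 0; df <- NA_real_; p <- 1
    } else {
      warning("zero variance in both groups with different means; p -> 0")
      stat <- Inf * sign(mean(a) - mean(b)); df <- NA_real_; p <- 0
    }
  } else {
    tt <- t.test(a, b, var.equal = FALSE)
    stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  ann <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  structure(list(
    groups = data.frame(group = c(label_a, label_b),
                        n = c(length(a), length(b)),
                        mean = c(mean(a), mean(b)),
                        sd = c(sd(a), sd(b)),
                        stringsAsFactors = FALSE),
    statistic = stat, df = df, p_value = p, annotation = ann
  ), class = "assay_summary")
}

#' @export
print.assay_summary <- function(x, ...) {
  g <- x$groups
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %s: n=%d, mean %.3g +/- %.3g SD\n",
                g$group[i], g$n[i], g$mean[i], g$sd[i]))
  cat(sprintf("  Welch t = %.3g, p = %.3g %s\n", x$statistic, x$p_value,
              x$annotation))
  invisible(x)
}

#' Summarize microfluidic passing times
#'
#' Per-group mean +/- SD and histogram counts of per-cell channel passing
#' times; with exactly two groups a Welch comparison is attached.
#' Histogram bins are fixed-width from 0 to the pooled 99th percentile
#' (times above the last edge are not counted).
#'
#' @param times data.frame with columns \code{group} and \code{time_s}
#'   (seconds, > 0).
#' @param bins number of histogram bins.
#' @return list with \code{summary} (per-group n/mean/sd data.frame),
#'   \code{histogram} (data.frame: group, bin_lo, bin_hi, count) and
#'   \code{comparison} (an \code{assay_summary}, or \code{NULL} unless
#'   exactly two groups).
#' @export
passing_time_summary <- function(times, bins = 20) {
  stopifnot(all(c("group", "time_s") %in% names(times)))
  if (any(times$time_s <= 0)) stop("passing times must be > 0")
  ns <- table(times$group)
  if (any(ns < 2)) stop("need >= 2 cells per group")
  smry <- do.call(rbind, lapply(split(times$time_s, times$group), function(v)
    data.frame(n = length(v), mean = mean(v), sd = sd(v))))
  smry <- cbind(group = rownames(smry), smry, stringsAsFactors = FALSE)
  rownames(smry) <- NULL

  edges <- seq(0, quantile(times$time_s, 0.99), length.out = bins + 1)
  hist_df <- do.call(rbind, lapply(split(times$time_s, times$group),
    function(v) {
      cts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                      nbins = bins + 1)[seq_len(bins)]
      data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                 count = cts)
    }))
  hist_df <- cbind(group = rep(smry$group, each = bins), hist_df)
  rownames(hist_df) <- NULL

  cmp <- NULL
  if (length(ns) == 2) {
    gs <- names(ns)
    cmp <- compare_groups(times$time_s[times$group == gs[1]],
                          times$time_s[times$group == gs[2]],
                          gs[1], gs[2])
  }
  list(summary = smry, histogram = hist_df, comparison = cmp)
}
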