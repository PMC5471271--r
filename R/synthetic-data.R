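#' Simulate a three-group log2 expression matrix with planted marker genes
#'
#' Generates a genes x samples matrix of log2 expression values for the three
#' cell groups of the study design (\code{parental}, \code{TMD}, \code{BMD})
#' with i.i.d. Gaussian noise on the log2 scale.  Two kinds of signal genes
#' can be planted:
#' \itemize{
#'   \item \emph{axis genes}, whose true mean differs between TMD and BMD by
#'     a signed effect (log2 units) while the parental mean sits at the
#'     baseline -- these drive the TMD--BMD contrast picked up by the
#'     metastasis axis;
#'   \item \emph{PC1 genes}, with a monotone parental < TMD < BMD trend that
#'     spreads the three groups along the first principal component.
#' }
#' All remaining genes share one mean across groups.  The ground truth
#' (planted gene ids, signed effects, true group means, noise SD) is
#' returned alongside the matrix so tests can score recovery; downstream
#' analysis code must never read it.
#'
#' @param n_genes total number of genes (>= 10).
#' @param n_reps_per_group replicates per group (>= 2); the study design is 3.
#' @param axis_effects numeric vector of signed TMD-minus-BMD effects, one
#'   planted axis gene each (log2 units).  May be empty.
#' @param pc1_effects numeric vector of BMD-minus-parental spans for planted
#'   monotone-trend genes (log2 units).  May be empty.
#' @param noise_sd Gaussian noise SD on the log2 scale (>= 0).
#' @param baseline baseline log2 expression level of every gene.
#' @param seed integer seed; mandatory, the generator is a pure function of
#'   its arguments and the seed.
#' @return A list with components \code{matrix} (an
#'   \code{\link{expression_matrix}}) and \code{truth} (list with
#'   \code{planted_axis_genes}, \code{planted_pc1_genes}, \code{noise_sd},
#'   \code{group_means}).
#' @examples
#' sim <- gen_expression(100, 3, axis_effects = c(2, -2), seed = 1)
#' dim(sim$matrix$values)
#' @export
gen_expression <- function(n_genes, n_reps_per_group = 3,
                           axis_effects = numeric(0),
                           pc1_effects = numeric(0),
                           noise_sd = 0.5, baseline = 8, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (n_genes < 10) stop("'n_genes' must be >= 10")
  if (n_reps_per_group < 2) stop("'n_reps_per_group' must be >= 2")
  if (!all(is.finite(axis_effects)) || !all(is.finite(pc1_effects)))
    stop("planted effects must be finite")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  n_axis <- length(axis_effects)
  n_pc1 <- length(pc1_effects)
  if (n_axis + n_pc1 > n_genes)
    stop("more planted genes than total genes")

  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  axis_ids <- if (n_axis) gene_ids[seq_len(n_axis)] else character(0)
  pc1_ids <- if (n_pc1) gene_ids[n_axis + seq_len(n_pc1)] else character(0)

  group_levels <- c("parental", "TMD", "BMD")
  groups <- rep(group_levels, each = n_reps_per_group)
  sample_ids <- paste0(tolower(groups), "_", rep(seq_len(n_reps_per_group), 3))
  names(groups) <- sample_ids

  # true group means: baseline everywhere, then plant the signals
  mu <- matrix(baseline, n_genes, 3, dimnames = list(gene_ids, group_levels))
  if (n_axis) {
    mu[axis_ids, "TMD"] <- baseline + axis_effects / 2
    mu[axis_ids, "BMD"] <- baseline - axis_effects / 2
  }
  if (n_pc1) {
    mu[pc1_ids, "parental"] <- baseline - pc1_effects / 2
    mu[pc1_ids, "BMD"] <- baseline + pc1_effects / 2
  }

  vals <- withr::with_seed(seed, {
    m <- mu[, match(groups, group_levels), drop = FALSE]
    m + rnorm(length(m), sd = noise_sd)
  })
  dimnames(vals) <- list(gene_ids, sample_ids)

  truth <- list(
    planted_axis_genes = setNames(axis_effects, axis_ids),
    planted_pc1_genes = setNames(pc1_effects, pc1_ids),
    noise_sd = noise_sd,
    group_means = mu
  )
  list(matrix = expression_matrix(vals, groups), truth = truth)
}

#' Describe a synthetic spheroid boundary
#'
#' The boundary model is an ellipse modulated by low-order Fourier
#' harmonics: in polar coordinates about \code{center},
#' \deqn{r(\theta) = e(\theta)\,\bigl(1 + \sum_k a_k \cos(k\theta + \phi_k)\bigr)}
#' where \eqn{e(\theta)} is the radial profile of an area-preserving ellipse
#' with semi-axes \code{base_radius * sqrt(axis_ratio)} and
#' \code{base_radius / sqrt(axis_ratio)}.  Harmonic amplitudes are the
#' roughness dial: the roughness score is defined as deviation from a fitted
#' ellipse, so amplitude 0 gives a (near-)zero score and larger amplitudes
#' strictly larger scores.
#'
#' @param base_radius radius scale in pixels (>= 5).
#' @param axis_ratio ellipse major/minor axis ratio (>= 1).
#' @param orientation major-axis angle, radians.
#' @param harmonics data.frame with columns \code{k} (integer order),
#'   \code{amplitude} and \code{phase}; \code{sum(abs(amplitude))} must be
#'   < 1 so the boundary stays star-shaped.
#' @param center length-2 pixel coordinates (row, col), or \code{NULL} for
#'   the image center.
#' @return An object of class \code{spheroid_truth}.
#' @export
spheroid_truth <- function(base_radius, axis_ratio = 1, orientation = 0,
                           harmonics = data.frame(k = integer(0),
                                                  amplitude = numeric(0),
                                                  phase = numeric(0)),
                           center = NULL) {
  if (base_radius < 5) stop("'base_radius' must be >= 5 pixels")
  if (axis_ratio < 1) stop("'axis_ratio' must be >= 1")
  stopifnot(all(c("k", "amplitude", "phase") %in% names(harmonics)))
  if (sum(abs(harmonics$amplitude)) >= 1)
    stop("sum of |harmonic amplitudes| must be < 1 (star-shaped boundary)")
  structure(list(base_radius = base_radius, axis_ratio = axis_ratio,
                 orientation = orientation, harmonics = harmonics,
                 center = center),
            class = "spheroid_truth")
}

# polar boundary radius at angles theta (absolute image angles)
.spheroid_radius <- function(truth, theta) {
  a <- truth$base_radius * sqrt(truth$axis_ratio)
  b <- truth$base_radius / sqrt(truth$axis_ratio)
  th <- theta - truth$orientation
  ell <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  mod <- rep(1, length(theta))
  h <- truth$harmonics
  for (i in seq_len(nrow(h)))
    mod <- mod + h$amplitude[i] * cos(h$k[i] * theta + h$phase[i])
  ell * mod
}

#' Render a synthetic spheroid image and its reference mask
#'
#' Rasterizes the star-shaped boundary of a \code{\link{spheroid_truth}} on
#' a pixel grid (pixel centers at integer coordinates, origin top-left) and
#' produces a grayscale image with foreground/background contrast plus
#' additive Gaussian noise, clipped to [0, 1].
#'
#' @param truth a \code{\link{spheroid_truth}}.
#' @param image_shape integer (rows, cols) of the output image.
#' @param noise_level additive Gaussian noise SD on the [0, 1] intensity
#'   scale.
#' @param seed integer seed (required when \code{noise_level > 0}).
#' @param fg,bg foreground / background intensities.
#' @return list with \code{image} (numeric matrix in [0,1]), \code{mask}
#'   (the rasterized interior, a \code{\link{binary_mask}}) and
#'   \code{truth}.
#' @export
gen_spheroid_image <- function(truth, image_shape = c(192, 192),
                               noise_level = 0.05, seed = NULL,
                               fg = 0.8, bg = 0.2) {
  stopifnot(inherits(truth, "spheroid_truth"))
  if (noise_level > 0 && is.null(seed)) stop("'seed' is required when noise_level > 0")
  nr <- image_shape[1]; nc <- image_shape[2]
  ctr <- truth$center
  if (is.null(ctr)) ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  rmax <- truth$base_radius * sqrt(truth$axis_ratio) *
    (1 + sum(abs(truth$harmonics$amplitude)))
  if (ctr[1] - rmax < 1 || ctr[1] + rmax > nr ||
      ctr[2] - rmax < 1 || ctr[2] + rmax > nc)
    stop("spheroid boundary exits the image frame")
  rmin <- truth$base_radius / sqrt(truth$axis_ratio) *
    (1 - sum(abs(truth$harmonics$amplitude)))
  if (rmin < 2) stop("boundary radius drops below 2 px; reduce amplitudes or axis_ratio")

  dx <- matrix(seq_len(nr) - ctr[1], nr, nc)
  dy <- matrix(rep(seq_len(nc) - ctr[2], each = nr), nr, nc)
  theta <- atan2(dy, dx)
  rr <- sqrt(dx^2 + dy^2)
  mask <- rr <= .spheroid_radius(truth, theta)

  img <- ifelse(mask, fg, bg)
  if (noise_level > 0)
    img <- img + withr::with_seed(seed, rnorm(length(img), sd = noise_level))
  img <- matrix(pmin(1, pmax(0, img)), nr, nc)
  list(image = img, mask = binary_mask(mask), truth = truth)
}

#' Generate a scratch-assay mask pair with known closure
#'
#' Emulates a wound-healing scratch assay: a vertical cell-free band of the
#' stated width at time 0, partially re-occupied by cells at time t.  Masks
#' are \code{TRUE} in the cell-free zone.  The band shrinks symmetrically so
#' that the remaining cell-free area is \code{(1 - closure_fraction)} times
#' the initial one, up to whole-pixel rasterization.
#'
#' @param frame_shape integer (rows, cols).
#' @param scratch_width initial band width in pixels.
#' @param closure_fraction fraction of the band re-occupied at time t, in
#'   [0, 1].
#' @param seed integer seed (reserved; the band itself is deterministic).
#' @return list with logical matrices \code{t0} and \code{t}.
#' @export
gen_scratch_pair <- function(frame_shape = c(200, 300), scratch_width = 120,
                             closure_fraction, seed = NULL) {
  if (closure_fraction < 0 || closure_fraction > 1)
    stop("'closure_fraction' must be in [0, 1]")
  nr <- frame_shape[1]; nc <- frame_shape[2]
  if (scratch_width > nc) stop("scratch wider than frame")
  band_cols <- function(width) {
    if (width <= 0) return(integer(0))
    lo <- floor((nc - width) / 2) + 1
    seq(lo, lo + width - 1)
  }
  t0 <- matrix(FALSE, nr, nc); t0[, band_cols(scratch_width)] <- TRUE
  wt <- round(scratch_width * (1 - closure_fraction))
  tt <- matrix(FALSE, nr, nc); tt[, band_cols(wt)] <- TRUE
  list(t0 = t0, t = tt)
}

#' Render a textured microscopy-like image from a cell-free mask
#'
#' Cell-covered regions get high-variance speckle texture; the cell-free
#' zone is nearly flat.  Used to exercise local-variance segmentation.
#'
#' @param free_mask logical matrix, \code{TRUE} = cell-free.
#' @param cell_texture_sd texture SD of the cell-covered region.
#' @param free_sd residual noise SD in the cell-free zone.
#' @param seed integer seed.
#' @return numeric matrix in [0, 1].
#' @export
gen_scratch_image <- function(free_mask, cell_texture_sd = 0.18,
                              free_sd = 0.01, seed) {
  if (missing(seed)) stop("'seed' is required")
  withr::with_seed(seed, {
    img <- matrix(0.5, nrow(free_mask), ncol(free_mask))
    img[!free_mask] <- 0.5 + rnorm(sum(!free_mask), sd = cell_texture_sd)
    img[free_mask] <- 0.5 + rnorm(sum(free_mask), sd = free_sd)
    matrix(pmin(1, pmax(0, img)), nrow(free_mask), ncol(free_mask))
  })
}

#' Generate an image of disjoint stained cell spots
#'
#' Emulates a stained transwell-membrane field for invasion counting:
#' \code{n_spots} bright discs on a dark background.  Centers are sampled
#' uniformly; with the default minimum separation spots rarely touch.
#'
#' @param n_spots number of cells.
#' @param frame_shape integer (rows, cols).
#' @param radius_range disc radius range in pixels.
#' @param min_sep minimum center separation (pixels); 0 allows overlap.
#' @param seed integer seed.
#' @return list with \code{image} (numeric [0,1]) and \code{centers}.
#' @export
gen_invasion_image <- function(n_spots, frame_shape = c(256, 256),
                               radius_range = c(3, 5), min_sep = 14, seed) {
  if (missing(seed)) stop("'seed' is required")
  nr <- frame_shape[1]; nc <- frame_shape[2]
  withr::with_seed(seed, {
    centers <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(centers) < n_spots && tries < n_spots * 400) {
      tries <- tries + 1
      p <- c(runif(1, 8, nr - 8), runif(1, 8, nc - 8))
      if (nrow(centers) == 0 ||
          min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)) >= min_sep)
        centers <- rbind(centers, p)
    }
    if (nrow(centers) < n_spots)
      stop("could not place all spots; enlarge frame or reduce min_sep")
    radii <- runif(n_spots, radius_range[1], radius_range[2])
    img <- matrix(0.1, nr, nc)
    xs <- matrix(seq_len(nr), nr, nc)
    ys <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    for (i in seq_len(n_spots))
      img[(xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <= radii[i]^2] <- 0.9
    list(image = img, centers = centers)
  })
}

.aa_letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

#' Generate an annotated variant table
#'
#' Emits a table in the annotated-variant dialect used throughout the
#' package (tab-separated, columns \code{symbol}, \code{description},
#' \code{allele_freq}, \code{base_change}, \code{aa_change}; allele
#' frequency printed with 2 decimals; premature stop spelled \code{stop}):
#' \code{n_stopgain} stop-gain rows plus \code{n_missense} single-residue
#' substitutions, allele frequencies uniform in \code{af_range}.
#'
#' @param n_stopgain,n_missense non-negative row counts.
#' @param af_range allele-frequency range, within [0, 1].
#' @param seed integer seed.
#' @param path optional file path; when given the table is written as TSV.
#' @return the variant data.frame (invisibly when \code{path} is given).
#' @export
gen_variant_table <- function(n_stopgain, n_missense, af_range = c(0, 1),
                              seed, path = NULL) {
  if (missing(seed)) stop("'seed' is required")
  if (n_stopgain < 0 || n_missense < 0) stop("counts must be non-negative")
  if (af_range[1] < 0 || af_range[2] > 1 || af_range[1] > af_range[2])
    stop("'af_range' must satisfy 0 <= low <= high <= 1")
  n <- n_stopgain + n_missense
  if (n == 0) {
    tab <- data.frame(symbol = character(0), description = character(0),
                      allele_freq = numeric(0), base_change = character(0),
                      aa_change = character(0))
    if (!is.null(path)) {
      write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
      return(invisible(tab))
    }
    return(tab)
  }
  tab <- withr::with_seed(seed, {
    base_from <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    base_to <- vapply(base_from, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    aa_from <- sample(.aa_letters, n, replace = TRUE)
    aa_to <- c(rep("stop", n_stopgain),
               vapply(seq_len(n_missense), function(i)
                 sample(setdiff(.aa_letters, aa_from[n_stopgain + i]), 1), ""))
    data.frame(
      symbol = sprintf("SYN%04d", seq_len(n)),
      description = sprintf("synthetic gene %d", seq_len(n)),
      allele_freq = round(runif(n, af_range[1], af_range[2]), 2),
      base_change = paste0(base_from, "/", base_to),
      aa_change = paste0(aa_from, "/", aa_to),
      stringsAsFactors = FALSE
    )
  })
  if (!is.null(path)) {
    write.table(format(tab, nsmall = 2, trim = TRUE), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Simulate microfluidic passing times
#'
#' Draws per-cell channel passing times from a log-normal family:
#' \code{time = location * exp(scale * Z)} with standard-normal \code{Z}, so
#' times are strictly positive and right-skewed, the location parameter is
#' the median time and scale 0 is degenerate at the location.
#'
#' @param n_per_group cells per group (>= 2).
#' @param group_params named list, one element per group, each
#'   \code{c(location = seconds, scale = dimensionless)}.
#' @param seed integer seed.
#' @return data.frame with columns \code{group} and \code{time_s}.
#' @export
gen_passing_times <- function(n_per_group = 50,
                              group_params = list(
                                control = c(location = 10, scale = 0.6),
                                treated = c(location = 20, scale = 0.6)),
                              seed) {
  if (missing(seed)) stop("'seed' is required")
  if (n_per_group < 2) stop("'n_per_group' must be >= 2")
  locs <- vapply(group_params, `[[`, 0, "location")
  scls <- vapply(group_params, `[[`, 0, "scale")
  if (any(locs <= 0) || any(scls < 0)) stop("locations must be > 0 and scales >= 0")
  withr::with_seed(seed, {
    times <- unlist(lapply(seq_along(group_params), function(i)
      locs[i] * exp(scls[i] * rnorm(n_per_group))), use.names = FALSE)
    data.frame(group = rep(names(group_params), each = n_per_group),
               time_s = times, stringsAsFactors = FALSE)
  })
}
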