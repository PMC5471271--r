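#' Path to the packaged BMD mutation table
#'
#' The annotated somatic variants called in BMD cells against the TMD
#' reference (4 stop-gains and 21 amino-acid substitutions), transcribed
#' cell-for-cell from the study's printed mutation table into the package's
#' TSV dialect.  One gene symbol containing a typographic dash in print
#' (KRTAP4-12) is transcribed with an ASCII hyphen.
#'
#' @return path to the TSV fixture.
#' @export
bmd_variant_table_path <- function() {
  system.file("extdata", "bmd_variants_table1.tsv", package = "metastaxis",
              mustWork = TRUE)
}

#' Build a run configuration
#'
#' Collects every tunable stage parameter with its default.  Unknown names
#' are rejected so typos fail loudly.  Configurations round-trip through
#' YAML unchanged via \code{\link{write_run_config}} /
#' \code{\link{read_run_config}}.
#'
#' @param ... named overrides of the defaults.
#' @return named list of class \code{run_config}.
#' @export
run_config <- function(...) {
  defaults <- list(
    k_per_end = 10,            # genes kept per metastasis-axis end
    axis_from = "BMD", axis_to = "TMD",
    threshold = "otsu",        # spheroid / invasion threshold method
    min_size = 50,             # px^2, smallest particle kept
    fill_holes = TRUE,
    pixel_size = 1,
    spot_min_area = 20,        # px^2, invasion spot size floor
    variance_window = 15,      # px, scratch local-variance window
    bins = 20,                 # passing-time histogram bins
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param config a \code{run_config}.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Write / read an expression matrix as TSV
#'
#' The on-disk dialect: a genes x samples TSV whose first column
#' (\code{gene_id}) holds gene ids, plus a two-column sidecar TSV
#' (\code{sample_id}, \code{group}) mapping samples to groups.
#'
#' @param X an \code{\link{expression_matrix}}.
#' @param path,group_path paths of the matrix TSV and group-map TSV.
#' @return \code{write_expression_tsv} the paths invisibly;
#'   \code{read_expression_tsv} an \code{expression_matrix}.
#' @export
write_expression_tsv <- function(X, path, group_path) {
  stopifnot(inherits(X, "expression_matrix"))
  df <- data.frame(gene_id = X$gene_ids, X$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = X$sample_ids, group = unname(X$groups)),
              group_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, group_path))
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, group_path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be 'gene_id'")
  gm <- read.delim(group_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(gm)))
    stop("group map needs columns 'sample_id' and 'group'")
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$gene_id
  expression_matrix(vals, setNames(gm$group, gm$sample_id))
}

#' Read / write grayscale images and masks
#'
#' Thin wrappers over the EBImage PNG/TIFF readers returning plain numeric
#' matrices in [0, 1] (first channel of color images).
#'
#' @param path image file path.
#' @return numeric matrix (\code{read_gray_image}) or logical matrix
#'   (\code{read_mask}).
#' @export
read_gray_image <- function(path) .as_gray(readImage(path))

#' @rdname read_gray_image
#' @export
read_mask <- function(path) read_gray_image(path) > 0.5

#' @rdname read_gray_image
#' @param x numeric matrix in [0, 1] or logical matrix.
#' @export
write_gray_image <- function(x, path) {
  writeImage(Image(x * 1), path)
  invisible(path)
}

#' Run the metastasis-axis stage end to end
#'
#' Decomposes the expression matrix, sets the metastasis axis between the
#' configured group centroids, projects all genes into the rotated frame
#' and selects the extreme candidates.  When \code{out_dir} is given, writes
#' \code{axis_scores.tsv} (gene_id, coord_pc1deg, coord_pc2deg, rank,
#' direction) and \code{axis_model.json} (singular values, variance
#' explained, centroids, axis, angle, selection size).
#'
#' @param X an \code{\link{expression_matrix}}, or a length-2 character
#'   vector of (matrix TSV, group-map TSV) paths.
#' @param config a \code{\link{run_config}}.
#' @param out_dir optional output directory (created if needed).
#' @return list with \code{model}, \code{scores}, \code{selection}.
#' @export
run_axis <- function(X, config = run_config(), out_dir = NULL) {
  if (is.character(X)) {
    if (length(X) != 2) stop("character input must be c(matrix_tsv, group_map_tsv)")
    X <- read_expression_tsv(X[1], X[2])
  }
  model <- center_and_decompose(X)
  model <- compute_metastasis_axis(model, config$axis_from, config$axis_to)
  scores <- project_genes(model)
  sel <- select_extreme_genes(scores, config$k_per_end)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(scores, file.path(out_dir, "axis_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
      singular_values = model$singular_values[1:2],
      variance_explained = model$variance_explained[1:2],
      centroids = as.data.frame(model$centroids),
      axis = model$axis, axis_angle_deg = model$axis_angle_deg,
      selection_size = nrow(sel)
    ), file.path(out_dir, "axis_model.json"), auto_unbox = TRUE, digits = NA)
  }
  list(model = model, scores = scores, selection = sel)
}

#' Run spheroid morphometrics over a set of images
#'
#' Computes one \code{\link{morphometrics}} record per input; per-image
#' failures are caught, reported and do not stop the run.  With a group
#' label per image and at least two groups, area, circularity and
#' normalized roughness are compared between the first two group levels.
#'
#' @param inputs a named list of images/masks, or a character vector of
#'   image paths (names / file names become image ids).
#' @param groups optional character vector of group labels, parallel to
#'   \code{inputs}.
#' @param config a \code{\link{run_config}}.
#' @param out_dir optional output directory; writes
#'   \code{morphometrics.csv}.
#' @return list with \code{records} (data.frame, one row per successful
#'   image, with \code{image_id} and optional \code{group}),
#'   \code{failures} (named character vector of error messages) and
#'   \code{comparisons} (named list of \code{assay_summary}, or NULL).
#' @export
run_morphometrics <- function(inputs, groups = NULL, config = run_config(),
                              out_dir = NULL) {
  if (is.character(inputs)) {
    nm <- if (!is.null(names(inputs))) names(inputs) else basename(inputs)
    inputs <- setNames(lapply(inputs, read_gray_image), nm)
  }
  if (length(inputs) == 0) stop("no input images")
  if (is.null(names(inputs)))
    names(inputs) <- sprintf("image_%03d", seq_along(inputs))
  recs <- list(); fails <- character(0)
  for (id in names(inputs)) {
    r <- tryCatch(
      morphometrics(inputs[[id]], threshold = config$threshold,
                    min_size = config$min_size,
                    fill_holes = config$fill_holes,
                    pixel_size = config$pixel_size),
      error = function(e) conditionMessage(e))
    if (is.character(r)) fails[id] <- r
    else recs[[id]] <- cbind(image_id = id, r)
  }
  records <- if (length(recs)) do.call(rbind, recs) else NULL
  if (!is.null(records)) rownames(records) <- NULL
  comparisons <- NULL
  if (!is.null(records) && !is.null(groups)) {
    g <- groups[match(records$image_id, names(inputs))]
    records$group <- g
    lv <- unique(g)
    if (length(lv) >= 2) {
      comparisons <- lapply(c("area", "circularity", "roughness_norm"),
        function(metric) compare_groups(records[[metric]][g == lv[1]],
                                        records[[metric]][g == lv[2]],
                                        lv[1], lv[2]))
      names(comparisons) <- c("area", "circularity", "roughness_norm")
    }
  }
  if (!is.null(out_dir) && !is.null(records)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(records, file.path(out_dir, "morphometrics.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
  }
  list(records = records, failures = fails, comparisons = comparisons)
}

#' Run the variant filtering stage
#'
#' Reads an annotated variant TSV, keeps stop-gain and missense records (by
#' default), and summarizes counts and allele frequencies.  When
#' \code{out_dir} is given, writes \code{variants_filtered.tsv} and
#' \code{variant_counts.json} (per-class totals plus allele-frequency
#' min/max of the kept records).
#'
#' @param path variant TSV path (see \code{\link{read_variant_table}}).
#' @param classes,min_af filter settings, see \code{\link{filter_and_count}}.
#' @param out_dir optional output directory.
#' @return list with \code{records}, \code{counts}, \code{af} (min/max/mean
#'   of kept records, NULL when none kept).
#' @export
run_variants <- function(path, classes = c("stop_gain", "missense"),
                         min_af = 0, out_dir = NULL) {
  tab <- read_variant_table(path)
  fc <- filter_and_count(tab, classes = classes, min_af = min_af)
  af <- if (nrow(fc$records)) af_summary(fc$records) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(fc$records, file.path(out_dir, "variants_filtered.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(counts = as.list(fc$counts), af = af),
                         file.path(out_dir, "variant_counts.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(records = fc$records, counts = fc$counts, af = af)
}

#' Run a full synthetic study
#'
#' Generates a complete synthetic data set -- an expression matrix with
#' planted axis markers, TMD-like (large, rough) and BMD-like (small,
#' smooth) spheroid images, scratch pairs with higher closure for the
#' TMD-like condition, a variant table, and two-group passing times -- runs
#' every analysis stage on it, and writes a JSON + markdown report of the
#' qualitative findings (which end-to-end tests assert).
#'
#' @param seed integer master seed; every stage derives its own seed from
#'   it, so runs are reproducible bit-for-bit.
#' @param out_dir output directory (created).
#' @param n_genes,n_axis_genes expression simulation size.
#' @return list with per-stage results and \code{report} (named list of the
#'   qualitative findings).
#' @export
run_demo <- function(seed = 0, out_dir = tempfile("metastaxis_demo_"),
                     n_genes = 2000, n_axis_genes = 20) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run_config(seed = seed)

  # --- expression + metastasis axis ---------------------------------------
  effects <- rep(c(3, -3), length.out = n_axis_genes)
  effects[1] <- 4.5                      # one strongest TMD-high marker
  sim <- gen_expression(n_genes, 3, axis_effects = effects,
                        pc1_effects = rep(2, 10), noise_sd = 0.3,
                        seed = seed + 11L)
  axis_res <- run_axis(sim$matrix, cfg, out_dir = file.path(out_dir, "tables"))
  top_gene <- axis_res$scores$gene_id[1]
  planted <- names(sim$truth$planted_axis_genes)
  recall <- mean(planted %in%
    select_extreme_genes(axis_res$scores, n_axis_genes / 2)$gene_id)

  # --- spheroids: TMD-like rough/large vs BMD-like smooth/small -----------
  make_spheroids <- function(label, radius, amp, n, seed0) {
    lapply(seq_len(n), function(i) {
      h <- if (amp > 0) data.frame(k = 6, amplitude = amp, phase = 0.4 * i)
           else data.frame(k = integer(0), amplitude = numeric(0),
                           phase = numeric(0))
      gen_spheroid_image(spheroid_truth(radius + i - 1, harmonics = h),
                         image_shape = c(200, 200), noise_level = 0.05,
                         seed = seed0 + i)$image
    })
  }
  imgs <- c(make_spheroids("TMD", 55, 0.15, 6, seed + 100L),
            make_spheroids("BMD", 35, 0.0, 6, seed + 200L))
  names(imgs) <- c(sprintf("TMD_%d", 1:6), sprintf("BMD_%d", 1:6))
  sph_groups <- rep(c("TMD", "BMD"), each = 6)
  morph <- run_morphometrics(imgs, groups = sph_groups, config = cfg,
                             out_dir = file.path(out_dir, "tables"))
  mg <- split(morph$records, morph$records$group)

  # --- scratch closure: TMD-like closes faster ----------------------------
  closure <- vapply(c(TMD = 0.6, BMD = 0.25), function(cf) {
    pr <- gen_scratch_pair(closure_fraction = cf, seed = seed)
    scratch_closure(pr$t0, pr$t, elapsed = 10)$closure_fraction
  }, 0)

  # --- variants -----------------------------------------------------------
  vpath <- file.path(out_dir, "variants_synthetic.tsv")
  gen_variant_table(4, 21, af_range = c(0.2, 1), seed = seed + 300L,
                    path = vpath)
  vres <- run_variants(vpath, out_dir = file.path(out_dir, "tables"))

  # --- passing times ------------------------------------------------------
  pt <- gen_passing_times(50, seed = seed + 400L)
  pts <- passing_time_summary(pt)

  report <- list(
    seed = seed,
    top_axis_gene = top_gene,
    top_axis_gene_is_planted_marker = top_gene == planted[1],
    planted_gene_recall = recall,
    axis_angle_deg = axis_res$model$axis_angle_deg,
    tmd_mean_area = mean(mg$TMD$area),
    bmd_mean_area = mean(mg$BMD$area),
    tmd_mean_roughness_norm = mean(mg$TMD$roughness_norm),
    bmd_mean_roughness_norm = mean(mg$BMD$roughness_norm),
    tmd_mean_circularity = mean(mg$TMD$circularity),
    bmd_mean_circularity = mean(mg$BMD$circularity),
    roughness_annotation = morph$comparisons$roughness_norm$annotation,
    closure_tmd = unname(closure["TMD"]),
    closure_bmd = unname(closure["BMD"]),
    variant_counts = as.list(vres$counts),
    passing_time_p = pts$comparison$p_value
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  md <- c("# Synthetic study report",
          sprintf("- seed: %d", seed),
          sprintf("- top metastasis-axis gene: %s (planted marker: %s)",
                  top_gene, report$top_axis_gene_is_planted_marker),
          sprintf("- planted axis-gene recall: %.2f", recall),
          sprintf("- metastasis-axis angle from PC2: %.1f deg",
                  report$axis_angle_deg),
          sprintf("- spheroid area TMD-like vs BMD-like: %.0f vs %.0f px^2",
                  report$tmd_mean_area, report$bmd_mean_area),
          sprintf("- roughness_norm TMD-like vs BMD-like: %.3f vs %.3f (%s)",
                  report$tmd_mean_roughness_norm,
                  report$bmd_mean_roughness_norm,
                  report$roughness_annotation),
          sprintf("- scratch closure TMD-like vs BMD-like: %.2f vs %.2f",
                  report$closure_tmd, report$closure_bmd),
          sprintf("- variants kept: %d stop-gain, %d missense",
                  report$variant_counts$stop_gain,
                  report$variant_counts$missense),
          sprintf("- passing-time comparison p = %.3g", report$passing_time_p))
  writeLines(md, file.path(out_dir, "report.md"))
  list(axis = axis_res, morphometrics = morph, variants = vres,
       passing_times = pts, report = report, out_dir = out_dir)
}
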