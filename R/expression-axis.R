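#' Construct a validated expression matrix
#'
#' Container for a log2 genes x samples expression matrix with a
#' sample-to-group map.  Group labels are free-form but the canonical study
#' design uses \code{parental}, \code{TMD} and \code{BMD}.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   dimnames; no missing values.
#' @param groups named character vector mapping each sample id to its group;
#'   every group must have at least 2 samples.
#' @return object of class \code{expression_matrix} with fields
#'   \code{values}, \code{gene_ids}, \code{sample_ids}, \code{groups}.
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs gene row names and sample column names")
  if (anyDuplicated(rownames(values))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  if (!all(colnames(values) %in% names(groups)))
    stop("every sample needs a group label")
  groups <- groups[colnames(values)]
  if (any(table(groups) < 2)) stop("every group must have >= 2 samples")
  structure(list(values = values, gene_ids = rownames(values),
                 sample_ids = colnames(values), groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n  groups:",
      paste(sprintf("%s (n=%d)", names(table(x$groups)), table(x$groups)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Rank-2 decomposition of a gene-centered expression matrix
#'
#' Mean-centers each gene across samples and computes the singular value
#' decomposition of the centered matrix, keeping the first two components
#' (the PC1/PC2 plane in which samples and genes are jointly displayed).
#' Sample scores are the unit-norm right-singular directions; gene loadings
#' carry the singular values (\code{U \%*\% diag(d)}), so a gene's loading
#' magnitude reflects its contribution to between-sample covariance and the
#' product \code{loadings \%*\% t(scores)} is the best rank-2 approximation
#' of the centered matrix.
#'
#' SVD signs are fixed deterministically: PC1 is oriented so the parental
#' group centroid score does not exceed the BMD centroid score, and PC2 so
#' the TMD centroid score is at least the BMD one (falling back to a
#' largest-loading-positive rule when those groups are absent).
#'
#' @param X an \code{\link{expression_matrix}}.
#' @return object of class \code{plane_model} with sample scores, gene
#'   loadings, singular values, variance explained, per-group centroids in
#'   the score plane, and unset metastasis-axis fields.
#' @seealso \code{\link{compute_metastasis_axis}}, \code{\link{project_genes}}
#' @export
center_and_decompose <- function(X) {
  stopifnot(inherits(X, "expression_matrix"))
  V <- X$values
  if (nrow(V) < 2 || ncol(V) < 3) stop("need >= 2 genes and >= 3 samples")
  Xc <- V - rowMeans(V)
  if (max(abs(Xc)) < 1e-12)
    stop("degenerate decomposition: all gene rows are constant across samples")
  sv <- svd(Xc)
  d <- sv$d
  scores <- sv$v[, 1:2, drop = FALSE]
  loadings <- sv$u[, 1:2, drop = FALSE] %*% diag(d[1:2], 2)
  rownames(scores) <- X$sample_ids
  rownames(loadings) <- X$gene_ids
  colnames(scores) <- colnames(loadings) <- c("PC1", "PC2")

  centroid <- function(s) {
    t(vapply(split(seq_along(X$groups), X$groups),
             function(i) colMeans(s[i, , drop = FALSE]), numeric(2)))
  }
  cen <- centroid(scores)
  # deterministic sign convention
  flip <- c(FALSE, FALSE)
  if (all(c("parental", "BMD") %in% rownames(cen)))
    flip[1] <- cen["parental", 1] > cen["BMD", 1]
  else flip[1] <- loadings[which.max(abs(loadings[, 1])), 1] < 0
  if (all(c("TMD", "BMD") %in% rownames(cen)))
    flip[2] <- cen["TMD", 2] < cen["BMD", 2]
  else flip[2] <- loadings[which.max(abs(loadings[, 2])), 2] < 0
  for (j in 1:2) if (flip[j]) {
    scores[, j] <- -scores[, j]
    loadings[, j] <- -loadings[, j]
  }
  cen <- centroid(scores)

  structure(list(
    basis = scores,                 # orthonormal sample-space directions
    sample_scores = scores,
    gene_loadings = loadings,
    singular_values = d,
    variance_explained = d^2 / sum(d^2),
    centroids = cen,
    groups = X$groups,
    axis = NULL, axis_angle_deg = NULL,
    axis_from = NULL, axis_to = NULL
  ), class = "plane_model")
}

#' @export
print.plane_model <- function(x, ...) {
  cat("plane_model:", nrow(x$gene_loadings), "genes,",
      nrow(x$sample_scores), "samples\n")
  cat(sprintf("  variance explained: PC1 %.1f%%, PC2 %.1f%%\n",
              100 * x$variance_explained[1], 100 * x$variance_explained[2]))
  if (!is.null(x$axis))
    cat(sprintf("  metastasis axis: %s -> %s, %.1f deg from PC2\n",
                x$axis_from, x$axis_to, x$axis_angle_deg))
  invisible(x)
}

# acute angle (degrees) between a plane direction and the PC2 axis
.angle_from_diff <- function(d) {
  nrm <- sqrt(sum(d^2))
  acos(pmin(1, abs(d[2]) / nrm)) * 180 / pi
}

#' Set the metastasis axis of a plane model
#'
#' The metastasis axis is the unit vector in the PC1/PC2 sample plane
#' parallel to the line connecting the two group centroids, oriented from
#' \code{from_group} to \code{to_group} (default BMD to TMD, so a positive
#' projection marks the TMD-high end).  The reported angle is the acute
#' angle between this axis and the PC2 direction, in degrees.
#'
#' @param model a \code{plane_model} from \code{\link{center_and_decompose}}.
#' @param from_group,to_group group labels defining the axis direction.
#' @return the model with \code{axis} and \code{axis_angle_deg} set.
#' @export
compute_metastasis_axis <- function(model, from_group = "BMD",
                                    to_group = "TMD") {
  stopifnot(inherits(model, "plane_model"))
  cen <- model$centroids
  if (!all(c(from_group, to_group) %in% rownames(cen)))
    stop("both groups must be present in the model")
  d <- cen[to_group, ] - cen[from_group, ]
  nrm <- sqrt(sum(d^2))
  if (nrm < 1e-12) stop("undefined axis: group centroids coincide in the plane")
  axis <- d / nrm
  model$axis <- unname(axis)
  model$axis_angle_deg <- .angle_from_diff(axis)
  model$axis_from <- from_group
  model$axis_to <- to_group
  model
}

#' Project gene loadings onto the rotated metastasis-axis frame
#'
#' Rotates each gene's (PC1, PC2) loading into the (PC1deg, PC2deg) frame
#' whose second coordinate runs along the metastasis axis.  The rotation is
#' rigid, so each gene's squared loading norm is preserved.  Genes are
#' ranked by \code{|coord_pc2deg|} in decreasing order (ties broken by gene
#' id), and signed TMD-high / BMD-high by the sign of the axis coordinate.
#'
#' @param model a \code{plane_model} with the axis set.
#' @return data.frame with columns \code{gene_id}, \code{coord_pc1deg},
#'   \code{coord_pc2deg}, \code{rank}, \code{direction}, ordered by rank.
#' @export
project_genes <- function(model) {
  stopifnot(inherits(model, "plane_model"))
  if (is.null(model$axis)) stop("metastasis axis not set; call compute_metastasis_axis()")
  ax <- model$axis
  perp <- c(ax[2], -ax[1])   # (PC1deg, PC2deg) stays right-handed
  L <- model$gene_loadings
  sc <- data.frame(
    gene_id = rownames(L),
    coord_pc1deg = as.numeric(L %*% perp),
    coord_pc2deg = as.numeric(L %*% ax),
    stringsAsFactors = FALSE
  )
  ord <- order(-abs(sc$coord_pc2deg), sc$gene_id)
  sc <- sc[ord, ]
  sc$rank <- seq_len(nrow(sc))
  sc$direction <- ifelse(sc$coord_pc2deg >= 0, "TMD-high", "BMD-high")
  rownames(sc) <- NULL
  sc
}

#' Select genes at the extremes of the metastasis axis
#'
#' Returns the \code{k_per_end} genes with the most positive and the
#' \code{k_per_end} with the most negative axis coordinate -- the candidate
#' markers at the two ends of the TMD--BMD contrast -- ordered by
#' \code{|coord_pc2deg|} decreasing.
#'
#' @param scores data.frame from \code{\link{project_genes}}.
#' @param k_per_end genes to keep per end (>= 0); clamped with a warning
#'   when the request exceeds the gene count.
#' @return subset of \code{scores}, ordered by rank.
#' @export
select_extreme_genes <- function(scores, k_per_end = 10) {
  if (k_per_end < 0) stop("'k_per_end' must be >= 0")
  if (k_per_end == 0) return(scores[0, ])
  n <- nrow(scores)
  if (2 * k_per_end > n) {
    warning("k_per_end exceeds half the gene count; clamping")
    k_per_end <- floor(n / 2)
  }
  ord <- order(-scores$coord_pc2deg, scores$gene_id)
  pos <- scores$gene_id[head(ord, k_per_end)]
  neg <- scores$gene_id[tail(ord, k_per_end)]
  out <- scores[scores$gene_id %in% c(pos, neg), ]
  out[order(out$rank), ]
}

#' Linear-scale fold change between two groups
#'
#' Computes \code{2^(mean_A - mean_B)} from the log2 expression values of
#' one gene.
#'
#' @param X an \code{\link{expression_matrix}}.
#' @param gene gene id.
#' @param groupA,groupB group labels (numerator, denominator).
#' @return fold change on the linear scale.
#' @export
group_fold_change <- function(X, gene, groupA, groupB) {
  stopifnot(inherits(X, "expression_matrix"))
  if (!gene %in% X$gene_ids) stop("unknown gene: ", gene)
  if (!all(c(groupA, groupB) %in% X$groups))
    stop("unknown group label")
  v <- X$values[gene, ]
  2^(mean(v[X$groups == groupA]) - mean(v[X$groups == groupB]))
}
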