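# shared in-code fixtures

# rasterized disc mask (pixel centers at integer coordinates)
disc_mask <- function(r, n = 2 * (ceiling(r) + 8), center = c(n, n) / 2) {
  xs <- matrix(seq_len(n), n, n)
  ys <- matrix(rep(seq_len(n), each = n), n, n)
  (xs - center[1])^2 + (ys - center[2])^2 <= r^2
}

# rasterized solid ellipse, axes aligned after rotation by theta
ellipse_mask <- function(a, b, theta = 0, n = 2 * (ceiling(a) + 10)) {
  c0 <- (n + 1) / 2
  xs <- matrix(seq_len(n), n, n) - c0
  ys <- matrix(rep(seq_len(n), each = n), n, n) - c0
  u <- cos(theta) * xs + sin(theta) * ys
  v <- -sin(theta) * xs + cos(theta) * ys
  (u / a)^2 + (v / b)^2 <= 1
}

# exact ellipse perimeter by numerical quadrature of the arc-length integral
ellipse_perimeter_oracle <- function(a, b) {
  f <- function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2)
  4 * stats::integrate(f, 0, pi / 2, rel.tol = 1e-10)$value
}

# noiseless expression matrix rebuilt from generator truth
truth_matrix <- function(sim) {
  mu <- sim$truth$group_means
  m <- mu[, match(sim$matrix$groups, colnames(mu)), drop = FALSE]
  dimnames(m) <- dimnames(sim$matrix$values)
  expression_matrix(m, sim$matrix$groups)
}

# recall of planted axis genes in the matched-size extreme selection
planted_recall <- function(sim, k = NULL) {
  planted <- names(sim$truth$planted_axis_genes)
  if (is.null(k)) k <- length(planted) / 2
  sel <- select_extreme_genes(run_axis(sim$matrix)$scores, k)
  mean(planted %in% sel$gene_id)
}
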