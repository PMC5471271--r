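test_that("decomposition centers genes and matches the full-SVD oracle (Eckart-Young)", {
  set.seed(3)
  for (dims in list(c(50, 9), c(20, 9), c(12, 6))) {
    vals <- matrix(rnorm(prod(dims)), dims[1],
                   dimnames = list(sprintf("g%02d", 1:dims[1]),
                                   sprintf("s%d", 1:dims[2])))
    groups <- setNames(rep(c("parental", "TMD", "BMD"),
                           each = dims[2] / 3), colnames(vals))
    X <- expression_matrix(vals, groups)
    m <- center_and_decompose(X)
    Xc <- vals - rowMeans(vals)
    expect_lt(max(abs(rowMeans(Xc))), 1e-12)
    # rank-2 reconstruction error equals the tail of an independent full SVD
    rec <- m$gene_loadings %*% t(m$sample_scores)
    err <- sum((Xc - rec)^2)
    d_oracle <- svd(Xc, nu = 0, nv = 0)$d
    expect_equal(err, sum(d_oracle[-(1:2)]^2), tolerance = 1e-8)
    expect_equal(crossprod(m$basis), diag(2), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(diff(m$variance_explained) <= 1e-12))
  }
})

test_that("degenerate and rank-1 matrices are handled", {
  vals <- matrix(5, 4, 6, dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  groups <- setNames(rep(c("TMD", "BMD"), each = 3), colnames(vals))
  expect_error(center_and_decompose(expression_matrix(vals, groups)),
               "degenerate")
  # one planted trend, no noise: rank exactly 1
  sim <- gen_expression(10, 3, pc1_effects = 2, noise_sd = 0, seed = 1)
  m <- center_and_decompose(sim$matrix)
  expect_equal(m$variance_explained[1:2], c(1, 0), tolerance = 1e-12)
})

test_that("metastasis axis is the unit BMD-to-TMD centroid direction with acute PC2 angle", {
  sim <- gen_expression(100, 3, axis_effects = rep(c(2, -2), each = 5),
                        pc1_effects = rep(2, 5), noise_sd = 0.1, seed = 4)
  m <- compute_metastasis_axis(center_and_decompose(sim$matrix))
  d <- m$centroids["TMD", ] - m$centroids["BMD", ]
  expect_equal(m$axis, unname(d / sqrt(sum(d^2))))
  expect_equal(sqrt(sum(m$axis^2)), 1)
  expect_gte(m$axis_angle_deg, 0)
  expect_lte(m$axis_angle_deg, 90)
  # closed-form angles from centroid differences
  expect_equal(.angle_from_diff(c(0, 3)), 0)
  expect_equal(.angle_from_diff(c(tan(20 * pi / 180), 1)), 20)
  expect_equal(.angle_from_diff(c(1, 0)), 90)
})

test_that("coincident centroids raise an undefined-axis error", {
  sim <- gen_expression(20, 3, pc1_effects = 2, noise_sd = 0, seed = 1)
  m <- center_and_decompose(sim$matrix)
  # no TMD-BMD contrast was planted: centroids coincide in the plane
  m$centroids["TMD", ] <- m$centroids["BMD", ]
  expect_error(compute_metastasis_axis(m), "undefined")
})

test_that("planted centroid angle is recovered from noisy data within 5 degrees", {
  errs <- vapply(1:10, function(s) {
    sim <- gen_expression(200, 3, axis_effects = rep(c(2, -2), each = 5),
                          pc1_effects = rep(2.5, 8), noise_sd = 0.2,
                          seed = s + 10)
    planted <- run_axis(truth_matrix(sim))$model$axis_angle_deg
    abs(run_axis(sim$matrix)$model$axis_angle_deg - planted)
  }, 0)
  expect_lt(max(errs), 5)
})

test_that("gene projection is a norm-preserving rotation with deterministic ranks", {
  sim <- gen_expression(150, 3, axis_effects = rep(c(2, -2), each = 5),
                        noise_sd = 0.3, seed = 6)
  m <- compute_metastasis_axis(center_and_decompose(sim$matrix))
  sc <- project_genes(m)
  L <- m$gene_loadings[sc$gene_id, ]
  expect_equal(sc$coord_pc1deg^2 + sc$coord_pc2deg^2,
               unname(rowSums(L^2)), tolerance = 1e-10)
  expect_identical(sort(sc$rank), seq_len(nrow(sc)))
  expect_true(all(diff(abs(sc$coord_pc2deg)) <= 1e-12))
  expect_identical(sc$direction, ifelse(sc$coord_pc2deg >= 0,
                                        "TMD-high", "BMD-high"))
  # axis equal to PC2 exactly: axis coordinate is the PC2 loading
  m2 <- m; m2$axis <- c(0, 1)
  sc2 <- project_genes(m2)
  expect_equal(sc2$coord_pc2deg, unname(m$gene_loadings[sc2$gene_id, 2]))
  m$axis <- NULL
  expect_error(project_genes(m), "axis not set")
})

test_that("the strongest noiseless marker attains rank 1", {
  sim <- gen_expression(100, 3, axis_effects = c(5, rep(c(1, -1), 10)),
                        noise_sd = 0, seed = 1)
  sc <- run_axis(sim$matrix)$scores
  expect_identical(sc$gene_id[1], names(sim$truth$planted_axis_genes)[1])
  expect_identical(sc$direction[1], "TMD-high")
})

test_that("extreme-gene selection recovers planted markers and clamps k", {
  sim <- gen_expression(2000, 3, axis_effects = rep(c(3, -3), each = 10),
                        noise_sd = 0.3, seed = 5)
  sc <- run_axis(sim$matrix)$scores
  sel <- select_extreme_genes(sc, 10)
  expect_equal(nrow(sel), 20)
  expect_gte(sum(names(sim$truth$planted_axis_genes) %in% sel$gene_id), 18)
  expect_setequal(unique(sel$direction), c("TMD-high", "BMD-high"))
  expect_equal(nrow(select_extreme_genes(sc, 0)), 0)
  expect_warning(sel_all <- select_extreme_genes(sc[1:10, ], 8), "clamp")
  expect_equal(nrow(sel_all), 10)
})

test_that("recovery holds at 3x the noise SD and permutation collapses the axis", {
  # recovery invariant: planted effects exactly 3x noise SD, matched-size
  # selection, averaged over 20 seeds
  rec <- vapply(1:20, function(s)
    planted_recall(gen_expression(60, 3,
                                  axis_effects = rep(c(0.6, -0.6), each = 10),
                                  noise_sd = 0.2, seed = s)), 0)
  expect_gte(mean(rec), 0.9)

  # permuting sample labels collapses the TMD-BMD centroid separation
  # (tested where the planted contrast dominates the plane), and in the
  # marginal-SNR regime the selection recall drops with it
  sig <- gen_expression(2000, 3, axis_effects = rep(c(3, -3), each = 10),
                        noise_sd = 0.3, seed = 7)
  m <- center_and_decompose(sig$matrix)
  true_len <- sqrt(sum((m$centroids["TMD", ] - m$centroids["BMD", ])^2))
  set.seed(42)
  perm_len <- replicate(20, {
    gp <- setNames(sample(unname(sig$matrix$groups)), sig$matrix$sample_ids)
    mp <- center_and_decompose(expression_matrix(sig$matrix$values, gp))
    sqrt(sum((mp$centroids["TMD", ] - mp$centroids["BMD", ])^2))
  })
  expect_lt(median(perm_len), true_len / 2)

  marg <- gen_expression(2000, 3, axis_effects = rep(c(1.5, -1.5), each = 10),
                         noise_sd = 0.5, seed = 7)
  true_rec <- planted_recall(marg)
  set.seed(43)
  perm_rec <- replicate(20, {
    gp <- setNames(sample(unname(marg$matrix$groups)), marg$matrix$sample_ids)
    Xp <- expression_matrix(marg$matrix$values, gp)
    sel <- select_extreme_genes(run_axis(Xp)$scores, 10)
    mean(names(marg$truth$planted_axis_genes) %in% sel$gene_id)
  })
  expect_lt(mean(perm_rec), true_rec)
})

test_that("pure-noise selection is consistent with its own permutation null", {
  sim <- gen_expression(500, 3, noise_sd = 0.5, seed = 9)
  obs <- mean(abs(select_extreme_genes(run_axis(sim$matrix)$scores,
                                       10)$coord_pc2deg))
  set.seed(11)
  null <- replicate(99, {
    gp <- setNames(sample(unname(sim$matrix$groups)), sim$matrix$sample_ids)
    Xp <- expression_matrix(sim$matrix$values, gp)
    mean(abs(select_extreme_genes(run_axis(Xp)$scores, 10)$coord_pc2deg))
  })
  expect_gte(obs, quantile(null, 0.025))
  expect_lte(obs, quantile(null, 0.975))
})

test_that("fold change exponentiates log2 group-mean differences", {
  sim <- gen_expression(20, 3, axis_effects = 2.22, noise_sd = 0, seed = 1)
  gene <- names(sim$truth$planted_axis_genes)
  expect_equal(group_fold_change(sim$matrix, gene, "TMD", "BMD"), 2^2.22)
  expect_equal(group_fold_change(sim$matrix, gene, "TMD", "BMD"), 4.66,
               tolerance = 1e-3)
  expect_equal(group_fold_change(sim$matrix, "gene_0005", "TMD", "BMD"), 1)
  expect_error(group_fold_change(sim$matrix, "nope", "TMD", "BMD"), "unknown")
  expect_error(group_fold_change(sim$matrix, gene, "TMD", "xx"), "unknown")
})
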