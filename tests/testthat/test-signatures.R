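# Covariate regression, overfit-SVM signature selection, maturation
# ordering, conserved-marker intersection.

test_that("covariate regression: exact algebraic cases", {
  set.seed(1)
  cov <- rnorm(40)
  g_orth <- rnorm(40)
  g_orth <- g_orth - cov * sum(g_orth * (cov - mean(cov))) /
    sum((cov - mean(cov))^2)  # force orthogonality is not needed; use residual
  mat <- rbind(orth = residuals(lm(g_orth ~ cov)) + 5,
               linear = 2 * cov)
  colnames(mat) <- sprintf("c%02d", 1:40)
  res <- regress_out_covariate(mat, cov)
  expect_equal(res["orth", ], mat["orth", ], tolerance = 1e-10)
  expect_lt(var(res["linear", ]), 1e-20)
  expect_equal(mean(res["linear", ]), mean(mat["linear", ]))  # means restored
  expect_warning(regress_out_covariate(mat, rep(1, 40)), "Constant covariate")
})

test_that("planted age effects vanish after regression", {
  q <- two_class_cohort(seed = 51)
  age <- as.numeric(factor(q$cells$age))
  resid <- regress_out_covariate(log_rpm(q, 1e4), age)
  ag <- q$genes$gene_id[q$genes$role == "age"]
  cors <- abs(apply(resid[ag, ], 1, cor, age))
  expect_true(all(cors < 0.05))
})

test_that("signature selection recovers planted markers, excludes age genes", {
  q <- two_class_cohort(seed = 52)
  labels <- setNames(q$cells$true_class, q$cells$cell_id)
  resid <- regress_out_covariate(log_rpm(q, 1e4),
                                 as.numeric(factor(q$cells$age)))
  sig <- select_conserved_signature(resid, labels, counts = q,
                                    n_per_class = 150)
  role <- setNames(q$genes$role, q$genes$gene_id)
  d5 <- signature_genes(sig, "Dock5")
  l1 <- signature_genes(sig, "Lsp1")
  expect_equal(sum(role[d5] == "marker_Dock5"), 20L)
  expect_equal(sum(role[l1] == "marker_Lsp1"), 20L)
  expect_equal(sum(role[c(d5, l1)] == "age"), 0L)
  expect_length(intersect(d5, l1), 0)  # disjoint lists
  expect_true(all(c(-0.5, 0.5) %in% range(sig$genes$rescaled_fc)))
  expect_error(select_conserved_signature(resid, labels, n_per_class = 5000),
               "n_per_class")
})

test_that("swapping class labels swaps gene lists and negates weights", {
  q <- two_class_cohort(seed = 53, n = 40, n_genes = 500)
  labels <- setNames(q$cells$true_class, q$cells$cell_id)
  resid <- regress_out_covariate(log_rpm(q, 1e4),
                                 as.numeric(factor(q$cells$age)))
  sig <- select_conserved_signature(resid, labels, counts = q, n_per_class = 50)
  swapped <- setNames(ifelse(unname(labels) == "Dock5", "Lsp1", "Dock5"),
                      names(labels))
  # relabel so sorted class names stay the same but membership flips
  sig2 <- select_conserved_signature(resid, swapped, counts = q, n_per_class = 50)
  expect_setequal(signature_genes(sig, "Dock5"), signature_genes(sig2, "Lsp1"))
  expect_setequal(signature_genes(sig, "Lsp1"), signature_genes(sig2, "Dock5"))
  common <- signature_genes(sig, "Dock5")
  w1 <- sig$genes$weight[match(common, sig$genes$gene)]
  w2 <- sig2$genes$weight[match(common, sig2$genes$gene)]
  expect_equal(w1, -w2, tolerance = 1e-6)
})

test_that("fold-change rescaling is the linear min-max map", {
  expect_equal(ngcdev:::rescale_fc(c(-2, 0, 2)), c(-0.5, 0, 0.5))
  expect_equal(range(ngcdev:::rescale_fc(rnorm(100))), c(-0.5, 0.5))
})

test_that("maturation model orders timepoints and scores are linear", {
  cfg <- sim_config(seed = 54, n_cells_per_group = 50, n_genes = 500,
                    age_effect_size = 1)
  q <- generate_query_cohort(cfg, ages = c("P15", "P30", "P56"),
                             frac_low_quality = 0)
  tp <- setNames(q$cells$age, q$cells$cell_id)
  m <- fit_maturation_order(q, tp, levels = c("P15", "P30", "P56"),
                            folds = 5, lambda_grid = c(0.1, 1, 10))
  sc <- score_maturation(m, q)
  means <- tapply(sc$maturation_score, factor(q$cells$age,
                                              c("P15", "P30", "P56")), mean)
  expect_true(all(diff(means) > 0))
  # duplicated cell scores identically; averaged cell scores the average
  ln <- log_rpm(q)
  x <- ln[, 1:2]
  avg <- cbind(x, avg = rowMeans(x))
  sc2 <- score_maturation(m, avg)
  expect_equal(sc2$maturation_score[3],
               mean(sc2$maturation_score[1:2]), tolerance = 1e-8)
  dup <- cbind(x[, 1, drop = FALSE], again = x[, 1])
  sc3 <- score_maturation(m, dup)
  expect_equal(sc3$maturation_score[1], sc3$maturation_score[2])
  expect_error(fit_maturation_order(q, tp, levels = "P15"), "two timepoints")
})

test_that("shuffled timepoint labels drop CV accuracy to chance", {
  cfg <- sim_config(seed = 55, n_cells_per_group = 40, n_genes = 400,
                    age_effect_size = 1.5)
  q <- generate_query_cohort(cfg, ages = c("P15", "P30"), frac_low_quality = 0)
  tp <- setNames(q$cells$age, q$cells$cell_id)
  m <- fit_maturation_order(q, tp, folds = 5, lambda_grid = c(0.1, 1))
  set.seed(2)
  tp_shuf <- setNames(sample(unname(tp)), names(tp))
  m_shuf <- fit_maturation_order(q, tp_shuf, folds = 5,
                                 lambda_grid = c(0.1, 1))
  expect_gt(max(m$cv$accuracy), max(m_shuf$cv$accuracy))
  n <- n_cells(q)
  expect_lt(abs(max(m_shuf$cv$accuracy) - 0.5), 3 * sqrt(0.25 / n) + 0.05)
})

test_that("penalized ordinal fit agrees with the unpenalized reference on easy data", {
  skip_if_not_installed("MASS")
  set.seed(3)
  n <- 150
  x1 <- rnorm(n); x2 <- rnorm(n)
  latent <- 2 * x1 - x2 + rlogis(n)
  y <- cut(latent, c(-Inf, -1, 1, Inf), labels = c("t1", "t2", "t3"))
  X <- rbind(g1 = x1, g2 = x2)
  colnames(X) <- sprintf("c%03d", 1:n)
  m <- fit_maturation_order(X, setNames(as.character(y), colnames(X)),
                            levels = c("t1", "t2", "t3"), folds = 5,
                            n_var_genes = 2, lambda_grid = 1e-4)
  ours <- score_maturation(m, X)$maturation_score
  ref <- MASS::polr(y ~ x1 + x2)
  ref_lp <- drop(cbind(x1, x2) %*% coef(ref))
  expect_gt(cor(ours, ref_lp, method = "spearman"), 0.99)
})

test_that("maturation score is invariant to constant gene scaling", {
  cfg <- sim_config(seed = 56, n_cells_per_group = 40, n_genes = 300,
                    age_effect_size = 1.5)
  q <- generate_query_cohort(cfg, frac_low_quality = 0)
  ln <- log_rpm(q)
  tp <- setNames(q$cells$age, q$cells$cell_id)
  m1 <- fit_maturation_order(ln, tp, folds = 5, lambda_grid = 1)
  m2 <- fit_maturation_order(ln * 3, tp, folds = 5, lambda_grid = 1)
  s1 <- score_maturation(m1, ln)$maturation_score
  s2 <- score_maturation(m2, ln * 3)$maturation_score
  expect_gt(cor(s1, s2, method = "spearman"), 0.99)
})

test_that("scoring warns on missing genes and errors on empty intersection", {
  cfg <- sim_config(seed = 57, n_cells_per_group = 30, n_genes = 300,
                    age_effect_size = 1.5)
  q <- generate_query_cohort(cfg, frac_low_quality = 0)
  tp <- setNames(q$cells$age, q$cells$cell_id)
  m <- fit_maturation_order(q, tp, folds = 5, lambda_grid = 1)
  ln <- log_rpm(q)
  part <- ln[intersect(m$genes[-1], rownames(ln)), , drop = FALSE]
  expect_warning(score_maturation(m, part), "imputing")
  none <- ln[setdiff(rownames(ln), m$genes), , drop = FALSE]
  expect_error(score_maturation(m, none), "No model genes")
})

test_that("conserved-marker intersection filters and scores both epochs", {
  cfg <- sim_config(seed = 58, n_cells_per_group = 150)
  emb <- generate_embryonic_continuum(cfg, classes = c("Dock5", "Lsp1"))
  q <- generate_query_cohort(cfg, classes = c("Dock5", "Lsp1"),
                             frac_low_quality = 0)
  labels <- setNames(q$cells$true_class, q$cells$cell_id)
  resid <- regress_out_covariate(log_rpm(q, 1e4),
                                 as.numeric(factor(q$cells$age)))
  sig <- select_conserved_signature(resid, labels, counts = q,
                                    n_per_class = 150)
  itc <- intersect_time_conserved(sig, emb, emb$cells$true_class == "Dock5",
                                  q, q$cells$true_class == "Dock5",
                                  class = "Dock5")
  role <- setNames(q$genes$role, q$genes$gene_id)
  planted <- itc[role[itc$gene] == "marker_Dock5", ]
  expect_equal(nrow(planted), 20L)
  expect_true(all(planted$z_embryonic > 2))
  expect_true(all(planted$z_postnatal > 2))
  expect_true(all(itc$mean_log_rpm_embryonic > 0.05))
  # a gene absent embryonically is excluded
  emb_small <- subset_cells(emb, seq_len(n_cells(emb)))
  emb_small$counts[signature_genes(sig, "Dock5")[1], ] <- 0
  itc2 <- intersect_time_conserved(sig, emb_small,
                                   emb$cells$true_class == "Dock5",
                                   q, q$cells$true_class == "Dock5",
                                   class = "Dock5")
  expect_false(signature_genes(sig, "Dock5")[1] %in% itc2$gene)
})
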