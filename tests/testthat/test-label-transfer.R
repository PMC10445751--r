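# Joint embedding, kNN and SVM classifiers, consensus assignment.

test_that("a query identical to the reference lands on its twin", {
  cfg <- small_config(seed = 41)
  atlas <- generate_reference_atlas(cfg, classes = c("A", "B"))
  twin <- atlas
  twin$cells$cell_id <- paste0("twin_", twin$cells$cell_id)
  colnames(twin$counts) <- twin$cells$cell_id
  emb <- embed_joint(atlas, twin, n_dims = 10)
  ref <- as.matrix(emb[emb$origin == "reference", grep("^PC", names(emb))])
  qry <- as.matrix(emb[emb$origin == "query", grep("^PC", names(emb))])
  nn <- FNN::get.knnx(ref, qry, k = 1)
  expect_true(all(nn$nn.index[, 1] == seq_len(nrow(qry))))
  expect_true(all(nn$nn.dist[, 1] < 1e-8))
})

test_that("well-separated classes give a clean embedding (silhouette > 0.5)", {
  cfg <- sim_config(seed = 42, n_cells_per_group = 60, n_genes = 400,
                    marker_log_fc = 3)
  atlas <- generate_reference_atlas(cfg, classes = c("A", "B"))
  query <- generate_query_cohort(cfg, classes = c("A", "B"),
                                 frac_low_quality = 0)
  silhouette <- function(emb) {
    qc <- emb[emb$origin == "query", ]
    coords <- as.matrix(qc[, grep("^PC", names(qc))])
    labs <- query$cells$true_class
    d <- as.matrix(dist(coords))
    mean(vapply(seq_len(nrow(coords)), function(i) {
      same <- setdiff(which(labs == labs[i]), i)
      a <- mean(d[i, same])
      b <- mean(d[i, labs != labs[i]])
      (b - a) / max(a, b)
    }, numeric(1)))
  }
  emb <- embed_joint(atlas, query, n_dims = 10, method = "pca_project")
  expect_gt(silhouette(emb), 0.5)
  # deterministic
  emb2 <- embed_joint(atlas, query, n_dims = 10, method = "pca_project")
  expect_equal(emb, emb2)
  # the default (per-dataset standardized) embedding also separates classes
  emb3 <- embed_joint(atlas, query, n_dims = 10)
  expect_equal(nrow(emb3), nrow(emb))
  expect_gt(silhouette(emb3), 0.2)
})

test_that("kNN majority, vote fraction and tie rule are exact", {
  # constructed embedding: 3 reference points, 1 query point
  mk_emb <- function(ref_xy, qry_xy) {
    out <- tibble::tibble(
      cell_id = c(sprintf("r%d", seq_len(nrow(ref_xy))), "q1"),
      origin = c(rep("reference", nrow(ref_xy)), "query"),
      PC1 = c(ref_xy[, 1], qry_xy[1]), PC2 = c(ref_xy[, 2], qry_xy[2]))
    class(out) <- c("ngc_embedding", class(out))
    out
  }
  emb <- mk_emb(rbind(c(0, 0), c(1, 0), c(2, 0)), c(0.6, 0))
  labs <- c(r1 = "A", r2 = "A", r3 = "B")
  res <- knn_classify(emb, labs, k = 3)
  expect_equal(res$knn_label, "A")
  expect_equal(res$knn_vote_fraction, 2 / 3)
  # k = 1 on a coincident point
  res1 <- knn_classify(mk_emb(rbind(c(0, 0), c(5, 5)), c(0, 0)),
                       c(r1 = "B", r2 = "A"), k = 1)
  expect_equal(res1$knn_label, "B")
  expect_equal(res1$knn_vote_fraction, 1)
  # tie at k = 2 resolved by the nearest neighbour's label
  res2 <- knn_classify(mk_emb(rbind(c(1, 0), c(-2, 0)), c(0, 0)),
                       c(r1 = "A", r2 = "B"), k = 2)
  expect_equal(res2$knn_label, "A")
  expect_error(knn_classify(emb, labs, k = 10), "k")
})

test_that("kNN equals a brute-force all-pairs scan", {
  cfg <- small_config(seed = 43)
  atlas <- generate_reference_atlas(cfg, classes = c("A", "B"))
  query <- generate_query_cohort(cfg, classes = c("A", "B"),
                                 frac_low_quality = 0)
  emb <- embed_joint(atlas, query, n_dims = 8)
  labs <- setNames(atlas$cells$true_class, atlas$cells$cell_id)
  res <- knn_classify(emb, labs, k = 7)
  ref <- as.matrix(emb[emb$origin == "reference", grep("^PC", names(emb))])
  qry <- as.matrix(emb[emb$origin == "query", grep("^PC", names(emb))])
  rlab <- unname(labs[emb$cell_id[emb$origin == "reference"]])
  brute <- vapply(seq_len(nrow(qry)), function(i) {
    d <- sqrt(colSums((t(ref) - qry[i, ])^2))
    nl <- rlab[order(d)[1:7]]
    tab <- table(nl)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) top else nl[1]
  }, character(1))
  expect_equal(res$knn_label, brute)
})

test_that("linear SVM separates separable classes and permuted labels are chance", {
  q <- two_class_cohort(seed = 44, marker_log_fc = 2, n = 60, n_genes = 600)
  labels <- setNames(q$cells$true_class, q$cells$cell_id)
  svm <- train_linear_svm(q, labels)
  pred <- predict(svm, q)
  expect_equal(mean(pred$svm_label == q$cells$true_class), 1)
  expect_error(train_linear_svm(q, setNames(rep("A", n_cells(q)),
                                            q$cells$cell_id)), "two classes")
  # permutation null: held-out accuracy within 3 binomial SD of chance
  set.seed(1)
  perm <- setNames(sample(unname(labels)), names(labels))
  half <- seq_len(n_cells(q)) %% 2 == 0
  ln <- log_rpm(q, 1e4)
  svm_p <- train_linear_svm(ln[, half], perm[colnames(ln)[half]])
  acc <- mean(predict(svm_p, ln[, !half])$svm_label ==
                unname(perm[colnames(ln)[!half]]))
  n_test <- sum(!half)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n_test))
  # deterministic refit
  svm2 <- train_linear_svm(q, labels)
  expect_equal(svm$weights, svm2$weights)
})

test_that("consensus follows agreement, flags contradictory fluorescence", {
  knn <- tibble::tibble(cell_id = c("c1", "c2", "c3"),
                        knn_label = c("A", "A", "A"),
                        knn_vote_fraction = c(1, 0.9, 1))
  svm <- tibble::tibble(cell_id = c("c1", "c2", "c3"),
                        svm_label = c("A", "B", "A"),
                        svm_decision = c(1.2, 0.4, 0.8))
  fl <- tibble::tibble(cell_id = c("c1", "c2", "c3"),
                       tdtom = c(TRUE, TRUE, FALSE))
  res <- consensus_assign(knn, svm, fluorescence = fl, tdtom_classes = "A")
  expect_equal(res$consensus_label, c("A", "INCONCLUSIVE", "A"))
  expect_equal(res$core, c(TRUE, FALSE, FALSE))
  expect_error(consensus_assign(knn[1:2, ], svm), "different cell sets")
  # symmetric in classifier order (labels compared, not positions)
  res2 <- consensus_assign(
    dplyr::rename(svm, knn_label = "svm_label",
                  knn_vote_fraction = "svm_decision"),
    dplyr::rename(knn, svm_label = "knn_label",
                  svm_decision = "knn_vote_fraction"),
    fluorescence = fl, tdtom_classes = "A")
  expect_equal(res2$consensus_label, res$consensus_label)
  # invariant to class relabeling
  relab <- function(x) chartr("AB", "XY", x)
  resR <- consensus_assign(dplyr::mutate(knn, knn_label = relab(knn_label)),
                           dplyr::mutate(svm, svm_label = relab(svm_label)))
  expect_equal(resR$consensus_label == "INCONCLUSIVE",
               res$consensus_label == "INCONCLUSIVE")
})

test_that("assignment summary reproduces worked percentages", {
  asg <- tibble::tibble(consensus_label = rep(c("Dock5", "Lsp1", "INCONCLUSIVE"),
                                              c(76, 35, 36)))
  s <- summarize_assignments(asg)
  expect_equal(s$pct[s$label == "Dock5"], 100 * 76 / 147, tolerance = 1e-10)
  expect_equal(attr(s, "assigned_pct"), 100 * 111 / 147, tolerance = 1e-10)
})

test_that("seeded cluster enrichment estimates flagged percentages", {
  cl <- tibble::tibble(cell_id = sprintf("c%03d", 1:300),
                       cluster = rep(1:2, each = 150))
  # cluster 1 fully flagged; cluster 2 half flagged
  flag <- setNames(c(rep(TRUE, 150), rep(c(TRUE, FALSE), 75)), cl$cell_id)
  res <- cluster_group_enrichment(cl, flag, sample_size = 95, seed = 5)
  expect_equal(res$pct_flagged[res$cluster == 1], 100)
  # binomial 99% CI around 50% at n = 95
  half <- res$pct_flagged[res$cluster == 2] / 100
  expect_lt(abs(half - 0.5), 2.58 * sqrt(0.25 / 95))
  # sample size lowered to the smallest cluster
  cl_small <- tibble::tibble(cell_id = sprintf("s%02d", 1:30),
                             cluster = rep(1:2, c(10, 20)))
  fs <- setNames(rep(TRUE, 30), cl_small$cell_id)
  res_small <- cluster_group_enrichment(cl_small, fs, sample_size = 95, seed = 1)
  expect_true(all(res_small$sample_size == 10))
  # deterministic
  expect_identical(res, cluster_group_enrichment(cl, flag, sample_size = 95,
                                                 seed = 5))
})

test_that("consensus label transfer recovers planted classes", {
  cfg <- sim_config(seed = 45, n_cells_per_group = 100, n_genes = 800)
  atlas <- generate_reference_atlas(cfg)
  query <- generate_query_cohort(cfg, frac_low_quality = 0)
  emb <- embed_joint(atlas, query, n_dims = 15)
  labs <- setNames(atlas$cells$true_class, atlas$cells$cell_id)
  knn <- knn_classify(emb, labs, k = 15)
  svm_pred <- predict(train_linear_svm(atlas, labs), query)
  asg <- consensus_assign(knn, svm_pred,
                          fluorescence = query$cells[, c("cell_id", "tdtom")],
                          tdtom_classes = c("Dock5", "Lsp1"))
  expect_gte(mean(asg$consensus_label == query$cells$true_class), 0.95)
  expect_lte(mean(asg$consensus_label == "INCONCLUSIVE"), 0.10)
})
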