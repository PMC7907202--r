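test_that("sigmoid and softmax behave per their closed forms", {
  expect_identical(sigmoid(0), 0.5)
  expect_equal(sigmoid(c(-1e3, 1e3)), c(0, 1), tolerance = 1e-12)
  P <- nodulefuse:::.softmax_rows(matrix(c(1000, -1000, 3, 3), 2, 2,
                                         byrow = TRUE))
  expect_equal(rowSums(P), c(1, 1), tolerance = 1e-12)
  expect_equal(P[2, ], c(0.5, 0.5))
})

test_that("branch classifiers learn separable clusters and normalize outputs", {
  dat <- two_cluster_data()
  clf <- train_branch(dat$X, dat$y,
                      ae_config(c(8L, 5L, 3L), epochs_finetune = 150L,
                                seed = 1))
  P <- predict_branch(clf, dat$X)
  expect_equal(unname(rowSums(P)), rep(1, 100), tolerance = 1e-9)
  expect_gte(mean((P[, "malignant"] >= 0.5) == (dat$y == "malignant")), 0.95)
  expect_identical(ncol(encode_branch(clf, dat$X)), 3L)

  # deterministic given the seed
  clf2 <- train_branch(dat$X, dat$y,
                       ae_config(c(8L, 5L, 3L), epochs_finetune = 150L,
                                 seed = 1))
  expect_identical(predict_branch(clf2, dat$X), P)
  clf3 <- train_branch(dat$X, dat$y,
                       ae_config(c(8L, 5L, 3L), epochs_finetune = 150L,
                                 seed = 2))
  expect_false(identical(predict_branch(clf3, dat$X), P))
})

test_that("branch training rejects degenerate inputs", {
  dat <- two_cluster_data(n = 20)
  expect_error(train_branch(dat$X, rep("benign", 20),
                            ae_config(c(5L, 3L))),
               class = "nf_training_error")
  bad <- dat$X; bad[3, 7] <- NaN
  expect_error(train_branch(bad, dat$y, ae_config(c(5L, 3L))),
               class = "nf_schema_error")
  clf <- train_branch(dat$X, dat$y, ae_config(c(5L, 3L)))
  expect_error(predict_branch(clf, dat$X[, 1:9]), class = "nf_schema_error")
  tampered <- dat$X; tampered[1, 1] <- NA
  expect_error(predict_branch(clf, tampered), class = "nf_schema_error")
  expect_error(ae_config(c(5L, 7L)), class = "nf_value_error")
})

test_that("the fusion stage consumes the 7-dim probability vector", {
  f <- synth_features()
  cfg <- tiny_fusion_config()
  model <- train_fusion(f$shape, f$app, f$voc, f$size, f$y, cfg)
  expect_identical(model$fusion$input_dim, 7L)
  pred <- predict_fusion(model, f$shape, f$app, f$voc, f$size)
  expect_true(all(pred$prob_malignant >= 0 & pred$prob_malignant <= 1))
  expect_identical(pred$label,
                   ifelse(pred$prob_malignant >= 0.5, "malignant", "benign"))
  # training exemplars of a well-separated cohort are recovered
  expect_gte(mean(pred$label == f$y), 0.9)

  # determinism end to end
  model2 <- train_fusion(f$shape, f$app, f$voc, f$size, f$y, cfg)
  expect_identical(predict_fusion(model2, f$shape, f$app, f$voc, f$size), pred)

  # missing marker group
  expect_error(train_fusion(f$shape, NULL, f$voc, f$size, f$y, cfg),
               class = "nf_data_error")
  nav <- f$voc; nav[2, 3] <- NA
  expect_error(train_fusion(f$shape, f$app, nav, f$size, f$y, cfg),
               class = "nf_data_error")
  expect_error(predict_fusion(model, f$shape, f$app, nav, f$size),
               class = "nf_schema_error")

  # softmax-only fusion reading
  cfg2 <- tiny_fusion_config(); cfg2$fusion_mode <- "softmax_only"
  m3 <- train_fusion(f$shape, f$app, f$voc, f$size, f$y, cfg2)
  expect_length(m3$fusion$layers, 0)
  expect_identical(m3$fusion$input_dim, 7L)
})

test_that("feature-space bookkeeping matches the default architecture", {
  fs <- describe_feature_space()
  expect_identical(fs$raw_dim, 1098L)
  expect_identical(fs$reduced_dim, 121L)
  expect_identical(fs$raw_dim, sum(fs$per_group_raw))
  expect_identical(fs$reduced_dim, sum(fs$per_group_reduced))
  expect_identical(unname(fs$per_group_raw),
                   c(70L, 1000L, 1L, 27L))
  expect_identical(unname(fs$per_group_reduced),
                   c(10L, 100L, 1L, 10L))
})

test_that("confusion metrics follow their definitions", {
  met <- nodulefuse:::.metrics_from_predictions
  lab <- rep(c("malignant", "benign"), each = 5)
  perfect <- met(lab, c(rep(0.9, 5), rep(0.1, 5)))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$auc, 1)
  allpos <- met(lab, rep(0.9, 10))
  expect_equal(allpos$sensitivity, 100)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$accuracy, 50)
  with(perfect, expect_identical(TP + FP + TN + FN, length(lab)))
})

test_that("LOSO evaluation is seeded-deterministic and leakage-free", {
  co <- tiny_cohort()
  cfg <- tiny_fusion_config()
  feats <- extract_cohort_features(co, cfg)
  rep1 <- evaluate_cohort(co, "loso", config = cfg, feats = feats)
  rep2 <- evaluate_cohort(co, "loso", config = cfg, feats = feats)
  expect_identical(rep1$per_subject$prob_malignant,
                   rep2$per_subject$prob_malignant)
  expect_identical(rep1$confusion, rep2$confusion)
  with(rep1$confusion, expect_identical(TP + FP + TN + FN, rep1$n))
  expect_true(rep1$auc >= 0 && rep1$auc <= 1)

  # permuting a held-out subject's label never changes its own prediction
  flip <- co
  flip$labels[3] <- setdiff(c("benign", "malignant"), co$labels[3])
  flip$manifest$entries$label <- flip$labels
  ffeats <- feats
  ffeats$labels <- flip$labels
  rep3 <- evaluate_cohort(flip, "loso", config = cfg, feats = ffeats)
  expect_identical(rep3$per_subject$prob_malignant[3],
                   rep1$per_subject$prob_malignant[3])
  expect_identical(rep3$per_subject$prob_shape[3],
                   rep1$per_subject$prob_shape[3])

  # split protocol: stratified, both classes in the test fold
  rep_s <- evaluate_cohort(co, "split", split_fraction = 0.5, config = cfg,
                           feats = feats, seed = 4)
  expect_identical(rep_s$mode, "split")
  expect_true(all(c("benign", "malignant") %in% rep_s$per_subject$label))
})
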