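test_that("rank-based AUC matches the definition on canonical cases", {
  expect_equal(compute_auc(c(5, 6, 7, 1, 2, 3),
                           rep(c("pathogenic", "benign"), each = 3)), 1)
  expect_equal(compute_auc(c(1, 2, 3, 5, 6, 7),
                           rep(c("pathogenic", "benign"), each = 3)), 0)
  expect_equal(compute_auc(c(1, 2, 1, 2),
                           rep(c("pathogenic", "benign"), each = 2)), 0.5)
  expect_error(compute_auc(1:4, rep("pathogenic", 4)), "both classes")
  set.seed(31)
  null_auc <- compute_auc(rnorm(4000), sample(c("pathogenic", "benign"),
                                              4000, replace = TRUE))
  expect_equal(null_auc, 0.5, tolerance = 0.05)
})

test_that("AUC equals the all-pairs oracle on 200 random instances", {
  set.seed(32)
  for (rep in 1:200) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    v <- c(rnorm(n1, mean = runif(1, -1, 1)), rnorm(n0))
    if (rep %% 3 == 0) v <- round(v)  # force ties regularly
    lab <- rep(c("pathogenic", "benign"), c(n1, n0))
    expect_equal(compute_auc(v, lab), auc_oracle(v, lab))
  }
})

test_that("AUC antisymmetry: AUC(v) + AUC(-v) = 1", {
  set.seed(33)
  for (rep in 1:25) {
    v <- rnorm(30)
    lab <- sample(rep(c("pathogenic", "benign"), 15))
    expect_equal(compute_auc(v, lab) + compute_auc(-v, lab), 1)
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(34)
  v <- rnorm(60); lab <- sample(rep(c("pathogenic", "benign"), 30))
  ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = v,
                                        levels = c("benign", "pathogenic"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(compute_auc(v, lab), ref)
})

test_that("feature screening on the reported AUC table selects the four classifiers", {
  tab <- msh2_reference_auc
  sel <- select_features(tab, threshold = 0.75)
  expect_setequal(sel, c("ecs", "avg_rmsd", "rmsf_wt", "folding_ddg"))
  expect_equal(sel[1], "ecs")            # descending AUC order
  expect_equal(sel[4], "folding_ddg")
  expect_setequal(select_features(tab, threshold = 0.79),
                  c("ecs", "avg_rmsd", "rmsf_wt"))
  expect_length(select_features(data.frame(feature = "x", auc = 0.5)), 0)
})

test_that("oriented AUC table flips inverted features and uses |ddG|", {
  ft <- generate_feature_table(seed = 2)
  tab <- auc_table(ft)
  expect_true(all(tab$auc >= 0.5 - 1e-9))
  expect_equal(tab$orientation[tab$feature == "rmsf_wt"], "negated")
  expect_match(tab$orientation[tab$feature == "folding_ddg"], "absolute")
  # the signed ddG alone cannot reach the oriented value of |ddG|
  signed <- compute_auc(ft$folding_ddg, ft$class)
  oriented <- tab$auc[tab$feature == "folding_ddg"]
  expect_gt(oriented, max(signed, 1 - signed))
})

test_that("train/test split is reproducible, conservative and stratified", {
  ft <- generate_feature_table(seed = 3)
  s1 <- split_train_test(ft, 52, 23, seed = 9)
  s2 <- split_train_test(ft, 52, 23, seed = 9)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$train), 52)
  expect_equal(nrow(s1$test), 23)
  key <- function(d) sort(paste(d$position, d$mut_aa))
  expect_setequal(c(key(s1$train), key(s1$test)), key(ft))
  # stratification keeps the class ratio at the benchmark sizes
  expect_equal(sum(s1$train$class == "pathogenic"), 24)
  expect_equal(sum(s1$test$class == "pathogenic"), 10)
  expect_error(split_train_test(ft, 52, 22, seed = 1), "must equal")
})

test_that("KNN predictions match the brute-force neighbor oracle", {
  set.seed(35)
  ft <- generate_feature_table(seed = 4)
  sp <- split_train_test(ft, 52, 23, seed = 4)
  for (k in c(1, 3, 6)) {
    model <- knn_fit(sp$train, k = k)
    pred <- predict(model, sp$test)
    qm <- cbind(abs(sp$test$folding_ddg), sp$test$ecs, sp$test$rmsf_wt)
    qs <- sweep(sweep(qm, 2, model$center), 2, model$scale, `/`)
    oracle <- vapply(seq_len(nrow(qs)), function(i)
      knn_oracle(model$x, model$labels, qs[i, ], k), character(1))
    expect_equal(pred, oracle)
  }
})

test_that("KNN basics: self-query at k=1, training accuracy, k bound", {
  ft <- generate_feature_table(seed = 5)
  model <- knn_fit(ft, k = 1)
  expect_equal(predict(model, ft), as.character(ft$class))
  expect_equal(evaluate_model(model, ft), 1)
  expect_error(knn_fit(ft[1:4, ], k = 10), "exceeds")
})

test_that("KNN is invariant to affine rescaling of a feature column", {
  ft <- generate_feature_table(seed = 6)
  sp <- split_train_test(ft, 52, 23, seed = 6)
  base <- predict(knn_fit(sp$train, k = 6), sp$test)
  rescaled_train <- sp$train; rescaled_test <- sp$test
  rescaled_train$ecs <- 100 * rescaled_train$ecs - 7
  rescaled_test$ecs <- 100 * rescaled_test$ecs - 7
  expect_equal(predict(knn_fit(rescaled_train, k = 6), rescaled_test), base)
})

test_that("feature assembly joins sources by position and by identity", {
  variants <- data.frame(hgvs_p = c("p.Ala10Val", "p.Gly20Arg"),
                         class = "vus", stringsAsFactors = FALSE)
  ecs_prof <- data.frame(position = c(10, 20), ecs = c(0.9, 0.4))
  rmsf_prof <- data.frame(position = c(10, 20), rmsf_wt = c(1.2, 4.1))
  ddg <- data.frame(hgvs_p = c("p.Ala10Val", "p.Gly20Arg"),
                    folding_ddg = c(-1.4, 0.2))
  got <- assemble_features(variants,
                           list(ecs = ecs_prof, rmsf = rmsf_prof, ddg = ddg))
  expect_equal(got$ecs, c(0.9, 0.4))
  expect_equal(got$folding_ddg, c(-1.4, 0.2))
  expect_error(
    assemble_features(variants, list(ecs = ecs_prof[1, ], ddg = ddg,
                                     rmsf = rmsf_prof)),
    "p.Gly20Arg")
  expect_error(assemble_features(variants, list(ddg = ddg)), "ecs")
})

test_that("the four reported VUS rows assemble into complete classifier rows", {
  got <- assemble_features(cbind(msh2_vus_features[, "hgvs_p", drop = FALSE],
                                 class = "vus"),
                           list(printed = msh2_vus_features))
  expect_equal(nrow(got), 4)
  expect_equal(got$rmsf_wt, msh2_vus_features$rmsf_wt)
})

test_that("SVM comparison model trains and separates a linear toy problem", {
  toy <- data.frame(
    class = rep(c("pathogenic", "benign"), each = 20),
    folding_ddg = c(rnorm(20, 3, 0.3), rnorm(20, 0.3, 0.2)),
    ecs = c(rnorm(20, 0.95, 0.02), rnorm(20, 0.5, 0.05)),
    rmsf_wt = c(rnorm(20, 1.5, 0.2), rnorm(20, 4, 0.3)))
  fit <- svm_fit(toy, kernel = "linear")
  expect_equal(evaluate_model(fit, toy), 1)
  expect_error(svm_fit(toy[toy$class == "benign", ]), "both classes")
})
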