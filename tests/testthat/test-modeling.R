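# two-class Gaussian toy data as an expr_mat plus a manual training_set
make_gaussian_study <- function(n_per_class = 30, n_feat = 10, sep = 3,
                                holdout = 5, seed = 1) {
  withr::with_seed(seed, {
    mu <- c(rep(0, n_per_class), rep(sep, n_per_class))
    v <- t(sapply(mu, function(m) rnorm(n_feat, mean = m)))
  })
  ids <- sprintf("pp%03d", seq_len(2 * n_per_class))
  values <- t(v)
  rownames(values) <- paste0("f", seq_len(n_feat)); colnames(values) <- ids
  act <- ids[seq_len(n_per_class)]
  ina <- ids[n_per_class + seq_len(n_per_class)]
  tset <- structure(list(
    mie_label = "TOY (+)", cell_line = "CLA",
    active_profiles = act[-(seq_len(holdout))],
    inactive_profiles = ina[-(seq_len(holdout))],
    holdout_active = act[seq_len(holdout)],
    holdout_inactive = ina[seq_len(holdout)],
    active_chemicals = c(toychem = n_per_class), rng_seed = seed),
    class = "training_set")
  list(features = expr_mat(values, rep("landmark", n_feat)), tset = tset)
}

test_that("eligibility enforces both the chemical and profile floors", {
  rec <- rbind(
    data.frame(chemical_id = paste0("a", 1:5), target = "AAA",
               mode = "negative", support = 6L),
    data.frame(chemical_id = paste0("b", 1:4), target = "BBB",
               mode = "negative", support = 9L),
    data.frame(chemical_id = paste0("c", 1:6), target = "CCC",
               mode = "negative", support = 7L))
  clusters <- cluster_mies(collect_mies(derive_mie_records(rec)))
  meta <- rbind(toy_meta(setNames(rep(10L, 5), paste0("a", 1:5))),
                toy_meta(setNames(rep(50L, 4), paste0("b", 1:4)),
                         start = 100L),
                toy_meta(setNames(c(9L, rep(8L, 5)), paste0("c", 1:6)),
                         start = 400L))
  out <- eligible_mies(clusters, meta, "CLA")
  expect_equal(out$eligible[match("AAA (-)", out$display_name)], TRUE)
  expect_equal(out$eligible[match("BBB (-)", out$display_name)], FALSE)
  expect_equal(out$n_profiles[match("CCC (-)", out$display_name)], 49L)
  expect_equal(out$eligible[match("CCC (-)", out$display_name)], FALSE)
})

test_that("accuracy is the proportion of correct assignments", {
  expect_equal(accuracy(3, 2, 1, 2), 0.625)
  expect_equal(accuracy(10, 5, 0, 0), 1)
  expect_equal(accuracy(0, 0, 4, 6), 0)
  expect_error(accuracy(0, 0, 0, 0), "at least one")
  expect_error(accuracy(-1, 1, 1, 1), "non-negative")
})

test_that("training sets are balanced, disjoint, and honor exclusions", {
  derived <- derive_mie_records(SIM$records)
  clusters <- cluster_mies(collect_mies(derived))
  meta <- cap_profiles(SIM$meta[SIM$meta$cell_line == "CLA", ],
                       rng_seed = 5)
  cl <- clusters[1, , drop = FALSE]
  chem <- cl$chemicals[[1]]
  exemplar <- names(chem)[which.max(chem)]
  tset <- assemble_training_set(cl, derived, meta,
                                exclude_chemicals = exemplar, rng_seed = 9)
  validate_training_set(tset, meta, exclude_chemicals = exemplar)
  n_act <- length(tset$active_profiles) + length(tset$holdout_active)
  n_ina <- length(tset$inactive_profiles) + length(tset$holdout_inactive)
  expect_equal(n_act, n_ina)
  expect_equal(length(tset$holdout_active), floor(0.2 * n_act))
  # no inactive profile's chemical annotated to the MIE at any support/mode
  ina_chems <- meta$chemical_id[meta$profile_id %in%
                                  c(tset$inactive_profiles,
                                    tset$holdout_inactive)]
  annotated_to_mie <-
    unique(derived$chemical_id[derived$target %in% cl$targets[[1]]])
  expect_length(intersect(ina_chems, annotated_to_mie), 0L)
  # moderate-support association still blocks the inactive pool
  mod_chems <- moderate_support_chemicals(cl, derived)
  expect_length(intersect(ina_chems, mod_chems), 0L)
  # reproducibility
  tset2 <- assemble_training_set(cl, derived, meta,
                                 exclude_chemicals = exemplar, rng_seed = 9)
  expect_identical(tset, tset2)
})

test_that("an undersized inactive pool is rejected with diagnostics", {
  rec <- rbind(
    data.frame(chemical_id = paste0("a", 1:5), target = "AAA",
               mode = "negative", support = 6L),
    data.frame(chemical_id = "z1", target = "ZZZ",
               mode = "negative", support = 8L))
  derived <- derive_mie_records(rec)
  clusters <- cluster_mies(collect_mies(derived))
  meta <- rbind(toy_meta(setNames(rep(10L, 5), paste0("a", 1:5))),
                toy_meta(c(z1 = 3L), start = 200L))
  cl <- clusters[clusters$display_name == "AAA (-)", , drop = FALSE]
  expect_error(assemble_training_set(cl, derived, meta, rng_seed = 1),
               "inactive pool too small")
})

test_that("stratified folds partition each class evenly and reproducibly", {
  y <- factor(rep(c("active", "inactive"), c(23, 23)))
  f <- stratified_folds(y, 5, seed = 4)
  expect_setequal(unique(f), 1:5)
  expect_true(all(abs(diff(range(table(f)))) <= 2))
  for (k in 1:5) {
    expect_true(all(table(y[f == k]) >= 4))
  }
  expect_identical(f, stratified_folds(y, 5, seed = 4))
  expect_error(stratified_folds(factor(rep(c("a", "b"), c(3, 40))), 5),
               "at least n_folds")
})

test_that("cross-validation separates well-separated classes and reports honestly", {
  study <- make_gaussian_study(sep = 3)
  for (alg in c("SVM_L", "KNN", "NB")) {
    spec <- classifier_spec(alg, n_folds = 5, seed = 2)
    res <- cross_validated_train(study$tset, study$features, spec)
    expect_gte(res$internal_accuracy, 0.95)
    expect_equal(res$internal_accuracy, mean(res$fold_accuracies),
                 tolerance = 1e-12)
    expect_length(res$fold_accuracies, 5L)
    expect_gte(res$holdout_accuracy, 0.9)
  }
})

test_that("label-free data yields chance-level internal accuracy", {
  accs <- vapply(1:12, function(i) {
    withr::with_seed(100 + i, {
      v <- matrix(rnorm(20 * 40), 20)
    })
    ids <- sprintf("q%03d", 1:40)
    rownames(v) <- paste0("f", 1:20); colnames(v) <- ids
    tset <- structure(list(
      mie_label = "NOISE (+)", cell_line = "CLA",
      active_profiles = ids[1:20], inactive_profiles = ids[21:40],
      holdout_active = character(), holdout_inactive = character(),
      active_chemicals = c(x = 20), rng_seed = i), class = "training_set")
    spec <- classifier_spec("SVM_L", list(cost = 1), seed = i)
    cross_validated_train(tset, expr_mat(v, rep("landmark", 20)), spec,
                          refit = FALSE)$internal_accuracy
  }, 0)
  # mean fold accuracy should hover around 0.5
  expect_lt(abs(mean(accs) - 0.5), 3 * sd(accs) / sqrt(length(accs)) + 0.05)
})

test_that("grid search ties resolve to the first grid point", {
  study <- make_gaussian_study(sep = 5)
  spec <- classifier_spec("KNN", grid = list(k = c(5, 7)), seed = 3)
  res <- cross_validated_train(study$tset, study$features, spec)
  cv <- res$cv_table
  if (cv$mean_accuracy[1] == cv$mean_accuracy[2]) {
    expect_equal(res$best_params$k, 5)
  } else {
    expect_equal(res$best_params$k, cv$k[which.max(cv$mean_accuracy)])
  }
})

test_that("prediction scores rank separable data perfectly and are deterministic", {
  study <- make_gaussian_study(sep = 4)
  spec <- classifier_spec("SVM_L", list(cost = 1), seed = 6)
  res <- cross_validated_train(study$tset, study$features, spec)
  sc <- predict_scores(res, study$features)
  expect_true(all(sc >= 0 & sc <= 1))
  act <- c(study$tset$active_profiles, study$tset$holdout_active)
  ina <- c(study$tset$inactive_profiles, study$tset$holdout_inactive)
  expect_gt(min(sc[act]), max(sc[ina]))  # AUC = 1 on separable data
  # duplicated profile column scores identically
  dup <- study$features$values[, c(colnames(study$features$values), act[1])]
  colnames(dup)[ncol(dup)] <- "dup_profile"
  sc2 <- predict_scores(res, expr_mat(dup, rep("landmark", nrow(dup))))
  expect_equal(unname(sc2["dup_profile"]), unname(sc2[act[1]]))
  # feature mismatch is diagnosed
  shrunk <- expr_mat(study$features$values[-1, , drop = FALSE],
                     rep("landmark", nrow(study$features$values) - 1))
  expect_error(predict_scores(res, shrunk), "missing feature")
})

test_that("all six algorithm families train on the same interface", {
  study <- make_gaussian_study(sep = 3, n_per_class = 25)
  for (alg in mie_algorithms()) {
    spec <- classifier_spec(alg, n_folds = 5, seed = 8)
    res <- cross_validated_train(study$tset, study$features, spec)
    expect_s3_class(res, "classifier_result")
    expect_gte(res$internal_accuracy, 0.8)
    sc <- predict_scores(res, study$features)
    expect_true(all(is.finite(sc)))
  }
})
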