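#' Determine MIEs eligible for classifier training
#'
#' An MIE (cluster) is eligible in a cell line when it has at least
#' \code{min_chemicals} chemicals annotated at support >=
#' \code{min_support} and the total number of (capped) profiles associated
#' with those chemicals in the cell line is at least \code{min_profiles}.
#'
#' @param clusters Cluster table from [cluster_mies()].
#' @param meta Profile metadata, already capped (see [cap_profiles()]).
#' @param cell_line Cell line to evaluate.
#' @param min_chemicals,min_support,min_profiles Eligibility floors
#'   (defaults 5, 5, 50).
#' @return Data frame \code{cluster_id}, \code{display_name},
#'   \code{n_chemicals}, \code{n_profiles}, \code{eligible}.
#' @export
eligible_mies <- function(clusters, meta, cell_line, min_chemicals = 5L,
                          min_support = 5L, min_profiles = 50L) {
  meta <- meta[meta$cell_line == cell_line & !is.na(meta$chemical_id), ,
               drop = FALSE]
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    chem <- clusters$chemicals[[i]]
    high <- names(chem)[chem >= min_support]
    n_prof <- sum(meta$chemical_id %in% high)
    data.frame(cluster_id = clusters$cluster_id[i],
               display_name = clusters$display_name[i],
               n_chemicals = length(high), n_profiles = n_prof,
               eligible = length(high) >= min_chemicals &&
                 n_prof >= min_profiles,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble a balanced active/inactive training set for one MIE
#'
#' MIE-active profiles are those of the cluster's high-support chemicals in
#' the given cell line. An equally sized MIE-inactive set is drawn at random
#' from profiles of chemicals that (a) carry no annotation to any of the
#' cluster's targets at any support level or mode and (b) are annotated to
#' some other MIE at support >= \code{min_support}. 20% of each class
#' (floor rounding) is split off as holdout. Profiles of
#' \code{exclude_chemicals} (e.g. exemplars) never appear anywhere.
#'
#' @param cluster One-row slice of the cluster table.
#' @param records Derived annotation records ([derive_mie_records()]),
#'   including low-support rows.
#' @param meta Capped metadata restricted to one cell line.
#' @param exclude_chemicals Chemicals excluded entirely (default none).
#' @param holdout_frac Holdout fraction per class (default 0.2).
#' @param min_support High-confidence support floor (default 5).
#' @param rng_seed Integer seed for inactive sampling and the holdout split.
#' @return An object of class \code{training_set}.
#' @export
assemble_training_set <- function(cluster, records, meta,
                                  exclude_chemicals = character(),
                                  holdout_frac = 0.2, min_support = 5L,
                                  rng_seed = 1L) {
  cl <- if (nrow(cluster) > 1L) stop("pass a single cluster row") else cluster
  meta <- meta[!is.na(meta$chemical_id), , drop = FALSE]
  if (length(unique(meta$cell_line)) > 1L)
    stop("meta must be restricted to a single cell line")
  targets <- cl$targets[[1L]]
  chem <- cl$chemicals[[1L]]
  active_chems <- setdiff(names(chem)[chem >= min_support],
                          exclude_chemicals)
  active <- meta$profile_id[meta$chemical_id %in% active_chems]
  if (!length(active)) stop("no active profiles available")

  # any annotation to the modeled targets, at any support and any mode,
  # blocks a chemical from the inactive pool
  blocked <- unique(records$chemical_id[records$target %in% targets])
  annotated <- unique(records$chemical_id[records$high_support])
  pool_chems <- setdiff(intersect(annotated, meta$chemical_id),
                        c(blocked, exclude_chemicals))
  pool <- meta$profile_id[meta$chemical_id %in% pool_chems]
  if (length(pool) < length(active))
    stop(sprintf(paste0("inactive pool too small for '%s': %d candidate",
                        " profiles (%d chemicals) for %d active profiles"),
                 cl$display_name, length(pool), length(pool_chems),
                 length(active)))

  withr::with_seed(rng_seed, {
    inactive <- sort(sample(sort(pool), length(active)))
    n_hold <- floor(holdout_frac * length(active))
    hold_a <- sort(sample(sort(active), n_hold))
    hold_i <- sort(sample(inactive, n_hold))
  })
  chem_counts <- table(meta$chemical_id[meta$profile_id %in% active])
  structure(list(
    mie_label = cl$display_name,
    cell_line = meta$cell_line[1L],
    active_profiles = setdiff(sort(active), hold_a),
    inactive_profiles = setdiff(inactive, hold_i),
    holdout_active = hold_a,
    holdout_inactive = hold_i,
    active_chemicals = setNames(as.integer(chem_counts),
                                names(chem_counts)),
    rng_seed = rng_seed), class = "training_set")
}

#' Validate training-set invariants
#'
#' Asserts class balance (before the holdout split), training/holdout
#' disjointness, and total exclusion of the given chemicals.
#'
#' @param tset A \code{training_set}.
#' @param meta Metadata used to build it.
#' @param exclude_chemicals Chemicals that must be absent everywhere.
#' @return \code{TRUE} invisibly; stops on violation.
#' @export
validate_training_set <- function(tset, meta,
                                  exclude_chemicals = character()) {
  all_a <- c(tset$active_profiles, tset$holdout_active)
  all_i <- c(tset$inactive_profiles, tset$holdout_inactive)
  if (length(all_a) != length(all_i))
    stop("active and inactive sets are not balanced")
  train <- c(tset$active_profiles, tset$inactive_profiles)
  hold <- c(tset$holdout_active, tset$holdout_inactive)
  if (length(intersect(train, hold)))
    stop("training and holdout sets overlap")
  if (anyDuplicated(c(all_a, all_i)))
    stop("a profile appears in more than one partition")
  if (length(exclude_chemicals)) {
    chems <- meta$chemical_id[meta$profile_id %in% c(all_a, all_i)]
    if (any(chems %in% exclude_chemicals, na.rm = TRUE))
      stop("excluded chemical present in training or holdout data")
  }
  invisible(TRUE)
}

#' Classification accuracy from a confusion matrix
#'
#' Proportion of correct assignments,
#' \eqn{(TP + TN) / (TP + TN + FP + FN)}.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total < 1) stop("at least one prediction is required")
  (tp + tn) / total
}

#' Specify a classifier family, hyperparameter grid, and folding
#'
#' Supported algorithms: support vector machines with linear
#' (\code{SVM_L}), polynomial (\code{SVM_P}) and radial (\code{SVM_R})
#' kernels, k-nearest neighbours (\code{KNN}), a single-hidden-layer
#' multilayer perceptron (\code{MLP}) and naive Bayes (\code{NB}).
#'
#' @param algorithm One of \code{"SVM_L"}, \code{"SVM_P"}, \code{"SVM_R"},
#'   \code{"KNN"}, \code{"MLP"}, \code{"NB"}.
#' @param grid Named list of hyperparameter value vectors; defaults per
#'   algorithm via [default_grid()].
#' @param n_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed governing fold assignment and stochastic fits.
#' @return An object of class \code{classifier_spec}.
#' @export
classifier_spec <- function(algorithm, grid = default_grid(algorithm),
                            n_folds = 5L, seed = 1L) {
  algorithm <- match.arg(algorithm, mie_algorithms())
  if (!length(grid)) stop("hyperparameter grid must be nonempty")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  structure(list(algorithm = algorithm, grid = grid,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @rdname classifier_spec
#' @export
mie_algorithms <- function() c("SVM_L", "SVM_P", "SVM_R", "KNN", "MLP", "NB")

#' @rdname classifier_spec
#' @export
default_grid <- function(algorithm) {
  switch(algorithm,
         SVM_L = list(cost = c(0.25, 0.5, 1)),
         SVM_P = list(cost = c(0.25, 0.5, 1), degree = 3),
         SVM_R = list(cost = c(0.25, 0.5, 1)),
         KNN = list(k = c(5, 7, 9)),
         MLP = list(size = c(3, 5, 9)),
         NB = list(laplace = c(0, 1)),
         stop("unknown algorithm: ", algorithm))
}

grid_rows <- function(grid) {
  g <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

# fit one model; X is profiles x features, y a factor with levels
# c("inactive", "active")
fit_model <- function(algorithm, X, y, params, probability = FALSE,
                      fit_seed = 1L) {
  handle <- withr::with_seed(fit_seed, switch(
    algorithm,
    SVM_L = e1071::svm(X, y, kernel = "linear", cost = params$cost,
                       scale = FALSE, probability = probability),
    SVM_P = e1071::svm(X, y, kernel = "polynomial", cost = params$cost,
                       degree = params$degree %||% 3, scale = FALSE,
                       probability = probability),
    SVM_R = e1071::svm(X, y, kernel = "radial", cost = params$cost,
                       scale = FALSE, probability = probability),
    KNN = list(train = X, y = y, k = params$k),
    MLP = nnet::nnet(X, as.numeric(y == "active"), size = params$size,
                     entropy = TRUE, maxit = 150, decay = 5e-4,
                     trace = FALSE, MaxNWts = 100000),
    NB = e1071::naiveBayes(X, y, laplace = params$laplace %||% 0)))
  structure(list(algorithm = algorithm, fit = handle, params = params,
                 feature_ids = colnames(X)), class = "mie_model")
}

# predict classes or active-class scores from a fitted handle
predict_model <- function(model, X, type = c("class", "score")) {
  type <- match.arg(type)
  miss <- setdiff(model$feature_ids, colnames(X))
  if (length(miss))
    stop("feature space mismatch; missing feature(s): ",
         paste(head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) " ..." else "")
  X <- X[, model$feature_ids, drop = FALSE]
  alg <- model$algorithm
  if (alg %in% c("SVM_L", "SVM_P", "SVM_R")) {
    if (type == "class") return(predict(model$fit, X))
    pr <- predict(model$fit, X, probability = TRUE)
    prob <- attr(pr, "probabilities")
    if (!is.null(prob) && "active" %in% colnames(prob))
      return(setNames(prob[, "active"], rownames(X)))
    # model fitted without a probability machine: logistic squash of the
    # signed decision value (rank-preserving)
    dv <- attr(predict(model$fit, X, decision.values = TRUE),
               "decision.values")[, 1L]
    sgn <- if (grepl("^active/", colnames(
      attr(predict(model$fit, X[1, , drop = FALSE],
                   decision.values = TRUE), "decision.values"))[1L]))
      1 else -1
    return(setNames(stats::plogis(sgn * dv), rownames(X)))
  }
  if (alg == "KNN") {
    pred <- class::knn(model$fit$train, X, model$fit$y, k = model$fit$k,
                       prob = TRUE)
    if (type == "class") return(pred)
    p <- attr(pred, "prob")
    return(setNames(ifelse(pred == "active", p, 1 - p), rownames(X)))
  }
  if (alg == "MLP") {
    s <- as.numeric(predict(model$fit, X, type = "raw"))
    if (type == "score") return(setNames(s, rownames(X)))
    return(factor(ifelse(s > 0.5, "active", "inactive"),
                  levels = c("inactive", "active")))
  }
  # NB
  if (type == "class") return(predict(model$fit, X))
  setNames(predict(model$fit, X, type = "raw")[, "active"], rownames(X))
}

#' Stratified fold assignment
#'
#' @param y Factor of class labels.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..n_folds, one per observation.
#' @export
stratified_folds <- function(y, n_folds = 5L, seed = 1L) {
  if (min(table(y)) < n_folds)
    stop("each class needs at least n_folds observations")
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (lev in levels(y)) {
      idx <- sample(which(y == lev))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Train a classifier with cross-validated grid search
#'
#' For each hyperparameter grid point, accuracies are computed on a fixed
#' stratified fold assignment; the best grid point is the one with maximal
#' mean fold accuracy (ties resolved in grid order). The model is then refit
#' on all training data and scored on the 20% holdout.
#'
#' @param tset A \code{training_set} from [assemble_training_set()].
#' @param features An [expr_mat()] containing all referenced profiles.
#' @param spec A [classifier_spec()].
#' @param refit Set \code{FALSE} to skip the final refit and holdout scoring
#'   (used for null ensembles, where only the internal accuracy is consumed).
#' @return An object of class \code{classifier_result} with elements
#'   \code{internal_accuracy} (mean of \code{fold_accuracies} at the best
#'   grid point), \code{holdout_accuracy}, \code{best_params},
#'   \code{cv_table} and the fitted \code{model}.
#' @export
cross_validated_train <- function(tset, features, spec, refit = TRUE) {
  stopifnot(inherits(tset, "training_set"),
            inherits(features, "expr_mat"),
            inherits(spec, "classifier_spec"))
  train_ids <- c(tset$active_profiles, tset$inactive_profiles)
  miss <- setdiff(train_ids, colnames(features$values))
  if (length(miss)) stop("training profiles missing from features: ",
                         paste(head(miss, 3L), collapse = ", "))
  X <- t(features$values[, train_ids, drop = FALSE])
  y <- factor(rep(c("active", "inactive"),
                  c(length(tset$active_profiles),
                    length(tset$inactive_profiles))),
              levels = c("inactive", "active"))
  folds <- stratified_folds(y, spec$n_folds, seed = spec$seed)
  rows <- grid_rows(spec$grid)
  cv_acc <- matrix(NA_real_, length(rows), spec$n_folds)
  for (gi in seq_along(rows)) {
    for (k in seq_len(spec$n_folds)) {
      in_k <- folds == k
      fit <- fit_model(spec$algorithm, X[!in_k, , drop = FALSE],
                       y[!in_k], rows[[gi]],
                       fit_seed = derive_seed(spec$seed, gi * 101L + k))
      pred <- predict_model(fit, X[in_k, , drop = FALSE], "class")
      cv_acc[gi, k] <- mean(pred == y[in_k])
    }
  }
  means <- rowMeans(cv_acc)
  best <- which.max(means)  # first index on ties
  model <- NULL
  holdout_accuracy <- NA_real_
  if (refit) {
    model <- fit_model(spec$algorithm, X, y, rows[[best]],
                       probability = TRUE,
                       fit_seed = derive_seed(spec$seed, 999983L))
    hold_ids <- c(tset$holdout_active, tset$holdout_inactive)
    if (length(hold_ids)) {
      Xh <- t(features$values[, hold_ids, drop = FALSE])
      yh <- factor(rep(c("active", "inactive"),
                       c(length(tset$holdout_active),
                         length(tset$holdout_inactive))),
                   levels = c("inactive", "active"))
      holdout_accuracy <- mean(predict_model(model, Xh, "class") == yh)
    }
  }
  structure(list(
    mie_label = tset$mie_label,
    algorithm = spec$algorithm,
    best_params = rows[[best]],
    internal_accuracy = means[best],
    holdout_accuracy = holdout_accuracy,
    fold_accuracies = cv_acc[best, ],
    cv_table = data.frame(do.call(rbind, lapply(rows, unlist)),
                          mean_accuracy = means),
    model = model,
    n_train = nrow(X)), class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("<classifier_result> %s / %s: internal %.3f, holdout %s\n",
              x$mie_label, x$algorithm, x$internal_accuracy,
              ifelse(is.na(x$holdout_accuracy), "NA",
                     sprintf("%.3f", x$holdout_accuracy))))
  invisible(x)
}

#' Score profiles with a fitted classifier
#'
#' Returns the MIE-activity score for every profile column, in \[0, 1\],
#' higher meaning more MIE-active. Class-probability outputs are used where
#' the algorithm provides them; otherwise a monotone logistic transform of
#' the decision value (only score ranks are consumed downstream).
#'
#' @param result A \code{classifier_result} with a fitted model.
#' @param features An [expr_mat()].
#' @return Named numeric vector of scores over the profile columns.
#' @export
predict_scores <- function(result, features) {
  stopifnot(inherits(result, "classifier_result"))
  if (is.null(result$model))
    stop("classifier_result carries no fitted model (trained with refit = FALSE?)")
  X <- t(features$values)
  predict_model(result$model, X, "score")
}
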