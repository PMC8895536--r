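#' Build a chemical-replacement null active set
#'
#' Each chemical in the original MIE-active set is swapped for a replacement
#' chemical drawn at random from chemicals that are annotated to at least
#' one other MIE at high support, carry no annotation to the modeled MIE's
#' targets at any support level or mode, and have at least as many available
#' profiles as the slot being filled. The replacement contributes exactly
#' the replaced chemical's profile count, so the null set matches the
#' original in both chemical count and total profile count. Replacements
#' are unique within one null draw.
#'
#' @param original_counts Named integer vector, original active chemical ->
#'   profile count used in training.
#' @param records Derived annotation records (all support levels).
#' @param meta Capped metadata restricted to one cell line.
#' @param targets Target gene symbols of the modeled cluster.
#' @param exclude_chemicals Chemicals barred from replacement (e.g.
#'   exemplars).
#' @param min_support High-confidence support floor (default 5).
#' @param rng_seed Integer seed.
#' @return List with \code{chemicals} (replacement -> profile count) and
#'   \code{profiles} (selected profile ids).
#' @export
build_null_active_set <- function(original_counts, records, meta, targets,
                                  exclude_chemicals = character(),
                                  min_support = 5L, rng_seed = 1L) {
  meta <- meta[!is.na(meta$chemical_id), , drop = FALSE]
  blocked <- unique(records$chemical_id[records$target %in% targets])
  annotated <- unique(records$chemical_id[records$high_support])
  avail <- table(meta$chemical_id)
  eligible <- setdiff(intersect(annotated, names(avail)),
                      c(blocked, exclude_chemicals))
  slots <- sort(original_counts, decreasing = TRUE)
  chosen <- character(0)
  profiles <- character(0)
  withr::with_seed(rng_seed, {
    for (s in seq_along(slots)) {
      need <- slots[s]
      cand <- setdiff(eligible[avail[eligible] >= need], chosen)
      if (!length(cand))
        stop(sprintf(paste0("no eligible replacement for slot %d ",
                            "(chemical '%s', %d profiles)"),
                     s, names(slots)[s], need))
      pick <- if (length(cand) == 1L) cand else sample(sort(cand), 1L)
      chosen <- c(chosen, pick)
      pool <- sort(meta$profile_id[meta$chemical_id == pick])
      profiles <- c(profiles,
                    if (length(pool) == need) pool
                    else sample(pool, need))
    }
  })
  list(chemicals = setNames(as.integer(slots), chosen),
       profiles = profiles)
}

#' Empirical p-value from a null accuracy distribution
#'
#' The proportion of null classifiers whose internal accuracy is greater
#' than or equal to the original classifier's.
#'
#' @param original_accuracy Internal accuracy of the original model.
#' @param null_accuracies Numeric vector of null internal accuracies.
#' @return p in \[0, 1\].
#' @export
empirical_p <- function(original_accuracy, null_accuracies) {
  stop_if_not_scalar_number(original_accuracy, "original_accuracy")
  if (!length(null_accuracies)) stop("null accuracy list is empty")
  mean(null_accuracies >= original_accuracy)
}

#' Train a chemical-replacement null ensemble for one classifier
#'
#' For each of \code{n_null} iterations, the MIE-active chemical set is
#' randomized via [build_null_active_set()], an inactive set is re-drawn
#' independently under the original rules (excluding the null-active
#' chemicals), and a classifier is trained with the identical fold and grid
#' procedure. Only the internal accuracy is recorded per iteration.
#'
#' @param result Original \code{classifier_result}.
#' @param tset Original \code{training_set}.
#' @param cluster The modeled cluster row.
#' @param records,meta,features As used for the original model (meta capped,
#'   one cell line).
#' @param spec The original [classifier_spec()].
#' @param n_null Number of null iterations (default 100; scale up for full
#'   runs).
#' @param exclude_chemicals Chemicals excluded everywhere (e.g. exemplars).
#' @param min_support High-confidence support floor (default 5).
#' @param rng_seed Integer seed for the ensemble.
#' @return An object of class \code{null_ensemble} with the null accuracy
#'   vector and the resulting [empirical_p()].
#' @export
null_ensemble <- function(result, tset, cluster, records, meta, features,
                          spec, n_null = 100L,
                          exclude_chemicals = character(),
                          min_support = 5L, rng_seed = 1L) {
  meta <- meta[!is.na(meta$chemical_id), , drop = FALSE]
  targets <- cluster$targets[[1L]]
  counts <- tset$active_chemicals
  null_acc <- numeric(n_null)
  for (i in seq_len(n_null)) {
    seed_i <- derive_seed(rng_seed, i)
    null_active <- build_null_active_set(
      counts, records, meta, targets,
      exclude_chemicals = exclude_chemicals,
      min_support = min_support, rng_seed = seed_i)
    null_tset <- null_training_set(null_active, tset, records, meta,
                                   targets, exclude_chemicals,
                                   min_support, seed_i)
    null_spec <- classifier_spec(spec$algorithm, spec$grid, spec$n_folds,
                                 seed = derive_seed(seed_i, 7L))
    fit <- cross_validated_train(null_tset, features, null_spec,
                                 refit = FALSE)
    null_acc[i] <- fit$internal_accuracy
  }
  p <- empirical_p(result$internal_accuracy, null_acc)
  structure(list(mie_label = result$mie_label,
                 algorithm = result$algorithm,
                 n_null = n_null,
                 null_internal_accuracies = null_acc,
                 original_internal_accuracy = result$internal_accuracy,
                 empirical_p = p), class = "null_ensemble")
}

# balanced inactive re-draw + holdout split for one null iteration; the
# inactive pool additionally excludes the null-active chemicals
null_training_set <- function(null_active, tset, records, meta, targets,
                              exclude_chemicals, min_support, rng_seed) {
  active <- sort(null_active$profiles)
  blocked <- unique(records$chemical_id[records$target %in% targets])
  annotated <- unique(records$chemical_id[records$high_support])
  pool_chems <- setdiff(intersect(annotated, meta$chemical_id),
                        c(blocked, exclude_chemicals,
                          names(null_active$chemicals)))
  pool <- meta$profile_id[meta$chemical_id %in% pool_chems]
  if (length(pool) < length(active))
    stop("inactive pool too small for null iteration")
  withr::with_seed(derive_seed(rng_seed, 13L), {
    inactive <- sort(sample(sort(pool), length(active)))
    n_hold <- floor(0.2 * length(active))
    hold_a <- sort(sample(active, n_hold))
    hold_i <- sort(sample(inactive, n_hold))
  })
  structure(list(
    mie_label = tset$mie_label, cell_line = tset$cell_line,
    active_profiles = setdiff(active, hold_a),
    inactive_profiles = setdiff(inactive, hold_i),
    holdout_active = hold_a, holdout_inactive = hold_i,
    active_chemicals = null_active$chemicals,
    rng_seed = rng_seed), class = "training_set")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "<null_ensemble> %s / %s: %d nulls, original %.3f, empirical p = %.3f\n",
    x$mie_label, x$algorithm, x$n_null, x$original_internal_accuracy,
    x$empirical_p))
  invisible(x)
}

#' Select candidate high-performance classifiers
#'
#' Per MIE, among non-excluded algorithms with empirical p <= \code{alpha},
#' the classifier with the highest internal accuracy is selected. MIEs with
#' no passing algorithm are omitted. Polynomial-kernel SVMs are excluded by
#' default (the overfitting-prone family).
#'
#' @param results Data frame with columns \code{mie}, \code{algorithm},
#'   \code{internal_accuracy}.
#' @param ensembles Data frame with columns \code{mie}, \code{algorithm},
#'   \code{empirical_p}.
#' @param alpha Significance threshold (default 0.05).
#' @param excluded_algorithms Algorithms ignored (default \code{"SVM_P"}).
#' @return Data frame of selected candidates, one row per passing MIE.
#' @export
select_candidates <- function(results, ensembles, alpha = 0.05,
                              excluded_algorithms = "SVM_P") {
  merged <- merge(results, ensembles, by = c("mie", "algorithm"))
  merged <- merged[!(merged$algorithm %in% excluded_algorithms) &
                     merged$empirical_p <= alpha, , drop = FALSE]
  if (!nrow(merged)) return(merged)
  keep <- unlist(lapply(split(seq_len(nrow(merged)), merged$mie),
                        function(idx) {
                          idx[which.max(merged$internal_accuracy[idx])]
                        }))
  out <- merged[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
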