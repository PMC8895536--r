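#' Run the MIE classification pipeline for one cell line
#'
#' End-to-end driver: derives and clusters MIE labels from raw annotation
#' records, caps profiles per chemical, selects and standardizes the
#' feature space, determines eligible MIEs, assembles balanced training
#' sets, trains one classifier per eligible MIE, and (optionally) attaches
#' a chemical-replacement null ensemble with its empirical p-value.
#'
#' @param records Raw annotation data frame ([read_annotations()] layout,
#'   decoded modes).
#' @param meta Profile metadata for all cell lines.
#' @param expr An [expr_mat()] covering the metadata profiles.
#' @param cell_line Cell line to model.
#' @param algorithm Classifier family (see [classifier_spec()]).
#' @param grid Hyperparameter grid (defaults per algorithm).
#' @param feature_space \code{"landmark"}, \code{"all_genes"} or
#'   \code{"pathway"}.
#' @param gene_sets Gene sets for the pathway space.
#' @param min_support,min_chemicals,min_profiles Eligibility floors
#'   (defaults 5, 5, 50).
#' @param cap Per-chemical profile cap (default 20).
#' @param cut_height MIE clustering cut height (default 0.7).
#' @param n_null Null classifiers per MIE (0 disables significance
#'   testing).
#' @param exclude_chemicals Chemicals (e.g. exemplars) excluded from all
#'   training, holdout and null sets.
#' @param seed Master seed; all randomness derives from it.
#' @return List with \code{clusters}, \code{eligibility}, \code{features}
#'   (standardized [expr_mat()]), \code{meta} (capped, cell-line
#'   restricted), \code{derived} records, per-MIE \code{fits} (training
#'   set, classifier result, ensemble) and a summary \code{results} data
#'   frame.
#' @export
mie_pipeline <- function(records, meta, expr, cell_line,
                         algorithm = "SVM_L",
                         grid = default_grid(algorithm),
                         feature_space = "landmark", gene_sets = NULL,
                         min_support = 5L, min_chemicals = 5L,
                         min_profiles = 50L, cap = 20L, cut_height = 0.7,
                         n_null = 0L, exclude_chemicals = character(),
                         seed = 1L) {
  derived <- derive_mie_records(records, min_support)
  clusters <- cluster_mies(collect_mies(derived), cut_height)

  meta_cl <- meta[meta$cell_line == cell_line, , drop = FALSE]
  capped <- cap_profiles(meta_cl, cap, rng_seed = derive_seed(seed, 1L))
  feats <- select_feature_space(
    expr_mat(expr$values[, meta_cl$profile_id, drop = FALSE],
             unname(expr$feature_class)),
    feature_space, gene_sets = gene_sets)
  feats <- standardize(feats)

  elig <- eligible_mies(clusters, capped, cell_line, min_chemicals,
                        min_support, min_profiles)
  fits <- list()
  for (i in which(elig$eligible)) {
    cl <- clusters[i, , drop = FALSE]
    mie <- cl$display_name
    sub_seed <- derive_seed(seed, 1000L + cl$cluster_id)
    tset <- assemble_training_set(cl, derived, capped,
                                  exclude_chemicals = exclude_chemicals,
                                  min_support = min_support,
                                  rng_seed = sub_seed)
    spec <- classifier_spec(algorithm, grid,
                            seed = derive_seed(sub_seed, 2L))
    res <- cross_validated_train(tset, feats, spec)
    ens <- NULL
    if (n_null > 0L) {
      ens <- null_ensemble(res, tset, cl, derived, capped, feats, spec,
                           n_null = n_null,
                           exclude_chemicals = exclude_chemicals,
                           min_support = min_support,
                           rng_seed = derive_seed(sub_seed, 3L))
    }
    fits[[mie]] <- list(cluster = cl, training_set = tset, result = res,
                        ensemble = ens)
  }
  results <- do.call(rbind, lapply(fits, function(f) data.frame(
    mie = f$result$mie_label, cell_line = cell_line,
    algorithm = f$result$algorithm,
    internal_accuracy = f$result$internal_accuracy,
    holdout_accuracy = f$result$holdout_accuracy,
    empirical_p = if (is.null(f$ensemble)) NA_real_
    else f$ensemble$empirical_p,
    stringsAsFactors = FALSE)))
  rownames(results) <- NULL
  list(clusters = clusters, eligibility = elig, features = feats,
       meta = capped, derived = derived, fits = fits, results = results)
}

#' Moderate-support chemicals of a cluster
#'
#' Chemicals annotated to any of the cluster's targets only at moderate
#' support (3-4), used for rank-based enrichment validation.
#'
#' @param cluster One cluster row.
#' @param derived Derived annotation records.
#' @param band Inclusive support band (default \code{c(3, 4)}).
#' @return Character vector of chemical ids.
#' @export
moderate_support_chemicals <- function(cluster, derived, band = c(3L, 4L)) {
  rec <- derived[derived$target %in% cluster$targets[[1L]], , drop = FALSE]
  by_chem <- tapply(rec$support, rec$chemical_id, max)
  names(by_chem)[by_chem >= band[1L] & by_chem <= band[2L]]
}
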