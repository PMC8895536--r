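#' Construct an expression matrix container
#'
#' A light container for a features-by-profiles matrix of moderated z-scores
#' (or pathway scores) with a per-feature class flag distinguishing directly
#' measured landmark genes, computationally inferred genes, and derived
#' pathway features.
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   profiles in columns (colnames = profile ids).
#' @param feature_class Character vector along rows, each one of
#'   \code{"landmark"}, \code{"inferred"}, \code{"pathway"}.
#' @return An object of class \code{expr_mat}.
#' @export
expr_mat <- function(values, feature_class) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique rownames (feature ids)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("values must have unique colnames (profile ids)")
  if (anyNA(values)) stop("expression values must have no missing entries")
  if (length(feature_class) != nrow(values))
    stop("feature_class must have one entry per feature")
  if (!all(feature_class %in% c("landmark", "inferred", "pathway")))
    stop("feature_class entries must be landmark, inferred or pathway")
  structure(list(values = values,
                 feature_class = setNames(feature_class, rownames(values))),
            class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d features x %d profiles (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$feature_class)),
                            table(x$feature_class)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Read / write expression matrices as TSV
#'
#' Layout: first column \code{feature_id}, second column
#' \code{feature_class}, remaining columns one per profile.
#'
#' @param path File path.
#' @return [read_expression()] returns an [expr_mat()].
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3L || names(df)[1L] != "feature_id" ||
      names(df)[2L] != "feature_class")
    stop("expression TSV must start with feature_id and feature_class columns")
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(values) <- df$feature_id
  expr_mat(values, df$feature_class)
}

#' @rdname read_expression
#' @param x An [expr_mat()].
#' @export
write_expression <- function(x, path) {
  df <- data.frame(feature_id = rownames(x$values),
                   feature_class = unname(x$feature_class),
                   x$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read profile metadata
#'
#' Expected columns: \code{profile_id}, \code{chemical_id} (empty or
#' \code{NA} for non-chemical perturbagens), \code{cell_line}, \code{dose},
#' \code{dose_unit}, \code{duration_h}. Dose and duration are carried as
#' metadata only; no filtering is applied on them.
#'
#' @param path TSV path.
#' @return Data frame of profile metadata.
#' @export
read_profile_meta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  needed <- c("profile_id", "chemical_id", "cell_line")
  if (!all(needed %in% names(df)))
    stop("metadata must contain columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(df$profile_id)) stop("profile_id values must be unique")
  df
}

#' Attach chemical identifiers to profile metadata
#'
#' Joins a perturbagen-to-chemical mapping onto metadata. Profiles whose
#' perturbagen has no mapping keep a missing \code{chemical_id} and are
#' thereby ineligible for training labels.
#'
#' @param meta Metadata data frame with a \code{perturbagen_id} column.
#' @param mapping Data frame with columns \code{perturbagen_id},
#'   \code{chemical_id}; keys must be unique.
#' @return \code{meta} with \code{chemical_id} filled in and a logical
#'   \code{trainable} column.
#' @export
join_chemicals <- function(meta, mapping) {
  if (!"perturbagen_id" %in% names(meta))
    stop("meta must contain a perturbagen_id column")
  dup <- unique(mapping$perturbagen_id[duplicated(mapping$perturbagen_id)])
  if (length(dup)) {
    conflict <- vapply(dup, function(p) {
      length(unique(mapping$chemical_id[mapping$perturbagen_id == p])) > 1L
    }, TRUE)
    if (any(conflict))
      stop("perturbagen(s) mapped to multiple chemical_ids: ",
           paste(dup[conflict], collapse = ", "))
    mapping <- mapping[!duplicated(mapping$perturbagen_id), , drop = FALSE]
  }
  idx <- match(meta$perturbagen_id, mapping$perturbagen_id)
  meta$chemical_id <- mapping$chemical_id[idx]
  meta$trainable <- !is.na(meta$chemical_id)
  meta
}

#' Cap the number of profiles retained per chemical
#'
#' Chemicals with more than \code{max_per_chemical} profiles in a cell line
#' have a random subset of exactly \code{max_per_chemical} retained, so that
#' no single heavily-assayed chemical dominates a training set. Profiles with
#' a missing \code{chemical_id} (non-chemical perturbagens) are never
#' removed. Selection is reproducible for a fixed seed and independent of
#' input row order.
#'
#' @param meta Profile metadata data frame.
#' @param max_per_chemical Cap (default 20).
#' @param rng_seed Integer seed.
#' @return The capped metadata (original row order preserved).
#' @export
cap_profiles <- function(meta, max_per_chemical = 20L, rng_seed = 1L) {
  if (max_per_chemical < 1L) stop("max_per_chemical must be >= 1")
  keep <- rep(TRUE, nrow(meta))
  key <- paste(meta$cell_line, meta$chemical_id, sep = "\r")
  key[is.na(meta$chemical_id)] <- NA
  groups <- sort(unique(key[!is.na(key)]))
  withr::with_seed(rng_seed, {
    for (g in groups) {
      idx <- which(!is.na(key) & key == g)
      if (length(idx) > max_per_chemical) {
        idx <- idx[order(meta$profile_id[idx])]
        keep[sample(idx, length(idx) - max_per_chemical)] <- FALSE
      }
    }
  })
  meta[keep, , drop = FALSE]
}

#' Standardize features across profiles
#'
#' Subtracts each feature's mean across profiles and divides by its sample
#' standard deviation (n - 1 denominator). Constant features map to all
#' zeros so matrix shapes stay stable.
#'
#' @param x An [expr_mat()] with at least two profiles.
#' @return Standardized [expr_mat()].
#' @export
standardize <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  if (ncol(x$values) < 2L) stop("standardization needs >= 2 profiles")
  m <- rowMeans(x$values)
  s <- apply(x$values, 1L, sd)
  v <- (x$values - m) / ifelse(s > 0, s, 1)
  v[s == 0, ] <- 0
  expr_mat(v, unname(x$feature_class))
}

#' Select the feature space used for classifier training
#'
#' \code{"landmark"} keeps directly measured genes only; \code{"all_genes"}
#' keeps landmark plus inferred genes; \code{"pathway"} converts gene-level
#' values to single-sample gene-set enrichment scores (see
#' [pathway_matrix()]) which are then standardized exactly like gene
#' features.
#'
#' @param x An [expr_mat()].
#' @param space One of \code{"landmark"}, \code{"all_genes"},
#'   \code{"pathway"}.
#' @param gene_sets Named list of gene symbol vectors; required for
#'   \code{space = "pathway"}.
#' @param weight,stat Passed to [pathway_matrix()].
#' @return An [expr_mat()] in the requested space (profile order unchanged).
#' @export
select_feature_space <- function(x, space = c("landmark", "all_genes",
                                              "pathway"),
                                 gene_sets = NULL, weight = 0.25,
                                 stat = "integral") {
  space <- match.arg(space)
  stopifnot(inherits(x, "expr_mat"))
  if (space == "pathway") {
    if (is.null(gene_sets))
      stop("gene_sets are required for the pathway feature space")
    return(standardize(pathway_matrix(x, gene_sets, weight = weight,
                                      stat = stat)))
  }
  want <- if (space == "landmark") "landmark" else c("landmark", "inferred")
  keep <- x$feature_class %in% want
  if (!any(keep))
    stop("no features of class ", paste(want, collapse = "/"),
         " present in the matrix")
  expr_mat(x$values[keep, , drop = FALSE], unname(x$feature_class[keep]))
}
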