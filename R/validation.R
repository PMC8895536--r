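#' Select exemplar chemicals for modeled MIEs
#'
#' Candidate exemplars are the union of each MIE's top chemicals ranked by
#' support level (top 10 by default, among high-support chemicals with at
#' least one profile). MIEs are processed iteratively (descending best
#' candidate support, ties by label); a candidate is feasible only if
#' excluding all its profiles -- on top of previously selected exemplars --
#' leaves every modeled MIE with at least \code{min_chemicals} chemicals and
#' \code{min_profiles} profiles. A feasible chemical appearing in several
#' exemplar-lacking MIEs' candidate lists is assigned to all of them at
#' once. MIEs for which no candidate is feasible get a missing assignment.
#'
#' @param clusters Modeled cluster rows (see [cluster_mies()]).
#' @param meta Capped metadata restricted to one cell line.
#' @param min_chemicals,min_profiles Training-data floors that must survive
#'   exclusion (defaults 5 and 50).
#' @param min_support High-confidence support floor (default 5).
#' @param top_n Candidate list depth per MIE (default 10).
#' @return Data frame \code{mie}, \code{chemical_id}, \code{support}
#'   (\code{NA}s for unassignable MIEs).
#' @export
select_exemplars <- function(clusters, meta, min_chemicals = 5L,
                             min_profiles = 50L, min_support = 5L,
                             top_n = 10L) {
  meta <- meta[!is.na(meta$chemical_id), , drop = FALSE]
  prof_counts <- table(meta$chemical_id)
  count_of <- function(chems) {
    n <- prof_counts[chems]
    sum(n, na.rm = TRUE)
  }
  # per-MIE high-support chemicals with profiles, and top-n candidates
  info <- lapply(seq_len(nrow(clusters)), function(i) {
    chem <- clusters$chemicals[[i]]
    chem <- chem[chem >= min_support]
    chem <- chem[names(chem) %in% names(prof_counts)]
    chem <- chem[order(-chem, names(chem))]
    list(mie = clusters$display_name[i], chems = chem,
         candidates = head(chem, top_n))
  })
  names(info) <- vapply(info, `[[`, "", "mie")
  feasible_after <- function(excluded) {
    all(vapply(info, function(x) {
      left <- setdiff(names(x$chems), excluded)
      length(left) >= min_chemicals && count_of(left) >= min_profiles
    }, TRUE))
  }
  best_support <- vapply(info, function(x)
    if (length(x$candidates)) max(x$candidates) else -Inf, 0)
  order_mies <- names(info)[order(-best_support, names(info))]
  assigned <- setNames(rep(NA_character_, length(info)), names(info))
  support_of <- setNames(rep(NA_integer_, length(info)), names(info))
  excluded <- character(0)
  for (m in order_mies) {
    if (!is.na(assigned[m])) next
    for (cand in names(info[[m]]$candidates)) {
      if (cand %in% excluded) next
      if (feasible_after(c(excluded, cand))) {
        excluded <- c(excluded, cand)
        for (m2 in names(info)) {
          if (is.na(assigned[m2]) && cand %in% names(info[[m2]]$candidates)) {
            assigned[m2] <- cand
            support_of[m2] <- info[[m2]]$candidates[[cand]]
          }
        }
        break
      }
    }
  }
  data.frame(mie = names(assigned), chemical_id = unname(assigned),
             support = unname(support_of), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Percentile rank from a rank and a population size
#'
#' Convention: \code{(n - rank) / (n - 1)}, so rank 1 maps to 1 and rank
#' \code{n} to 0.
#'
#' @param rank Rank with 1 = highest (ties may carry fractional mean ranks).
#' @param n Number of ranked chemicals.
#' @return Percentile in \[0, 1\].
#' @export
percentile_from_rank <- function(rank, n) {
  if (any(n < 2)) stop("at least two ranked chemicals are required")
  (n - rank) / (n - 1)
}

#' Chemical-level median scores, ranks and percentiles
#'
#' Profile-level prediction scores are aggregated to a median per chemical;
#' chemicals are ranked (1 = highest median, ties share the mean of their
#' ranks) and converted to percentiles via [percentile_from_rank()].
#' Profiles with missing \code{chemical_id} (non-chemical perturbagens) and
#' profiles of excluded chemicals (e.g. a classifier's training chemicals)
#' are removed first.
#'
#' @param scores Named numeric vector of per-profile scores.
#' @param meta Profile metadata covering the scored profiles.
#' @param exclude_chemicals Chemicals removed before ranking.
#' @return Data frame \code{chemical_id}, \code{median_score}, \code{rank},
#'   \code{n}, \code{percentile}, sorted by rank.
#' @export
chemical_percentiles <- function(scores, meta,
                                 exclude_chemicals = character()) {
  idx <- match(names(scores), meta$profile_id)
  if (anyNA(idx)) stop("scores contain profiles absent from metadata")
  chem <- meta$chemical_id[idx]
  keep <- !is.na(chem) & !(chem %in% exclude_chemicals)
  chem <- chem[keep]
  sc <- scores[keep]
  meds <- tapply(sc, chem, median)
  n <- length(meds)
  if (n < 2L) stop("fewer than two chemicals remain after exclusions")
  rk <- rank(-meds, ties.method = "average")
  out <- data.frame(chemical_id = names(meds),
                    median_score = as.numeric(meds),
                    rank = as.numeric(rk), n = n,
                    percentile = percentile_from_rank(as.numeric(rk), n),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$rank), , drop = FALSE]
}

#' Confirm candidate classifiers by exemplar percentile rank
#'
#' A candidate is confirmed when its training-excluded exemplar chemical
#' ranks at or above \code{threshold} (default: top 10% of all chemicals).
#' Candidates without an exemplar pass through flagged
#' \code{"unconfirmable"}.
#'
#' @param candidates Data frame with a \code{mie} column (see
#'   [select_candidates()]).
#' @param exemplars Data frame from [select_exemplars()].
#' @param rank_tables Named list (by MIE) of [chemical_percentiles()]
#'   tables computed with each classifier's training chemicals excluded.
#' @param threshold Confirmation floor on the exemplar percentile
#'   (default 0.90).
#' @return Data frame \code{mie}, \code{exemplar}, \code{exemplar_percentile},
#'   \code{status} in \{confirmed, rejected, unconfirmable\}.
#' @export
confirm_high_performance <- function(candidates, exemplars, rank_tables,
                                     threshold = 0.90) {
  rows <- lapply(candidates$mie, function(m) {
    ex <- exemplars$chemical_id[match(m, exemplars$mie)]
    if (is.na(ex) || is.null(rank_tables[[m]]))
      return(data.frame(mie = m, exemplar = NA_character_,
                        exemplar_percentile = NA_real_,
                        status = "unconfirmable", stringsAsFactors = FALSE))
    tab <- rank_tables[[m]]
    p <- tab$percentile[match(ex, tab$chemical_id)]
    if (is.na(p))
      return(data.frame(mie = m, exemplar = ex,
                        exemplar_percentile = NA_real_,
                        status = "unconfirmable", stringsAsFactors = FALSE))
    data.frame(mie = m, exemplar = ex, exemplar_percentile = p,
               status = if (p >= threshold) "confirmed" else "rejected",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-sided KS enrichment of a score subset
#'
#' Two-sample, one-tailed Kolmogorov-Smirnov test of whether the subset's
#' scores are stochastically greater than the background's. The statistic is
#' the maximum of (background ECDF - subset ECDF).
#'
#' @param subset_scores Scores of the chemicals under test (e.g.
#'   moderate-support chemicals plus the exemplar).
#' @param background_scores Scores of all chemicals.
#' @return List with \code{statistic} and \code{p_value}.
#' @export
ks_enrichment <- function(subset_scores, background_scores) {
  if (!length(subset_scores)) stop("subset is empty")
  if (length(background_scores) <= length(subset_scores))
    stop("background must be larger than the subset")
  ht <- suppressWarnings(
    ks.test(subset_scores, background_scores, alternative = "less"))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Representative baseline expression (NX) for an MIE
#'
#' The median normalized-expression value across the MIE's target genes in
#' one cell line; targets without a value are dropped with a warning.
#'
#' @param nx Data frame with columns \code{gene}, \code{cell_line},
#'   \code{nx}.
#' @param targets Target gene symbols of the MIE.
#' @param cell_line Cell line to look up.
#' @return Median NX value.
#' @export
mie_nx <- function(nx, targets, cell_line) {
  sub <- nx[nx$cell_line == cell_line & nx$gene %in% targets, , drop = FALSE]
  if (!nrow(sub)) stop("no NX values available for targets: ",
                       paste(targets, collapse = ", "))
  missing <- setdiff(targets, sub$gene)
  if (length(missing))
    warning("no NX value for target(s): ", paste(missing, collapse = ", "))
  median(sub$nx)
}

#' Log2 fold change of NX values between two cell lines
#'
#' \code{log2((nx_a + pseudocount) / (nx_b + pseudocount))}. Values are
#' stored uncapped; any plotting cap (e.g. +/- 4) is a display choice only.
#'
#' @param nx_a,nx_b Non-negative NX values.
#' @param pseudocount Added to both values (default 0.1).
#' @return Signed log2 fold change.
#' @export
nx_l2fc <- function(nx_a, nx_b, pseudocount = 0.1) {
  if (any(c(nx_a, nx_b) < 0)) stop("NX values must be non-negative")
  log2((nx_a + pseudocount) / (nx_b + pseudocount))
}

#' Compare classifier accuracies across two cell lines
#'
#' Inner-joins two per-MIE accuracy tables, computes the Pearson
#' correlation with its t-test p-value and the least-squares line, and
#' tabulates the per-MIE accuracy difference (a - b).
#'
#' @param results_a,results_b Data frames with columns \code{mie},
#'   \code{internal_accuracy}.
#' @return List with \code{table} (joined, with \code{accuracy_diff}),
#'   \code{r}, \code{p_value}, \code{slope}, \code{intercept}.
#' @export
compare_cell_lines <- function(results_a, results_b) {
  tab <- merge(results_a[, c("mie", "internal_accuracy")],
               results_b[, c("mie", "internal_accuracy")],
               by = "mie", suffixes = c("_a", "_b"))
  if (nrow(tab) < 3L) stop("need at least 3 MIEs modeled in both cell lines")
  tab$accuracy_diff <- tab$internal_accuracy_a - tab$internal_accuracy_b
  ct <- cor.test(tab$internal_accuracy_a, tab$internal_accuracy_b)
  fit <- lm(internal_accuracy_b ~ internal_accuracy_a, data = tab)
  list(table = tab[order(-tab$accuracy_diff), , drop = FALSE],
       r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
}

#' Paired Wilcoxon signed-rank comparison of accuracy vectors
#'
#' @param accuracies_a,accuracies_b Equal-length paired vectors (length >=
#'   5).
#' @param alternative \code{"two_sided"} or \code{"greater"} (a greater
#'   than b).
#' @return p-value; identical vectors give the degenerate p = 1.
#' @export
paired_rank_comparison <- function(accuracies_a, accuracies_b,
                                   alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  if (length(accuracies_a) != length(accuracies_b))
    stop("paired vectors must have equal length")
  if (length(accuracies_a) < 5L) stop("need at least 5 pairs")
  if (all(accuracies_a == accuracies_b)) return(1)
  alt <- if (alternative == "two_sided") "two.sided" else "greater"
  suppressWarnings(
    wilcox.test(accuracies_a, accuracies_b, paired = TRUE,
                alternative = alt)$p.value)
}
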