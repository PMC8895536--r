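#' Configuration for the synthetic LINCS-like study generator
#'
#' Defines the study conditions under which the pipeline is exercised:
#' chemical and MIE counts, the landmark/inferred feature split, planted
#' signature geometry, annotation support structure (including
#' moderate-support and unspecified-mode records, opposing-mode conflicts
#' and paralog MIE pairs), the per-chemical profile-count distribution with
#' an explicit heavy tail beyond the 20-profile cap, and per-cell-line
#' responsiveness multipliers.
#'
#' @param n_chemicals Number of chemicals (default 120).
#' @param n_mies Number of planted MIE groups (default 8).
#' @param n_landmark,n_inferred Feature counts (defaults 100 and 200).
#' @param genes_per_signature Landmark genes per planted signature
#'   (default 10).
#' @param effect_size Signal amplitude in z-score units (default 2).
#' @param noise_sd Gaussian noise standard deviation (default 1).
#' @param profiles_mean,profiles_dispersion Negative-binomial mean and size
#'   for per-chemical profile counts, truncated to \[3, 20\] (defaults 8
#'   and 5).
#' @param profiles_tail_prob Probability that a chemical instead draws a
#'   count above 20 (default 0.05), emulating heavily assayed chemicals.
#' @param support_max Upper bound of high-confidence support levels
#'   (default 30; high-support values are drawn uniformly from
#'   5..\code{support_max}).
#' @param fraction_moderate Fraction of each group's chemicals annotated
#'   only at support 3-4 (default 0.2).
#' @param fraction_unspecified Unspecified-mode records added, as a fraction
#'   of the real record count (default 0.05).
#' @param paralog_pairs Number of MIE groups annotated under two paralogous
#'   target symbols with >= 90% shared chemicals (default 2).
#' @param conflicts_per_group Chemicals per group that also carry a
#'   lower-support opposing-mode record (default 2).
#' @param cell_lines Cell line names (default \code{c("CLA", "CLB")}).
#' @param responsiveness Optional cell_line x MIE matrix of multipliers in
#'   \[0, 1\]; the default is fully responsive everywhere except MIE 1 in
#'   the second cell line (multiplier 0), planting one cross-cell contrast.
#' @param n_control_profiles Non-chemical control profiles per cell line
#'   (default 10).
#' @param seed Integer master seed.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(n_chemicals = 120L, n_mies = 8L, n_landmark = 100L,
                       n_inferred = 200L, genes_per_signature = 10L,
                       effect_size = 2, noise_sd = 1, profiles_mean = 8,
                       profiles_dispersion = 5, profiles_tail_prob = 0.05,
                       support_max = 30L, fraction_moderate = 0.2,
                       fraction_unspecified = 0.05, paralog_pairs = 2L,
                       conflicts_per_group = 2L,
                       cell_lines = c("CLA", "CLB"),
                       responsiveness = NULL, n_control_profiles = 10L,
                       seed = 1L) {
  cfg <- list(n_chemicals = as.integer(n_chemicals),
              n_mies = as.integer(n_mies),
              n_landmark = as.integer(n_landmark),
              n_inferred = as.integer(n_inferred),
              genes_per_signature = as.integer(genes_per_signature),
              effect_size = effect_size, noise_sd = noise_sd,
              profiles_mean = profiles_mean,
              profiles_dispersion = profiles_dispersion,
              profiles_tail_prob = profiles_tail_prob,
              support_max = as.integer(support_max),
              fraction_moderate = fraction_moderate,
              fraction_unspecified = fraction_unspecified,
              paralog_pairs = as.integer(paralog_pairs),
              conflicts_per_group = as.integer(conflicts_per_group),
              cell_lines = cell_lines,
              n_control_profiles = as.integer(n_control_profiles),
              seed = as.integer(seed))
  if (any(c(cfg$n_chemicals, cfg$n_mies, cfg$n_landmark,
            cfg$genes_per_signature) < 1L))
    stop("all counts must be positive")
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (cfg$n_mies * cfg$genes_per_signature > cfg$n_landmark)
    stop("more signature genes requested than landmark genes available")
  if (cfg$paralog_pairs > cfg$n_mies)
    stop("paralog_pairs cannot exceed n_mies")
  if (is.null(responsiveness)) {
    responsiveness <- matrix(1, length(cell_lines), cfg$n_mies,
                             dimnames = list(cell_lines, NULL))
    if (length(cell_lines) >= 2L) responsiveness[2L, 1L] <- 0
  }
  if (any(responsiveness < 0 | responsiveness > 1))
    stop("responsiveness multipliers must lie in [0, 1]")
  cfg$responsiveness <- responsiveness
  structure(cfg, class = "sim_config")
}

landmark_ids <- function(cfg) sprintf("L%03d", seq_len(cfg$n_landmark))
inferred_ids <- function(cfg) sprintf("I%03d", seq_len(cfg$n_inferred))

#' Simulate a chemical-protein annotation table with planted MIE structure
#'
#' Generates records emulating a literature-support-annotated chemical-
#' target database: each chemical belongs to one planted MIE group, most at
#' high support (5..support_max) and a configured fraction only at moderate
#' support (3-4); paralog groups are annotated under two target symbols with
#' >= 90% shared chemicals; some chemicals carry an additional lower-support
#' opposing-mode record; unspecified-mode rows are sprinkled in.
#'
#' @param config A [sim_config()].
#' @return List with \code{records} (annotation data frame in
#'   [read_annotations()] layout) and \code{truth} (planted group
#'   membership, signatures, modes, targets, responsiveness).
#' @export
simulate_annotations <- function(config) {
  cfg <- config
  chems <- sprintf("CHEM%03d", seq_len(cfg$n_chemicals))
  modes <- rep(c("positive", "negative"), length.out = cfg$n_mies)
  targets <- lapply(seq_len(cfg$n_mies), function(g) {
    if (g <= cfg$paralog_pairs) sprintf("TGT%02d%s", g, c("A", "B"))
    else sprintf("TGT%02d", g)
  })
  group_of <- rep(seq_len(cfg$n_mies), length.out = cfg$n_chemicals)

  withr::with_seed(derive_seed(cfg$seed, 1L), {
    sig_idx <- matrix(sample(cfg$n_landmark,
                             cfg$n_mies * cfg$genes_per_signature),
                      nrow = cfg$n_mies, byrow = TRUE)
    sig_w <- matrix(sample(c(-1, 1), cfg$n_mies * cfg$genes_per_signature,
                           replace = TRUE),
                    nrow = cfg$n_mies)
    rec <- list()
    for (g in seq_len(cfg$n_mies)) {
      cg <- chems[group_of == g]
      n_mod <- round(cfg$fraction_moderate * length(cg))
      support <- c(sample(3:4, n_mod, replace = TRUE),
                   sample(5:cfg$support_max, length(cg) - n_mod,
                          replace = TRUE))
      # moderate-support chemicals last in the group ordering
      support <- support[order(c(rep(2L, n_mod),
                                 rep(1L, length(cg) - n_mod)))]
      for (tg in seq_along(targets[[g]])) {
        keep <- if (tg == 1L) seq_along(cg)
        else seq_len(ceiling(0.92 * length(cg)))
        rec[[length(rec) + 1L]] <- data.frame(
          chemical_id = cg[keep], target = targets[[g]][tg],
          mode = modes[g], support = support[keep],
          stringsAsFactors = FALSE)
      }
      # opposing-mode conflicts at strictly lower support
      high <- which(support >= 5L)
      n_conf <- min(cfg$conflicts_per_group, length(high))
      if (n_conf > 0L) {
        idx <- high[seq_len(n_conf)]
        rec[[length(rec) + 1L]] <- data.frame(
          chemical_id = cg[idx], target = targets[[g]][1L],
          mode = ifelse(modes[g] == "positive", "negative", "positive"),
          support = pmax(1L, support[idx] - 2L),
          stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, rec)
    n_unspec <- round(cfg$fraction_unspecified * nrow(records))
    if (n_unspec > 0L) {
      records <- rbind(records, data.frame(
        chemical_id = sample(chems, n_unspec, replace = TRUE),
        target = sprintf("MISC%02d", sample(20L, n_unspec, replace = TRUE)),
        mode = "unspecified",
        support = sample(10L, n_unspec, replace = TRUE),
        stringsAsFactors = FALSE))
    }
    records <- records[!duplicated(records[c("chemical_id", "target",
                                             "mode")]), , drop = FALSE]
  })
  rownames(records) <- NULL
  truth <- list(chemicals = chems, group_of = setNames(group_of, chems),
                modes = modes, targets = targets,
                signature_idx = sig_idx, signature_weights = sig_w,
                responsiveness = cfg$responsiveness)
  list(records = records, truth = truth)
}

#' Simulate expression profiles, metadata and an NX table
#'
#' Each profile of chemical c in cell line L is the sum of c's planted MIE
#' signatures scaled by \code{effect_size} and the cell line's
#' responsiveness multiplier, plus Gaussian noise, over landmark genes;
#' inferred genes are fixed random linear combinations of the landmark
#' values with extra noise. Per-chemical profile counts follow the
#' configured distribution including a tail beyond 20; non-chemical control
#' profiles carry a missing chemical id. The NX table assigns each target
#' gene a baseline expression of 10 x responsiveness in each cell line, so
#' an unresponsive cell line shows NX = 0 for that MIE's targets.
#'
#' @param config A [sim_config()].
#' @param truth Truth object from [simulate_annotations()].
#' @return List with \code{expr} (an [expr_mat()]), \code{meta} (profile
#'   metadata) and \code{nx} (gene x cell line NX table).
#' @export
simulate_expression <- function(config, truth) {
  cfg <- config
  withr::with_seed(derive_seed(cfg$seed, 2L), {
    # per-chemical, per-cell-line profile counts
    meta_rows <- list()
    for (line in cfg$cell_lines) {
      for (ch in truth$chemicals) {
        if (runif(1) < cfg$profiles_tail_prob) {
          n <- 21L + rpois(1L, 3)
        } else {
          n <- min(20L, max(3L, rnbinom(1L, mu = cfg$profiles_mean,
                                        size = cfg$profiles_dispersion)))
        }
        meta_rows[[length(meta_rows) + 1L]] <- data.frame(
          chemical_id = rep(ch, n), cell_line = line,
          stringsAsFactors = FALSE)
      }
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        chemical_id = rep(NA_character_, cfg$n_control_profiles),
        cell_line = line, stringsAsFactors = FALSE)
    }
    meta <- do.call(rbind, meta_rows)
    meta <- data.frame(profile_id = sprintf("P%05d", seq_len(nrow(meta))),
                       meta,
                       dose = sample(c(0.1, 1, 10), nrow(meta),
                                     replace = TRUE),
                       dose_unit = "uM",
                       duration_h = sample(c(6, 24), nrow(meta),
                                           replace = TRUE),
                       stringsAsFactors = FALSE)

    # mean landmark signal per chemical x cell line
    n_prof <- nrow(meta)
    L <- matrix(rnorm(cfg$n_landmark * n_prof, sd = cfg$noise_sd),
                cfg$n_landmark, n_prof)
    for (j in seq_len(n_prof)) {
      ch <- meta$chemical_id[j]
      if (is.na(ch)) next
      g <- truth$group_of[[ch]]
      resp <- truth$responsiveness[meta$cell_line[j], g]
      if (resp > 0) {
        idx <- truth$signature_idx[g, ]
        L[idx, j] <- L[idx, j] +
          cfg$effect_size * resp * truth$signature_weights[g, ]
      }
    }
    W <- matrix(rnorm(cfg$n_inferred * cfg$n_landmark,
                      sd = 1 / sqrt(cfg$n_landmark)),
                cfg$n_inferred, cfg$n_landmark)
    I <- W %*% L + matrix(rnorm(cfg$n_inferred * n_prof,
                                sd = 0.5 * cfg$noise_sd),
                          cfg$n_inferred, n_prof)
  })
  values <- rbind(L, I)
  rownames(values) <- c(landmark_ids(cfg), inferred_ids(cfg))
  colnames(values) <- meta$profile_id
  expr <- expr_mat(values, rep(c("landmark", "inferred"),
                               c(cfg$n_landmark, cfg$n_inferred)))
  nx_rows <- list()
  for (g in seq_len(cfg$n_mies)) {
    for (tg in truth$targets[[g]]) {
      for (line in cfg$cell_lines) {
        nx_rows[[length(nx_rows) + 1L]] <- data.frame(
          gene = tg, cell_line = line,
          nx = 10 * truth$responsiveness[line, g],
          stringsAsFactors = FALSE)
      }
    }
  }
  list(expr = expr, meta = meta, nx = do.call(rbind, nx_rows))
}

#' Simulate gene sets over the measured features
#'
#' One set per planted MIE group containing its signature landmark genes,
#' plus random filler sets, exercising the pathway feature space.
#'
#' @param config A [sim_config()].
#' @param truth Truth object from [simulate_annotations()].
#' @param n_random Number of random filler sets (default 12).
#' @param random_set_size Genes per filler set (default 15).
#' @return Named list of gene id vectors.
#' @export
simulate_gene_sets <- function(config, truth, n_random = 12L,
                               random_set_size = 15L) {
  cfg <- config
  ids <- c(landmark_ids(cfg), inferred_ids(cfg))
  sets <- lapply(seq_len(cfg$n_mies), function(g)
    landmark_ids(cfg)[truth$signature_idx[g, ]])
  names(sets) <- sprintf("SIG_MIE%02d", seq_len(cfg$n_mies))
  withr::with_seed(derive_seed(cfg$seed, 3L), {
    rand <- lapply(seq_len(n_random), function(i)
      sample(ids, random_set_size))
  })
  names(rand) <- sprintf("RANDOM%02d", seq_len(n_random))
  c(sets, rand)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper producing, from one seed, the annotation table,
#' expression matrix, profile metadata, NX table and gene sets the rest of
#' the package consumes.
#'
#' @param config A [sim_config()] (default configuration if omitted).
#' @return List with \code{records}, \code{truth}, \code{expr}, \code{meta},
#'   \code{nx}, \code{gene_sets}, \code{config}.
#' @export
simulate_study <- function(config = sim_config()) {
  ann <- simulate_annotations(config)
  ex <- simulate_expression(config, ann$truth)
  sets <- simulate_gene_sets(config, ann$truth)
  list(records = ann$records, truth = ann$truth, expr = ex$expr,
       meta = ex$meta, nx = ex$nx, gene_sets = sets, config = config)
}

#' Write a simulated study to disk in the package's exchange formats
#'
#' Emits \code{annotations.tsv}, \code{expression.tsv}, \code{meta.tsv},
#' \code{nx.tsv}, \code{gene_sets.gmt} and \code{truth.json}.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- sim$records
  ann$mode <- c(positive = "+", negative = "-",
                unspecified = "unspecified")[ann$mode]
  write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_expression(sim$expr, file.path(dir, "expression.tsv"))
  write.table(sim$meta, file.path(dir, "meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  write.table(sim$nx, file.path(dir, "nx.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gmt <- vapply(names(sim$gene_sets), function(n)
    paste(c(n, "simulated", sim$gene_sets[[n]]), collapse = "\t"), "")
  writeLines(gmt, file.path(dir, "gene_sets.gmt"))
  truth <- sim$truth
  truth$signature_idx <- unname(split(truth$signature_idx,
                                      row(truth$signature_idx)))
  truth$signature_weights <- unname(split(truth$signature_weights,
                                          row(truth$signature_weights)))
  truth$responsiveness <- as.data.frame(truth$responsiveness)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
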