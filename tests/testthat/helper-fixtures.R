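# shared fixtures, built in code at load time

# a small planted-signal study reused across test files
small_config <- function(seed = 42L, ...) {
  sim_config(n_chemicals = 60L, n_mies = 4L, n_landmark = 60L,
             n_inferred = 30L, genes_per_signature = 8L,
             profiles_mean = 8, n_control_profiles = 5L, seed = seed, ...)
}
SIM <- simulate_study(small_config())

toy_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) data.frame(
    chemical_id = r[[1]], target = r[[2]], mode = r[[3]],
    support = as.integer(r[[4]]), stringsAsFactors = FALSE)))
}

# metadata with n profiles per chemical in one cell line
toy_meta <- function(counts, cell_line = "CLA", start = 1L) {
  chems <- rep(names(counts), counts)
  data.frame(profile_id = sprintf("PX%04d", seq_along(chems) + start - 1L),
             chemical_id = chems, cell_line = cell_line,
             stringsAsFactors = FALSE)
}

# printed (rank, n, percentile) triples used as a regression set for the
# percentile convention (validation statistics of the reference screen)
PRINTED_PERCENTILES <- data.frame(
  rank = c(2826, 4291.5, 10226, 3042, 26, 517, 1125, 357, 922, 8838,
           3438, 5357, 3, 322, 4782, 8663, 16, 27),
  n = c(11666, 11672, 11665, 11623, 11661, 11604, 11620, 11589, 11672,
        11630, 11522, 11626, 11572, 11639, 11556, 11671, 11652, 11636),
  percentile = c(0.76, 0.63, 0.12, 0.74, 1.00, 0.96, 0.90, 0.97, 0.92,
                 0.24, 0.70, 0.54, 1.00, 0.97, 0.59, 0.26, 1.00, 1.00))

# step-by-step enumeration of the gene-set running-sum walk, kept
# independent of the package's vectorized implementation
ssgsea_brute <- function(values, genes, weight, stat = "integral") {
  ord <- order(values, decreasing = TRUE)
  v <- values[ord]
  inset <- names(v) %in% genes
  m <- sum(inset)
  N <- length(v)
  denom <- sum(abs(v[inset])^weight)
  p_in <- 0; p_out <- 0
  steps <- numeric(N)
  for (i in seq_len(N)) {
    if (inset[i]) {
      p_in <- p_in + if (denom > 0) abs(v[i])^weight / denom else 1 / m
    } else {
      p_out <- p_out + 1 / (N - m)
    }
    steps[i] <- p_in - p_out
  }
  if (stat == "integral") sum(steps) else steps[which.max(abs(steps))]
}
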