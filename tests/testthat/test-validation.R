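test_that("the percentile convention reproduces every printed pair at 2 dp", {
  got <- percentile_from_rank(PRINTED_PERCENTILES$rank,
                              PRINTED_PERCENTILES$n)
  expect_equal(round(got, 2), PRINTED_PERCENTILES$percentile)
  expect_equal(percentile_from_rank(1, 100), 1)
  expect_equal(percentile_from_rank(100, 100), 0)
  expect_error(percentile_from_rank(1, 1), "at least two")
})

test_that("chemical percentiles aggregate medians and exclude as instructed", {
  meta <- data.frame(profile_id = sprintf("p%02d", 1:9),
                     chemical_id = c("A", "A", "A", "B", "B", "C", "C",
                                     NA, "D"),
                     cell_line = "CLA", stringsAsFactors = FALSE)
  scores <- setNames(c(0.9, 0.8, 0.7, 0.4, 0.6, 0.2, 0.3, 0.99, 0.55),
                     meta$profile_id)
  tab <- chemical_percentiles(scores, meta)
  expect_equal(tab$chemical_id, c("A", "D", "B", "C"))
  expect_equal(tab$median_score, c(0.8, 0.55, 0.5, 0.25))
  expect_equal(tab$percentile, c(1, 2 / 3, 1 / 3, 0))
  # control profile (NA chemical) was ignored, not ranked
  expect_false(any(is.na(tab$chemical_id)))
  # training-chemical exclusion
  tab2 <- chemical_percentiles(scores, meta, exclude_chemicals = "A")
  expect_equal(tab2$n[1], 3L)
  expect_false("A" %in% tab2$chemical_id)
  expect_error(chemical_percentiles(scores, meta,
                                    exclude_chemicals = c("A", "B", "C")),
               "fewer than two")
  # ties share the mean of their ranks
  s3 <- setNames(c(0.5, 0.5, 0.1), c("p01", "p04", "p06"))
  t3 <- chemical_percentiles(s3, meta)
  expect_equal(t3$rank[t3$chemical_id %in% c("A", "B")], c(1.5, 1.5))
})

test_that("exemplar selection respects training-data floors and shares chemicals", {
  # two MIEs sharing top-supported chemical C, each with 6 chemicals
  rec <- rbind(
    data.frame(chemical_id = c("C", paste0("a", 1:5)), target = "AAA",
               mode = "negative", support = c(20L, rep(8L, 5))),
    data.frame(chemical_id = c("C", paste0("b", 1:5)), target = "BBB",
               mode = "negative", support = c(18L, rep(7L, 5))))
  clusters <- cluster_mies(collect_mies(derive_mie_records(rec)))
  meta <- rbind(toy_meta(c(C = 10L)),
                toy_meta(setNames(rep(10L, 10), c(paste0("a", 1:5),
                                                  paste0("b", 1:5))),
                         start = 100L))
  ex <- select_exemplars(clusters, meta)
  # each MIE retains 5 chemicals x 10 profiles = 50 after excluding C
  expect_equal(ex$chemical_id, c("C", "C"))
  expect_equal(ex$support, c(20L, 18L))

  # with only 50 profiles total, excluding any chemical breaks the floor
  meta2 <- rbind(toy_meta(c(C = 5L)),
                 toy_meta(setNames(rep(5L, 10), c(paste0("a", 1:5),
                                                  paste0("b", 1:5))),
                          start = 100L))
  ex2 <- select_exemplars(clusters, meta2)
  expect_true(all(is.na(ex2$chemical_id)))

  # an MIE with exactly the minimum chemical count can never give one up
  rec3 <- data.frame(chemical_id = paste0("z", 1:5), target = "ZZZ",
                     mode = "negative", support = 9L)
  cl3 <- cluster_mies(collect_mies(derive_mie_records(rec3)))
  ex3 <- select_exemplars(cl3, toy_meta(setNames(rep(20L, 5),
                                                 paste0("z", 1:5))))
  expect_true(is.na(ex3$chemical_id))
})

test_that("confirmation thresholds apply at the boundary and flag missing exemplars", {
  candidates <- data.frame(mie = c("M1", "M2", "M3", "M4"))
  exemplars <- data.frame(mie = c("M1", "M2", "M3", "M4"),
                          chemical_id = c("e1", "e2", "e3", NA),
                          support = c(10L, 9L, 8L, NA))
  rt <- function(chems, percs) data.frame(chemical_id = chems,
                                          percentile = percs)
  rank_tables <- list(M1 = rt(c("e1", "x"), c(0.92, 0.5)),
                      M2 = rt(c("e2", "x"), c(0.24, 0.5)),
                      M3 = rt(c("e3", "x"), c(0.90, 0.5)))
  out <- confirm_high_performance(candidates, exemplars, rank_tables)
  expect_equal(out$status, c("confirmed", "rejected", "confirmed",
                             "unconfirmable"))
})

test_that("KS enrichment is one-sided toward high scores", {
  withr::with_seed(8, {
    background <- runif(1000)
  })
  top <- sort(background, decreasing = TRUE)[1:20]
  expect_lt(ks_enrichment(top, background)$p_value, 0.01)
  bottom <- sort(background)[1:20]
  expect_gt(ks_enrichment(bottom, background)$p_value, 0.5)
  expect_error(ks_enrichment(numeric(), background), "empty")
  expect_error(ks_enrichment(background, background[1:5]), "larger")
})

test_that("representative NX values take the median over targets", {
  nx <- data.frame(gene = c("AR", "ESR1", "ESR2", "KDR"),
                   cell_line = "MCF7like",
                   nx = c(1.2, 1.0, 3.0, 5.0))
  expect_equal(mie_nx(nx, "AR", "MCF7like"), 1.2)
  expect_equal(mie_nx(nx, c("ESR1", "ESR2", "KDR"), "MCF7like"), 3.0)
  expect_warning(two <- mie_nx(nx, c("ESR1", "GONE"), "MCF7like"),
                 "GONE")
  expect_equal(two, 1.0)
  expect_error(mie_nx(nx, "NOPE", "MCF7like"), "no NX values")
})

test_that("NX log2 fold changes match the worked examples and are antisymmetric", {
  expect_equal(round(nx_l2fc(1.2, 0.0), 2), 3.70)
  expect_equal(round(nx_l2fc(0.0, 10.5), 2), -6.73)
  expect_equal(nx_l2fc(2.5, 2.5), 0)
  withr::with_seed(13, {
    for (i in 1:20) {
      a <- runif(1, 0, 20); b <- runif(1, 0, 20)
      expect_equal(nx_l2fc(a, b), -nx_l2fc(b, a))
    }
  })
  expect_error(nx_l2fc(-1, 2), "non-negative")
})

test_that("cross-cell comparisons recover exact linear relations", {
  a <- data.frame(mie = paste0("M", 1:6),
                  internal_accuracy = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95))
  ident <- compare_cell_lines(a, a)
  expect_equal(ident$r, 1)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)
  expect_true(all(ident$table$accuracy_diff == 0))
  b <- a; b$internal_accuracy <- 1 - a$internal_accuracy
  anti <- compare_cell_lines(a, b)
  expect_equal(anti$r, -1)
  expect_error(compare_cell_lines(a[1:2, ], a[1:2, ]), "at least 3")
})

test_that("paired Wilcoxon comparisons behave at the degenerate and shifted poles", {
  x <- seq(0.5, 0.9, length.out = 20)
  expect_equal(paired_rank_comparison(x, x), 1)
  expect_lt(paired_rank_comparison(x, x + 0.1), 0.01)
  # sign-flipping all differences leaves the two-sided p unchanged
  withr::with_seed(4, {
    y <- x + rnorm(20, 0, 0.05)
  })
  expect_equal(paired_rank_comparison(x, y),
               paired_rank_comparison(y, x))
  # one-sided direction: a > b yields small p only in the stated direction
  expect_lt(paired_rank_comparison(x + 0.1, x, "greater"), 0.01)
  expect_gt(paired_rank_comparison(x, x + 0.1, "greater"), 0.99)
  expect_error(paired_rank_comparison(x[1:3], x[1:3]), "at least 5")
})
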