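calls_df <- function(junctions, individuals, chrom = "chr1", depth = 200L,
                     polarity = "+") {
  data.frame(chrom = chrom, junction = as.integer(junctions),
             polarity = polarity, peak_depth = depth,
             individual = individuals)
}

test_that("unification follows the leader rule at the 200 bp tolerance", {
  # 150 bp apart -> same cluster
  cl <- unify_sites(calls_df(c(1000, 1150), c("catA", "catB")))
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$prevalence, 2L)

  # 250 bp apart -> two clusters
  cl2 <- unify_sites(calls_df(c(1000, 1250), c("catA", "catB")))
  expect_equal(nrow(cl2$clusters), 2L)

  # chain 1000/1150/1320: leader anchoring prevents unbounded chaining
  cl3 <- unify_sites(calls_df(c(1000, 1150, 1320),
                              c("catA", "catB", "catC")))
  expect_equal(nrow(cl3$clusters), 2L)
  grp <- unname(split(cl3$members$junction, cl3$members$cluster_id))
  expect_true(setequal(grp[[1]], c(1000L, 1150L)))
  expect_equal(grp[[2]], 1320L)

  # an individual contributing twice keeps only its deeper call
  dup <- calls_df(c(1000, 1050), c("catA", "catA"), depth = c(50L, 300L))
  cld <- unify_sites(dup)
  expect_equal(nrow(cld$members), 1L)
  expect_equal(cld$members$peak_depth, 300L)
})

test_that("cluster prevalences conserve calls and respect tolerance", {
  co <- small_cohort(seed = 23L)
  # synthetic per-individual call lists straight from truth
  calls <- data.frame(chrom = co$truth$chrom, junction = co$truth$junction,
                      polarity = co$truth$polarity, peak_depth = 200L,
                      individual = co$truth$individual)
  cl <- unify_sites(calls, 200L)
  expect_equal(sum(cl$clusters$prevalence), nrow(calls))   # partition
  # idempotence on representatives
  reps <- data.frame(chrom = cl$clusters$chrom,
                     junction = cl$clusters$junction,
                     polarity = cl$clusters$polarity, peak_depth = 1L,
                     individual = "rep")
  cl2 <- unify_sites(reps, 200L)
  expect_equal(nrow(cl2$clusters), nrow(cl$clusters))
  # increasing tolerance never increases the cluster count
  n_prev <- Inf
  for (tol in c(50L, 200L, 1000L, 5000L)) {
    n <- nrow(unify_sites(calls, tol)$clusters)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("prevalence classes count singletons, k-thresholds and fixed", {
  cl <- list(clusters = data.frame(
    cluster_id = sprintf("cl%d", 1:4), chrom = "chr1",
    junction = c(1e3, 5e3, 9e3, 2e4), prevalence = c(1L, 1L, 3L, 20L),
    polarity = "+", n_members = c(1L, 1L, 3L, 20L)))
  class(cl) <- "site_clusters"
  s <- classify_prevalence(cl, 20, k_list = 10L)
  expect_equal(s$n_singletons, 2L)
  expect_equal(s$n_at_least_k[["k10"]], 1L)
  expect_equal(s$n_fixed, 1L)
  expect_equal(s$n_total_calls, 25L)

  # the cohort worked example: 412 singletons of 765 clusters -> 53.9%
  prev <- c(rep(1L, 412), rep(2L, 353))
  cl$clusters <- data.frame(cluster_id = sprintf("cl%d", 1:765),
                            chrom = "chr1", junction = seq_len(765) * 1000,
                            prevalence = prev, polarity = "+",
                            n_members = prev)
  s2 <- classify_prevalence(cl, 20)
  expect_equal(s2$n_clusters, 765L)
  expect_equal(round(100 * s2$singleton_fraction, 1), 53.9)
})

test_that("the sharing matrix counts co-membership symmetrically", {
  m <- data.frame(
    cluster_id = c("c1", "c1", "c2", "c2", "c3", "c3", "c3", "c4"),
    individual = c("A", "B", "A", "B", "A", "B", "C", "C"),
    chrom = "chr1", junction = 1L, polarity = "+", peak_depth = 1L)
  cl <- structure(list(clusters = NULL, members = m), class = "site_clusters")
  sm <- pairwise_shared_matrix(cl, c("A", "B", "C"))
  expect_equal(sm["A", ], c(A = 3L, B = 3L, C = 1L))
  expect_equal(sm["B", ], c(A = 3L, B = 3L, C = 1L))
  expect_equal(sm["C", ], c(A = 1L, B = 1L, C = 2L))
  expect_identical(sm, t(sm))

  # disjoint site sets share nothing
  m2 <- data.frame(cluster_id = c("c1", "c2"), individual = c("A", "B"),
                   chrom = "chr1", junction = 1L, polarity = "+",
                   peak_depth = 1L)
  cl2 <- structure(list(members = m2), class = "site_clusters")
  expect_equal(pairwise_shared_matrix(cl2, c("A", "B"))["A", "B"], 0L)
})

test_that("Kruskal-Wallis matches its rank-formula value and base R", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(round(kw$statistic, 3), 3.857)

  expect_equal(kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))$statistic, 0)
  expect_equal(kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))$p.value, 1)

  # shift invariance of ranks
  a <- list(c(3, 1, 4, 1), c(5, 9, 2, 6))
  expect_equal(kruskal_wallis(a)$statistic,
               kruskal_wallis(lapply(a, `+`, 100))$statistic)

  # oracle: stats::kruskal.test with ties, 100 random inputs
  withr::with_seed(303, {
    for (rep in 1:100) {
      k <- sample(2:4, 1)
      groups <- lapply(seq_len(k), function(i)
        sample(0:20, sample(3:12, 1), replace = TRUE))
      ours <- kruskal_wallis(groups)
      ref <- stats::kruskal.test(unlist(groups),
                                 rep(seq_len(k), lengths(groups)))
      expect_equal(ours$statistic, unname(ref$statistic),
                   tolerance = 1e-10)
      if (ours$statistic > 0)
        expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("population summaries compare cohorts and honour exclusion", {
  co <- small_cohort(seed = 29L)
  calls <- data.frame(chrom = co$truth$chrom, junction = co$truth$junction,
                      polarity = co$truth$polarity, peak_depth = 200L,
                      individual = co$truth$individual)
  cl <- unify_sites(calls)
  ps <- population_summary(cl, co$individuals)
  expect_equal(sum(ps$table$n_total), nrow(cl$members))
  expect_equal(sum(ps$table$n_unique),
               sum(table(cl$members$cluster_id) == 1))

  drop <- co$individuals$individual[1]
  ps2 <- population_summary(cl, co$individuals, exclude = drop)
  expect_false(drop %in% ps2$table$individual)
  # exclusion removes exactly that individual's rows and its singletons
  expect_equal(nrow(ps2$table), nrow(ps$table) - 1L)
  expect_equal(sum(ps2$table$n_total),
               nrow(cl$members) - sum(cl$members$individual == drop))
  expect_error(population_summary(cl, co$individuals, exclude = "nosuch"),
               "nosuch")

  # identical distributions give H = 0; shifting one population raises H
  base <- c(10, 12, 14, 16, 18, 20, 22)
  eq <- kruskal_wallis(list(base, base, base))
  shifted <- kruskal_wallis(list(base, base, base + 50))
  expect_gt(shifted$statistic, eq$statistic)
})
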