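test_that("length and depth filters are strict at their boundaries", {
  iv <- data.frame(chrom = "chr1",
                   start = c(0L, 2000L, 4000L, 6000L, 8000L),
                   end = c(100L, 3000L, 4400L, 6400L, 8400L),
                   peak_depth = c(500L, 500L, 100L, 250L, 101L),
                   basepairs = 1L)
  kept <- filter_sites(iv, site_calling_params())
  # length exactly 100 rejected; length exactly 1000 rejected;
  # depth exactly 100 rejected; interior points kept
  expect_equal(kept$start, c(6000L, 8000L))
})

test_that("blunt-edge polarity follows the coverage shape", {
  p <- site_calling_params()
  x <- profile_reads(c(200L, 198L, 150L, 90L, 40L, 10L), run = 50L,
                     offset = 1000L)
  track <- compute_coverage(x)
  iv <- extract_intervals(track, p)
  pj <- infer_polarity(iv[1, ], track, p)
  expect_equal(pj$polarity, "+")
  expect_equal(pj$junction, 1000L)

  m <- mirror_reads(x, 5000L)
  trackm <- compute_coverage(m)
  ivm <- extract_intervals(trackm, p)
  pjm <- infer_polarity(ivm[1, ], trackm, p)
  expect_equal(pjm$polarity, "-")
  expect_equal(pjm$junction, ivm$end[1])

  # rectangular plateau: both edges blunt -> ambiguous
  r <- make_reads(rep(2000, 150), rep(2400, 150))
  trackr <- compute_coverage(r)
  ivr <- extract_intervals(trackr, p)
  pjr <- infer_polarity(ivr[1, ], trackr, p)
  expect_equal(pjr$polarity, "ambiguous")
})

test_that("an ambiguous interval places its junction at the sharpest step", {
  p <- site_calling_params()
  # blunt junction at 2000 with decaying tail, shelved by one stray
  # background read that extends the interval 300 bp to the left
  x <- profile_reads(c(200L, 198L, 150L, 90L, 40L, 10L), run = 50L,
                     offset = 2000L)
  x$reads <- rbind(x$reads,
                   data.frame(chrom = "chr1", start = 1700L, end = 2050L,
                              strand = "+", read_id = "bg1"))
  track <- compute_coverage(x)
  iv <- extract_intervals(track, p)
  expect_equal(iv$start[1], 1700L)
  pj <- infer_polarity(iv[1, ], track, p)
  expect_equal(pj$polarity, "ambiguous")
  expect_equal(pj$junction, 2000L)
})

test_that("env-adjacent sites are flagged, not silently dropped", {
  p <- site_calling_params()
  sites <- data.frame(chrom = "chr1",
                      start = c(10000L, 5000000L),
                      end = c(10400L, 5000400L))
  env <- data.frame(chrom = "chr1", start = 10900L, end = 12000L,
                    strand = "+")
  out <- exclude_env(sites, env, p)
  expect_equal(out$env_flagged, c(TRUE, FALSE))   # 500 bp away -> flagged
  expect_equal(nrow(primary_sites(out)), 1L)
  out2 <- exclude_env(sites, env[0, ], p)
  expect_false(any(out2$env_flagged))
})

test_that("call_sites recovers planted junctions end to end", {
  g <- genome_model(data.frame(name = "chr1", length = 2e6))
  junctions <- as.integer(seq(50000, 1900000, length.out = 10))
  co <- structure(list(
    genome = g,
    config = cohort_config(background_read_rate = 0,
                           target_junction_depth = 200, seed = 31),
    individuals = data.frame(individual = "catA", population = "pop1"),
    truth = data.frame(chrom = "chr1", junction = junctions,
                       polarity = rep(c("+", "-"), 5),
                       site_id = sprintf("s%02d", 1:10),
                       origin = "private", individual = "catA",
                       population = "pop1")),
    class = "synthetic_cohort")
  co$genome$env_loci <- co$genome$env_loci[0, ]
  reads <- simulate_enrichment_reads(co, "catA")
  sites <- call_sites(reads, NULL)
  expect_equal(nrow(sites), 10L)
  expect_equal(sites$junction, junctions)
  expect_equal(sites$polarity, rep(c("+", "-"), 5))
  expect_true(all(sites$peak_depth > 100))

  # a 50x site fails the depth filter and is never called
  co$config$target_junction_depth <- 50
  sites50 <- call_sites(simulate_enrichment_reads(co, "catA"), NULL)
  expect_equal(nrow(sites50), 0L)
})

test_that("env junction stacks surface only in the flagged table", {
  g <- toy_genome(n_chrom = 1, chrom_length = 2e6)
  co <- structure(list(
    genome = g,
    config = cohort_config(background_read_rate = 0, seed = 41),
    individuals = data.frame(individual = "catA", population = "pop1"),
    truth = data.frame(chrom = character(), junction = integer(),
                       polarity = character(), site_id = character(),
                       origin = character(), individual = character(),
                       population = character())),
    class = "synthetic_cohort")
  reads <- simulate_enrichment_reads(co, "catA")
  expect_gt(nrow(reads$reads), 0L)     # env stack emitted
  sites <- call_sites(reads, g$env_loci)
  expect_true(all(sites$env_flagged))
  expect_equal(nrow(primary_sites(sites)), 0L)
})

test_that("raising min_depth only removes sites, lowering only adds", {
  co <- small_cohort(seed = 19L)
  ind <- co$individuals$individual[1]
  reads <- simulate_enrichment_reads(co, ind)
  key <- function(s) paste(s$chrom, s$junction)
  s_default <- call_sites(reads, co$genome$env_loci,
                          site_calling_params(min_depth = 100))
  s_high <- call_sites(reads, co$genome$env_loci,
                       site_calling_params(min_depth = 180))
  s_low <- call_sites(reads, co$genome$env_loci,
                      site_calling_params(min_depth = 10))
  expect_true(all(key(s_high) %in% key(s_default)))
  expect_true(all(key(s_default) %in% key(s_low)))
})

test_that("recall and precision stay high on the default cohort", {
  # default study conditions at reduced seed count; the acceptance suite
  # runs the full 20-seed version
  stats <- c(matched = 0, truth = 0, called = 0)
  for (seed in 1:3) {
    co <- simulate_cohort(cohort_config(seed = seed))
    for (ind in co$individuals$individual) {
      reads <- simulate_enrichment_reads(co, ind)
      sites <- call_sites(reads, co$genome$env_loci)
      ev <- evaluate_recovery(sites,
                              co$truth[co$truth$individual == ind, ])
      stats <- stats + c(ev$n_matched, ev$n_truth,
                         nrow(primary_sites(sites)))
    }
  }
  expect_gte(stats[["matched"]] / stats[["truth"]], 0.95)
  expect_gte(stats[["matched"]] / stats[["called"]], 0.95)
})
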