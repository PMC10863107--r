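test_that("cohort truth respects the inheritance limit cases", {
  g <- toy_genome(n_chrom = 2, chrom_length = 1e6)
  # every individual carries exactly its population pool
  co <- simulate_cohort(cohort_config(
    n_populations = 2, individuals_per_population = c(3L, 2L),
    shared_site_pool_size = 8L, private_site_rate = 0,
    inheritance_probability = 1, seed = 5), g)
  for (ind in co$individuals$individual) {
    tr <- co$truth[co$truth$individual == ind, ]
    expect_equal(nrow(tr), 8L)
    expect_true(all(tr$origin == "inherited"))
  }
  pool_ids <- unique(co$truth$site_id[co$truth$population == "pop1"])
  expect_length(pool_ids, 8L)

  # all-private cohort: each site appears in exactly one individual
  co2 <- simulate_cohort(cohort_config(
    n_populations = 2, individuals_per_population = c(3L, 2L),
    shared_site_pool_size = 5L, private_site_rate = 5,
    inheritance_probability = 0, seed = 5), g)
  expect_true(all(co2$truth$origin == "private"))
  expect_false(anyDuplicated(co2$truth$site_id) > 0)
})

test_that("simulation is deterministic for a fixed seed", {
  a <- small_cohort(seed = 42L)
  b <- small_cohort(seed = 42L)
  expect_identical(a$truth, b$truth)
  ra <- simulate_enrichment_reads(a, a$individuals$individual[2])
  rb <- simulate_enrichment_reads(b, b$individuals$individual[2])
  expect_identical(ra$reads, rb$reads)
  expect_false(identical(a$truth, small_cohort(seed = 43L)$truth))
})

test_that("truth placement respects spacing and errors on short chromosomes", {
  co <- small_cohort(seed = 2L)
  env <- co$genome$env_loci
  spacing <- co$config$min_site_spacing
  for (i in seq_len(nrow(co$truth))) {
    e <- env[env$chrom == co$truth$chrom[i], ]
    if (nrow(e) > 0)
      expect_true(all(co$truth$junction[i] <= e$start - spacing |
                        co$truth$junction[i] >= e$end + spacing))
  }
  by_ind <- split(co$truth, co$truth$individual)
  for (tr in by_ind) {
    for (ch in unique(tr$chrom)) {
      j <- sort(tr$junction[tr$chrom == ch])
      if (length(j) > 1) expect_true(all(diff(j) >= spacing))
    }
  }
  tiny <- genome_model(data.frame(name = "chrZ", length = 3000L))
  expect_error(
    simulate_cohort(cohort_config(n_populations = 1,
                                  individuals_per_population = 1L,
                                  shared_site_pool_size = 5L,
                                  seed = 1), tiny),
    "chrZ")
})

test_that("junction stacks are blunt at the junction and decay outward", {
  g <- genome_model(data.frame(name = "chr1", length = 100000L))
  co <- structure(list(
    genome = g,
    config = cohort_config(background_read_rate = 0,
                           target_junction_depth = 200, seed = 9),
    individuals = data.frame(individual = "catA", population = "pop1"),
    truth = data.frame(chrom = "chr1", junction = 10000L, polarity = "+",
                       site_id = "s1", origin = "private",
                       individual = "catA", population = "pop1")),
    class = "synthetic_cohort")
  co$genome$env_loci <- co$genome$env_loci[0, ]
  reads <- simulate_enrichment_reads(co, "catA")
  expect_true(all(reads$reads$start == 10000L))
  depth <- naive_pileup(reads$reads, "chr1", 100000L)
  expect_equal(max(depth), depth[10001])          # peak at the junction base
  right <- depth[10001:(10001 + 600)]
  expect_true(all(diff(right) <= 0))              # non-increasing tail
  expect_true(all(depth[1:10000] == 0))           # blunt: nothing upstream

  # minus polarity is the mirror image
  co$truth$polarity <- "-"
  rr <- simulate_enrichment_reads(co, "catA")
  expect_true(all(rr$reads$end == 10000L))

  # no sites, no env, no background -> empty read set
  co$truth <- co$truth[0, ]
  expect_equal(nrow(simulate_enrichment_reads(co, "catA")$reads), 0L)
  expect_error(simulate_enrichment_reads(co, "nosuchcat"), "nosuchcat")
})

test_that("per-site read counts are Poisson around the target depth", {
  g <- genome_model(data.frame(name = "chr1", length = 1e6))
  n_sites <- 30L
  co <- structure(list(
    genome = g,
    config = cohort_config(background_read_rate = 0,
                           target_junction_depth = 200, seed = 21),
    individuals = data.frame(individual = "catA", population = "pop1"),
    truth = data.frame(chrom = "chr1",
                       junction = as.integer(seq(10000, 900000,
                                                 length.out = n_sites)),
                       polarity = "+",
                       site_id = sprintf("s%02d", seq_len(n_sites)),
                       origin = "private", individual = "catA",
                       population = "pop1")),
    class = "synthetic_cohort")
  co$genome$env_loci <- co$genome$env_loci[0, ]
  reads <- simulate_enrichment_reads(co, "catA")
  per_site <- table(sub("_r[0-9]+$", "", reads$reads$read_id))
  expect_length(per_site, n_sites)
  # each count within 3 sigma of Poisson(200); mean close to target
  expect_true(all(abs(per_site - 200) <= 3 * sqrt(200) + 1))
  expect_lt(abs(mean(per_site) - 200), 3 * sqrt(200 / n_sites))
})

test_that("truth tables round-trip through BED6", {
  co <- small_cohort(seed = 13L)
  dir <- withr::local_tempdir()
  write_truth(co, dir)
  ind <- co$individuals$individual[1]
  back <- read_truth(file.path(dir, paste0(ind, ".truth.bed")))
  tr <- co$truth[co$truth$individual == ind, ]
  expect_equal(back$chrom, tr$chrom)
  expect_equal(back$junction, tr$junction)
  expect_equal(back$polarity, tr$polarity)
  expect_equal(back$origin, tr$origin)
  expect_equal(back$site_id, tr$site_id)
  # stated convention: inherited -> score 1, private -> 0
  raw <- read.table(file.path(dir, paste0(ind, ".truth.bed")), sep = "\t")
  expect_equal(raw$V5, as.integer(tr$origin == "inherited"))
  expect_equal(raw$V6, tr$polarity)
})
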