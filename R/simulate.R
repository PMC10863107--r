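#' Cohort simulation parameters
#'
#' Study conditions for the in silico cohort: three cat populations of
#' differing relatedness (7, 6 and 7 individuals), each with its own pool
#' of heritable integration sites, plus private sites unique to single
#' animals. Library geometry follows the enrichment assay: sonication
#' fragments averaging 400 bp, 2x250 bp paired sequencing whose overlapping
#' mates tile the whole fragment (footprint cap `read_length` = 500 bp),
#' and junction stacks of on average `target_junction_depth` reads anchored
#' at the 5'-LTR boundary.
#'
#' @param n_populations number of populations.
#' @param individuals_per_population integer vector, one entry per population.
#' @param shared_site_pool_size heritable-site pool size per population
#'   (recycled).
#' @param private_site_rate Poisson mean of private sites per individual.
#' @param inheritance_probability probability an individual carries each
#'   site of its population pool.
#' @param fragment_mean,fragment_sd sheared fragment length distribution (bp).
#' @param read_length maximum aligned footprint per fragment (bp).
#' @param target_junction_depth Poisson mean read count per junction.
#' @param background_read_rate off-target reads per Mbp of genome.
#' @param min_site_spacing minimum distance (bp) between a planted site and
#'   any env locus or other site on the same individual; default twice the
#'   env exclusion window.
#' @param seed master integer seed.
#' @return an object of class `cohort_config` (a named list).
#' @export
cohort_config <- function(n_populations = 3,
                          individuals_per_population = c(7L, 6L, 7L),
                          shared_site_pool_size = 40L,
                          private_site_rate = 10,
                          inheritance_probability = 0.5,
                          fragment_mean = 400,
                          fragment_sd = 80,
                          read_length = 500L,
                          target_junction_depth = 200,
                          background_read_rate = 100,
                          min_site_spacing = 2000L,
                          seed = 1L) {
  individuals_per_population <- rep_len(as.integer(individuals_per_population),
                                        n_populations)
  shared_site_pool_size <- rep_len(as.integer(shared_site_pool_size),
                                   n_populations)
  cfg <- list(n_populations = as.integer(n_populations),
              individuals_per_population = individuals_per_population,
              shared_site_pool_size = shared_site_pool_size,
              private_site_rate = private_site_rate,
              inheritance_probability = inheritance_probability,
              fragment_mean = fragment_mean,
              fragment_sd = fragment_sd,
              read_length = as.integer(read_length),
              target_junction_depth = target_junction_depth,
              background_read_rate = background_read_rate,
              min_site_spacing = as.integer(min_site_spacing),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_populations < 1) stop_ltr("need at least one population")
  if (any(cfg$individuals_per_population < 0) ||
      any(cfg$shared_site_pool_size < 0) || cfg$private_site_rate < 0 ||
      cfg$target_junction_depth < 0 || cfg$background_read_rate < 0)
    stop_ltr("counts and rates must be non-negative")
  if (cfg$inheritance_probability < 0 || cfg$inheritance_probability > 1)
    stop_ltr("inheritance_probability must be in [0, 1]")
  if (cfg$fragment_mean <= 0 || cfg$fragment_sd < 0 || cfg$read_length < 1)
    stop_ltr("fragment/read geometry must be positive")
  invisible(cfg)
}

# Uniform placement with rejection against env loci and previously placed
# junctions (spacing = min_site_spacing). Fails loudly when a chromosome
# cannot host the requested sites.
place_junctions <- function(n, genome, cfg, occupied) {
  chroms <- genome$chromosomes
  margin <- cfg$min_site_spacing
  usable <- chroms$length - 2 * margin
  if (all(usable <= 0) && n > 0)
    stop_ltr("chromosome too short to place requested sites: ",
             chroms$name[which.min(chroms$length)])
  out <- data.frame(chrom = character(n), junction = integer(n),
                    polarity = character(n))
  for (k in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(2000L)) {
      ci <- sample.int(nrow(chroms), 1L, prob = pmax(usable, 0))
      j <- margin + floor(runif(1) * usable[ci])
      ch <- chroms$name[ci]
      env <- genome$env_loci[genome$env_loci$chrom == ch, , drop = FALSE]
      if (nrow(env) > 0 &&
          any(j > env$start - margin & j < env$end + margin)) next
      occ <- occupied$junction[occupied$chrom == ch]
      if (length(occ) > 0 && any(abs(occ - j) < margin)) next
      out$chrom[k] <- ch
      out$junction[k] <- as.integer(j)
      out$polarity[k] <- if (runif(1) < 0.5) "+" else "-"
      occupied <- rbind(occupied,
                        data.frame(chrom = ch, junction = as.integer(j)))
      placed <- TRUE
      break
    }
    if (!placed)
      stop_ltr("chromosome too short to place requested sites: ",
               chroms$name[which.max(chroms$length)])
  }
  list(sites = out, occupied = occupied)
}

#' Simulate a multi-population cohort with known integration truth
#'
#' Draws, per population, a pool of heritable integration sites, then gives
#' each individual a Bernoulli(`inheritance_probability`) subset of its
#' population pool plus Poisson(`private_site_rate`) private sites placed
#' uniformly, rejecting positions within `min_site_spacing` of an env locus
#' or another site on the same individual. Deterministic for a fixed seed.
#'
#' @param config a [cohort_config()].
#' @param genome a [genome_model()]; defaults to [toy_genome()].
#' @return an object of class `synthetic_cohort`: list with `genome`,
#'   `config`, `individuals` (individual, population) and `truth`
#'   (individual, chrom, junction, polarity, origin, site_id, population).
#' @export
simulate_cohort <- function(config = cohort_config(), genome = toy_genome()) {
  validate_cohort_config(config)
  withr::with_seed(child_seed(config$seed, 0L), {
    pops <- paste0("pop", seq_len(config$n_populations))
    individuals <- data.frame(
      individual = unlist(lapply(seq_along(pops), function(p)
        sprintf("%s_cat%02d", pops[p],
                seq_len(config$individuals_per_population[p])))),
      population = rep(pops, config$individuals_per_population),
      stringsAsFactors = FALSE
    )
    # heritable pools, one per population; spacing enforced within population
    pools <- vector("list", length(pops))
    for (p in seq_along(pops)) {
      occ <- data.frame(chrom = character(), junction = integer())
      placed <- place_junctions(config$shared_site_pool_size[p], genome,
                                config, occ)
      pool <- placed$sites
      if (nrow(pool) > 0)
        pool$site_id <- sprintf("%s_s%03d", pops[p], seq_len(nrow(pool)))
      pools[[p]] <- pool
    }
    truth <- list()
    for (i in seq_len(nrow(individuals))) {
      ind <- individuals$individual[i]
      pop <- individuals$population[i]
      pool <- pools[[match(pop, pops)]]
      keep <- if (nrow(pool) > 0)
        runif(nrow(pool)) < config$inheritance_probability else logical(0)
      inherited <- pool[keep, , drop = FALSE]
      occ <- data.frame(chrom = inherited$chrom, junction = inherited$junction)
      n_priv <- rpois(1L, config$private_site_rate)
      priv <- place_junctions(n_priv, genome, config, occ)$sites
      if (nrow(priv) > 0)
        priv$site_id <- sprintf("%s_p%03d", ind, seq_len(nrow(priv)))
      tr <- rbind(
        if (nrow(inherited) > 0)
          cbind(inherited[c("chrom", "junction", "polarity", "site_id")],
                origin = "inherited"),
        if (nrow(priv) > 0)
          cbind(priv[c("chrom", "junction", "polarity", "site_id")],
                origin = "private")
      )
      if (is.null(tr))
        tr <- data.frame(chrom = character(), junction = integer(),
                         polarity = character(), site_id = character(),
                         origin = character())
      tr$individual <- ind
      tr$population <- pop
      truth[[i]] <- tr
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    truth <- truth[order(truth$individual, truth$chrom, truth$junction), ]
    rownames(truth) <- NULL
    structure(list(genome = genome, config = config,
                   individuals = individuals, truth = truth),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$individuals), "individuals in",
      x$config$n_populations, "populations;", nrow(x$truth),
      "true integrations\n")
  invisible(x)
}

# junction read stack: blunt edge at `junction`, tail into flank.
# + polarity: footprint [junction, junction+len); -: [junction-len, junction)
junction_stack <- function(chrom, junction, polarity, n, cfg, chrom_len,
                           id_prefix) {
  if (n == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      read_id = character()))
  f <- rtruncnorm(n, cfg$fragment_mean, cfg$fragment_sd,
                  lower = 1, upper = 3 * cfg$fragment_mean)
  len <- pmax(1L, pmin(as.integer(round(f)), cfg$read_length))
  if (polarity == "+") {
    start <- rep(junction, n); end <- pmin(junction + len, chrom_len)
  } else {
    start <- pmax(junction - len, 0L); end <- rep(junction, n)
  }
  ok <- end > start
  data.frame(chrom = chrom, start = as.integer(start[ok]),
             end = as.integer(end[ok]),
             strand = polarity,
             read_id = paste0(id_prefix, "_r", seq_len(sum(ok))))
}

#' Simulate LTR-enrichment read alignments for one individual
#'
#' Emulates linker-mediated PCR geometry: every true integration emits a
#' Poisson(`target_junction_depth`) stack of aligned footprints whose
#' LTR-primer side starts exactly at the junction (the blunt edge) and
#' whose other end decays with the fragment-length distribution (truncated
#' normal, capped at `read_length`). Each reference env locus emits the
#' same junction signature (the 3'-LTR flanking *env* is captured by the
#' primer too), and uniform background reads are added at
#' `background_read_rate` per Mbp.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param individual individual id present in the cohort.
#' @param config optional override; defaults to `cohort$config`.
#' @return an `aligned_reads` object (see [aligned_reads()]).
#' @export
simulate_enrichment_reads <- function(cohort, individual,
                                      config = cohort$config) {
  idx <- match(individual, cohort$individuals$individual)
  if (is.na(idx)) stop_ltr("unknown individual: ", individual)
  genome <- cohort$genome
  withr::with_seed(child_seed(config$seed, idx), {
    truth <- cohort$truth[cohort$truth$individual == individual, ,
                          drop = FALSE]
    parts <- list()
    for (k in seq_len(nrow(truth))) {
      n <- rpois(1L, config$target_junction_depth)
      parts[[length(parts) + 1L]] <- junction_stack(
        truth$chrom[k], truth$junction[k], truth$polarity[k], n, config,
        chrom_length(genome, truth$chrom[k]),
        paste0(individual, "_", truth$site_id[k]))
    }
    env <- genome$env_loci
    for (k in seq_len(nrow(env))) {
      # primer-side junction at the LTR/genome boundary of the env provirus
      jn <- if (env$strand[k] == "+") env$start[k] else env$end[k]
      n <- rpois(1L, config$target_junction_depth)
      parts[[length(parts) + 1L]] <- junction_stack(
        env$chrom[k], jn, env$strand[k], n, config,
        chrom_length(genome, env$chrom[k]),
        paste0(individual, "_env", k))
    }
    genome_mbp <- sum(genome$chromosomes$length) / 1e6
    n_bg <- rpois(1L, config$background_read_rate * genome_mbp)
    if (n_bg > 0) {
      ci <- sample.int(nrow(genome$chromosomes), n_bg, replace = TRUE,
                       prob = genome$chromosomes$length)
      clen <- genome$chromosomes$length[ci]
      f <- rtruncnorm(n_bg, config$fragment_mean, config$fragment_sd,
                      lower = 1, upper = 3 * config$fragment_mean)
      len <- pmax(1L, pmin(as.integer(round(f)), config$read_length))
      start <- floor(runif(n_bg) * pmax(clen - len, 1))
      parts[[length(parts) + 1L]] <- data.frame(
        chrom = genome$chromosomes$name[ci],
        start = as.integer(start),
        end = as.integer(pmin(start + len, clen)),
        strand = ifelse(runif(n_bg) < 0.5, "+", "-"),
        read_id = paste0(individual, "_bg", seq_len(n_bg)))
    }
    reads <- if (length(parts)) do.call(rbind, parts) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), read_id = character())
    aligned_reads(reads, individual = individual, genome = genome,
                  sort = TRUE)
  })
}

#' Write per-individual truth tables as BED6
#'
#' One file `<individual>.truth.bed` per individual: columns chrom,
#' junction, junction+1, site id, score (1 = inherited, 0 = private) and
#' strand (LTR polarity). Round-trips losslessly through [read_truth()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_truth <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ind in cohort$individuals$individual) {
    tr <- cohort$truth[cohort$truth$individual == ind, , drop = FALSE]
    bed <- data.table::data.table(
      chrom = tr$chrom, start = tr$junction, end = tr$junction + 1L,
      name = tr$site_id, score = as.integer(tr$origin == "inherited"),
      strand = tr$polarity)
    p <- file.path(dir, paste0(ind, ".truth.bed"))
    data.table::fwrite(bed, p, sep = "\t", col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read one truth BED file written by [write_truth()]
#'
#' @param path BED6 truth file.
#' @return data.frame with chrom, junction, polarity, origin, site_id.
#' @export
read_truth <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), junction = integer(),
                      polarity = character(), origin = character(),
                      site_id = character()))
  bed <- data.table::fread(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  data.frame(chrom = bed$chrom, junction = as.integer(bed$start),
             polarity = bed$strand,
             origin = ifelse(bed$score == 1L, "inherited", "private"),
             site_id = bed$name)
}
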