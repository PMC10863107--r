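#' Reference genome model
#'
#' A lightweight description of a reference genome: chromosome names and
#' lengths plus the endogenous proviral *env* loci that are fixed in the
#' reference. Only lengths are needed downstream; no sequence is stored.
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param env_loci data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `strand`, or NULL for none.
#' @return an object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, env_loci = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name))
    stop_ltr("duplicated chromosome names in genome model")
  if (any(chromosomes$length <= 0))
    stop_ltr("chromosome lengths must be positive")
  if (is.null(env_loci)) {
    env_loci <- data.frame(chrom = character(), start = integer(),
                           end = integer(), strand = character())
  }
  env_loci$chrom <- as.character(env_loci$chrom)
  bad <- !(env_loci$chrom %in% chromosomes$name)
  if (any(bad))
    stop_ltr("env locus on unknown chromosome: ", env_loci$chrom[bad][1L])
  len <- chromosomes$length[match(env_loci$chrom, chromosomes$name)]
  if (any(env_loci$start < 0 | env_loci$end > len | env_loci$start >= env_loci$end))
    stop_ltr("env loci must lie within their chromosome")
  structure(list(chromosomes = chromosomes, env_loci = env_loci),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes,",
      sum(x$chromosomes$length), "bp,", nrow(x$env_loci), "env loci\n")
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  if (anyNA(i)) stop_ltr("unknown chromosome: ", chrom[is.na(i)][1L])
  genome$chromosomes$length[i]
}

#' Toy multi-chromosome genome with fixed env loci
#'
#' Default in silico reference used by the cohort simulator: four
#' chromosomes of 2.5 Mbp each, with one 2 kb endogenous *env* locus fixed
#' at a deterministic position on every chromosome (so the env-exclusion
#' stage always has signal to remove).
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param env_per_chrom env loci per chromosome.
#' @return a [genome_model()].
#' @export
toy_genome <- function(n_chrom = 4, chrom_length = 2.5e6, env_per_chrom = 1) {
  nm <- paste0("chr", LETTERS[seq_len(n_chrom)], "1")
  chroms <- data.frame(name = nm, length = as.integer(chrom_length))
  env <- NULL
  if (env_per_chrom > 0) {
    # evenly spaced, away from chromosome ends
    pos <- round(chrom_length * (seq_len(env_per_chrom) / (env_per_chrom + 1)))
    env <- data.frame(
      chrom = rep(nm, each = env_per_chrom),
      start = as.integer(rep(pos, times = n_chrom)),
      end = as.integer(rep(pos + 2000L, times = n_chrom)),
      strand = rep(c("+", "-"), length.out = n_chrom * env_per_chrom)
    )
  }
  genome_model(chroms, env)
}
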