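# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own interval machinery.

# per-base depth vector for one chromosome, by naive counting
naive_pileup <- function(reads, chrom, len) {
  depth <- integer(len)
  r <- reads[reads$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(r))) {
    if (r$end[i] > r$start[i])
      depth[(r$start[i] + 1):r$end[i]] <- depth[(r$start[i] + 1):r$end[i]] + 1L
  }
  depth
}

# expand a collapsed coverage track back to a per-base vector
track_to_vector <- function(track, chrom, len) {
  depth <- integer(len)
  t <- track[track$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(t)))
    depth[(t$start[i] + 1):t$end[i]] <- t$depth[i]
  depth
}

# maximal runs of depth >= floor from a per-base vector: naive interval
# extraction oracle; returns data.frame(start, end, peak_depth)
naive_intervals <- function(depth, floor = 1L) {
  on <- depth >= floor
  if (!any(on)) return(data.frame(start = integer(), end = integer(),
                                  peak_depth = integer()))
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             peak_depth = vapply(which(keep), function(k)
               max(depth[(starts[k] + 1):ends[k]]), integer(1)))
}

# all-pairs gene proximity oracle (no interval index)
naive_proximity <- function(clusters, genes, promoter = 1000L,
                            enhancer = 1000000L, oriented = TRUE) {
  rows <- list()
  for (i in seq_len(nrow(clusters))) {
    j <- clusters$junction[i]
    for (k in seq_len(nrow(genes))) {
      if (genes$chrom[k] != clusters$chrom[i]) next
      d_body <- max(genes$start[k] - j, j - genes$end[k], 0L)
      if (d_body <= enhancer)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster_id = clusters$cluster_id[i], gene_id = genes$gene_id[k],
          relation = "enhancer", distance = d_body)
      d_tss <- genes$tss[k] - j
      pol <- clusters$polarity[i]
      hit <- if (oriented && pol == "+") d_tss >= 0 && d_tss <= promoter
      else if (oriented && pol == "-") d_tss <= 0 && -d_tss <= promoter
      else abs(d_tss) <= promoter
      if (hit)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster_id = clusters$cluster_id[i], gene_id = genes$gene_id[k],
          relation = "promoter", distance = abs(d_tss))
    }
  }
  if (!length(rows)) return(data.frame(cluster_id = character(),
                                       gene_id = character(),
                                       relation = character(),
                                       distance = integer()))
  out <- do.call(rbind, rows)
  out[order(out$cluster_id, out$relation, out$gene_id), ]
}

# quick read-set builder
make_reads <- function(starts, ends, chrom = "chr1", strand = "+",
                       individual = "catA") {
  n <- length(starts)
  aligned_reads(data.frame(chrom = rep_len(chrom, n), start = starts,
                           end = ends, strand = rep_len(strand, n),
                           read_id = if (n) paste0("r", seq_len(n))
                                     else character(0)),
                individual = individual)
}

# stepped coverage profile as a read set: depth vector given per run of
# `run` bp; realised by stacking nested right-extending reads
profile_reads <- function(depths, run = 50L, offset = 1000L,
                          individual = "catA") {
  starts <- integer(0); ends <- integer(0)
  n_runs <- length(depths)
  # build per-base depth by summing reads [offset, offset + k*run)
  # reads ending at run boundary k: count = depth[k] - depth[k+1]
  d <- c(depths, 0L)
  for (k in seq_len(n_runs)) {
    n_k <- d[k] - d[k + 1]
    if (n_k > 0) {
      starts <- c(starts, rep(offset, n_k))
      ends <- c(ends, rep(offset + k * run, n_k))
    }
  }
  make_reads(starts, ends, individual = individual)
}

# mirror a read set around coordinate axis C (start' = 2C - end)
mirror_reads <- function(x, C) {
  r <- x$reads
  aligned_reads(data.frame(chrom = r$chrom, start = 2L * C - r$end,
                           end = 2L * C - r$start,
                           strand = ifelse(r$strand == "+", "-", "+"),
                           read_id = r$read_id),
                individual = x$individual)
}

# tiny deterministic cohort for fast end-to-end tests
small_cohort <- function(seed = 11L, ...) {
  cfg <- cohort_config(n_populations = 2,
                       individuals_per_population = c(3L, 3L),
                       shared_site_pool_size = 10L,
                       private_site_rate = 4,
                       seed = seed, ...)
  simulate_cohort(cfg, toy_genome(n_chrom = 2, chrom_length = 1e6))
}
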