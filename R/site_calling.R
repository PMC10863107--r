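#' Site-calling parameters
#'
#' Thresholds for turning junction-anchored coverage into called
#' integration sites. The length and depth filters are strict
#' inequalities: a candidate is kept only if `min_len < length < max_len`
#' and `peak depth > min_depth`. Depth is the peak per-base depth within
#' the interval — junction-anchored enrichment concentrates reads at the
#' LTR boundary, so the peak is the quantity the assay controls.
#'
#' @param min_len minimum site length in bp, exclusive (default 100).
#' @param max_len maximum site length in bp, exclusive (default 1000).
#' @param min_depth minimum peak depth, exclusive (default 100).
#' @param coverage_floor minimum per-base depth for a position to seed or
#'   extend a candidate interval (default 1, i.e. any covered base).
#' @param blunt_tolerance bp from an interval boundary within which the
#'   depth must reach `blunt_fraction * peak` for the edge to count as the
#'   blunt LTR junction (default 10).
#' @param blunt_fraction fraction of peak depth defining the blunt rise
#'   (default 0.5).
#' @param env_window bp added on both sides of a site when testing overlap
#'   with reference env loci (default 1000).
#' @param merge_within_individual junction distance (bp) under which two
#'   candidate sites of the same individual collapse to the deeper one
#'   (default 200, the same tolerance used across individuals).
#' @return an object of class `site_calling_params`.
#' @export
site_calling_params <- function(min_len = 100L, max_len = 1000L,
                                min_depth = 100L, coverage_floor = 1L,
                                blunt_tolerance = 10L, blunt_fraction = 0.5,
                                env_window = 1000L,
                                merge_within_individual = 200L) {
  p <- list(min_len = as.integer(min_len), max_len = as.integer(max_len),
            min_depth = as.integer(min_depth),
            coverage_floor = as.integer(coverage_floor),
            blunt_tolerance = as.integer(blunt_tolerance),
            blunt_fraction = blunt_fraction,
            env_window = as.integer(env_window),
            merge_within_individual = as.integer(merge_within_individual))
  if (p$min_len >= p$max_len) stop_ltr("min_len must be < max_len")
  if (p$min_depth < 1) stop_ltr("min_depth must be >= 1")
  if (p$blunt_fraction <= 0 || p$blunt_fraction > 1)
    stop_ltr("blunt_fraction must be in (0, 1]")
  structure(p, class = "site_calling_params")
}

#' Compute a collapsed per-base coverage track
#'
#' Exact pileup of read footprints, reported as maximal runs of constant
#' non-zero depth (the `genomecov -bg` layout). Unsorted input is sorted
#' internally. The conservation identity
#' `sum(run length * depth) == sum(read lengths)` holds exactly.
#'
#' @param reads an [aligned_reads()] object or a data.frame with `chrom`,
#'   `start`, `end`.
#' @return a `coverage_track`: data.frame with chrom, start, end, depth.
#' @export
compute_coverage <- function(reads) {
  r <- if (inherits(reads, "aligned_reads")) reads$reads else reads
  out <- list()
  for (ch in sort(unique(r$chrom))) {
    ri <- r[r$chrom == ch, , drop = FALSE]
    cov <- IRanges::coverage(IRanges::IRanges(ri$start + 1L, ri$end))
    v <- S4Vectors::runValue(cov)
    l <- S4Vectors::runLength(cov)
    ends <- cumsum(as.numeric(l))
    starts <- ends - as.numeric(l)
    keep <- v > 0
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = as.integer(starts[keep]),
                              end = as.integer(ends[keep]),
                              depth = as.integer(v[keep]))
  }
  track <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               depth = integer())
  rownames(track) <- NULL
  class(track) <- c("coverage_track", "data.frame")
  track
}

#' Extract candidate site intervals from a coverage track
#'
#' Maximal runs of consecutive positions with depth at or above
#' `coverage_floor`, each annotated with its peak depth and covered
#' base-pair mass.
#'
#' @param track a `coverage_track`.
#' @param params a [site_calling_params()].
#' @return data.frame with chrom, start, end, peak_depth, basepairs.
#' @export
extract_intervals <- function(track, params = site_calling_params()) {
  t <- as.data.frame(track)
  t <- t[t$depth >= params$coverage_floor, , drop = FALSE]
  if (nrow(t) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), peak_depth = integer(),
                      basepairs = integer()))
  t <- t[order(t$chrom, t$start), , drop = FALSE]
  new_block <- c(TRUE, t$chrom[-1] != t$chrom[-nrow(t)] |
                   t$start[-1] != t$end[-nrow(t)])
  grp <- cumsum(new_block)
  dt <- data.table::as.data.table(t)
  dt$grp <- grp
  res <- dt[, list(chrom = chrom[1L], start = min(start), end = max(end),
                   peak_depth = max(depth),
                   basepairs = as.integer(sum((end - start) * depth))),
            by = "grp"]
  res$grp <- NULL
  as.data.frame(res)
}

#' Apply the length and depth filters
#'
#' Strict inequalities on all three thresholds: keep an interval iff
#' `min_len < end - start < max_len` and `peak_depth > min_depth`.
#'
#' @param intervals output of [extract_intervals()].
#' @param params a [site_calling_params()].
#' @return the retained rows.
#' @export
filter_sites <- function(intervals, params = site_calling_params()) {
  len <- intervals$end - intervals$start
  keep <- len > params$min_len & len < params$max_len &
    intervals$peak_depth > params$min_depth
  out <- intervals[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-position depth vector of one interval, from the collapsed track
interval_profile <- function(interval, track) {
  t <- as.data.frame(track)
  t <- t[t$chrom == interval$chrom & t$end > interval$start &
           t$start < interval$end, , drop = FALSE]
  depth <- integer(interval$end - interval$start)
  for (k in seq_len(nrow(t))) {
    a <- max(t$start[k], interval$start) - interval$start + 1L
    b <- min(t$end[k], interval$end) - interval$start
    depth[a:b] <- t$depth[k]
  }
  depth
}

#' Infer LTR polarity and junction position of a candidate interval
#'
#' The 5'-LTR junction appears as a blunt coverage edge: depth rises from
#' zero to at least `blunt_fraction * peak` within `blunt_tolerance` bp of
#' the interval boundary, while the fragment-length tail decays gradually.
#' Exactly one blunt edge assigns polarity (`+` when the blunt edge is the
#' left boundary, `-` when it is the right) and puts the junction at that
#' boundary. With zero or two blunt edges the call is `ambiguous` and the
#' junction is placed at the sharpest depth step inside the interval
#' (largest single-step rise or fall, leftmost on ties), which is robust to
#' stray background reads shelving the true edge.
#'
#' @param interval one-row data.frame (chrom, start, end, peak_depth).
#' @param track the `coverage_track` the interval was extracted from.
#' @param params a [site_calling_params()].
#' @return list with `polarity` and `junction`.
#' @export
infer_polarity <- function(interval, track, params = site_calling_params()) {
  depth <- interval_profile(interval, track)
  peak <- max(depth)
  thr <- params$blunt_fraction * peak
  first_hi <- which(depth >= thr)[1L]
  last_hi <- which(depth >= thr)
  last_hi <- last_hi[length(last_hi)]
  blunt_left <- (first_hi - 1L) <= params$blunt_tolerance
  blunt_right <- (length(depth) - last_hi) <= params$blunt_tolerance
  if (xor(blunt_left, blunt_right)) {
    if (blunt_left)
      return(list(polarity = "+", junction = interval$start))
    return(list(polarity = "-", junction = interval$end))
  }
  # ambiguous: sharpest depth step, including the rises/falls at the ends
  steps <- diff(c(0L, depth, 0L))
  j <- interval$start + which.max(abs(steps)) - 1L
  list(polarity = "ambiguous", junction = as.integer(j))
}

#' Flag sites adjacent to reference env loci
#'
#' A site is env-flagged iff its interval, extended by `env_window` on both
#' sides, overlaps any reference env locus. Flagged sites are kept in the
#' returned table (column `env_flagged`) so they can be reported in a
#' secondary table rather than silently dropped; [primary_sites()] returns
#' the unflagged subset.
#'
#' @param sites data.frame of called sites with chrom, start, end.
#' @param env_loci data.frame with chrom, start, end (0-based half-open),
#'   or NULL / empty for none.
#' @param params a [site_calling_params()].
#' @return `sites` with a logical `env_flagged` column.
#' @export
exclude_env <- function(sites, env_loci, params = site_calling_params()) {
  sites$env_flagged <- rep(FALSE, nrow(sites))
  if (is.null(env_loci) || nrow(env_loci) == 0 || nrow(sites) == 0)
    return(sites)
  for (i in seq_len(nrow(sites))) {
    a <- sites$start[i] - params$env_window
    b <- sites$end[i] + params$env_window
    e <- env_loci[env_loci$chrom == sites$chrom[i], , drop = FALSE]
    sites$env_flagged[i] <- nrow(e) > 0 && any(e$start < b & e$end > a)
  }
  sites
}

#' @rdname exclude_env
#' @param sites a called-site table with an `env_flagged` column.
#' @export
primary_sites <- function(sites) {
  out <- sites[!sites$env_flagged, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call integration sites for one individual
#'
#' The full per-individual pipeline: pileup, candidate-interval
#' extraction, length/depth filtering, polarity and junction inference,
#' within-individual merging (candidates whose junctions lie closer than
#' `merge_within_individual` collapse to the deeper one), and env-adjacency
#' flagging. Output is sorted by (chrom, junction) and keeps env-flagged
#' rows; use [primary_sites()] for the primary output.
#'
#' @param reads an [aligned_reads()] object.
#' @param env_loci reference env loci (data.frame chrom/start/end) or NULL.
#' @param params a [site_calling_params()].
#' @return data.frame of called sites: chrom, start, end, junction,
#'   polarity, peak_depth, n_reads, individual, env_flagged.
#' @export
call_sites <- function(reads, env_loci = NULL,
                       params = site_calling_params()) {
  track <- compute_coverage(reads)
  cand <- extract_intervals(track, params)
  cand <- filter_sites(cand, params)
  n <- nrow(cand)
  pol <- character(n); jn <- integer(n)
  for (i in seq_len(n)) {
    pj <- infer_polarity(cand[i, , drop = FALSE], track, params)
    pol[i] <- pj$polarity
    jn[i] <- pj$junction
  }
  r <- reads$reads
  n_reads <- integer(n)
  if (n > 0 && nrow(r) > 0) {
    for (i in seq_len(n)) {
      n_reads[i] <- sum(r$chrom == cand$chrom[i] & r$start < cand$end[i] &
                          r$end > cand$start[i])
    }
  }
  sites <- data.frame(chrom = cand$chrom, start = cand$start, end = cand$end,
                      junction = jn, polarity = pol,
                      peak_depth = cand$peak_depth, n_reads = n_reads,
                      individual = rep(reads$individual, n))
  sites <- merge_within(sites, params$merge_within_individual)
  sites <- exclude_env(sites, env_loci, params)
  sites <- sites[order(sites$chrom, sites$junction), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

# greedy leader collapse of near-duplicate junctions within one individual:
# within a leader-anchored group (< tol bp from the group's first junction)
# only the deepest call survives
merge_within <- function(sites, tol) {
  if (nrow(sites) < 2) return(sites)
  sites <- sites[order(sites$chrom, sites$junction), , drop = FALSE]
  keep <- logical(nrow(sites))
  i <- 1L
  while (i <= nrow(sites)) {
    grp <- i
    j <- i + 1L
    while (j <= nrow(sites) && sites$chrom[j] == sites$chrom[i] &&
           abs(sites$junction[j] - sites$junction[i]) < tol) {
      grp <- c(grp, j)
      j <- j + 1L
    }
    keep[grp[which.max(sites$peak_depth[grp])]] <- TRUE
    i <- j
  }
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
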