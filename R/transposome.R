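#' Unify called sites across individuals into clusters
#'
#' Junctions from different individuals are considered the same insertion
#' when they differ by less than `tolerance` bp. Because that pairwise
#' criterion is not transitive, clustering is greedy leader clustering:
#' per chromosome, calls are scanned in junction order and a call joins the
#' open cluster iff its junction lies within `tolerance` of the cluster's
#' leader (the leftmost, founding member); otherwise it founds a new
#' cluster. If an individual would contribute two calls to one cluster,
#' the deeper call is kept. Deterministic.
#'
#' @param sites data.frame of per-individual calls (already merged within
#'   individual) with columns chrom, junction, polarity, peak_depth,
#'   individual — or a list of such data.frames.
#' @param tolerance junction distance in bp (default 200).
#' @return list of class `site_clusters` with elements `clusters`
#'   (cluster_id, chrom, junction = median member junction, prevalence,
#'   polarity = consensus, n_members) and `members` (cluster_id,
#'   individual, chrom, junction, polarity, peak_depth).
#' @export
unify_sites <- function(sites, tolerance = 200L) {
  if (is.list(sites) && !is.data.frame(sites))
    sites <- do.call(rbind, sites)
  need <- c("chrom", "junction", "individual")
  stopifnot(all(need %in% names(sites)))
  if (!"peak_depth" %in% names(sites)) sites$peak_depth <- 1L
  if (!"polarity" %in% names(sites)) sites$polarity <- "ambiguous"
  sites <- sites[order(sites$chrom, sites$junction, sites$individual), ,
                 drop = FALSE]
  n <- nrow(sites)
  cl <- integer(n)
  cid <- 0L
  leader <- NA_integer_
  leader_chrom <- ""
  for (i in seq_len(n)) {
    if (cid == 0L || sites$chrom[i] != leader_chrom ||
        abs(sites$junction[i] - leader) >= tolerance) {
      cid <- cid + 1L
      leader <- sites$junction[i]
      leader_chrom <- sites$chrom[i]
    }
    cl[i] <- cid
  }
  members <- data.frame(cluster_id = cl, individual = sites$individual,
                        chrom = sites$chrom, junction = sites$junction,
                        polarity = sites$polarity,
                        peak_depth = sites$peak_depth)
  # one member per individual per cluster: keep the deeper call
  members <- members[order(members$cluster_id, members$individual,
                           -members$peak_depth), , drop = FALSE]
  dup <- duplicated(members[c("cluster_id", "individual")])
  members <- members[!dup, , drop = FALSE]
  rownames(members) <- NULL
  mdt <- data.table::as.data.table(members)
  clusters <- mdt[, list(chrom = chrom[1L],
                         junction = as.integer(median(junction)),
                         prevalence = length(unique(individual)),
                         polarity = consensus_polarity(polarity),
                         n_members = .N),
                  by = "cluster_id"]
  clusters <- as.data.frame(clusters)
  clusters$cluster_id <- sprintf("cl%05d", clusters$cluster_id)
  members$cluster_id <- sprintf("cl%05d", members$cluster_id)
  structure(list(clusters = clusters, members = members,
                 tolerance = as.integer(tolerance)),
            class = "site_clusters")
}

consensus_polarity <- function(pol) {
  pol <- pol[pol %in% c("+", "-")]
  if (length(pol) == 0) return("ambiguous")
  np <- sum(pol == "+"); nm <- sum(pol == "-")
  if (np > nm) "+" else if (nm > np) "-" else "ambiguous"
}

#' @export
print.site_clusters <- function(x, ...) {
  cat("site_clusters:", nrow(x$clusters), "clusters from",
      nrow(x$members), "calls (tolerance", x$tolerance, "bp)\n")
  invisible(x)
}

#' Summarise insertion prevalence across the cohort
#'
#' Counts singleton clusters (present in exactly one individual), clusters
#' present in at least each `k` of `k_list`, and fixed clusters (present in
#' every individual). The singleton fraction is reported both as a
#' proportion and as a percentage rounded to one decimal, the convention
#' used for cohort summaries (412 singletons among 765 clusters prints as
#' 53.9).
#'
#' @param clusters a `site_clusters` object (or its `clusters` data.frame).
#' @param n_individuals cohort size.
#' @param k_list prevalence thresholds to report (default 10).
#' @return list of class `prevalence_summary`.
#' @export
classify_prevalence <- function(clusters, n_individuals, k_list = 10L) {
  cl <- if (inherits(clusters, "site_clusters")) clusters$clusters else clusters
  prev <- cl$prevalence
  n_at_least_k <- vapply(k_list, function(k) sum(prev >= k), integer(1))
  names(n_at_least_k) <- paste0("k", k_list)
  structure(list(
    n_total_calls = sum(prev),
    n_clusters = length(prev),
    n_singletons = sum(prev == 1L),
    n_at_least_k = n_at_least_k,
    n_fixed = sum(prev == n_individuals),
    singleton_fraction = if (length(prev)) sum(prev == 1L) / length(prev)
                         else NA_real_,
    n_individuals = n_individuals
  ), class = "prevalence_summary")
}

#' @export
print.prevalence_summary <- function(x, ...) {
  cat("prevalence_summary:", x$n_clusters, "clusters from", x$n_total_calls,
      "calls across", x$n_individuals, "individuals\n")
  cat("  singletons:", x$n_singletons,
      sprintf("(%.1f%%)", 100 * x$singleton_fraction), "\n")
  for (k in names(x$n_at_least_k))
    cat("  present in >=", sub("^k", "", k), "individuals:",
        x$n_at_least_k[[k]], "\n")
  cat("  fixed (all individuals):", x$n_fixed, "\n")
  invisible(x)
}

#' Pairwise shared-insertion matrix
#'
#' Entry (i, j) is the number of clusters containing both individuals; the
#' diagonal holds each individual's cluster count. Symmetric by
#' construction.
#'
#' @param clusters a `site_clusters` object.
#' @param individuals individual ids ordering the matrix; defaults to the
#'   individuals observed in the membership table.
#' @return an integer matrix.
#' @export
pairwise_shared_matrix <- function(clusters, individuals = NULL) {
  m <- clusters$members
  if (is.null(individuals)) individuals <- sort(unique(m$individual))
  inc <- table(factor(m$cluster_id), factor(m$individual, levels = individuals))
  inc <- (unclass(inc) > 0) * 1L
  out <- t(inc) %*% inc
  storage.mode(out) <- "integer"
  dimnames(out) <- list(individuals, individuals)
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' Implemented from the rank formula with mid-ranks for ties and the
#' standard tie correction; the p-value uses the chi-square approximation
#' with `length(groups) - 1` degrees of freedom. When every observation is
#' identical the statistic is 0 with p = 1.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return list with `statistic` (H), `df` and `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 || any(lengths(groups) == 0))
    stop_ltr("need at least two non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)  # mid-ranks
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  tie <- table(x)
  corr <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (corr <= 0) {
    H <- 0
  } else {
    H <- H / corr
  }
  df <- length(groups) - 1L
  list(statistic = H, df = df,
       p.value = if (H == 0) 1 else pchisq(H, df, lower.tail = FALSE))
}

#' Per-population summary and rank tests
#'
#' Builds the per-individual table of total and unique (cohort-singleton)
#' insertion counts, then compares populations with [kruskal_wallis()] on
#' both columns. Optionally repeats the bookkeeping with one named
#' individual excluded: its membership rows are removed, so its singleton
#' clusters vanish and shared clusters lose one member, mirroring a manual
#' outlier-exclusion reanalysis.
#'
#' @param clusters a `site_clusters` object.
#' @param populations data.frame with columns `individual`, `population`.
#' @param exclude optional individual id to drop before summarising.
#' @return list of class `population_summary` with `table` (individual,
#'   population, n_total, n_unique), `kw_total`, `kw_unique`, `excluded`.
#' @export
population_summary <- function(clusters, populations, exclude = NULL) {
  m <- clusters$members
  pops <- populations
  if (!is.null(exclude)) {
    if (!exclude %in% pops$individual)
      stop_ltr("unknown individual to exclude: ", exclude)
    m <- m[m$individual != exclude, , drop = FALSE]
    pops <- pops[pops$individual != exclude, , drop = FALSE]
  }
  prev <- table(m$cluster_id)
  singleton_ids <- names(prev)[prev == 1L]
  tab <- data.frame(individual = pops$individual,
                    population = pops$population)
  tab$n_total <- vapply(tab$individual,
                        function(i) sum(m$individual == i), integer(1))
  tab$n_unique <- vapply(tab$individual, function(i)
    sum(m$individual == i & m$cluster_id %in% singleton_ids), integer(1))
  by_pop_total <- split(tab$n_total, tab$population)
  by_pop_unique <- split(tab$n_unique, tab$population)
  structure(list(table = tab,
                 kw_total = kruskal_wallis(by_pop_total),
                 kw_unique = kruskal_wallis(by_pop_unique),
                 excluded = exclude),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat("population_summary", if (!is.null(x$excluded))
    paste0("(excluding ", x$excluded, ")") else "", "\n")
  agg <- stats::aggregate(cbind(n_total, n_unique) ~ population,
                          data = x$table,
                          FUN = function(v) round(mean(v), 1))
  print(agg, row.names = FALSE)
  cat(sprintf("  total insertions:  H = %.3f, p = %.3f\n",
              x$kw_total$statistic, x$kw_total$p.value))
  cat(sprintf("  unique insertions: H = %.3f, p = %.3f\n",
              x$kw_unique$statistic, x$kw_unique$p.value))
  invisible(x)
}
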