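#' Expression-overlay parameters
#'
#' Thresholds for the expression overlay: the expressed-gene filter (CPM
#' at or above `cpm_min` in at least `min_sample_fraction` of samples),
#' the significance rule (BH-adjusted permutation p at most
#' `fdr_threshold` and |log2 fold change| at least `lfc_threshold`) and
#' the minimum number of carrier and non-carrier samples required before a
#' presence/absence contrast is attempted.
#'
#' @param cpm_min CPM threshold (default 1).
#' @param min_sample_fraction fraction of samples (default 0.25).
#' @param lfc_threshold absolute log2 fold-change threshold (default 1).
#' @param fdr_threshold BH-adjusted p-value threshold (default 0.05).
#' @param min_group_presence minimum carriers and non-carriers (default 3).
#' @param n_permutations label permutations per contrast (default 10000).
#' @param seed integer seed for the permutation stream.
#' @return an object of class `overlay_params`.
#' @export
overlay_params <- function(cpm_min = 1, min_sample_fraction = 0.25,
                           lfc_threshold = 1, fdr_threshold = 0.05,
                           min_group_presence = 3L, n_permutations = 10000L,
                           seed = 1L) {
  if (cpm_min <= 0 || lfc_threshold <= 0 || min_sample_fraction <= 0)
    stop_ltr("thresholds must be positive")
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop_ltr("fdr_threshold must be in (0, 1)")
  structure(list(cpm_min = cpm_min,
                 min_sample_fraction = min_sample_fraction,
                 lfc_threshold = lfc_threshold,
                 fdr_threshold = fdr_threshold,
                 min_group_presence = as.integer(min_group_presence),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "overlay_params")
}

#' Counts-per-million normalization
#'
#' `cpm[g, s] = counts[g, s] / library_size[s] * 1e6`, so every column of
#' the result sums to one million.
#'
#' @param counts non-negative gene x sample count matrix.
#' @return matrix of the same shape.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_ltr("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop_ltr("every sample needs library size > 0")
  sweep(counts, 2L, lib, "/") * 1e6
}

#' Expressed-gene filter
#'
#' Keeps genes with CPM at or above `cpm_min` in at least
#' `ceiling(min_sample_fraction * n_samples)` samples.
#'
#' @param counts gene x sample count matrix.
#' @param params an [overlay_params()].
#' @return character vector of retained gene ids (rownames).
#' @export
filter_expressed <- function(counts, params = overlay_params()) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 0) stop_ltr("no samples in count matrix")
  x <- cpm(counts)
  need <- ceiling(params$min_sample_fraction * ncol(counts))
  keep <- rowSums(x >= params$cpm_min) >= need
  rownames(counts)[keep]
}

#' Two-group expression contrast by label permutation
#'
#' Per gene, the statistic is the absolute log2 fold change of group mean
#' CPM (with a 0.5-raw-count-equivalent pseudo-CPM added to each group
#' mean before the log). The p-value is the permutation tail probability
#' over random relabelings of the pooled samples (group sizes preserved),
#' `(1 + #{|logFC*| >= |logFC|}) / (1 + n_permutations)`, BH-adjusted
#' across genes. A gene is flagged significant iff `q <= fdr_threshold`
#' and `|logFC| >= lfc_threshold`.
#'
#' @param counts gene x sample count matrix. Library sizes are the full
#'   column sums of this matrix, so a subset of genes can be tested (via
#'   `genes`) under the correct whole-library normalization.
#' @param group_a,group_b character vectors of sample (column) names; each
#'   must have at least two samples.
#' @param params an [overlay_params()].
#' @param genes optional character vector restricting the tested rows.
#' @return data.frame with gene, logFC (A over B), p_perm, q, significant.
#' @export
group_contrast <- function(counts, group_a, group_b,
                           params = overlay_params(), genes = NULL) {
  counts <- as.matrix(counts)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_ltr("each group needs at least two samples for the permutation test")
  if (length(intersect(group_a, group_b)) > 0)
    stop_ltr("groups overlap")
  miss <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(miss) > 0) stop_ltr("unknown sample: ", miss[1L])
  all_s <- c(group_a, group_b)
  lib <- colSums(counts[, all_s, drop = FALSE])
  sub <- counts[, all_s, drop = FALSE]
  if (!is.null(genes)) sub <- sub[genes, , drop = FALSE]
  x <- sweep(sub, 2L, lib, "/") * 1e6
  nA <- length(group_a)
  nU <- ncol(sub)

  lfc_for <- function(idx_a) {
    idx_b <- setdiff(seq_len(nU), idx_a)
    pseudoA <- 0.5 / mean(lib[idx_a]) * 1e6
    pseudoB <- 0.5 / mean(lib[idx_b]) * 1e6
    log2((rowMeans(x[, idx_a, drop = FALSE]) + pseudoA) /
           (rowMeans(x[, idx_b, drop = FALSE]) + pseudoB))
  }
  obs <- lfc_for(seq_len(nA))
  exceed <- rep(0L, nrow(x))
  withr::with_seed(child_seed(params$seed, 1L), {
    for (b in seq_len(params$n_permutations)) {
      idx <- sample.int(nU, nA)
      exceed <- exceed + (abs(lfc_for(idx)) >= abs(obs))
    }
  })
  p <- (1 + exceed) / (1 + params$n_permutations)
  q <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(x) %||% as.character(seq_len(nrow(x))),
             logFC = as.numeric(obs), p_perm = as.numeric(p),
             q = as.numeric(q),
             significant = q <= params$fdr_threshold &
               abs(obs) >= params$lfc_threshold,
             row.names = NULL)
}

#' Presence/absence contrast of LTR-proximal genes
#'
#' For every unified site carried by at least `min_group_presence`
#' expression samples and absent from at least as many, contrasts carriers
#' against non-carriers restricted to the genes within that site's
#' promoter and enhancer windows (two separate tests). Presence is coded
#' per individual: an expression sample carries a cluster iff its
#' individual is among the cluster's members.
#'
#' @param counts gene x sample count matrix.
#' @param sample_individuals named character vector mapping sample name ->
#'   individual id.
#' @param clusters a `site_clusters` object.
#' @param annotation a `proximity_table` from [annotate_all()].
#' @param params an [overlay_params()].
#' @return data.frame with cluster_id, window, gene, logFC, p_perm, q,
#'   significant, n_carriers, n_noncarriers.
#' @export
ltr_presence_contrast <- function(counts, sample_individuals, clusters,
                                  annotation, params = overlay_params()) {
  counts <- as.matrix(counts)
  samples <- colnames(counts)
  miss <- setdiff(samples, names(sample_individuals))
  if (length(miss) > 0) stop_ltr("no individual mapping for sample ", miss[1L])
  ann <- annotation$table
  out <- list()
  for (cid in unique(ann$cluster_id)) {
    carriers_ind <- clusters$members$individual[
      clusters$members$cluster_id == cid]
    carrier_s <- samples[sample_individuals[samples] %in% carriers_ind]
    noncarrier_s <- setdiff(samples, carrier_s)
    if (length(carrier_s) < params$min_group_presence ||
        length(noncarrier_s) < params$min_group_presence)
      next
    for (win in c("promoter", "enhancer")) {
      genes <- ann$gene_id[ann$cluster_id == cid & ann$relation == win]
      genes <- intersect(genes, rownames(counts))
      if (length(genes) == 0) next
      res <- group_contrast(counts, carrier_s, noncarrier_s, params,
                            genes = genes)
      out[[length(out) + 1L]] <- data.frame(
        cluster_id = cid, window = win, gene = res$gene,
        logFC = res$logFC, p_perm = res$p_perm, q = res$q,
        significant = res$significant,
        n_carriers = length(carrier_s),
        n_noncarriers = length(noncarrier_s))
    }
  }
  if (length(out) == 0)
    return(data.frame(cluster_id = character(), window = character(),
                      gene = character(), logFC = numeric(),
                      p_perm = numeric(), q = numeric(),
                      significant = logical(), n_carriers = integer(),
                      n_noncarriers = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
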