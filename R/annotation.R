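#' Gene-proximity parameters
#'
#' Two biologically motivated windows around each unified junction: the
#' promoter window (an LTR promoter can drive a gene whose TSS lies up to
#' ~1 kb downstream of the junction) and the enhancer window (LTR enhancer
#' effects reach genes up to ~1 Mbp away in either direction).
#'
#' @param promoter_window bp (default 1000).
#' @param enhancer_window bp (default 1e6).
#' @param promoter_oriented when TRUE (default) "downstream" is taken with
#'   respect to the cluster's consensus LTR polarity; ambiguous clusters
#'   fall back to the unoriented rule (TSS within `promoter_window` on
#'   either side).
#' @return an object of class `proximity_params`.
#' @export
proximity_params <- function(promoter_window = 1000L,
                             enhancer_window = 1000000L,
                             promoter_oriented = TRUE) {
  if (promoter_window > enhancer_window)
    stop_ltr("promoter_window must be <= enhancer_window")
  structure(list(promoter_window = as.integer(promoter_window),
                 enhancer_window = as.integer(enhancer_window),
                 promoter_oriented = isTRUE(promoter_oriented)),
            class = "proximity_params")
}

# distance from a junction point to a gene body [start, end); 0 if inside
gene_body_distance <- function(junction, start, end) {
  pmax(start - junction, junction - end, 0L)
}

#' Genes near one unified site
#'
#' The enhancer set contains genes whose body lies within
#' `enhancer_window` of the junction (distance 0 when overlapping); the
#' promoter set contains genes whose TSS lies within `promoter_window`
#' downstream of the junction with respect to the cluster polarity (or on
#' either side, for ambiguous clusters or `promoter_oriented = FALSE`).
#' The promoter set is always a subset of the enhancer set. A site with an
#' empty enhancer set is an orphan.
#'
#' @param cluster one-row data.frame with chrom, junction, polarity.
#' @param genes gene table from [read_gene_annotation()].
#' @param params a [proximity_params()].
#' @return list of class `proximity_annotation` with `promoter_genes` and
#'   `enhancer_genes` (data.frames gene_id/distance) and `orphan`.
#' @export
genes_near_site <- function(cluster, genes, params = proximity_params()) {
  g <- genes[genes$chrom == cluster$chrom, , drop = FALSE]
  d_body <- gene_body_distance(cluster$junction, g$start, g$end)
  enh <- d_body <= params$enhancer_window
  d_tss <- g$tss - cluster$junction  # signed: positive = TSS to the right
  if (params$promoter_oriented && cluster$polarity %in% c("+", "-")) {
    prom <- if (cluster$polarity == "+")
      d_tss >= 0 & d_tss <= params$promoter_window
    else
      d_tss <= 0 & -d_tss <= params$promoter_window
  } else {
    prom <- abs(d_tss) <= params$promoter_window
  }
  prom <- prom & enh
  enhancer_genes <- data.frame(gene_id = g$gene_id[enh],
                               distance = as.integer(d_body[enh]))
  promoter_genes <- data.frame(gene_id = g$gene_id[prom],
                               distance = as.integer(abs(d_tss)[prom]))
  structure(list(promoter_genes = promoter_genes,
                 enhancer_genes = enhancer_genes,
                 orphan = nrow(enhancer_genes) == 0),
            class = "proximity_annotation")
}

#' Annotate all clusters with nearby genes
#'
#' Interval-indexed scan over all (cluster, gene) pairs; one output row per
#' pair and relation. Genes on chromosomes absent from the cluster table
#' are ignored with a warning. Also builds the reverse index gene ->
#' clusters.
#'
#' @param clusters a `site_clusters` object or its `clusters` data.frame.
#' @param genes gene table from [read_gene_annotation()].
#' @param params a [proximity_params()].
#' @return list of class `proximity_table` with `table` (cluster_id,
#'   gene_id, relation in promoter/enhancer, distance), `orphans`
#'   (cluster ids) and `gene_index` (named list gene -> cluster ids).
#' @export
annotate_all <- function(clusters, genes, params = proximity_params()) {
  cl <- if (inherits(clusters, "site_clusters")) clusters$clusters else clusters
  stray <- setdiff(unique(genes$chrom), unique(cl$chrom))
  if (length(stray) > 0 && nrow(cl) > 0)
    warning("ignoring genes on chromosomes without sites: ",
            paste(stray, collapse = ", "))
  rows <- list()
  orphans <- character(0)
  # interval index: junction points vs enhancer-expanded gene bodies
  # (expanded one extra bp each side; exact distances are re-checked in
  # genes_near_site, so the index only has to be a superset)
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start - params$enhancer_window, 1L),
                     genes$end + params$enhancer_window + 1L))
  gr_junc <- GenomicRanges::GRanges(
    cl$chrom, IRanges::IRanges(cl$junction + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_junc, gr_genes)
  hit_by_cluster <- split(S4Vectors::subjectHits(hits),
                          factor(S4Vectors::queryHits(hits),
                                 levels = seq_len(nrow(cl))))
  for (i in seq_len(nrow(cl))) {
    gi <- hit_by_cluster[[i]]
    ann <- genes_near_site(cl[i, , drop = FALSE],
                           genes[gi, , drop = FALSE], params)
    if (ann$orphan) {
      orphans <- c(orphans, cl$cluster_id[i])
      next
    }
    eg <- ann$enhancer_genes
    pg <- ann$promoter_genes
    rows[[length(rows) + 1L]] <- rbind(
      if (nrow(pg) > 0) data.frame(cluster_id = cl$cluster_id[i],
                                   gene_id = pg$gene_id,
                                   relation = "promoter",
                                   distance = pg$distance),
      data.frame(cluster_id = cl$cluster_id[i], gene_id = eg$gene_id,
                 relation = "enhancer", distance = eg$distance))
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(), gene_id = character(),
               relation = character(), distance = integer())
  tab <- tab[order(tab$cluster_id, tab$relation, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  gene_index <- split(tab$cluster_id, tab$gene_id)
  gene_index <- lapply(gene_index, function(v) sort(unique(v)))
  structure(list(table = tab, orphans = sort(unique(orphans)),
                 gene_index = gene_index),
            class = "proximity_table")
}

#' @export
print.proximity_table <- function(x, ...) {
  cat("proximity_table:", nrow(x$table), "cluster-gene relations,",
      length(x$orphans), "orphan clusters\n")
  invisible(x)
}
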