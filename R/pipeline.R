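#' Whole-pipeline configuration
#'
#' One structured configuration for an end-to-end run: cohort simulation
#' parameters, site-calling thresholds, the cross-individual merge
#' tolerance, proximity windows and overlay thresholds, plus the single
#' master seed from which every stage derives its own substream.
#' Round-trips losslessly through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param cohort a [cohort_config()].
#' @param calling a [site_calling_params()].
#' @param tolerance cross-individual junction merge tolerance in bp.
#' @param proximity a [proximity_params()].
#' @param overlay an [overlay_params()].
#' @param counts_path,sample_map optional expression overlay inputs: a
#'   gene x sample TSV of raw counts and a named mapping sample ->
#'   individual (list or named character vector).
#' @param exclude_individual optional individual excluded in the repeated
#'   population comparison (outlier reanalysis).
#' @param prevalence_k prevalence thresholds reported by
#'   [classify_prevalence()].
#' @param seed master seed; overrides the seeds of the nested blocks.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            calling = site_calling_params(),
                            tolerance = 200L,
                            proximity = proximity_params(),
                            overlay = overlay_params(),
                            counts_path = NULL,
                            sample_map = NULL,
                            exclude_individual = NULL,
                            prevalence_k = 10L,
                            seed = 1L) {
  cohort$seed <- as.integer(seed)
  overlay$seed <- child_seed(seed, 9001L)
  structure(list(cohort = cohort, calling = calling,
                 tolerance = as.integer(tolerance), proximity = proximity,
                 overlay = overlay, counts_path = counts_path,
                 sample_map = sample_map,
                 exclude_individual = exclude_individual,
                 prevalence_k = as.integer(prevalence_k),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  flat <- lapply(unclass(config), function(x)
    if (is.list(x) && !is.null(attr(x, "class"))) unclass(x) else x)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    cohort = do.call(cohort_config, y$cohort),
    calling = do.call(site_calling_params, y$calling),
    tolerance = y$tolerance,
    proximity = do.call(proximity_params, y$proximity),
    overlay = do.call(overlay_params, y$overlay),
    counts_path = y$counts_path,
    sample_map = y$sample_map,
    exclude_individual = y$exclude_individual,
    prevalence_k = y$prevalence_k,
    seed = y$seed)
}

#' Run the full pipeline on a simulated cohort
#'
#' simulate -> call sites per individual -> unify -> prevalence and
#' population summaries -> gene-proximity annotation (against the given
#' gene table, if any) -> optional expression overlay. Writes per-stage
#' TSV outputs plus a machine-readable JSON manifest (seed, parameters,
#' per-stage record counts and conservation checks) under `out_dir`.
#' Identical config and seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @param genome a [genome_model()]; default [toy_genome()].
#' @param genes optional gene table ([read_gene_annotation()] layout) for
#'   the annotation stage.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with cohort, sites, clusters, prevalence,
#'   populations, annotation, overlay and manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         genome = toy_genome(), genes = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[ltrmap] ", ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  result <- tryCatch({
    say("simulating cohort (seed ", config$seed, ")")
    cohort <- simulate_cohort(config$cohort, genome)
    write_truth(cohort, file.path(out_dir, "truth"))

    stage <- "call-sites"
    say("calling sites for ", nrow(cohort$individuals), " individuals")
    env <- genome$env_loci
    all_sites <- list()
    for (ind in cohort$individuals$individual) {
      reads <- simulate_enrichment_reads(cohort, ind, config$cohort)
      all_sites[[ind]] <- call_sites(reads, env, config$calling)
    }
    sites <- do.call(rbind, all_sites)
    rownames(sites) <- NULL
    write_site_table(primary_sites(sites),
                     file.path(out_dir, "sites.tsv"))
    write_site_table(sites[sites$env_flagged, , drop = FALSE],
                     file.path(out_dir, "sites_env_flagged.tsv"))

    stage <- "unify"
    primary <- primary_sites(sites)
    clusters <- unify_sites(primary, config$tolerance)
    say(nrow(clusters$clusters), " clusters from ", nrow(primary), " calls")
    cl_out <- clusters$clusters
    cl_out$display <- site_label(cl_out$chrom, cl_out$junction)
    data.table::fwrite(cl_out, file.path(out_dir, "clusters.tsv"),
                       sep = "\t")
    data.table::fwrite(clusters$members,
                       file.path(out_dir, "cluster_members.tsv"), sep = "\t")

    stage <- "summarize"
    prevalence <- classify_prevalence(clusters,
                                      nrow(cohort$individuals),
                                      config$prevalence_k)
    sharing <- pairwise_shared_matrix(clusters,
                                      cohort$individuals$individual)
    data.table::fwrite(as.data.frame(sharing),
                       file.path(out_dir, "sharing_matrix.tsv"),
                       sep = "\t", row.names = TRUE)
    populations <- list(
      included = population_summary(clusters, cohort$individuals))
    if (!is.null(config$exclude_individual))
      populations$excluded <- population_summary(
        clusters, cohort$individuals, config$exclude_individual)

    stage <- "annotate"
    annotation <- NULL
    if (!is.null(genes)) {
      annotation <- annotate_all(clusters, genes, config$proximity)
      data.table::fwrite(annotation$table,
                         file.path(out_dir, "annotation.tsv"), sep = "\t")
    }

    stage <- "overlay"
    overlay <- NULL
    if (!is.null(config$counts_path) && !is.null(annotation)) {
      counts <- as.matrix(data.table::fread(config$counts_path),
                          rownames = 1)
      overlay <- ltr_presence_contrast(
        counts, unlist(config$sample_map), clusters, annotation,
        config$overlay)
      data.table::fwrite(overlay, file.path(out_dir, "overlay.tsv"),
                         sep = "\t")
    }

    stage <- "manifest"
    conservation <- list(
      prevalence_sums_to_calls =
        prevalence$n_total_calls == nrow(clusters$members),
      sharing_matrix_symmetric = isTRUE(all.equal(sharing, t(sharing))))
    manifest <- list(
      package = "ltrmap",
      version = as.character(packageVersion("ltrmap")),
      seed = config$seed,
      parameters = list(cohort = unclass(config$cohort),
                        calling = unclass(config$calling),
                        tolerance = config$tolerance,
                        proximity = unclass(config$proximity)),
      counts = list(
        individuals = nrow(cohort$individuals),
        true_integrations = nrow(cohort$truth),
        called_sites = nrow(sites),
        env_flagged = sum(sites$env_flagged),
        primary_calls = nrow(primary),
        clusters = nrow(clusters$clusters),
        singletons = prevalence$n_singletons,
        fixed = prevalence$n_fixed,
        annotation_rows = if (is.null(annotation)) 0L
                          else nrow(annotation$table),
        overlay_tests = if (is.null(overlay)) 0L else nrow(overlay)),
      conservation = conservation)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("done")
    list(cohort = cohort, sites = sites, clusters = clusters,
         prevalence = prevalence, sharing = sharing,
         populations = populations, annotation = annotation,
         overlay = overlay, manifest = manifest)
  }, error = function(e) {
    stop_ltr("pipeline failed at stage '", stage, "': ",
             conditionMessage(e))
  })
  invisible(result)
}
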