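SUMMARY_SCHEMA_VERSION <- "1.0"

#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. Every
#' stage parameter defaults to the published analysis value: rarefaction
#' depths 15,000 (vaginal) / 2,500 (bladder) reads, a 5% per-sample
#' abundance filter, contaminant-score thresholds 0.5 (vaginal) / 0.3
#' (bladder), silhouette k in 2..6, 1,000 permutation trials with a 5%
#' tail, and a 0.10 betweenness keystone cutoff.
#'
#' @param input optional named list of file paths
#'   (`counts_vaginal, counts_bladder, metadata, tree_vaginal,
#'   tree_bladder`); when `NULL` the study-shaped synthetic scenario is
#'   simulated from `seed`.
#' @param outdir output directory (created if missing).
#' @param seed global integer seed; per-stage seeds are derived from it so
#'   stages rerun in isolation reproduce the full run.
#' @param rarefaction_depth,filter_threshold,decontam_threshold,k_range
#'   preprocessing and clustering parameters (see Details).
#' @param sparcc named list of [sparcc()] overrides.
#' @param permutation_trials,permutation_tail null-threshold settings
#'   (`trials = 100` is the documented fast mode).
#' @param betweenness_cutoff keystone cutoff.
#' @param permanova_permutations label permutations for PERMANOVA.
#' @param decontam_first run contaminant screening before the abundance
#'   filter (the published order is unstated; both are supported).
#' @param quiet suppress progress messages.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, outdir = tempfile("urogenet_run_"),
                            seed = 1,
                            rarefaction_depth = c(vaginal = 15000, bladder = 2500),
                            filter_threshold = 0.05,
                            decontam_threshold = c(vaginal = 0.5, bladder = 0.3),
                            k_range = 2:6,
                            sparcc = list(),
                            permutation_trials = 1000,
                            permutation_tail = 0.05,
                            betweenness_cutoff = 0.10,
                            permanova_permutations = 999,
                            decontam_first = FALSE,
                            quiet = FALSE) {
  stopifnot(all(c("vaginal", "bladder") %in% names(rarefaction_depth)),
            all(c("vaginal", "bladder") %in% names(decontam_threshold)),
            filter_threshold > 0, filter_threshold < 1,
            permutation_trials >= 1,
            permutation_tail >= 0, permutation_tail < 1,
            betweenness_cutoff > 0, betweenness_cutoff < 1)
  if (!is.null(input)) {
    need <- c("counts_vaginal", "counts_bladder", "metadata",
              "tree_vaginal", "tree_bladder")
    missing <- setdiff(need, names(input))
    if (length(missing) > 0)
      stop_ug("input lacks path(s): %s", paste(missing, collapse = ", "))
    for (p in unlist(input[need]))
      if (!file.exists(p)) stop_ug("input file not found: %s", p)
  }
  structure(list(input = input, outdir = outdir, seed = as.integer(seed),
                 rarefaction_depth = rarefaction_depth,
                 filter_threshold = filter_threshold,
                 decontam_threshold = decontam_threshold,
                 k_range = k_range, sparcc = sparcc,
                 permutation_trials = permutation_trials,
                 permutation_tail = permutation_tail,
                 betweenness_cutoff = betweenness_cutoff,
                 permanova_permutations = permanova_permutations,
                 decontam_first = decontam_first, quiet = quiet),
            class = "pipeline_config")
}

# Deterministic per-stage seed fan-out (documented derivation; < 2^31).
stage_seed <- function(seed, stage) {
  stages <- c("simulate", "preprocess", "diversity", "cluster", "network",
              "overlap")
  k <- match(stage, stages)
  if (is.na(k)) stop_ug("unknown stage '%s'", stage)
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

pmsg <- function(config, fmt, ...) {
  if (!isTRUE(config$quiet)) message(sprintf(paste0("[urogenet] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (if no input files) -> preprocess -> diversity ->
#' clustering -> networks (per cohort x site) -> overlap, writing every
#' intermediate artifact under `config$outdir` plus a machine-readable
#' `summary.json` (node/edge counts, modularity, connectance, codelength,
#' silhouette widths, keystone lists, overlap fractions). Fully
#' deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly; artifacts are on disk.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop_ug("config must be a pipeline_config")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  data <- pipeline_stage_data(config)
  prep <- list(vaginal = preprocess_site(config, data, "vaginal"),
               bladder = preprocess_site(config, data, "bladder"))
  div <- lapply(c(vaginal = "vaginal", bladder = "bladder"),
                function(s) diversity_site(config, data, prep[[s]], s))
  clus <- lapply(c(vaginal = "vaginal", bladder = "bladder"),
                 function(s) cluster_site(config, data, div[[s]]$wunifrac, s))
  nets <- network_stage(config, data, prep)
  ovl <- overlap_stage(config, data, prep)

  summary <- list(
    schema_version = SUMMARY_SCHEMA_VERSION,
    seed = config$seed,
    parameters = config[c("rarefaction_depth", "filter_threshold",
                          "decontam_threshold", "permutation_trials",
                          "permutation_tail", "betweenness_cutoff",
                          "permanova_permutations", "decontam_first")],
    preprocess = lapply(prep, `[[`, "summary"),
    diversity = lapply(div, `[[`, "summary"),
    clustering = lapply(clus, `[[`, "summary"),
    networks = nets$summary,
    overlap = ovl$summary)
  validate_summary(summary)
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  pmsg(config, "done in %.1f s; outputs in %s",
       as.numeric(difftime(Sys.time(), t0, units = "secs")), config$outdir)
  invisible(summary)
}

validate_summary <- function(s) {
  need <- c("schema_version", "seed", "parameters", "preprocess", "diversity",
            "clustering", "networks", "overlap")
  missing <- setdiff(need, names(s))
  if (length(missing) > 0)
    stop_ug("summary schema violation; missing: %s", paste(missing, collapse = ", "))
  if (!identical(s$schema_version, SUMMARY_SCHEMA_VERSION))
    stop_ug("unexpected summary schema version")
  invisible(s)
}

pipeline_stage_data <- function(config) {
  if (is.null(config$input)) {
    pmsg(config, "simulate: study-shaped scenario (seed %d)",
         stage_seed(config$seed, "simulate"))
    data <- simulate_study(seed = stage_seed(config$seed, "simulate"))
    write_simulated_inputs(data, file.path(config$outdir, "inputs"))
    data
  } else {
    inp <- config$input
    md <- read_sample_metadata(inp$metadata)
    list(vaginal = read_count_table(inp$counts_vaginal),
         bladder = read_count_table(inp$counts_bladder),
         metadata = md,
         tree_vaginal = ape::read.tree(inp$tree_vaginal),
         tree_bladder = ape::read.tree(inp$tree_bladder),
         phylum = if (!is.null(inp$taxonomy)) {
           tx <- read_taxonomy(inp$taxonomy)
           setNames(tx$phylum, tx$taxon_id)
         } else NULL)
  }
}

write_simulated_inputs <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(data$vaginal, file.path(dir, "counts_vaginal.tsv"))
  write_count_table(data$bladder, file.path(dir, "counts_bladder.tsv"))
  write_sample_metadata(data$metadata, file.path(dir, "metadata.tsv"))
  ape::write.tree(data$tree_vaginal, file.path(dir, "tree_vaginal.nwk"))
  ape::write.tree(data$tree_bladder, file.path(dir, "tree_bladder.nwk"))
  truth <- data$truth
  truth$contaminant_flags <- as.list(truth$contaminant_flags)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
}

preprocess_site <- function(config, data, site) {
  counts <- data[[site]]
  md <- data$metadata
  depth <- config$rarefaction_depth[[site]]
  pmsg(config, "preprocess %s: rarefy to %d, filter > %.0f%%, decontam < %.2f",
       site, depth, 100 * config$filter_threshold,
       config$decontam_threshold[[site]])
  rar <- rarefy(counts, depth, seed = stage_seed(config$seed, "preprocess"))
  conc <- setNames(md$dna_concentration, md$sample_id)[rownames(rar)]
  run_decontam <- function(tab) {
    if (all(is.na(conc))) return(list(table = tab, removed = character(0)))
    dc <- decontam_frequency(tab, conc, config$decontam_threshold[[site]])
    list(table = dc$table, removed = dc$removed)
  }
  if (config$decontam_first) {
    dc <- run_decontam(rar)
    filt <- abundance_filter(dc$table, config$filter_threshold)
  } else {
    filt0 <- abundance_filter(rar, config$filter_threshold)
    dc <- run_decontam(filt0)
    filt <- dc$table
  }
  write_count_table(filt, file.path(config$outdir,
                                    sprintf("counts_%s_processed.tsv", site)))
  list(table = filt,
       summary = list(site = site,
                      samples_in = nrow(counts),
                      samples_retained = nrow(filt),
                      dropped_samples = as.list(attr(rar, "dropped_samples")),
                      taxa_in = ncol(counts),
                      taxa_retained = ncol(filt),
                      contaminants_removed = dc$removed))
}

diversity_site <- function(config, data, prep, site) {
  tab <- prep$table
  tree <- ape::keep.tip(data[[paste0("tree_", site)]], colnames(tab))
  alpha <- alpha_diversity(tab)
  bc <- bray_curtis(tab)
  wu <- weighted_unifrac(tab, tree)
  uu <- unweighted_unifrac(tab, tree)
  ord <- pcoa(wu)
  md <- data$metadata[rownames(tab), ]
  perma <- permanova(wu, md,
                     terms = c("age", "bmi", "menopause", "estrogen_use", "cohort"),
                     test_term = "cohort",
                     permutations = config$permanova_permutations,
                     seed = stage_seed(config$seed, "diversity"))
  out <- config$outdir
  write.table(alpha, file.path(out, sprintf("alpha_%s.tsv", site)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_distance_matrix(bc, file.path(out, sprintf("braycurtis_%s.tsv", site)))
  write_distance_matrix(wu, file.path(out, sprintf("wunifrac_%s.tsv", site)))
  write_distance_matrix(uu, file.path(out, sprintf("uunifrac_%s.tsv", site)))
  write.table(data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates, check.names = FALSE),
              file.path(out, sprintf("pcoa_%s.tsv", site)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pmsg(config, "diversity %s: PERMANOVA cohort p = %.3f", site, perma$p_value)
  list(wunifrac = wu,
       summary = list(site = site,
                      permanova_cohort_F = perma$pseudo_F,
                      permanova_cohort_p = perma$p_value))
}

cluster_site <- function(config, data, wu, site) {
  sel <- select_k(wu, config$k_range)
  md <- data$metadata[rownames(wu), ]
  assoc <- lapply(c(cohort = "cohort", menopause = "menopause",
                    vaginal_product_use = "vaginal_product_use"),
                  function(v) cluster_association(sel$cluster,
                                                  setNames(md[[v]], md$sample_id),
                                                  seed = stage_seed(config$seed, "cluster"))$p_value)
  write.table(data.frame(sample_id = names(sel$cluster), cluster = sel$cluster),
              file.path(config$outdir, sprintf("clusters_%s.tsv", site)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_dendrogram(sel$dend, file.path(config$outdir,
                                       sprintf("dendrogram_%s.tsv", site)))
  pmsg(config, "cluster %s: k = %d (mean silhouette %.2f)", site, sel$k,
       sel$silhouette)
  list(summary = c(list(site = site, k = sel$k,
                        silhouette = sel$silhouette,
                        silhouette_by_k = as.list(sel$silhouette_by_k)),
                   association_p = list(assoc)))
}

network_stage <- function(config, data, prep) {
  nseed <- stage_seed(config$seed, "network")
  md <- data$metadata
  out <- list(); summaries <- list()
  for (site in c("vaginal", "bladder")) {
    tab <- prep[[site]]$table
    pmsg(config, "network %s: permutation threshold (%d trials)", site,
         config$permutation_trials)
    null <- permutation_threshold(tab, trials = config$permutation_trials,
                                  tail = config$permutation_tail,
                                  seed = nseed,
                                  sparcc_params = config$sparcc)
    for (grp in c("case", "control")) {
      ids <- md$sample_id[md$cohort == grp]
      sub <- tab[intersect(rownames(tab), ids), , drop = FALSE]
      sub <- sub[, colSums(sub) > 0, drop = FALSE]
      fit <- do.call(sparcc, c(list(x = sub, seed = nseed), config$sparcc))
      net <- build_network(fit, null$threshold)
      key <- sprintf("%s_%s", grp, site)
      write.table(
        data.frame(taxon = rownames(fit$cor), fit$cor, check.names = FALSE),
        file.path(config$outdir, sprintf("sparcc_%s.tsv", key)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_network_edgelist(net, file.path(config$outdir,
                                            sprintf("network_%s.tsv", key)))
      if (length(net$nodes) > 0)
        write_network_graphml(net, file.path(config$outdir,
                                             sprintf("network_%s.graphml", key)))
      summaries[[key]] <- network_summary(config, net, nseed, key)
      out[[key]] <- net
    }
  }
  list(networks = out, summary = summaries)
}

network_summary <- function(config, net, nseed, key) {
  if (length(net$nodes) == 0)
    return(list(network = key, n_nodes = 0, n_edges = 0))
  part <- detect_communities(net, trials = 10, seed = nseed)
  bc <- betweenness_centrality(net)
  keys <- keystone_taxa(bc, config$betweenness_cutoff)
  write.table(data.frame(taxon = names(part$membership),
                         module = part$membership,
                         betweenness = bc[names(part$membership)]),
              file.path(config$outdir, sprintf("centrality_%s.tsv", key)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  top_neigh <- if (nrow(keys) > 0)
    neighbor_correlations(net, keys$taxon[1], top_n = 10) else NULL
  pmsg(config, "network %s: %d nodes, %d edges, %d modules (Q = %.2f)",
       key, length(net$nodes), nrow(net$edges), part$n_modules,
       part$modularity)
  list(network = key,
       n_nodes = length(net$nodes),
       n_edges = nrow(net$edges),
       threshold = net$threshold,
       n_modules = part$n_modules,
       codelength = part$codelength,
       modularity = part$modularity,
       normalized_connectance = if (length(net$nodes) >= 2)
         normalized_connectance(net) else NA,
       keystone = keys,
       top_keystone_neighbors = top_neigh)
}

overlap_stage <- function(config, data, prep) {
  md <- data$metadata
  summaries <- list()
  for (grp in c("case", "control")) {
    ids <- md$sample_id[md$cohort == grp]
    va <- prep$vaginal$table
    bl <- prep$bladder$table
    va <- va[intersect(rownames(va), ids), , drop = FALSE]
    bl <- bl[intersect(rownames(bl), ids), , drop = FALSE]
    ov <- genus_overlap(presence_set(va), presence_set(bl))
    medtab <- if (!is.null(data$phylum))
      median_abundance_table(va, bl, ov$shared, data$phylum) else NULL
    if (!is.null(medtab))
      write.table(cbind(cohort = grp, medtab),
                  file.path(config$outdir, sprintf("overlap_median_%s.tsv", grp)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    summaries[[grp]] <- list(
      cohort = grp,
      n_vaginal = length(presence_set(va)),
      n_bladder = length(presence_set(bl)),
      n_shared = length(ov$shared),
      shared_fraction = ov$shared_fraction,
      fraction_of_vaginal = ov$fraction_of_a,
      fraction_of_bladder = ov$fraction_of_b,
      venn = list(vaginal_only = length(ov$unique_a),
                  bladder_only = length(ov$unique_b),
                  shared = length(ov$shared)))
    pmsg(config, "overlap %s: %d shared genera (%.0f%% of union)", grp,
         length(ov$shared), 100 * ov$shared_fraction)
  }
  jsonlite::write_json(summaries, file.path(config$outdir, "overlap_venn.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  list(summary = summaries)
}
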