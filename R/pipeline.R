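# End-to-end orchestration: load -> normalize -> assign -> structure ->
# diversity -> clones/dispersal/temporal, with a JSON run manifest that
# makes the whole analysis replayable from (inputs, seeds) alone.

.stage_log <- function(...) message("[clonalscope] ", ...)

#' Run the full analysis pipeline
#'
#' Executes every stage of the genotype analysis on an isolate CSV and a
#' reference-panel CSV and writes all reports plus a manifest into
#' `out_dir`. Stages: plate normalization (optional), ploidy inference and
#' nearest-reference group assignment, nearest-neighbour imputation +
#' allele-presence PCA + minimum spanning tree (optionally repeated on a
#' randomly 2N-constrained copy with a concordance report), per-group
#' diversity table with bootstrap CIs, clone detection with winery
#' persistence, pair distances and distance classes, regional group
#' composition, within-sample diversity, and vintage-binned temporal group
#' proportions.
#'
#' @param isolates_csv Path to the isolate table CSV.
#' @param refs_csv Path to the reference panel CSV.
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; stage seeds derive from it.
#' @param n_boot Bootstrap replicates for diversity and temporal CIs.
#' @param normalize_control Control strain id for plate normalization, or
#'   `NULL` to skip the stage.
#' @param reference_plate Reference plate id (required with
#'   `normalize_control`).
#' @param constrain_2n If `TRUE`, also analyze a randomly 2N-constrained
#'   copy of the table and report assignment concordance.
#' @param n_axes PCA axes carried into the spanning tree.
#' @return The run manifest (list), invisibly; written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(isolates_csv, refs_csv, out_dir, seed = 1L,
                         n_boot = 100L, normalize_control = NULL,
                         reference_plate = NULL, constrain_2n = FALSE,
                         n_axes = 2L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  paths <- list()
  refs <- read_reference_panel(refs_csv)
  tab <- read_isolates(isolates_csv, refs$panel)

  if (!is.null(normalize_control)) {
    .stage_log("normalizing plates against ", normalize_control)
    if (is.null(reference_plate))
      stop("reference_plate required when normalize_control is given")
    ctrl <- plate_control(normalize_control, reference_plate)
    tab <- normalize_plates(tab, ctrl)
    tab <- drop_controls(tab, ctrl)
    paths$normalized <- file.path(out_dir, "normalized.csv")
    write_isolates(tab, paths$normalized)
    utils::write.csv(
      data.frame(plate_id = rownames(attr(tab, "plate_offsets")),
                 attr(tab, "plate_offsets"), check.names = FALSE),
      file.path(out_dir, "plate_offsets.csv"), row.names = FALSE)
    paths$plate_offsets <- file.path(out_dir, "plate_offsets.csv")
  }

  .stage_log("assigning genetic groups")
  assignment <- assign_groups(tab, refs)
  tab <- assigned_table(assignment)
  ploidies <- table_ploidies(tab)
  paths$assigned <- file.path(out_dir, "assigned.csv")
  write_isolates(tab, paths$assigned)
  paths$assignment <- file.path(out_dir, "assignment.csv")
  out_assign <- cbind(as.data.frame(assignment),
                      putative_ploidy = unname(ploidies))
  utils::write.csv(out_assign, paths$assignment, row.names = FALSE, na = "")

  .stage_log("imputation, PCA, minimum spanning tree")
  imputed <- impute_missing_nn(tab, seed = seed)
  pca <- run_pca(encode_alleles(imputed), n_components = max(2L, n_axes))
  mst <- minimum_spanning_tree(pca, n_axes = n_axes)
  paths$pca <- file.path(out_dir, "pca_scores.tsv")
  utils::write.table(
    data.frame(strain_id = rownames(pca$scores), pca$scores,
               check.names = FALSE),
    paths$pca, sep = "\t", row.names = FALSE, quote = FALSE)
  paths$mst <- file.path(out_dir, "mst_edges.tsv")
  utils::write.table(as.data.frame(mst), paths$mst, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  concordance <- NULL
  if (constrain_2n) {
    .stage_log("2N-constrained control analysis")
    tab2 <- constrain_to_2n(tab, seed = seed + 1L)
    assignment2 <- assign_groups(tab2, refs)
    concordance <- clustering_concordance(assignment, assignment2)
    imputed2 <- impute_missing_nn(tab2, seed = seed)
    pca2 <- run_pca(encode_alleles(imputed2), n_components = max(2L, n_axes))
    mst2 <- minimum_spanning_tree(pca2, n_axes = n_axes)
    paths$pca_2n <- file.path(out_dir, "pca_scores_2n.tsv")
    utils::write.table(
      data.frame(strain_id = rownames(pca2$scores), pca2$scores,
                 check.names = FALSE),
      paths$pca_2n, sep = "\t", row.names = FALSE, quote = FALSE)
    paths$mst_2n <- file.path(out_dir, "mst_edges_2n.tsv")
    utils::write.table(as.data.frame(mst2), paths$mst_2n, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths$concordance <- file.path(out_dir, "concordance.json")
    jsonlite::write_json(
      list(overall = unclass(concordance)[1],
           per_group = as.list(attr(concordance, "per_group"))),
      paths$concordance, auto_unbox = TRUE, digits = NA)
  }

  .stage_log("diversity report (", n_boot, " bootstrap replicates)")
  div <- diversity_report(tab, refs, n_boot = n_boot, seed = seed + 2L)
  paths$diversity <- file.path(out_dir, "diversity.csv")
  utils::write.csv(div, paths$diversity, row.names = FALSE, na = "NR")

  .stage_log("clones, persistence, dispersal")
  clones <- find_clone_groups(tab)
  paths$clones <- file.path(out_dir, "clone_groups.csv")
  membership <- data.frame(
    clone_id = rep(clones$groups$clone_id, lengths(clones$members)),
    strain_id = unlist(clones$members), stringsAsFactors = FALSE)
  utils::write.csv(merge(membership, clones$groups, by = "clone_id"),
                   paths$clones, row.names = FALSE)
  persistence <- winery_persistence(clones, tab)
  paths$persistence <- file.path(out_dir, "persistence.csv")
  utils::write.csv(persistence, paths$persistence, row.names = FALSE)
  pairs <- clone_pair_distances(clones, tab)
  paths$pair_distances <- file.path(out_dir, "pair_distances.tsv")
  utils::write.table(pairs, paths$pair_distances, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  classes <- bin_distances(pairs$km)
  paths$distance_classes <- file.path(out_dir, "distance_classes.json")
  jsonlite::write_json(
    list(classes = as.data.frame(classes),
         local_fraction = attr(classes, "local_fraction")),
    paths$distance_classes, auto_unbox = TRUE, digits = NA)

  .stage_log("regional, sample and temporal summaries")
  for (by in c("region", "country")) {
    dist_by <- region_group_distribution(tab, by)
    p <- file.path(out_dir, paste0("groups_by_", by, ".csv"))
    utils::write.csv(
      data.frame(area = rownames(dist_by$counts), dist_by$counts,
                 check.names = FALSE),
      p, row.names = FALSE)
    paths[[paste0("groups_by_", by)]] <- p
  }
  samp <- sample_group_diversity(tab)
  paths$sample_diversity <- file.path(out_dir, "sample_diversity.csv")
  utils::write.csv(samp, paths$sample_diversity, row.names = FALSE)
  temporal <- temporal_group_proportions(tab, n_boot = n_boot,
                                         seed = seed + 3L)
  paths$temporal <- file.path(out_dir, "temporal_proportions.csv")
  utils::write.csv(temporal, paths$temporal, row.names = FALSE)

  manifest <- list(
    package = "clonalscope",
    version = as.character(utils::packageVersion("clonalscope")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, n_boot = n_boot, n_axes = n_axes,
    constrain_2n = constrain_2n,
    normalize_control = normalize_control,
    reference_plate = reference_plate,
    inputs = list(
      isolates_csv = isolates_csv,
      isolates_md5 = unname(tools::md5sum(isolates_csv)),
      refs_csv = refs_csv,
      refs_md5 = unname(tools::md5sum(refs_csv))),
    outputs = lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    summary = list(
      n_isolates = n_isolates(tab),
      n_genotypes = length(unique(genotype_keys(tab))),
      n_clone_groups = nrow(clones$groups),
      putative_triploid_fraction =
        mean(ploidies == 3L, na.rm = TRUE),
      concordance_2n = if (is.null(concordance)) NULL
                       else unclass(concordance)[1])
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  .stage_log("done: ", out_dir)
  invisible(manifest)
}

#' Run the pipeline from a JSON config file
#'
#' Thin wrapper over [run_pipeline()]: the JSON object maps directly onto
#' its arguments (`isolates_csv`, `refs_csv`, `out_dir`, `seed`, `n_boot`,
#' `normalize_control`, `reference_plate`, `constrain_2n`, `n_axes`).
#' Relative paths resolve against the config file's directory.
#'
#' @param config_path Path to the JSON config.
#' @return The run manifest, invisibly.
#' @export
run_all <- function(config_path) {
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  base <- dirname(normalizePath(config_path))
  resolve <- function(p) if (is.null(p) || grepl("^(/|[A-Za-z]:)", p)) p
                         else file.path(base, p)
  run_pipeline(
    isolates_csv = resolve(cfg$isolates_csv),
    refs_csv = resolve(cfg$refs_csv),
    out_dir = resolve(cfg$out_dir),
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
    n_boot = if (is.null(cfg$n_boot)) 100L else as.integer(cfg$n_boot),
    normalize_control = cfg$normalize_control,
    reference_plate = cfg$reference_plate,
    constrain_2n = isTRUE(cfg$constrain_2n),
    n_axes = if (is.null(cfg$n_axes)) 2L else as.integer(cfg$n_axes))
}
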