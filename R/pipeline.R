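# End-to-end orchestration: synthesize a project, cluster its glycan
# profiles, predict the clusters from expression, and (optionally) fit the
# mechanistic model to two cluster-mean profiles and compare them.  Every
# artifact directory is stamped with the configuration and master seed so a
# run can be reproduced exactly.

#' Run the full analysis pipeline on a synthetic project
#'
#' Stages: (1) generate profiles and expression blocks from `spec`;
#' (2) average duplicate measurements, elbow-select k, k-means cluster the
#' profiles; (3) build the block design, cross-validate the multi-block
#' sPLS-DA model against the *inferred* clusters and stability-select
#' predictive genes; (4) optionally fit the Golgi model to the two most
#' separated cluster-mean profiles by ABC and report per-enzyme shifts.
#' Every stage draws its seed from the master seed via a named substream, so
#' stages are independently reproducible.
#'
#' @param out_dir output directory (created if needed).
#' @param spec a `project_spec` (default [project_spec_a()]).
#' @param seed master seed.
#' @param k number of clusters, or `"auto"` for the elbow heuristic.
#' @param keepX retained genes per block and component in the predictive
#'   model (default 10).
#' @param n_components components of the predictive model (default 2).
#' @param run_abc also run the ABC cluster comparison (slow; default FALSE).
#' @param abc an [abc_config()] used when `run_abc = TRUE`.
#' @return invisibly, a list with the stage results; tables are written
#'   under `out_dir`.
#' @export
run_pipeline <- function(out_dir, spec = project_spec_a(), seed = 1,
                         k = "auto", keepX = 10, n_components = 2,
                         run_abc = FALSE,
                         abc = abc_config(chain_length = 400, n_chains = 2,
                                          n_glycans = 2000,
                                          tie_cisternae = TRUE)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_line <- function(...) message("[glygolgi] ", ...)

  log_line("stage synth: generating ", spec$name)
  ds <- make_dataset(spec, seed = derive_seed(seed, "synth"))
  write_profile_table(ds$profiles$profiles,
                      file.path(out_dir, "profiles.csv"))
  for (d in names(ds$expression$blocks))
    write_expression_table(ds$expression$blocks[[d]],
                           file.path(out_dir, paste0("expression_", d, ".csv")))

  log_line("stage cluster: elbow + k-means")
  # duplicate measurements are averaged (and renormalized) before clustering
  sample_mean <- rowsum(ds$profiles$profiles, ds$profiles$sample_id) /
    as.vector(table(ds$profiles$sample_id)[unique(ds$profiles$sample_id)])
  sample_mean <- sample_mean / rowSums(sample_mean)
  elbow <- elbow_curve(sample_mean, k_max = min(6, nrow(sample_mean)),
                       seed = derive_seed(seed, "elbow"))
  k_use <- if (identical(k, "auto")) best_elbow_k(elbow) else as.integer(k)
  km <- kmeans_profiles(sample_mean, k_use, seed = derive_seed(seed, "kmeans"))
  pca <- pca_profiles(sample_mean)
  ch <- characterize_clusters(km, sample_mean, pca)
  cluster_name <- ch$clusters$name[km$labels]
  write.csv(data.frame(sample_id = rownames(sample_mean),
                       cluster = km$labels, cluster_name = cluster_name),
            file.path(out_dir, "clusters.csv"), row.names = FALSE)
  write.csv(elbow, file.path(out_dir, "elbow.csv"), row.names = FALSE)

  log_line("stage predict: block-sPLS-DA with 10-fold CV")
  row_cluster <- factor(cluster_name[match(ds$profiles$sample_id,
                                           rownames(sample_mean))])
  panel_blocks <- lapply(ds$expression$blocks, function(b)
    filter_gene_panel(log2(b + 1), ds$expression$gene_panel))
  design <- build_design(panel_blocks)
  cv <- cv_block_splsda(panel_blocks, row_cluster, design,
                        n_components = n_components,
                        keepX = lapply(panel_blocks, function(b) keepX),
                        seed = derive_seed(seed, "cv"),
                        group = ds$profiles$sample_id)
  stable <- stability_select(cv)
  write.csv(stable, file.path(out_dir, "stable_genes.csv"), row.names = FALSE)
  write.csv(data.frame(class = names(cv$class_auc), auc = cv$class_auc),
            file.path(out_dir, "auc.csv"), row.names = FALSE)

  comparison <- NULL
  if (run_abc) {
    log_line("stage fit-abc: comparing the two most separated clusters")
    cent <- km$centroids[order(-km$sizes)[1:2], , drop = FALSE]
    abc$seed <- derive_seed(seed, "abc")
    comparison <- compare_clusters(cent[1, ] / sum(cent[1, ]),
                                   cent[2, ] / sum(cent[2, ]), abc)
    write.csv(comparison$enzyme_table,
              file.path(out_dir, "enzyme_shifts.csv"), row.names = FALSE)
  }

  stamp <- list(package = "glygolgi",
                version = as.character(utils::packageVersion("glygolgi")),
                seed = seed, k = k_use, keepX = keepX,
                n_components = n_components, run_abc = run_abc,
                spec_name = spec$name,
                elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(stamp, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("done in ", round(stamp$elapsed_s, 1), " s")
  invisible(list(dataset = ds, elbow = elbow, kmeans = km, pca = pca,
                 characterization = ch, design = design, cv = cv,
                 stable = stable, comparison = comparison))
}
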