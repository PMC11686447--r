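#!/usr/bin/env Rscript
# Predict each project's glycan clusters from its three-day glycogene
# expression: filter to the N-glycogene panel, build the pairwise-sPLS
# design matrix, tune sparsity by nested 10-fold CV, refit, evaluate
# one-vs-rest AUCs and stability-select predictive genes (>= 7/10 folds).

library(glygolgi)

seed <- 3
panel <- default_gene_panel()
for (project in c("projectA", "projectB")) {
  pdir <- file.path("results", "data", project)
  clusters <- read.csv(file.path(pdir, "clusters.csv"))
  blocks <- lapply(c(day0 = "day0", day6 = "day6", day10 = "day10"),
                   function(d) {
    b <- read_expression_table(file.path(pdir,
                                         paste0("expression_", d, ".csv")))
    filter_gene_panel(log2(b + 1), panel)
  })
  sample_id <- sub("_r[0-9]+$", "", rownames(blocks$day0))
  y <- factor(clusters$cluster_name[match(sample_id, clusters$sample_id)])

  design <- build_design(blocks)
  tn <- tune_model(blocks, y, design, grid_ncomp = 2,
                   grid_keepX = c(5, 10, 20), seed = seed, group = sample_id)
  cv <- cv_block_splsda(blocks, y, design, n_components = tn$n_components,
                        keepX = lapply(blocks, function(b) tn$keepX),
                        seed = seed + 1, group = sample_id)
  stable <- stability_select(cv)

  message(project, ": tuned keepX = ", tn$keepX,
          ", per-class AUC = ",
          paste(names(cv$class_auc), round(cv$class_auc, 2),
                sep = "=", collapse = " "),
          "; ", nrow(stable), " stable genes (",
          sum(stable$block == "day0"), " at day 0)")
  write.csv(stable, file.path(pdir, "stable_genes.csv"), row.names = FALSE)
  write.csv(data.frame(class = names(cv$class_auc), auc = cv$class_auc),
            file.path(pdir, "auc.csv"), row.names = FALSE)
  bl_auc <- as.data.frame(cv$block_class_auc)
  bl_auc$class <- rownames(bl_auc)
  write.csv(bl_auc, file.path(pdir, "block_auc.csv"), row.names = FALSE)
}
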