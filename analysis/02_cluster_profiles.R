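#!/usr/bin/env Rscript
# Cluster the day-15 glycan profiles of each project: average duplicate
# measurements, pick k by the elbow heuristic, run k-means, characterize the
# clusters by their dominant glycans, and overlay the PCA.  Expects the
# tables written by 01_simulate_data.R.

library(glygolgi)

seed <- 2
for (project in c("projectA", "projectB")) {
  pdir <- file.path("results", "data", project)
  profiles <- read_profile_table(file.path(pdir, "profiles.csv"))
  sample_id <- sub("_r[0-9]+$", "", rownames(profiles))
  sm <- rowsum(profiles, sample_id)
  sm <- sm / rowSums(sm)

  elbow <- elbow_curve(sm, k_max = 6, seed = seed)
  k <- best_elbow_k(elbow)
  km <- kmeans_profiles(sm, k, seed = seed + 1)
  pca <- pca_profiles(sm)
  ch <- characterize_clusters(km, sm, pca)

  truth <- read.csv(file.path(pdir, "true_labels.csv"))
  truth_per_sample <- truth$true_cluster[match(rownames(sm),
                                               truth$sample_id)]
  ari <- mclust::adjustedRandIndex(km$labels, truth_per_sample)

  message(project, ": elbow k = ", k,
          ", clusters = ", paste(ch$clusters$name, collapse = "/"),
          ", ARI vs planted labels = ", round(ari, 3))
  write.csv(elbow, file.path(pdir, "elbow.csv"), row.names = FALSE)
  write.csv(data.frame(sample_id = rownames(sm), cluster = km$labels,
                       cluster_name = ch$clusters$name[km$labels]),
            file.path(pdir, "clusters.csv"), row.names = FALSE)
  write.csv(data.frame(species = colnames(sm), pc1 = pca$loadings[, 1],
                       pc2 = pca$loadings[, 2]),
            file.path(pdir, "pca_loadings.csv"), row.names = FALSE)
}
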