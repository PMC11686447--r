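#!/usr/bin/env Rscript
# Generate the synthetic two-project study: cluster-structured day-15 glycan
# profiles (duplicate measurements per sample) and three-day glycogene
# expression blocks with planted markers.  Writes delimited tables under
# results/data/.

library(glygolgi)

seed <- 1
out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (spec in list(project_spec_a(), project_spec_b())) {
  ds <- make_dataset(spec, seed = seed + nchar(spec$name))
  pdir <- file.path(out, spec$name)
  dir.create(pdir, showWarnings = FALSE)
  write_profile_table(ds$profiles$profiles, file.path(pdir, "profiles.csv"))
  for (d in names(ds$expression$blocks))
    write_expression_table(ds$expression$blocks[[d]],
                           file.path(pdir, paste0("expression_", d, ".csv")))
  write.csv(data.frame(row = rownames(ds$profiles$profiles),
                       sample_id = ds$profiles$sample_id,
                       true_cluster = as.character(ds$true_labels)),
            file.path(pdir, "true_labels.csv"), row.names = FALSE)
  write.csv(ds$true_markers, file.path(pdir, "true_markers.csv"),
            row.names = FALSE)
  message(spec$name, ": ", nrow(ds$profiles$profiles), " profile rows, ",
          length(ds$expression$gene_panel), " panel genes + ",
          spec$n_background_genes, " background genes per day block")
}
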