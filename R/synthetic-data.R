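# Synthetic stand-in for the (confidential) two-project CHO bioprocess
# dataset: cluster-structured day-15 glycan profiles with duplicate
# measurements, and negative-binomial glycogene expression blocks at three
# time points with planted differential markers.  Everything is parameterized
# and fully deterministic under a seed, and ground truth (labels, markers,
# simulator parameters) travels with the data so recovery can be scored.

#' Glycan species tracked by the synthetic profile generator
#' @return character vector of canonical species names.
#' @export
glycan_species <- function() {
  c("Man5", "Man6", "Man7", "Man8", "Man9",
    "G0-GN", "G0", "G0F", "G1F", "G2F")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) { g[which.max(alpha)] <- 1 }
  g / sum(g)
}

#' Specification of one synthetic project
#'
#' @param name project label.
#' @param n_samples biological samples (the study had 53 across two
#'   projects).
#' @param n_replicates duplicate measurements per sample (study: 2).
#' @param clusters list of cluster templates: each
#'   `list(name, weight, centroid, concentration)` with `centroid` a valid
#'   profile over [glycan_species()] and `concentration` the Dirichlet
#'   precision of sample-level profiles around it.
#' @param markers data.frame(gene, cluster, day, log2_effect): genes shifted
#'   by `log2_effect` in the given cluster's samples on the given day.
#' @param n_background_genes extra non-panel genes with no class signal.
#' @param nb_dispersion negative-binomial dispersion (default 0.1).
#' @param inter_gene_correlation strength in [0, 1) of a sample-level
#'   equicorrelated latent factor on log-expression (default 0.1); raise it
#'   to emulate strongly intercorrelated time points.
#' @param replicate_concentration Dirichlet precision of replicate profiles
#'   around their sample mean (default 2000: small technical noise).
#' @return a `project_spec` list.
#' @export
project_spec <- function(name, n_samples, n_replicates = 2, clusters,
                         markers = NULL, n_background_genes = 24,
                         nb_dispersion = 0.1, inter_gene_correlation = 0.1,
                         replicate_concentration = 2000) {
  w <- vapply(clusters, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) stop("cluster weights must sum to 1", call. = FALSE)
  for (cl in clusters) {
    if (all(cl$centroid == 0)) stop("degenerate (zero) centroid", call. = FALSE)
    validate_profile(cl$centroid, tol = 1e-9)
  }
  stopifnot(inter_gene_correlation >= 0, inter_gene_correlation < 1)
  structure(list(name = name, n_samples = as.integer(n_samples),
                 n_replicates = as.integer(n_replicates),
                 clusters = clusters, markers = markers,
                 n_background_genes = as.integer(n_background_genes),
                 nb_dispersion = nb_dispersion,
                 inter_gene_correlation = inter_gene_correlation,
                 replicate_concentration = replicate_concentration),
            class = "project_spec")
}

centroid_from <- function(...) {
  v <- c(...)
  p <- setNames(numeric(length(glycan_species())), glycan_species())
  p[names(v)] <- v
  validate_profile(p, tol = 1e-9)
  p
}

#' Preset emulating project A (two clusters: Man5- vs G0F-dominant)
#'
#' Stylized centroid templates (not digitized from any measured dataset);
#' markers plant the biology discussed for this contrast: Alg5 elevated with
#' the high-Man5 cluster at day 0, Man2a1 and Man1c1 with the G0F cluster.
#' @param n_samples samples (default 26).
#' @return a `project_spec`.
#' @export
project_spec_a <- function(n_samples = 26) {
  project_spec(
    "projectA", n_samples = n_samples,
    clusters = list(
      list(name = "Man5", weight = 0.5, concentration = 80,
           centroid = centroid_from(Man5 = 0.50, Man6 = 0.06, Man7 = 0.04,
                                    Man8 = 0.03, Man9 = 0.02, `G0-GN` = 0.03,
                                    G0 = 0.05, G0F = 0.17, G1F = 0.07,
                                    G2F = 0.03)),
      list(name = "G0F", weight = 0.5, concentration = 80,
           centroid = centroid_from(Man5 = 0.08, Man6 = 0.02, Man7 = 0.01,
                                    Man8 = 0.01, Man9 = 0.01, `G0-GN` = 0.02,
                                    G0 = 0.06, G0F = 0.52, G1F = 0.20,
                                    G2F = 0.07))),
    markers = data.frame(
      gene = c("Alg5", "Man1a1", "Man2a1", "Man1c1"),
      cluster = c("Man5", "Man5", "G0F", "G0F"),
      day = c("day0", "day0", "day0", "day10"),
      log2_effect = 1))
}

#' Preset emulating project B (three clusters: G0/G0F/G1F-dominant)
#'
#' Markers plant early-pathway genes (Alg5, Alg8, Dpm1) with the
#' under-processed G0 cluster and the UDP-Gal transporter (Slc35a2) plus
#' St3gal1 with the G1F cluster, all at day 0 with 2-fold shifts.
#' @param n_samples samples (default 27).
#' @return a `project_spec`.
#' @export
project_spec_b <- function(n_samples = 27) {
  project_spec(
    "projectB", n_samples = n_samples,
    clusters = list(
      list(name = "G0", weight = 1 / 3, concentration = 100,
           centroid = centroid_from(Man5 = 0.08, Man6 = 0.02, Man7 = 0.01,
                                    Man8 = 0.01, Man9 = 0.01, `G0-GN` = 0.04,
                                    G0 = 0.45, G0F = 0.25, G1F = 0.10,
                                    G2F = 0.03)),
      list(name = "G0F", weight = 1 / 3, concentration = 100,
           centroid = centroid_from(Man5 = 0.05, Man6 = 0.01, Man7 = 0.01,
                                    Man8 = 0.01, Man9 = 0.01, `G0-GN` = 0.02,
                                    G0 = 0.10, G0F = 0.55, G1F = 0.18,
                                    G2F = 0.06)),
      list(name = "G1F", weight = 1 / 3, concentration = 100,
           centroid = centroid_from(Man5 = 0.04, Man6 = 0.01, Man7 = 0.01,
                                    Man8 = 0.01, Man9 = 0.01, `G0-GN` = 0.02,
                                    G0 = 0.05, G0F = 0.25, G1F = 0.42,
                                    G2F = 0.18))),
    markers = data.frame(
      gene = c("Alg5", "Alg8", "Dpm1", "Slc35a2", "St3gal1"),
      cluster = c("G0", "G0", "G0", "G1F", "G1F"),
      day = "day0",
      log2_effect = 1))
}

#' Generate cluster-structured glycan profiles
#'
#' Per sample: a cluster drawn by weight, a sample-level mean profile from a
#' Dirichlet centered on the cluster centroid (precision = the cluster's
#' `concentration`), and replicate rows from a tighter Dirichlet around that
#' mean.
#'
#' @param spec a `project_spec`.
#' @param seed integer seed.
#' @return list with `profiles` (rows = sample x replicate, columns =
#'   species), `labels` (factor per row), `sample_id` (per row),
#'   `sample_labels` (per sample), `metadata` data.frame.
#' @export
make_profiles <- function(spec, seed = 1) {
  old <- get_rng_state(); on.exit(set_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  species <- names(spec$clusters[[1]]$centroid)
  w <- vapply(spec$clusters, `[[`, numeric(1), "weight")
  cl_names <- vapply(spec$clusters, `[[`, character(1), "name")
  n <- spec$n_samples; reps <- spec$n_replicates
  cl_idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  rows <- n * reps
  profiles <- matrix(NA_real_, rows, length(species),
                     dimnames = list(NULL, species))
  sample_id <- character(rows); row_label <- character(rows)
  rn <- character(rows)
  r <- 0L
  for (i in seq_len(n)) {
    cl <- spec$clusters[[cl_idx[i]]]
    mean_i <- rdirichlet1(cl$concentration * cl$centroid)
    for (j in seq_len(reps)) {
      r <- r + 1L
      profiles[r, ] <- rdirichlet1(spec$replicate_concentration * mean_i)
      sample_id[r] <- sprintf("%s_S%02d", spec$name, i)
      row_label[r] <- cl$name
      rn[r] <- sprintf("%s_S%02d_r%d", spec$name, i, j)
    }
  }
  rownames(profiles) <- rn
  list(profiles = profiles,
       labels = factor(row_label, levels = cl_names),
       sample_id = sample_id,
       sample_labels = setNames(factor(cl_names[cl_idx], levels = cl_names),
                                unique(sample_id)),
       metadata = data.frame(row = rn, sample_id = sample_id,
                             cluster = row_label))
}

#' Generate three-day expression blocks with planted markers
#'
#' Negative-binomial counts for the N-glycogene panel plus background genes;
#' marker genes are shifted by their log2 effect in their cluster's samples
#' on their day; a sample-level equicorrelated latent factor (strength
#' `inter_gene_correlation`) induces correlation between genes.  The three
#' day blocks share the one day-15 glycan cluster label per sample.
#'
#' @param spec a `project_spec`.
#' @param profiles result of [make_profiles()] (supplies labels and row ids).
#' @param seed integer seed.
#' @param panel gene panel (default: the packaged N-glycogene panel).
#' @return an omics block set: list with `blocks` (named list day0/day6/day10
#'   of samples x genes count matrices), `labels`, `sample_id`, `gene_panel`,
#'   `markers`.
#' @export
make_expression <- function(spec, profiles, seed = 2,
                            panel = default_gene_panel()) {
  old <- get_rng_state(); on.exit(set_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  genes <- c(panel, if (spec$n_background_genes > 0)
    sprintf("BG%04d", seq_len(spec$n_background_genes)))
  if (!is.null(spec$markers) && !all(spec$markers$gene %in% genes))
    stop("marker genes must be members of the gene universe", call. = FALSE)
  days <- c("day0", "day6", "day10")
  rows <- rownames(profiles$profiles)
  n_rows <- length(rows)
  sample_of_row <- profiles$sample_id
  usamp <- unique(sample_of_row)
  base <- runif(length(genes), 3, 9)          # log2 baseline abundance
  names(base) <- genes
  rho <- spec$inter_gene_correlation
  size <- 1 / spec$nb_dispersion
  blocks <- list()
  for (d in days) {
    day_shift <- runif(length(genes), -0.2, 0.2)
    u <- rnorm(length(usamp))                  # per-sample latent factor
    names(u) <- usamp
    log2mu <- matrix(rep(base + day_shift, each = n_rows), n_rows,
                     length(genes), dimnames = list(rows, genes))
    log2mu <- log2mu + rho * u[sample_of_row]
    if (!is.null(spec$markers)) {
      mk <- spec$markers[spec$markers$day == d, , drop = FALSE]
      for (i in seq_len(nrow(mk))) {
        in_cl <- profiles$labels == mk$cluster[i]
        log2mu[in_cl, mk$gene[i]] <-
          log2mu[in_cl, mk$gene[i]] + mk$log2_effect[i]
      }
    }
    counts <- matrix(rnbinom(n_rows * length(genes), mu = 2^log2mu,
                             size = size),
                     n_rows, length(genes), dimnames = list(rows, genes))
    blocks[[d]] <- counts
  }
  list(blocks = blocks, labels = profiles$labels,
       sample_id = sample_of_row, gene_panel = panel,
       markers = spec$markers)
}

#' Generate a complete synthetic dataset for one project
#'
#' @param spec a `project_spec`.
#' @param seed master seed (profile and expression substreams are derived
#'   from it).
#' @return list with `profiles`, `expression`, `true_labels`,
#'   `true_markers`, `spec`.
#' @export
make_dataset <- function(spec, seed = 1) {
  pr <- make_profiles(spec, seed = derive_seed(seed, "profiles"))
  ex <- make_expression(spec, pr, seed = derive_seed(seed, "expression"))
  list(profiles = pr, expression = ex, true_labels = pr$labels,
       true_markers = spec$markers, spec = spec)
}

#' The packaged N-glycogene panel
#'
#' Seventy-six genes relevant to N-linked glycosylation, assembled from the
#' canonical processing enzymes (mannosidases, Mgat family, Fut8,
#' galactosyl- and sialyltransferases), the LLO synthesis pathway (Alg and
#' dolichol/DPM genes), the oligosaccharyltransferase complex, ER glucosidase
#' and quality-control genes, nucleotide-sugar transporters and precursor
#' metabolism.  Shipped as an editable text resource
#' (`inst/extdata/nglycogenes.txt`).
#'
#' @return character vector of 76 gene symbols.
#' @export
default_gene_panel <- function() {
  path <- system.file("extdata", "nglycogenes.txt", package = "glygolgi")
  if (path == "") path <- file.path("inst", "extdata", "nglycogenes.txt")
  readLines(path)
}

#' Core biantennary rule set for recovery experiments
#'
#' The canonical pathway without tri-/tetra-antennary branching and
#' sialylation (Mgat4, Mgat5, SiaT removed): the topology used by the
#' parameter-recovery benchmark, where every active enzyme must be
#' identifiable from the terminal profile.
#'
#' @return a rule list (subset of [default_rules()]).
#' @export
core_biantennary_rules <- function() {
  Filter(function(r) !r$enzyme %in% c("Mgat4", "Mgat5", "SiaT"),
         default_rules())
}

#' Base parameters of the recovery benchmark
#'
#' Tied (cisterna-uniform) activities on the core biantennary topology,
#' chosen so every active enzyme is two-sided identifiable from the terminal
#' profile: mannosidase trimming is incomplete (Man6-Man9 remain visible),
#' Man5, hybrid, G0-GN, G0/G0F and galactosylated species are all populated.
#' A parameter constrained only from one side (e.g. a trimming rate above
#' which the profile saturates) has a posterior median that wanders with the
#' prior, which would confound shift-based recovery scoring.
#'
#' @param K number of cisternae.
#' @return an `enzyme_params` with tied activities.
#' @export
recovery_base_params <- function(K = 4) {
  act <- matrix(c(1.4, 1.5, 1.8, 0.8, 1.5, 0, 0, 0.5, 0), 9, K,
                dimnames = list(GLYCAN_ENZYMES, NULL))
  enzyme_params(act, lock_resolution_rate = 5, residence_time = 1)
}

#' Build a synthetic ABC fitting target with known ground truth
#'
#' Applies per-enzyme fold-changes to a base parameter set, simulates a
#' profile from the perturbed parameters, and returns it together with the
#' ground truth so parameter-recovery experiments can be scored.
#'
#' @param params_base an `enzyme_params` (default [default_enzyme_params()]).
#' @param perturbation named vector of fold-changes per enzyme (applied to
#'   all cisternae), e.g. `c(Mgat1 = 0.25)`.
#' @param n_glycans glycans to simulate (default 10000).
#' @param seed integer seed.
#' @param engine optional prebuilt [ssa_engine()].
#' @return list with `observed` (profile), `true_params`, `base_params`,
#'   `perturbation`.
#' @export
make_abc_target <- function(params_base = default_enzyme_params(),
                            perturbation = c(Mgat1 = 0.25),
                            n_glycans = 10000, seed = 1, engine = NULL) {
  act <- params_base$activity
  for (e in names(perturbation)) {
    if (!e %in% rownames(act)) stop("unknown enzyme: ", e, call. = FALSE)
    act[e, ] <- act[e, ] * perturbation[[e]]
  }
  true_params <- enzyme_params(act, params_base$lock_resolution_rate,
                               params_base$residence_time)
  res <- simulate_profile(true_params, n_glycans, seed = seed, engine = engine)
  list(observed = res$profile, true_params = true_params,
       base_params = params_base, perturbation = perturbation)
}
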