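# Unsupervised structure in glycan profiles: PCA, k-means with elbow-based
# cluster-count selection, and per-cluster characterization.  Profiles are
# clustered on raw fractions (the compositional CLR transform is available as
# an option but is not the default).

#' Validate a sample x species profile matrix
#'
#' @param x numeric matrix, rows = samples (profiles), columns = glycan
#'   species; each row must sum to 1 within `tol` and be non-negative.
#' @param tol row-sum tolerance.
#' @return `x`, invisibly.
#' @export
validate_profile_matrix <- function(x, tol = 1e-6) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("profile matrix has negative entries", call. = FALSE)
  off <- abs(rowSums(x) - 1)
  if (any(off > tol))
    stop("profile rows do not sum to 1 (max deviation ",
         format(max(off)), ")", call. = FALSE)
  invisible(x)
}

#' PCA of glycan profiles
#'
#' Centered (optionally unit-scaled) SVD-based principal component analysis.
#' The loadings expose which glycan species drive sample separation.
#'
#' @param x profile matrix (samples x species).
#' @param n_components number of components to return.
#' @param scale. scale species to unit variance first (default `FALSE`).
#' @return list with `scores` (samples x components), `loadings` (species x
#'   components, orthonormal), `variance_explained` (fractions, summing to
#'   <= 1).  A matrix with no variance yields all-zero scores and variance
#'   with a `glygolgi_degenerate_variance` warning.
#' @export
pca_profiles <- function(x, n_components = min(dim(x)) - 1L, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 samples and 2 species", call. = FALSE)
  n_components <- max(1L, min(n_components, ncol(x), nrow(x) - 1L))
  tot <- sum(apply(x, 2, var))
  if (tot == 0) {
    warning(structure(class = c("glygolgi_degenerate_variance", "warning",
                                "condition"),
                      list(message = "profile matrix has no variance",
                           call = sys.call())))
    return(list(scores = matrix(0, nrow(x), n_components),
                loadings = matrix(0, ncol(x), n_components,
                                  dimnames = list(colnames(x), NULL)),
                variance_explained = rep(0, n_components)))
  }
  sdev0 <- apply(x, 2, sd) == 0
  if (scale. && any(sdev0)) x <- x[, !sdev0, drop = FALSE]
  p <- prcomp(x, center = TRUE, scale. = scale.)
  ncomp <- min(n_components, ncol(p$rotation))
  list(scores = p$x[, seq_len(ncomp), drop = FALSE],
       loadings = p$rotation[, seq_len(ncomp), drop = FALSE],
       variance_explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(ncomp)])
}

# k-means++ seeding (squared-distance-proportional center choice); base R's
# kmeans only offers random initialisation.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1L, prob = probs), ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

#' k-means clustering of glycan profiles
#'
#' Lloyd iterations (via `stats::kmeans`) from k-means++ seedings; the best of
#' `n_restarts` runs by within-cluster sum of squares (WCSS) is returned.
#' Deterministic given `seed`.
#'
#' @param x profile matrix (samples x species).
#' @param k number of clusters (1..n_samples).
#' @param n_restarts independent seedings (default 10).
#' @param seed integer seed.
#' @param init_centers optional extra initial center matrices to try (used by
#'   [elbow_curve()] for warm starts).
#' @param clr apply the centered log-ratio transform first (default `FALSE`).
#' @return list with `labels` (1..k per sample), `k`, `wcss`, `centroids`
#'   (k x species), `sizes`.
#' @export
kmeans_profiles <- function(x, k, n_restarts = 10, seed = NULL,
                            init_centers = NULL, clr = FALSE) {
  x <- as.matrix(x)
  if (k < 1 || k > nrow(x)) stop("k must be in 1..n_samples", call. = FALSE)
  if (clr) {
    lx <- log(pmax(x, 1e-12))
    x <- lx - rowMeans(lx)
  }
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  run_once <- function(centers) {
    centers <- unique(centers)
    if (nrow(centers) < k) return(NULL)
    tryCatch(kmeans(x, centers = centers, iter.max = 100,
                    algorithm = "Lloyd"),
             error = function(e) NULL, warning = function(w) {
               suppressWarnings(kmeans(x, centers = centers, iter.max = 200,
                                       algorithm = "Lloyd"))
             })
  }
  fits <- list()
  for (r in seq_len(n_restarts))
    fits <- c(fits, list(run_once(kmeanspp_centers(x, k))))
  for (ic in init_centers %||% list()) fits <- c(fits, list(run_once(ic)))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("k-means failed for k = ", k, call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "tot.withinss"))]]
  list(labels = best$cluster, k = as.integer(k), wcss = best$tot.withinss,
       centroids = best$centers, sizes = best$size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' WCSS elbow curve over candidate cluster counts
#'
#' Runs [kmeans_profiles()] for k = 1..`k_max`; each k is additionally
#' warm-started from the previous solution (its centroids plus the sample
#' farthest from its centroid as the new center), which makes the curve
#' non-increasing in k.
#'
#' @inheritParams kmeans_profiles
#' @param k_max largest k (<= n_samples).
#' @return data.frame with columns `k`, `wcss`.
#' @export
elbow_curve <- function(x, k_max, n_restarts = 10, seed = NULL, clr = FALSE) {
  x <- as.matrix(x)
  if (k_max > nrow(x)) stop("k_max exceeds the sample count", call. = FALSE)
  wcss <- numeric(k_max)
  prev <- NULL
  for (k in seq_len(k_max)) {
    warm <- NULL
    if (!is.null(prev)) {
      xm <- if (clr) { lx <- log(pmax(x, 1e-12)); lx - rowMeans(lx) } else x
      resid <- rowSums((xm - prev$centroids[prev$labels, , drop = FALSE])^2)
      warm <- list(rbind(prev$centroids, xm[which.max(resid), ]))
    }
    fit <- kmeans_profiles(x, k, n_restarts = n_restarts,
                           seed = if (is.null(seed)) NULL
                                  else derive_seed(seed, paste0("k", k)),
                           init_centers = warm, clr = clr)
    wcss[k] <- fit$wcss
    prev <- fit
  }
  data.frame(k = seq_len(k_max), wcss = wcss)
}

#' Elbow heuristic: k with the largest relative WCSS drop
#'
#' @param elbow data.frame from [elbow_curve()].
#' @return the selected k (an integer >= 2).
#' @export
best_elbow_k <- function(elbow) {
  stopifnot(nrow(elbow) >= 2)
  drop_rel <- (head(elbow$wcss, -1) - elbow$wcss[-1]) /
    pmax(head(elbow$wcss, -1), .Machine$double.eps)
  elbow$k[which.max(drop_rel) + 1L]
}

#' Characterize clusters by their dominant glycans
#'
#' Reports, per cluster, the centroid profile and its dominant species, plus
#' the species with the largest between-cluster centroid spread; with a PCA
#' result attached, the top-loading species are listed as well.  Clusters are
#' named after their dominant glycan (e.g. Man5 vs G0F), matching how glycan
#' clusters are labelled in practice.
#'
#' @param assignment result of [kmeans_profiles()].
#' @param x the profile matrix that was clustered.
#' @param pca optional result of [pca_profiles()] on `x`.
#' @param diff_threshold minimum centroid difference for a species to be
#'   reported as discriminating (default 0.05).
#' @param n_top number of top-loading species to list.
#' @return list with `clusters` (data.frame: cluster, name, size, dominant
#'   species and fraction), `discriminating` (species above threshold),
#'   `top_loadings`, `empty` (flagged empty clusters).
#' @export
characterize_clusters <- function(assignment, x, pca = NULL,
                                  diff_threshold = 0.05, n_top = 3L) {
  x <- as.matrix(x)
  k <- assignment$k
  cent <- matrix(NA_real_, k, ncol(x),
                 dimnames = list(NULL, colnames(x)))
  sizes <- integer(k)
  for (j in seq_len(k)) {
    rows <- assignment$labels == j
    sizes[j] <- sum(rows)
    if (sizes[j] > 0) cent[j, ] <- colMeans(x[rows, , drop = FALSE])
  }
  empty <- which(sizes == 0)
  dom <- apply(cent, 1, function(r) colnames(x)[which.max(r)])
  spread <- apply(cent, 2, function(col) diff(range(col, na.rm = TRUE)))
  disc <- sort(spread[spread > diff_threshold], decreasing = TRUE)
  top_load <- NULL
  if (!is.null(pca)) {
    l1 <- pca$loadings[, 1]
    top_load <- names(sort(abs(l1), decreasing = TRUE))[seq_len(min(n_top,
                                                                    length(l1)))]
  }
  list(clusters = data.frame(cluster = seq_len(k), name = dom, size = sizes,
                             dominant_fraction = cent[cbind(seq_len(k),
                               max.col(cent, ties.method = "first"))]),
       centroids = cent,
       discriminating = disc,
       top_loadings = top_load,
       empty = empty)
}
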