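# Predicting glycan-profile clusters from glycogene expression at three
# culture time points, via a multi-block sparse PLS discriminant model
# (sGCCA-style: power iterations on design-weighted covariances with
# hard-threshold sparsity), 10-fold cross-validation, rank-based AUC, and
# >= 7/10 stability selection of predictive genes.

#' Subset an expression block to a gene panel
#'
#' @param expression samples x genes numeric matrix.
#' @param panel character vector of gene identifiers (order preserved).
#' @return the column subset, in panel order; genes absent from the block are
#'   reported in a warning, never silently dropped.  Zero overlap is an error.
#' @export
filter_gene_panel <- function(expression, panel) {
  if (length(panel) == 0) stop("empty gene panel", call. = FALSE)
  present <- panel[panel %in% colnames(expression)]
  missing <- setdiff(panel, present)
  if (length(present) == 0)
    stop("no panel gene found in the expression block", call. = FALSE)
  if (length(missing))
    warning("panel genes absent from the block: ",
            paste(missing, collapse = ", "), call. = FALSE)
  expression[, present, drop = FALSE]
}

std_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

std_apply <- function(x, st) sweep(sweep(x, 2, st$center), 2, st$scale, "/")

# Retain the `keep` largest-|w| entries, zero the rest, renormalize to unit
# norm.  Ties broken by first occurrence for determinism.
hard_threshold <- function(w, keep) {
  keep <- min(keep, length(w))
  ord <- order(abs(w), decreasing = TRUE)
  w[-ord[seq_len(keep)]] <- 0
  n <- sqrt(sum(w^2))
  if (n > 0) w / n else w
}

#' Sparse PLS of two blocks
#'
#' Iterative (NIPALS-style) sparse partial least squares: per component, a
#' power iteration estimates the loading pair maximising the covariance
#' between block scores; sparsity is imposed by retaining the `keepX`/`keepY`
#' largest-weight features and renormalising; both blocks are then deflated
#' on their own scores (canonical mode).
#'
#' @param block_X,block_Y samples x features matrices with aligned rows.
#' @param n_components number of latent components.
#' @param keepX,keepY number of features retained per component (scalar or
#'   per-component vector; default all).
#' @param max_iter,tol convergence controls (500, 1e-6); non-convergence is
#'   flagged, not fatal.
#' @param center,scale standardization of both blocks (defaults `TRUE`).
#' @return list with `scores_X`, `scores_Y` (samples x components),
#'   `loadings_X`, `loadings_Y`, and `converged` per component.
#' @export
spls_pair <- function(block_X, block_Y, n_components = 2,
                      keepX = ncol(block_X), keepY = ncol(block_Y),
                      max_iter = 500, tol = 1e-6,
                      center = TRUE, scale = TRUE) {
  X <- as.matrix(block_X); Y <- as.matrix(block_Y)
  if (nrow(X) != nrow(Y)) stop("blocks must have aligned samples", call. = FALSE)
  if (max(keepX) > ncol(X) || max(keepY) > ncol(Y))
    stop("keep counts exceed feature counts", call. = FALSE)
  keepX <- rep_len(keepX, n_components)
  keepY <- rep_len(keepY, n_components)
  if (center || scale) {
    stx <- std_fit(X); sty <- std_fit(Y)
    if (!scale) { stx$scale[] <- 1; sty$scale[] <- 1 }
    X <- std_apply(X, stx); Y <- std_apply(Y, sty)
  }
  p <- ncol(X); q <- ncol(Y); n <- nrow(X)
  TX <- matrix(NA_real_, n, n_components)
  TY <- matrix(NA_real_, n, n_components)
  U <- matrix(0, p, n_components, dimnames = list(colnames(X), NULL))
  V <- matrix(0, q, n_components, dimnames = list(colnames(Y), NULL))
  converged <- logical(n_components)
  for (h in seq_len(n_components)) {
    M <- crossprod(X, Y)
    sv <- svd(M, nu = 1, nv = 1)
    u <- hard_threshold(sv$u[, 1], keepX[h])
    v <- hard_threshold(sv$v[, 1], keepY[h])
    for (it in seq_len(max_iter)) {
      u_new <- hard_threshold(as.numeric(M %*% v), keepX[h])
      v_new <- hard_threshold(as.numeric(crossprod(M, u_new)), keepY[h])
      delta <- max(abs(u_new - u), abs(v_new - v))
      u <- u_new; v <- v_new
      if (delta < tol) { converged[h] <- TRUE; break }
    }
    if (!converged[h])
      warning("sPLS component ", h, " did not converge in ", max_iter,
              " iterations; partial result returned", call. = FALSE)
    tx <- as.numeric(X %*% u); ty <- as.numeric(Y %*% v)
    TX[, h] <- tx; TY[, h] <- ty
    U[, h] <- u; V[, h] <- v
    if (sum(tx^2) > 0) X <- X - tx %*% crossprod(tx, X) / sum(tx^2)
    if (sum(ty^2) > 0) Y <- Y - ty %*% crossprod(ty, Y) / sum(ty^2)
  }
  list(scores_X = TX, scores_Y = TY, loadings_X = U, loadings_Y = V,
       converged = converged)
}

#' Build a block design matrix from pairwise component correlations
#'
#' For each block pair, a one-component sPLS is fitted and the design weight
#' set to 1 when the absolute score correlation reaches `threshold`, else to
#' `low` — the correlations between pairwise components informing how
#' strongly blocks are linked in the multi-block model.
#'
#' @param blocks named list of samples x features matrices.
#' @param threshold correlation cut for a strong link (default 0.8).
#' @param low weight for weakly correlated pairs (default 0.1).
#' @return symmetric blocks x blocks matrix with zero diagonal.
#' @export
build_design <- function(blocks, threshold = 0.8, low = 0.1) {
  if (length(blocks) < 2) stop("need at least 2 blocks", call. = FALSE)
  B <- length(blocks)
  D <- matrix(0, B, B, dimnames = list(names(blocks), names(blocks)))
  for (i in seq_len(B - 1)) for (j in (i + 1):B) {
    fit <- spls_pair(blocks[[i]], blocks[[j]], n_components = 1)
    r <- suppressWarnings(cor(fit$scores_X[, 1], fit$scores_Y[, 1]))
    w <- if (!is.na(r) && abs(r) >= threshold) 1 else low
    D[i, j] <- D[j, i] <- w
  }
  D
}

class_indicator <- function(y) {
  y <- factor(y)
  Y <- matrix(0, length(y), nlevels(y),
              dimnames = list(NULL, levels(y)))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

#' Fit a multi-block sparse PLS discriminant model
#'
#' sGCCA-style estimation against a class-indicator block: per component,
#' block loadings are found by power iterations maximising the sum of
#' design-weighted covariances between block scores, where each expression
#' block additionally links to the class block with weight 1; sparsity per
#' block is imposed by hard-thresholding to `keepX` features; each block is
#' deflated on its own score.  Class centroids are computed on the block
#' scores averaged across expression blocks.
#'
#' @param blocks named list of samples x genes matrices (aligned rows).
#' @param y class labels (factor, >= 2 levels).
#' @param design symmetric block design matrix (see [build_design()]); `NULL`
#'   for a fully connected design of 1s.
#' @param n_components number of components (default 2).
#' @param keepX named list (per block) of per-component retained-feature
#'   counts; scalars are recycled.  Default: all features.
#' @param max_iter,tol convergence controls.
#' @return a `block_splsda` model.
#' @export
fit_block_splsda <- function(blocks, y, design = NULL, n_components = 2,
                             keepX = NULL, max_iter = 500, tol = 1e-6) {
  y <- factor(y)
  if (nlevels(y) < 2) stop("need >= 2 classes", call. = FALSE)
  B <- length(blocks)
  bn <- names(blocks)
  if (is.null(design)) {
    design <- matrix(1, B, B, dimnames = list(bn, bn)); diag(design) <- 0
  }
  if (is.null(keepX)) keepX <- lapply(blocks, function(b) ncol(b))
  keepX <- lapply(bn, function(b) rep_len(keepX[[b]], n_components))
  names(keepX) <- bn
  for (b in bn)
    if (max(keepX[[b]]) > ncol(blocks[[b]]))
      stop("keepX exceeds the width of block ", b, call. = FALSE)
  sts <- lapply(blocks, std_fit)
  Xs <- mapply(std_apply, blocks, sts, SIMPLIFY = FALSE)
  Yc <- scale(class_indicator(y))
  ylevels <- levels(y)
  n <- nrow(Yc)
  # augmented design: every expression block links to the class block
  Dfull <- rbind(cbind(design, rep(1, B)), c(rep(1, B), 0))
  loadings <- lapply(bn, function(b)
    matrix(0, ncol(blocks[[b]]), n_components,
           dimnames = list(colnames(blocks[[b]]), NULL)))
  names(loadings) <- bn
  defl <- lapply(bn, function(b) vector("list", n_components))
  names(defl) <- bn
  scores <- lapply(bn, function(b) matrix(NA_real_, n, n_components))
  names(scores) <- bn
  W <- c(Xs, list(.Y = Yc))
  for (h in seq_len(n_components)) {
    a <- lapply(seq_len(B + 1), function(bi) {
      Xb <- W[[bi]]
      sv <- svd(crossprod(Xb, W[[B + 1]]), nu = 1, nv = 0)
      v <- sv$u[, 1]
      v / sqrt(sum(v^2))
    })
    t_s <- lapply(seq_len(B + 1), function(bi) as.numeric(W[[bi]] %*% a[[bi]]))
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (bi in seq_len(B + 1)) {
        target <- Reduce(`+`, lapply(seq_len(B + 1), function(k)
          if (k == bi) 0 else Dfull[bi, k] * t_s[[k]]))
        w <- as.numeric(crossprod(W[[bi]], target))
        keep <- if (bi <= B) keepX[[bi]][h] else length(w)
        w <- hard_threshold(w, keep)
        delta <- max(delta, max(abs(w - a[[bi]])))
        a[[bi]] <- w
        t_s[[bi]] <- as.numeric(W[[bi]] %*% w)
      }
      if (delta < tol) break
    }
    for (bi in seq_len(B)) {
      b <- bn[bi]
      loadings[[b]][, h] <- a[[bi]]
      scores[[b]][, h] <- t_s[[bi]]
      tb <- t_s[[bi]]
      pb <- if (sum(tb^2) > 0) as.numeric(crossprod(W[[bi]], tb)) / sum(tb^2)
            else rep(0, ncol(W[[bi]]))
      defl[[b]][[h]] <- pb
      W[[bi]] <- W[[bi]] - tb %*% t(pb)
    }
    ty <- t_s[[B + 1]]
    if (sum(ty^2) > 0)
      W[[B + 1]] <- W[[B + 1]] - ty %*% crossprod(ty, W[[B + 1]]) / sum(ty^2)
  }
  avg <- Reduce(`+`, scores) / B
  centroids_of <- function(S) {
    m <- do.call(rbind, lapply(ylevels, function(cl)
      colMeans(S[y == cl, , drop = FALSE])))
    rownames(m) <- ylevels
    m
  }
  centroids <- centroids_of(avg)
  block_centroids <- lapply(scores, centroids_of)
  structure(list(loadings = loadings, deflation = defl, std = sts,
                 scores = scores, avg_scores = avg,
                 centroids = centroids, block_centroids = block_centroids,
                 design = design, keepX = keepX,
                 n_components = n_components, levels = ylevels, y = y),
            class = "block_splsda")
}

project_block <- function(model, block_name, newx) {
  st <- model$std[[block_name]]
  genes <- names(st$center)
  missing <- setdiff(genes, colnames(newx))
  if (length(missing))
    stop("test block ", block_name, " lacks model features: ",
         paste(missing, collapse = ", "), call. = FALSE)
  Xb <- std_apply(newx[, genes, drop = FALSE], st)
  H <- model$n_components
  Tt <- matrix(NA_real_, nrow(Xb), H)
  for (h in seq_len(H)) {
    t_h <- as.numeric(Xb %*% model$loadings[[block_name]][, h])
    Tt[, h] <- t_h
    Xb <- Xb - t_h %*% t(model$deflation[[block_name]][[h]])
  }
  Tt
}

#' Predict class membership for new samples
#'
#' Projects each test block through the model's loadings (replaying the
#' training deflation), averages block scores, and assigns each sample to the
#' nearest class centroid.  Per-class scores (negative distances, overall and
#' per block) are exposed for ROC analysis.
#'
#' @param model a `block_splsda` model.
#' @param newblocks named list of samples x genes matrices with the model's
#'   features.
#' @return list with `predicted` (factor), `class_scores` (samples x
#'   classes), `block_class_scores`, `block_scores`.
#' @export
predict_classes <- function(model, newblocks) {
  bn <- names(model$loadings)
  Ts <- lapply(bn, function(b) project_block(model, b, newblocks[[b]]))
  names(Ts) <- bn
  avg <- Reduce(`+`, Ts) / length(Ts)
  dist_to <- function(S, cent) {
    vapply(seq_len(nrow(cent)), function(ci)
      rowSums(sweep(S, 2, cent[ci, ])^2), numeric(nrow(S)))
  }
  sc <- -sqrt(matrix(dist_to(avg, model$centroids), nrow = nrow(avg)))
  colnames(sc) <- model$levels
  block_sc <- lapply(bn, function(b) {
    m <- -sqrt(matrix(dist_to(Ts[[b]], model$block_centroids[[b]]),
                      nrow = nrow(avg)))
    colnames(m) <- model$levels
    m
  })
  names(block_sc) <- bn
  pred <- factor(model$levels[max.col(sc, ties.method = "first")],
                 levels = model$levels)
  list(predicted = pred, class_scores = sc,
       block_class_scores = block_sc, block_scores = Ts)
}

#' Rank-based ROC AUC
#'
#' The Mann-Whitney formulation: the probability that a random positive
#' outranks a random negative, with ties handled by midranks.  1 means
#' perfect separation of the class, 0.5 chance-level.
#'
#' @param scores numeric score per sample (larger = more class-like).
#' @param labels class labels.
#' @param class_id the positive class (one-vs-rest).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, class_id) {
  pos <- labels == class_id
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0)
    stop("AUC undefined: only one class present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

# Stratified folds at the biological-sample level: duplicate measurements of
# one sample always share a fold (leakage guard).
make_folds <- function(y, n_folds, seed, group = NULL) {
  if (is.null(group)) group <- seq_along(y)
  old <- get_rng_state(); on.exit(set_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  ug <- unique(group)
  gclass <- vapply(ug, function(g) as.character(y[group == g][1]), character(1))
  if (any(table(gclass) < n_folds))
    warning("a class has fewer samples than folds; ",
            "using stratified round-robin assignment", call. = FALSE)
  gfold <- integer(length(ug)); names(gfold) <- as.character(ug)
  for (cl in unique(gclass)) {
    idx <- sample(which(gclass == cl))
    gfold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  gfold[match(as.character(group), as.character(ug))]
}

#' Cross-validated multi-block sPLS-DA
#'
#' Stratified 10-fold cross-validation (duplicates of a biological sample are
#' kept in one fold): per fold the model is refitted on the training portion
#' (standardization fitted within the fold, leakage-safe), the selected genes
#' per block recorded, and the held-out samples scored.  AUCs are one-vs-rest
#' per class, overall and per block, on the pooled held-out scores.
#'
#' @inheritParams fit_block_splsda
#' @param n_folds number of folds (default 10).
#' @param seed fold/fit seed; identical seeds give identical folds,
#'   selections and AUCs.
#' @param group optional biological-sample id per row.
#' @return a `cv_report`: `selection_freq` and `selection_count` per block,
#'   `fold_selected`, `fold_loadings`, `class_auc`, `block_class_auc`,
#'   `mean_auc`, `pooled_scores`, `pooled_labels`, `class_means`, `folds`.
#' @export
cv_block_splsda <- function(blocks, y, design = NULL, n_components = 2,
                            keepX = NULL, n_folds = 10, seed = 1,
                            group = NULL) {
  y <- factor(y)
  folds <- make_folds(y, n_folds, seed, group)
  bn <- names(blocks)
  n <- length(y)
  sel_count <- lapply(blocks, function(b)
    setNames(numeric(ncol(b)), colnames(b)))
  load_sum <- sel_count
  fold_selected <- vector("list", n_folds)
  pooled <- matrix(NA_real_, n, nlevels(y), dimnames = list(NULL, levels(y)))
  pooled_block <- lapply(bn, function(b) pooled)
  names(pooled_block) <- bn
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    if (!any(te)) next
    fit <- fit_block_splsda(lapply(blocks, function(b) b[tr, , drop = FALSE]),
                            y[tr], design = design,
                            n_components = n_components, keepX = keepX)
    sel_f <- lapply(bn, function(b) {
      L <- fit$loadings[[b]]
      rownames(L)[rowSums(abs(L)) > 0]
    })
    names(sel_f) <- bn
    fold_selected[[f]] <- sel_f
    for (b in bn) {
      sel_count[[b]][sel_f[[b]]] <- sel_count[[b]][sel_f[[b]]] + 1
      load_sum[[b]] <- load_sum[[b]] + rowSums(abs(fit$loadings[[b]]))
    }
    pr <- predict_classes(fit, lapply(blocks, function(b) b[te, , drop = FALSE]))
    pooled[te, ] <- pr$class_scores
    for (b in bn) pooled_block[[b]][te, ] <- pr$block_class_scores[[b]]
  }
  auc_of <- function(scores)
    vapply(levels(y), function(cl)
      tryCatch(roc_auc(scores[, cl], y, cl), error = function(e) NA_real_),
      numeric(1))
  class_auc <- auc_of(pooled)
  block_class_auc <- vapply(bn, function(b) auc_of(pooled_block[[b]]),
                            numeric(nlevels(y)))
  class_means <- lapply(bn, function(b) {
    Z <- scale(blocks[[b]])
    t(vapply(levels(y), function(cl)
      colMeans(Z[y == cl, , drop = FALSE]), numeric(ncol(Z))))
  })
  names(class_means) <- bn
  structure(list(selection_count = sel_count,
                 selection_freq = lapply(sel_count, function(s) s / n_folds),
                 mean_abs_loading = lapply(bn, function(b)
                   load_sum[[b]] / pmax(sel_count[[b]], 1)),
                 fold_selected = fold_selected,
                 class_auc = class_auc,
                 block_class_auc = block_class_auc,
                 mean_auc = mean(class_auc, na.rm = TRUE),
                 pooled_scores = pooled, pooled_labels = y,
                 class_means = class_means,
                 folds = folds, n_folds = n_folds),
            class = "cv_report")
}

#' Tune component count and sparsity by nested cross-validation
#'
#' Grid search over `n_components` and a shared per-block `keepX`, scored by
#' the cross-validated balanced error rate; among configurations within one
#' standard error of the best, the sparsest (then simplest) is chosen.
#'
#' @inheritParams cv_block_splsda
#' @param grid_ncomp candidate component counts.
#' @param grid_keepX candidate retained-feature counts (applied to every
#'   block and component).
#' @return list with `n_components`, `keepX`, and the scored `grid`.
#' @export
tune_model <- function(blocks, y, design = NULL, grid_ncomp = 1:2,
                       grid_keepX = c(5, 10, 20), n_folds = 10, seed = 1,
                       group = NULL) {
  if (length(grid_ncomp) == 0 || length(grid_keepX) == 0)
    stop("empty tuning grid", call. = FALSE)
  grid_keepX <- grid_keepX[grid_keepX <= min(vapply(blocks, ncol, integer(1)))]
  y <- factor(y)
  res <- expand.grid(n_components = grid_ncomp, keepX = grid_keepX)
  res$ber <- NA_real_; res$ber_se <- NA_real_
  for (i in seq_len(nrow(res))) {
    cv <- cv_block_splsda(blocks, y, design,
                          n_components = res$n_components[i],
                          keepX = lapply(blocks, function(b) res$keepX[i]),
                          n_folds = n_folds, seed = seed, group = group)
    pred <- factor(colnames(cv$pooled_scores)[
      max.col(cv$pooled_scores, ties.method = "first")], levels = levels(y))
    per_class_err <- vapply(levels(y), function(cl)
      mean(pred[y == cl] != cl), numeric(1))
    res$ber[i] <- mean(per_class_err)
    fold_ber <- vapply(seq_len(cv$n_folds), function(f) {
      te <- cv$folds == f
      if (!any(te)) return(NA_real_)
      mean(pred[te] != y[te])
    }, numeric(1))
    res$ber_se[i] <- sd(fold_ber, na.rm = TRUE) /
      sqrt(sum(!is.na(fold_ber)))
  }
  best <- which.min(res$ber)
  cut <- res$ber[best] + res$ber_se[best]
  cand <- res[res$ber <= cut, , drop = FALSE]
  cand <- cand[order(cand$keepX, cand$n_components), , drop = FALSE]
  list(n_components = cand$n_components[1], keepX = cand$keepX[1], grid = res)
}

#' Stability selection of predictive genes
#'
#' A gene has strong predictive power when it is selected in at least
#' `min_folds` of the 10 cross-validation folds.  Each stable gene is
#' annotated with the class in which it is elevated (largest standardized
#' class mean).
#'
#' @param cv_report a `cv_report` from [cv_block_splsda()].
#' @param min_folds selection-count threshold (default 7).
#' @return data.frame: `gene`, `block`, `class`, `frequency`,
#'   `mean_abs_loading`, sorted by block then decreasing frequency.
#' @export
stability_select <- function(cv_report, min_folds = 7) {
  bn <- names(cv_report$selection_count)
  out <- lapply(seq_along(bn), function(bi) {
    b <- bn[bi]
    cnt <- cv_report$selection_count[[b]]
    genes <- names(cnt)[cnt >= min_folds]
    if (!length(genes)) return(NULL)
    cm <- cv_report$class_means[[b]]
    cls <- rownames(cm)[apply(cm[, genes, drop = FALSE], 2, which.max)]
    data.frame(gene = genes, block = b, class = cls,
               frequency = cnt[genes] / cv_report$n_folds,
               mean_abs_loading = cv_report$mean_abs_loading[[bi]][genes],
               row.names = NULL)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(gene = character(0), block = character(0),
                      class = character(0), frequency = numeric(0),
                      mean_abs_loading = numeric(0)))
  out[order(out$block, -out$frequency), , drop = FALSE]
}
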