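# Independent oracles and shared fixtures used across the suite.

# Exact terminal distribution of the per-glycan continuous-time Markov chain,
# by matrix exponentials of the cisterna-wise generators.  Independent of the
# event-loop simulator: only the enumerated transition structure is shared.
ctmc_terminal_distribution <- function(engine, params) {
  tab <- engine$table
  n <- engine$n_states
  tr <- tab$transitions
  K <- length(params$residence_time)
  rates <- glygolgi:::rates_matrix(engine, params)
  p <- numeric(n)
  p[engine$start_index] <- 1
  for (c in seq_len(K)) {
    Q <- matrix(0, n, n)
    for (i in seq_len(nrow(tr)))
      Q[tr$from[i], tr$to[i]] <- Q[tr$from[i], tr$to[i]] + rates[tr$rule[i], c]
    diag(Q) <- diag(Q) - rowSums(Q)
    P <- as.matrix(Matrix::expm(Q * params$residence_time[c]))
    p <- as.numeric(p %*% P)
  }
  resolved <- numeric(n)
  for (i in seq_len(n))
    resolved[tab$resolve_to[i]] <- resolved[tab$resolve_to[i]] + p[i]
  agg <- tapply(resolved, tab$names, sum)
  out <- as.numeric(agg)
  names(out) <- names(agg)
  out[out > 0 | TRUE]
}

total_variation <- function(p, q) {
  al <- glygolgi:::align_profiles(p, q)
  sum(abs(al$a - al$b)) / 2
}

# Trapezoidal ROC integration, the cross-check for the rank-based AUC.
trapezoid_auc <- function(scores, labels, class_id) {
  pos <- labels == class_id
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[pos] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(scores[!pos] >= t), numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# Rule set restricted to a linear trimming chain (Man9 -> Man5).
man1_only_rules <- function() Filter(function(r) r$enzyme == "Man1",
                                     default_rules())

# Small separable two-class expression fixture: `shift` added to the first
# `n_signal` genes of class "b" in every block.
separable_blockset <- function(n_per_class = 12, p = 20, n_signal = 4,
                               shift = 3, n_blocks = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    y <- factor(rep(c("a", "b"), each = n_per_class))
    blocks <- lapply(seq_len(n_blocks), function(b) {
      m <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, sprintf("g%02d", seq_len(p))))
      m[y == "b", seq_len(n_signal)] <- m[y == "b", seq_len(n_signal)] + shift
      m
    })
    names(blocks) <- paste0("block", seq_len(n_blocks))
    list(blocks = blocks, y = y)
  })
}
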