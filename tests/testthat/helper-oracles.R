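# Independent brute-force oracles used to check the package implementation.
# Everything here is written from the definitions, deliberately avoiding the
# package's own code paths (plain loops, no shared helpers).

# recount a rule's metrics molecule by molecule
brute_metrics <- function(dataset, desc_df, Q, x_beta = 110, l_beta = 20) {
  ids <- dataset$ids
  covered <- character(0)
  for (id in ids) {
    ok <- TRUE
    if (nrow(desc_df)) {
      for (k in seq_len(nrow(desc_df))) {
        v <- dataset$values[id, desc_df$descriptor[k]]
        if (is.na(v) || v < desc_df$lo[k] || v > desc_df$hi[k]) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) covered <- c(covered, id)
  }
  is_pos <- function(id) all(Q %in% dataset$labels[[id]])
  tp <- sum(vapply(covered, is_pos, TRUE))
  support_Q <- sum(vapply(ids, is_pos, TRUE))
  P <- if (length(covered)) tp / length(covered) else 0
  R <- if (support_Q) tp / support_Q else 0
  beta <- (0.5 * (1 + tanh((support_Q - x_beta) / l_beta)))^2
  list(coverage = covered, support_D = length(covered), positives = tp,
       support_Q = support_Q, precision = P, recall = R,
       f1 = if (P + R > 0) 2 * P * R / (P + R) else 0,
       f_beta = if (beta * P + R > 0) (1 + beta) * P * R / (beta * P + R) else 0)
}

# exhaustive search over every interval description on the observed-value
# grid (including "no condition" per descriptor); returns the best feasible
# f_beta and the corresponding coverage sets
oracle_best <- function(dataset, Q, min_supp = 1, max_supp = Inf,
                        max_properties = Inf, x_beta = 110, l_beta = 20) {
  vals <- dataset$values
  p <- ncol(vals)
  pos <- vapply(dataset$ids, function(id) all(Q %in% dataset$labels[[id]]),
                TRUE)
  support_Q <- sum(pos)
  beta <- (0.5 * (1 + tanh((support_Q - x_beta) / l_beta)))^2
  intervals <- lapply(seq_len(p), function(j) {
    u <- sort(unique(vals[, j][!is.na(vals[, j])]))
    out <- list(NULL)
    for (a in seq_along(u))
      for (b in a:length(u))
        out[[length(out) + 1L]] <- c(u[a], u[b])
    out
  })
  best <- -Inf
  best_covs <- list()
  n <- nrow(vals)
  rec <- function(j, keep, nconds) {
    if (j > p) {
      sD <- sum(keep)
      if (sD < min_supp || sD > max_supp || nconds > max_properties) return()
      tp <- sum(pos & keep)
      P <- if (sD) tp / sD else 0
      R <- if (support_Q) tp / support_Q else 0
      fb <- if (beta * P + R > 0) (1 + beta) * P * R / (beta * P + R) else 0
      if (fb > best + 1e-12) {
        best <<- fb
        best_covs <<- list(dataset$ids[keep])
      } else if (abs(fb - best) <= 1e-12) {
        best_covs[[length(best_covs) + 1L]] <<- dataset$ids[keep]
      }
      return()
    }
    for (iv in intervals[[j]]) {
      if (is.null(iv)) rec(j + 1L, keep, nconds)
      else {
        v <- vals[, j]
        rec(j + 1L, keep & !is.na(v) & v >= iv[1] & v <= iv[2], nconds + 1L)
      }
    }
  }
  rec(1L, rep(TRUE, n), 0L)
  list(f_beta = best, coverages = best_covs)
}

# random small annotated dataset for property tests
random_dataset <- function(n = 8, p = 3, n_qual = 3, seed = 1) {
  set.seed(seed)
  vals <- matrix(round(stats::runif(n * p), 2), n, p,
                 dimnames = list(as.character(seq_len(n)),
                                 paste0("x", seq_len(p))))
  quals <- paste0("q", seq_len(n_qual))
  labels <- lapply(seq_len(n), function(i)
    sample(quals, 1 + stats::rbinom(1, n_qual - 1, 0.4)))
  names(labels) <- rownames(vals)
  odorant_dataset(vals, labels)
}

# exact null F distribution for tiny datasets: enumerate all M^X ordered
# draws with replacement
enumerate_null_F <- function(pos, X, support_Q, beta, recall_mode = "distinct") {
  M <- length(pos)
  grid <- as.matrix(expand.grid(rep(list(seq_len(M)), X)))
  apply(grid, 1, function(draw) {
    n_match <- sum(pos[draw])
    P <- n_match / X
    R <- if (recall_mode == "distinct")
      min(sum(pos[unique(draw)]) / support_Q, 1)
    else min(n_match / support_Q, 1)
    if (beta * P + R > 0) (1 + beta) * P * R / (beta * P + R) else 0
  })
}
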