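#' Bootstrap confidence-interval significance of a ruleset's F-measure
#'
#' Tests whether the F-measure of a selected ruleset for a quality exceeds
#' what same-size random molecule sets achieve. With X the size of the
#' ruleset's union coverage, `n_resamples` sets of X molecules are drawn
#' uniformly with replacement from the whole dataset; each resample's
#' F-measure is computed for the target quality, and the empirical
#' two-sided confidence interval at `ci_level` is formed from the resampled
#' values. The ruleset is significant when its observed F lies above the
#' upper CI bound (one-sided, as the observed value must beat chance).
#'
#' Per resample, precision counts every draw matching the quality (a
#' molecule drawn twice counts twice) over X; recall counts distinct drawn
#' molecules matching the quality over the quality's support, capped at 1
#' (`recall_mode = "multiset"` counts duplicates instead). The F-measure is
#' the same adaptive F-beta used in mining by default, or F1.
#'
#' @param dataset an [odorant_dataset()].
#' @param ruleset a `RuleCombination`, a `MiningRun`, a list of rules /
#'   rule entries, or a character vector of molecule ids (the coverage
#'   itself).
#' @param qualities the target quality set Q.
#' @param n_resamples number of bootstrap resamples (default 100000).
#' @param ci_level confidence level (default 0.99).
#' @param seed integer seed (required for reproducibility).
#' @param measure `"fbeta"` (default, adaptive) or `"f1"`.
#' @param x_beta,l_beta,beta_direction see [beta_weight()].
#' @param recall_mode `"distinct"` (default) or `"multiset"`.
#' @return list of class `BootstrapResult`: `quality`, `coverage_size_X`,
#'   `n_resamples`, `ci_level`, `ci_low`, `ci_high`, `observed_F`,
#'   `significant`, `seed`, `measure`.
#' @export
bootstrap_ci <- function(dataset, ruleset, qualities, n_resamples = 100000,
                         ci_level = 0.99, seed = 1L,
                         measure = c("fbeta", "f1"),
                         x_beta = 110, l_beta = 20,
                         beta_direction = "increasing",
                         recall_mode = c("distinct", "multiset")) {
  measure <- match.arg(measure)
  recall_mode <- match.arg(recall_mode)
  qualities <- sort(unique(as.character(qualities)))
  if (n_resamples < 100) warning("fewer than 100 resamples: CI is unreliable")
  pos <- positives_for(dataset, qualities)
  support_Q <- sum(pos)
  if (support_Q == 0) stop("quality set has zero support in the dataset")
  cov_ids <- ruleset_coverage(ruleset, dataset)
  if (!length(cov_ids)) stop("ruleset union coverage is empty")
  X <- length(cov_ids)
  M <- length(dataset$ids)
  beta <- if (measure == "fbeta")
    beta_weight(support_Q, x_beta, l_beta, beta_direction) else 1

  cov_idx <- match(cov_ids, dataset$ids)
  tp <- sum(pos[cov_idx])
  obs_P <- tp / X
  obs_R <- tp / support_Q
  observed_F <- f_beta_measure(obs_P, obs_R, beta)

  set.seed(seed)
  Fs <- resample_F(pos, M, X, n_resamples, support_Q, beta, recall_mode)
  alpha <- (1 - ci_level) / 2
  ci <- stats::quantile(Fs, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(quality = qualities, coverage_size_X = X,
                 n_resamples = as.integer(n_resamples),
                 ci_level = ci_level, ci_low = ci[1], ci_high = ci[2],
                 observed_F = observed_F,
                 significant = observed_F > ci[2],
                 seed = as.integer(seed), measure = measure),
            class = "BootstrapResult")
}

# vectorized null F distribution: B resamples of X uniform draws (with
# replacement) from M molecules; pos is the positive indicator.
# chunked so peak memory stays bounded.
resample_F <- function(pos, M, X, B, support_Q, beta, recall_mode) {
  Fs <- numeric(B)
  chunk <- max(1L, min(B, as.integer(ceiling(5e6 / X))))
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    ids <- sample.int(M, X * b, replace = TRUE)
    hit <- pos[ids]
    n_match <- .colSums(hit, X, b)
    P <- n_match / X
    if (recall_mode == "multiset") {
      R <- pmin(n_match / support_Q, 1)
    } else {
      col <- rep.int(seq_len(b), rep.int(X, b))
      key <- (col - 1) * M + ids
      key <- key[hit]
      u <- unique(key)
      n_distinct <- tabulate((u - 1L) %/% M + 1L, nbins = b)
      R <- pmin(n_distinct / support_Q, 1)
    }
    Fs[done + seq_len(b)] <- f_beta_measure(P, R, beta)
    done <- done + b
  }
  Fs
}

ruleset_coverage <- function(ruleset, dataset) {
  if (is.character(ruleset)) return(intersect(dataset$ids, ruleset))
  if (inherits(ruleset, "RuleCombination")) return(ruleset$union_coverage)
  if (inherits(ruleset, "MiningRun")) ruleset <- ruleset$rules
  if (inherits(ruleset, "SORule")) ruleset <- list(ruleset)
  rules <- lapply(ruleset, function(r) if (inherits(r, "SORule")) r else r$rule)
  idx <- sort(unique(unlist(lapply(rules, function(r)
    coverage_index(r$description, dataset)))))
  dataset$ids[idx]
}

#' @export
print.BootstrapResult <- function(x, ...) {
  cat(sprintf(
    "bootstrap %s for {%s}: observed F=%.4f, %d%% CI [%.4f, %.4f] (X=%d, B=%d) -> %s\n",
    x$measure, paste(x$quality, collapse = ", "), x$observed_F,
    round(100 * x$ci_level), x$ci_low, x$ci_high, x$coverage_size_X,
    x$n_resamples, if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Bootstrap significance for a batch of selected rulesets
#'
#' Runs [bootstrap_ci()] per quality with independent per-quality seeds
#' derived from a master seed. Per-quality errors are reported without
#' aborting the batch.
#'
#' @param selections list of `SelectionResult`s (the first best combination
#'   of each is tested) or a named list of rulesets keyed by quality.
#' @param dataset an [odorant_dataset()].
#' @param n_resamples,ci_level,measure,x_beta,l_beta,recall_mode passed to
#'   [bootstrap_ci()].
#' @param seed master seed; quality i uses `seed + i`.
#' @param path optional CSV output path.
#' @return data.frame with one row per quality.
#' @export
batch_significance <- function(selections, dataset, n_resamples = 100000,
                               ci_level = 0.99, seed = 1L,
                               measure = "fbeta", x_beta = 110, l_beta = 20,
                               recall_mode = "distinct", path = NULL) {
  rows <- list()
  for (i in seq_along(selections)) {
    s <- selections[[i]]
    if (inherits(s, "SelectionResult")) {
      if (!length(s$best)) next
      ruleset <- s$best[[1]]
      Q <- s$quality
    } else {
      ruleset <- s
      Q <- names(selections)[i]
    }
    res <- tryCatch(
      bootstrap_ci(dataset, ruleset, Q, n_resamples = n_resamples,
                   ci_level = ci_level, seed = seed + i, measure = measure,
                   x_beta = x_beta, l_beta = l_beta,
                   recall_mode = recall_mode),
      error = function(e) {
        warning("bootstrap for {", paste(Q, collapse = ","), "} failed: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      quality = paste(res$quality, collapse = ","),
      X = res$coverage_size_X, observed_F = res$observed_F,
      ci_low = res$ci_low, ci_high = res$ci_high,
      significant = res$significant, seed = res$seed,
      n_resamples = res$n_resamples, measure = res$measure,
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(quality = character(0), X = integer(0),
               observed_F = numeric(0), ci_low = numeric(0),
               ci_high = numeric(0), significant = logical(0),
               seed = integer(0), n_resamples = integer(0),
               measure = character(0))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
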