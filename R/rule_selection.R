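#' Metrics of a rule combination (disjunction of rules)
#'
#' A combination of up to twelve rules describes a quality by the union of
#' its members' coverages: a molecule is described iff it is covered by at
#' least one rule. Precision and recall are computed on that union with the
#' usual positive criterion (the molecule carries every quality of Q), the
#' error is `1 - precision`, and the distance is the Euclidean distance of
#' the `(error, recall)` point from the ideal `(0, 1)`.
#'
#' @param rules list of [so_rule()] objects (or entries with a `$rule`
#'   element), 1 to `max_rules` of them, all targeting `qualities`.
#' @param qualities the target quality set Q.
#' @param dataset an [odorant_dataset()].
#' @param source_min_supp optional `min_supp` the candidate rules came from
#'   (reporting only).
#' @param max_rules upper bound on combination size (default 12).
#' @return list of class `RuleCombination`: `quality`, `rules`,
#'   `union_coverage`, `precision`, `recall`, `error`, `distance`,
#'   `source_min_supp`, `flags`.
#' @export
combination_metrics <- function(rules, qualities, dataset,
                                source_min_supp = NA_integer_,
                                max_rules = 12) {
  rules <- lapply(rules, function(r) if (inherits(r, "SORule")) r else r$rule)
  if (!length(rules) || length(rules) > max_rules)
    stop("a combination holds between 1 and ", max_rules, " rules")
  covs <- lapply(rules, function(r) coverage_index(r$description, dataset))
  union_idx <- sort(unique(unlist(covs)))
  pos <- positives_for(dataset, qualities)
  support_Q <- sum(pos)
  flags <- character(0)
  if (!length(union_idx)) flags <- c(flags, "empty_coverage")
  tp <- sum(pos[union_idx])
  precision <- if (length(union_idx)) tp / length(union_idx) else 0
  recall <- if (support_Q > 0) tp / support_Q else {
    flags <- c(flags, "zero_support_Q"); 0
  }
  error <- 1 - precision
  structure(list(quality = sort(unique(as.character(qualities))),
                 rules = rules,
                 union_coverage = dataset$ids[union_idx],
                 precision = precision, recall = recall,
                 error = error,
                 distance = sqrt(error^2 + (1 - recall)^2),
                 source_min_supp = as.integer(source_min_supp),
                 flags = flags),
            class = "RuleCombination")
}

#' @export
print.RuleCombination <- function(x, ...) {
  cat(sprintf("%d rule(s) for {%s}: P=%.3f R=%.3f error=%.3f distance=%.3f\n",
              length(x$rules), paste(x$quality, collapse = ", "),
              x$precision, x$recall, x$error, x$distance))
  invisible(x)
}

#' Select the best rule combination for a quality
#'
#' Given candidate rules from one or more mining runs (typically one per
#' `min_supp` setting), selects the combination of up to `max_rules` rules
#' with minimal Euclidean distance to the ideal `(error 0, recall 1)` point.
#' Within each run, candidates are ranked by precision (descending) and the
#' nested prefixes of size 1..`max_rules` are evaluated; candidates from
#' different runs are not mixed within one combination. All ties at the
#' minimal distance (within `tol`) are kept. With `strategy = "exhaustive"`
#' and a candidate pool of at most `exhaustive_limit` rules, every non-empty
#' subset up to `max_rules` is searched instead (the oracle for the prefix
#' strategy on small pools).
#'
#' @param runs a `MiningRun`, a list of `MiningRun`s, or a list of rule-entry
#'   lists; names (or each run's config) supply `source_min_supp`.
#' @param qualities the target quality set; defaults to the first run's.
#' @param dataset an [odorant_dataset()].
#' @param max_rules maximum combination size (default 12).
#' @param strategy `"prefix"` (default) or `"exhaustive"`.
#' @param exhaustive_limit pool size cap for the exhaustive search.
#' @param tol tie tolerance on the distance.
#' @return list of class `SelectionResult`: `quality`, `best` (list of
#'   [combination_metrics()] ties), `distance`, `group`, `flags`.
#' @export
select_best <- function(runs, qualities = NULL, dataset, max_rules = 12,
                        strategy = c("prefix", "exhaustive"),
                        exhaustive_limit = 15, tol = 1e-12) {
  strategy <- match.arg(strategy)
  if (inherits(runs, "MiningRun")) runs <- list(runs)
  norm <- list()
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    if (inherits(run, "try-error")) next
    if (inherits(run, "MiningRun")) {
      if (is.null(qualities)) qualities <- run$target
      norm[[length(norm) + 1L]] <-
        list(rules = lapply(run$rules, `[[`, "rule"),
             min_supp = run$config$min_supp)
    } else {
      rl <- lapply(run, function(r) if (inherits(r, "SORule")) r else r$rule)
      nm <- names(runs)[i]
      ms <- if (is.null(nm) || is.na(nm) || !nzchar(nm)) NA_integer_
            else suppressWarnings(as.integer(nm))
      if (length(ms) != 1L) ms <- NA_integer_
      norm[[length(norm) + 1L]] <- list(rules = rl, min_supp = ms)
    }
  }
  if (is.null(qualities)) stop("qualities must be supplied")
  qualities <- sort(unique(as.character(qualities)))
  empty <- structure(list(quality = qualities, best = list(),
                          distance = NA_real_, group = NA_integer_,
                          flags = "no_candidates"),
                     class = "SelectionResult")
  if (!length(norm) || !sum(vapply(norm, function(r) length(r$rules), 0L)))
    return(empty)

  combos <- list()
  for (run in norm) {
    rules <- run$rules
    if (!length(rules)) next
    prec <- vapply(rules, function(r)
      evaluate_rule(r, dataset)$precision, 0)
    ord <- order(-prec)
    rules <- rules[ord]
    if (strategy == "exhaustive" && length(rules) <= exhaustive_limit) {
      n <- length(rules)
      for (size in seq_len(min(n, max_rules))) {
        idx_sets <- utils::combn(n, size, simplify = FALSE)
        for (ix in idx_sets)
          combos[[length(combos) + 1L]] <-
            combination_metrics(rules[ix], qualities, dataset,
                                source_min_supp = run$min_supp,
                                max_rules = max_rules)
      }
    } else {
      if (strategy == "exhaustive")
        message("pool of ", length(rules), " rules exceeds exhaustive_limit; ",
                "falling back to prefix search")
      for (size in seq_len(min(length(rules), max_rules)))
        combos[[length(combos) + 1L]] <-
          combination_metrics(rules[seq_len(size)], qualities, dataset,
                              source_min_supp = run$min_supp,
                              max_rules = max_rules)
    }
  }
  d <- vapply(combos, `[[`, 0, "distance")
  dmin <- min(d)
  best <- combos[d <= dmin + tol]
  structure(list(quality = qualities, best = best, distance = dmin,
                 group = classify_group(best[[1]]$error, best[[1]]$recall),
                 flags = character(0)),
            class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  if (!length(x$best)) {
    cat("SelectionResult for {", paste(x$quality, collapse = ", "),
        "}: no candidates\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("SelectionResult for {%s}: distance %.4f, group %d, %d tie(s)\n",
              paste(x$quality, collapse = ", "), x$distance, x$group,
              length(x$best)))
  invisible(x)
}

#' Classify a (error, recall) point into the four confidence groups
#'
#' Group 1: error < 0.5 and recall >= 0.5 (best described qualities);
#' group 2: error < 0.5 and recall < 0.5; group 3: error >= 0.5 and
#' recall >= 0.5; group 4: error >= 0.5 and recall < 0.5.
#'
#' @param error,recall numbers in \[0, 1\] (vectorized).
#' @return integer group in 1..4.
#' @export
classify_group <- function(error, recall) {
  if (any(error < 0 | error > 1 | recall < 0 | recall > 1, na.rm = TRUE))
    stop("error and recall must lie in [0, 1]")
  ifelse(error < 0.5,
         ifelse(recall >= 0.5, 1L, 2L),
         ifelse(recall >= 0.5, 3L, 4L))
}

#' Assign distance quartiles across qualities
#'
#' Ranks qualities by their best distance-to-ideal (ascending) and splits at
#' the empirical 25/50/75 percentiles (linear-interpolation quantiles). A
#' quality falls in Q1 when its distance is <= the 25th percentile, and so
#' on; with fewer than 4 qualities all are assigned Q1 with a warning.
#'
#' @param distances named numeric vector (names = qualities) or a list of
#'   `SelectionResult`s.
#' @return named factor with levels Q1..Q4.
#' @export
assign_quartiles <- function(distances) {
  if (is.list(distances) && !is.numeric(distances)) {
    nm <- vapply(distances, function(s) paste(s$quality, collapse = ","), "")
    distances <- stats::setNames(vapply(distances, `[[`, 0, "distance"), nm)
  }
  if (length(distances) < 4) {
    warning("fewer than 4 qualities: all assigned Q1")
    return(stats::setNames(
      factor(rep("Q1", length(distances)), levels = paste0("Q", 1:4)),
      names(distances)))
  }
  qs <- stats::quantile(distances, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  lab <- ifelse(distances <= qs[1], "Q1",
                ifelse(distances <= qs[2], "Q2",
                       ifelse(distances <= qs[3], "Q3", "Q4")))
  stats::setNames(factor(lab, levels = paste0("Q", 1:4)), names(distances))
}

#' Build the per-quality selection report table
#'
#' One row per quality: number of rules in the best combination, precision,
#' recall, error, distance, group, quartile and the `min_supp` run the
#' combination came from. Ties share the minimal distance; the first tie is
#' reported.
#'
#' @param selections list of `SelectionResult`s.
#' @param path optional CSV output path.
#' @return data.frame (invisibly written to `path` when given).
#' @export
selection_report <- function(selections, path = NULL) {
  keep <- vapply(selections, function(s) length(s$best) > 0, TRUE)
  sel <- selections[keep]
  if (!length(sel)) {
    df <- data.frame(quality = character(0), n_rules = integer(0),
                     precision = numeric(0), recall = numeric(0),
                     error = numeric(0), distance = numeric(0),
                     group = integer(0), quartile = character(0),
                     source_min_supp = integer(0), n_ties = integer(0))
    if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
    return(df)
  }
  quart <- suppressWarnings(assign_quartiles(sel))
  df <- do.call(rbind, lapply(seq_along(sel), function(i) {
    s <- sel[[i]]
    b <- s$best[[1]]
    data.frame(quality = paste(s$quality, collapse = ","),
               n_rules = length(b$rules),
               precision = b$precision, recall = b$recall,
               error = b$error, distance = b$distance,
               group = s$group, quartile = as.character(quart[i]),
               source_min_supp = b$source_min_supp,
               n_ties = length(s$best),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
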