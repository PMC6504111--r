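#' Load a rated odorant panel from CSV
#'
#' A panel CSV holds an `id` column, numeric descriptor columns, and one
#' `rating:<quality>` column per rated quality with a continuous score per
#' molecule (panel-specific scale, e.g. 0-100 or 0-9).
#'
#' @param file path to the panel CSV.
#' @return list of class `RatedPanel` with `dataset` (an [odorant_dataset()]
#'   in panel mode) and `ratings` (named list of numeric vectors keyed by
#'   quality, one score per molecule).
#' @export
load_panel <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "id") stop("panel file must start with an 'id' column")
  rating_cols <- grep("^rating:", names(df), value = TRUE)
  desc_cols <- setdiff(names(df), c("id", rating_cols))
  if (!length(desc_cols)) stop("no descriptor columns in ", file)
  ids <- as.character(df$id)
  vals <- matrix(NA_real_, length(ids), length(desc_cols),
                 dimnames = list(ids, desc_cols))
  for (j in desc_cols) {
    raw <- trimws(df[[j]]); raw[raw %in% c("", "NA")] <- NA
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric descriptor value at row %d, column '%s'",
                   bad[1], j))
    vals[, j] <- num
  }
  ratings <- lapply(rating_cols, function(j) as.numeric(df[[j]]))
  names(ratings) <- sub("^rating:", "", rating_cols)
  for (q in names(ratings))
    if (anyNA(ratings[[q]]))
      stop("missing rating for quality '", q, "'")
  structure(list(dataset = odorant_dataset(vals, ids = ids, mode = "panel"),
                 ratings = ratings),
            class = "RatedPanel")
}

#' Write a rated panel to CSV (inverse of [load_panel()])
#' @param panel a `RatedPanel`.
#' @param file output path.
#' @export
write_panel <- function(panel, file) {
  ds <- panel$dataset
  df <- data.frame(id = ds$ids, stringsAsFactors = FALSE, check.names = FALSE)
  for (j in ds$descriptors) df[[j]] <- format_num(ds$values[, j])
  for (q in names(panel$ratings))
    df[[paste0("rating:", q)]] <- format_num(panel$ratings[[q]])
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(panel)
}

#' Apply a ruleset to a panel: Rule(1) / Rule(0) membership
#'
#' A panel molecule is Rule(1) iff it lies in the union coverage of the
#' ruleset (it satisfies every interval of at least one rule). A molecule
#' with a missing value on a restricted descriptor of every rule is Rule(0)
#' and flagged.
#'
#' @param ruleset a `RuleCombination`, `MiningRun`, list of rules/entries or
#'   a single [so_rule()].
#' @param panel a `RatedPanel` or [odorant_dataset()].
#' @return named logical vector (TRUE = Rule(1)); attribute
#'   `missing_flagged` lists ids forced to Rule(0) by missing values.
#' @export
apply_ruleset <- function(ruleset, panel) {
  ds <- if (inherits(panel, "RatedPanel")) panel$dataset else panel
  rules <- ruleset_rules(ruleset)
  needed <- unique(unlist(lapply(rules, function(r) r$description$descriptor)))
  gap <- setdiff(needed, ds$descriptors)
  if (length(gap))
    stop("panel lacks descriptor column(s): ", paste(gap, collapse = ", "))
  member <- rep(FALSE, length(ds$ids))
  for (r in rules)
    member[coverage_index(r$description, ds)] <- TRUE
  miss <- if (length(needed))
    ds$ids[!member & apply(is.na(ds$values[, needed, drop = FALSE]), 1, any)]
  else character(0)
  structure(stats::setNames(member, ds$ids), missing_flagged = miss)
}

ruleset_rules <- function(ruleset) {
  if (inherits(ruleset, "SORule")) return(list(ruleset))
  if (inherits(ruleset, "RuleCombination")) return(ruleset$rules)
  if (inherits(ruleset, "MiningRun")) ruleset <- ruleset$rules
  lapply(ruleset, function(r) if (inherits(r, "SORule")) r else r$rule)
}

#' One-way fixed-effects ANOVA with eta-squared
#'
#' Compares continuous scores between the Rule(1) and Rule(0) groups:
#' classical one-way ANOVA with F on (1, n-2) degrees of freedom and effect
#' size `eta^2 = SS_between / SS_total`. On two groups F equals the squared
#' pooled-variance t statistic. Zero within-group variance with unequal
#' means yields `F = Inf`, `p = 0`.
#'
#' @param scores numeric vector of perceptual ratings.
#' @param membership logical vector (TRUE = Rule(1)), same length.
#' @param min_rule1 warn when the Rule(1) group is smaller than this.
#' @return list of class `AnovaResult`: `n_rule1`, `n_rule0`, `mean_rule1`,
#'   `mean_rule0`, `F`, `df`, `p`, `eta_squared`.
#' @export
one_way_anova <- function(scores, membership, min_rule1 = 5) {
  stopifnot(length(scores) == length(membership))
  membership <- as.logical(membership)
  ok <- !is.na(scores) & !is.na(membership)
  scores <- scores[ok]; membership <- membership[ok]
  n1 <- sum(membership); n0 <- sum(!membership)
  if (n1 == 0 || n0 == 0)
    stop("both Rule(1) and Rule(0) groups must be non-empty")
  if (n1 < min_rule1)
    warning("Rule(1) group has only ", n1, " molecules")
  g <- factor(membership, levels = c(FALSE, TRUE))
  fit <- stats::lm(scores ~ g)
  an <- stats::anova(fit)
  ssb <- an$`Sum Sq`[1]; ssw <- an$`Sum Sq`[2]
  sst <- ssb + ssw
  # zero sums of squares up to floating-point noise from the lm fit
  scale0 <- (abs(mean(scores)) + 1)^2 * length(scores) * 1e-14
  if (sst <= scale0) {                        # all scores identical
    Fv <- 0; p <- 1; eta <- 0
  } else if (ssw <= 1e-12 * sst) {            # distinct means, no spread
    Fv <- Inf; p <- 0; eta <- 1
  } else {
    Fv <- an$`F value`[1]; p <- an$`Pr(>F)`[1]
    eta <- ssb / sst
  }
  structure(list(n_rule1 = n1, n_rule0 = n0,
                 mean_rule1 = mean(scores[membership]),
                 mean_rule0 = mean(scores[!membership]),
                 F = Fv, df = c(1L, n1 + n0 - 2L), p = p,
                 eta_squared = eta),
            class = "AnovaResult")
}

#' @export
print.AnovaResult <- function(x, ...) {
  cat(sprintf(
    "F(%d,%d) = %.4g, p = %.4g, eta^2 = %.3f (Rule(1): n=%d mean=%.2f; Rule(0): n=%d mean=%.2f)\n",
    x$df[1], x$df[2], x$F, x$p, x$eta_squared,
    x$n_rule1, x$mean_rule1, x$n_rule0, x$mean_rule0))
  invisible(x)
}

#' Validate rulesets on a rated odorant panel
#'
#' For each quality shared between the rulesets and the panel ratings
#' (optionally through an alias table mapping ruleset quality names to panel
#' quality names), applies the ruleset, skips the quality when fewer than
#' `min_rule1` panel molecules are Rule(1), and otherwise compares ratings
#' between Rule(1) and Rule(0) molecules with [one_way_anova()].
#'
#' @param rulesets named list keyed by quality; values as in
#'   [apply_ruleset()].
#' @param panel a `RatedPanel`.
#' @param min_rule1 minimum Rule(1) group size for a comparison (default 5).
#' @param alias optional data.frame with columns `ruleset_quality`,
#'   `panel_quality`.
#' @param path optional CSV output path.
#' @return data.frame with one row per tested quality: group sizes, means,
#'   SEMs, F, df, p, eta_squared; skipped qualities are absent (logged).
#' @export
validate_panel <- function(rulesets, panel, min_rule1 = 5, alias = NULL,
                           path = NULL) {
  stopifnot(inherits(panel, "RatedPanel"))
  map <- stats::setNames(names(rulesets), names(rulesets))
  if (!is.null(alias))
    map[as.character(alias$ruleset_quality)] <- as.character(alias$panel_quality)
  rows <- list()
  for (q in names(rulesets)) {
    pq <- map[[q]]
    if (is.null(pq) || !pq %in% names(panel$ratings)) {
      message("quality '", q, "' not rated in panel; skipped")
      next
    }
    member <- apply_ruleset(rulesets[[q]], panel)
    n1 <- sum(member)
    if (n1 < min_rule1) {
      message("quality '", q, "': only ", n1,
              " Rule(1) molecule(s); skipped")
      next
    }
    if (n1 == length(member)) {
      message("quality '", q, "': all molecules Rule(1); skipped")
      next
    }
    scores <- panel$ratings[[pq]]
    res <- one_way_anova(scores, member, min_rule1 = min_rule1)
    sem <- function(x) stats::sd(x) / sqrt(length(x))
    rows[[length(rows) + 1L]] <- data.frame(
      quality = q, panel_quality = pq,
      n_rule1 = res$n_rule1, n_rule0 = res$n_rule0,
      mean_rule1 = res$mean_rule1, mean_rule0 = res$mean_rule0,
      sem_rule1 = sem(scores[as.logical(member)]),
      sem_rule0 = sem(scores[!member]),
      F = res$F, df1 = res$df[1], df2 = res$df[2],
      p = res$p, eta_squared = res$eta_squared,
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else {
    warning("no shared qualities between rulesets and panel ratings")
    data.frame(quality = character(0), panel_quality = character(0),
               n_rule1 = integer(0), n_rule0 = integer(0),
               mean_rule1 = numeric(0), mean_rule0 = numeric(0),
               sem_rule1 = numeric(0), sem_rule0 = numeric(0),
               F = numeric(0), df1 = integer(0), df2 = integer(0),
               p = numeric(0), eta_squared = numeric(0))
  }
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
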