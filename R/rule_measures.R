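#' Interval-pattern description
#'
#' A description is a conjunction of closed intervals over a subset of
#' descriptors: a molecule is covered iff every restricted descriptor value
#' `f(m)` satisfies `lo <= f(m) <= hi`. An empty description covers every
#' molecule (vacuous conjunction).
#'
#' @param ... named length-2 numeric vectors, e.g. `MW = c(128, 151)`.
#' @param conditions alternatively, a data.frame with columns
#'   `descriptor`, `lo`, `hi`.
#' @return object of class `Description`: data.frame `descriptor`, `lo`, `hi`.
#' @export
description <- function(..., conditions = NULL) {
  if (is.null(conditions)) {
    dots <- list(...)
    conditions <- data.frame(
      descriptor = as.character(names(dots)),
      lo = vapply(dots, function(b) as.numeric(b[1]), 0),
      hi = vapply(dots, function(b) as.numeric(b[2]), 0),
      stringsAsFactors = FALSE)
  } else {
    conditions <- data.frame(descriptor = as.character(conditions$descriptor),
                             lo = as.numeric(conditions$lo),
                             hi = as.numeric(conditions$hi),
                             stringsAsFactors = FALSE)
  }
  rownames(conditions) <- NULL
  if (anyDuplicated(conditions$descriptor))
    stop("at most one interval per descriptor")
  if (any(is.na(conditions$lo)) || any(is.na(conditions$hi)))
    stop("interval bounds must be finite numbers")
  if (any(conditions$lo > conditions$hi))
    stop("lower bound exceeds upper bound for: ",
         paste(conditions$descriptor[conditions$lo > conditions$hi],
               collapse = ", "))
  structure(conditions, class = c("Description", "data.frame"))
}

#' @export
format.Description <- function(x, ...) {
  if (!nrow(x)) return("<unrestricted>")
  paste(sprintf("[%g <= %s <= %g]", x$lo, x$descriptor, x$hi), collapse = " ")
}

#' @export
print.Description <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Structure-odor rule
#'
#' A rule `D -> Q` pairs an interval-pattern [description()] `D` with a
#' non-empty set of target olfactory qualities `Q`.
#'
#' @param description a [description()].
#' @param qualities character vector (non-empty) of target labels.
#' @param provenance named list of the mining parameters that produced the
#'   rule (free-form; stored for reporting).
#' @return object of class `SORule`.
#' @export
so_rule <- function(description, qualities, provenance = list()) {
  stopifnot(inherits(description, "Description"))
  qualities <- sort(unique(as.character(qualities)))
  if (!length(qualities)) stop("qualities must be non-empty")
  structure(list(description = description, qualities = qualities,
                 provenance = provenance),
            class = "SORule")
}

#' @export
print.SORule <- function(x, ...) {
  cat(format(x$description), "->", paste(x$qualities, collapse = ", "), "\n")
  invisible(x)
}

#' Does a molecule's label set match a target quality set?
#'
#' A molecule is a positive for `Q` iff it carries every quality of `Q`
#' (`Q` is a subset of the molecule's label set). A molecule with extra
#' labels still counts.
#'
#' @param labels character vector of molecule labels.
#' @param qualities character vector, the target set `Q`.
#' @return logical scalar.
#' @export
matches_quality <- function(labels, qualities) {
  all(qualities %in% labels)
}

# logical positive indicator over all molecules, vectorized
positives_for <- function(dataset, qualities) {
  vapply(dataset$labels, function(l) all(qualities %in% l), TRUE,
         USE.NAMES = FALSE)
}

#' Molecules covered by a description
#'
#' Returns the ids of molecules satisfying every interval of the description,
#' both bounds inclusive, in dataset row order. A molecule with a missing
#' value on a restricted descriptor is not covered.
#'
#' @param description a [description()].
#' @param dataset an [odorant_dataset()].
#' @return character vector of molecule ids.
#' @export
rule_coverage <- function(description, dataset) {
  dataset$ids[coverage_index(description, dataset)]
}

coverage_index <- function(description, dataset) {
  keep <- rep(TRUE, length(dataset$ids))
  if (nrow(description)) {
    bad <- setdiff(description$descriptor, dataset$descriptors)
    if (length(bad))
      stop("unknown descriptor(s): ", paste(bad, collapse = ", "))
    for (k in seq_len(nrow(description))) {
      v <- dataset$values[, description$descriptor[k]]
      keep <- keep & !is.na(v) & v >= description$lo[k] & v <= description$hi[k]
    }
  }
  which(keep)
}

#' Support-adaptive beta weight
#'
#' The weight placed on precision vs recall in the adaptive F-beta measure,
#' a squared sigmoid of the target quality's support `x`:
#' `beta(x) = (0.5 * (1 + tanh((x - x_beta) / l_beta)))^2`.
#' It increases from 0 (rare qualities: F-beta tends to precision) to 1
#' (frequent qualities: recall gains weight), with `beta(x_beta) = 0.25`.
#' `l_beta` sets the transition width in molecules.
#'
#' @param x support of the quality set (count of positive molecules).
#' @param x_beta sigmoid centre (default 110 molecules).
#' @param l_beta sigmoid width (> 0; default 20 molecules).
#' @param direction `"increasing"` (default) or `"decreasing"` (mirror
#'   variant weighting recall for rare qualities).
#' @return beta in (0, 1); vectorized over `x`.
#' @export
beta_weight <- function(x, x_beta = 110, l_beta = 20,
                        direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (!is.numeric(l_beta) || l_beta <= 0) stop("l_beta must be > 0")
  z <- (x - x_beta) / l_beta
  if (direction == "decreasing") z <- -z
  (0.5 * (1 + tanh(z)))^2
}

#' Weighted F measure
#'
#' `F_beta = (1 + beta) * P * R / (beta * P + R)`, with the convention 0 when
#' the denominator is 0. At `beta = 1` this is the harmonic mean (F1); at
#' `beta = 0` it reduces to the precision `P`; as `beta` grows it approaches
#' the recall `R`.
#'
#' @param precision,recall numbers in \[0, 1\] (vectorized).
#' @param beta non-negative weight.
#' @return F value in \[min(P, R), max(P, R)\] (0 on empty denominator).
#' @export
f_beta_measure <- function(precision, recall, beta) {
  den <- beta * precision + recall
  out <- ifelse(den > 0, (1 + beta) * precision * recall / den, 0)
  as.numeric(out)
}

#' Evaluate a structure-odor rule on a dataset
#'
#' Computes support, precision, recall, F1 and the support-adaptive F-beta of
#' a rule `D -> Q`. Precision is the fraction of covered molecules carrying
#' every quality of `Q`; recall is the fraction of all `Q`-positive molecules
#' that are covered. Zero denominators yield 0 with a flag (never an error).
#'
#' @param rule an [so_rule()], or a [description()] combined with `qualities`.
#' @param dataset an [odorant_dataset()].
#' @param qualities target quality set when `rule` is a bare description.
#' @param x_beta,l_beta adaptive-F parameters, see [beta_weight()].
#' @param beta_direction passed to [beta_weight()].
#' @return list of class `RuleMetrics`: `support_D`, `positives_in_coverage`,
#'   `support_Q`, `precision`, `recall`, `f1`, `f_beta`, `beta`, `flags`.
#' @export
evaluate_rule <- function(rule, dataset, qualities = NULL,
                          x_beta = 110, l_beta = 20,
                          beta_direction = "increasing") {
  if (inherits(rule, "SORule")) {
    desc <- rule$description
    qualities <- rule$qualities
  } else {
    desc <- rule
    if (is.null(qualities)) stop("qualities required for a bare description")
  }
  pos <- positives_for(dataset, qualities)
  cov <- coverage_index(desc, dataset)
  metrics_from_counts(support_D = length(cov),
                      positives = sum(pos[cov]),
                      support_Q = sum(pos),
                      x_beta = x_beta, l_beta = l_beta,
                      beta_direction = beta_direction)
}

metrics_from_counts <- function(support_D, positives, support_Q,
                                x_beta = 110, l_beta = 20,
                                beta_direction = "increasing") {
  flags <- character(0)
  precision <- if (support_D > 0) positives / support_D else {
    flags <- c(flags, "empty_coverage"); 0
  }
  recall <- if (support_Q > 0) positives / support_Q else {
    flags <- c(flags, "zero_support_Q"); 0
  }
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  beta <- beta_weight(support_Q, x_beta, l_beta, beta_direction)
  fb <- f_beta_measure(precision, recall, beta)
  structure(list(support_D = as.integer(support_D),
                 positives_in_coverage = as.integer(positives),
                 support_Q = as.integer(support_Q),
                 precision = precision, recall = recall,
                 f1 = f1, f_beta = fb, beta = beta, flags = flags),
            class = "RuleMetrics")
}

#' @export
print.RuleMetrics <- function(x, ...) {
  cat(sprintf(
    "support %d (positives %d / support_Q %d): P=%.3f R=%.3f F1=%.3f Fbeta=%.3f (beta=%.3f)\n",
    x$support_D, x$positives_in_coverage, x$support_Q,
    x$precision, x$recall, x$f1, x$f_beta, x$beta))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
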