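#' Planted interval-box rule for the synthetic generator
#'
#' Defines a ground-truth subgroup: molecules inside the axis-aligned box get
#' the quality label with probability `p_inside`, molecules outside with
#' probability `p_outside`. A recoverable rule needs
#' `p_inside > p_outside`.
#'
#' @param quality label assigned by the rule.
#' @param box a [description()] over a few descriptors.
#' @param p_inside,p_outside labelling probabilities in \[0, 1\].
#' @return list of class `PlantedRule`.
#' @export
planted_rule <- function(quality, box, p_inside = 0.9, p_outside = 0.02) {
  stopifnot(inherits(box, "Description"),
            p_inside >= 0, p_inside <= 1, p_outside >= 0, p_outside <= 1)
  structure(list(quality = as.character(quality), box = box,
                 p_inside = p_inside, p_outside = p_outside),
            class = "PlantedRule")
}

#' Specification of a synthetic odorant dataset
#'
#' The defaults emulate the statistical shape of the reference olfactory
#' dataset: 1689 molecules, 82 descriptors, 74 olfactory qualities with
#' strongly unbalanced supports spanning roughly 2 to 570 molecules
#' (geometric frequency profile) and about 2.88 labels per molecule.
#' Planted interval-box rules (if any) overlay that background for their
#' target quality.
#'
#' @param n_molecules,n_descriptors dataset dimensions.
#' @param distribution `"uniform"` (0,1) or `"normal"` (0,1) descriptors.
#' @param planted_rules list of [planted_rule()]s.
#' @param n_background_qualities number of background labels.
#' @param mean_labels_per_molecule target mean number of labels.
#' @param support_range target (min, max) background label supports; the
#'   geometric profile interpolates between them and is then rescaled so the
#'   expected labels per molecule match `mean_labels_per_molecule`.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return list of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_molecules = 1689, n_descriptors = 82,
                           distribution = c("uniform", "normal"),
                           planted_rules = list(),
                           n_background_qualities = 74,
                           mean_labels_per_molecule = 2.88,
                           support_range = c(2, 570),
                           seed = 1L) {
  distribution <- match.arg(distribution)
  stopifnot(n_molecules >= 1, n_descriptors >= 1,
            n_background_qualities >= 0,
            mean_labels_per_molecule >= 0)
  structure(list(n_molecules = as.integer(n_molecules),
                 n_descriptors = as.integer(n_descriptors),
                 distribution = distribution,
                 planted_rules = planted_rules,
                 n_background_qualities = as.integer(n_background_qualities),
                 mean_labels_per_molecule = mean_labels_per_molecule,
                 support_range = support_range,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic odorant dataset with planted rules
#'
#' Samples the descriptor matrix, assigns each planted rule's label by box
#' membership (Bernoulli `p_inside` / `p_outside`), sprinkles background
#' labels with a geometric (unbalanced) frequency profile scaled to the
#' target mean labels per molecule, and guarantees every molecule carries at
#' least one label. Fully reproducible from the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (an [odorant_dataset()]) and `truth`
#'   (per planted rule: realized coverage ids, support, precision, recall).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  n <- spec$n_molecules
  p <- spec$n_descriptors
  vals <- matrix(if (spec$distribution == "uniform") stats::runif(n * p)
                 else stats::rnorm(n * p),
                 n, p, dimnames = list(as.character(seq_len(n)),
                                       sprintf("d%02d", seq_len(p))))
  ids <- rownames(vals)
  labels <- rep(list(character(0)), n)
  names(labels) <- ids

  # planted rules first: label by box membership
  lo_supp <- if (spec$distribution == "uniform") 0 else -Inf
  hi_supp <- if (spec$distribution == "uniform") 1 else Inf
  for (pr in spec$planted_rules) {
    if (any(pr$box$lo < lo_supp) || any(pr$box$hi > hi_supp))
      stop("planted box outside descriptor support")
    jj <- match(pr$box$descriptor, colnames(vals))
    if (anyNA(jj)) stop("planted box names unknown descriptors")
    inside <- rep(TRUE, n)
    for (k in seq_along(jj))
      inside <- inside & vals[, jj[k]] >= pr$box$lo[k] &
        vals[, jj[k]] <= pr$box$hi[k]
    prob <- ifelse(inside, pr$p_inside, pr$p_outside)
    hit <- stats::runif(n) < prob
    for (i in which(hit))
      labels[[i]] <- c(labels[[i]], pr$quality)
  }

  # background labels: geometric support profile scaled to the target mean
  kq <- spec$n_background_qualities
  if (kq > 0 && spec$mean_labels_per_molecule > 0) {
    prof <- exp(seq(log(max(spec$support_range[1], 1)),
                    log(max(spec$support_range[2], 1)),
                    length.out = kq))
    planted_mean <- mean(vapply(labels, length, 1L))
    target <- max(spec$mean_labels_per_molecule - planted_mean, 0.1)
    prob_q <- prof / sum(prof) * target
    prob_q <- pmin(prob_q, 1)
    qnames <- sprintf("q%02d", seq_len(kq))
    for (q in seq_len(kq)) {
      hit <- stats::runif(n) < prob_q[q]
      for (i in which(hit))
        labels[[i]] <- c(labels[[i]], qnames[q])
    }
    # guarantee >= 1 label per molecule (frequent labels more likely)
    empty <- which(vapply(labels, length, 1L) == 0L)
    if (length(empty)) {
      fill <- sample(qnames, length(empty), replace = TRUE,
                     prob = prob_q / sum(prob_q))
      for (k in seq_along(empty))
        labels[[empty[k]]] <- fill[k]
    }
  } else {
    empty <- which(vapply(labels, length, 1L) == 0L)
    if (length(empty) && length(spec$planted_rules)) {
      for (i in empty) labels[[i]] <- spec$planted_rules[[1]]$quality
    }
  }
  labels <- lapply(labels, function(l) sort(unique(l)))
  vocab <- unique(c(vapply(spec$planted_rules, `[[`, "", "quality"),
                    if (spec$n_background_qualities > 0)
                      sprintf("q%02d", seq_len(spec$n_background_qualities))))
  ds <- odorant_dataset(vals, labels, ids = ids, qualities = vocab)

  truth <- lapply(spec$planted_rules, function(pr) {
    cov <- rule_coverage(pr$box, ds)
    m <- evaluate_rule(pr$box, ds, qualities = pr$quality)
    list(quality = pr$quality, box = pr$box, coverage = cov,
         support = m$support_D, precision = m$precision, recall = m$recall)
  })
  list(dataset = ds, truth = truth)
}

#' Jaccard recovery score of mined rules against a planted rule
#'
#' Maximum over the mined rules of the Jaccard similarity between the mined
#' rule's coverage and the planted box's coverage, both evaluated on the
#' same dataset. 1 means a mined rule covers exactly the planted subgroup;
#' 0 means no mined rule overlaps it (or no rules were mined).
#'
#' @param mined a `MiningRun` or list of rules / rule entries.
#' @param planted a [planted_rule()] or a truth entry from
#'   [generate_dataset()].
#' @param dataset the [odorant_dataset()] both refer to.
#' @return number in \[0, 1\].
#' @export
recovery_score <- function(mined, planted, dataset) {
  rules <- ruleset_rules(mined)
  if (!length(rules)) return(0)
  box <- if (inherits(planted, "PlantedRule")) planted$box else planted$box
  target <- rule_coverage(box, dataset)
  jac <- vapply(rules, function(r) {
    cov <- rule_coverage(r$description, dataset)
    u <- length(union(cov, target))
    if (u == 0) 0 else length(intersect(cov, target)) / u
  }, 0)
  max(jac)
}
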