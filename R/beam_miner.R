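#' Miner configuration
#'
#' Bundles the search constraints and quality-measure parameters of the rule
#' miner. Defaults mirror the reference study settings: `max_output` 100,
#' `beam_width` 30, `max_qual` 1, `max_properties` 8, `max_supp` 700,
#' `x_beta` 110, `l_beta` 20, and `min_supp` 5 (the study swept
#' `min_supp` over 5, 10, 20, 30; see [mine_all()]).
#'
#' @param min_supp minimum support of an emitted rule's description.
#' @param max_supp maximum support of an emitted rule's description.
#' @param max_qual maximum size of a target quality set.
#' @param max_properties maximum number of restricted descriptors per rule.
#' @param beam_width beam width of the search.
#' @param max_output maximum number of rules returned per target.
#' @param x_beta,l_beta adaptive F-beta parameters, see [beta_weight()].
#' @param beta_direction see [beta_weight()].
#' @param grid `"observed"` for minimal shrinks on the observed-value grid
#'   (exact, best for small data), or an integer k for a k-quantile grid per
#'   descriptor (coarser, much faster on large datasets).
#' @param terminate `"exhaust"` (default) explores the refinement lattice
#'   until no candidate meets `min_supp`; `"plateau"` stops as soon as no
#'   candidate improves the best F-beta seen (greedy hill-climb variant).
#' @param seed reserved for stochastic extensions; the miner itself is
#'   deterministic.
#' @return a list of class `MinerConfig`.
#' @export
miner_config <- function(min_supp = 5, max_supp = 700, max_qual = 1,
                         max_properties = 8, beam_width = 30,
                         max_output = 100, x_beta = 110, l_beta = 20,
                         beta_direction = "increasing",
                         grid = "observed",
                         terminate = c("exhaust", "plateau"),
                         seed = 1L) {
  terminate <- match.arg(terminate)
  stopifnot(min_supp >= 1, max_supp >= min_supp, max_qual >= 1,
            max_properties >= 1, beam_width >= 1, max_output >= 1,
            l_beta > 0)
  if (!identical(grid, "observed")) {
    grid <- as.integer(grid)
    stopifnot(grid >= 2)
  }
  structure(list(min_supp = as.integer(min_supp),
                 max_supp = as.integer(max_supp),
                 max_qual = as.integer(max_qual),
                 max_properties = as.integer(max_properties),
                 beam_width = as.integer(beam_width),
                 max_output = as.integer(max_output),
                 x_beta = x_beta, l_beta = l_beta,
                 beta_direction = beta_direction,
                 grid = grid, terminate = terminate,
                 seed = as.integer(seed)),
            class = "MinerConfig")
}

#' Read a miner configuration from YAML
#'
#' Accepts the field names as printed in the reference study
#' (`maxoutput`, `beamwidth`, `MaxQual`, `MaxProperties`, `maxSupp`,
#' `XBeta`, `lBeta`, `minSupp`) as well as the native [miner_config()]
#' argument names. `minSupp` may be a vector (a sweep); the first value seeds
#' the config and the full vector is kept in the `min_supp_sweep` attribute.
#'
#' @param path YAML file path.
#' @return a `MinerConfig`.
#' @export
read_miner_config <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(...) {
    for (nm in c(...)) if (!is.null(y[[nm]])) return(y[[nm]])
    NULL
  }
  sweep <- pick("minSupp", "min_supp")
  args <- list(
    min_supp = if (!is.null(sweep)) sweep[[1]] else NULL,
    max_supp = pick("maxSupp", "max_supp"),
    max_qual = pick("MaxQual", "maxQual", "max_qual"),
    max_properties = pick("MaxProperties", "maxProp", "max_properties"),
    beam_width = pick("beamwidth", "beam_width"),
    max_output = pick("maxoutput", "max_output"),
    x_beta = pick("XBeta", "xBeta", "x_beta"),
    l_beta = pick("lBeta", "IBeta", "l_beta"),
    beta_direction = pick("beta_direction"),
    grid = pick("grid"),
    terminate = pick("terminate"),
    seed = pick("seed"))
  cfg <- do.call(miner_config, args[!vapply(args, is.null, TRUE)])
  attr(cfg, "min_supp_sweep") <-
    if (!is.null(sweep)) as.integer(unlist(sweep)) else cfg$min_supp
  cfg
}

#' Enumerate target quality sets
#'
#' All non-empty quality sets Q drawn from the dataset vocabulary with
#' `|Q| <= max_qual` and dataset support at least `min_supp`, in
#' lexicographic order of their comma-joined labels. Support of a set counts
#' molecules carrying every quality of the set.
#'
#' @param dataset an [odorant_dataset()].
#' @param max_qual maximum set size.
#' @param min_supp minimum support.
#' @return list of character vectors.
#' @export
enumerate_targets <- function(dataset, max_qual = 1, min_supp = 1) {
  vocab <- sort(dataset$qualities)
  out <- list()
  for (k in seq_len(min(max_qual, length(vocab)))) {
    sets <- utils::combn(vocab, k, simplify = FALSE)
    for (Q in sets)
      if (sum(positives_for(dataset, Q)) >= min_supp)
        out[[length(out) + 1L]] <- Q
  }
  keys <- vapply(out, paste, "", collapse = ",")
  out[order(keys, method = "radix")]
}

# --- refinement machinery ---------------------------------------------------

# per-descriptor bound grids: observed -> NULL (use values in coverage),
# integer k -> unique k-quantiles of the full column
make_grids <- function(dataset, grid) {
  if (identical(grid, "observed")) return(NULL)
  lapply(seq_along(dataset$descriptors), function(j) {
    v <- dataset$values[, j]
    sort(unique(stats::quantile(v[!is.na(v)],
                                probs = seq(0, 1, length.out = grid),
                                names = FALSE, type = 7)))
  })
}

# minimal one-step specializations of node (lo/hi with NA = unrestricted),
# relative to its coverage cov (integer row indices). Returns a list of
# lists(j, lo, hi, side).
node_refinements <- function(lo, hi, cov, values, grids, max_properties) {
  p <- ncol(values)
  n_conds <- sum(!is.na(lo))
  out <- vector("list", 2L * p)
  n_out <- 0L
  for (j in seq_len(p)) {
    unrestricted <- is.na(lo[j])
    if (unrestricted && n_conds >= max_properties) next
    v <- values[cov, j]
    v <- v[!is.na(v)]
    if (!length(v)) next
    u1 <- min(v); uK <- max(v)
    if (u1 == uK) next                      # single distinct value: no shrink
    if (is.null(grids)) {
      su <- sort(unique(v))
      lo_cand <- su[2L]                     # next observed value above the min
      hi_cand <- su[length(su) - 1L]        # next observed value below the max
    } else {
      g <- grids[[j]]
      gl <- g[g > u1]
      gh <- g[g < uK]
      lo_cand <- if (length(gl)) min(gl) else NA_real_
      hi_cand <- if (length(gh)) max(gh) else NA_real_
    }
    cur_lo <- if (unrestricted) u1 else lo[j]
    cur_hi <- if (unrestricted) uK else hi[j]
    if (!is.na(lo_cand) && lo_cand <= cur_hi) {
      n_out <- n_out + 1L
      out[[n_out]] <- list(j = j, lo = lo_cand, hi = cur_hi)
    }
    if (!is.na(hi_cand) && hi_cand >= cur_lo) {
      n_out <- n_out + 1L
      out[[n_out]] <- list(j = j, lo = cur_lo, hi = hi_cand)
    }
  }
  out[seq_len(n_out)]
}

#' One-step refinements of a description
#'
#' The minimal specializations the miner explores from a given description:
#' for each descriptor, shrink the lower bound up to the next grid value
#' inside the current coverage, or the upper bound down to the next grid
#' value. Introducing a condition on an unrestricted descriptor counts toward
#' `max_properties`. No refinement empties the interval.
#'
#' @param desc a [description()].
#' @param dataset an [odorant_dataset()].
#' @param config a [miner_config()] (supplies `max_properties` and `grid`).
#' @return list of [description()] objects.
#' @export
refine_description <- function(desc, dataset, config = miner_config()) {
  p <- length(dataset$descriptors)
  lo <- hi <- rep(NA_real_, p)
  if (nrow(desc)) {
    jj <- match(desc$descriptor, dataset$descriptors)
    if (anyNA(jj)) stop("unknown descriptor(s) in description")
    lo[jj] <- desc$lo
    hi[jj] <- desc$hi
  }
  cov <- coverage_index(desc, dataset)
  grids <- make_grids(dataset, config$grid)
  refs <- node_refinements(lo, hi, cov, dataset$values, grids,
                           config$max_properties)
  lapply(refs, function(r) {
    lo2 <- lo; hi2 <- hi
    lo2[r$j] <- r$lo; hi2[r$j] <- r$hi
    jj <- which(!is.na(lo2))
    description(conditions = data.frame(
      descriptor = dataset$descriptors[jj], lo = lo2[jj], hi = hi2[jj],
      stringsAsFactors = FALSE))
  })
}

# deterministic candidate ordering: f_beta desc, support desc, fewer
# conditions, then lexicographic on the condition string
order_entries <- function(entries) {
  fb <- vapply(entries, function(e) e$f_beta, 0)
  su <- vapply(entries, function(e) e$support, 0L)
  nc <- vapply(entries, function(e) e$n_conds, 0L)
  lex <- vapply(entries, function(e) e$lex, "")
  order(-fb, -su, nc, lex, method = "radix")
}

entry_lex <- function(lo, hi, descriptors) {
  jj <- which(!is.na(lo))
  if (!length(jj)) return("")
  paste(sprintf("%s:%.17g:%.17g", descriptors[jj], lo[jj], hi[jj]),
        collapse = "|")
}

#' Mine structure-odor rules for one target quality set
#'
#' Beam search over interval-pattern descriptions. The beam starts from the
#' unrestricted description; every level scores all minimal refinements of
#' the beam members by the adaptive F-beta of `D -> Q`, drops candidates
#' below `min_supp`, deduplicates by coverage set, and keeps the
#' `beam_width` best. All distinct candidates ever seen feed a result pool;
#' the `max_output` best that also satisfy `support <= max_supp` are
#' returned. The search is fully deterministic.
#'
#' @param dataset an [odorant_dataset()].
#' @param qualities character vector, the target quality set Q.
#' @param config a [miner_config()].
#' @return list of class `MiningRun`: `target`, `config`, `rules` (list of
#'   entries with `rule`, `metrics`, `coverage`), `trace` (per-level stats).
#' @export
mine_rules <- function(dataset, qualities, config = miner_config()) {
  qualities <- sort(unique(as.character(qualities)))
  if (!all(qualities %in% dataset$qualities))
    stop("target qualities outside the dataset vocabulary: ",
         paste(setdiff(qualities, dataset$qualities), collapse = ", "))
  values <- dataset$values
  p <- ncol(values)
  pos <- positives_for(dataset, qualities)
  support_Q <- sum(pos)
  beta <- beta_weight(support_Q, config$x_beta, config$l_beta,
                      config$beta_direction)
  grids <- make_grids(dataset, config$grid)

  score <- function(cov) {
    sD <- length(cov)
    if (sD == 0L) return(c(0, 0))
    tp <- sum(pos[cov])
    P <- tp / sD
    R <- if (support_Q > 0) tp / support_Q else 0
    den <- beta * P + R
    c(if (den > 0) (1 + beta) * P * R / den else 0, tp)
  }

  new_entry <- function(lo, hi, cov) {
    sc <- score(cov)
    list(lo = lo, hi = hi, cov = cov, support = length(cov),
         positives = as.integer(sc[2]), f_beta = sc[1],
         n_conds = sum(!is.na(lo)),
         lex = entry_lex(lo, hi, dataset$descriptors))
  }
  cov_key <- function(cov) paste(sort(dataset$ids[cov]), collapse = "\r")

  root <- new_entry(rep(NA_real_, p), rep(NA_real_, p),
                    seq_len(length(dataset$ids)))
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(cov_key(root$cov), TRUE, envir = visited)

  pool <- list()
  if (root$support >= config$min_supp) pool[[1L]] <- root
  prune_pool <- function(pool) {
    if (length(pool) <= 4L * config$max_output) return(pool)
    pool[utils::head(order_entries(pool), 2L * config$max_output)]
  }

  beam <- if (root$support >= config$min_supp) list(root) else list()
  best_ever <- if (length(pool)) root$f_beta else -Inf
  trace <- list()
  level <- 0L
  while (length(beam)) {
    level <- level + 1L
    cands <- list()
    n_c <- 0L
    for (member in beam) {
      refs <- node_refinements(member$lo, member$hi, member$cov, values,
                               grids, config$max_properties)
      for (r in refs) {
        v <- values[member$cov, r$j]
        cov2 <- member$cov[!is.na(v) & v >= r$lo & v <= r$hi]
        if (length(cov2) < config$min_supp) next
        key <- cov_key(cov2)
        if (exists(key, envir = visited, inherits = FALSE)) next
        assign(key, TRUE, envir = visited)
        lo2 <- member$lo; hi2 <- member$hi
        lo2[r$j] <- r$lo; hi2[r$j] <- r$hi
        n_c <- n_c + 1L
        cands[[n_c]] <- new_entry(lo2, hi2, cov2)
      }
    }
    if (!n_c) break
    ord <- order_entries(cands)
    beam <- cands[utils::head(ord, config$beam_width)]
    pool <- prune_pool(c(pool, cands))
    level_best <- cands[[ord[1L]]]$f_beta
    trace[[level]] <- data.frame(level = level, n_candidates = n_c,
                                 best_f_beta = max(level_best, best_ever))
    if (config$terminate == "plateau" && level_best <= best_ever) break
    best_ever <- max(best_ever, level_best)
  }

  pool <- pool[vapply(pool, function(e) e$support <= config$max_supp, TRUE)]
  pool <- pool[utils::head(order_entries(pool), config$max_output)]
  rules <- lapply(pool, function(e) {
    jj <- which(!is.na(e$lo))
    desc <- description(conditions = data.frame(
      descriptor = dataset$descriptors[jj], lo = e$lo[jj], hi = e$hi[jj],
      stringsAsFactors = FALSE))
    list(rule = so_rule(desc, qualities,
                        provenance = config[c("min_supp", "max_supp",
                                              "max_qual", "max_properties",
                                              "beam_width", "max_output",
                                              "x_beta", "l_beta")]),
         metrics = metrics_from_counts(e$support, e$positives, support_Q,
                                       config$x_beta, config$l_beta,
                                       config$beta_direction),
         coverage = dataset$ids[e$cov])
  })
  structure(list(target = qualities, config = config, rules = rules,
                 trace = if (length(trace)) do.call(rbind, trace)
                         else data.frame(level = integer(0),
                                         n_candidates = integer(0),
                                         best_f_beta = numeric(0))),
            class = "MiningRun")
}

#' @export
print.MiningRun <- function(x, ...) {
  cat(sprintf("MiningRun for {%s}: %d rule(s), %d search level(s)\n",
              paste(x$target, collapse = ", "), length(x$rules),
              nrow(x$trace)))
  if (length(x$rules)) {
    m <- x$rules[[1]]$metrics
    cat("best:", format(x$rules[[1]]$rule$description),
        sprintf(" Fbeta=%.3f P=%.3f R=%.3f supp=%d\n",
                m$f_beta, m$precision, m$recall, m$support_D))
  }
  invisible(x)
}

#' Mine rules for every eligible target quality set
#'
#' Runs [mine_rules()] for each target from [enumerate_targets()]. Per-target
#' errors are caught and reported without aborting the batch.
#'
#' @param dataset an [odorant_dataset()].
#' @param config a [miner_config()].
#' @param targets optional list of quality sets (defaults to all eligible).
#' @param verbose print per-target progress to stderr.
#' @return named list of `MiningRun` objects (names are comma-joined quality
#'   sets); failed targets carry a `try-error`.
#' @export
mine_all <- function(dataset, config = miner_config(), targets = NULL,
                     verbose = FALSE) {
  if (is.null(targets))
    targets <- enumerate_targets(dataset, config$max_qual, config$min_supp)
  out <- list()
  for (Q in targets) {
    key <- paste(Q, collapse = ",")
    if (verbose) message("mining {", key, "}")
    out[[key]] <- tryCatch(mine_rules(dataset, Q, config),
                           error = function(e) {
                             warning("mining {", key, "} failed: ",
                                     conditionMessage(e))
                             structure(conditionMessage(e),
                                       class = "try-error")
                           })
  }
  out
}

# --- ruleset JSON serialization --------------------------------------------

rule_to_list <- function(entry) {
  r <- entry$rule
  m <- entry$metrics
  list(quality = as.list(r$qualities),
       conditions = lapply(seq_len(nrow(r$description)), function(k)
         list(descriptor = r$description$descriptor[k],
              lo = r$description$lo[k], hi = r$description$hi[k])),
       metrics = list(support = m$support_D,
                      positives = m$positives_in_coverage,
                      support_Q = m$support_Q,
                      precision = m$precision, recall = m$recall,
                      f1 = m$f1, f_beta = m$f_beta, beta = m$beta),
       provenance = r$provenance)
}

#' Write a ruleset to JSON
#'
#' Serializes mined rules (a `MiningRun` or a list of rule entries) as a JSON
#' array of `{quality, conditions, metrics, provenance}` objects at full
#' numeric precision, so a write -> read round trip is bit-exact.
#'
#' @param rules a `MiningRun` or list of entries with `rule` and `metrics`.
#' @param path output file.
#' @export
write_ruleset <- function(rules, path) {
  if (inherits(rules, "MiningRun")) rules <- rules$rules
  json <- jsonlite::toJSON(lapply(rules, rule_to_list),
                           auto_unbox = TRUE, digits = I(17), null = "null",
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a ruleset from JSON
#'
#' @param path file written by [write_ruleset()].
#' @return list of entries with `rule` ([so_rule()]) and `metrics`.
#' @export
read_ruleset <- function(path) {
  arr <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(arr, function(x) {
    conds <- if (length(x$conditions)) data.frame(
      descriptor = vapply(x$conditions, `[[`, "", "descriptor"),
      lo = vapply(x$conditions, function(c) as.numeric(c$lo), 0),
      hi = vapply(x$conditions, function(c) as.numeric(c$hi), 0),
      stringsAsFactors = FALSE)
    else data.frame(descriptor = character(0), lo = numeric(0),
                    hi = numeric(0), stringsAsFactors = FALSE)
    m <- x$metrics
    metrics <- structure(list(
      support_D = as.integer(m$support),
      positives_in_coverage = as.integer(m$positives),
      support_Q = as.integer(m$support_Q),
      precision = as.numeric(m$precision), recall = as.numeric(m$recall),
      f1 = as.numeric(m$f1), f_beta = as.numeric(m$f_beta),
      beta = as.numeric(m$beta), flags = character(0)),
      class = "RuleMetrics")
    list(rule = so_rule(description(conditions = conds),
                        unlist(x$quality),
                        provenance = x$provenance),
         metrics = metrics)
  })
}
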