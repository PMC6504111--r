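#' Construct an odorant dataset
#'
#' An `OdorantDataset` couples a numeric descriptor matrix (molecules in rows,
#' physicochemical descriptors in columns) with a multi-label annotation:
#' each molecule carries a set of olfactory-quality labels. Validation panels
#' may carry empty label sets (`mode = "panel"`); annotated datasets used for
#' mining require at least one label per molecule.
#'
#' @param values numeric matrix, molecules x descriptors; rownames are taken
#'   as molecule identifiers when `ids` is `NULL`. Entries may be `NA`.
#' @param labels named list mapping molecule id to a character vector of
#'   quality labels. Molecules absent from the list get an empty label set.
#' @param ids character vector of molecule identifiers (unique).
#' @param qualities optional character vector fixing the quality vocabulary;
#'   defaults to the union of all labels.
#' @param mode `"annotated"` (every molecule needs >= 1 label) or `"panel"`.
#' @return an object of class `OdorantDataset`: a list with elements
#'   `ids`, `descriptors`, `values`, `labels`, `qualities`, `mode`.
#' @export
odorant_dataset <- function(values, labels = list(), ids = NULL,
                            qualities = NULL, mode = c("annotated", "panel")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate molecule ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(ids) != nrow(values))
    stop("length(ids) != nrow(values)")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("d", seq_len(ncol(values)))
  rownames(values) <- ids
  lab <- rep(list(character(0)), length(ids))
  names(lab) <- ids
  if (length(labels)) {
    unknown <- setdiff(names(labels), ids)
    if (length(unknown))
      stop("labels refer to unknown molecule ids: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    for (id in names(labels))
      lab[[id]] <- sort(unique(as.character(labels[[id]])))
  }
  if (is.null(qualities)) {
    qualities <- sort(unique(unlist(lab, use.names = FALSE)))
  } else {
    qualities <- sort(unique(as.character(qualities)))
    extra <- setdiff(unlist(lab, use.names = FALSE), qualities)
    if (length(extra))
      stop("labels outside the quality vocabulary: ",
           paste(unique(extra), collapse = ", "))
  }
  if (mode == "annotated" && length(ids)) {
    n0 <- sum(vapply(lab, length, 1L) == 0L)
    if (n0 > 0)
      stop(n0, " molecule(s) without labels in annotated mode")
  }
  structure(list(ids = ids, descriptors = colnames(values), values = values,
                 labels = lab, qualities = qualities, mode = mode),
            class = "OdorantDataset")
}

#' @export
print.OdorantDataset <- function(x, ...) {
  cat(sprintf("OdorantDataset: %d molecules x %d descriptors, %d qualities (%s mode)\n",
              length(x$ids), length(x$descriptors), length(x$qualities), x$mode))
  invisible(x)
}

#' Load an odorant dataset from descriptor and label CSV files
#'
#' The descriptor file must have an `id` column followed by numeric descriptor
#' columns. The label file is either long form (`id,quality`, one row per
#' label) or wide form (`id,qualities` with `;`-separated labels); the dialect
#' is auto-detected from the header. Molecules present in only one of the two
#' files are dropped with a warning in annotated mode, or kept label-free in
#' panel mode.
#'
#' @param descriptor_file path to the descriptor CSV.
#' @param label_file path to the label CSV, or `NULL` (panel mode only).
#' @param mode `"annotated"` or `"panel"`.
#' @return an [odorant_dataset()].
#' @export
load_dataset <- function(descriptor_file, label_file = NULL,
                         mode = c("annotated", "panel")) {
  mode <- match.arg(mode)
  desc <- utils::read.csv(descriptor_file, check.names = FALSE,
                          colClasses = "character")
  if (!"id" %in% names(desc)[1])
    stop("descriptor file must start with an 'id' column: ", descriptor_file)
  ids <- as.character(desc[["id"]])
  if (anyDuplicated(ids))
    stop("duplicate molecule ids in ", descriptor_file, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dcols <- setdiff(names(desc), "id")
  if (!length(dcols)) stop("no descriptor columns in ", descriptor_file)
  vals <- matrix(NA_real_, length(ids), length(dcols),
                 dimnames = list(ids, dcols))
  for (j in dcols) {
    raw <- trimws(desc[[j]])
    raw[raw %in% c("", "NA", "na", "NaN")] <- NA
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric descriptor value '%s' at row %d (id %s), column '%s'",
                   raw[bad[1]], bad[1], ids[bad[1]], j))
    vals[, j] <- num
  }
  labels <- list()
  if (!is.null(label_file)) {
    labels <- read_labels(label_file)
    lab_ids <- names(labels)
    only_desc <- setdiff(ids, lab_ids)
    only_lab <- setdiff(lab_ids, ids)
    if (!length(intersect(ids, lab_ids)) && length(labels))
      stop("descriptor and label files share no molecule ids")
    if (length(only_lab)) {
      warning(length(only_lab),
              " molecule(s) present only in the label file; dropped")
      labels <- labels[intersect(lab_ids, ids)]
    }
    if (length(only_desc) && mode == "annotated") {
      warning(length(only_desc),
              " molecule(s) present only in the descriptor file; dropped")
      vals <- vals[setdiff(ids, only_desc), , drop = FALSE]
      ids <- rownames(vals)
    }
  } else if (mode == "annotated") {
    stop("annotated mode requires a label file")
  }
  odorant_dataset(vals, labels, ids = ids, mode = mode)
}

read_labels <- function(label_file) {
  df <- utils::read.csv(label_file, check.names = FALSE,
                        colClasses = "character")
  if (all(c("id", "quality") %in% names(df))) {         # long form
    split(as.character(df$quality), factor(df$id, levels = unique(df$id)))
  } else if (all(c("id", "qualities") %in% names(df))) { # wide form
    out <- lapply(strsplit(as.character(df$qualities), ";", fixed = TRUE),
                  function(q) trimws(q[nzchar(trimws(q))]))
    names(out) <- as.character(df$id)
    if (anyDuplicated(names(out)))
      stop("duplicate molecule ids in ", label_file)
    out
  } else {
    stop("label file header must be 'id,quality' (long) or 'id,qualities' (wide)")
  }
}

#' Write an odorant dataset as descriptor and label CSV files
#'
#' Inverse of [load_dataset()]: a load -> write -> load round trip reproduces
#' ids, values and label sets exactly.
#'
#' @param dataset an [odorant_dataset()].
#' @param descriptor_file,label_file output paths.
#' @param label_form `"long"` or `"wide"`.
#' @export
write_dataset <- function(dataset, descriptor_file, label_file = NULL,
                          label_form = c("long", "wide")) {
  label_form <- match.arg(label_form)
  df <- data.frame(id = dataset$ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in dataset$descriptors)
    df[[j]] <- format_num(dataset$values[, j])
  utils::write.csv(df, descriptor_file, row.names = FALSE, quote = FALSE,
                   na = "")
  if (!is.null(label_file)) {
    has <- vapply(dataset$labels, length, 1L) > 0L
    if (label_form == "long") {
      ldf <- data.frame(
        id = rep(dataset$ids[has], vapply(dataset$labels[has], length, 1L)),
        quality = unlist(dataset$labels[has], use.names = FALSE),
        stringsAsFactors = FALSE)
    } else {
      ldf <- data.frame(
        id = dataset$ids[has],
        qualities = vapply(dataset$labels[has], paste, "", collapse = ";"),
        stringsAsFactors = FALSE)
    }
    utils::write.csv(ldf, label_file, row.names = FALSE, quote = FALSE)
  }
  invisible(dataset)
}

# full-precision decimal text so CSV round trips are exact
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_
    else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, "")
  out
}

#' The six-molecule toy olfactory dataset
#'
#' A small worked-example dataset: six molecules described by molecular weight
#' (`MW`), atom count (`nAT`) and carbon count (`nC`), each annotated with
#' qualities among fruity, vanillin and woody. Useful for illustrating
#' coverage, precision and recall of a structure-odor rule.
#'
#' @return an [odorant_dataset()] with 6 molecules, 3 descriptors, 3 qualities.
#' @examples
#' toy <- toy_dataset()
#' rule_coverage(description(MW = c(128, 151), nAT = c(23, 29), nC = c(9, 12)), toy)
#' @export
toy_dataset <- function() {
  vals <- matrix(c(150, 21, 11,
                   128, 29,  9,
                   136, 24, 10,
                   152, 23, 11,
                   151, 27, 12,
                   142, 27, 10),
                 nrow = 6, byrow = TRUE,
                 dimnames = list(as.character(1:6), c("MW", "nAT", "nC")))
  labels <- list(`1` = c("vanillin", "woody"),
                 `2` = "fruity",
                 `3` = c("fruity", "woody"),
                 `4` = "woody",
                 `5` = c("fruity", "vanillin"),
                 `6` = c("fruity", "vanillin"))
  odorant_dataset(vals, labels)
}

#' Filter descriptors: constants, missing values, correlated pairs
#'
#' Reproduces a standard descriptor-curation pass: drop constant columns, drop
#' columns containing missing values, then greedily prune correlated columns.
#' Columns are visited in file order; a column is dropped when its absolute
#' Pearson correlation with an already-kept column exceeds
#' `correlation_threshold` (the earlier column is kept).
#'
#' @param dataset an [odorant_dataset()].
#' @param drop_constant,drop_missing logical flags.
#' @param correlation_threshold in (0, 1]; pairwise-complete Pearson.
#' @return list with `dataset` (filtered) and `report` (data.frame of
#'   `descriptor`, `reason`, `detail`).
#' @export
filter_descriptors <- function(dataset, drop_constant = TRUE,
                               drop_missing = TRUE,
                               correlation_threshold = 0.85) {
  if (!is.numeric(correlation_threshold) || length(correlation_threshold) != 1 ||
      correlation_threshold <= 0 || correlation_threshold > 1)
    stop("correlation_threshold must lie in (0, 1]")
  v <- dataset$values
  report <- data.frame(descriptor = character(0), reason = character(0),
                       detail = character(0), stringsAsFactors = FALSE)
  add <- function(nm, reason, detail = "") {
    report <<- rbind(report, data.frame(descriptor = nm, reason = reason,
                                        detail = detail,
                                        stringsAsFactors = FALSE))
  }
  keep <- colnames(v)
  if (drop_constant) {
    for (j in keep) {
      u <- unique(v[, j][!is.na(v[, j])])
      if (length(u) <= 1L) add(j, "constant")
    }
    keep <- setdiff(keep, report$descriptor)
  }
  if (drop_missing) {
    for (j in keep) if (anyNA(v[, j])) add(j, "missing")
    keep <- setdiff(keep, report$descriptor)
  }
  if (length(keep) >= 2) {
    cm <- suppressWarnings(
      stats::cor(v[, keep, drop = FALSE], use = "pairwise.complete.obs"))
    kept <- character(0)
    for (j in keep) {
      r <- if (length(kept)) abs(cm[j, kept]) else numeric(0)
      r[is.na(r)] <- 0
      if (length(r) && any(r > correlation_threshold)) {
        partner <- kept[which.max(r)]
        add(j, "correlated", sprintf("|r|=%.4f with %s", max(r), partner))
      } else kept <- c(kept, j)
    }
    keep <- kept
  }
  out <- dataset
  out$values <- v[, keep, drop = FALSE]
  out$descriptors <- keep
  list(dataset = out, report = report)
}

#' Fraction of summed column variance retained by a descriptor subset
#'
#' Ratio of the summed per-column variances of `subset` to that of all
#' descriptors, computed on raw (unstandardized) values with missing entries
#' removed per column. This is a simple summed-variance definition of
#' "variance retained"; set `standardize = TRUE` to compute it on z-scored
#' columns (each complete column then contributes variance 1).
#'
#' @param dataset an [odorant_dataset()].
#' @param subset character vector of descriptor names (may be empty).
#' @param standardize divide each column by its standard deviation first.
#' @return a number in \[0, 1\].
#' @export
variance_retained <- function(dataset, subset, standardize = FALSE) {
  if (!length(dataset$descriptors) || !nrow(dataset$values))
    stop("empty dataset")
  if (!length(subset)) return(0)
  subset <- as.character(subset)
  bad <- setdiff(subset, dataset$descriptors)
  if (length(bad))
    stop("unknown descriptors: ", paste(bad, collapse = ", "))
  colvar <- apply(dataset$values, 2, stats::var, na.rm = TRUE)
  colvar[is.na(colvar)] <- 0
  if (standardize) colvar <- as.numeric(colvar > 0)
  tot <- sum(colvar)
  if (tot == 0) return(0)
  sum(colvar[unique(subset)]) / tot
}

#' Summarize an odorant dataset
#'
#' Counts of molecules and qualities, mean/min/max labels per molecule, and
#' per-quality support (number of molecules carrying each label).
#'
#' @param dataset an [odorant_dataset()].
#' @return a list of class `DatasetSummary`.
#' @export
summarize_dataset <- function(dataset) {
  nlab <- vapply(dataset$labels, length, 1L)
  all_labels <- unlist(dataset$labels, use.names = FALSE)
  support <- table(factor(all_labels, levels = dataset$qualities))
  structure(list(
    n_molecules = length(dataset$ids),
    n_descriptors = length(dataset$descriptors),
    n_qualities = length(dataset$qualities),
    mean_labels_per_molecule = if (length(nlab)) mean(nlab) else 0,
    min_labels_per_molecule = if (length(nlab)) min(nlab) else 0L,
    max_labels_per_molecule = if (length(nlab)) max(nlab) else 0L,
    per_quality_support = stats::setNames(as.integer(support),
                                          names(support))),
    class = "DatasetSummary")
}

#' @export
print.DatasetSummary <- function(x, ...) {
  cat(sprintf(
    "%d molecules, %d descriptors, %d qualities; labels/molecule mean %.2f (min %d, max %d)\n",
    x$n_molecules, x$n_descriptors, x$n_qualities,
    x$mean_labels_per_molecule, x$min_labels_per_molecule,
    x$max_labels_per_molecule))
  if (x$n_qualities) {
    s <- x$per_quality_support
    cat(sprintf("per-quality support: mean %.2f, min %d, max %d\n",
                mean(s), min(s), max(s)))
  }
  invisible(x)
}
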