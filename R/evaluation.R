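# Cluster-quality evaluation against a ground-truth individual id.
#
# Clusters fall into four categories.  Type I (perfect): all the records of
# one individual and nothing else.  Type II: records of only one individual,
# but not all of them.  Type III: all the records of at least one individual
# mixed with records of others.  Type IV: fragments of several individuals.
# Every record inherits its cluster's label, and the categories are reported
# as record counts and percentages.  A cluster satisfying several narratives
# is labelled with precedence I > II > III > IV.  The accuracy measure
# extends two-class ROC accuracy to many classes: each cluster is owned by
# the individual holding the majority of its records (ties broken by the
# smallest individual id) and a record is correct iff it belongs to its
# cluster's owner.

truth_table <- function(truth) {
  dt <- data.table::as.data.table(truth)
  need <- c("dataset_id", "row_index", "individual")
  if (!all(need %in% names(dt)))
    stop("truth must have columns: ", paste(need, collapse = ", "))
  dt[, dataset_id := as.character(dataset_id)]
  dt[, row_index := as.integer(row_index)]
  dt[, individual := as.character(individual)]
  dt[, need, with = FALSE]
}

# Join a clustering with the truth; error if any record lacks a truth entry.
joined_truth <- function(clustering, truth) {
  tt <- truth_table(truth)
  asg <- clustering$assignments[, list(cluster_id, dataset_id, row_index)]
  j <- merge(asg, tt, by = c("dataset_id", "row_index"), all.x = TRUE,
             sort = FALSE)
  if (anyNA(j$individual)) {
    miss <- j[is.na(individual)][1L]
    stop("record (", miss$dataset_id, ", ", miss$row_index,
         ") is missing from the truth mapping")
  }
  j
}

#' Classify clusters into quality categories (Type I-IV)
#'
#' @param clustering an `rl_clusters` object.
#' @param truth data.frame with columns `dataset_id`, `row_index`,
#'   `individual`, covering every clustered record.
#' @return data.table with one row per cluster: `cluster_id`, `size`,
#'   `type` (factor `I`/`II`/`III`/`IV`).
#' @export
classify_clusters <- function(clustering, truth) {
  j <- joined_truth(clustering, truth)
  totals <- j[, list(total = .N), by = individual]
  per <- j[, list(count = .N), by = list(cluster_id, individual)]
  per <- merge(per, totals, by = "individual", sort = FALSE)
  stats <- per[, list(
    size = sum(count),
    pure = .N == 1L,
    complete_any = any(count == total)
  ), by = cluster_id]
  stats[, type := ifelse(pure & complete_any, "I",
                  ifelse(pure, "II",
                  ifelse(complete_any, "III", "IV")))]
  stats[, type := factor(type, levels = c("I", "II", "III", "IV"))]
  data.table::setorder(stats, cluster_id)
  stats[, list(cluster_id, size, type)]
}

#' Majority-owner (ROC-extended) accuracy
#'
#' @inheritParams classify_clusters
#' @return fraction in \[0, 1\]: records belonging to their cluster's
#'   majority owner, divided by the total number of records.
#' @export
roc_accuracy <- function(clustering, truth) {
  j <- joined_truth(clustering, truth)
  if (nrow(j) == 0L) stop("clustering contains no records")
  per <- j[, list(count = .N), by = list(cluster_id, individual)]
  data.table::setorder(per, cluster_id, -count, individual)
  correct <- per[, list(correct = count[1L]), by = cluster_id]
  sum(correct$correct) / nrow(j)
}

#' Evaluate a clustering against ground truth
#'
#' @inheritParams classify_clusters
#' @return an object of class `rl_evaluation`: per-type record counts and
#'   percentages, the correct-label count and the accuracy fraction.
#' @export
evaluate_clustering <- function(clustering, truth) {
  cls <- classify_clusters(clustering, truth)
  n <- sum(cls$size)
  counts <- vapply(levels(cls$type), function(tp) sum(cls$size[cls$type == tp]),
                   numeric(1))
  acc <- roc_accuracy(clustering, truth)
  structure(
    list(
      n_records = n,
      n_clusters = nrow(cls),
      type_counts = counts,
      type_pct = 100 * counts / n,
      correct_labels = round(acc * n),
      accuracy = acc
    ),
    class = "rl_evaluation"
  )
}

#' @export
print.rl_evaluation <- function(x, ...) {
  cat("<rl_evaluation> ", x$n_records, " records in ", x$n_clusters,
      " cluster(s)\n", sep = "")
  for (tp in names(x$type_counts))
    cat(sprintf("  Type %-3s %10d records  (%6.2f%%)\n", tp,
                as.integer(x$type_counts[[tp]]), x$type_pct[[tp]]))
  cat(sprintf("  correct labels: %d / %d  (accuracy %.4f)\n",
              as.integer(x$correct_labels), x$n_records, x$accuracy))
  invisible(x)
}

#' Write an evaluation report as flat key-value lines
#'
#' @param report an `rl_evaluation` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "rl_evaluation"))
  lines <- c(
    paste0("n_records = ", report$n_records),
    paste0("n_clusters = ", report$n_clusters),
    vapply(names(report$type_counts), function(tp) {
      paste0("type_", tp, "_records = ", as.integer(report$type_counts[[tp]]))
    }, character(1)),
    vapply(names(report$type_pct), function(tp) {
      paste0("type_", tp, "_pct = ", format(report$type_pct[[tp]], digits = 15))
    }, character(1)),
    paste0("correct_labels = ", as.integer(report$correct_labels)),
    paste0("accuracy = ", format(report$accuracy, digits = 15))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Derive a truth mapping from a dataset attribute
#'
#' Convenience for corpora whose ground truth is carried by a unique
#' attribute (e.g. a social security number).
#'
#' @param datasets list of [rl_dataset()] objects.
#' @param attribute truth attribute name; must be present in every dataset.
#' @return data.frame with columns `dataset_id`, `row_index`, `individual`.
#' @export
truth_from_attribute <- function(datasets, attribute) {
  if (inherits(datasets, "rl_dataset")) datasets <- list(datasets)
  parts <- lapply(datasets, function(d) {
    if (!attribute %in% d$attributes)
      stop("truth attribute '", attribute, "' missing from dataset '",
           d$dataset_id, "'")
    data.table::data.table(dataset_id = d$dataset_id,
                           row_index = seq_len(d$n) - 1L,
                           individual = d$records[[attribute]])
  })
  as.data.frame(data.table::rbindlist(parts))
}
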