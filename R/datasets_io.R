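# Record data model and file formats shared by every pipeline stage.
#
# A dataset is one tabular source: an identifier, an ordered attribute list
# (its schema) and character-valued records.  Values are kept verbatim;
# normalisation (upper-casing) happens when a corpus is built, so output
# files always show the original casing.

#' Construct a dataset from in-memory records
#'
#' @param dataset_id single string identifying the source.
#' @param data a data.frame (or coercible) of character values; column names
#'   are the dataset's attribute names.
#' @return an object of class `rl_dataset` with fields `dataset_id`,
#'   `attributes`, `records` (data.frame of characters) and `n`.
#' @export
rl_dataset <- function(dataset_id, data) {
  if (!is.character(dataset_id) || length(dataset_id) != 1L || is.na(dataset_id))
    stop("'dataset_id' must be a single string")
  data <- as.data.frame(data, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(names(data)))
    stop("duplicate attribute names in dataset '", dataset_id, "': ",
         paste(unique(names(data)[duplicated(names(data))]), collapse = ", "))
  for (j in seq_along(data)) data[[j]] <- as.character(data[[j]])
  rownames(data) <- NULL
  structure(
    list(dataset_id = dataset_id, attributes = names(data),
         records = data, n = nrow(data)),
    class = "rl_dataset"
  )
}

#' @export
print.rl_dataset <- function(x, ...) {
  cat("<rl_dataset> '", x$dataset_id, "': ", x$n, " records, attributes [",
      paste(x$attributes, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Read a dataset from a headered CSV file
#'
#' The first row must be a header of attribute names.  Values are read as
#' character strings and preserved verbatim (leading zeros included); empty
#' fields become empty strings, not missing values.
#'
#' @param path CSV file path.
#' @param dataset_id identifier for the source; defaults to the file name
#'   without extension.
#' @return an [rl_dataset()].
#' @export
read_dataset <- function(path,
                         dataset_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  hdr <- utils::read.csv(path, header = FALSE, nrows = 1L,
                         colClasses = "character", na.strings = character())
  hdr <- as.character(unlist(hdr, use.names = FALSE))
  if (length(hdr) == 0L || all(!nzchar(hdr)))
    stop("empty or missing header row in ", path)
  if (anyDuplicated(hdr))
    stop("duplicate header names in ", path, ": ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  body <- tryCatch(
    utils::read.csv(path, header = FALSE, skip = 1L, col.names = hdr,
                    colClasses = "character", na.strings = character(),
                    check.names = FALSE, fill = FALSE,
                    blank.lines.skip = TRUE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(as.data.frame(matrix(character(), 0, length(hdr),
                                    dimnames = list(NULL, hdr)),
                             stringsAsFactors = FALSE))
      stop("malformed CSV in ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  names(body) <- hdr
  rl_dataset(dataset_id, body)
}

#' Assemble datasets into a record corpus
#'
#' Builds the internal record table shared by all stages: one row per record
#' (`uid` 1..N), with one column per attribute across the union of schemas.
#' `NA` marks an attribute absent from a record's schema; an empty string is
#' a present-but-empty value.  A parallel table of upper-cased values is kept
#' for blocking and distance computation.
#'
#' @param datasets list of [rl_dataset()] objects with distinct ids.
#' @return an object of class `rl_corpus`.
#' @export
build_corpus <- function(datasets) {
  if (inherits(datasets, "rl_dataset")) datasets <- list(datasets)
  if (length(datasets) == 0L) stop("at least one dataset is required")
  ids <- vapply(datasets, function(d) d$dataset_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate dataset ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  attrs <- unique(unlist(lapply(datasets, function(d) d$attributes)))
  parts <- lapply(datasets, function(d) {
    dt <- data.table::data.table(
      dataset_id = rep(d$dataset_id, d$n),
      row_index = seq_len(d$n) - 1L  # 0-based row indexing throughout
    )
    for (a in attrs) dt[[a]] <- if (a %in% d$attributes) d$records[[a]] else NA_character_
    dt
  })
  records <- data.table::rbindlist(parts)
  records[, uid := seq_len(.N)]
  data.table::setcolorder(records, c("uid", "dataset_id", "row_index", attrs))
  norm <- data.table::as.data.table(lapply(records[, attrs, with = FALSE], toupper))
  schemas <- lapply(datasets, function(d) d$attributes)
  names(schemas) <- ids
  structure(
    list(records = records, norm = norm, attributes = attrs,
         schemas = schemas, dataset_ids = ids, n = nrow(records)),
    class = "rl_corpus"
  )
}

#' @export
print.rl_corpus <- function(x, ...) {
  cat("<rl_corpus> ", x$n, " records from ", length(x$dataset_ids),
      " dataset(s); attributes [", paste(x$attributes, collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

# ---- configuration ---------------------------------------------------------

.distance_methods <- c("edit", "reversal", "truncation")

#' Build a linkage configuration
#'
#' @param blocking blocking specification: either a character vector of
#'   attribute names (each gets the default `k = 3`, `alphabet = "letters26"`)
#'   or a data.frame with columns `attribute`, `k`, `alphabet`.
#' @param comparison ordered character vector of comparison attributes.
#' @param threshold non-negative integer: the maximum total number of edit
#'   errors tolerated between two records considered a match.
#' @param method distance method: `"edit"`, `"reversal"` or `"truncation"`.
#' @param priority ordered character vector of priority attributes used to
#'   break assignment ties after complete linkage (may be empty).
#' @param truth optional name of a ground-truth attribute (e.g. `"ssn"`).
#' @param proportional if `TRUE`, the per-pair threshold becomes
#'   `ceiling(rho * min(total value length))` instead of the constant
#'   `threshold`.
#' @param rho proportional threshold rate in (0, 1]; only used when
#'   `proportional = TRUE`.
#' @return an object of class `rl_config`.
#' @export
link_config <- function(blocking, comparison, threshold, method = "edit",
                        priority = character(), truth = NULL,
                        proportional = FALSE, rho = 0.1) {
  if (is.character(blocking))
    blocking <- data.frame(attribute = blocking, k = 3L,
                           alphabet = "letters26", stringsAsFactors = FALSE)
  blocking <- as.data.frame(blocking, stringsAsFactors = FALSE)
  if (!all(c("attribute", "k", "alphabet") %in% names(blocking)))
    stop("'blocking' needs columns attribute, k, alphabet")
  if (nrow(blocking) == 0L) stop("at least one blocking attribute is required")
  blocking$k <- as.integer(blocking$k)
  if (anyNA(blocking$k) || any(blocking$k < 1L)) stop("each blocking k must be >= 1")
  for (al in blocking$alphabet) alphabet_chars(al)
  comparison <- as.character(comparison)
  if (length(comparison) == 0L) stop("'comparison' must name at least one attribute")
  threshold <- suppressWarnings(as.integer(threshold))
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0L)
    stop("'threshold' must be a single non-negative integer")
  if (!is.character(method) || length(method) != 1L ||
      !method %in% .distance_methods)
    stop("'method' must be one of: ", paste(.distance_methods, collapse = ", "))
  priority <- as.character(priority)
  if (!is.null(truth)) {
    truth <- as.character(truth)
    if (length(truth) != 1L) stop("'truth' must be a single attribute name")
  }
  if (!is.logical(proportional) || length(proportional) != 1L || is.na(proportional))
    stop("'proportional' must be TRUE or FALSE")
  rho <- as.numeric(rho)
  if (proportional && (length(rho) != 1L || is.na(rho) || rho <= 0 || rho > 1))
    stop("'rho' must be in (0, 1]")
  structure(
    list(blocking = blocking, comparison = comparison, threshold = threshold,
         method = method, priority = priority, truth = truth,
         proportional = proportional, rho = rho),
    class = "rl_config"
  )
}

#' @export
print.rl_config <- function(x, ...) {
  bs <- paste(sprintf("%s (k=%d, %s)", x$blocking$attribute, x$blocking$k,
                      x$blocking$alphabet), collapse = ", ")
  cat("<rl_config>\n",
      "  blocking:   ", bs, "\n",
      "  comparison: ", paste(x$comparison, collapse = ", "), "\n",
      "  method:     ", x$method,
      if (x$proportional) sprintf(" (proportional, rho=%g)", x$rho) else "", "\n",
      "  threshold:  ", x$threshold, "\n",
      "  priority:   ", if (length(x$priority)) paste(x$priority, collapse = ", ")
                        else "(none)", "\n",
      "  truth:      ", x$truth %||% "(none)", "\n", sep = "")
  invisible(x)
}

#' Read a configuration file
#'
#' The format is flat `key = value` lines (the `=` is optional; `#` starts a
#' comment).  Recognised keys:
#'
#' * `blocking` — comma-separated blocking specs, each
#'   `attribute[:k=INT][:alphabet=ID]` with defaults `k=3`,
#'   `alphabet=letters26`; alphabet ids are `letters26`, `digits10`,
#'   `alnum36`.
#' * `comparison` — comma-separated attribute names (required).
#' * `threshold` — non-negative integer (required).
#' * `method` — `edit` (default), `reversal` or `truncation`.
#' * `priority` — comma-separated attribute names (optional).
#' * `truth` — ground-truth attribute name (optional).
#' * `proportional` — `true`/`false` (default false); `rho` — rate in (0,1].
#'
#' Unknown keys are an error.
#'
#' @param path configuration file path.
#' @return an [link_config()] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=?\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L || !nzchar(m[2]))
      stop("cannot parse config line: '", ln, "'")
    kv[[m[2]]] <- trimws(m[3])
  }
  known <- c("blocking", "comparison", "threshold", "method", "priority",
             "truth", "proportional", "rho")
  unknown <- setdiff(names(kv), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (req in c("blocking", "comparison", "threshold"))
    if (is.null(kv[[req]])) stop("configuration key '", req, "' is required")
  split_list <- function(x) trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  parse_block <- function(spec) {
    parts <- trimws(strsplit(spec, ":", fixed = TRUE)[[1]])
    out <- list(attribute = parts[1], k = 3L, alphabet = "letters26")
    for (p in parts[-1]) {
      pm <- regmatches(p, regexec("^(k|alphabet)\\s*=\\s*(.+)$", p))[[1]]
      if (length(pm) != 3L) stop("cannot parse blocking spec '", spec, "'")
      if (pm[2] == "k") out$k <- as.integer(pm[3]) else out$alphabet <- pm[3]
    }
    out
  }
  blocks <- lapply(split_list(kv$blocking), parse_block)
  blocking <- data.frame(
    attribute = vapply(blocks, `[[`, "", "attribute"),
    k = vapply(blocks, `[[`, 1L, "k"),
    alphabet = vapply(blocks, `[[`, "", "alphabet"),
    stringsAsFactors = FALSE
  )
  parse_bool <- function(x) {
    if (is.null(x)) return(FALSE)
    lx <- tolower(x)
    if (lx %in% c("true", "yes", "1")) return(TRUE)
    if (lx %in% c("false", "no", "0")) return(FALSE)
    stop("cannot parse logical value '", x, "'")
  }
  link_config(
    blocking = blocking,
    comparison = split_list(kv$comparison),
    threshold = kv$threshold,
    method = kv$method %||% "edit",
    priority = if (is.null(kv$priority)) character() else split_list(kv$priority),
    truth = kv$truth,
    proportional = parse_bool(kv$proportional),
    rho = as.numeric(kv$rho %||% 0.1)
  )
}

# ---- clustering output -----------------------------------------------------

# Internal constructor: clusters = list of uid vectors over a corpus.
# Cluster ids are assigned by each cluster's smallest (dataset_id, row_index)
# member so that output files are reproducible bit-for-bit.
final_clustering <- function(clusters, corpus) {
  if (length(clusters) == 0L) {
    asg <- data.table::data.table(cluster_id = integer(),
                                  dataset_id = character(),
                                  row_index = integer(), uid = integer())
    return(structure(list(assignments = asg, n_clusters = 0L, n_records = 0L),
                     class = "rl_clusters"))
  }
  uid <- unlist(clusters, use.names = FALSE)
  cl <- rep(seq_along(clusters), lengths(clusters))
  asg <- data.table::data.table(
    cl = cl, uid = uid,
    dataset_id = corpus$records$dataset_id[uid],
    row_index = corpus$records$row_index[uid]
  )
  key <- asg[order(dataset_id, row_index), .(dataset_id = dataset_id[1],
                                             row_index = row_index[1]), by = cl]
  key <- key[order(dataset_id, row_index)]
  key[, cluster_id := seq_len(.N)]
  asg <- merge(asg, key[, .(cl, cluster_id)], by = "cl", sort = FALSE)
  asg <- asg[order(cluster_id, dataset_id, row_index),
             .(cluster_id, dataset_id, row_index, uid)]
  structure(list(assignments = asg, n_clusters = nrow(key),
                 n_records = nrow(asg)),
            class = "rl_clusters")
}

#' @export
print.rl_clusters <- function(x, ...) {
  cat("<rl_clusters> ", x$n_records, " records in ", x$n_clusters,
      " cluster(s)\n", sep = "")
  invisible(x)
}

#' Write a clustering to CSV
#'
#' One line per record with columns `cluster_id, dataset_id, row_index`,
#' sorted by those columns, so equal clusterings always produce byte-equal
#' files.
#'
#' @param clustering an `rl_clusters` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clustering, path) {
  stopifnot(inherits(clustering, "rl_clusters"))
  out <- clustering$assignments[order(cluster_id, dataset_id, row_index),
                                .(cluster_id, dataset_id, row_index)]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a clustering written by [write_clusters()]
#' @param path CSV file with columns `cluster_id, dataset_id, row_index`.
#' @return an `rl_clusters` object (without `uid` back-references).
#' @export
read_clusters <- function(path) {
  if (!file.exists(path)) stop("clusters file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = "dataset_id"))
  need <- c("cluster_id", "dataset_id", "row_index")
  if (!all(need %in% names(dt)))
    stop("clusters file must have columns: ", paste(need, collapse = ", "))
  dt <- dt[order(cluster_id, dataset_id, row_index)]
  dt[, uid := NA_integer_]
  structure(list(assignments = dt[, .(cluster_id, dataset_id, row_index, uid)],
                 n_clusters = data.table::uniqueN(dt$cluster_id),
                 n_records = nrow(dt)),
            class = "rl_clusters")
}
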