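# Exact-duplicate elimination.
#
# For every comparable pair of datasets (the attributes of one form a subset
# of the other's, self-pairs included) records are serialised to sort keys
# over the pair's common attributes, radix-sorted, and runs of equal keys are
# merged.  Merges from all pairs are accumulated with a union-find structure,
# yielding a partition of the corpus into clusters of identical records; one
# representative per cluster carries on to the approximate stages.

#' Comparable dataset pairs
#'
#' A pair `(X, Y)` is comparable when the attributes of `X` form a subset of
#' the attributes of `Y` (as sets).  Self-pairs `(X, X)` are included so that
#' duplicates within a single source are caught.  Order follows the input
#' dataset order, making the result deterministic.
#'
#' @param datasets list of [rl_dataset()] objects.
#' @return data.frame with columns `x`, `y` of dataset ids.
#' @export
comparable_pairs <- function(datasets) {
  if (inherits(datasets, "rl_dataset")) datasets <- list(datasets)
  if (length(datasets) == 0L) stop("at least one dataset is required")
  ids <- vapply(datasets, function(d) d$dataset_id, character(1))
  schemas <- lapply(datasets, function(d) d$attributes)
  xs <- character(); ys <- character()
  for (i in seq_along(datasets)) {
    for (j in seq_along(datasets)) {
      if (all(schemas[[i]] %in% schemas[[j]])) {
        xs <- c(xs, ids[i]); ys <- c(ys, ids[j])
      }
    }
  }
  data.frame(x = xs, y = ys, stringsAsFactors = FALSE)
}

#' Serialise records to sort keys
#'
#' Concatenates the (upper-cased) values of `attributes`, in order, joined by
#' a reserved separator character that lies outside all blocking alphabets.
#' Records identical on `attributes` therefore receive identical keys.
#'
#' @param values a named list / data.frame of character vectors (one element
#'   per attribute), or a single named character vector for one record.
#' @param attributes ordered attribute names to serialise.
#' @return character vector of keys.
#' @export
sort_key <- function(values, attributes) {
  if (is.character(values) && !is.null(names(values)))
    values <- as.list(values)
  n <- if (length(values)) length(values[[1]]) else 1L
  if (length(attributes) == 0L) return(rep("", n))
  cols <- lapply(attributes, function(a) {
    v <- values[[a]]
    if (is.null(v)) stop("attribute '", a, "' missing from record values")
    if (anyNA(v)) stop("attribute '", a, "' is absent (NA) for some records")
    toupper(v)
  })
  do.call(paste, c(cols, sep = .SEP))
}

#' Stable radix sort of string keys
#'
#' Least-significant-character radix sort: keys are padded (conceptually)
#' with a zero byte and sorted with one stable counting pass per character
#' position.  Equal keys keep their input order.
#'
#' @param keys character vector.
#' @param alphabet optional character vector of permitted characters; when
#'   supplied, a key containing any other character is an error naming that
#'   character.  The reserved separator and pad characters are always
#'   permitted.
#' @return integer permutation `p` such that `keys[p]` is sorted.
#' @export
radix_sort <- function(keys, alphabet = NULL) {
  n <- length(keys)
  if (n == 0L) return(integer())
  codes <- lapply(keys, utf8ToInt)
  L <- max(lengths(codes), 1L)
  if (!is.null(alphabet)) {
    allowed <- c(unlist(lapply(c(alphabet, .SEP, .PAD), utf8ToInt),
                        use.names = FALSE))
    bad <- setdiff(unique(unlist(codes, use.names = FALSE)), allowed)
    if (length(bad))
      stop("key character(s) outside the declared alphabet: ",
           paste(vapply(bad, intToUtf8, ""), collapse = ", "))
  }
  mat <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    ci <- codes[[i]]
    if (length(ci)) mat[i, seq_along(ci)] <- ci
  }
  ord <- seq_len(n)
  for (p in L:1) {
    cd <- mat[ord, p]
    nb <- max(cd) + 1L
    cnt <- tabulate(cd + 1L, nbins = nb)
    start <- cumsum(c(0L, cnt))[cd + 1L]
    pos <- start + data.table::rowid(cd)
    nxt <- integer(n)
    nxt[pos] <- ord
    ord <- nxt
  }
  ord
}

# Equal-key merges for one sorted batch.  `anchor` marks records that may
# merge with anyone in their run (within-pair semantics for cross-schema
# batches: two records of the superset-schema side merge only through an
# anchor record of the subset-schema side).  Returns a two-column matrix of
# uid edges.
equal_run_edges <- function(keys, uids, anchor = rep(TRUE, length(uids))) {
  if (length(keys) < 2L) return(NULL)
  ord <- radix_sort(keys)
  dt <- data.table::data.table(skey = keys[ord], uid = uids[ord],
                               anchor = anchor[ord])
  dt[, run := data.table::rleid(skey)]
  edges <- dt[, {
    if (.N > 1L && any(anchor)) {
      a <- uid[which(anchor)[1L]]
      others <- uid[uid != a]
      list(u = rep(a, length(others)), v = others)
    } else list(u = integer(), v = integer())
  }, by = run]
  if (nrow(edges) == 0L) NULL else cbind(edges$u, edges$v)
}

#' Find clusters of identical records
#'
#' For each comparable dataset pair, records equal on the pair's common
#' attributes are merged; merges accumulate across all pairs by transitive
#' closure (union-find), so the result partitions the corpus.  Datasets with
#' identical schemas are sorted in one combined batch (equality is transitive
#' on a fixed attribute set), which is result-equivalent to processing each
#' pair separately.
#'
#' @param datasets list of [rl_dataset()] objects.
#' @param corpus optional pre-built [build_corpus()] of the same datasets.
#' @param workers number of parallel workers for the sorting batches; results
#'   are identical for any value.
#' @return an object of class `rl_exact` with fields `corpus`, `membership`
#'   (integer vector uid -> cluster), `clusters` (list of uid vectors,
#'   ordered by smallest member), `representatives` (uid per cluster) and
#'   `n_clusters`.
#' @export
find_exact_clusters <- function(datasets, corpus = build_corpus(datasets),
                                workers = 1L) {
  if (inherits(datasets, "rl_dataset")) datasets <- list(datasets)
  N <- corpus$n
  ids <- corpus$dataset_ids
  dsindex <- split(seq_len(N), factor(corpus$records$dataset_id, levels = ids))
  schemas <- corpus$schemas
  sig <- vapply(schemas, function(a) paste(sort(a), collapse = .SEP), character(1))
  groups <- split(seq_along(ids), factor(sig, levels = unique(sig)))

  batches <- list()
  # within a schema group: one combined batch, all records are anchors
  for (g in groups) {
    uids <- unlist(dsindex[g], use.names = FALSE)
    if (length(uids) < 2L) next
    batches[[length(batches) + 1L]] <-
      list(uids = uids, attrs = schemas[[g[1L]]],
           anchor = rep(TRUE, length(uids)))
  }
  # strict subset relations across schema groups: records of the
  # subset-schema side anchor the merges (pairwise-pair semantics)
  gl <- unname(groups)
  for (i in seq_along(gl)) {
    for (j in seq_along(gl)) {
      if (i == j) next
      ai <- schemas[[gl[[i]][1L]]]; aj <- schemas[[gl[[j]][1L]]]
      if (all(ai %in% aj) && !all(aj %in% ai)) {
        ui <- unlist(dsindex[gl[[i]]], use.names = FALSE)
        uj <- unlist(dsindex[gl[[j]]], use.names = FALSE)
        batches[[length(batches) + 1L]] <-
          list(uids = c(ui, uj), attrs = ai,
               anchor = c(rep(TRUE, length(ui)), rep(FALSE, length(uj))))
      }
    }
  }

  run_batch <- function(b) {
    vals <- lapply(b$attrs, function(a) corpus$norm[[a]][b$uids])
    names(vals) <- b$attrs
    keys <- sort_key(vals, b$attrs)
    if (workers > 1L) {
      # shard each batch by key-prefix cells; equal keys share a cell, so
      # cell-wise grouping is exact
      part <- partition_prefix_ranges(36L, 2L, workers)
      cell <- prefix_cell(keys, 2L)
      grp <- integer(length(keys))
      for (gi in seq_along(part$groups)) grp[cell %in% part$groups[[gi]]] <- gi
      shards <- parallel::mclapply(seq_along(part$groups), function(gi) {
        sel <- grp == gi
        if (!any(sel)) return(NULL)
        equal_run_edges(keys[sel], b$uids[sel], b$anchor[sel])
      }, mc.cores = workers)
      bad <- vapply(shards, inherits, logical(1), "try-error")
      if (any(bad)) stop("parallel exact-match worker failed")
      do.call(rbind, shards[!vapply(shards, is.null, logical(1))])
    } else {
      equal_run_edges(keys, b$uids, b$anchor)
    }
  }
  edges <- do.call(rbind, Filter(Negate(is.null), lapply(batches, run_batch)))
  membership <- if (is.null(edges)) cpp_components(N, integer(), integer())
                else cpp_components(N, edges[, 1L], edges[, 2L])
  clusters <- unname(split(seq_len(N), membership))
  reps <- vapply(clusters, choose_representative, integer(1), corpus = corpus)
  structure(
    list(corpus = corpus, membership = membership, clusters = clusters,
         representatives = reps, n_clusters = length(clusters)),
    class = "rl_exact"
  )
}

#' @export
print.rl_exact <- function(x, ...) {
  cat("<rl_exact> ", x$corpus$n, " records -> ", x$n_clusters,
      " exact-match cluster(s)\n", sep = "")
  invisible(x)
}

#' Choose a cluster's representative record
#'
#' The member whose dataset schema has the most attributes; ties broken by
#' the smallest `(dataset_id, row_index)`.  Retaining the record with the
#' most attributes preserves comparison power in later stages.
#'
#' @param cluster integer vector of record uids.
#' @param corpus the [build_corpus()] the uids refer to.
#' @return a single uid.
#' @export
choose_representative <- function(cluster, corpus) {
  if (length(cluster) == 0L) stop("cluster must be non-empty")
  if (length(cluster) == 1L) return(cluster)
  nattr <- lengths(corpus$schemas)[corpus$records$dataset_id[cluster]]
  best <- cluster[nattr == max(nattr)]
  o <- order(corpus$records$dataset_id[best], corpus$records$row_index[best])
  best[o[1L]]
}
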