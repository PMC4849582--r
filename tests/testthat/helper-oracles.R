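# Independent oracles and fixture builders used across the suite.

# Full-matrix Levenshtein oracle (unbounded), via the generalised edit
# distance in base R.
lev_oracle <- function(a, b) drop(utils::adist(a, b))

# Stable comparison-based merge sort on byte codes, locale-free; the
# independent oracle for radix_sort().
merge_sort_order <- function(keys) {
  codes <- lapply(keys, utf8ToInt)
  le <- function(x, y) {
    l <- min(length(x), length(y))
    if (l > 0) {
      for (t in seq_len(l)) {
        if (x[t] < y[t]) return(TRUE)
        if (x[t] > y[t]) return(FALSE)
      }
    }
    length(x) <= length(y)
  }
  ms <- function(idx) {
    n <- length(idx)
    if (n <= 1L) return(idx)
    mid <- n %/% 2L
    L <- ms(idx[seq_len(mid)])
    R <- ms(idx[(mid + 1L):n])
    out <- integer(n); i <- 1L; j <- 1L; k <- 1L
    while (i <= length(L) && j <= length(R)) {
      if (le(codes[[L[i]]], codes[[R[j]]])) { out[k] <- L[i]; i <- i + 1L }
      else { out[k] <- R[j]; j <- j + 1L }
      k <- k + 1L
    }
    while (i <= length(L)) { out[k] <- L[i]; i <- i + 1L; k <- k + 1L }
    while (j <= length(R)) { out[k] <- R[j]; j <- j + 1L; k <- k + 1L }
    out
  }
  ms(seq_along(keys))
}

# All set partitions of 1..n as lists of integer vectors.
set_partitions <- function(n) {
  if (n == 0L) return(list(list()))
  out <- list()
  for (p in set_partitions(n - 1L)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# Direct implementations of the cluster-category definitions and the
# majority-owner accuracy, on a partition (list of index vectors) and a
# truth vector indexed by record.
classify_oracle <- function(partition, truth) {
  vapply(partition, function(S) {
    inds <- truth[S]
    u <- unique(inds)
    pure <- length(u) == 1L
    complete_any <- any(vapply(u, function(x)
      sum(inds == x) == sum(truth == x), logical(1)))
    if (pure && complete_any) "I"
    else if (pure) "II"
    else if (complete_any) "III"
    else "IV"
  }, character(1))
}

roc_oracle <- function(partition, truth) {
  correct <- vapply(partition, function(S) {
    tab <- table(truth[S])           # names sorted, so which.max breaks
    as.numeric(tab[which.max(tab)])  # ties by smallest individual id
  }, numeric(1))
  sum(correct) / length(truth)
}

# The three-record chain whose middle element links both ends while the
# ends are 2 apart: one single-linkage component at threshold 1, never one
# complete-linkage cluster.
chaining_fixture <- function() {
  A <- rl_dataset("A", data.frame(status = "sweat", type = "exercise",
                                  place = "gymnesium", stringsAsFactors = FALSE))
  B <- rl_dataset("B", data.frame(status = "sheat", place = "gymnesium",
                                  stringsAsFactors = FALSE))
  C <- rl_dataset("C", data.frame(status = "heat", stringsAsFactors = FALSE))
  cfg <- link_config(blocking = "status",
                     comparison = c("status", "type", "place"),
                     threshold = 1)
  list(datasets = list(A, B, C), config = cfg)
}

random_word <- function(len, alphabet = LETTERS) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# A single noisy dataset over a tiny alphabet: dense near-duplicates, so
# chaining and non-trivial complete-linkage splits actually occur.
fuzzy_dataset <- function(n, alphabet = c("A", "B"), len = 5L, id = "X") {
  vals <- vapply(seq_len(n), function(i) random_word(len, alphabet), "")
  rl_dataset(id, data.frame(x = vals, stringsAsFactors = FALSE))
}

fuzzy_config <- function(tau = 1L, k = 2L) {
  link_config(blocking = data.frame(attribute = "x", k = k,
                                    alphabet = "letters26"),
              comparison = "x", threshold = tau)
}

# Raw attribute values of one record, as record_distance() expects them.
rec_vals <- function(corpus, id) {
  v <- vapply(corpus$attributes, function(a) corpus$records[[a]][id],
              character(1))
  names(v) <- corpus$attributes
  v
}

# Diameter invariant: within every final cluster, all representative-level
# pairs are within the threshold.
expect_diameter_ok <- function(res, cfg) {
  corpus <- res$exact$corpus
  reps <- res$exact$representatives
  asg <- res$clustering$assignments
  for (cid in unique(asg$cluster_id)) {
    r <- intersect(asg$uid[asg$cluster_id == cid], reps)
    if (length(r) < 2L) next
    for (i in seq_len(length(r) - 1L)) {
      for (j in (i + 1L):length(r)) {
        d <- record_distance(rec_vals(corpus, r[i]), rec_vals(corpus, r[j]), cfg)
        expect_lte(d, cfg$threshold)
      }
    }
  }
  invisible(TRUE)
}

# Build an rl_clusters from an arbitrary partition of corpus uids.
make_clusters <- function(partition, corpus) {
  linkclust:::final_clustering(partition, corpus)
}

one_attr_corpus <- function(n, id = "D") {
  build_corpus(list(rl_dataset(id, data.frame(v = sprintf("R%03d", seq_len(n)),
                                              stringsAsFactors = FALSE))))
}

simple_truth <- function(corpus, individual) {
  data.frame(dataset_id = corpus$records$dataset_id,
             row_index = corpus$records$row_index,
             individual = individual, stringsAsFactors = FALSE)
}
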