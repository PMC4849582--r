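# Within-component complete-linkage agglomeration, priority refinement and
# expansion back to the original records.
#
# Each single-linkage component is re-clustered from singletons: the pair of
# clusters at globally minimum complete-linkage distance (the furthest-pair
# rule, EXCEEDS treated as +Inf) is merged while that minimum stays within
# the threshold.  Every output cluster therefore has diameter <= tau, which
# is what breaks the chaining of single linkage.  A priority-attribute pass
# then reassigns records whose cluster membership was ambiguous, and exact
# clusters are expanded so the final partition covers the whole corpus.

#' Agglomerative complete linkage on a precomputed distance matrix
#'
#' Starts from singletons and repeatedly merges the pair of clusters with the
#' smallest complete-linkage distance while that minimum is at most `tau`;
#' on a merge the matrix is updated with the maximum rule
#' `d(i+j, k) = max(d(i,k), d(j,k))`.  Ties on the minimum distance are broken
#' by the lexicographically smallest pair of cluster minimum ids, making runs
#' reproducible.
#'
#' @param D square numeric distance matrix (`Inf` for distances beyond the
#'   threshold).
#' @param tau merge threshold.
#' @param ids optional item ids used for tie-breaking and output (defaults to
#'   row numbers).
#' @return list of integer id vectors (each sorted), ordered by smallest id;
#'   every returned cluster has all pairwise `D` entries at most `tau`.  The
#'   sequence of merge distances (non-decreasing, a standard complete-linkage
#'   property) is attached as attribute `"merge_distances"`.
#' @export
complete_linkage_matrix <- function(D, tau, ids = seq_len(nrow(D))) {
  m <- nrow(D)
  if (m != ncol(D)) stop("'D' must be square")
  if (length(ids) != m) stop("'ids' must match the matrix dimension")
  if (m == 0L) return(list())
  members <- lapply(seq_len(m), function(i) ids[i])
  minid <- as.numeric(ids)
  active <- rep(TRUE, m)
  D <- as.matrix(D)
  diag(D) <- Inf
  merge_d <- numeric()
  while (sum(active) > 1L) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    best <- min(sub)
    if (!is.finite(best) || best > tau) break
    w <- which(sub == best, arr.ind = TRUE)
    w <- w[w[, 1L] < w[, 2L], , drop = FALSE]
    ci <- act[w[, 1L]]; cj <- act[w[, 2L]]
    lo <- pmin(minid[ci], minid[cj]); hi <- pmax(minid[ci], minid[cj])
    pick <- order(lo, hi)[1L]
    i <- ci[pick]; j <- cj[pick]
    if (minid[j] < minid[i]) { tmp <- i; i <- j; j <- tmp }
    merge_d <- c(merge_d, best)
    members[[i]] <- c(members[[i]], members[[j]])
    minid[i] <- min(minid[i], minid[j])
    upd <- pmax(D[i, ], D[j, ])
    D[i, ] <- upd; D[, i] <- upd
    D[i, i] <- Inf
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
  }
  out <- lapply(which(active), function(i) sort(members[[i]]))
  out <- out[order(vapply(out, min, numeric(1)))]
  attr(out, "merge_distances") <- merge_d
  out
}

# Pairwise record-distance matrix of a component (EXCEEDS -> Inf).
component_distance_matrix <- function(uids, corpus, config) {
  m <- length(uids)
  D <- matrix(Inf, m, m)
  diag(D) <- 0
  if (m > 1L) {
    i <- rep.int(seq_len(m - 1L), rev(seq_len(m - 1L)))
    j <- sequence(rev(seq_len(m - 1L))) + i
    d <- pair_record_distance(uids[i], uids[j], corpus, config)
    D[cbind(i, j)] <- d
    D[cbind(j, i)] <- d
  }
  D
}

#' Complete-linkage clusters within one component
#'
#' @param component integer vector of representative uids (one single-linkage
#'   component).
#' @param corpus the [build_corpus()] the uids refer to.
#' @param config an [link_config()] object.
#' @return list of sorted uid vectors; every cluster has diameter at most the
#'   threshold.
#' @export
complete_linkage_cluster <- function(component, corpus, config) {
  if (length(component) == 0L) stop("component must be non-empty")
  if (length(component) == 1L) return(list(component))
  D <- component_distance_matrix(component, corpus, config)
  complete_linkage_matrix(D, config$threshold, ids = component)
}

#' Priority score of a record against a cluster
#'
#' With `m` priority attributes, attribute at rank `i` (from 1) contributes
#' `2^(m - i)` when the record's value exactly equals the cluster's majority
#' value for that attribute (ties in the vote broken by the lexicographically
#' smallest value; absent values do not vote).  The weighting makes a match
#' on a higher-priority attribute dominate any combination of lower ones.
#'
#' @param uid record uid.
#' @param cluster integer vector of member uids the record is scored against.
#' @param corpus the [build_corpus()].
#' @param priority_attributes ordered character vector (may be empty).
#' @return a non-negative number.
#' @export
priority_score <- function(uid, cluster, corpus, priority_attributes) {
  m <- length(priority_attributes)
  if (m == 0L || length(cluster) == 0L) return(0)
  s <- 0
  for (i in seq_len(m)) {
    p <- priority_attributes[i]
    if (!p %in% corpus$attributes) next
    maj <- majority_value(corpus$norm[[p]][cluster])
    rv <- corpus$norm[[p]][uid]
    if (!is.na(maj) && !is.na(rv) && rv == maj) s <- s + 2^(m - i)
  }
  s
}

majority_value <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) return(NA_character_)
  tab <- table(values)
  top <- names(tab)[tab == max(tab)]
  sort(top)[1L]
}

#' Refine clusters of one component with the priority list
#'
#' One deterministic pass over the component's records in uid order: record
#' `r` moves from its current cluster to another cluster `c` of the same
#' component only if (a) adding `r` keeps every pairwise distance in `c`
#' within the threshold (the diameter property is preserved) and (b) the
#' priority score of `r` against `c` strictly exceeds its score against its
#' current cluster without itself.  Among qualifying destinations the highest
#' score wins, ties broken by smallest member uid.  Emptied clusters are
#' dropped.
#'
#' @param clusters list of uid vectors (complete-linkage clusters of one
#'   component).
#' @param corpus the [build_corpus()].
#' @param config an [link_config()] object.
#' @return refined list of uid vectors, still satisfying the diameter
#'   property.
#' @export
refine_clusters <- function(clusters, corpus, config) {
  if (length(config$priority) == 0L || length(clusters) < 2L) return(clusters)
  tau <- config$threshold
  all_uids <- sort(unlist(clusters, use.names = FALSE))
  for (r in all_uids) {
    ci <- which(vapply(clusters, function(cl) r %in% cl, logical(1)))[1L]
    cur_rest <- setdiff(clusters[[ci]], r)
    cur_score <- priority_score(r, cur_rest, corpus, config$priority)
    best_j <- NA_integer_
    best_score <- cur_score
    best_minid <- Inf
    for (j in seq_along(clusters)) {
      if (j == ci || length(clusters[[j]]) == 0L) next
      d <- pair_record_distance(rep(r, length(clusters[[j]])), clusters[[j]],
                                corpus, config)
      if (!all(is.finite(d)) || any(d > tau)) next
      sc <- priority_score(r, clusters[[j]], corpus, config$priority)
      if (sc > best_score ||
          (sc == best_score && sc > cur_score && min(clusters[[j]]) < best_minid)) {
        best_j <- j
        best_score <- sc
        best_minid <- min(clusters[[j]])
      }
    }
    if (!is.na(best_j) && best_score > cur_score) {
      clusters[[ci]] <- cur_rest
      clusters[[best_j]] <- sort(c(clusters[[best_j]], r))
    }
  }
  clusters <- clusters[lengths(clusters) > 0L]
  clusters[order(vapply(clusters, min, numeric(1)))]
}

#' Expand representative clusters to the full corpus
#'
#' Each representative is replaced by every member of its exact-match
#' cluster, so the result partitions the original corpus.
#'
#' @param rep_clusters list of representative uid vectors (a partition of the
#'   representative set).
#' @param exact an `rl_exact` object from [find_exact_clusters()].
#' @return an `rl_clusters` final clustering.
#' @export
expand <- function(rep_clusters, exact) {
  rep_to_cluster <- integer(exact$corpus$n)
  rep_to_cluster[exact$representatives] <- seq_along(exact$representatives)
  full <- lapply(rep_clusters, function(uids) {
    ec <- rep_to_cluster[uids]
    ec[is.na(ec)] <- 0L
    if (any(ec == 0L))
      stop("representative uid(s) not found in the exact cluster set: ",
           paste(uids[ec == 0L], collapse = ", "))
    sort(unlist(exact$clusters[ec], use.names = FALSE))
  })
  final_clustering(full, exact$corpus)
}
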