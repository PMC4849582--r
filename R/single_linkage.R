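# Threshold graph and single-linkage components.
#
# Vertices are representative records; an edge joins two representatives that
# co-occur in at least one block of at least one blocking attribute AND whose
# record distance is within the threshold.  Connected components of this
# simple graph are the single-linkage clusters.  Components can chain:
# records further apart than the threshold may share a component through
# intermediates, which is exactly what the complete-linkage stage repairs.

#' Build the threshold graph from block indexes
#'
#' Candidate pairs from all indexes are pooled and deduplicated, so each
#' unordered pair is distance-tested once no matter how many blocks it
#' shares.  An edge `(u, v)` is kept iff the bounded record distance is
#' numeric (i.e. at most the threshold).
#'
#' @param indexes an [build_block_index()] object or a list of them (one per
#'   blocking attribute; candidate pairs are unioned).
#' @param corpus the [build_corpus()] the indexed uids refer to.
#' @param config an [link_config()] object.
#' @param nodes uids forming the vertex set; defaults to the union of indexed
#'   uids.  Pass the full representative set so that unblockable records
#'   still appear as isolated vertices.
#' @param workers number of parallel workers for edge construction; the edge
#'   set is identical for any value.
#' @return an object of class `rl_graph`: `nodes` (sorted uids), `edges`
#'   (data.table `u`, `v`, `d` with `u < v`), and candidate-pair counts.
#' @export
build_edges <- function(indexes, corpus, config, nodes = NULL, workers = 1L) {
  if (inherits(indexes, "rl_block_index")) indexes <- list(indexes)
  if (is.null(nodes))
    nodes <- sort(unique(unlist(lapply(indexes, function(ix) ix$blocks$uid))))
  nodes <- sort(unique(as.integer(nodes)))

  if (workers > 1L) {
    # balanced block groups: cost of a block is its squared size
    all_blocks <- data.table::rbindlist(lapply(seq_along(indexes), function(i) {
      data.table::data.table(ix = i, kmer = indexes[[i]]$blocks$kmer,
                             uid = indexes[[i]]$blocks$uid)
    }))
    sizes <- all_blocks[, .N, by = list(ix, kmer)]
    costs <- as.numeric(sizes$N)^2
    names(costs) <- paste(sizes$ix, sizes$kmer, sep = .SEP)
    part <- group_blocks_balanced(costs, workers)
    all_blocks[, bkey := paste(ix, kmer, sep = .SEP)]
    shards <- parallel::mclapply(part$groups, function(bkeys) {
      sub <- all_blocks[bkey %in% bkeys]
      if (nrow(sub) < 2L) {
        return(data.table::data.table(u = integer(), v = integer(),
                                      d = numeric()))
      }
      p <- sub[, {
        m <- .N
        if (m > 1L) {
          i <- rep.int(seq_len(m - 1L), rev(seq_len(m - 1L)))
          j <- sequence(rev(seq_len(m - 1L))) + i
          list(u = uid[i], v = uid[j])
        } else list(u = integer(), v = integer())
      }, by = bkey][, list(u, v)]
      p <- unique(p)
      p[, d := pair_record_distance(u, v, corpus, config)]
      p
    }, mc.cores = workers)
    bad <- vapply(shards, inherits, logical(1), "try-error")
    if (any(bad)) stop("parallel edge-construction worker failed")
    pairs <- unique(data.table::rbindlist(shards), by = c("u", "v"))
  } else {
    pairs <- unique(data.table::rbindlist(lapply(indexes, index_candidate_pairs)))
    if (nrow(pairs)) pairs[, d := pair_record_distance(u, v, corpus, config)]
    else pairs[, d := numeric()]
  }
  n_candidates <- nrow(pairs)
  edges <- pairs[is.finite(d)]
  data.table::setorder(edges, u, v)
  structure(
    list(nodes = nodes, edges = edges, n_candidate_pairs = n_candidates),
    class = "rl_graph"
  )
}

#' @export
print.rl_graph <- function(x, ...) {
  cat("<rl_graph> ", length(x$nodes), " node(s), ", nrow(x$edges),
      " edge(s) from ", x$n_candidate_pairs, " candidate pair(s)\n", sep = "")
  invisible(x)
}

#' Connected components of the threshold graph
#'
#' Isolated nodes become singleton components.  Components are returned
#' sorted by their smallest member uid, members sorted ascending, so
#' enumeration is deterministic.
#'
#' @param graph an `rl_graph` from [build_edges()].
#' @return list of integer uid vectors partitioning `graph$nodes`.
#' @export
connected_components <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) return(list())
  idx <- match(graph$edges$u, nodes)
  jdx <- match(graph$edges$v, nodes)
  if (anyNA(idx) || anyNA(jdx)) stop("edge endpoint not in node set")
  lab <- cpp_components(n, idx, jdx)
  unname(split(nodes, lab))
}
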