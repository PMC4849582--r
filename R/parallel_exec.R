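# Deterministic work partitioning for parallel execution.
#
# Three strategies: contiguous key-prefix ranges for the exact-match sort,
# greedy longest-processing-time grouping of blocks weighted by squared size
# for edge construction, and contiguous component shards for complete
# linkage.  Each parallel phase is a pure function of its inputs merged in a
# fixed order, so the final clustering is identical to the sequential
# pipeline for every worker count.

#' Split key-prefix cells into contiguous near-equal ranges
#'
#' With an alphabet of `alphabet_size` characters and prefixes of
#' `prefix_length` characters there are `alphabet_size ^ prefix_length`
#' prefix cells; they are split into `p` contiguous groups whose sizes
#' differ by at most one.
#'
#' @param alphabet_size alphabet size (e.g. 26 or 36).
#' @param prefix_length number of leading characters.
#' @param p number of groups (>= 1).
#' @return an object of class `rl_partition`: `groups` (list of integer cell
#'   ids, 1-based) and `load` (cells per group).
#' @export
partition_prefix_ranges <- function(alphabet_size, prefix_length, p) {
  p <- as.integer(p)
  if (is.na(p) || p < 1L) stop("'p' must be a positive integer")
  ncells <- as.integer(alphabet_size^prefix_length)
  sizes <- rep(ncells %/% p, p) + c(rep(1L, ncells %% p),
                                    rep(0L, p - ncells %% p))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-p] + 1L)
  groups <- Map(function(s, e) if (e >= s) seq.int(s, e) else integer(),
                starts, ends)
  structure(list(groups = unname(groups),
                 load = as.numeric(sizes)),
            class = "rl_partition")
}

# Map keys to 1-based prefix cells over the 36-character alphanumeric
# alphabet (characters outside it, including keys shorter than the prefix,
# rank 0).  Equal keys always share a cell, which is all the exact-match
# sharding needs.
prefix_cell <- function(keys, prefix_length = 2L) {
  cell <- rep(0L, length(keys))
  for (i in seq_len(prefix_length)) {
    ch <- substr(keys, i, i)
    r <- match(ch, c(as.character(0:9), LETTERS), nomatch = 0L)
    cell <- cell * 37L + r
  }
  # compress to 1..36^prefix_length range by modulo; collisions only regroup
  # cells, never split equal keys
  (cell %% as.integer(36^prefix_length)) + 1L
}

#' Greedy balanced grouping of blocks by squared size
#'
#' The cost of a block is the square of its record count (pairwise
#' comparison work).  Blocks are assigned in descending cost order, each to
#' the currently lightest group (longest-processing-time rule), so the
#' heaviest and lightest group loads differ by at most the largest single
#' block cost.
#'
#' @param block_sizes named numeric vector: block id -> record count, or a
#'   named vector of pre-squared costs if `squared = TRUE`.
#' @param p number of groups.
#' @param squared set `TRUE` when `block_sizes` already holds costs.
#' @return an `rl_partition`: `groups` (list of block-name character
#'   vectors) and `load` (total cost per group).
#' @export
group_blocks_balanced <- function(block_sizes, p, squared = FALSE) {
  p <- as.integer(p)
  if (is.na(p) || p < 1L) stop("'p' must be a positive integer")
  if (is.null(names(block_sizes)))
    names(block_sizes) <- as.character(seq_along(block_sizes))
  cost <- if (squared) as.numeric(block_sizes) else as.numeric(block_sizes)^2
  ord <- order(-cost, names(block_sizes))
  groups <- vector("list", p)
  load <- numeric(p)
  for (i in ord) {
    g <- which.min(load)
    groups[[g]] <- c(groups[[g]], names(block_sizes)[i])
    load[g] <- load[g] + cost[i]
  }
  structure(list(groups = groups, load = load), class = "rl_partition")
}

#' @export
print.rl_partition <- function(x, ...) {
  cat("<rl_partition> ", length(x$groups), " group(s); loads: ",
      paste(format(x$load), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Run the full linkage pipeline with parallel workers
#'
#' Executes the same phases as [record_link()] with the work partitioned
#' across `workers` forked processes: the exact-match sort by key-prefix
#' ranges, blocking by record shards, edge construction by balanced block
#' groups and complete linkage by component shards.  Component discovery
#' stays centralised.  The result — including the bytes of the written
#' cluster file — is identical to the sequential pipeline on the same
#' inputs; a failed worker aborts the run rather than returning a partial
#' result.
#'
#' @param datasets list of [rl_dataset()] objects.
#' @param config an [link_config()] object.
#' @param workers number of workers (>= 1).
#' @return an `rl_linkage` object, as from [record_link()].
#' @export
run_parallel <- function(datasets, config, workers) {
  record_link(datasets, config, workers = workers)
}
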