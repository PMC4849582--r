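# The end-to-end linkage pipeline.

#' Link records across datasets
#'
#' Runs every phase in order: exact-duplicate clustering, k-mer blocking of
#' the representatives, threshold-graph construction, single-linkage
#' components, within-component complete linkage with priority refinement,
#' and expansion of the representatives back to all original records.
#'
#' @param datasets an [rl_dataset()] or list of them.
#' @param config an [link_config()] object.
#' @param workers number of workers; any value yields an identical result
#'   (see [run_parallel()]).
#' @return an object of class `rl_linkage`: `clustering` (`rl_clusters`),
#'   `manifest` (named list of per-phase counts), plus the intermediate
#'   `exact`, `graph` and `components` objects.
#' @export
record_link <- function(datasets, config, workers = 1L) {
  stopifnot(inherits(config, "rl_config"))
  if (inherits(datasets, "rl_dataset")) datasets <- list(datasets)
  workers <- max(1L, as.integer(workers))
  corpus <- build_corpus(datasets)

  exact <- find_exact_clusters(datasets, corpus = corpus, workers = workers)
  reps <- exact$representatives

  build_one_index <- function(i) {
    spec <- config$blocking[i, ]
    build_block_index(corpus, reps, spec$attribute, spec$k, spec$alphabet)
  }
  indexes <- if (workers > 1L) {
    # blocking by record shards: each worker indexes a contiguous shard of
    # the representatives; shard indexes are concatenated per attribute
    lapply(seq_len(nrow(config$blocking)), function(i) {
      spec <- config$blocking[i, ]
      shard <- split(reps, cut(seq_along(reps), workers, labels = FALSE))
      parts <- parallel::mclapply(shard, function(us)
        build_block_index(corpus, us, spec$attribute, spec$k, spec$alphabet),
        mc.cores = workers)
      if (any(vapply(parts, inherits, logical(1), "try-error")))
        stop("parallel blocking worker failed")
      blocks <- data.table::rbindlist(lapply(parts, `[[`, "blocks"))
      data.table::setorder(blocks, kmer, uid)
      structure(list(attribute = spec$attribute, k = spec$k,
                     alphabet = spec$alphabet, blocks = blocks),
                class = "rl_block_index")
    })
  } else {
    lapply(seq_len(nrow(config$blocking)), build_one_index)
  }

  graph <- build_edges(indexes, corpus, config, nodes = reps,
                       workers = workers)
  comps <- connected_components(graph)

  link_comp <- function(comp) {
    cl <- complete_linkage_cluster(comp, corpus, config)
    refine_clusters(cl, corpus, config)
  }
  rep_clusters <- if (workers > 1L) {
    shard_id <- cut(seq_along(comps), min(workers, length(comps)),
                    labels = FALSE)
    shards <- parallel::mclapply(split(comps, shard_id), function(cs)
      lapply(cs, link_comp), mc.cores = workers)
    if (any(vapply(shards, inherits, logical(1), "try-error")))
      stop("parallel complete-linkage worker failed")
    unlist(shards, recursive = FALSE, use.names = FALSE)
  } else {
    lapply(comps, link_comp)
  }
  rep_clusters <- unlist(rep_clusters, recursive = FALSE, use.names = FALSE)

  clustering <- expand(rep_clusters, exact)
  manifest <- list(
    n_datasets = length(datasets),
    n_records = corpus$n,
    n_exact_clusters = exact$n_clusters,
    n_blocks = sum(vapply(indexes, function(ix)
      data.table::uniqueN(ix$blocks$kmer), numeric(1))),
    n_candidate_pairs = graph$n_candidate_pairs,
    n_edges = nrow(graph$edges),
    n_components = length(comps),
    n_final_clusters = clustering$n_clusters,
    workers = workers
  )
  structure(
    list(clustering = clustering, manifest = manifest, exact = exact,
         graph = graph, components = comps, config = config),
    class = "rl_linkage"
  )
}

#' @export
print.rl_linkage <- function(x, ...) {
  m <- x$manifest
  cat("<rl_linkage>\n")
  for (k in names(m)) cat(sprintf("  %-18s %s\n", k, format(m[[k]])))
  invisible(x)
}

#' Write a run manifest as flat key-value lines
#'
#' @param linkage an `rl_linkage` object.
#' @param path output file path.
#' @param extra optional named list of additional entries (e.g. input file
#'   digests, seeds, output paths).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(linkage, path, extra = list()) {
  stopifnot(inherits(linkage, "rl_linkage"))
  m <- c(linkage$manifest, extra)
  writeLines(paste0(names(m), " = ",
                    vapply(m, function(x) paste(format(x), collapse = ","),
                           character(1))),
             path)
  invisible(path)
}
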