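# Seedable synthetic dataset generators with ground truth.
#
# The base population has four attributes: first_name (drawn from a finite
# pool, so individuals share first names and blocks are realistically
# populated), last_name (a constructed surname code with a guaranteed
# minimum edit separation between distinct individuals), ssn (unique, the
# ground-truth key) and dob.  Corruption introduces exactly one random
# insertion, deletion or substitution in the last name.  Three corpus
# layouts emulate increasing error burden: probabilistic corruption of
# replicated copies (type 1), fully corrupted copies mixed with clean ones
# (type 2), and attribute-reduced fully-corrupted copies plus exact clones
# (type 3).

# Surname codes: the individual index is written in base 26 and each digit
# becomes a letter repeated .NAME_BLOCK times.  Two distinct codes differ in
# at least one digit block, so their edit distance is at least .NAME_BLOCK;
# with .NAME_BLOCK = 5 distinct individuals stay separated by more than
# 2 * tau for the default threshold tau = 2 even after one corrupting edit
# on each side.
.NAME_BLOCK <- 5L

surname_code <- function(idx0, code_length) {
  out <- rep("", length(idx0))
  x <- idx0
  for (d in seq_len(code_length)) {
    out <- paste0(strrep(LETTERS[(x %% 26L) + 1L], .NAME_BLOCK), out)
    x <- x %/% 26L
  }
  out
}

#' Generate a base population dataset
#'
#' Deterministic under `seed`.  Distinct individuals receive last names with
#' pairwise edit distance of at least 5, so their concatenated comparison
#' strings differ by more than twice the default threshold of 2; `ssn`
#' values are unique and serve as the ground-truth key.
#'
#' @param n number of individuals (>= 1).
#' @param seed RNG seed.
#' @param first_name_pool size of the first-name pool (names are sampled
#'   with replacement, so individuals share first names).
#' @param code_length number of base-26 digits in the surname code; defaults
#'   to the smallest length that can hold `n` distinct codes.
#' @return an [rl_dataset()] with attributes `first_name`, `last_name`,
#'   `ssn`, `dob` and id `"base"`.
#' @export
generate_base <- function(n, seed, first_name_pool = 500L, code_length = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  if (is.null(code_length))
    code_length <- max(3L, as.integer(ceiling(log(max(n, 2L)) / log(26))))
  capacity <- 26^code_length
  if (capacity < n)
    stop("n = ", n, " exceeds the surname-code capacity 26^", code_length,
         " = ", format(capacity), "; increase 'code_length' for a larger pool")
  with_seed(seed, {
    pool <- unique(vapply(seq_len(first_name_pool), function(i) {
      paste(sample(LETTERS, sample(5:8, 1L), replace = TRUE), collapse = "")
    }, character(1)))
    first <- sample(pool, n, replace = TRUE)
    codes <- sample.int(capacity, n) - 1
    last <- surname_code(codes, code_length)
    ssn <- sprintf("%09d", sample.int(999999999L, n))
    dob <- sprintf("%02d%02d%04d", sample.int(28L, n, replace = TRUE),
                   sample.int(12L, n, replace = TRUE),
                   sample(1940:2005, n, replace = TRUE))
    rl_dataset("base", data.frame(first_name = first, last_name = last,
                                  ssn = ssn, dob = dob,
                                  stringsAsFactors = FALSE))
  })
}

#' Apply exactly one random edit to a string
#'
#' One insertion, deletion or substitution (operation, position and letter
#' uniform over the valid choices) of an upper-case letter.  The result
#' always differs from the input and has edit distance exactly 1 from it.
#' Uses the current RNG state; wrap in `set.seed()` for reproducibility.
#'
#' @param value a non-empty string (an empty string forces an insertion).
#' @return the corrupted string.
#' @export
corrupt_one_edit <- function(value) {
  l <- nchar(value)
  repeat {
    op <- sample(c("insert", "delete", "substitute"), 1L)
    if (l == 0L && op != "insert") next  # re-draw: nothing to delete/replace
    if (op == "insert") {
      pos <- sample.int(l + 1L, 1L) - 1L
      ch <- sample(LETTERS, 1L)
      return(paste0(substr(value, 1L, pos), ch, substr(value, pos + 1L, l)))
    } else if (op == "delete") {
      pos <- sample.int(l, 1L)
      return(paste0(substr(value, 1L, pos - 1L), substr(value, pos + 1L, l)))
    } else {
      pos <- sample.int(l, 1L)
      cur <- substr(value, pos, pos)
      ch <- sample(setdiff(LETTERS, cur), 1L)
      return(paste0(substr(value, 1L, pos - 1L), ch, substr(value, pos + 1L, l)))
    }
  }
}

corrupt_copy <- function(base_df, p) {
  df <- base_df
  hit <- which(runif(nrow(df)) < p)
  for (i in hit) df$last_name[i] <- corrupt_one_edit(df$last_name[i])
  df
}

simulation_object <- function(type, datasets, base, meta) {
  truth <- data.table::rbindlist(lapply(datasets, function(d) {
    data.table::data.table(dataset_id = d$dataset_id,
                           row_index = seq_len(d$n) - 1L,
                           individual = rep(base$records$ssn, length.out = d$n))
  }))
  structure(list(type = type, datasets = datasets, base = base,
                 truth = as.data.frame(truth), meta = meta),
            class = "rl_simulation")
}

#' @export
print.rl_simulation <- function(x, ...) {
  cat("<rl_simulation> type ", x$type, ": ", length(x$datasets),
      " dataset(s), ", sum(vapply(x$datasets, function(d) d$n, integer(1))),
      " records total (seed ", x$meta$seed, ")\n", sep = "")
  invisible(x)
}

#' Generate a type-1 corpus: replicated copies with probabilistic corruption
#'
#' The base dataset is replicated `copies` times; in every copy each record's
#' last name independently receives one random edit with probability `p`.
#'
#' @param n number of individuals.
#' @param seed RNG seed (controls base generation and corruption).
#' @param copies number of replicated datasets.
#' @param p per-record corruption probability.
#' @param ... passed to [generate_base()].
#' @return an `rl_simulation`: `datasets` (list of [rl_dataset()]), `truth`
#'   (`dataset_id`, `row_index`, `individual`), `base` and `meta`.
#' @export
generate_type1 <- function(n, seed, copies = 10L, p = 0.15, ...) {
  if (p < 0 || p > 1) stop("'p' must be in [0, 1]")
  base <- generate_base(n, seed, ...)
  datasets <- with_seed(seed + 1L, {
    lapply(seq_len(copies), function(cc) {
      rl_dataset(sprintf("copy%02d", cc), corrupt_copy(base$records, p))
    })
  })
  simulation_object(1L, datasets, base,
                    list(type = 1L, n = n, copies = copies, p = p, seed = seed))
}

#' Generate a type-2 corpus: clean copies mixed with fully-corrupted clones
#'
#' Two fully corrupted variants of the base (every record gets exactly one
#' edit) are built; the corpus is `clean_copies` clean replicas plus each
#' corrupted variant cloned `clone_each` times, giving
#' `clean_copies + 2 * clone_each` datasets (default 4 + 6 = 10).
#'
#' @param n number of individuals.
#' @param seed RNG seed.
#' @param clean_copies number of uncorrupted replicas.
#' @param clone_each number of clones of each corrupted variant.
#' @param ... passed to [generate_base()].
#' @return an `rl_simulation`.
#' @export
generate_type2 <- function(n, seed, clean_copies = 4L, clone_each = 3L, ...) {
  base <- generate_base(n, seed, ...)
  corrupted <- with_seed(seed + 1L, {
    list(corrupt_copy(base$records, 1), corrupt_copy(base$records, 1))
  })
  datasets <- list()
  for (cc in seq_len(clean_copies))
    datasets[[length(datasets) + 1L]] <-
      rl_dataset(sprintf("clean%02d", cc), base$records)
  for (v in 1:2) for (cl in seq_len(clone_each))
    datasets[[length(datasets) + 1L]] <-
      rl_dataset(sprintf("corrupt%d_clone%d", v, cl), corrupted[[v]])
  simulation_object(2L, datasets, base,
                    list(type = 2L, n = n, clean_copies = clean_copies,
                         clone_each = clone_each, seed = seed))
}

#' Generate a type-3 corpus: attribute-reduced corrupted copies plus clones
#'
#' Three copies of the base drop different attribute subsets (so schemas are
#' pairwise distinct and subset-comparable), every record's last name gets
#' exactly one edit, and each resulting dataset is cloned once — the exact
#' matching phase should therefore halve the number of representatives.
#'
#' @param n number of individuals.
#' @param seed RNG seed.
#' @param drop_plan list of three character vectors: attributes dropped from
#'   each copy.
#' @param ... passed to [generate_base()].
#' @return an `rl_simulation`.
#' @export
generate_type3 <- function(n, seed,
                           drop_plan = list(character(0), "dob",
                                            c("dob", "ssn")), ...) {
  if (length(drop_plan) != 3L) stop("'drop_plan' must have three entries")
  base <- generate_base(n, seed, ...)
  kept <- lapply(drop_plan, function(dr) setdiff(base$attributes, dr))
  if (!all(c("first_name", "last_name") %in% unique(unlist(kept))))
    warning("drop plan removes a comparison attribute from every copy; ",
            "approximate matching will have nothing to compare")
  reduced <- with_seed(seed + 1L, {
    lapply(seq_len(3L), function(i) {
      df <- corrupt_copy(base$records, 1)[, kept[[i]], drop = FALSE]
      df
    })
  })
  datasets <- list()
  for (i in 1:3)
    datasets[[length(datasets) + 1L]] <-
      rl_dataset(sprintf("reduced%d", i), reduced[[i]])
  for (i in 1:3)
    datasets[[length(datasets) + 1L]] <-
      rl_dataset(sprintf("reduced%d_clone", i), reduced[[i]])
  simulation_object(3L, datasets, base,
                    list(type = 3L, n = n, seed = seed,
                         drop_plan = drop_plan))
}

#' The five-record two-dataset walkthrough fixture
#'
#' A tiny corpus of two sources sharing first name, last name and date of
#' birth, with one cross-source exact duplicate and three near-duplicate
#' surnames, together with its linkage configuration (blocking on 3-mers of
#' the first name, comparison on first + last name, date of birth as the
#' priority attribute, threshold 1).  Running the full pipeline on it yields
#' 4 exact-match clusters, 2 single-linkage components and 3 final clusters.
#'
#' @return list with elements `datasets` (list of two [rl_dataset()]) and
#'   `config` (an [link_config()]).
#' @export
worked_example_fixture <- function() {
  A <- rl_dataset("A", data.frame(
    first_name = c("Cade", "Cade", "Thor"),
    last_name = c("Bale", "Bolt", "Glenn"),
    dob = c("05011976", "05021986", "12011990"),
    stringsAsFactors = FALSE
  ))
  B <- rl_dataset("B", data.frame(
    first_name = c("Thor", "Cade"),
    last_name = c("Glenn", "Balt"),
    dob = c("12011990", "05011976"),
    stringsAsFactors = FALSE
  ))
  cfg <- link_config(
    blocking = "first_name",
    comparison = c("first_name", "last_name"),
    threshold = 1L,
    priority = "dob"
  )
  list(datasets = list(A, B), config = cfg)
}

#' Write a simulation to a directory
#'
#' Emits one CSV per dataset, a `truth.csv` (`dataset_id`, `row_index`,
#' `individual`) and a `metadata.txt` of flat key-value generator settings.
#'
#' @param sim an `rl_simulation`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "rl_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (d in sim$datasets)
    data.table::fwrite(d$records, file.path(dir, paste0(d$dataset_id, ".csv")))
  data.table::fwrite(sim$truth, file.path(dir, "truth.csv"))
  meta <- sim$meta
  writeLines(paste0(names(meta), " = ",
                    vapply(meta, function(x) paste(unlist(x), collapse = ","),
                           character(1))),
             file.path(dir, "metadata.txt"))
  invisible(dir)
}
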