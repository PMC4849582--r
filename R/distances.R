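# Threshold-bounded string and record distances.
#
# All distances are computed under a threshold tau: the result is either the
# exact distance (when <= tau) or EXCEEDS (Inf).  The edit distance kernel is
# a banded dynamic program that fills only the diagonal band of half-width
# tau and aborts as soon as a whole band row exceeds tau, so the cost is
# O(tau * min(length)) rather than quadratic.

.method_code <- c(edit = 0L, reversal = 1L, truncation = 2L)

bounded_dist_vec <- function(a, b, tau, method) {
  code <- .method_code[[method]]
  res <- cpp_bounded_dist(as.character(a), as.character(b),
                          as.integer(tau), code)
  out <- as.numeric(res)
  out[!is.na(res) & res < 0L] <- EXCEEDS
  out
}

#' Bounded Levenshtein (edit) distance
#'
#' Unit-cost insertions, deletions and substitutions.  Returns the distance
#' when it is at most `tau`, and [EXCEEDS] (`Inf`) otherwise.  Vectorised
#' over `a`, `b` and `tau` (lengths recycled from 1).
#'
#' @param a,b character vectors; compared verbatim (the pipeline upper-cases
#'   values before calling).
#' @param tau non-negative integer threshold(s).
#' @return numeric vector of distances, `Inf` where the threshold was
#'   exceeded.
#' @export
edit_distance_bounded <- function(a, b, tau) {
  bounded_dist_vec(a, b, tau, "edit")
}

#' Bounded reversal edit distance
#'
#' The minimum of the edit distance between `a` and `b` and the edit distance
#' between `reverse(a)` and `b`, bounded by `tau`.
#'
#' @inheritParams edit_distance_bounded
#' @return numeric vector of distances, `Inf` where the threshold was
#'   exceeded.
#' @export
reversal_edit_distance <- function(a, b, tau) {
  bounded_dist_vec(a, b, tau, "reversal")
}

#' Bounded truncation edit distance
#'
#' The longer string is truncated (free of charge) to the length of the
#' shorter one before the bounded edit distance is computed.
#'
#' @inheritParams edit_distance_bounded
#' @return numeric vector of distances, `Inf` where the threshold was
#'   exceeded.
#' @export
truncation_edit_distance <- function(a, b, tau) {
  bounded_dist_vec(a, b, tau, "truncation")
}

#' Bounded distance between two records
#'
#' The sum, over the comparison attributes shared by both records, of the
#' configured per-attribute bounded distance, with early abort to [EXCEEDS]
#' once the running sum exceeds the threshold.  An attribute is shared when
#' it is in `config$comparison` and present (non-`NA`) in both records.
#' Values are upper-cased before comparison.
#'
#' @param r1,r2 named character vectors (or named lists) of attribute values;
#'   `NA` marks an attribute absent from the record's schema.
#' @param config an [link_config()] object.
#' @return a single numeric distance; `Inf` when the threshold is exceeded,
#'   or `Inf` with attribute `reason = "no shared comparison attribute"` when
#'   the records share no comparison attribute.
#' @export
record_distance <- function(r1, r2, config) {
  r1 <- unlist(r1); r2 <- unlist(r2)
  cols_a <- lapply(config$comparison, function(a)
    if (a %in% names(r1)) toupper(as.character(r1[[a]])) else NA_character_)
  cols_b <- lapply(config$comparison, function(a)
    if (a %in% names(r2)) toupper(as.character(r2[[a]])) else NA_character_)
  res <- cpp_record_distance(cols_a, cols_b, config$threshold,
                             .method_code[[config$method]],
                             config$proportional, config$rho)
  if (res == -2L)
    return(structure(EXCEEDS, reason = "no shared comparison attribute"))
  if (res == -1L) EXCEEDS else as.numeric(res)
}

# Vectorised record distance over uid pairs of a corpus.
pair_record_distance <- function(u, v, corpus, config) {
  if (length(u) == 0L) return(numeric())
  cols_a <- lapply(config$comparison, function(a) {
    if (a %in% corpus$attributes) corpus$norm[[a]][u]
    else rep(NA_character_, length(u))
  })
  cols_b <- lapply(config$comparison, function(a) {
    if (a %in% corpus$attributes) corpus$norm[[a]][v]
    else rep(NA_character_, length(v))
  })
  res <- cpp_record_distance(cols_a, cols_b, config$threshold,
                             .method_code[[config$method]],
                             config$proportional, config$rho)
  out <- as.numeric(res)
  out[res < 0L] <- EXCEEDS
  out
}
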