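# k-mer blocking of representative records.
#
# A value of length l contributes its l - k + 1 contiguous substrings
# (k-mers); records sharing at least one k-mer of a blocking attribute land
# in at least one common block, so only block-co-occurring pairs are ever
# compared.  With a declared alphabet of size s there are at most s^k blocks.

#' Extract the k-mers of a value
#'
#' The value is upper-cased and characters outside the declared alphabet are
#' removed before extraction.  Degenerate cases: a value shorter than `k`
#' yields a single key padded to length `k` with a reserved pad character; a
#' value with no alphabet character at all yields the attribute's single
#' "unblockable" overflow key, so no record is silently dropped.  Duplicate
#' k-mers within one value are returned once (set semantics).
#'
#' @param value a single string.
#' @param k window length, a positive integer.
#' @param alphabet one of `"letters26"`, `"digits10"`, `"alnum36"`.
#' @return character vector of keys, each of length `k`.
#' @export
kmers <- function(value, k, alphabet = "letters26") {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be a positive integer")
  v <- normalize_blocking_value(value, alphabet)
  l <- nchar(v)
  if (l == 0L) return(strrep(.PAD, k))
  if (l < k) return(paste0(v, strrep(.PAD, k - l)))
  unique(substring(v, 1L:(l - k + 1L), k:l))
}

normalize_blocking_value <- function(value, alphabet) {
  chars <- alphabet_chars(alphabet)
  pattern <- paste0("[^", paste(chars, collapse = ""), "]")
  gsub(pattern, "", toupper(value))
}

#' Build a k-mer block index over representative records
#'
#' @param corpus an [build_corpus()] object.
#' @param uids representative record uids to index.
#' @param attribute blocking attribute name.
#' @param k window length (default 3).
#' @param alphabet declared alphabet (default `"letters26"`).
#' @return an object of class `rl_block_index`: the blocking spec plus a
#'   `blocks` data.table of `(kmer, uid)` memberships.  Records whose dataset
#'   schema lacks the attribute are skipped for this index.
#' @export
build_block_index <- function(corpus, uids, attribute, k = 3L,
                              alphabet = "letters26") {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be a positive integer")
  if (!attribute %in% corpus$attributes)
    stop("blocking attribute '", attribute, "' not present in any dataset")
  vals <- corpus$norm[[attribute]][uids]
  keep <- !is.na(vals)
  u <- uids[keep]
  km <- lapply(vals[keep], kmers, k = k, alphabet = alphabet)
  blocks <- data.table::data.table(
    kmer = as.character(unlist(km, use.names = FALSE)),
    uid = rep(u, lengths(km))
  )
  data.table::setorder(blocks, kmer, uid)
  structure(
    list(attribute = attribute, k = k, alphabet = alphabet, blocks = blocks),
    class = "rl_block_index"
  )
}

#' @export
print.rl_block_index <- function(x, ...) {
  cat("<rl_block_index> attribute '", x$attribute, "' (k=", x$k, ", ",
      x$alphabet, "): ", data.table::uniqueN(x$blocks$kmer), " block(s), ",
      nrow(x$blocks), " membership(s)\n", sep = "")
  invisible(x)
}

#' Number of possible blocks for an alphabet and window length
#'
#' @param alphabet_size 26 (letters), 10 (digits) or 36 (alphanumeric).
#' @param k window length, a positive integer.
#' @return `alphabet_size ^ k` as a double.
#' @export
block_capacity <- function(alphabet_size, k) {
  if (!alphabet_size %in% c(26L, 10L, 36L))
    stop("'alphabet_size' must be 26, 10 or 36")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be a positive integer")
  as.numeric(alphabet_size)^k
}

#' Expected average number of records per block
#'
#' Each record's value of length `value_length` lands in
#' `value_length - k + 1` blocks, spread over `alphabet_size ^ k` possible
#' blocks.
#'
#' @param n_records number of records.
#' @param value_length typical length of the blocking attribute value.
#' @param alphabet_size 26, 10 or 36.
#' @param k window length.
#' @return expected records per block (double).
#' @export
expected_block_load <- function(n_records, value_length, alphabet_size, k) {
  if (value_length < k) stop("'value_length' must be at least 'k'")
  n_records * (value_length - k + 1) / block_capacity(alphabet_size, k)
}

# Candidate pairs of one index: all unordered uid pairs co-occurring in at
# least one block.  uids are sorted within a block, so u < v.
index_candidate_pairs <- function(index) {
  b <- index$blocks
  if (nrow(b) < 2L) {
    return(data.table::data.table(u = integer(), v = integer()))
  }
  pairs <- b[, {
    m <- .N
    if (m > 1L) {
      i <- rep.int(seq_len(m - 1L), rev(seq_len(m - 1L)))
      j <- sequence(rev(seq_len(m - 1L))) + i
      list(u = uid[i], v = uid[j])
    } else list(u = integer(), v = integer())
  }, by = kmer][, list(u, v)]
  unique(pairs)
}
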