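test_that("comparable pairs follow the subset-schema rule", {
  A <- rl_dataset("A", data.frame(a = "1", b = "2", c = "3", d = "4"))
  B <- rl_dataset("B", data.frame(a = "1", d = "4"))
  C <- rl_dataset("C", data.frame(a = "1", d = "4", e = "5"))
  cp <- comparable_pairs(list(A, B, C))
  has <- function(x, y) any(cp$x == x & cp$y == y)
  expect_true(has("B", "A"))
  expect_true(has("B", "C"))
  expect_false(has("A", "C"))
  expect_false(has("C", "A"))
  expect_true(all(c(has("A", "A"), has("B", "B"), has("C", "C"))))

  # single dataset: just the self-pair
  expect_equal(comparable_pairs(list(A)), data.frame(x = "A", y = "A"))

  # identical schemas: all ordered pairs, matching brute-force enumeration
  ds <- lapply(c("X", "Y", "Z"), function(id)
    rl_dataset(id, data.frame(a = "1", b = "2")))
  cp2 <- comparable_pairs(ds)
  expect_equal(nrow(cp2), 9L)
  brute <- expand.grid(x = c("X", "Y", "Z"), y = c("X", "Y", "Z"),
                       stringsAsFactors = FALSE)
  expect_setequal(paste(cp2$x, cp2$y), paste(brute$x, brute$y))
})

test_that("sort keys concatenate upper-cased values with the reserved separator", {
  k <- sort_key(c(first = "Thor", last = "Glenn", dob = "12011990"),
                c("first", "last", "dob"))
  expect_identical(k, paste("THOR", "GLENN", "12011990", sep = "\x1f"))
  expect_identical(sort_key(c(a = "x"), character()), "")
  r1 <- c(first = "Cade", last = "Bale")
  r2 <- c(first = "CADE", last = "bale")
  expect_identical(sort_key(r1, names(r1)), sort_key(r2, names(r2)))
  expect_error(sort_key(r1, c("first", "dob")), "missing")
})

test_that("radix sort is stable, lexicographic, and validates its alphabet", {
  expect_equal(radix_sort(c("b", "a", "a")), c(2L, 3L, 1L))
  srt <- c("ALPHA", "BETA", "GAMMA")
  expect_equal(radix_sort(srt), 1:3)
  expect_error(radix_sort(c("AB", "A9"), alphabet = LETTERS), "9")

  set.seed(42)
  for (rep in 1:3) {
    keys <- vapply(1:1000, function(i)
      random_word(sample(0:6, 1), c("A", "B", "C", "0", "1")), "")
    ours <- radix_sort(keys)
    oracle <- merge_sort_order(keys)
    expect_identical(ours, oracle)  # includes stability on duplicate keys
  }
})

test_that("exact clustering matches the walkthrough and a brute-force oracle", {
  fx <- worked_example_fixture()
  ex <- find_exact_clusters(fx$datasets)
  expect_equal(ex$n_clusters, 4L)
  # the two Thor records (uids 3 and 4) share a cluster
  expect_equal(ex$membership[3], ex$membership[4])
  expect_equal(sum(lengths(ex$clusters)), 5L)
  expect_true(all(vapply(seq_along(ex$clusters), function(i)
    ex$representatives[i] %in% ex$clusters[[i]], logical(1))))

  # all-distinct corpus: N singletons
  d <- rl_dataset("D", data.frame(v = c("P", "Q", "R")))
  expect_equal(find_exact_clusters(list(d))$n_clusters, 3L)

  # random corpora with planted duplicates vs a quadratic all-pairs oracle
  skip_if_not_installed("igraph")
  set.seed(7)
  for (rep in 1:5) {
    ds <- lapply(1:3, function(i) {
      nattr <- sample(2:3, 1)
      attrs <- c("a", "b", "c")[seq_len(nattr)]
      df <- as.data.frame(lapply(attrs, function(a)
        sample(c("X", "Y", "Z"), 8, replace = TRUE)))
      names(df) <- attrs
      rl_dataset(paste0("d", i), df)
    })
    corpus <- build_corpus(ds)
    ex <- find_exact_clusters(ds, corpus = corpus)
    # oracle: pairwise equality on comparable pairs + transitive closure
    cp <- comparable_pairs(ds)
    eu <- integer(); ev <- integer()
    for (pi in seq_len(nrow(cp))) {
      xi <- which(corpus$records$dataset_id == cp$x[pi])
      yi <- which(corpus$records$dataset_id == cp$y[pi])
      common <- intersect(corpus$schemas[[cp$x[pi]]], corpus$schemas[[cp$y[pi]]])
      kx <- sort_key(corpus$norm[xi, common, with = FALSE], common)
      ky <- sort_key(corpus$norm[yi, common, with = FALSE], common)
      for (i in seq_along(xi)) for (j in seq_along(yi)) {
        if (xi[i] != yi[j] && kx[i] == ky[j]) {
          eu <- c(eu, xi[i]); ev <- c(ev, yi[j])
        }
      }
    }
    g <- igraph::graph_from_edgelist(cbind(eu, ev), directed = FALSE)
    g <- igraph::add_vertices(g, corpus$n - igraph::vcount(g))
    oracle_mem <- igraph::components(g)$membership
    expect_equal(length(unique(oracle_mem)), ex$n_clusters)
    expect_true(all(table(oracle_mem, ex$membership) %in%
                      c(0L, table(oracle_mem))))
    # same partition: cross-tab has one non-zero cell per row/column
    tab <- table(oracle_mem, ex$membership)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("representatives retain the most attributes, ties by position", {
  fx <- worked_example_fixture()
  ex <- find_exact_clusters(fx$datasets)
  thor_cluster <- ex$clusters[[ex$membership[3]]]
  expect_setequal(thor_cluster, c(3L, 4L))
  expect_equal(choose_representative(thor_cluster, ex$corpus), 3L)

  # a 4-attribute record beats a 2-attribute record equal on the common pair
  big <- rl_dataset("big", data.frame(a = "1", b = "2", c = "3", d = "4"))
  small <- rl_dataset("small", data.frame(a = "1", b = "2"))
  corpus <- build_corpus(list(small, big))  # small first: position must lose
  ex2 <- find_exact_clusters(list(small, big), corpus = corpus)
  expect_equal(ex2$n_clusters, 1L)
  expect_equal(choose_representative(ex2$clusters[[1]], corpus), 2L)
  expect_equal(choose_representative(5L, corpus = corpus), 5L)  # singleton
})

test_that("re-running exact clustering on distinct representatives is the identity", {
  set.seed(31)
  df <- data.frame(a = sample(c("U", "V", "W"), 12, replace = TRUE),
                   b = sample(c("U", "V"), 12, replace = TRUE))
  ds <- list(rl_dataset("d1", df), rl_dataset("d2", df[sample(12), ]))
  ex <- find_exact_clusters(ds)
  corpus <- ex$corpus
  repdf <- as.data.frame(corpus$records[ex$representatives, c("a", "b"),
                                        with = FALSE])
  ex2 <- find_exact_clusters(list(rl_dataset("reps", repdf)))
  expect_equal(ex2$n_clusters, ex$n_clusters)  # all singletons
  expect_true(all(lengths(ex2$clusters) == 1L))
})
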