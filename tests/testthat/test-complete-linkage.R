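test_that("complete linkage splits the near-name component without chaining", {
  fx <- worked_example_fixture()
  ex <- find_exact_clusters(fx$datasets)
  cl <- complete_linkage_cluster(c(1L, 2L, 5L), ex$corpus, fx$config)
  expect_length(cl, 2L)
  sizes <- sort(lengths(cl))
  expect_equal(sizes, c(1L, 2L))  # Balt pairs with exactly one of Bale/Bolt
  expect_false(any(lengths(cl) == 3L))

  # singleton component is returned unchanged
  expect_equal(complete_linkage_cluster(3L, ex$corpus, fx$config), list(3L))
})

test_that("the sweat/sheat/heat chain is never merged into one cluster", {
  fx <- chaining_fixture()
  ex <- find_exact_clusters(fx$datasets)
  cl <- complete_linkage_cluster(1:3, ex$corpus, fx$config)
  expect_length(cl, 2L)
  expect_false(any(lengths(cl) == 3L))
  # the merged pair must be an adjacent pair of the chain, never the ends
  two <- cl[[which(lengths(cl) == 2L)]]
  expect_false(setequal(two, c(1L, 3L)))
})

test_that("the threshold cut matches a hierarchical-clustering oracle", {
  set.seed(55)
  for (rep in 1:20) {
    m <- sample(2:8, 1)
    D <- matrix(0, m, m)
    D[upper.tri(D)] <- runif(m * (m - 1) / 2)  # continuous: ties a.s. absent
    D <- D + t(D)
    tau <- runif(1, 0.2, 0.8)
    ours <- complete_linkage_matrix(D, tau)
    hc <- stats::hclust(stats::as.dist(D), method = "complete")
    cut <- stats::cutree(hc, h = tau)
    oracle <- unname(split(seq_len(m), cut))
    oracle <- lapply(oracle, as.integer)
    oracle <- oracle[order(vapply(oracle, min, numeric(1)))]
    expect_equal(unclass(ours)[seq_along(ours)], oracle,
                 ignore_attr = TRUE)
    # merge distances are non-decreasing (standard complete-linkage property)
    md <- attr(ours, "merge_distances")
    if (length(md) > 1) expect_true(all(diff(md) >= 0))
    # and every cluster respects the diameter bound
    for (cl in ours)
      if (length(cl) > 1)
        expect_lte(max(D[cl, cl]), tau)
  }
})

test_that("priority scores weight earlier attributes with higher powers of two", {
  fx <- worked_example_fixture()
  ex <- find_exact_clusters(fx$datasets)
  # Balt (uid 5, dob 05011976) against {Bale} matches, against {Bolt} not
  expect_equal(priority_score(5L, 1L, ex$corpus, "dob"), 1)
  expect_equal(priority_score(5L, 2L, ex$corpus, "dob"), 0)
  expect_equal(priority_score(5L, 1L, ex$corpus, character()), 0)
  # two priority attributes: high-rank-only match beats low-rank-only match
  corpus <- build_corpus(list(rl_dataset("D", data.frame(
    p1 = c("A", "A", "B"), p2 = c("X", "Y", "X")))))
  high_only <- priority_score(1L, 2L, corpus, c("p1", "p2"))  # p1 matches
  low_only <- priority_score(1L, 3L, corpus, c("p1", "p2"))   # p2 matches
  expect_equal(high_only, 2)
  expect_equal(low_only, 1)
  expect_gt(high_only, low_only)
  # majority vote with tie broken by the lexicographically smallest value
  corpus2 <- build_corpus(list(rl_dataset("E", data.frame(
    p = c("B", "A", "B", "A", "Z")))))
  expect_equal(priority_score(5L, 1:4, corpus2, "p"), 0)
  expect_equal(priority_score(2L, c(1L, 3L, 4L), corpus2, "p"), 0)  # maj B? A:1 B:2
  expect_equal(priority_score(1L, c(2L, 3L, 4L), corpus2, "p"), 0)  # maj A
  expect_equal(priority_score(2L, c(1L, 4L), corpus2, "p"), 1)      # tie -> A
})

test_that("priority refinement resolves the date-of-birth tie deterministically", {
  fx <- worked_example_fixture()
  ex <- find_exact_clusters(fx$datasets)
  cl <- complete_linkage_cluster(c(1L, 2L, 5L), ex$corpus, fx$config)
  ref <- refine_clusters(cl, ex$corpus, fx$config)
  # Balt (5) must end beside Bale (1): same dob
  which5 <- which(vapply(ref, function(s) 5L %in% s, logical(1)))
  expect_true(1L %in% ref[[which5]])
  # with an empty priority list nothing moves
  cfg0 <- link_config("first_name", comparison = c("first_name", "last_name"),
                      threshold = 1)
  expect_equal(refine_clusters(cl, ex$corpus, cfg0), cl)
})

test_that("refinement never breaks the diameter invariant on adversarial inputs", {
  set.seed(202)
  for (rep in 1:10) {
    d <- fuzzy_dataset(6, alphabet = c("A", "B"), len = 4L)
    d$records$p <- sample(c("U", "V"), 6, replace = TRUE)
    d2 <- rl_dataset("X", d$records)
    cfg <- link_config(data.frame(attribute = "x", k = 2, alphabet = "letters26"),
                       comparison = "x", threshold = 1, priority = "p")
    corpus <- build_corpus(list(d2))
    ix <- build_block_index(corpus, 1:6, "x", 2)
    g <- build_edges(ix, corpus, cfg, nodes = 1:6)
    for (comp in connected_components(g)) {
      cl <- complete_linkage_cluster(comp, corpus, cfg)
      ref <- refine_clusters(cl, corpus, cfg)
      expect_setequal(unlist(ref), comp)
      for (s in ref) {
        if (length(s) < 2) next
        for (i in 1:(length(s) - 1)) for (j in (i + 1):length(s)) {
          expect_lte(record_distance(rec_vals(corpus, s[i]),
                                     rec_vals(corpus, s[j]), cfg),
                     cfg$threshold)
        }
      }
    }
  }
})

test_that("expansion restores every original record exactly once", {
  fx <- worked_example_fixture()
  res <- record_link(fx$datasets, fx$config)
  expect_equal(res$clustering$n_clusters, 3L)
  expect_equal(sort(table(res$clustering$assignments$cluster_id),
                    decreasing = TRUE),
               sort(table(c(1, 1, 2, 3, 3)), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_equal(res$clustering$n_records, 5L)
  expect_equal(anyDuplicated(res$clustering$assignments$uid), 0L)

  # all-singleton exact clusters: expansion is the identity on memberships
  d <- rl_dataset("D", data.frame(v = c("P", "Q", "R")))
  ex <- find_exact_clusters(list(d))
  out <- expand(list(c(1L, 2L), 3L), ex)
  expect_equal(out$n_clusters, 2L)
  expect_equal(out$n_records, 3L)
  expect_error(expand(list(99L), ex), "not found")
})
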