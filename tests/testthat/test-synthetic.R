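test_that("base generation is deterministic with unique truth keys", {
  b1 <- generate_base(50, seed = 1)
  b2 <- generate_base(50, seed = 1)
  expect_identical(b1$records, b2$records)
  expect_false(identical(b1$records, generate_base(50, seed = 2)$records))
  expect_equal(anyDuplicated(b1$records$ssn), 0L)
  expect_equal(b1$attributes, c("first_name", "last_name", "ssn", "dob"))
  expect_error(generate_base(1000, seed = 1, code_length = 1), "capacity")
})

test_that("distinct individuals stay separated by more than twice the default threshold", {
  b <- generate_base(1000, seed = 3)
  ln <- b$records$last_name
  n <- length(ln)
  i <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  j <- sequence(rev(seq_len(n - 1L))) + i
  d <- edit_distance_bounded(ln[i], ln[j], 4)
  expect_true(all(is_exceeds(d)))  # every pair further than 4 = 2 * tau
})

test_that("corruption applies exactly one edit, uniformly over operations", {
  set.seed(8)
  for (rep in 1:100) {
    v <- random_word(sample(2:10, 1))
    w <- corrupt_one_edit(v)
    expect_false(identical(v, w))
    expect_equal(lev_oracle(v, w), 1)
  }
  w0 <- corrupt_one_edit("")  # deletion/substitution re-drawn into insertion
  expect_equal(nchar(w0), 1L)
  # operation frequencies near-uniform: classify by length change
  set.seed(9)
  ops <- vapply(1:3000, function(i) {
    w <- corrupt_one_edit("MELVILLE")
    nchar(w) - 8L
  }, integer(1))
  counts <- table(factor(ops, levels = c(-1L, 0L, 1L)))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("type-1 corpora hit the configured corruption rate and edge cases", {
  sim <- generate_type1(300, seed = 21, copies = 10, p = 0.15)
  expect_length(sim$datasets, 10L)
  expect_true(all(vapply(sim$datasets, function(d) d$n, integer(1)) == 300L))
  base_ln <- sim$base$records$last_name
  ncorrupt <- sum(vapply(sim$datasets, function(d)
    sum(d$records$last_name != base_ln), integer(1)))
  bounds <- stats::qbinom(c(0.005, 0.995), 3000, 0.15)
  expect_gte(ncorrupt, bounds[1])
  expect_lte(ncorrupt, bounds[2])
  # reproducibility
  sim2 <- generate_type1(300, seed = 21, copies = 10, p = 0.15)
  expect_identical(lapply(sim$datasets, `[[`, "records"),
                   lapply(sim2$datasets, `[[`, "records"))
  # p = 0: all copies identical to base
  sim0 <- generate_type1(50, seed = 4, copies = 3, p = 0)
  for (d in sim0$datasets) expect_identical(d$records, sim0$base$records)
  # p = 1: every record at last-name distance exactly 1
  sim1 <- generate_type1(50, seed = 4, copies = 2, p = 1)
  for (d in sim1$datasets) {
    dd <- diag(utils::adist(d$records$last_name, sim1$base$records$last_name))
    expect_true(all(dd == 1))
  }
})

test_that("type-2 corpora mix clean replicas with triplicated corrupted clones", {
  sim <- generate_type2(40, seed = 13)
  expect_length(sim$datasets, 10L)  # 4 clean + 2 variants x 3 clones
  recs <- lapply(sim$datasets, `[[`, "records")
  for (i in 1:4) expect_identical(recs[[i]], sim$base$records)
  # each corrupted variant's clones (datasets 5-7 and 8-10) are byte-identical
  expect_identical(recs[[5]], recs[[6]])
  expect_identical(recs[[6]], recs[[7]])
  expect_identical(recs[[8]], recs[[10]])
  expect_false(identical(recs[[5]], recs[[8]]))
  # every corrupted record differs from its original by one last-name edit
  d <- diag(utils::adist(recs[[5]]$last_name, sim$base$records$last_name))
  expect_true(all(d == 1))
})

test_that("type-3 corpora expose subset schemas and exact clone halving", {
  sim <- generate_type3(30, seed = 17)
  expect_length(sim$datasets, 6L)
  schemas <- lapply(sim$datasets[1:3], `[[`, "attributes")
  expect_true(all(!duplicated(lapply(schemas, sort))))  # pairwise distinct
  ex <- find_exact_clusters(sim$datasets)
  # every record merges with (at least) its clone
  mem <- ex$membership
  corpus <- ex$corpus
  for (i in 1:3) {
    a <- which(corpus$records$dataset_id == sprintf("reduced%d", i))
    b <- which(corpus$records$dataset_id == sprintf("reduced%d_clone", i))
    expect_equal(mem[a], mem[b])
  }
  expect_lte(ex$n_clusters, corpus$n / 2)
  expect_warning(generate_type3(5, seed = 1,
                                drop_plan = list("first_name",
                                                 c("first_name", "last_name"),
                                                 "last_name")),
                 NA)  # comparison attrs survive in the union -> no warning
  expect_warning(generate_type3(5, seed = 1,
                                drop_plan = list(c("first_name", "dob"),
                                                 "first_name",
                                                 c("first_name", "ssn"))),
                 "comparison attribute")
})

test_that("the walkthrough fixture reproduces the printed pipeline landmarks", {
  fx <- worked_example_fixture()
  expect_length(fx$datasets, 2L)
  expect_equal(sum(vapply(fx$datasets, function(d) d$n, integer(1))), 5L)
  expect_equal(fx$datasets[[1]]$records$dob[1], "05011976")
  res <- record_link(fx$datasets, fx$config)
  expect_equal(res$manifest$n_exact_clusters, 4L)
  expect_equal(res$manifest$n_final_clusters, 3L)
})

test_that("simulations write datasets, truth and metadata to disk", {
  dir <- withr::local_tempdir()
  sim <- generate_type1(20, seed = 5, copies = 3, p = 0.2)
  write_simulation(sim, dir)
  files <- list.files(dir)
  expect_setequal(files, c("copy01.csv", "copy02.csv", "copy03.csv",
                           "truth.csv", "metadata.txt"))
  back <- read_dataset(file.path(dir, "copy02.csv"), "copy02")
  expect_identical(back$records, sim$datasets[[2]]$records)
  tr <- utils::read.csv(file.path(dir, "truth.csv"), colClasses = "character")
  expect_equal(nrow(tr), 60L)
  meta <- readLines(file.path(dir, "metadata.txt"))
  expect_true(any(grepl("^seed = 5$", meta)))
})
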