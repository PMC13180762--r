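test_that("JSONL records build a hypergraph with remapped time indices", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_jsonl_fixture(f, c(
    '{"id":"p1","year":2000,"concepts":["TP53","EGFR","KRAS"]}',
    '{"id":"p2","year":2001,"concepts":["TP53","BRAF"]}',
    '{"id":"p3","year":2001,"concepts":["EGFR","BRAF","MYC"]}'))
  th <- read_hyperedges(f, "jsonl")
  expect_equal(length(th$edges), 3L)
  expect_equal(th$T_index, 1L)
  expect_equal(vapply(th$edges, function(e) e$t, integer(1)), c(0L, 1L, 1L))
  expect_equal(th$vocab$N, 5L)
  expect_equal(th$years, c(2000L, 2001L))
})

test_that("duplicate concepts within a record collapse to a set", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_jsonl_fixture(f,
    '{"id":"p1","year":2005,"concepts":["TP53","EGFR","TP53"]}')
  th <- read_hyperedges(f, "jsonl")
  expect_equal(length(th$edges[[1]]$members), 2L)
})

test_that("malformed and empty inputs raise parse errors naming the line", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_jsonl_fixture(f, c(
    '{"id":"p1","year":2000,"concepts":["A","B"]}',
    '{"id":"p2","year":2001,"concepts":[]}'))
  expect_error(read_hyperedges(f, "jsonl"), "line 2")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), f2)
  expect_error(read_hyperedges(f2, "jsonl"), "empty")
  f3 <- withr::local_tempfile(fileext = ".jsonl")
  write_jsonl_fixture(f3, "not json at all {{{")
  expect_error(read_hyperedges(f3, "jsonl"), "line 1")
})

test_that("write/read round trip preserves ids, years and member sets (both dialects)", {
  set.seed(41)
  th <- random_th(n_concepts = 10L, n_edges = 8L, n_years = 4L)
  for (dialect in c("jsonl", "tsv")) {
    f <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_hyperedges(th, f, dialect)
    th2 <- read_hyperedges(f, dialect)
    expect_equal(length(th2$edges), length(th$edges))
    for (i in seq_along(th$edges)) {
      e1 <- th$edges[[i]]; e2 <- th2$edges[[i]]
      expect_equal(sort(th2$vocab$labels[e2$members]),
                   sort(th$vocab$labels[e1$members]))
      expect_equal(th2$years[e2$t + 1L], th$years[e1$t + 1L])
      expect_equal(e2$source, e1$source)
    }
  }
})

test_that("size filter keeps exactly the in-range hyperedges and is idempotent", {
  sizes <- c(4L, 5L, 11L, 30L, 31L)
  th <- make_th(lapply(seq_along(sizes), function(i)
    list(2000L + i, seq_len(sizes[i]))), n_concepts = 31L)
  fl <- filter_by_size(th, 5L, 30L)
  expect_equal(sort(vapply(fl$edges, function(e) length(e$members), integer(1))),
               c(5L, 11L, 30L))
  fl2 <- filter_by_size(fl, 5L, 30L)
  expect_equal(length(fl2$edges), length(fl$edges))
  expect_identical(lapply(fl2$edges, `[[`, "members"),
                   lapply(fl$edges, `[[`, "members"))
  # identity case: all sizes in range
  th_ok <- make_th(list(list(2000L, 1:5), list(2001L, 2:7)))
  fl_ok <- filter_by_size(th_ok, 5L, 30L)
  expect_equal(length(fl_ok$edges), 2L)
  # empty hypergraph result
  th_small <- make_th(list(list(2000L, 1:2)))
  expect_equal(length(filter_by_size(th_small, 5L, 30L)$edges), 0L)
})

test_that("vocabulary compaction drops concepts with no surviving incidence", {
  th <- make_th(list(list(2000L, 1:5), list(2001L, c(1:4, 6L))), n_concepts = 7L)
  fl <- filter_by_size(th, 5L, 30L)
  expect_equal(fl$vocab$N, 6L)   # concept 7 never used, dropped
  fl_keep <- filter_by_size(th, 5L, 30L, compact_vocab = FALSE)
  expect_equal(fl_keep$vocab$N, 7L)
})

test_that("period split halves validation with the odd element in val_opt", {
  mk <- function(n_val) {
    edges <- c(lapply(1:4, function(i) list(2000L, c(i, i + 1L, 20L))),
               lapply(seq_len(n_val), function(i) list(2001L, c(i, i + 2L, 21L))),
               lapply(1:3, function(i) list(2002L, c(i, i + 3L, 22L))))
    make_th(edges, n_concepts = 22L)
  }
  sy <- list(train = c(2000, 2000), val = c(2001, 2001), test = c(2002, 2002))
  s10 <- split_by_period(mk(10L), sy, val_half_seed = 5L)
  expect_equal(length(s10$val_opt), 5L)
  expect_equal(length(s10$val_trail), 5L)
  s7 <- split_by_period(mk(7L), sy, val_half_seed = 5L)
  expect_equal(length(s7$val_opt), 4L)
  expect_equal(length(s7$val_trail), 3L)
  # determinism and disjointness
  s7b <- split_by_period(mk(7L), sy, val_half_seed = 5L)
  expect_identical(s7$val_opt, s7b$val_opt)
  expect_length(intersect(s7$val_opt, s7$val_trail), 0L)
  expect_setequal(c(s7$val_opt, s7$val_trail), 5:11)
})

test_that("leakage removal drops only exact member-set duplicates of train", {
  th <- make_th(list(
    list(2000L, c(1L, 2L, 3L, 4L, 5L)),     # train
    list(2001L, c(1L, 2L, 3L, 4L, 5L)),     # val: exact duplicate -> removed
    list(2001L, c(1L, 2L, 3L, 4L, 6L)),     # val: 4/5 overlap -> retained
    list(2002L, c(1L, 2L, 3L, 4L, 5L)),     # test: duplicate at other year -> removed
    list(2002L, c(2L, 3L, 4L, 5L, 6L))))    # test: retained
  sy <- list(train = c(2000, 2000), val = c(2001, 2001), test = c(2002, 2002))
  s <- remove_split_leakage(split_by_period(th, sy, 1L))
  expect_equal(s$train, 1L)
  expect_setequal(c(s$val_opt, s$val_trail), 3L)
  expect_equal(s$test, 5L)
  # exhaustive property: no val/test member set equals any train member set
  keys <- function(ids) vapply(th$edges[ids], function(e)
    paste(e$members, collapse = ","), character(1))
  expect_length(intersect(keys(c(s$val_opt, s$val_trail, s$test)), keys(s$train)), 0L)
  # empty test split stays empty without error
  th2 <- make_th(list(list(2000L, 1:3), list(2001L, 2:4)))
  sy2 <- list(train = c(2000, 2000), val = c(2001, 2001), test = c(2005, 2006))
  s2 <- suppressWarnings(split_by_period(th2, sy2, 1L))
  expect_length(remove_split_leakage(s2)$test, 0L)
})

test_that("incidence matrix has exact memberships and column sums equal sizes", {
  th <- make_th(list(list(2000L, c(1L, 2L)), list(2000L, c(2L, 3L))))
  H <- incidence(th$edges, th$vocab)
  expect_equal(unname(H), rbind(c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(unname(colSums(H)),
               vapply(th$edges, function(e) length(e$members), integer(1)) * 1.0)
  # degenerate shapes
  expect_equal(dim(incidence(list(), th$vocab)), c(3L, 0L))
  full <- make_th(list(list(2000L, 1:3)))
  expect_equal(unname(incidence(full$edges, full$vocab)), matrix(1, 3, 1))
  # random property: column sums always equal hyperedge sizes
  set.seed(11)
  for (i in 1:10) {
    thr <- random_th()
    Hr <- incidence(thr$edges, thr$vocab)
    expect_equal(unname(colSums(Hr)),
                 as.numeric(vapply(thr$edges, function(e) length(e$members), integer(1))))
  }
})
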