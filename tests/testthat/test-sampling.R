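test_that("hard negatives replace exactly ceiling(r * size) members and keep size", {
  e <- new_hyperedge_for_test(1:10, t = 2L)
  set.seed(1)
  neg <- hard_negative(e, 0.2, 1:40)
  expect_length(neg$members, 10L)
  expect_equal(length(setdiff(e$members, neg$members)), 2L)
  expect_equal(neg$t, e$t)
  # ceiling rule: |e| = 5, r = 0.2 -> exactly 1 replaced
  e5 <- new_hyperedge_for_test(1:5, t = 0L)
  neg5 <- hard_negative(e5, 0.2, 1:40)
  expect_equal(length(setdiff(e5$members, neg5$members)), 1L)
  # r = 0 is the identity
  expect_equal(hard_negative(e, 0, 1:40)$members, e$members)
})

test_that("hard negative contracts hold over many random draws", {
  set.seed(7)
  for (i in 1:250) {
    size <- sample(3:20, 1L)
    r <- sample(c(0.1, 0.2, 0.5, 1), 1L)
    e <- new_hyperedge_for_test(sample.int(100L, size), t = 1L)
    neg <- hard_negative(e, r, 1:100)
    k <- ceiling(r * size)
    expect_length(neg$members, size)
    expect_equal(length(setdiff(e$members, neg$members)), k)
    expect_equal(length(intersect(e$members, neg$members)) / size, 1 - k / size)
    if (r == 1) expect_length(intersect(e$members, neg$members), 0L)
    expect_false(any(duplicated(neg$members)))
  }
})

test_that("hard negative errors when candidates cannot supply the replacements", {
  e <- new_hyperedge_for_test(1:10, t = 0L)
  expect_error(hard_negative(e, 0.5, 1:12), "candidates")
})

test_that("global negatives exclude the given id and are uniform", {
  th <- make_th(list(list(2000L, 1:3), list(2000L, 2:4),
                     list(2001L, 3:5), list(2001L, 4:6)))
  set.seed(3)
  draws <- replicate(9000, global_negative(th, 1L)$id)
  expect_false(any(draws == 1L))
  tab <- table(factor(draws, levels = 2:4))
  chisq <- sum((tab - 3000)^2 / 3000)
  expect_lt(chisq, qchisq(0.999, df = 2))   # uniform over the 3 others
  # two-hyperedge graph: forced choice; single hyperedge: error
  th2 <- make_th(list(list(2000L, 1:3), list(2001L, 2:4)))
  expect_equal(global_negative(th2, 1L)$id, 2L)
  th1 <- make_th(list(list(2000L, 1:3)))
  expect_error(global_negative(th1, 1L), "fewer than 2")
})

test_that("trails walk backward deterministically on a forced chain", {
  th <- chain_th(4L)
  tr <- trail(th, th$edges[[4]])
  expect_equal(tr$predecessors, c(1L, 2L, 3L))
  # target at t = 0 has no earlier steps
  expect_length(trail(th, th$edges[[1]])$predecessors, 0L)
})

test_that("trails truncate without overlap unless gap skipping is allowed", {
  # year 2001 hyperedge shares nothing with the 2002 target; 2000 does
  th <- make_th(list(list(2000L, c(1L, 2L)), list(2001L, c(9L, 10L)),
                     list(2002L, c(1L, 3L))), n_concepts = 10L)
  tgt <- th$edges[[3]]
  expect_length(trail(th, tgt, allow_gap_skip = FALSE)$predecessors, 0L)
  expect_equal(trail(th, tgt, allow_gap_skip = TRUE)$predecessors, 1L)
})

test_that("generated trails satisfy ordering and overlap invariants", {
  set.seed(21)
  sim <- tiny_sim()
  th <- sim$th
  n_checked <- 0L
  for (rep in 1:1000) {
    tid <- sample.int(length(th$edges), 1L)
    tr <- trail(th, th$edges[[tid]])
    seq_edges <- c(th$edges[tr$predecessors], th$edges[tid])
    ts <- vapply(seq_edges, function(e) e$t, integer(1))
    if (length(seq_edges) > 1L) {
      expect_true(all(diff(ts) > 0L))
      for (j in seq_len(length(seq_edges) - 1L))
        expect_gte(length(intersect(seq_edges[[j]]$members,
                                    seq_edges[[j + 1L]]$members)), 1L)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 500L)
})

test_that("overlap-weighted selection frequencies are overlap-proportional", {
  # three candidates with overlaps 1, 2, 3 against the target
  th <- make_th(list(
    list(2000L, c(1L, 11L, 12L, 13L)),          # overlap 1
    list(2000L, c(1L, 2L, 14L, 15L)),           # overlap 2
    list(2000L, c(1L, 2L, 3L, 16L)),            # overlap 3
    list(2001L, c(1L, 2L, 3L, 4L))), n_concepts = 16L)
  tgt <- th$edges[[4]]
  set.seed(5)
  draws <- replicate(10000, trail(th, tgt, policy = "overlap_weighted")$predecessors)
  tab <- table(factor(draws, levels = 1:3))
  expected <- 10000 * c(1, 2, 3) / 6
  chisq <- sum((tab - expected)^2 / expected)
  expect_lt(chisq, qchisq(0.999, df = 2))
  # overlap_power policy: frequencies proportional to overlap^gamma
  draws_p <- replicate(10000, trail(th, tgt, policy = "overlap_power",
                                    gamma = 3)$predecessors)
  tab_p <- table(factor(draws_p, levels = 1:3))
  expected_p <- 10000 * c(1, 8, 27) / 36
  chisq_p <- sum((tab_p - expected_p)^2 / expected_p)
  expect_lt(chisq_p, qchisq(0.999, df = 2))
  # uniform policy: equal frequencies
  draws_u <- replicate(10000, trail(th, tgt, policy = "uniform")$predecessors)
  tab_u <- table(factor(draws_u, levels = 1:3))
  chisq_u <- sum((tab_u - 10000 / 3)^2 / (10000 / 3))
  expect_lt(chisq_u, qchisq(0.999, df = 2))
})

test_that("instance assembly counts negatives per scored position and is deterministic", {
  sim <- tiny_sim()
  th <- sim$th
  targets <- th$snapshots[[4]][1:3]
  cfg_off <- sampler_config(per_step_negatives = FALSE, sampler_seed = 9L)
  insts <- build_instances(targets, th, cfg_off)
  expect_length(insts, 3L)
  for (i in insts) {
    expect_length(i$hard, 1L)
    expect_length(i$gns, 1L)
    expect_equal(i$scored, length(i$seq_ids))
  }
  cfg_on <- sampler_config(per_step_negatives = TRUE, sampler_seed = 9L)
  insts_on <- build_instances(targets, th, cfg_on)
  for (i in insts_on) {
    expect_length(i$hard, length(i$seq_ids))
    expect_length(i$gns, length(i$seq_ids))
    # hard negatives preserve the timestamp of the positive they corrupt
    for (j in seq_along(i$scored))
      expect_equal(i$hard[[j]]$t, i$ts[i$scored[j]])
  }
  expect_identical(build_instances(targets, th, cfg_on), insts_on)
  # negatives restricted to a pool never come from outside it
  pool <- th$snapshots[[1]]
  insts_p <- build_instances(targets, th, cfg_on, negative_pool = pool)
  for (i in insts_p) for (g in i$gns) expect_true(g$id %in% pool)
})
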