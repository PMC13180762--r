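test_that("zero epochs leave parameters at initialization", {
  sim <- tiny_sim()
  cfg <- tiny_config(epochs = 0L, seed = 5L)
  fit <- hypertrail(sim$th, cfg)
  X0 <- init_concept_features(fit$PE, cfg$d)
  expect_identical(fit$params$X, X0)
  expect_equal(nrow(fit$log), 0L)
})

test_that("training is deterministic given the seed", {
  sim <- tiny_sim()
  cfg <- tiny_config(epochs = 2L, seed = 6L)
  f1 <- hypertrail(sim$th, cfg)
  f2 <- hypertrail(sim$th, cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)
  cfg2 <- tiny_config(epochs = 2L, seed = 7L)
  f3 <- hypertrail(sim$th, cfg2)
  expect_false(identical(f1$params$scorer$S2, f3$params$scorer$S2))
})

test_that("full-model gradients agree with finite differences", {
  sim <- tiny_sim(seed = 11L)
  th <- sim$th
  cfg <- hypertrail_config(d = 6L, d_time = 2L, n_heads = 2L, ffn_width = 5L,
                           scorer_hidden = 4L, walk_length_L = 3L,
                           epochs = 0L, seed = 3L, beta = 0.5)
  splits <- suppressWarnings(split_by_period(
    th, list(train = c(2000, 2002), val = c(2003, 2003), test = c(2004, 2004)), 7L))
  PE <- hypertrail:::positional_encodings_for(th, splits, cfg)
  params <- hypertrail:::init_params(init_concept_features(PE, cfg$d), cfg)
  insts <- build_instances(splits$train, th, sampler_config(sampler_seed = 11L))
  inst <- insts[[which(vapply(insts, function(i) length(i$seq_ids), integer(1)) >= 2L)[1]]]
  loss_at <- function(p) {
    hypertrail:::instance_pass(inst, th, p, cfg, hypertrail:::grad_env(p, cfg))
  }
  acc <- hypertrail:::grad_env(params, cfg)
  loss_at_params <- hypertrail:::instance_pass(inst, th, params, cfg, acc)
  g <- hypertrail:::grads_from_env(acc, params)
  expect_true(is.finite(loss_at_params))
  eps <- 1e-6
  fd <- function(mutate) {
    p_up <- mutate(params, eps); p_dn <- mutate(params, -eps)
    (loss_at(p_up) - loss_at(p_dn)) / (2 * eps)
  }
  U <- sort(unique(unlist(lapply(th$edges[inst$seq_ids], `[[`, "members"))))
  checks <- list(
    list(fd(function(p, e) { p$X[U[1], 1] <- p$X[U[1], 1] + e; p }), g$X[U[1], 1]),
    list(fd(function(p, e) { p$hcn$layers[[1]]$A1[2, 3] <- p$hcn$layers[[1]]$A1[2, 3] + e; p }),
         g$hcn$layers[[1]]$A1[2, 3]),
    list(fd(function(p, e) { p$Wt[1] <- p$Wt[1] + e; p }), g$Wt[1]),
    list(fd(function(p, e) { p$blocks[[1]]$Wq[1, 2] <- p$blocks[[1]]$Wq[1, 2] + e; p }),
         g$blocks[[1]]$Wq[1, 2]),
    list(fd(function(p, e) { p$blocks[[1]]$F1[3, 1] <- p$blocks[[1]]$F1[3, 1] + e; p }),
         g$blocks[[1]]$F1[3, 1]),
    list(fd(function(p, e) { p$blocks[[1]]$g1[2] <- p$blocks[[1]]$g1[2] + e; p }),
         g$blocks[[1]]$g1[2]),
    list(fd(function(p, e) { p$scorer$S2[1, 1] <- p$scorer$S2[1, 1] + e; p }),
         g$scorer$S2[1, 1]),
    list(fd(function(p, e) { p$bt <- p$bt + e; p }), g$bt))
  for (chk in checks)
    expect_equal(chk[[2]], chk[[1]], tolerance = 1e-4)
})

test_that("a single easy instance can be overfit", {
  # one chain lineage: trail context pins down the target exactly
  th <- chain_th(4L)
  cfg <- hypertrail_config(d = 8L, d_time = 2L, walk_length_L = 3L,
                           n_heads = 2L, ffn_width = 10L, scorer_hidden = 8L,
                           r = 0.5, lr = 0.01, epochs = 120L, batch_size = 1L,
                           beta = 0.5, seed = 8L, min_size = 1L, max_size = 30L)
  splits <- suppressWarnings(split_by_period(
    th, list(train = c(2000, 2001), val = c(2002, 2002), test = c(2003, 2003)), 1L))
  PE <- hypertrail:::positional_encodings_for(th, splits, cfg)
  params <- hypertrail:::init_params(init_concept_features(PE, cfg$d), cfg)
  insts <- build_instances(2L, th, sampler_config(r = 0.5, sampler_seed = 2L),
                           negative_pool = splits$train)
  tr <- train_model(insts, th, params, cfg, resample_negatives = FALSE)
  inst <- insts[[1]]
  n <- length(inst$seq_ids)
  members <- lapply(th$edges[inst$seq_ids], `[[`, "members")
  s_pos <- hypertrail:::model_forward(members, inst$ts, tr$params, cfg)$s[n]
  j <- match(n, inst$scored)
  members[[n]] <- inst$hard[[j]]$members
  s_hard <- hypertrail:::model_forward(members, inst$ts, tr$params, cfg)$s[n]
  expect_gt(s_pos, 0.9)
  expect_lt(s_hard, 0.1)
  # smoothed loss decreased
  expect_lt(mean(tail(tr$log$loss, 10)), mean(head(tr$log$loss, 10)))
})

test_that("training loss decreases on planted-lineage data in most seeds", {
  ok <- 0L
  for (s in 1:5) {
    sim <- tiny_sim(seed = 20L + s)
    cfg <- tiny_config(epochs = 10L, seed = s, lr = 3e-3)
    fit <- hypertrail(sim$th, cfg)
    sm <- stats::filter(fit$log$loss, rep(1 / 3, 3), sides = 1)
    if (mean(tail(fit$log$loss, 3)) < mean(head(fit$log$loss, 3))) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("non-finite loss aborts with a diagnostic", {
  th <- chain_th(3L)
  cfg <- hypertrail_config(d = 4L, d_time = 2L, walk_length_L = 3L,
                           n_heads = 1L, epochs = 1L, min_size = 1L,
                           seed = 1L)
  splits <- suppressWarnings(split_by_period(
    th, list(train = c(2000, 2000), val = c(2001, 2001), test = c(2002, 2002)), 1L))
  PE <- hypertrail:::positional_encodings_for(th, splits, cfg)
  params <- hypertrail:::init_params(init_concept_features(PE, cfg$d), cfg)
  params$scorer$s2b <- 1e308
  params$scorer$S2[] <- 1e308
  insts <- build_instances(1L, th, sampler_config(sampler_seed = 3L))
  expect_error(train_model(insts, th, params, cfg), "non-finite")
})

test_that("model methods print, plot, coefficients and predictions work", {
  sim <- tiny_sim()
  fit <- hypertrail(sim$th, tiny_config(epochs = 1L, seed = 9L))
  expect_output(print(fit), "Temporal hypergraph contrastive model")
  expect_output(summary(fit), "splits")
  expect_type(coef(fit), "list")
  expect_true(is.matrix(coef(fit)$X))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  p <- predict(fit, fit$splits$test[1:3])
  expect_length(p, 3L)
  expect_true(all(p > 0 & p < 1))
  # deterministic under the same seed
  expect_identical(p, predict(fit, fit$splits$test[1:3]))
})
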