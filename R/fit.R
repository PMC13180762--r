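# Model assembly, hand-derived reverse-mode gradients, Adam optimizer, the
# training loop, and the top-level `hypertrail()` fitting function.

#' Model and pipeline configuration
#'
#' All tunable parameters of the pipeline, with desk-scale defaults. The
#' token dimension is `d + d_time` and must be divisible by `n_heads`.
#'
#' @param min_size,max_size Hyperedge size filter bounds (defaults 5, 30).
#' @param split_years Named list `train`/`val`/`test` of calendar-year
#'   ranges; `NULL` (default) assigns the last year to test, the
#'   second-to-last to validation and the rest to training.
#' @param val_half_seed Seed for the random validation halving.
#' @param r Hard-negative replacement fraction (default 0.2).
#' @param predecessor_policy,per_step_negatives,allow_gap_skip See
#'   [sampler_config()].
#' @param d Concept/hyperedge embedding dimension (default 32).
#' @param d_time Time-encoding dimension (default 8).
#' @param walk_length_L Random-walk positional-encoding length (default 5).
#' @param hcn_layers Hypergraph-convolution layers (default 1).
#' @param hcn_nonlinearity `"tanh"` (default), `"relu"` or `"identity"`.
#' @param hcn_phi1 Hyperedge aggregator phi1: `"mean"` (default) or `"sum"`.
#' @param hcn_phi2_agg Incident-message aggregation in the node update:
#'   `"sum"` (default; preserves local degree) or `"mean"`.
#' @param pe_graph_scope `"train_only"` (default; positional encodings are
#'   computed on the training-period hypergraph to avoid structural leakage
#'   from future periods) or `"full"`.
#' @param n_heads Attention heads (default 2).
#' @param n_blocks Encoder blocks (default 1).
#' @param ffn_width Feed-forward width (default `2 * (d + d_time)`).
#' @param scorer_hidden Scorer hidden width (default `d + d_time`).
#' @param alpha,margin,beta,eps See [loss_config()].
#' @param lr Adam learning rate (default `1e-2`).
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to all
#'   weight matrices and the concept feature table (default 0).
#' @param epochs Training epochs (default 40).
#' @param batch_size Instances per gradient step (default 32).
#' @param seed Master seed; sampler and initialization seeds derive from it.
#' @return List of class `hypertrail_config`.
#' @export
hypertrail_config <- function(min_size = 5L, max_size = 30L,
                              split_years = NULL, val_half_seed = NULL,
                              r = 0.2, predecessor_policy = "overlap_power",
                              trail_gamma = 8, per_step_negatives = TRUE,
                              allow_gap_skip = FALSE,
                              d = 32L, d_time = 8L, walk_length_L = 5L,
                              hcn_layers = 1L, hcn_nonlinearity = "tanh",
                              hcn_phi1 = "mean", hcn_phi2_agg = "sum",
                              pe_graph_scope = c("train_only", "full"),
                              n_heads = 2L, n_blocks = 1L,
                              ffn_width = 2L * (d + d_time),
                              scorer_hidden = d + d_time,
                              alpha = 0.5, margin = 1, beta = 0.5, eps = 1e-7,
                              lr = 1e-2, weight_decay = 0,
                              epochs = 40L, batch_size = 32L,
                              seed = 1L) {
  pe_graph_scope <- match.arg(pe_graph_scope)
  d_token <- d + d_time
  if (d_token %% n_heads != 0L)
    stopf("d + d_time = %d must be divisible by n_heads = %d", d_token, n_heads)
  structure(list(min_size = min_size, max_size = max_size,
                 split_years = split_years,
                 val_half_seed = val_half_seed,
                 r = r, predecessor_policy = predecessor_policy,
                 trail_gamma = trail_gamma,
                 per_step_negatives = per_step_negatives,
                 allow_gap_skip = allow_gap_skip,
                 d = d, d_time = d_time, d_token = d_token,
                 walk_length_L = walk_length_L,
                 hcn_layers = hcn_layers, hcn_nonlinearity = hcn_nonlinearity,
                 hcn_phi1 = hcn_phi1, hcn_phi2_agg = hcn_phi2_agg,
                 pe_graph_scope = pe_graph_scope,
                 n_heads = n_heads, n_blocks = n_blocks,
                 ffn_width = ffn_width, scorer_hidden = scorer_hidden,
                 alpha = alpha, margin = margin, beta = beta, eps = eps,
                 lr = lr, weight_decay = weight_decay,
                 epochs = epochs, batch_size = batch_size,
                 seed = as.integer(seed)),
            class = "hypertrail_config")
}

# ---- parameter initialization -------------------------------------------

init_params <- function(X0, config) {
  with_seed(derive_seed(config$seed, 11L), {
    list(X = X0,
         hcn = hcn_params(config$d, config$hcn_layers, config$hcn_nonlinearity,
                          config$hcn_phi1 %||% "mean",
                          config$hcn_phi2_agg %||% "sum"),
         # geometric frequencies no faster than one cycle per ~6 steps: the
         # encoding varies smoothly in t, so it extrapolates to time indices
         # beyond the training range instead of aliasing
         Wt = 1 / 10^seq(0, 1.5, length.out = config$d_time),
         bt = 0,
         blocks = lapply(seq_len(config$n_blocks), function(b)
           attention_params(config$d_token, config$n_heads, config$ffn_width)),
         scorer = scorer_params(config$d_token, config$scorer_hidden))
  })
}

# ---- full model forward / backward --------------------------------------

model_forward <- function(members_list, ts, params, config) {
  hc <- hcn_forward(members_list, params$X, params$hcn)
  Arg <- outer(as.numeric(ts), params$Wt) + params$bt
  Tok <- cbind(hc$Z, cos(Arg))
  caches <- vector("list", config$n_blocks)
  Zb <- Tok
  for (b in seq_len(config$n_blocks)) {
    bf <- block_forward(Zb, params$blocks[[b]])
    caches[[b]] <- bf$cache
    Zb <- bf$out
  }
  sc <- scorer_forward(Zb, params$scorer)
  list(s = sc$s, H = Zb,
       cache = list(hcn = hc$cache, Arg = Arg, ts = as.numeric(ts),
                    blocks = caches, scorer = sc$cache))
}

# dlogit: length-n gradient on the pre-sigmoid logits; dHext: n x d_token
# external gradient on the final contextualized embeddings (or NULL).
model_backward <- function(dlogit, dHext, fwd, params, config) {
  sb <- scorer_backward(dlogit, fwd$cache$scorer, params$scorer)
  dH <- sb$dH
  if (!is.null(dHext)) dH <- dH + dHext
  bgrads <- vector("list", config$n_blocks)
  for (b in rev(seq_len(config$n_blocks))) {
    bb <- block_backward(dH, fwd$cache$blocks[[b]], params$blocks[[b]])
    bgrads[[b]] <- bb$grads
    dH <- bb$dZ
  }
  d <- config$d
  dZ <- dH[, seq_len(d), drop = FALSE]
  dPsi <- dH[, d + seq_len(config$d_time), drop = FALSE]
  dArg <- -sin(fwd$cache$Arg) * dPsi
  hb <- hcn_backward(dZ, fwd$cache$hcn)
  list(blocks = bgrads, scorer = sb$grads, hcn = hb$layers,
       Wt = colSums(dArg * fwd$cache$ts), bt = sum(dArg),
       dXU = hb$dXU, U = hb$U)
}

# ---- gradient bookkeeping ------------------------------------------------

# Numeric-leaf tree arithmetic over nested parameter lists.
tree_zero <- function(x) {
  if (is.list(x)) lapply(x, tree_zero)
  else if (is.numeric(x)) x * 0
  else x
}

# Adds gradient tree `b` into `a`; matches by name where names exist so a
# gradient tree may omit non-learnable fields (e.g. `n_heads`).
tree_add <- function(a, b) {
  if (is.list(a)) {
    keys <- if (!is.null(names(b))) names(b) else seq_along(b)
    for (k in keys) a[[k]] <- tree_add(a[[k]], b[[k]])
    a
  } else if (is.numeric(a)) a + b else a
}

tree_scale <- function(a, s) {
  if (is.list(a)) lapply(a, tree_scale, s = s)
  else if (is.numeric(a)) a * s else a
}

tree_sq_sum <- function(a) {
  if (is.list(a)) sum(vapply(a, tree_sq_sum, numeric(1)))
  else if (is.numeric(a)) sum(a^2) else 0
}

adam_step <- function(p, g, st, lr, t, b1 = 0.9, b2 = 0.999, e = 1e-8,
                      wd = 0) {
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out_m <- m; out_v <- v
      keys <- if (!is.null(names(g))) names(g) else seq_along(g)
      for (i in keys) {
        r <- step(p[[i]], g[[i]], m[[i]], v[[i]])
        p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(p = p, m = out_m, v = out_v)
    } else if (is.numeric(p)) {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mh <- m / (1 - b1^t)
      vh <- v / (1 - b2^t)
      # decoupled decay on matrices only (biases, gains and the time encoder
      # are left undecayed, as is conventional)
      dec <- if (wd > 0 && is.matrix(p)) lr * wd * p else 0
      list(p = p - lr * mh / (sqrt(vh) + e) - dec, m = m, v = v)
    } else list(p = p, m = m, v = v)
  }
  step(p, g, st$m, st$v)
}

# Gradient tree (everything except X) matching model_backward's pieces.
empty_grads <- function(params) {
  list(blocks = lapply(params$blocks, tree_zero),
       scorer = tree_zero(params$scorer),
       hcn = tree_zero(params$hcn$layers),
       Wt = 0 * params$Wt, bt = 0)
}

# Mutable gradient accumulator: one environment per parameter group, so
# per-pass accumulation never copies list spines.
grad_env <- function(params, config) {
  as_env <- function(x) list2env(tree_zero(x), parent = emptyenv())
  acc <- new.env(parent = emptyenv())
  acc$blocks <- lapply(params$blocks, function(b)
    as_env(b[setdiff(names(b), "n_heads")]))
  acc$scorer <- as_env(params$scorer)
  acc$hcn <- lapply(params$hcn$layers, as_env)
  acc$Wt <- 0 * params$Wt
  acc$bt <- 0
  acc$dX <- matrix(0, nrow(params$X), config$d)
  acc
}

# Fold one backward pass into the accumulator.
absorb_grads <- function(acc, mb) {
  for (b in seq_along(mb$blocks)) {
    eb <- acc$blocks[[b]]; pb <- mb$blocks[[b]]
    for (nm in names(pb)) eb[[nm]] <- eb[[nm]] + pb[[nm]]
  }
  es <- acc$scorer; ps <- mb$scorer
  for (nm in names(ps)) es[[nm]] <- es[[nm]] + ps[[nm]]
  for (l in seq_along(mb$hcn)) {
    el <- acc$hcn[[l]]; pl <- mb$hcn[[l]]
    for (nm in names(pl)) el[[nm]] <- el[[nm]] + pl[[nm]]
  }
  acc$Wt <- acc$Wt + mb$Wt
  acc$bt <- acc$bt + mb$bt
  acc$dX[mb$U, ] <- acc$dX[mb$U, , drop = FALSE] + mb$dXU
  invisible(acc)
}

# Snapshot the accumulator as the nested gradient tree used by the tests
# and the optimizer ("X", "hcn", "Wt", "bt", "blocks", "scorer").
grads_from_env <- function(acc, params) {
  list(X = acc$dX,
       hcn = list(layers = lapply(acc$hcn, as.list),
                  nonlinearity = params$hcn$nonlinearity),
       Wt = acc$Wt, bt = acc$bt,
       blocks = lapply(acc$blocks, as.list),
       scorer = as.list(acc$scorer))
}

# ---- per-instance loss and gradients ------------------------------------

# Run the positive pass plus hard/global negative passes for one instance,
# accumulating loss and gradients. `acc` is an environment holding `g`
# (gradient tree) and `dX` (N x d matrix); returns the instance loss.
instance_pass <- function(inst, th, params, config, acc) {
  lcfg <- loss_config(config$alpha, config$margin, config$beta, config$eps)
  members <- lapply(th$edges[inst$seq_ids], `[[`, "members")
  ts <- inst$ts
  n <- length(members)
  fwd_pos <- model_forward(members, ts, params, config)
  s_all <- fwd_pos$s
  dlogit_pos <- numeric(n)
  dH_pos <- if (config$beta > 0) matrix(0, n, config$d_token) else NULL
  loss <- 0
  neg_passes <- list()
  for (j in seq_along(inst$scored)) {
    k <- inst$scored[j]
    # hard negative pass: sequence truncated at k, negative substituted at k
    hj <- inst$hard[[j]]
    mh <- members[seq_len(k)]; mh[[k]] <- hj$members
    th_ts <- ts[seq_len(k)]; th_ts[k] <- hj$t
    fwd_h <- model_forward(mh, th_ts, params, config)
    # global negative pass: its own timestamp, at position k
    gj <- inst$gns[[j]]
    mg <- members[seq_len(k)]; mg[[k]] <- gj$members
    tg_ts <- ts[seq_len(k)]; tg_ts[k] <- gj$t
    fwd_g <- model_forward(mg, tg_ts, params, config)
    s_pos <- s_all[k]; s_hard <- fwd_h$s[k]; s_gns <- fwd_g$s[k]
    loss <- loss + bce_loss(s_pos, s_hard, s_gns, config$eps)
    dlogit_pos[k] <- dlogit_pos[k] + (s_pos - 1)
    dlh <- numeric(k); dlh[k] <- s_hard
    dlg <- numeric(k); dlg[k] <- s_gns
    dHh <- NULL; dHg <- NULL
    if (config$beta > 0 && k > 1L) {
      a <- fwd_pos$H[k - 1L, ]; p <- fwd_pos$H[k, ]
      nh <- fwd_h$H[k, ]; ng <- fwd_g$H[k, ]
      loss <- loss + config$beta *
        contrastive_loss(a, p, nh, ng, config$alpha, config$margin)
      cg <- contrastive_loss_grads(a, p, nh, ng, config$alpha, config$margin)
      dH_pos[k - 1L, ] <- dH_pos[k - 1L, ] + config$beta * cg$d_prev
      dH_pos[k, ] <- dH_pos[k, ] + config$beta * cg$d_pos
      dHh <- matrix(0, k, config$d_token); dHh[k, ] <- config$beta * cg$d_hard
      dHg <- matrix(0, k, config$d_token); dHg[k, ] <- config$beta * cg$d_gns
    }
    neg_passes[[length(neg_passes) + 1L]] <- list(fwd = fwd_h, dl = dlh, dH = dHh)
    neg_passes[[length(neg_passes) + 1L]] <- list(fwd = fwd_g, dl = dlg, dH = dHg)
  }
  absorb_grads(acc, model_backward(dlogit_pos, dH_pos, fwd_pos, params, config))
  for (np in neg_passes)
    absorb_grads(acc, model_backward(np$dl, np$dH, np$fwd, params, config))
  loss
}

#' Train the temporal hypergraph model
#'
#' Runs the training loop: for each instance, a positive forward pass over
#' its trail-plus-target sequence, then one forward pass per scored position
#' with the hard (resp. global) negative substituted at that position, from
#' which only that position's score and embedding are read. Gradients of the
#' combined BCE + contrastive objective are accumulated over a batch,
#' averaged, globally clipped and applied with Adam. Deterministic given the
#' configuration seed.
#'
#' @param instances Instances from [build_instances()].
#' @param th The [temporal_hypergraph()] the instance ids refer to.
#' @param params Initial parameters (from the internal initializer or a
#'   previous fit's `$params`).
#' @param config A [hypertrail_config()].
#' @param resample_negatives Draw fresh hard/global negatives each epoch
#'   (default `TRUE`); seeds derive from the configuration seed so training
#'   stays deterministic.
#' @param negative_pool Hyperedge ids global negatives are drawn from when
#'   resampling (default: every hyperedge appearing in the instances'
#'   sequences).
#' @return List with `params` (trained) and `log` (data frame of per-epoch
#'   mean instance loss).
#' @export
train_model <- function(instances, th, params, config,
                        resample_negatives = TRUE, negative_pool = NULL) {
  if (length(instances) == 0L) stopf("train_model: no training instances")
  negative_pool <- negative_pool %||%
    sort(unique(unlist(lapply(instances, `[[`, "seq_ids"))))
  st <- list(m = tree_zero(params), v = tree_zero(params))
  n_inst <- length(instances)
  epoch_loss <- numeric(config$epochs)
  tstep <- 0L
  N <- nrow(params$X)
  with_seed(derive_seed(config$seed, 23L), {
    for (ep in seq_len(config$epochs)) {
      if (resample_negatives && ep > 1L)
        instances <- resample_negatives(instances, th, config$r, negative_pool,
                                        seed = derive_seed(config$seed, 1000L + ep))
      ord <- sample.int(n_inst)
      total <- 0
      for (start in seq(1L, n_inst, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n_inst)]
        acc <- grad_env(params, config)
        for (ii in idx)
          total <- total + instance_pass(instances[[ii]], th, params, config, acc)
        if (!is.finite(total))
          stopf("train_model: non-finite loss at epoch %d; try a lower learning rate", ep)
        g <- tree_scale(grads_from_env(acc, params), 1 / length(idx))
        gn <- sqrt(tree_sq_sum(g))
        if (!is.finite(gn))
          stopf("train_model: non-finite gradients at epoch %d; try a lower learning rate", ep)
        if (gn > 5) g <- tree_scale(g, 5 / gn)
        tstep <- tstep + 1L
        res <- adam_step(params, g, st, config$lr, tstep,
                         wd = config$weight_decay %||% 0)
        params <- res$p; st$m <- res$m; st$v <- res$v
      }
      epoch_loss[ep] <- total / n_inst
    }
  })
  list(params = params, log = data.frame(epoch = seq_len(config$epochs),
                                         loss = epoch_loss))
}

# ---- top-level fit -------------------------------------------------------

default_split_years <- function(years) {
  uy <- sort(unique(years))
  if (length(uy) < 3L) stopf("need at least 3 distinct years to split")
  list(train = c(uy[1], uy[length(uy) - 2L]),
       val = c(uy[length(uy) - 1L], uy[length(uy) - 1L]),
       test = c(uy[length(uy)], uy[length(uy)]))
}

#' Fit a temporal hypergraph contrastive model
#'
#' The top-level fitting function. Filters hyperedges by size, splits by
#' period (halving the validation years into an optimization half and a
#' trail half), removes train/evaluation leakage, computes random-walk
#' positional encodings on the training-period bipartite expansion,
#' assembles training instances (trail, hard negative and global negative
#' per scored position), and trains the causally masked transformer with the
#' combined BCE + time-anchored contrastive objective.
#'
#' @param th A [temporal_hypergraph()], e.g. from [read_hyperedges()] or
#'   [simulate_hypergraph()].
#' @param config A [hypertrail_config()].
#' @return An object of class `hypertrail`: `params`, `config`, `th` (the
#'   filtered hypergraph), `splits`, `instances`, `PE`, and `log`.
#' @seealso [evaluate_model()], [predict.hypertrail()]
#' @export
hypertrail <- function(th, config = hypertrail_config()) {
  thf <- filter_by_size(th, config$min_size, config$max_size)
  split_years <- config$split_years %||%
    default_split_years(vapply(thf$edges, function(e) thf$years[e$t + 1L], integer(1)))
  splits <- split_by_period(thf, split_years,
                            config$val_half_seed %||% derive_seed(config$seed, 5L))
  splits <- remove_split_leakage(splits)
  PE <- positional_encodings_for(thf, splits, config)
  X0 <- init_concept_features(PE, config$d)
  scfg <- sampler_config(config$r, config$predecessor_policy,
                         config$trail_gamma, config$per_step_negatives,
                         config$allow_gap_skip,
                         sampler_seed = derive_seed(config$seed, 3L))
  instances <- build_instances(splits$train, thf, scfg,
                               negative_pool = splits$train)
  params <- init_params(X0, config)
  trained <- train_model(instances, thf, params, config)
  structure(list(params = trained$params, config = config, th = thf,
                 splits = splits, instances = instances, PE = PE,
                 log = trained$log, sampler = scfg),
            class = "hypertrail")
}

# Positional encodings restricted to the configured graph scope; concepts
# with zero degree in scope get all-zero encodings.
positional_encodings_for <- function(th, splits, config) {
  ids <- if (config$pe_graph_scope == "train_only") splits$train
         else seq_along(th$edges)
  N <- th$vocab$N
  PE <- matrix(0, N, config$walk_length_L)
  if (length(ids) == 0L) return(PE)
  H <- incidence(th$edges[ids], th$vocab)
  seen <- which(rowSums(H) > 0)
  bw <- bipartite_expand(H[seen, , drop = FALSE])
  PE[seen, ] <- rw_positional_encodings(bw, config$walk_length_L)
  PE
}

# ---- S3 methods ----------------------------------------------------------

#' @exportS3Method base::print
print.hypertrail <- function(x, ...) {
  cat("Temporal hypergraph contrastive model\n")
  cat(sprintf("  hypergraph: %d concepts, %d hyperedges, %d time steps\n",
              x$th$vocab$N, length(x$th$edges), x$th$T_index + 1L))
  cat(sprintf("  instances: %d (train), r = %.2f, beta = %.2f\n",
              length(x$instances), x$config$r, x$config$beta))
  cat(sprintf("  dims: d = %d, d_time = %d, heads = %d, blocks = %d\n",
              x$config$d, x$config$d_time, x$config$n_heads, x$config$n_blocks))
  if (nrow(x$log) > 0)
    cat(sprintf("  training loss: %.4f (epoch 1) -> %.4f (epoch %d)\n",
                x$log$loss[1], x$log$loss[nrow(x$log)], nrow(x$log)))
  invisible(x)
}

#' @exportS3Method base::summary
summary.hypertrail <- function(object, ...) {
  s <- object$splits
  cat("Fit summary\n")
  print(object)
  cat(sprintf("  splits: train %d, val_opt %d, val_trail %d, test %d\n",
              length(s$train), length(s$val_opt), length(s$val_trail),
              length(s$test)))
  invisible(object)
}

#' @export
coef.hypertrail <- function(object, ...) object$params

#' @export
plot.hypertrail <- function(x, ...) {
  plot(x$log$epoch, x$log$loss, type = "b", xlab = "epoch",
       ylab = "mean instance loss", main = "Training loss", ...)
  invisible(x)
}

#' Score target hyperedges under a fitted model
#'
#' For each target, builds a trail of ideas from the history pool, runs the
#' positive forward pass, and returns the prediction score at the final
#' (target) position.
#'
#' @param object A fitted [hypertrail()] model.
#' @param targets Hyperedge ids of `object$th`, or a list of hyperedge
#'   objects (each with `members` and `t`).
#' @param history Hyperedge ids allowed as trail predecessors; defaults to
#'   the training split plus the trail half of the validation split.
#' @param seed Seed for the (stochastic) trail walks.
#' @param ... Unused.
#' @return Numeric vector of scores in (0, 1).
#' @export
predict.hypertrail <- function(object, targets,
                               history = c(object$splits$train,
                                           object$splits$val_trail),
                               seed = 1L, ...) {
  th <- object$th
  cfg <- object$config
  edges <- if (is.numeric(targets)) th$edges[targets] else targets
  with_seed(derive_seed(seed, 7L), {
    vapply(edges, function(tgt) {
      hist_ok <- history[vapply(th$edges[history], function(e) e$t, integer(1)) < tgt$t]
      tr <- trail(th, tgt, policy = cfg$predecessor_policy,
                  gamma = cfg$trail_gamma %||% 8,
                  allow_gap_skip = cfg$allow_gap_skip, within = hist_ok)
      seq_edges <- c(th$edges[tr$predecessors], list(tgt))
      fwd <- model_forward(lapply(seq_edges, `[[`, "members"),
                           vapply(seq_edges, function(e) e$t, integer(1)),
                           object$params, cfg)
      fwd$s[length(seq_edges)]
    }, numeric(1))
  })
}
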