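# Evaluation: ranking metrics, the trail-aware test protocol, empirical
# checks of the hard-negative difficulty curve and of the temporal-anchor
# separation property, and consistency/ablation reporting.

#' Classification and ranking metrics
#'
#' AUC is the rank statistic over positive-negative pairs with ties counted
#' one half; average precision is the area under the precision-recall curve
#' by the standard step rule; accuracy, precision and F1 use the decision
#' threshold with scores `>= threshold` predicted positive.
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 labels of the same length; both classes must be present.
#' @param threshold Decision threshold (default 0.5).
#' @return Object of class `metrics_report`: `auc`, `accuracy`, `precision`,
#'   `f1`, `average_precision`, `n_pos`, `n_neg`, `threshold`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stopf("compute_metrics: AUC undefined with a single class (%d pos, %d neg)",
          n_pos, n_neg)
  rk <- rank(scores)            # midranks handle ties as one half
  auc <- (sum(rk[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  lab_sorted <- labels[ord]
  prec_at <- cumsum(lab_sorted) / seq_along(lab_sorted)
  ap <- sum(prec_at * lab_sorted) / n_pos
  pred <- as.integer(scores >= threshold)
  acc <- mean(pred == labels)
  tp <- sum(pred == 1L & labels == 1L)
  prec <- if (sum(pred == 1L) > 0L) tp / sum(pred == 1L) else 0
  rec <- tp / n_pos
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  structure(list(auc = auc, accuracy = acc, precision = prec, f1 = f1,
                 average_precision = ap, n_pos = n_pos, n_neg = n_neg,
                 threshold = threshold),
            class = "metrics_report")
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat(sprintf("AUC %.3f | Acc %.3f | Prec %.3f | F1 %.3f | AvgPrec %.3f  (%d pos / %d neg)\n",
              x$auc, x$accuracy, x$precision, x$f1, x$average_precision,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Trail-aware model evaluation
#'
#' For each target hyperedge: builds its trail of ideas from the history
#' pool (only hyperedges strictly earlier than the target are eligible),
#' scores the target at the final position (label 1) and a freshly sampled
#' negative at the same position (label 0), then pools the balanced score
#' set into ranking metrics. Deterministic given the seed.
#'
#' @param model A fitted [hypertrail()] object.
#' @param targets Hyperedge ids to evaluate (default: the test split).
#' @param history Hyperedge ids available for trails and global negatives
#'   (default: training split plus the trail half of the validation split).
#' @param negatives `"hard"` (default; replacement-rate `r` corruption of
#'   each target) or `"global"` (uniform draw from the history pool).
#' @param r Replacement rate for hard negatives (default: the model's
#'   training `r`).
#' @param seed Evaluation seed.
#' @return A `metrics_report` with an extra `scores` data frame attached as
#'   attribute `"scores"`.
#' @export
evaluate_model <- function(model, targets = model$splits$test,
                           history = c(model$splits$train,
                                       model$splits$val_trail),
                           negatives = c("hard", "global"),
                           r = model$config$r, seed = 1L) {
  negatives <- match.arg(negatives)
  th <- model$th
  cfg <- model$config
  if (length(targets) == 0L) stopf("evaluate_model: no targets")
  hist_ts <- vapply(th$edges[history], function(e) e$t, integer(1))
  rows <- with_seed(derive_seed(seed, 13L), {
    lapply(targets, function(tid) {
      tgt <- th$edges[[tid]]
      pool <- history[hist_ts < tgt$t]
      tr <- trail(th, tgt, policy = cfg$predecessor_policy,
                  gamma = cfg$trail_gamma %||% 8,
                  allow_gap_skip = cfg$allow_gap_skip, within = pool)
      stopifnot(all(vapply(th$edges[tr$predecessors], function(e) e$t,
                           integer(1)) < tgt$t))
      seq_ids <- c(tr$predecessors, tid)
      members <- lapply(th$edges[seq_ids], `[[`, "members")
      ts <- vapply(th$edges[seq_ids], function(e) e$t, integer(1))
      n <- length(seq_ids)
      s_pos <- model_forward(members, ts, model$params, cfg)$s[n]
      neg <- if (negatives == "hard") {
        hard_negative(tgt, r, replacement_pool(th, tgt, r))
      } else {
        if (length(pool) < 1L) stopf("evaluate_model: empty history pool for global negatives")
        th$edges[[pool[sample.int(length(pool), 1L)]]]
      }
      members[[n]] <- neg$members
      ts[n] <- neg$t
      s_neg <- model_forward(members, ts, model$params, cfg)$s[n]
      c(s_pos, s_neg)
    })
  })
  scores <- unlist(rows)
  labels <- rep(c(1L, 0L), length(targets))
  rep_ <- compute_metrics(scores, labels)
  attr(rep_, "scores") <- data.frame(
    target_id = rep(unlist(targets), each = 2L), score = scores, label = labels)
  rep_
}

#' Hard-negative difficulty curve
#'
#' Trains and evaluates one model per replacement rate on a fixed synthetic
#' dataset, varying only `r` (training negatives and evaluation negatives
#' alike). Lower `r` makes negatives more similar to the positives, so the
#' achievable AUC is expected to fall as `r` decreases.
#'
#' @param synth_cfg A [synthetic_config()] defining the shared dataset.
#' @param r_values Ascending replacement rates.
#' @param config Base [hypertrail_config()]; its `r` and `seed` are
#'   overridden per run.
#' @param seeds Training seeds (default `1:3`).
#' @return List with `results` (data frame `r`, `seed`, `auc`), `auc_by_r`
#'   (named mean AUC per rate) and `rank_correlation` (Spearman correlation
#'   of mean AUC with `r`).
#' @export
claim1_curve <- function(synth_cfg, r_values, config = hypertrail_config(),
                         seeds = 1:3) {
  stopifnot(!is.unsorted(r_values))
  sim <- simulate_hypergraph(synth_cfg)
  rows <- list()
  for (s in seeds) for (r in r_values) {
    cfg <- config
    cfg$r <- r
    cfg$seed <- as.integer(s)
    fit <- hypertrail(sim$th, cfg)
    rep_ <- evaluate_model(fit, negatives = "hard", r = r,
                           seed = derive_seed(s, 17L))
    rows[[length(rows) + 1L]] <- data.frame(r = r, seed = s, auc = rep_$auc)
  }
  results <- do.call(rbind, rows)
  auc_by_r <- vapply(split(results$auc, results$r), mean, numeric(1))
  rho <- if (length(r_values) > 1L)
    stats::cor(as.numeric(names(auc_by_r)), auc_by_r, method = "spearman")
  else NA_real_
  list(results = results, auc_by_r = auc_by_r, rank_correlation = rho)
}

#' Temporal-anchor separation rate
#'
#' Fraction of instances whose positive final-position embedding is strictly
#' closer to the historical anchor (the contextualized embedding at the
#' previous position) than the hard negative's embedding is. Instances with
#' empty trails have no anchor and are excluded; ties count as failures.
#'
#' @param model A fitted [hypertrail()] object.
#' @param instances Instances from [build_instances()] over `model$th`.
#' @return Fraction in `[0, 1]`.
#' @export
claim2_rate <- function(model, instances) {
  th <- model$th
  cfg <- model$config
  eligible <- Filter(function(i) length(i$seq_ids) >= 2L, instances)
  if (length(eligible) == 0L)
    stopf("claim2_rate: no instances with a nonempty trail")
  hits <- vapply(eligible, function(inst) {
    members <- lapply(th$edges[inst$seq_ids], `[[`, "members")
    ts <- inst$ts
    n <- length(members)
    fwd <- model_forward(members, ts, model$params, cfg)
    a <- fwd$H[n - 1L, ]; p <- fwd$H[n, ]
    j <- match(n, inst$scored)
    if (is.na(j)) return(NA)
    hj <- inst$hard[[j]]
    members[[n]] <- hj$members; ts[n] <- hj$t
    nh <- model_forward(members, ts, model$params, cfg)$H[n, ]
    sqrt(sum((a - p)^2)) < sqrt(sum((a - nh)^2))
  }, logical(1))
  hits <- hits[!is.na(hits)]
  if (length(hits) == 0L) stopf("claim2_rate: no instances with a scored target position")
  mean(hits)
}

#' Cross-dataset consistency report
#'
#' Mean, sample (n-1) standard deviation and coefficient of variation
#' (percent) of a per-dataset metric.
#'
#' @param values Numeric vector of per-dataset metric values (length >= 2).
#' @return List with `values`, `mean`, `sd`, `cv` (percent).
#' @export
consistency <- function(values) {
  if (length(values) < 2L) stopf("consistency: need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  list(values = values, mean = m, sd = s, cv = 100 * s / m)
}

#' Ablation contribution
#'
#' Absolute (`full - ablated`) and relative (percent of full performance)
#' contribution of a component measured by removing it.
#'
#' @param full Metric of the full model.
#' @param ablated Metric with the component removed.
#' @return List with `absolute` and `relative_pct`.
#' @export
ablation_contribution <- function(full, ablated) {
  if (full == 0) stopf("ablation_contribution: relative contribution undefined for full = 0")
  list(absolute = full - ablated, relative_pct = 100 * (full - ablated) / full)
}
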