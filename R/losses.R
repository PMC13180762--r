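# Training losses: binary cross-entropy over positive/hard/global scores and
# the time-anchored margin contrastive loss.

#' Binary cross-entropy loss over one scored position
#'
#' `-log(s_pos) - log(1 - s_hard) - log(1 - s_gns)`, with all scores clamped
#' to `[eps, 1 - eps]` so the value stays finite.
#'
#' @param s_pos Score of the positive hyperedge.
#' @param s_hard Score of its hard negative.
#' @param s_gns Score of the global negative.
#' @param eps Clamp for log arguments (default `1e-7`).
#' @return Nonnegative scalar.
#' @export
bce_loss <- function(s_pos, s_hard, s_gns, eps = 1e-7) {
  s_pos <- clamp(s_pos, eps, 1 - eps)
  s_hard <- clamp(s_hard, eps, 1 - eps)
  s_gns <- clamp(s_gns, eps, 1 - eps)
  -log(s_pos) - log(1 - s_hard) - log(1 - s_gns)
}

#' Time-anchored contrastive loss
#'
#' Pulls the positive hyperedge embedding toward the historical anchor (the
#' previous position's contextualized embedding) and pushes both negatives
#' beyond a margin:
#' `2 * alpha * ||a - p||^2 +
#'  (1 - alpha) * (max(0, Margin - ||a - nh||)^2 + max(0, Margin - ||a - ng||)^2)`.
#'
#' @param h_prev Anchor embedding (historical context at the previous step).
#' @param h_pos Positive hyperedge embedding.
#' @param h_hard Hard-negative embedding.
#' @param h_gns Global-negative embedding.
#' @param alpha Pull/push balance in `[0, 1]` (default 0.5).
#' @param margin Minimum desired separation (default 1).
#' @return Nonnegative scalar.
#' @export
contrastive_loss <- function(h_prev, h_pos, h_hard, h_gns,
                             alpha = 0.5, margin = 1) {
  stopifnot(length(h_prev) == length(h_pos),
            length(h_prev) == length(h_hard),
            length(h_prev) == length(h_gns))
  pull <- sum((h_prev - h_pos)^2)
  hinge <- function(h) max(0, margin - sqrt(sum((h_prev - h)^2)))^2
  2 * alpha * pull + (1 - alpha) * (hinge(h_hard) + hinge(h_gns))
}

# Gradients of contrastive_loss wrt (h_prev, h_pos, h_hard, h_gns).
contrastive_loss_grads <- function(h_prev, h_pos, h_hard, h_gns,
                                   alpha = 0.5, margin = 1) {
  d_prev <- 4 * alpha * (h_prev - h_pos)
  d_pos <- -4 * alpha * (h_prev - h_pos)
  hinge_g <- function(h) {
    diff <- h_prev - h
    dist <- sqrt(sum(diff^2))
    if (dist >= margin || dist == 0) return(list(da = 0 * h, dn = 0 * h))
    coef <- -2 * (margin - dist) / dist
    list(da = (1 - alpha) * coef * diff, dn = -(1 - alpha) * coef * diff)
  }
  gh <- hinge_g(h_hard); gg <- hinge_g(h_gns)
  list(d_prev = d_prev + gh$da + gg$da, d_pos = d_pos,
       d_hard = gh$dn, d_gns = gg$dn)
}

#' Loss configuration
#'
#' @param alpha Contrastive pull/push balance in `[0, 1]` (default 0.5).
#' @param margin Contrastive separation margin (default 1).
#' @param beta Weight of the contrastive loss relative to BCE (default 0.5).
#' @param eps Clamp for log arguments (default `1e-7`).
#' @return List of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.5, margin = 1, beta = 0.5, eps = 1e-7) {
  stopifnot(alpha >= 0, alpha <= 1, margin > 0, beta >= 0, beta <= 1, eps > 0)
  structure(list(alpha = alpha, margin = margin, beta = beta, eps = eps),
            class = "loss_config")
}

#' Per-instance training loss
#'
#' Sums, over the scored positions of one instance, the binary cross-entropy
#' term plus `beta` times the time-anchored contrastive term. The
#' contrastive term needs an anchor (the previous position's embedding) and
#' is therefore omitted at the first sequence position. Averaging over
#' instances is the caller's responsibility.
#'
#' @param s_pos,s_hard,s_gns Numeric vectors of scores per scored position.
#' @param h_seq Matrix of positive-pass contextualized embeddings (one row
#'   per sequence position).
#' @param h_hard,h_gns Matrices of negative embeddings (one row per scored
#'   position), or `NULL` when `beta = 0`.
#' @param positions Integer vector: the sequence position each score refers
#'   to (1-based; defaults to `seq_along(s_pos)`).
#' @param config A [loss_config()].
#' @return Scalar loss (sum over the instance's scored positions).
#' @export
instance_loss <- function(s_pos, s_hard, s_gns, h_seq = NULL, h_hard = NULL,
                          h_gns = NULL, positions = seq_along(s_pos),
                          config = loss_config()) {
  stopifnot(length(s_hard) == length(s_pos), length(s_gns) == length(s_pos))
  total <- 0
  for (j in seq_along(positions)) {
    total <- total + bce_loss(s_pos[j], s_hard[j], s_gns[j], config$eps)
    k <- positions[j]
    if (config$beta > 0 && k > 1L) {
      if (is.null(h_seq) || is.null(h_hard) || is.null(h_gns))
        stopf("instance_loss: embeddings required at scored position %d (beta > 0)", k)
      total <- total + config$beta *
        contrastive_loss(h_seq[k - 1L, ], h_seq[k, ], h_hard[j, ], h_gns[j, ],
                         config$alpha, config$margin)
    }
  }
  total
}
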