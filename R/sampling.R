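# Negative sampling and trail-of-ideas generation.
#
# Hard negatives corrupt a real hyperedge by replacing a fraction r of its
# concepts, producing deceptively similar fakes; global negatives are drawn
# uniformly from the whole hypergraph. Trails are temporally constrained
# backward random walks over concept-overlapping hyperedges.

#' Hard negative hyperedge
#'
#' Corrupts a real hyperedge by replacing exactly `ceiling(r * |e|)` of its
#' concepts (0 when `r = 0`) with concepts drawn uniformly without
#' replacement from `candidate_vocab` excluding the hyperedge's own members.
#' Size and timestamp are preserved. Uses R's global RNG; seed upstream for
#' determinism.
#'
#' @param e A hyperedge (list with `members` and `t`).
#' @param r Replacement fraction in `[0, 1]`.
#' @param candidate_vocab Integer vector of candidate concept ids.
#' @return A hyperedge with `id = NA`, same size and timestamp, and the
#'   replaced members swapped for fresh concepts.
#' @export
hard_negative <- function(e, r, candidate_vocab) {
  stopifnot(r >= 0, r <= 1)
  size <- length(e$members)
  k <- if (r <= 0) 0L else as.integer(ceiling(r * size))
  if (k == 0L) return(new_hyperedge(NA_integer_, e$members, e$t, e$source))
  pool <- setdiff(candidate_vocab, e$members)
  if (length(pool) < k)
    stopf("hard_negative: need %d replacement concepts but only %d candidates available",
          k, length(pool))
  drop_idx <- sample.int(size, k)
  fresh <- pool[sample.int(length(pool), k)]
  new_hyperedge(NA_integer_, c(e$members[-drop_idx], fresh), e$t, e$source)
}

#' Global negative hyperedge
#'
#' Draws one hyperedge uniformly from the entire temporal hypergraph across
#' all timestamps, excluding the given hyperedge id.
#'
#' @param th A [temporal_hypergraph()].
#' @param exclude_id Hyperedge id to exclude.
#' @return A hyperedge from `th` with `id != exclude_id`.
#' @export
global_negative <- function(th, exclude_id) {
  if (length(th$edges) < 2L)
    stopf("global_negative: hypergraph has fewer than 2 hyperedges")
  ids <- setdiff(seq_along(th$edges), exclude_id)
  th$edges[[ids[sample.int(length(ids), 1L)]]]
}

#' Trail of ideas
#'
#' Generates the historical context for a target hyperedge by walking
#' backward in time: at each step, a predecessor at the previous time index
#' sharing at least one concept with the current hyperedge is selected, with
#' probability increasing in the overlap size (mirroring preferential
#' attachment: heavily overlapping hyperedges are more likely to be
#' revisited). The walk recurses until time 0 or until no qualifying
#' predecessor exists; with `allow_gap_skip` the search continues one time
#' step further back instead of truncating.
#'
#' Policies: `"overlap_power"` (default) selects with probability
#' proportional to `overlap^gamma`, concentrating the walk on the strongest
#' continuation and suppressing chance-level single-concept overlaps;
#' `"overlap_weighted"` is proportional to the raw overlap;
#' `"uniform"` ignores overlap size beyond the qualifying threshold.
#'
#' @param th A [temporal_hypergraph()].
#' @param target A hyperedge of `th` (or any hyperedge with `members`, `t`).
#' @param policy `"overlap_power"` (default), `"overlap_weighted"` or
#'   `"uniform"`.
#' @param gamma Exponent for `"overlap_power"` (default 8).
#' @param allow_gap_skip Continue past empty/non-overlapping years (default
#'   `FALSE`).
#' @param within Optional integer vector restricting the predecessor pool to
#'   these hyperedge ids (used for test-time trails drawn from a history
#'   pool).
#' @return Object of class `ht_trail`: list with `target_id` and
#'   `predecessors`, an id vector ordered oldest first (possibly empty).
#' @export
trail <- function(th, target,
                  policy = c("overlap_power", "overlap_weighted", "uniform"),
                  gamma = 8, allow_gap_skip = FALSE, within = NULL) {
  policy <- match.arg(policy)
  preds <- integer(0)
  cur <- target$members
  tt <- target$t - 1L
  while (tt >= 0L) {
    cand <- th$snapshots[[tt + 1L]]
    if (!is.null(within)) cand <- intersect(cand, within)
    if (length(cand) > 0L) {
      ov <- vapply(th$edges[cand], function(e)
        length(intersect(e$members, cur)), integer(1))
      ok <- ov > 0L
    } else ok <- logical(0)
    if (!any(ok)) {
      if (allow_gap_skip) { tt <- tt - 1L; next } else break
    }
    cand <- cand[ok]; ov <- ov[ok]
    w <- switch(policy,
                overlap_power = as.numeric(ov)^gamma,
                overlap_weighted = as.numeric(ov),
                uniform = rep(1, length(cand)))
    pick <- cand[sample.int(length(cand), 1L, prob = w)]
    preds <- c(pick, preds)
    cur <- th$edges[[pick]]$members
    tt <- th$edges[[pick]]$t - 1L
  }
  structure(list(target_id = target$id, predecessors = preds),
            class = "ht_trail")
}

#' Sampler configuration
#'
#' @param r Hard-negative replacement fraction in `[0, 1]` (default 0.2).
#' @param predecessor_policy Trail predecessor selection: `"overlap_power"`
#'   (default), `"overlap_weighted"` or `"uniform"`; see [trail()].
#' @param trail_gamma Exponent for the `"overlap_power"` policy (default 8).
#' @param per_step_negatives Generate one hard and one global negative per
#'   scored trail position (default `TRUE`); when `FALSE` only the target
#'   position is scored.
#' @param allow_gap_skip Let trails search further back past years with no
#'   overlapping predecessor (default `FALSE`).
#' @param sampler_seed Integer seed controlling trail and negative sampling.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(r = 0.2, predecessor_policy = "overlap_power",
                           trail_gamma = 8, per_step_negatives = TRUE,
                           allow_gap_skip = FALSE, sampler_seed = 1L) {
  stopifnot(r >= 0, r <= 1)
  structure(list(r = r, predecessor_policy = predecessor_policy,
                 trail_gamma = trail_gamma,
                 per_step_negatives = per_step_negatives,
                 allow_gap_skip = allow_gap_skip,
                 sampler_seed = as.integer(sampler_seed)),
            class = "sampler_config")
}

# Candidate vocabulary for a hard negative at time t: the period vocabulary
# V^(t) when it can supply the replacements, else the global vocabulary.
replacement_pool <- function(th, e, r) {
  k <- if (r <= 0) 0L else as.integer(ceiling(r * length(e$members)))
  pool <- period_vocabulary(th, e$t)
  if (length(setdiff(pool, e$members)) < k) pool <- seq_len(th$vocab$N)
  pool
}

#' Assemble training instances
#'
#' For every target hyperedge: generate its trail, then one hard and one
#' global negative per scored position (all positions when
#' `per_step_negatives`, else only the final/target position). Deterministic
#' given `config$sampler_seed`.
#'
#' @param targets Integer vector of target hyperedge ids (e.g.
#'   `splits$train`).
#' @param th A [temporal_hypergraph()] supplying trails and negatives.
#' @param config A [sampler_config()].
#' @param within Optional id vector restricting trail predecessors.
#' @param negative_pool Hyperedge ids global negatives may be drawn from
#'   (default: all of `th`). When assembling training instances this should
#'   be the training split, so no evaluation-period hyperedge is ever seen
#'   during training.
#' @return List of instances; each has `target_id`, `seq_ids` (trail ids then
#'   target id), `ts` (0-based timestamps), `scored` (scored positions,
#'   1-based), `hard` (list of hard-negative hyperedges per scored position)
#'   and `gns` (list of global-negative hyperedges per scored position).
#' @export
build_instances <- function(targets, th, config = sampler_config(),
                            within = NULL, negative_pool = NULL) {
  negative_pool <- negative_pool %||% seq_along(th$edges)
  with_seed(config$sampler_seed, {
    lapply(targets, function(tid) {
      tgt <- th$edges[[tid]]
      tr <- trail(th, tgt, policy = config$predecessor_policy,
                  gamma = config$trail_gamma %||% 8,
                  allow_gap_skip = config$allow_gap_skip, within = within)
      seq_ids <- c(tr$predecessors, tid)
      n <- length(seq_ids)
      scored <- if (isTRUE(config$per_step_negatives)) seq_len(n) else n
      hard <- lapply(scored, function(k) {
        pos <- th$edges[[seq_ids[k]]]
        hard_negative(pos, config$r, replacement_pool(th, pos, config$r))
      })
      gns <- lapply(scored, function(k) {
        pool <- setdiff(negative_pool, seq_ids[k])
        if (length(pool) < 1L) stopf("build_instances: empty global-negative pool")
        th$edges[[pool[sample.int(length(pool), 1L)]]]
      })
      list(target_id = tid, seq_ids = seq_ids,
           ts = vapply(th$edges[seq_ids], function(e) e$t, integer(1)),
           scored = scored, hard = hard, gns = gns)
    })
  })
}

#' Resample the negatives of existing instances
#'
#' Draws fresh hard and global negatives for every scored position, keeping
#' trails fixed. Used by the training loop to present new corruptions each
#' epoch so the model cannot memorize any particular negative set.
#'
#' @param instances Instances from [build_instances()].
#' @param th The [temporal_hypergraph()] the ids refer to.
#' @param r Replacement fraction.
#' @param negative_pool Hyperedge ids global negatives may come from.
#' @param seed Integer seed.
#' @return The instances with new `hard` and `gns` entries.
#' @export
resample_negatives <- function(instances, th, r, negative_pool, seed) {
  with_seed(seed, {
    lapply(instances, function(inst) {
      inst$hard <- lapply(inst$scored, function(k) {
        pos <- th$edges[[inst$seq_ids[k]]]
        hard_negative(pos, r, replacement_pool(th, pos, r))
      })
      inst$gns <- lapply(inst$scored, function(k) {
        pool <- setdiff(negative_pool, inst$seq_ids[k])
        th$edges[[pool[sample.int(length(pool), 1L)]]]
      })
      inst
    })
  })
}
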