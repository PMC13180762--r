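# Hyperedge tokenization: random-walk positional encodings on the bipartite
# expansion (global awareness), local hypergraph convolution (local
# awareness), and learnable cosine time encodings (temporal context).

#' Bipartite expansion of a hypergraph
#'
#' Builds the `(N+M) x (N+M)` random-walk matrix of the star/bipartite
#' expansion: concept vertices first, hyperedge vertices last, off-diagonal
#' blocks holding the incidence matrix and its transpose, zero diagonal
#' blocks, each row normalized by its degree so every row sums to 1.
#'
#' @param H Incidence matrix from [incidence()] (concepts x hyperedges).
#' @return Object of class `bipartite_walk`: sparse row-stochastic matrix `B`
#'   plus `n_concepts` and `n_hyperedges`.
#' @export
bipartite_expand <- function(H) {
  N <- nrow(H); M <- ncol(H)
  deg_c <- rowSums(H); deg_e <- colSums(H)
  if (any(deg_c == 0))
    stopf("bipartite_expand: concept(s) with zero degree (%s); compact the vocabulary upstream",
          paste(utils::head(which(deg_c == 0), 5L), collapse = ", "))
  if (any(deg_e == 0)) stopf("bipartite_expand: empty hyperedge column(s)")
  Hs <- methods::as(Matrix::Matrix(H, sparse = TRUE), "generalMatrix")
  B <- rbind(cbind(Matrix::Matrix(0, N, N, sparse = TRUE),
                   Matrix::Diagonal(N, 1 / deg_c) %*% Hs),
             cbind(Matrix::Diagonal(M, 1 / deg_e) %*% Matrix::t(Hs),
                   Matrix::Matrix(0, M, M, sparse = TRUE)))
  structure(list(B = B, n_concepts = N, n_hyperedges = M),
            class = "bipartite_walk")
}

#' Random-walk positional encodings
#'
#' For each concept `j`, entry `(j, l)` is the probability that a random walk
#' on the bipartite expansion starting at `j` returns to `j` in `l` steps,
#' i.e. the `j`-th diagonal entry of the `l`-th power of the walk matrix,
#' computed by iterated multiplication. Odd-step entries are exactly zero by
#' bipartite parity.
#'
#' @param bw A [bipartite_expand()] result.
#' @param L Walk length (default 5).
#' @return `N x L` matrix of return probabilities.
#' @export
rw_positional_encodings <- function(bw, L = 5L) {
  stopifnot(L >= 1L)
  N <- bw$n_concepts
  PE <- matrix(0, N, L)
  P <- bw$B
  PE[, 1] <- Matrix::diag(P)[seq_len(N)]
  if (L > 1L) for (l in 2:L) {
    P <- P %*% bw$B
    PE[, l] <- Matrix::diag(P)[seq_len(N)]
  }
  PE
}

#' Initialize the learnable concept feature table
#'
#' Columns `1..L` copy the positional encodings; columns `L+1..d` are zero
#' padding. The table is the trainable starting point for the concept
#' features.
#'
#' @param PE Positional-encoding matrix (`N x L`).
#' @param d Feature dimension, `d >= L`.
#' @return `N x d` matrix.
#' @export
init_concept_features <- function(PE, d) {
  L <- ncol(PE)
  if (d < L) stopf("feature dimension d = %d must be >= walk length L = %d", d, L)
  cbind(PE, matrix(0, nrow(PE), d - L))
}

#' Hypergraph-convolution parameters
#'
#' One layer computes `h_i = phi1(x_j, j in e_i)` (mean by default), then
#' `x~_j = nonlinearity(x_j A1 + agg(h_i, e_i incident to j) A2)` where the
#' incident-message aggregation is summation by default (see `phi2_agg`),
#' and the hyperedge readout `z_i = mean(x~_j, j in e_i)`.
#'
#' @param d Feature dimension.
#' @param n_layers Number of layers (default 1).
#' @param nonlinearity `"tanh"` (default), `"relu"` or `"identity"`.
#' @param phi1 Hyperedge aggregator: `"mean"` (default) or `"sum"`.
#' @param phi2_agg Aggregation of incident hyperedge messages inside the
#'   node update: `"sum"` (default) or `"mean"`. Summation preserves each
#'   concept's local degree — how many sequence hyperedges it belongs to —
#'   which is the signal separating kept from replaced concepts.
#' @param init `"xavier"` uniform initialization, or `"identity"` (both
#'   weight matrices the identity; useful for testing).
#' @return List of class `hcn_params` with `layers` (each `A1`, `A2`),
#'   `nonlinearity`, `phi1` and `phi2_agg`.
#' @export
hcn_params <- function(d, n_layers = 1L, nonlinearity = "tanh",
                       phi1 = c("mean", "sum"), phi2_agg = c("sum", "mean"),
                       init = c("xavier", "identity")) {
  init <- match.arg(init)
  phi1 <- match.arg(phi1)
  phi2_agg <- match.arg(phi2_agg)
  mk <- function() {
    if (init == "identity") diag(d)
    else matrix(stats::runif(d * d, -sqrt(6 / (2 * d)), sqrt(6 / (2 * d))), d, d)
  }
  structure(list(layers = lapply(seq_len(n_layers),
                                 function(i) list(A1 = mk(), A2 = mk())),
                 nonlinearity = nonlinearity, phi1 = phi1,
                 phi2_agg = phi2_agg),
            class = "hcn_params")
}

hcn_act <- function(x, kind) {
  switch(kind, tanh = tanh(x), relu = pmax(x, 0), identity = x,
         stopf("unknown nonlinearity '%s'", kind))
}

hcn_act_grad <- function(pre, post, kind) {
  switch(kind, tanh = 1 - post^2, relu = (pre > 0) * 1, identity = 1,
         stopf("unknown nonlinearity '%s'", kind))
}

# Internal HCN forward over a local hypergraph. members_list: list of integer
# member vectors; X: full N x d feature table. Returns the n x d hyperedge
# embeddings plus everything needed for the backward pass.
hcn_forward <- function(members_list, X, params) {
  n <- length(members_list)
  d <- ncol(X)
  U <- sort(unique(unlist(members_list)))
  if (length(U) == 0L) stopf("local_hcn: no members in local hypergraph")
  if (max(U) > nrow(X)) stopf("local_hcn: member id %d absent from feature table", max(U))
  nu <- length(U)
  # E: n x nu edge-mean aggregator; Dm: nu x nu... Dm is nu x n node-side mean.
  E <- matrix(0, n, nu)
  for (i in seq_len(n)) {
    ix <- match(members_list[[i]], U)
    E[i, ix] <- 1 / length(ix)
  }
  inc <- (E > 0) * 1          # n x nu incidence of the local hypergraph
  degu <- colSums(inc)        # local degree of each concept (>= 1)
  Dm <- if (identical(params$phi2_agg %||% "mean", "sum")) t(inc)
        else t(inc) / degu    # nu x n: sum or mean over incident edges
  Xu <- X[U, , drop = FALSE]
  Eh <- if (identical(params$phi1 %||% "mean", "sum")) inc else E
  layers <- vector("list", length(params$layers))
  Xi <- Xu
  for (l in seq_along(params$layers)) {
    A1 <- params$layers[[l]]$A1; A2 <- params$layers[[l]]$A2
    Hh <- Eh %*% Xi           # n x d hyperedge aggregates (phi1)
    Mh <- Dm %*% Hh           # nu x d mean incident aggregate per concept
    Pre <- Xi %*% A1 + Mh %*% A2
    Post <- hcn_act(Pre, params$nonlinearity)
    layers[[l]] <- list(Xin = Xi, Hh = Hh, Mh = Mh, Pre = Pre, Post = Post)
    Xi <- Post
  }
  Z <- E %*% Xi               # n x d readout (mean over members)
  list(Z = Z, cache = list(U = U, E = E, Eh = Eh, Dm = Dm, layers = layers,
                           nonlinearity = params$nonlinearity,
                           params = params$layers, d = d))
}

# Backward through hcn_forward. dZ: n x d. Returns gradients for each layer's
# A1/A2 and a sparse update for X (rows U).
hcn_backward <- function(dZ, cache) {
  E <- cache$E; Eh <- cache$Eh; Dm <- cache$Dm
  nl <- length(cache$layers)
  dXi <- crossprod(E, dZ)
  g_layers <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    lay <- cache$layers[[l]]
    A1 <- cache$params[[l]]$A1; A2 <- cache$params[[l]]$A2
    dPre <- dXi * hcn_act_grad(lay$Pre, lay$Post, cache$nonlinearity)
    g_layers[[l]] <- list(A1 = crossprod(lay$Xin, dPre), A2 = crossprod(lay$Mh, dPre))
    dXin <- tcrossprod(dPre, A1)
    dMh <- tcrossprod(dPre, A2)
    dHh <- crossprod(Dm, dMh)
    dXin <- dXin + crossprod(Eh, dHh)
    dXi <- dXin
  }
  list(layers = g_layers, dXU = dXi, U = cache$U)
}

#' Local hypergraph-convolution embeddings
#'
#' Runs the hypergraph convolution over a local hypergraph
#' (a trail's hyperedges plus the candidate being scored) and returns one
#' embedding per hyperedge. Permutation invariant in member order and
#' independent of hyperedge id labels.
#'
#' @param local_edges List of hyperedges.
#' @param features `N x d` concept feature table.
#' @param params [hcn_params()].
#' @return `n x d` matrix of hyperedge embeddings, rows named by hyperedge id.
#' @export
local_hcn <- function(local_edges, features, params) {
  Z <- hcn_forward(lapply(local_edges, `[[`, "members"), features, params)$Z
  rownames(Z) <- vapply(local_edges, function(e) as.character(e$id), character(1))
  Z
}

#' Learnable cosine time encoding
#'
#' `psi(t) = cos(W t + b)` componentwise, with `W` a learnable vector of
#' length `d_time` and `b` a learnable scalar broadcast across components.
#' `t` is the 0-based remapped time index, keeping the cosine argument
#' well-scaled.
#'
#' @param t Nonnegative integer time index (vectorized).
#' @param W Frequency vector of length `d_time`.
#' @param b Phase scalar.
#' @return Matrix `length(t) x d_time` of values in `[-1, 1]` (a plain
#'   vector if `t` is scalar).
#' @export
time_encode <- function(t, W, b) {
  stopifnot(all(t >= 0))
  out <- cos(outer(as.numeric(t), as.numeric(W)) + b)
  if (length(t) == 1L) drop(out) else out
}

#' Tokenize a hyperedge embedding
#'
#' Concatenates the structural embedding with its time encoding; the token's
#' first `d` positions are the embedding.
#'
#' @param z Embedding vector of length `d`.
#' @param psi Time-encoding vector of length `d_time`.
#' @return Token vector of length `d + d_time`.
#' @export
tokenize <- function(z, psi) c(as.numeric(z), as.numeric(psi))
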