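## Neighborhood attention shared by the dependency-tree and PAS encoders:
## softmax over LeakyReLU-activated additive scores of projected
## (query, member) pairs, GAT-style.

#' Initialize attention parameters
#'
#' The score of member `k` against query `q` is
#' `a' [W q || W h_k]` passed through LeakyReLU, then softmax-normalized
#' over the member set. `Wq` optionally projects a query living in a
#' different space (the dependency encoder queries with the parent's input
#' embedding, which has dimension `d_q != d_h`); when `d_q == d_h` and
#' `query_projection = FALSE` the raw query is used as is.
#'
#' @param d_h hidden dimension of member states.
#' @param d_q query dimension before projection (default `d_h`).
#' @param slope LeakyReLU negative slope (default 0.2, the GAT convention;
#'   unstated upstream).
#' @param query_projection whether to learn a separate `Wq` (`d_h x d_q`).
#' @param init_scale half-width of the uniform initialization.
#' @return list with elements `W`, `a`, `slope` and optionally `Wq`.
#' @export
attention_params <- function(d_h, d_q = d_h, slope = 0.2,
                             query_projection = (d_q != d_h),
                             init_scale = 0.1) {
  p <- list(
    W = matrix(stats::runif(d_h * d_h, -init_scale, init_scale), d_h, d_h),
    a = stats::runif(2 * d_h, -init_scale, init_scale)
  )
  if (query_projection) {
    p$Wq <- matrix(stats::runif(d_h * d_q, -init_scale, init_scale), d_h, d_q)
  }
  p$slope <- slope   # hyperparameter, kept last so (un)flattening preserves order
  p
}

## forward with cache for backprop; query already in d_h space
attn_forward <- function(query, members, params) {
  d_h <- nrow(members)
  p <- params$W %*% query                       # d_h
  r <- params$W %*% members                     # d_h x k
  a1 <- params$a[seq_len(d_h)]
  a2 <- params$a[d_h + seq_len(d_h)]
  raw <- unname(drop(crossprod(r, a2))) + sum(a1 * p)  # k
  act <- leaky_relu(raw, params$slope)
  w <- softmax(act)
  list(weights = w, raw = raw, p = p, r = r, members = members, query = query)
}

#' Attention coefficients over a member set
#'
#' @param query numeric query vector (length `d_h` after any projection).
#' @param members matrix of member hidden states, one column each
#'   (`d_h x k`), or a list of vectors.
#' @param params parameters from [attention_params()].
#' @return weight vector summing to 1 over the members.
#' @export
attention_coefficients <- function(query, members, params) {
  if (is.list(members)) members <- do.call(cbind, members)
  if (is.null(dim(members))) members <- matrix(members, ncol = 1L)
  if (ncol(members) == 0L) {
    stop_eatree("attention requires a nonempty member set", "eatree_domain_error")
  }
  if (nrow(members) != length(query)) {
    stop_eatree("query/member dimension mismatch", "eatree_shape_error")
  }
  attn_forward(query, members, params)$weights
}

#' Weighted aggregation of member states
#'
#' @param weights weight vector (typically from [attention_coefficients()]).
#' @param member_states matrix (`d_h x k`) or list of vectors.
#' @return the weighted sum, a vector of length `d_h`.
#' @export
attentive_aggregate <- function(weights, member_states) {
  if (is.list(member_states)) member_states <- do.call(cbind, member_states)
  if (is.null(dim(member_states))) member_states <- matrix(member_states, ncol = 1L)
  if (length(weights) != ncol(member_states)) {
    stop_eatree("one weight per member state required", "eatree_shape_error")
  }
  drop(member_states %*% weights)
}

## Backward through attn_forward given d(htilde) where
## htilde = members %*% weights. Returns gradients and upstream deltas.
## query_grad: whether to return d(query) (PAS side) — the dep side instead
## needs dq to flow into Wq x_j, which the caller handles.
attn_backward <- function(cache, params, dhtil) {
  w <- cache$weights
  k <- length(w)
  d_h <- nrow(cache$members)
  a1 <- params$a[seq_len(d_h)]
  a2 <- params$a[d_h + seq_len(d_h)]
  dmem <- cache$members * 0
  ## htilde = sum_k w_k h_k
  dalpha <- drop(crossprod(cache$members, dhtil))      # k
  dmem <- dmem + outer(dhtil, w)                       # d_h x k
  ds <- w * (dalpha - sum(w * dalpha))                 # softmax backward
  dz <- ds * ifelse(cache$raw > 0, 1, params$slope)    # LeakyReLU backward
  dp <- sum(dz) * a1                                   # d_h
  dr <- outer(a2, dz)                                  # d_h x k
  ga1 <- sum(dz) * cache$p
  ga2 <- drop(cache$r %*% dz)
  gW <- tcrossprod(dp, cache$query) + tcrossprod(dr, cache$members)
  dmem <- dmem + crossprod(params$W, dr)
  dquery <- drop(crossprod(params$W, dp))
  list(gW = gW, ga = c(ga1, ga2), dmembers = dmem, dquery = dquery)
}
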