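## Child-Sum Tree-LSTM cell and post-order tree encoding, plus the
## fully-connected recursive (RecurNN) baseline parent update.

#' Initialize Child-Sum Tree-LSTM cell parameters
#'
#' One `(W, U, b)` triple per gate `f`, `i`, `o`, `u`: input matrices are
#' `d_h x d_x`, recurrent matrices `d_h x d_h`, biases length `d_h`.
#'
#' @param d_x input (embedding) dimension.
#' @param d_h hidden dimension.
#' @param init_scale half-width of the uniform initialization.
#' @return named list of the 12 arrays.
#' @export
cell_params <- function(d_x, d_h, init_scale = 0.1) {
  m <- function(r, c) matrix(stats::runif(r * c, -init_scale, init_scale), r, c)
  out <- list()
  for (g in c("f", "i", "o", "u")) {
    out[[paste0("W", g)]] <- m(d_h, d_x)
    out[[paste0("U", g)]] <- m(d_h, d_h)
    out[[paste0("b", g)]] <- stats::runif(d_h, -init_scale, init_scale)
  }
  out
}

#' RecurNN parent update (fully-connected recursive baseline)
#'
#' The pre-LSTM recursive baseline: the parent embedding is
#' `sigma(W . (x_1; ...; x_n))` over the concatenated child embeddings,
#' zero-padded to a fixed maximum arity.
#'
#' @param child_embeddings list of child vectors (each length `d`).
#' @param W weight matrix, `d x (max_arity * d)`.
#' @param max_arity configured capacity.
#' @return parent embedding vector of length `d`.
#' @export
recurnn_update <- function(child_embeddings, W, max_arity) {
  n <- length(child_embeddings)
  if (n > max_arity) {
    stop_eatree(sprintf("%d children exceed configured max arity %d", n, max_arity),
                "eatree_capacity_error")
  }
  d <- length(child_embeddings[[1]])
  x <- numeric(max_arity * d)
  for (i in seq_len(n)) x[(i - 1) * d + seq_len(d)] <- child_embeddings[[i]]
  if (ncol(W) != length(x)) stop_eatree("W width must be max_arity * d", "eatree_shape_error")
  drop(sigmoid(W %*% x))
}

## core cell with full cache; child_c/child_h are d_h x c matrices (0 cols
## for a leaf); htil is the aggregate (plain sum unless overridden)
cell_forward <- function(x, child_c, child_h, cp, htil = NULL) {
  nc <- ncol(child_h)
  if (is.null(htil)) htil <- if (nc) rowSums(child_h) else numeric(nrow(cp$Uf))
  i <- drop(sigmoid(cp$Wi %*% x + cp$Ui %*% htil + cp$bi))
  o <- drop(sigmoid(cp$Wo %*% x + cp$Uo %*% htil + cp$bo))
  u <- drop(tanh(cp$Wu %*% x + cp$Uu %*% htil + cp$bu))
  cc <- i * u
  f <- NULL
  if (nc) {
    f <- sigmoid(sweep(cp$Uf %*% child_h, 1, drop(cp$Wf %*% x) + cp$bf, `+`))
    cc <- cc + rowSums(f * child_c)
  }
  tc <- tanh(cc)
  h <- o * tc
  list(c = cc, h = h, i = i, o = o, u = u, f = f, tanhc = tc, htil = htil,
       x = x, child_c = child_c, child_h = child_h)
}

#' Child-Sum Tree-LSTM cell update
#'
#' Computes one parent's `(c_j, h_j)` from its input embedding and child
#' states: the child hidden states are aggregated (plain sum, or an
#' attention-weighted sum supplied via `aggregate_override`); the input,
#' output and update gates read the aggregate; each child gets its own
#' forget gate read from that child's hidden state; then
#' `c_j = i * u + sum_k f_jk * c_k` and `h_j = o * tanh(c_j)`.
#'
#' @param x_j input embedding (length `d_x`).
#' @param child_states list of `list(c =, h =)` pairs; empty for a leaf.
#' @param params from [cell_params()].
#' @param aggregate_override optional replacement for the plain child-state
#'   sum (used by the attentive variants).
#' @return `list(c =, h =)`, the new node state.
#' @export
child_sum_cell <- function(x_j, child_states, params, aggregate_override = NULL) {
  d_h <- nrow(params$Uf)
  if (length(x_j) != ncol(params$Wf)) {
    stop_eatree("input embedding has wrong dimension", "eatree_shape_error")
  }
  ch <- do.call(cbind, lapply(child_states, `[[`, "h")) %||% matrix(0, d_h, 0)
  cc <- do.call(cbind, lapply(child_states, `[[`, "c")) %||% matrix(0, d_h, 0)
  if (length(child_states) && nrow(ch) != d_h) {
    stop_eatree("child state has wrong dimension", "eatree_shape_error")
  }
  st <- cell_forward(x_j, cc, ch, params, htil = aggregate_override)
  list(c = st$c, h = st$h)
}

## Full-sentence dependency-tree forward pass with cache.
## X: d_x x n embeddings. Returns per-node caches in post-order.
tree_forward <- function(tree, X, cp, attn = NULL, attentive = FALSE) {
  n <- n_tokens(tree)
  d_h <- nrow(cp$Uf)
  order <- post_order(tree)
  kids <- lapply(seq_len(n), function(j) which(tree$head == j))
  H <- matrix(0, d_h, n); C <- matrix(0, d_h, n)
  caches <- vector("list", n)
  for (j in order) {
    ks <- kids[[j]]
    htil <- NULL
    acache <- NULL
    if (attentive && length(ks)) {
      q <- drop(attn$Wq %*% X[, j])
      acache <- attn_forward(q, H[, ks, drop = FALSE], attn)
      htil <- drop(acache$members %*% acache$weights)
    }
    cell <- cell_forward(X[, j], C[, ks, drop = FALSE], H[, ks, drop = FALSE],
                         cp, htil = htil)
    H[, j] <- cell$h; C[, j] <- cell$c
    caches[[j]] <- list(cell = cell, attn = acache, kids = ks)
  }
  list(H = H, C = C, caches = caches, order = order)
}

## Backward through tree_forward. dH: d_h x n gradient wrt each h_j from the
## classifier. Accumulates parameter gradients into `grads` (same shapes as
## params); returns the updated gradient list.
tree_backward <- function(tree, X, cp, attn, attentive, fwd, dH,
                          g_cell, g_attn = NULL) {
  n <- n_tokens(tree)
  d_h <- nrow(cp$Uf)
  dC <- matrix(0, d_h, n)
  dHacc <- dH
  for (j in rev(fwd$order)) {
    cache <- fwd$caches[[j]]
    cell <- cache$cell
    ks <- cache$kids
    dh <- dHacc[, j]; dc <- dC[, j]
    do <- dh * cell$tanhc
    dcj <- dc + dh * cell$o * (1 - cell$tanhc^2)
    di <- dcj * cell$u
    du <- dcj * cell$i
    dzi <- di * cell$i * (1 - cell$i)
    dzo <- do * cell$o * (1 - cell$o)
    dzu <- du * (1 - cell$u^2)
    x <- cell$x
    g_cell$Wi <- g_cell$Wi + tcrossprod(dzi, x)
    g_cell$Wo <- g_cell$Wo + tcrossprod(dzo, x)
    g_cell$Wu <- g_cell$Wu + tcrossprod(dzu, x)
    g_cell$Ui <- g_cell$Ui + tcrossprod(dzi, cell$htil)
    g_cell$Uo <- g_cell$Uo + tcrossprod(dzo, cell$htil)
    g_cell$Uu <- g_cell$Uu + tcrossprod(dzu, cell$htil)
    g_cell$bi <- g_cell$bi + dzi
    g_cell$bo <- g_cell$bo + dzo
    g_cell$bu <- g_cell$bu + dzu
    dhtil <- drop(crossprod(cp$Ui, dzi) + crossprod(cp$Uo, dzo) +
                  crossprod(cp$Uu, dzu))
    if (length(ks)) {
      f <- cell$f
      df <- dcj * cell$child_c                  # d_h x c
      dC[, ks] <- dC[, ks] + dcj * f
      dzf <- df * f * (1 - f)
      g_cell$Wf <- g_cell$Wf + tcrossprod(rowSums(dzf), x)
      g_cell$Uf <- g_cell$Uf + tcrossprod(dzf, cell$child_h)
      g_cell$bf <- g_cell$bf + rowSums(dzf)
      dkids <- crossprod(cp$Uf, dzf)            # d_h x c
      if (attentive) {
        ab <- attn_backward(cache$attn, attn, dhtil)
        g_attn$W <- g_attn$W + ab$gW
        g_attn$a <- g_attn$a + ab$ga
        dkids <- dkids + ab$dmembers
        g_attn$Wq <- g_attn$Wq + tcrossprod(ab$dquery, x)
      } else {
        dkids <- dkids + matrix(dhtil, d_h, length(ks))
      }
      dHacc[, ks] <- dHacc[, ks] + dkids
    }
  }
  list(g_cell = g_cell, g_attn = g_attn)
}

#' Encode a dependency tree with a Child-Sum Tree-LSTM
#'
#' Runs an iterative post-order traversal, assigning every node a
#' `(cell, hidden)` state. In `"plain"` mode child hidden states are summed
#' (the classic Child-Sum aggregate); in `"attentive"` mode they are
#' combined by softmax/LeakyReLU attention, the parent's projected input
#' embedding serving as the query.
#'
#' @param tree a [dep_tree()].
#' @param X embedding matrix, `d_x` rows by `n_tokens` columns.
#' @param params cell parameters from [cell_params()].
#' @param mode `"plain"` or `"attentive"`.
#' @param attn attention parameters from
#'   `attention_params(d_h, d_q = d_x, query_projection = TRUE)`; required in
#'   attentive mode.
#' @return list with `states` (per-node `list(c =, h =)`), `H` and `C`
#'   (`d_h x n` matrices) and, in attentive mode, `attention_maps`: one
#'   `list(node =, members =, weights =)` per internal node.
#' @export
encode_tree <- function(tree, X, params, mode = c("plain", "attentive"),
                        attn = NULL) {
  mode <- match.arg(mode)
  attentive <- mode == "attentive"
  if (attentive && is.null(attn)) {
    stop_eatree("attentive mode requires attention parameters", "eatree_domain_error")
  }
  fwd <- tree_forward(tree, X, params, attn, attentive)
  states <- lapply(seq_len(n_tokens(tree)),
                   function(j) list(c = fwd$C[, j], h = fwd$H[, j]))
  maps <- list()
  if (attentive) {
    for (j in fwd$order) {
      a <- fwd$caches[[j]]$attn
      if (!is.null(a)) {
        maps[[length(maps) + 1L]] <- list(node = j, members = fwd$caches[[j]]$kids,
                                          weights = a$weights)
      }
    }
  }
  list(states = states, H = fwd$H, C = fwd$C, attention_maps = maps)
}
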