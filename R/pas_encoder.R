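## Attentive encoder over the predicate-argument structure (PAS) graph and
## fusion with the dependency-tree representation. The gated tree-cell
## equations are executed on the (possibly cyclic) graph as K synchronous
## message-passing layers with self-loops — the standard GAT execution
## model; layer-0 states are zero and each layer's gates read the previous
## layer's neighbor states.

#' Initialize PAS-encoder parameters
#'
#' @param d_x input (embedding) dimension.
#' @param d_h hidden dimension.
#' @param K number of synchronous layers (default 2).
#' @param init_scale half-width of the uniform initialization.
#' @return list with `cell` ([cell_params()]), `attn`
#'   ([attention_params()], queried by previous-layer hidden states) and `K`.
#' @export
pas_params <- function(d_x, d_h, K = 2L, init_scale = 0.1) {
  if (K < 1L) stop_eatree("PAS layer count K must be >= 1", "eatree_domain_error")
  list(cell = cell_params(d_x, d_h, init_scale),
       attn = attention_params(d_h, init_scale = init_scale),
       K = as.integer(K))
}

## members for node j: sorted(N_j) plus j itself (self-loop), so isolated
## nodes attend only to themselves
pas_members <- function(graph) {
  lapply(seq_len(graph$n_tokens), function(j) sort(union(graph$neighbors[[j]], j)))
}

pas_forward <- function(graph, X, params, attentive = TRUE) {
  n <- graph$n_tokens
  d_h <- nrow(params$cell$Uf)
  members <- pas_members(graph)
  H <- matrix(0, d_h, n); C <- matrix(0, d_h, n)
  layers <- vector("list", params$K)
  for (l in seq_len(params$K)) {
    Hprev <- H; Cprev <- C
    Hnew <- matrix(0, d_h, n); Cnew <- matrix(0, d_h, n)
    caches <- vector("list", n)
    for (j in seq_len(n)) {
      m <- members[[j]]
      acache <- NULL
      if (attentive) {
        acache <- attn_forward(Hprev[, j], Hprev[, m, drop = FALSE], params$attn)
        htil <- drop(acache$members %*% acache$weights)
      } else {
        htil <- rowMeans(Hprev[, m, drop = FALSE])
      }
      cell <- cell_forward(X[, j], Cprev[, m, drop = FALSE],
                           Hprev[, m, drop = FALSE], params$cell, htil = htil)
      Hnew[, j] <- cell$h; Cnew[, j] <- cell$c
      caches[[j]] <- list(cell = cell, attn = acache, m = m)
    }
    layers[[l]] <- list(caches = caches, Hprev = Hprev, Cprev = Cprev)
    H <- Hnew; C <- Cnew
  }
  list(H = H, C = C, layers = layers, members = members)
}

pas_backward <- function(graph, X, params, attentive, fwd, dH,
                         g_cell, g_attn) {
  n <- graph$n_tokens
  d_h <- nrow(params$cell$Uf)
  cp <- params$cell
  dC <- matrix(0, d_h, n)
  for (l in rev(seq_len(params$K))) {
    layer <- fwd$layers[[l]]
    dHprev <- matrix(0, d_h, n); dCprev <- matrix(0, d_h, n)
    for (j in seq_len(n)) {
      cell <- layer$caches[[j]]$cell
      m <- layer$caches[[j]]$m
      dh <- dH[, j]; dc <- dC[, j]
      if (all(dh == 0) && all(dc == 0)) next
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
      f <- cell$f
      df <- dcj * cell$child_c
      dCprev[, m] <- dCprev[, m] + dcj * f
      dzf <- df * f * (1 - f)
      g_cell$Wf <- g_cell$Wf + tcrossprod(rowSums(dzf), x)
      g_cell$Uf <- g_cell$Uf + tcrossprod(dzf, cell$child_h)
      g_cell$bf <- g_cell$bf + rowSums(dzf)
      dmem <- crossprod(cp$Uf, dzf)
      if (attentive) {
        ab <- attn_backward(layer$caches[[j]]$attn, params$attn, dhtil)
        g_attn$W <- g_attn$W + ab$gW
        g_attn$a <- g_attn$a + ab$ga
        dmem <- dmem + ab$dmembers
        dHprev[, j] <- dHprev[, j] + ab$dquery
      } else {
        dmem <- dmem + matrix(dhtil / length(m), d_h, length(m))
      }
      dHprev[, m] <- dHprev[, m] + dmem
    }
    dH <- dHprev; dC <- dCprev
  }
  list(g_cell = g_cell, g_attn = g_attn)
}

#' Encode a PAS graph
#'
#' Runs `K` synchronous attention + gated-update layers over the undirected
#' neighborhood view of the graph (self-loops included, so isolated nodes
#' attend to themselves with weight 1). Attention queries each node's
#' previous-layer hidden state; forget gates consume neighbors'
#' previous-layer `(c, h)` pairs.
#'
#' @param graph a [pas_graph()].
#' @param X embedding matrix, `d_x` rows by `n_tokens` columns.
#' @param params from [pas_params()].
#' @param attentive if `FALSE`, neighbors are averaged uniformly (the
#'   attention-ablated variant).
#' @return list with `states`, `H`, `C` (final layer) and `attention_maps`
#'   (final layer, one per node).
#' @export
encode_pas <- function(graph, X, params, attentive = TRUE) {
  fwd <- pas_forward(graph, X, params, attentive)
  n <- graph$n_tokens
  states <- lapply(seq_len(n), function(j) list(c = fwd$C[, j], h = fwd$H[, j]))
  maps <- lapply(seq_len(n), function(j) {
    cache <- fwd$layers[[params$K]]$caches[[j]]
    w <- if (attentive) cache$attn$weights else rep(1 / length(cache$m), length(cache$m))
    list(node = j, members = cache$m, weights = w)
  })
  list(states = states, H = fwd$H, C = fwd$C, attention_maps = maps)
}

#' Fuse dependency-tree and PAS representations
#'
#' Per token, the concatenation `[h_dep ; h_pas]` (length `2 * d_h`); with
#' the corpus-scale hidden size 256 the fused vector has length 512. Tokens
#' missing on either side contribute a zero block.
#'
#' @param dep_H dependency-side hidden matrix (`d_h x n`) or `NULL`.
#' @param pas_H PAS-side hidden matrix (`d_h x n`) or `NULL`.
#' @param rho optional scalar gate multiplying the PAS block before
#'   concatenation (a learned coefficient when enabled in training).
#' @return fused matrix, `2 * d_h` rows by `n` columns.
#' @export
fuse <- function(dep_H, pas_H, rho = 1) {
  if (is.null(dep_H) && is.null(pas_H)) {
    stop_eatree("at least one representation required", "eatree_domain_error")
  }
  if (!is.null(dep_H) && !is.null(pas_H)) {
    if (!identical(dim(dep_H), dim(pas_H))) {
      stop_eatree("dependency/PAS token sets do not align", "eatree_alignment_error")
    }
  }
  d_h <- nrow(dep_H %||% pas_H)
  n <- ncol(dep_H %||% pas_H)
  rbind(dep_H %||% matrix(0, d_h, n), rho * (pas_H %||% matrix(0, d_h, n)))
}
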