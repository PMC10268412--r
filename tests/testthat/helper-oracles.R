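## Independent oracles used across the suite. These deliberately do not
## call the package's encoder internals: the sequential LSTM is written
## from the textbook recurrence, the scalar cell evaluations from the gate
## equations directly.

sigma_ <- function(x) 1 / (1 + exp(-x))

## sequential LSTM, leaf-to-root over columns of X
oracle_seq_lstm <- function(X, cp) {
  d_h <- nrow(cp$Uf)
  h <- numeric(d_h); cc <- numeric(d_h)
  states <- vector("list", ncol(X))
  for (t in seq_len(ncol(X))) {
    x <- X[, t]
    f <- drop(sigma_(cp$Wf %*% x + cp$Uf %*% h + cp$bf))
    i <- drop(sigma_(cp$Wi %*% x + cp$Ui %*% h + cp$bi))
    o <- drop(sigma_(cp$Wo %*% x + cp$Uo %*% h + cp$bo))
    u <- drop(tanh(cp$Wu %*% x + cp$Uu %*% h + cp$bu))
    cc <- i * u + f * cc
    h <- o * tanh(cc)
    states[[t]] <- list(c = cc, h = h)
  }
  states
}

## scalar (d_x = d_h = 1) gated update given aggregate htil and child
## (c, h) pairs — direct evaluation of the gate equations
oracle_scalar_cell <- function(x, htil, child_c, child_h, W = 1, U = 1, b = 0) {
  i <- sigma_(W * x + U * htil + b)
  o <- sigma_(W * x + U * htil + b)
  u <- tanh(W * x + U * htil + b)
  f <- sigma_(W * x + U * child_h + b)
  cc <- i * u + sum(f * child_c)
  list(c = cc, h = o * tanh(cc), i = i, o = o, u = u, f = f)
}

## scalar attention weights per softmax(LeakyReLU(a1 W q + a2 W h_k))
oracle_scalar_attn <- function(q, hs, W = 1, a = c(1, 1), slope = 0.2) {
  z <- a[1] * W * q + a[2] * W * hs
  z <- ifelse(z > 0, z, slope * z)
  exp(z) / sum(exp(z))
}

## central finite differences of the batch loss wrt every parameter
oracle_fd_grads <- function(model, batch, lambda, h = 1e-5, idx = NULL) {
  flat <- eatree:::flatten_params(model$params)
  idx <- idx %||% seq_along(flat)
  num <- numeric(length(idx))
  for (q in seq_along(idx)) {
    i <- idx[q]
    fp <- flat; fp[i] <- fp[i] + h
    mp <- model; mp$params <- eatree:::unflatten_params(fp, model$params)
    lp <- eatree:::loss_and_grads(mp, batch, lambda = lambda)$loss
    fm <- flat; fm[i] <- fm[i] - h
    mm <- model; mm$params <- eatree:::unflatten_params(fm, model$params)
    lm <- eatree:::loss_and_grads(mm, batch, lambda = lambda)$loss
    num[q] <- (lp - lm) / (2 * h)
  }
  num
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## small random labeled instance for gradient checks
make_random_instance <- function(n = 5L, d_x = 4L, m = 3L, seed = 1L) {
  set.seed(seed)
  tree <- random_tree(n)
  edges <- data.frame(pred = sample(n, 3, replace = TRUE),
                      arg = sample(n, 3, replace = TRUE),
                      role = sample(c("arg1", "arg2"), 3, replace = TRUE))
  edges <- edges[edges$pred != edges$arg, , drop = FALSE]
  pas <- pas_graph("s1", edges, n)
  list(X = matrix(rnorm(d_x * n), d_x, n), tree = tree, pas = pas,
       y = sample(m, n, replace = TRUE))
}

## random single-rooted tree over n tokens
random_tree <- function(n, sid = "s1") {
  perm <- sample(n)
  head <- integer(n)
  for (t in seq_len(n)[-1]) head[perm[t]] <- perm[sample(t - 1L, 1L)]
  dep_tree(sid, form = paste0("w", seq_len(n)), head = head)
}
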