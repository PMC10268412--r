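## Full trigger-detection model: dependency-tree encoder, PAS encoder,
## fusion and softmax classifier, with hand-derived analytic gradients.

#' Ablation configuration
#'
#' The four switchable components: the dependency branch, the PAS branch,
#' and attention within each. At least one branch must stay on.
#'
#' @param use_dep,use_pas,attn_dep,attn_pas logical flags.
#' @return named logical list of class `ablation_config`.
#' @export
ablation_config <- function(use_dep = TRUE, use_pas = TRUE,
                            attn_dep = TRUE, attn_pas = TRUE) {
  if (!use_dep && !use_pas) {
    stop_eatree("at least one of use_dep/use_pas must be TRUE", "eatree_domain_error")
  }
  structure(list(use_dep = use_dep, use_pas = use_pas,
                 attn_dep = attn_dep, attn_pas = attn_pas),
            class = "ablation_config")
}

#' The eight ablation variants
#'
#' Compact names encode the component grid: positions are PAS-attention,
#' PAS, dependency-attention, dependency; an uppercase letter means the
#' component is present, lowercase means reduced. `APAD` is the full model;
#' `apaD` is the plain dependency-only Child-Sum model; `APad` is the pure
#' attentive PAS model.
#'
#' @return named list of [ablation_config()] objects.
#' @export
ablation_variants <- function() {
  v <- list(
    APAD = c(TRUE,  TRUE,  TRUE,  TRUE),
    aPAD = c(FALSE, TRUE,  TRUE,  TRUE),
    apAD = c(FALSE, FALSE, TRUE,  TRUE),
    aPaD = c(FALSE, TRUE,  FALSE, TRUE),
    apaD = c(FALSE, FALSE, FALSE, TRUE),
    APaD = c(TRUE,  TRUE,  FALSE, TRUE),
    APad = c(TRUE,  TRUE,  FALSE, FALSE),
    aPad = c(FALSE, TRUE,  FALSE, FALSE)
  )
  lapply(v, function(x) ablation_config(use_dep = x[4], use_pas = x[2],
                                        attn_dep = x[3], attn_pas = x[1]))
}

#' Initialize a trigger-detection model
#'
#' All parameter groups are always allocated (so differently-ablated models
#' built from the same RNG state share identical initializations); ablation
#' flags decide which groups participate in the forward pass.
#'
#' @param d_x embedding dimension.
#' @param d_h hidden dimension.
#' @param labels a [label_set()].
#' @param ablation an [ablation_config()].
#' @param K PAS layer count.
#' @param slope LeakyReLU negative slope for both attention modules.
#' @param rho_gate if `TRUE`, a learned scalar gate multiplies the PAS block
#'   before fusion (off by default).
#' @param init_scale half-width of the uniform initialization.
#' @return object of class `trigger_model`.
#' @export
trigger_model <- function(d_x, d_h, labels, ablation = ablation_config(),
                          K = 2L, slope = 0.2, rho_gate = FALSE,
                          init_scale = 0.1) {
  m <- length(labels)
  params <- list(
    dep = cell_params(d_x, d_h, init_scale),
    dep_attn = attention_params(d_h, d_q = d_x, slope = slope,
                                query_projection = TRUE, init_scale = init_scale),
    pas = cell_params(d_x, d_h, init_scale),
    pas_attn = attention_params(d_h, slope = slope, init_scale = init_scale),
    cls = list(W = matrix(stats::runif(m * 2 * d_h, -init_scale, init_scale), m, 2 * d_h),
               b = stats::runif(m, -init_scale, init_scale))
  )
  if (rho_gate) params$rho <- 1
  structure(list(d_x = d_x, d_h = d_h, labels = labels, ablation = ablation,
                 K = as.integer(K), slope = slope, rho_gate = rho_gate,
                 params = params),
            class = "trigger_model")
}

#' @export
print.trigger_model <- function(x, ...) {
  ab <- x$ablation
  cat(sprintf("<trigger_model d_x=%d d_h=%d |labels|=%d K=%d dep=%s(attn=%s) pas=%s(attn=%s)>\n",
              x$d_x, x$d_h, length(x$labels), x$K,
              ab$use_dep, ab$attn_dep, ab$use_pas, ab$attn_pas))
  invisible(x)
}

pas_param_view <- function(model) {
  list(cell = model$params$pas, attn = model$params$pas_attn, K = model$K)
}

#' Softmax token classifier
#'
#' A single affine map from fused representations to trigger-class
#' probabilities.
#'
#' @param fused matrix `2*d_h x n` of fused token representations.
#' @param W,b classifier weights (`m x 2*d_h`) and bias (length `m`).
#' @return probability matrix `m x n`, columns summing to 1.
#' @export
classify <- function(fused, W, b) {
  if (ncol(W) != nrow(fused)) stop_eatree("classifier width mismatch", "eatree_shape_error")
  logits <- W %*% fused + b
  probs <- apply(logits, 2, softmax)
  matrix(probs, nrow = nrow(W), ncol = ncol(fused))
}

## full forward pass for one sentence; X is d_x x n (already dropped-out if
## training)
model_forward <- function(model, X, tree, pas) {
  ab <- model$ablation
  n <- ncol(X)
  dep_fwd <- NULL; pas_fwd <- NULL
  dep_H <- NULL; pas_H <- NULL
  if (ab$use_dep) {
    dep_fwd <- tree_forward(tree, X, model$params$dep, model$params$dep_attn,
                            attentive = ab$attn_dep)
    dep_H <- dep_fwd$H
  }
  if (ab$use_pas) {
    pas_fwd <- pas_forward(pas, X, pas_param_view(model), attentive = ab$attn_pas)
    pas_H <- pas_fwd$H
  }
  rho <- if (model$rho_gate) model$params$rho else 1
  d_h <- model$d_h
  fused <- fuse(dep_H %||% matrix(0, d_h, n), pas_H %||% matrix(0, d_h, n), rho = rho)
  probs <- classify(fused, model$params$cls$W, model$params$cls$b)
  list(fused = fused, probs = probs, dep_fwd = dep_fwd, pas_fwd = pas_fwd,
       dep_H = dep_H, pas_H = pas_H, X = X)
}

zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else x * 0

zero_grads <- function(params) rapply(params, zero_like, how = "replace")

## Cross-entropy + L2 loss and analytic gradients over a batch of
## sentences. Each instance: list(X, tree, pas, y) with y integer labels
## (1 = NONE). Returns list(loss, grads, n_tokens).
loss_and_grads <- function(model, batch, lambda = 0) {
  ab <- model$ablation
  d_h <- model$d_h
  grads <- zero_grads(model$params)
  k_total <- sum(vapply(batch, function(b) length(b$y), integer(1)))
  if (k_total == 0L) stop_eatree("batch contains no labeled nodes", "eatree_domain_error")
  nll <- 0
  for (inst in batch) {
    fw <- model_forward(model, inst$X, inst$tree, inst$pas)
    n <- ncol(inst$X)
    p_correct <- fw$probs[cbind(inst$y, seq_len(n))]
    nll <- nll + sum(-log(pmax(p_correct, 1e-300)))
    dlogits <- fw$probs
    dlogits[cbind(inst$y, seq_len(n))] <- dlogits[cbind(inst$y, seq_len(n))] - 1
    dlogits <- dlogits / k_total
    grads$cls$W <- grads$cls$W + tcrossprod(dlogits, fw$fused)
    grads$cls$b <- grads$cls$b + rowSums(dlogits)
    dfused <- crossprod(model$params$cls$W, dlogits)     # 2 d_h x n
    if (ab$use_dep) {
      bk <- tree_backward(inst$tree, inst$X, model$params$dep,
                          model$params$dep_attn, ab$attn_dep, fw$dep_fwd,
                          dfused[seq_len(d_h), , drop = FALSE],
                          grads$dep, grads$dep_attn)
      grads$dep <- bk$g_cell
      if (ab$attn_dep) grads$dep_attn <- bk$g_attn
    }
    if (ab$use_pas) {
      dpas <- dfused[d_h + seq_len(d_h), , drop = FALSE]
      if (model$rho_gate) {
        grads$rho <- grads$rho + sum(dpas * fw$pas_H)
        dpas <- model$params$rho * dpas
      }
      bk <- pas_backward(inst$pas, inst$X, pas_param_view(model), ab$attn_pas,
                         fw$pas_fwd, dpas, grads$pas, grads$pas_attn)
      grads$pas <- bk$g_cell
      if (ab$attn_pas) grads$pas_attn <- bk$g_attn
    }
  }
  loss <- nll / k_total
  if (lambda > 0) {
    flat <- unlist(strip_slopes(model$params), use.names = FALSE)
    loss <- loss + lambda / 2 * sum(flat^2)
    grads <- add_scaled(grads, model$params, lambda)
  }
  list(loss = loss, grads = grads, n_tokens = k_total)
}

## the LeakyReLU slope rides inside the attention parameter lists but is a
## hyperparameter, not a trainable weight
strip_slopes <- function(params) {
  params$dep_attn$slope <- NULL
  params$pas_attn$slope <- NULL
  params
}

add_scaled <- function(grads, params, lambda) {
  for (nm in c("dep", "pas")) {
    for (k in names(params[[nm]])) grads[[nm]][[k]] <- grads[[nm]][[k]] + lambda * params[[nm]][[k]]
  }
  for (nm in c("dep_attn", "pas_attn")) {
    for (k in setdiff(names(params[[nm]]), "slope")) {
      grads[[nm]][[k]] <- grads[[nm]][[k]] + lambda * params[[nm]][[k]]
    }
  }
  grads$cls$W <- grads$cls$W + lambda * params$cls$W
  grads$cls$b <- grads$cls$b + lambda * params$cls$b
  if (!is.null(params$rho)) grads$rho <- grads$rho + lambda * params$rho
  grads
}

## flatten/unflatten trainable parameters (used by the finite-difference
## harness and by serialization)
flatten_params <- function(params) unlist(strip_slopes(params), use.names = TRUE)

unflatten_params <- function(flat, template) {
  slopes <- list(dep_attn = template$dep_attn$slope, pas_attn = template$pas_attn$slope)
  out <- utils::relist(flat, strip_slopes(template))
  ## relist drops matrix dims; restore them
  restore <- function(new, old) {
    if (is.list(old)) {
      for (k in names(old)) new[[k]] <- restore(new[[k]], old[[k]])
      new
    } else if (is.matrix(old)) {
      matrix(new, nrow(old), ncol(old))
    } else as.numeric(new)
  }
  out <- restore(out, strip_slopes(template))
  out$dep_attn$slope <- slopes$dep_attn
  out$pas_attn$slope <- slopes$pas_attn
  out
}

#' Predict trigger annotations for a corpus
#'
#' Classifies every token from its fused representation, then recovers
#' prediction spans by merging runs of adjacent same-label tokens.
#'
#' @param model a trained [trigger_model()].
#' @param corpus list of [trigger_document()].
#' @param embeddings an [embedding_table()].
#' @return list with `annotations` (data.frame doc_id/label/char_start/
#'   char_end) and `token_labels` (per document, per sentence integer
#'   labels).
#' @export
predict_corpus <- function(model, corpus, embeddings) {
  ann <- data.frame(doc_id = character(0), label = character(0),
                    char_start = integer(0), char_end = integer(0),
                    stringsAsFactors = FALSE)
  tl <- list()
  for (doc in corpus) {
    doc_labels <- list()
    for (si in seq_along(doc$trees)) {
      tr <- doc$trees[[si]]
      X <- embed_tokens(embeddings, tr$tokens$form)
      pas <- doc$pas[[tr$sentence_id]] %||% pas_graph(tr$sentence_id, NULL, n_tokens(tr))
      fw <- model_forward(model, X, tr, pas)
      y <- apply(fw$probs, 2, which.max)
      doc_labels[[si]] <- y
      sp <- spans_from_labels(tr, y, model$labels)
      if (nrow(sp)) ann <- rbind(ann, cbind(doc_id = doc$doc_id, sp))
    }
    tl[[doc$doc_id]] <- doc_labels
  }
  list(annotations = ann, token_labels = tl)
}

#' Merge per-token labels into trigger spans
#'
#' Runs of adjacent tokens sharing a non-NONE label become one span (the
#' recovery rule matching per-token labeling of multi-word triggers).
#'
#' @param tree a [dep_tree()].
#' @param y integer token labels (1 = NONE).
#' @param labels a [label_set()].
#' @return data.frame with `label`, `char_start`, `char_end`.
#' @export
spans_from_labels <- function(tree, y, labels) {
  out <- data.frame(label = character(0), char_start = integer(0),
                    char_end = integer(0), stringsAsFactors = FALSE)
  n <- length(y)
  i <- 1L
  while (i <= n) {
    if (y[i] != 1L) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      out <- rbind(out, data.frame(label = labels[y[i]],
                                   char_start = tree$tokens$char_start[i],
                                   char_end = tree$tokens$char_end[j],
                                   stringsAsFactors = FALSE))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}
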