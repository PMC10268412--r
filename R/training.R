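## Loss, Adam optimization loop, and span-level evaluation.

#' Training configuration
#'
#' Defaults follow the corpus-scale recipe: batch size 32, dropout 0.2 on
#' input embeddings, learning rate 0.001, 50 epochs, L2 coefficient 0.003,
#' Adam moments beta1 = 0.88 / beta2 = 0.90, hidden size 256 and embedding
#' size 720. Tests and the synthetic suite pass smaller `hidden`/`embedding`
#' values for speed.
#'
#' @param batch_size sentences per parameter update.
#' @param dropout input-embedding dropout rate (training only).
#' @param learning_rate Adam step size.
#' @param epochs maximum epochs.
#' @param lambda L2 regularization coefficient.
#' @param beta1,beta2 Adam moment decay rates.
#' @param hidden hidden dimension `d_h`.
#' @param embedding embedding dimension `d_x`.
#' @param seed root seed for every random draw (init, shuffling, dropout).
#' @param early_stop_f1 optional: stop once training-set token-level
#'   micro-F1 reaches this value (percent); `NA` disables.
#' @param K PAS layer count.
#' @param rho_gate enable the learned scalar gate on the PAS block.
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, dropout = 0.2, learning_rate = 0.001,
                         epochs = 50L, lambda = 0.003, beta1 = 0.88,
                         beta2 = 0.90, hidden = 256L, embedding = 720L,
                         seed = 0L, early_stop_f1 = NA_real_, K = 2L,
                         rho_gate = FALSE) {
  cfg <- list(batch_size = as.integer(batch_size), dropout = dropout,
              learning_rate = learning_rate, epochs = as.integer(epochs),
              lambda = lambda, beta1 = beta1, beta2 = beta2,
              hidden = as.integer(hidden), embedding = as.integer(embedding),
              seed = as.integer(seed), early_stop_f1 = early_stop_f1,
              K = as.integer(K), rho_gate = rho_gate)
  stopifnot(cfg$batch_size > 0, cfg$dropout >= 0, cfg$dropout < 1,
            cfg$learning_rate >= 0, cfg$epochs >= 0, cfg$lambda >= 0,
            cfg$hidden > 0, cfg$embedding > 0)
  structure(cfg, class = "train_config")
}

#' Read a training configuration from a JSON file
#'
#' Keys mirror the [train_config()] argument names; missing keys take the
#' defaults.
#'
#' @param path JSON file path.
#' @return a [train_config()].
#' @export
read_train_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(train_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop_eatree(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
                "eatree_parse_error")
  }
  do.call(train_config, vals)
}

#' Cross-entropy loss with L2 penalty
#'
#' `-(1/k) sum log p_hat(correct class) + (lambda/2) * ||theta||^2` over the
#' `k` labeled nodes of a batch.
#'
#' @param probs probability matrix, classes by tokens (columns sum to 1).
#' @param y integer vector of correct classes, one per token.
#' @param theta parameter list (or numeric vector) entering the penalty;
#'   `NULL` for no penalty.
#' @param lambda L2 coefficient.
#' @return scalar loss.
#' @export
trigger_loss <- function(probs, y, theta = NULL, lambda = 0) {
  if (length(y) == 0L) stop_eatree("no labeled nodes", "eatree_domain_error")
  if (length(y) != ncol(probs)) stop_eatree("one label per token required",
                                            "eatree_shape_error")
  nll <- -mean(log(pmax(probs[cbind(y, seq_along(y))], 1e-300)))
  pen <- 0
  if (!is.null(theta) && lambda > 0) {
    flat <- if (is.numeric(theta)) theta else unlist(strip_slopes(theta), use.names = FALSE)
    pen <- lambda / 2 * sum(flat^2)
  }
  nll + pen
}

#' F1 from precision and recall percentages
#'
#' Harmonic mean `2PR/(P+R)`, rounded to 2 decimals as reported.
#'
#' @param precision_pct,recall_pct percentages in `[0, 100]`.
#' @return F1 percentage (0 with a warning when both inputs are 0).
#' @export
f1_score <- function(precision_pct, recall_pct) {
  if (precision_pct == 0 && recall_pct == 0) {
    warning("precision and recall both 0; F1 defined as 0")
    return(0)
  }
  round(2 * precision_pct * recall_pct / (precision_pct + recall_pct), 2)
}

#' Span-level evaluation against gold annotations
#'
#' Exact-span, exact-type matching on merged token spans; the NONE class is
#' never a positive. Reports micro-averaged precision/recall/F1 (percent),
#' a per-class breakdown and the macro average.
#'
#' @param predictions,gold data.frames with columns `doc_id`, `label`,
#'   `char_start`, `char_end`.
#' @param labels a [label_set()].
#' @return list of class `trigger_metrics`.
#' @export
evaluate_triggers <- function(predictions, gold, labels) {
  chk <- function(df, what) {
    if (nrow(df) && !all(df$label %in% setdiff(labels, "NONE"))) {
      stop_eatree(sprintf("%s contains labels outside the label set", what),
                  "eatree_label_error")
    }
  }
  chk(predictions, "predictions"); chk(gold, "gold")
  key <- function(df) paste(df$doc_id, df$label, df$char_start, df$char_end)
  pct <- function(num, den) if (den == 0) 0 else 100 * num / den
  per_class <- list()
  tp_all <- 0L
  for (cl in setdiff(labels, "NONE")) {
    p <- predictions[predictions$label == cl, , drop = FALSE]
    g <- gold[gold$label == cl, , drop = FALSE]
    tp <- sum(key(p) %in% key(g))
    tp_all <- tp_all + tp
    P <- pct(tp, nrow(p)); R <- pct(tp, nrow(g))
    per_class[[cl]] <- list(tp = tp, n_pred = nrow(p), n_gold = nrow(g),
                            precision = P, recall = R,
                            f1 = if (P == 0 && R == 0) 0 else f1_score(P, R))
  }
  if (nrow(predictions) == 0L && nrow(gold) > 0L) {
    warning("no predictions; precision defined as 0")
  }
  P <- pct(tp_all, nrow(predictions))
  R <- pct(tp_all, nrow(gold))
  F1 <- if (P == 0 && R == 0) 0 else f1_score(P, R)
  macro <- mean(vapply(per_class, `[[`, numeric(1), "f1"))
  structure(list(precision = P, recall = R, f1 = F1, macro_f1 = macro,
                 tp = tp_all, n_pred = nrow(predictions), n_gold = nrow(gold),
                 per_class = per_class),
            class = "trigger_metrics")
}

#' @export
print.trigger_metrics <- function(x, ...) {
  cat(sprintf("micro P/R/F1: %.2f / %.2f / %.2f  (tp=%d pred=%d gold=%d)\n",
              x$precision, x$recall, x$f1, x$tp, x$n_pred, x$n_gold))
  for (cl in names(x$per_class)) {
    pc <- x$per_class[[cl]]
    cat(sprintf("  %-16s P/R/F1: %6.2f / %6.2f / %6.2f\n", cl,
                pc$precision, pc$recall, pc$f1))
  }
  invisible(x)
}

adam_init <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      for (k in names(p)) {
        if (k == "slope") next
        r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
        p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

## materialize training instances: one per sentence
corpus_instances <- function(corpus, embeddings, labels) {
  out <- list()
  for (doc in corpus) {
    ys <- token_labels(doc, labels)
    for (si in seq_along(doc$trees)) {
      tr <- doc$trees[[si]]
      pas <- doc$pas[[tr$sentence_id]] %||% pas_graph(tr$sentence_id, NULL, n_tokens(tr))
      out[[length(out) + 1L]] <- list(
        X = embed_tokens(embeddings, tr$tokens$form),
        tree = tr, pas = pas, y = ys[[si]]
      )
    }
  }
  out
}

token_micro_f1 <- function(model, instances) {
  tp <- 0L; np <- 0L; ng <- 0L
  for (inst in instances) {
    fw <- model_forward(model, inst$X, inst$tree, inst$pas)
    y <- apply(fw$probs, 2, which.max)
    tp <- tp + sum(y != 1L & y == inst$y)
    np <- np + sum(y != 1L)
    ng <- ng + sum(inst$y != 1L)
  }
  if (np == 0L || ng == 0L) return(0)
  P <- 100 * tp / np; R <- 100 * tp / ng
  if (P == 0 && R == 0) 0 else 2 * P * R / (P + R)
}

#' Train a trigger-detection model
#'
#' Minimizes the regularized cross-entropy by Adam over mini-batches of
#' whole sentences. Every random draw (initialization, epoch shuffling,
#' dropout masks) flows from the single config seed, so a given
#' `(seed, corpus, config)` yields a bit-identical loss trace.
#'
#' @param corpus list of [trigger_document()] (training split).
#' @param embeddings an [embedding_table()].
#' @param labels a [label_set()].
#' @param config a [train_config()].
#' @param ablation an [ablation_config()].
#' @param model optional pre-built [trigger_model()] (otherwise initialized
#'   here from the seeded RNG).
#' @param verbose print one line per epoch.
#' @return list of class `trigger_fit`: `model`, `trace` (data.frame with
#'   epoch and mean loss), `config`, `ablation`, `epochs_run`.
#' @export
train_model <- function(corpus, embeddings, labels, config = train_config(),
                        ablation = ablation_config(), model = NULL,
                        verbose = FALSE) {
  set.seed(config$seed)
  if (is.null(model)) {
    model <- trigger_model(config$embedding, config$hidden, labels,
                           ablation = ablation, K = config$K,
                           rho_gate = config$rho_gate)
  } else {
    model$ablation <- ablation
  }
  instances <- corpus_instances(corpus, embeddings, labels)
  if (!length(instances)) stop_eatree("empty training corpus", "eatree_domain_error")
  state <- adam_init(model$params)
  trace <- data.frame(epoch = integer(0), loss = numeric(0))
  epochs_run <- 0L
  for (ep in seq_len(config$epochs)) {
    idx <- sample(length(instances))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(idx), by = config$batch_size)) {
      sel <- idx[start:min(start + config$batch_size - 1L, length(idx))]
      batch <- instances[sel]
      if (config$dropout > 0) {
        batch <- lapply(batch, function(inst) {
          mask <- matrix(stats::rbinom(length(inst$X), 1, 1 - config$dropout),
                         nrow(inst$X)) / (1 - config$dropout)
          inst$X <- inst$X * mask
          inst
        })
      }
      lg <- loss_and_grads(model, batch, lambda = config$lambda)
      if (!is.finite(lg$loss)) {
        stop_eatree(sprintf("non-finite loss at epoch %d", ep), "eatree_divergence_error")
      }
      if (config$learning_rate > 0) {
        st <- adam_step(model$params, lg$grads, state, config$learning_rate,
                        config$beta1, config$beta2)
        model$params <- st$params
        state <- st$state
      }
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    epochs_run <- ep
    trace <- rbind(trace, data.frame(epoch = ep, loss = ep_loss / nb))
    if (verbose) message(sprintf("epoch %3d  loss %.5f", ep, ep_loss / nb))
    if (!is.na(config$early_stop_f1)) {
      if (token_micro_f1(model, instances) >= config$early_stop_f1) break
    }
  }
  structure(list(model = model, trace = trace, config = config,
                 ablation = ablation, epochs_run = epochs_run),
            class = "trigger_fit")
}

#' @export
print.trigger_fit <- function(x, ...) {
  cat(sprintf("<trigger_fit: %d epochs, final loss %.5f>\n", x$epochs_run,
              utils::tail(x$trace$loss, 1)))
  invisible(x)
}
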