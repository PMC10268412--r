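## Seeded generator of synthetic corpora with the statistical structure the
## encoders assume: random single-rooted dependency trees, correlated PAS
## graphs, a planted trigger rule, and deterministic class-informative
## embeddings. Stands in for the licensed shared-task corpora so every
## stage is testable offline.

#' Synthetic-corpus configuration
#'
#' The planted rule: a token is a trigger of its word's class iff the word
#' belongs to the trigger vocabulary AND (one of its dependency children is
#' an entity word, OR — for the designated PAS-only fraction of trigger
#' words — one of its PAS neighbors is an entity word). Labels are then
#' flipped at the noise rate.
#'
#' @param n_train,n_test sentence counts (one sentence per document).
#' @param len_min,len_max sentence length range.
#' @param branching chain bias of the random-attachment tree sampler in
#'   `[0, 1]`: 0 attaches uniformly to any placed token, 1 always extends a
#'   chain.
#' @param n_trigger_words,n_entity_words,n_filler_words vocabulary sizes.
#' @param n_classes number of trigger classes (the label set adds NONE).
#' @param pas_only_frac fraction of trigger-vocabulary words whose triggers
#'   are detectable only through PAS neighbors.
#' @param pas_arc_frac probability that a dependency arc is echoed as a PAS
#'   edge.
#' @param noise label-flip probability.
#' @param embed_dim embedding dimension (must be at least
#'   `3 + n_classes`).
#' @param seed root seed; the same seed yields byte-identical corpus files.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_train = 200L, n_test = 50L, len_min = 5L,
                         len_max = 15L, branching = 0.3,
                         n_trigger_words = 12L, n_entity_words = 12L,
                         n_filler_words = 30L, n_classes = 3L,
                         pas_only_frac = 0.3, pas_arc_frac = 0.5,
                         noise = 0, embed_dim = 16L, seed = 0L) {
  cfg <- list(n_train = as.integer(n_train), n_test = as.integer(n_test),
              len_min = as.integer(len_min), len_max = as.integer(len_max),
              branching = branching, n_trigger_words = as.integer(n_trigger_words),
              n_entity_words = as.integer(n_entity_words),
              n_filler_words = as.integer(n_filler_words),
              n_classes = as.integer(n_classes),
              pas_only_frac = pas_only_frac, pas_arc_frac = pas_arc_frac,
              noise = noise, embed_dim = as.integer(embed_dim),
              seed = as.integer(seed))
  if (cfg$len_min < 2L) stop_eatree("sentence length must be >= 2", "eatree_config_error")
  if (cfg$n_trigger_words < 1L || cfg$n_entity_words < 1L) {
    stop_eatree("trigger and entity vocabularies must be nonempty", "eatree_config_error")
  }
  if (cfg$pas_only_frac < 0 || cfg$pas_only_frac > 1 || cfg$noise < 0 || cfg$noise > 1 ||
      cfg$pas_arc_frac < 0 || cfg$pas_arc_frac > 1 ||
      cfg$branching < 0 || cfg$branching > 1) {
    stop_eatree("fractions must lie in [0, 1]", "eatree_config_error")
  }
  if (cfg$embed_dim < 3L + cfg$n_classes) {
    stop_eatree("embed_dim must be at least 3 + n_classes", "eatree_config_error")
  }
  structure(cfg, class = "synth_config")
}

synth_vocab <- function(cfg) {
  trig <- sprintf("trg%02d", seq_len(cfg$n_trigger_words))
  ent <- sprintf("ent%02d", seq_len(cfg$n_entity_words))
  fill <- sprintf("wrd%02d", seq_len(cfg$n_filler_words))
  class_of <- 1L + (seq_len(cfg$n_trigger_words) - 1L) %% cfg$n_classes
  names(class_of) <- trig
  n_pas_only <- round(cfg$pas_only_frac * cfg$n_trigger_words)
  list(trigger = trig, entity = ent, filler = fill, class_of = class_of,
       pas_only = trig[seq_len(n_pas_only)])
}

## random single-rooted tree by sequential random attachment over surface
## positions 1..n visited in random order
synth_tree <- function(sid, words, branching) {
  n <- length(words)
  perm <- sample(n)
  head <- integer(n)
  for (t in seq_len(n)[-1]) {
    head[perm[t]] <- if (t > 2L && stats::runif(1) < branching) perm[t - 1L]
                     else perm[sample(t - 1L, 1L)]
  }
  deprel <- ifelse(head == 0L, "root", "dep")
  dep_tree(sid, form = words, head = head, deprel = deprel,
           pos = rep("NN", n))
}

synth_sentence <- function(cfg, vocab, sid) {
  n <- sample(cfg$len_min:cfg$len_max, 1L)
  kind <- sample(c("trigger", "entity", "filler"), n, replace = TRUE,
                 prob = c(0.25, 0.3, 0.45))
  words <- vapply(kind, function(k) sample(vocab[[k]], 1L), character(1))
  tree <- synth_tree(sid, words, cfg$branching)
  is_ent <- words %in% vocab$entity
  is_trg <- words %in% vocab$trigger
  ## PAS: echo of a subset of dependency arcs ...
  edges <- data.frame(pred = integer(0), arg = integer(0), role = character(0),
                      stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    if (tree$head[j] != 0L && stats::runif(1) < cfg$pas_arc_frac) {
      edges <- rbind(edges, data.frame(pred = tree$head[j], arg = j,
                                       role = sample(c("arg1", "arg2"), 1L),
                                       stringsAsFactors = FALSE))
    }
  }
  ## ... plus long-range predicate-argument edges from PAS-designated
  ## trigger tokens to entity tokens elsewhere in the sentence
  ents <- which(is_ent)
  for (j in which(words %in% vocab$pas_only)) {
    if (length(ents) && stats::runif(1) < 0.7) {
      a <- if (length(ents) == 1L) ents else sample(ents, 1L)
      if (a != j) {
        edges <- rbind(edges, data.frame(pred = j, arg = a,
                                         role = sample(c("arg1", "arg2"), 1L),
                                         stringsAsFactors = FALSE))
      }
    }
  }
  if (stats::runif(1) < 0.3 && n >= 2L) {
    pr <- sample(n, 2L)
    edges <- rbind(edges, data.frame(pred = pr[1], arg = pr[2], role = "other",
                                     stringsAsFactors = FALSE))
  }
  pas <- pas_graph(sid, edges, n)
  ## planted labels
  y <- rep(1L, n)
  for (j in which(is_trg)) {
    kids <- children(tree, j)
    dep_hit <- any(is_ent[kids])
    pas_hit <- (words[j] %in% vocab$pas_only) && any(is_ent[pas$neighbors[[j]]])
    if (dep_hit || pas_hit) y[j] <- 1L + vocab$class_of[[words[j]]]
  }
  if (cfg$noise > 0) {
    for (j in seq_len(n)) {
      if (stats::runif(1) < cfg$noise) {
        y[j] <- sample(setdiff(seq_len(cfg$n_classes + 1L), y[j]), 1L)
      }
    }
  }
  list(tree = tree, pas = pas, y = y)
}

synth_labels <- function(cfg) label_set(sprintf("Evt%d", seq_len(cfg$n_classes)))

synth_document <- function(cfg, vocab, labels, doc_id) {
  s <- synth_sentence(cfg, vocab, paste0(doc_id, "-s1"))
  text <- paste(s$tree$tokens$form, collapse = " ")
  spans <- spans_from_labels(s$tree, s$y, labels)
  triggers <- NULL
  if (nrow(spans)) {
    triggers <- cbind(annotation_id = sprintf("T%d", seq_len(nrow(spans)) +
                                                sum(s$tree$tokens$form %in% vocab$entity)),
                      spans)
  }
  ent_idx <- which(s$tree$tokens$form %in% vocab$entity)
  entities <- NULL
  if (length(ent_idx)) {
    entities <- data.frame(annotation_id = sprintf("T%d", seq_along(ent_idx)),
                           label = "Protein",
                           char_start = s$tree$tokens$char_start[ent_idx],
                           char_end = s$tree$tokens$char_end[ent_idx],
                           stringsAsFactors = FALSE)
  }
  doc <- trigger_document(doc_id, text, list(s$tree),
                          stats::setNames(list(s$pas), s$tree$sentence_id),
                          triggers = triggers, entities = entities)
  doc
}

#' Deterministic class-informative embeddings for a synthetic vocabulary
#'
#' Hash-seeded base vectors plus signal components: one dimension flags
#' trigger-vocabulary membership, one flags entity membership, and one
#' dimension per class one-hot-encodes a trigger word's class. The task is
#' thereby learnable at small dimensions without any download.
#'
#' @param vocab vocabulary list from the generator.
#' @param d embedding dimension.
#' @param seed hash seed.
#' @return an [embedding_table()] covering the whole vocabulary.
#' @export
synth_embeddings <- function(vocab, d = 16L, seed = 0L) {
  words <- c(vocab$trigger, vocab$entity, vocab$filler)
  vecs <- lapply(words, function(w) {
    v <- 0.5 * hash_vector(w, d, seed)
    if (w %in% vocab$trigger) {
      v[1] <- v[1] + 1.5
      v[3L + vocab$class_of[[w]]] <- v[3L + vocab$class_of[[w]]] + 1.5
    }
    if (w %in% vocab$entity) v[2] <- v[2] + 1.5
    v
  })
  embedding_table(d, stats::setNames(vecs, words), seed = seed)
}

#' Generate a synthetic trigger-detection corpus
#'
#' @param cfg a [synth_config()].
#' @return list of class `synth_corpus` with `train` and `test` document
#'   lists, `labels`, `embeddings`, `vocab` and `config`.
#' @export
generate_corpus <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  vocab <- synth_vocab(cfg)
  labels <- synth_labels(cfg)
  train <- lapply(seq_len(cfg$n_train), function(i)
    synth_document(cfg, vocab, labels, sprintf("train%04d", i)))
  test <- lapply(seq_len(cfg$n_test), function(i)
    synth_document(cfg, vocab, labels, sprintf("test%04d", i)))
  emb <- synth_embeddings(vocab, cfg$embed_dim, cfg$seed)
  structure(list(train = train, test = test, labels = labels,
                 embeddings = emb, vocab = vocab, config = cfg),
            class = "synth_corpus")
}

#' Gold annotations of a document list
#'
#' @param corpus list of [trigger_document()].
#' @return data.frame with `doc_id`, `label`, `char_start`, `char_end`.
#' @export
gold_annotations <- function(corpus) {
  out <- data.frame(doc_id = character(0), label = character(0),
                    char_start = integer(0), char_end = integer(0),
                    stringsAsFactors = FALSE)
  for (doc in corpus) {
    if (nrow(doc$triggers)) {
      out <- rbind(out, data.frame(doc_id = doc$doc_id, label = doc$triggers$label,
                                   char_start = doc$triggers$char_start,
                                   char_end = doc$triggers$char_end,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Rule-based oracle over the planted generator rule
#'
#' Recomputes the planted labels directly from the structures, optionally
#' blind to the PAS graph — the counting baseline that bounds what a
#' tree-only model can recover.
#'
#' @param corpus list of synthetic [trigger_document()].
#' @param vocab generator vocabulary.
#' @param labels a [label_set()].
#' @param use_pas if `FALSE` the PAS route of the rule is ignored.
#' @return annotation data.frame as in [gold_annotations()].
#' @export
planted_oracle <- function(corpus, vocab, labels, use_pas = TRUE) {
  out <- data.frame(doc_id = character(0), label = character(0),
                    char_start = integer(0), char_end = integer(0),
                    stringsAsFactors = FALSE)
  for (doc in corpus) {
    for (tr in doc$trees) {
      words <- tr$tokens$form
      is_ent <- words %in% vocab$entity
      pas <- doc$pas[[tr$sentence_id]]
      y <- rep(1L, length(words))
      for (j in which(words %in% vocab$trigger)) {
        hit <- any(is_ent[children(tr, j)])
        if (!hit && use_pas && !is.null(pas) && (words[j] %in% vocab$pas_only)) {
          hit <- any(is_ent[pas$neighbors[[j]]])
        }
        if (hit) y[j] <- 1L + vocab$class_of[[words[j]]]
      }
      sp <- spans_from_labels(tr, y, labels)
      if (nrow(sp)) out <- rbind(out, cbind(doc_id = doc$doc_id, sp))
    }
  }
  out
}
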