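test_that("synth_config validates its domain", {
  expect_error(synth_config(len_min = 1), class = "eatree_config_error")
  expect_error(synth_config(n_trigger_words = 0), class = "eatree_config_error")
  expect_error(synth_config(noise = 1.2), class = "eatree_config_error")
  expect_error(synth_config(embed_dim = 4, n_classes = 3),
               class = "eatree_config_error")
})

test_that("generation is deterministic: same seed, byte-identical files", {
  cfg <- synth_config(n_train = 6, n_test = 3, seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_corpus(generate_corpus(cfg)$train, d1)
  write_corpus(generate_corpus(cfg)$train, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
  ## different seed differs somewhere
  d3 <- withr::local_tempdir()
  write_corpus(generate_corpus(synth_config(n_train = 6, n_test = 3, seed = 12))$train, d3)
  same <- vapply(f1, function(f) identical(
    readLines(file.path(d1, f), warn = FALSE),
    readLines(file.path(d3, f), warn = FALSE)), logical(1))
  expect_false(all(same))
})

test_that("generated structures satisfy the tree and PAS invariants", {
  w <- generate_corpus(synth_config(n_train = 15, n_test = 5, seed = 2,
                                    pas_only_frac = 0.5))
  for (doc in c(w$train, w$test)) {
    for (tr in doc$trees) {
      n <- nrow(tr$tokens)
      expect_identical(sum(tr$head == 0L), 1L)
      sizes <- vapply(seq_len(n), function(j) length(children(tr, j)), integer(1))
      expect_identical(sum(sizes), n - 1L)
      g <- doc$pas[[tr$sentence_id]]
      for (j in seq_len(n)) {
        for (nb in g$neighbors[[j]]) expect_true(j %in% g$neighbors[[nb]])
      }
    }
  }
})

test_that("generated corpora round-trip through the corpus readers", {
  w <- generate_corpus(synth_config(n_train = 8, n_test = 2, seed = 3))
  dir <- withr::local_tempdir()
  write_corpus(w$train, dir)
  back <- read_corpus(dir, w$labels)
  expect_length(back, 8L)
  for (i in seq_along(back)) {
    orig <- w$train[[i]]
    expect_identical(back[[i]]$doc_id, orig$doc_id)
    expect_identical(back[[i]]$text, orig$text)
    expect_identical(back[[i]]$trees[[1]]$head, orig$trees[[1]]$head)
    expect_identical(back[[i]]$trees[[1]]$tokens$form, orig$trees[[1]]$tokens$form)
    expect_identical(
      back[[i]]$pas[[1]]$neighbors, orig$pas[[1]]$neighbors)
    expect_identical(back[[i]]$triggers[, c("label", "char_start", "char_end")],
                     orig$triggers[, c("label", "char_start", "char_end")],
                     ignore_attr = TRUE)
  }
})

test_that("the planted rule is recovered perfectly by the full oracle at noise 0", {
  w <- generate_corpus(synth_config(n_train = 40, n_test = 10, seed = 4,
                                    pas_only_frac = 0.4))
  gold <- gold_annotations(w$train)
  pred <- planted_oracle(w$train, w$vocab, w$labels, use_pas = TRUE)
  m <- evaluate_triggers(pred, gold, w$labels)
  expect_equal(m$f1, 100)
  ## with the PAS route disabled the oracle loses exactly the PAS-only
  ## triggers: precision stays perfect, recall drops
  blind <- planted_oracle(w$train, w$vocab, w$labels, use_pas = FALSE)
  mb <- evaluate_triggers(blind, gold, w$labels)
  expect_equal(mb$precision, 100)
  expect_lt(mb$recall, 100)
})

test_that("tree-only oracle recall drops roughly with the PAS-only fraction", {
  w <- generate_corpus(synth_config(n_train = 150, n_test = 10, seed = 5,
                                    pas_only_frac = 0.5))
  gold <- gold_annotations(w$train)
  full <- evaluate_triggers(planted_oracle(w$train, w$vocab, w$labels, TRUE),
                            gold, w$labels)
  blind <- evaluate_triggers(planted_oracle(w$train, w$vocab, w$labels, FALSE),
                             gold, w$labels)
  expect_equal(full$recall, 100)
  ## counting oracle: the tree-blind reader recovers exactly the gold spans
  ## in which every trigger token has an entity dependency child
  tree_only_spans <- 0L
  for (doc in w$train) {
    tr <- doc$trees[[1]]
    words <- tr$tokens$form
    is_ent <- words %in% w$vocab$entity
    y_full <- rep(1L, length(words)); y_dep <- rep(1L, length(words))
    for (j in which(words %in% w$vocab$trigger)) {
      dep_hit <- any(is_ent[children(tr, j)])
      pas_hit <- (words[j] %in% w$vocab$pas_only) &&
        any(is_ent[doc$pas[[tr$sentence_id]]$neighbors[[j]]])
      if (dep_hit || pas_hit) y_full[j] <- 1L + w$vocab$class_of[[words[j]]]
      if (dep_hit) y_dep[j] <- 1L + w$vocab$class_of[[words[j]]]
    }
    sp_full <- spans_from_labels(tr, y_full, w$labels)
    sp_dep <- spans_from_labels(tr, y_dep, w$labels)
    key <- function(d) paste(d$label, d$char_start, d$char_end)
    tree_only_spans <- tree_only_spans + sum(key(sp_dep) %in% key(sp_full))
  }
  expect_equal(blind$recall, 100 * tree_only_spans / nrow(gold), tolerance = 1e-9)
  expect_lt(blind$recall, full$recall)
})

test_that("a noisy world flips roughly the configured fraction of labels", {
  ## recompute the noise-free rule on a noisy corpus: the per-token
  ## disagreement rate estimates the label-flip probability
  w <- generate_corpus(synth_config(n_train = 60, n_test = 1, seed = 6,
                                    noise = 0.3))
  mismatch <- 0L; total <- 0L
  for (doc in w$train) {
    noisy <- token_labels(doc, w$labels)[[1]]
    tr <- doc$trees[[1]]
    words <- tr$tokens$form
    is_ent <- words %in% w$vocab$entity
    clean <- rep(1L, length(words))
    for (j in which(words %in% w$vocab$trigger)) {
      hit <- any(is_ent[children(tr, j)]) ||
        ((words[j] %in% w$vocab$pas_only) &&
           any(is_ent[doc$pas[[tr$sentence_id]]$neighbors[[j]]]))
      if (hit) clean[j] <- 1L + w$vocab$class_of[[words[j]]]
    }
    mismatch <- mismatch + sum(noisy != clean)
    total <- total + length(clean)
  }
  frac <- mismatch / total
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.4)
})
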