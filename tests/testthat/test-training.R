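test_that("classify produces shift-invariant distributions", {
  set.seed(30)
  fused <- matrix(rnorm(8 * 5), 8, 5)
  W0 <- matrix(0, 3, 8)
  expect_equal(classify(fused, W0, rep(0, 3)), matrix(1 / 3, 3, 5))
  W <- matrix(rnorm(24), 3, 8); b <- rnorm(3)
  p <- classify(fused, W, b)
  expect_equal(colSums(p), rep(1, 5), tolerance = 1e-6)
  expect_identical(apply(classify(fused, W, b + 5), 2, which.max),
                   apply(p, 2, which.max))
  expect_error(classify(fused, matrix(0, 3, 7), rep(0, 3)),
               class = "eatree_shape_error")
})

test_that("trigger_loss has its closed forms", {
  onehot <- diag(3)[, c(1, 2, 3)]
  expect_equal(trigger_loss(onehot, 1:3), 0, tolerance = 1e-9)
  unif <- matrix(1 / 4, 4, 6)
  expect_equal(trigger_loss(unif, rep(2L, 6)), log(4), tolerance = 1e-12)
  theta <- list(w = c(1, -2), b = 3)
  expect_equal(trigger_loss(onehot, 1:3, theta = c(1, -2, 3), lambda = 0.1),
               0.1 / 2 * 14, tolerance = 1e-9)
  expect_error(trigger_loss(unif, integer(0)), class = "eatree_domain_error")
})

test_that("f1_score reproduces printed worked examples and its properties", {
  expect_identical(f1_score(83.24, 80.90), 82.05)
  expect_identical(f1_score(66.12, 45.12), 53.64)
  expect_identical(f1_score(73.5, 73.5), 73.5)          # harmonic-mean fixpoint
  expect_identical(f1_score(40, 80), f1_score(80, 40))  # symmetry
  set.seed(31)
  for (r in 1:20) {
    P <- runif(1, 1, 100); R <- runif(1, 1, 100)
    F1 <- f1_score(P, R)
    expect_true(F1 >= min(P, R) - 0.005 && F1 <= max(P, R) + 0.005)
  }
  expect_warning(z <- f1_score(0, 0), "0")
  expect_identical(z, 0)
})

test_that("evaluate_triggers counts exact span+type matches", {
  labels <- label_set(c("A", "B"))
  gold <- data.frame(doc_id = c("d1", "d1", "d2", "d2"),
                     label = c("A", "B", "A", "B"),
                     char_start = c(0L, 10L, 0L, 5L),
                     char_end = c(4L, 14L, 4L, 9L))
  m <- evaluate_triggers(gold, gold, labels)
  expect_equal(c(m$precision, m$recall, m$f1), c(100, 100, 100))
  ## 2 correct of 3 predicted, gold size 4
  pred <- rbind(gold[c(1, 2), ],
                data.frame(doc_id = "d9", label = "A", char_start = 0L, char_end = 4L))
  m2 <- evaluate_triggers(pred, gold, labels)
  expect_equal(m2$precision, 200 / 3, tolerance = 1e-9)
  expect_equal(m2$recall, 50)
  expect_equal(m2$f1, 57.14)
  none <- gold[0, ]
  expect_warning(m3 <- evaluate_triggers(none, gold, labels), "no predictions")
  expect_equal(c(m3$precision, m3$recall, m3$f1), c(0, 0, 0))
  bad <- data.frame(doc_id = "d1", label = "Zzz", char_start = 0L, char_end = 4L)
  expect_error(evaluate_triggers(bad, gold, labels), class = "eatree_label_error")
})

make_tiny_world <- function(seed = 0, n_train = 12, n_test = 6, ...) {
  generate_corpus(synth_config(n_train = n_train, n_test = n_test,
                               len_min = 4, len_max = 7, seed = seed, ...))
}

test_that("zero learning rate leaves parameters unchanged", {
  w <- make_tiny_world()
  cfg <- train_config(hidden = 6, embedding = 16, epochs = 2, seed = 1,
                      learning_rate = 0, dropout = 0)
  set.seed(cfg$seed)
  init <- trigger_model(16, 6, w$labels)
  fit <- train_model(w$train, w$embeddings, w$labels, cfg)
  expect_equal(eatree:::flatten_params(fit$model$params),
               eatree:::flatten_params(init$params), tolerance = 0)
})

test_that("training is deterministic given the seed and reduces the loss", {
  w <- make_tiny_world()
  cfg <- train_config(hidden = 6, embedding = 16, epochs = 4, seed = 5,
                      learning_rate = 0.01, batch_size = 4)
  f1 <- train_model(w$train, w$embeddings, w$labels, cfg)
  f2 <- train_model(w$train, w$embeddings, w$labels, cfg)
  expect_identical(f1$trace$loss, f2$trace$loss)
  expect_identical(eatree:::flatten_params(f1$model$params),
                   eatree:::flatten_params(f2$model$params))
  expect_lt(utils::tail(f1$trace$loss, 1), f1$trace$loss[1])
})

test_that("analytic gradients match finite differences on small sentences", {
  set.seed(33)
  labels <- label_set(c("A", "B"))
  model <- trigger_model(4, 3, labels, K = 2)
  inst <- list(make_random_instance(n = 3, d_x = 4, m = 3, seed = 17))
  lg <- eatree:::loss_and_grads(model, inst, lambda = 0.003)
  flat_g <- eatree:::flatten_params(lg$grads)
  num <- oracle_fd_grads(model, inst, lambda = 0.003)
  rel <- abs(flat_g - num) / pmax(1e-8, abs(flat_g) + abs(num))
  expect_lt(max(rel), 1e-4)
})

test_that("config files round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(epochs = 3, hidden = 8, seed = 2), path,
                       auto_unbox = TRUE)
  cfg <- read_train_config(path)
  expect_identical(cfg$epochs, 3L)
  expect_identical(cfg$hidden, 8L)
  expect_identical(cfg$batch_size, 32L)  # untouched default
  jsonlite::write_json(list(bogus = 1), path, auto_unbox = TRUE)
  expect_error(read_train_config(path), class = "eatree_parse_error")
})

test_that("models survive JSON serialization", {
  set.seed(35)
  labels <- label_set(c("A", "B"))
  model <- trigger_model(4, 3, labels, rho_gate = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(back$params, model$params, tolerance = 1e-15)
  expect_identical(as.character(back$labels), as.character(model$labels))
  inst <- make_random_instance(n = 4, d_x = 4, m = 3, seed = 3)
  expect_equal(eatree:::model_forward(back, inst$X, inst$tree, inst$pas)$probs,
               eatree:::model_forward(model, inst$X, inst$tree, inst$pas)$probs,
               tolerance = 1e-12)
})
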