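conll_two_lines <- c("1\tThe\t_\tDT\tDT\t_\t2\tdet",
                     "2\tbinding\t_\tNN\tNN\t_\t0\troot")

test_that("read_conll parses blocks into trees", {
  trees <- read_conll(conll_two_lines)
  expect_length(trees, 1L)
  expect_identical(which(trees[[1]]$head == 0L), 2L)
  expect_identical(children(trees[[1]], 2), 1L)
  expect_identical(trees[[1]]$tokens$lemma[1], "The")  # "_" lemma falls back to form
  expect_identical(read_conll(character(0)), list())
  ## 10-column lines accepted, columns beyond DEPREL ignored
  ten <- paste0(conll_two_lines, "\t_\t_")
  expect_identical(read_conll(ten)[[1]]$head, read_conll(conll_two_lines)[[1]]$head)
})

test_that("read_conll rejects malformed input with useful errors", {
  expect_error(read_conll(c("1\ta\t_\tX\tX\t_\tx\tdep")),
               class = "eatree_parse_error")
  cyc <- c("1\ta\t_\tX\tX\t_\t2\tdep", "2\tb\t_\tX\tX\t_\t1\tdep")
  expect_error(read_conll(cyc), class = "eatree_structure_error")
  expect_error(read_conll("1\ta\tb"), class = "eatree_parse_error")
})

test_that("CoNLL read-write-read is a fixpoint", {
  set.seed(5)
  trees <- lapply(1:10, function(i) random_tree(sample(2:9, 1), sprintf("s%d", i)))
  once <- read_conll(write_conll(trees))
  twice <- read_conll(write_conll(once))
  expect_identical(lapply(once, unclass), lapply(twice, unclass))
  expect_identical(vapply(once, function(t) t$sentence_id, character(1)),
                   vapply(trees, function(t) t$sentence_id, character(1)))
})

test_that("read_pas groups, symmetrizes and is line-order invariant", {
  lines <- c("s1\t4\t2\targ1", "s1\t4\t7\targ2")
  g <- read_pas(lines)
  expect_identical(g$s1$neighbors[[4]], c(2L, 7L))
  expect_identical(read_pas(c(lines, lines[1]))$s1$edges, g$s1$edges)  # dedup
  expect_identical(read_pas(character(0)), list())
  g2 <- read_pas(rev(lines))
  expect_identical(g2$s1$edges[order(g2$s1$edges$arg), ],
                   g$s1$edges[order(g$s1$edges$arg), ],
                   ignore_attr = TRUE)
  expect_error(read_pas("s1\t1\t9\targ1", n_tokens = c(s1 = 3L)),
               class = "eatree_structure_error")
})

test_that("read_standoff routes T-lines by label set and checks offsets", {
  text <- "TNF stimulates Secretion of BHA"
  labels <- label_set(c("Location", "Neg_regulation"))
  ann <- c("T1\tProtein 0 3\tTNF",
           "T2\tLocation 15 24\tSecretion",
           "E1\tLocation:T2 Theme:T1")
  so <- read_standoff(text, ann, labels)
  expect_identical(so$triggers$label, "Location")
  expect_identical(so$entities$annotation_id, "T1")   # Protein not in label set
  expect_length(so$events, 1L)
  expect_error(read_standoff(text, c(ann, "E2\tLocation:T9"), labels),
               class = "eatree_reference_error")
  bad <- "T2\tLocation 15 24\tSecretXon"
  expect_error(read_standoff(text, bad, labels), class = "eatree_alignment_error")
  expect_warning(read_standoff(text, bad, labels, strict = FALSE), "match")
})

test_that("write_standoff round-trips triples and deduplicates", {
  expect_identical(write_standoff(data.frame(label = character(0),
                                             char_start = integer(0),
                                             char_end = integer(0)), "x"),
                   character(0))
  set.seed(9)
  labels <- label_set(c("A", "B"))
  words <- paste0("w", 1:20)
  text <- paste(words, collapse = " ")
  starts <- c(0L, cumsum(nchar(words) + 1L))[1:20]
  idx <- sample(20, 10)
  preds <- data.frame(label = sample(c("A", "B"), 10, replace = TRUE),
                      char_start = starts[idx],
                      char_end = starts[idx] + nchar(words[idx]))
  lines <- write_standoff(preds, text)
  expect_length(lines, 10L)
  back <- read_standoff(text, lines, labels)$triggers
  expect_setequal(paste(back$label, back$char_start, back$char_end),
                  paste(preds$label, preds$char_start, preds$char_end))
  expect_warning(write_standoff(preds[c(1, 1), ], text), "dedup")
  expect_error(write_standoff(data.frame(label = "NONE", char_start = 0L,
                                         char_end = 2L), text),
               class = "eatree_label_error")
})

test_that("token_labels projects multi-token annotations onto every covered token", {
  tree <- dep_tree("s1", form = c("critical", "role", "of", "X"),
                   head = c(2L, 0L, 2L, 3L))
  labels <- label_set("Regulation")
  ## "critical role" spans tokens 1-2: [0,13)
  doc <- trigger_document("d", "critical role of X", list(tree),
                          triggers = trigger_annotation("T1", "Regulation", 0, 13)[
                            , c("annotation_id", "label", "char_start", "char_end")])
  y <- token_labels(doc, labels)[[1]]
  expect_identical(y, c(2L, 2L, 1L, 1L))
  ## and spans_from_labels merges them back into one span
  sp <- spans_from_labels(tree, y, labels)
  expect_identical(nrow(sp), 1L)
  expect_identical(c(sp$char_start, sp$char_end), c(0L, 13L))
})

test_that("the shipped example files parse through all three readers", {
  ext <- function(f) system.file("extdata", f, package = "eatree")
  trees <- read_conll(ext("example.conll"))
  expect_length(trees, 1L)
  expect_identical(trees[[1]]$sentence_id, "ex1")
  expect_identical(which(trees[[1]]$head == 0L), 5L)
  pas <- read_pas(ext("example.pas"), c(ex1 = 9L))
  expect_identical(pas$ex1$neighbors[[5]], c(2L, 6L))
  labels <- label_set(c("Binding", "Phosphorylation"))
  so <- read_standoff(ext("example.txt"), ext("example.ann"), labels)
  expect_identical(sort(so$triggers$label), c("Binding", "Phosphorylation"))
  expect_identical(nrow(so$entities), 3L)
  expect_length(so$events, 2L)
  ## annotations align to tokens
  idx <- align_span(trees[[1]]$tokens, so$triggers$char_start[1],
                    so$triggers$char_end[1])
  expect_identical(trees[[1]]$tokens$form[idx], "binding")
})
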