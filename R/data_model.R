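## Core in-memory types: tokens, dependency trees, PAS graphs, label sets,
## trigger annotations, embedding tables.

#' Construct a dependency tree
#'
#' A parsed sentence: an ordered token table plus a head map. Heads use
#' 1-based token indices with 0 denoting the root. Character offsets are
#' 0-based and end-exclusive (the standoff convention).
#'
#' @param sentence_id character scalar.
#' @param form character vector of surface tokens.
#' @param head integer vector, `head[i]` is the parent of token `i` (0 = root).
#' @param deprel character vector of relation labels.
#' @param lemma,pos optional character vectors (default `form` / `"_"`).
#' @param char_start,char_end optional 0-based offsets into the source text.
#' @return an object of class `dep_tree`.
#' @export
dep_tree <- function(sentence_id, form, head, deprel = NULL,
                     lemma = NULL, pos = NULL,
                     char_start = NULL, char_end = NULL) {
  n <- length(form)
  head <- as.integer(head)
  stopifnot(length(head) == n)
  deprel <- deprel %||% rep("dep", n)
  lemma <- lemma %||% form
  pos <- pos %||% rep("_", n)
  if (is.null(char_start)) {
    ## default: single-space joined surface form
    char_start <- integer(n)
    pos0 <- 0L
    for (i in seq_len(n)) {
      char_start[i] <- pos0
      pos0 <- pos0 + nchar(form[i]) + 1L
    }
    char_end <- char_start + nchar(form)
  }
  if (any(char_start >= char_end)) {
    stop_eatree("char_start must be < char_end for every token", "eatree_structure_error")
  }
  roots <- which(head == 0L)
  if (length(roots) == 0L) {
    stop_eatree(sprintf("sentence %s: no root token (HEAD 0)", sentence_id),
                "eatree_structure_error")
  }
  if (length(roots) > 1L) {
    ## malformed parser output: keep all as roots of a virtual-root forest
    warning(sprintf("sentence %s: %d tokens with HEAD 0; treating as a virtual-root forest",
                    sentence_id, length(roots)))
  }
  if (any(head < 0L | head > n)) {
    stop_eatree(sprintf("sentence %s: HEAD out of range", sentence_id),
                "eatree_structure_error")
  }
  ## acyclicity + connectivity: every token must reach 0 following heads
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (j != 0L) {
      if (seen[j]) {
        stop_eatree(sprintf("sentence %s: cycle in head map at token %d", sentence_id, i),
                    "eatree_structure_error")
      }
      seen[j] <- TRUE
      j <- head[j]
    }
  }
  structure(list(
    sentence_id = as.character(sentence_id),
    tokens = data.frame(index = seq_len(n), form = form, lemma = lemma,
                        pos = pos, char_start = as.integer(char_start),
                        char_end = as.integer(char_end),
                        stringsAsFactors = FALSE),
    head = head,
    deprel = deprel
  ), class = "dep_tree")
}

#' @export
print.dep_tree <- function(x, ...) {
  cat(sprintf("<dep_tree %s: %d tokens, root at %s>\n", x$sentence_id,
              nrow(x$tokens), paste(which(x$head == 0L), collapse = ",")))
  invisible(x)
}

n_tokens <- function(tree) nrow(tree$tokens)

#' Children of a node in a dependency tree
#'
#' @param tree a [dep_tree()].
#' @param j token index.
#' @return integer vector of child indices in surface order (empty for leaves).
#' @export
children <- function(tree, j) {
  if (!(is.numeric(j) && length(j) == 1L && j >= 1 && j <= n_tokens(tree))) {
    stop_eatree(sprintf("token index %s out of range", paste(j, collapse = ",")),
                "eatree_index_error")
  }
  which(tree$head == as.integer(j))
}

## post-order over the (possibly multi-rooted) forest, iterative so deep
## parses cannot blow the call stack
post_order <- function(tree) {
  n <- n_tokens(tree)
  kids <- lapply(seq_len(n), function(j) which(tree$head == j))
  order <- integer(0)
  for (r in which(tree$head == 0L)) {
    stack <- list(list(node = r, stage = 1L))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (top$stage == 1L) {
        stack[[length(stack) + 1L]] <- list(node = top$node, stage = 2L)
        for (k in rev(kids[[top$node]])) {
          stack[[length(stack) + 1L]] <- list(node = k, stage = 1L)
        }
      } else {
        order <- c(order, top$node)
      }
    }
  }
  order
}

#' Construct a predicate-argument structure (PAS) graph
#'
#' Directed role-labeled edges from predicates to their arguments over the
#' tokens of one sentence; the neighborhood view used by the encoder is
#' undirected (symmetric).
#'
#' @param sentence_id character scalar.
#' @param edges data.frame with columns `pred`, `arg`, `role`; duplicates are
#'   dropped. Roles outside `arg1`..`arg4` map to `other` with a warning.
#' @param n_tokens number of tokens in the sentence.
#' @return an object of class `pas_graph` with a symmetric `neighbors` list.
#' @export
pas_graph <- function(sentence_id, edges, n_tokens) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(pred = integer(0), arg = integer(0),
                        role = character(0), stringsAsFactors = FALSE)
  }
  edges$pred <- as.integer(edges$pred)
  edges$arg <- as.integer(edges$arg)
  edges$role <- as.character(edges$role)
  ok_roles <- c("arg1", "arg2", "arg3", "arg4", "other")
  bad <- !(edges$role %in% ok_roles)
  if (any(bad)) {
    warning(sprintf("sentence %s: %d unknown PAS role(s) mapped to 'other'",
                    sentence_id, sum(bad)))
    edges$role[bad] <- "other"
  }
  if (nrow(edges) && any(edges$pred < 1L | edges$pred > n_tokens |
                         edges$arg < 1L | edges$arg > n_tokens)) {
    stop_eatree(sprintf("sentence %s: PAS edge endpoint out of token range", sentence_id),
                "eatree_structure_error")
  }
  edges <- unique(edges)
  nb <- vector("list", n_tokens)
  for (i in seq_len(n_tokens)) nb[[i]] <- integer(0)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      p <- edges$pred[r]; a <- edges$arg[r]
      if (p != a) {
        nb[[p]] <- union(nb[[p]], a)
        nb[[a]] <- union(nb[[a]], p)
      }
    }
    nb <- lapply(nb, sort)
  }
  structure(list(sentence_id = as.character(sentence_id), edges = edges,
                 n_tokens = as.integer(n_tokens), neighbors = nb),
            class = "pas_graph")
}

#' @export
print.pas_graph <- function(x, ...) {
  cat(sprintf("<pas_graph %s: %d tokens, %d edges>\n", x$sentence_id,
              x$n_tokens, nrow(x$edges)))
  invisible(x)
}

#' Construct a trigger label set
#'
#' The reserved background class `NONE` always sits at position 1.
#'
#' @param classes character vector of trigger class names (without `NONE`).
#' @return character vector of class `label_set`, `NONE` first.
#' @export
label_set <- function(classes) {
  classes <- as.character(classes)
  if (anyDuplicated(classes)) {
    stop_eatree("duplicate class names in label set", "eatree_label_error")
  }
  classes <- setdiff(classes, "NONE")
  structure(c("NONE", classes), class = "label_set")
}

#' Construct a trigger annotation
#'
#' @param annotation_id standoff id (e.g. `"T3"`).
#' @param label trigger class name (must not be `NONE`).
#' @param char_start,char_end 0-based end-exclusive offsets into the document.
#' @param token_indices optional aligned token span.
#' @return a one-row data.frame.
#' @export
trigger_annotation <- function(annotation_id, label, char_start, char_end,
                               token_indices = NULL) {
  if (identical(label, "NONE")) {
    stop_eatree("NONE is not an annotatable trigger label", "eatree_label_error")
  }
  if (char_start >= char_end) {
    stop_eatree("annotation offsets must satisfy start < end", "eatree_structure_error")
  }
  data.frame(annotation_id = annotation_id, label = label,
             char_start = as.integer(char_start), char_end = as.integer(char_end),
             token_indices = I(list(as.integer(token_indices %||% integer(0)))),
             stringsAsFactors = FALSE)
}

#' Align a character span to token indices
#'
#' Returns the minimal set of tokens whose offset ranges intersect the
#' half-open span `[start, end)`.
#'
#' @param tokens token data.frame with `char_start`, `char_end` columns
#'   (e.g. `tree$tokens`).
#' @param start,end 0-based end-exclusive character offsets.
#' @param lenient if `TRUE`, a span overlapping no token returns `integer(0)`
#'   instead of an error.
#' @return integer vector of token indices.
#' @export
align_span <- function(tokens, start, end, lenient = FALSE) {
  if (!(start >= 0 && start < end)) {
    stop_eatree("require 0 <= start < end", "eatree_alignment_error")
  }
  hit <- which(tokens$char_start < end & tokens$char_end > start)
  if (length(hit) == 0L && !lenient) {
    stop_eatree(sprintf("span [%d,%d) overlaps no token", start, end),
                "eatree_alignment_error")
  }
  hit
}

#' Build an embedding table
#'
#' A fixed word-vector lookup (the role pretrained SciBERT vectors play at
#' corpus scale). Unseen keys fall back to a deterministic hash vector, a
#' pure function of `(key, seed)`.
#'
#' @param dim embedding dimension (the corpus-scale default is 720; tests use
#'   small dimensions).
#' @param vectors named list of numeric vectors of length `dim`.
#' @param seed integer mixed into the fallback hash.
#' @return an object of class `embedding_table`.
#' @export
embedding_table <- function(dim = 720L, vectors = list(), seed = 0L) {
  if (length(vectors)) {
    lens <- vapply(vectors, length, integer(1))
    if (any(lens != dim)) {
      stop_eatree("all embedding vectors must have length `dim`", "eatree_shape_error")
    }
  }
  structure(list(dim = as.integer(dim), vectors = vectors, seed = as.integer(seed)),
            class = "embedding_table")
}

#' Look up embeddings for a vector of keys
#'
#' @param table an [embedding_table()].
#' @param keys character vector.
#' @return numeric matrix, `dim` rows by `length(keys)` columns.
#' @export
embed_tokens <- function(table, keys) {
  out <- matrix(0, nrow = table$dim, ncol = length(keys))
  for (i in seq_along(keys)) {
    v <- table$vectors[[keys[i]]]
    out[, i] <- v %||% hash_vector(keys[i], table$dim, table$seed)
  }
  colnames(out) <- keys
  out
}
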