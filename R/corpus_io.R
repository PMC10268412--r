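## Readers/writers: CoNLL dependencies, the 4-column PAS TSV dialect, and
## BioNLP-style standoff annotations (T/E lines over raw text).

read_lines_of <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) readLines(x, warn = FALSE)
  else unlist(strsplit(paste(x, collapse = "\n"), "\n"), use.names = FALSE)
}

#' Read CoNLL-format dependency parses
#'
#' Accepts the tab-separated CoNLL-X/2007 dialect: columns ID, FORM, LEMMA,
#' CPOSTAG, POSTAG, FEATS, HEAD, DEPREL; columns beyond DEPREL are ignored,
#' so both 8- and 10-column lines are accepted. Blank lines separate
#' sentences; `_` marks a missing value; `# sent_id = <id>` comments are
#' honored, otherwise sentences are numbered `s1`, `s2`, ...
#'
#' @param x a file path or character vector of lines.
#' @return list of [dep_tree()] objects.
#' @export
read_conll <- function(x) {
  lines <- read_lines_of(x)
  trees <- list()
  block <- character(0)
  sid <- NULL
  nsent <- 0L
  flush <- function() {
    if (!length(block)) return(invisible())
    nsent <<- nsent + 1L
    trees[[length(trees) + 1L]] <<- parse_conll_block(block, sid %||% paste0("s", nsent))
    block <<- character(0)
    sid <<- NULL
  }
  for (ln in lines) {
    if (grepl("^\\s*$", ln)) { flush(); next }
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*sent_id\\s*=\\s*(\\S+)", ln))[[1]]
      if (length(m) == 2L) sid <- m[2]
      next
    }
    block <- c(block, ln)
  }
  flush()
  trees
}

parse_conll_block <- function(block, sid) {
  fields <- strsplit(block, "\t", fixed = TRUE)
  ncols <- vapply(fields, length, integer(1))
  if (any(ncols < 8L)) {
    stop_eatree(sprintf("sentence %s: CoNLL line with fewer than 8 columns", sid),
                "eatree_parse_error")
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  ids <- suppressWarnings(as.integer(get(1)))
  heads <- suppressWarnings(as.integer(get(7)))
  if (anyNA(ids) || anyNA(heads)) {
    bad <- which(is.na(ids) | is.na(heads))[1]
    stop_eatree(sprintf("sentence %s, line %d: non-integer ID or HEAD", sid, bad),
                "eatree_parse_error")
  }
  if (!identical(ids, seq_along(ids))) {
    stop_eatree(sprintf("sentence %s: token IDs are not 1..n", sid), "eatree_parse_error")
  }
  form <- get(2)
  lemma <- get(3); lemma[lemma == "_"] <- form[lemma == "_"]
  pos <- get(4)
  dep_tree(sid, form = form, head = heads, deprel = get(8), lemma = lemma, pos = pos)
}

#' Write dependency trees as CoNLL
#'
#' Inverse of [read_conll()] on the fields it preserves (id, form, lemma,
#' pos, head, deprel).
#'
#' @param trees list of [dep_tree()].
#' @param path optional output file; if `NULL` the lines are returned.
#' @return character vector of lines, invisibly when `path` is given.
#' @export
write_conll <- function(trees, path = NULL) {
  out <- character(0)
  for (tr in trees) {
    out <- c(out, sprintf("# sent_id = %s", tr$sentence_id))
    tk <- tr$tokens
    out <- c(out, sprintf("%d\t%s\t%s\t%s\t%s\t_\t%d\t%s", tk$index, tk$form,
                          tk$lemma, tk$pos, tk$pos, tr$head, tr$deprel), "")
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Read PAS edge lists
#'
#' This package's ingestion dialect for deep-parser predicate-argument
#' output: a TSV with columns `sentence_id`, `predicate_index`,
#' `argument_index`, `role`, one edge per line. Duplicate lines are dropped
#' and neighborhoods symmetrized. Output is invariant to line order.
#'
#' @param x file path or character vector of lines.
#' @param n_tokens optional named integer vector giving each sentence's token
#'   count (for range checking); defaults to the maximum index seen.
#' @return named list of [pas_graph()] objects keyed by sentence id.
#' @export
read_pas <- function(x, n_tokens = NULL) {
  lines <- read_lines_of(x)
  lines <- lines[!grepl("^\\s*($|#)", lines)]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(fields, length, integer(1)) != 4L)) {
    stop_eatree("PAS TSV lines must have exactly 4 tab-separated columns",
                "eatree_parse_error")
  }
  df <- data.frame(
    sentence_id = vapply(fields, `[[`, character(1), 1),
    pred = suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2))),
    arg = suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3))),
    role = vapply(fields, `[[`, character(1), 4),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$pred) || anyNA(df$arg)) {
    stop_eatree("non-integer PAS index", "eatree_parse_error")
  }
  out <- list()
  for (sid in sort(unique(df$sentence_id))) {
    sub <- df[df$sentence_id == sid, c("pred", "arg", "role")]
    nt <- if (!is.null(n_tokens) && !is.na(n_tokens[sid])) n_tokens[[sid]]
          else max(sub$pred, sub$arg)
    out[[sid]] <- pas_graph(sid, sub, nt)
  }
  out
}

#' Write PAS graphs as TSV
#'
#' @param graphs list of [pas_graph()].
#' @param path optional output file.
#' @return character vector of lines, invisibly when `path` is given.
#' @export
write_pas <- function(graphs, path = NULL) {
  out <- character(0)
  for (g in graphs) {
    if (nrow(g$edges)) {
      out <- c(out, sprintf("%s\t%d\t%d\t%s", g$sentence_id, g$edges$pred,
                            g$edges$arg, g$edges$role))
    }
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Read BioNLP-style standoff annotations
#'
#' T-lines (`T<id>\\t<Type> <start> <end>\\t<surface>`) whose type is in
#' `labels` become trigger annotations; other T-lines (e.g. `Protein`) are
#' routed to the entity list. E-lines are parsed and kept as metadata only;
#' an E-line referencing an undefined T id is an error.
#'
#' @param text document text (a string) or path to a `.txt` file.
#' @param ann annotation lines or path to a `.ann`/`.a1`/`.a2` file.
#' @param labels a [label_set()].
#' @param strict if `TRUE`, a surface/offset mismatch is an error; otherwise
#'   a warning.
#' @return list with elements `text`, `triggers`, `entities` (data.frames)
#'   and `events` (character vector of raw E-lines).
#' @export
read_standoff <- function(text, ann, labels, strict = TRUE) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  lines <- read_lines_of(ann)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(annotation_id = character(0), label = character(0),
                      char_start = integer(0), char_end = integer(0),
                      stringsAsFactors = FALSE)
  triggers <- empty; entities <- empty; events <- character(0)
  t_ids <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "T")) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L) stop_eatree(sprintf("malformed T-line: %s", ln),
                                          "eatree_parse_error")
      mid <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      if (length(mid) != 3L) stop_eatree(sprintf("malformed T-line span: %s", ln),
                                         "eatree_parse_error")
      type <- mid[1]
      s <- as.integer(mid[2]); e <- as.integer(mid[3])
      surface <- if (length(parts) >= 3L) parts[3] else NA_character_
      if (!is.na(surface)) {
        actual <- substr(text, s + 1L, e)
        if (actual != surface) {
          msg <- sprintf("%s: surface %s does not match text at [%d,%d) (%s)",
                         parts[1], dQuote(surface), s, e, dQuote(actual))
          if (strict) stop_eatree(msg, "eatree_alignment_error") else warning(msg)
        }
      }
      row <- data.frame(annotation_id = parts[1], label = type,
                        char_start = s, char_end = e, stringsAsFactors = FALSE)
      t_ids <- c(t_ids, parts[1])
      if (type %in% labels) triggers <- rbind(triggers, row)
      else entities <- rbind(entities, row)
    } else if (startsWith(ln, "E")) {
      events <- c(events, ln)
      refs <- regmatches(ln, gregexpr("T\\d+", ln))[[1]]
      ## validated after all T-lines are seen
      attr(events, "refs") <- c(attr(events, "refs"), refs)
    }
  }
  bad <- setdiff(attr(events, "refs") %||% character(0), t_ids)
  if (length(bad)) {
    stop_eatree(sprintf("E-line references undefined annotation(s): %s",
                        paste(bad, collapse = ", ")), "eatree_reference_error")
  }
  attr(events, "refs") <- NULL
  list(text = text, triggers = triggers, entities = entities, events = events)
}

#' Write trigger predictions as standoff T-lines
#'
#' Sequentially numbered; identical (label, start, end) triples are
#' deduplicated with a warning. `read_standoff(write_standoff(x))` is the
#' identity on the triples.
#'
#' @param predictions data.frame with columns `label`, `char_start`,
#'   `char_end` (labels must not be `NONE`).
#' @param text document text used to fill the surface column.
#' @param path optional output file.
#' @return character vector of T-lines, invisibly when `path` is given.
#' @export
write_standoff <- function(predictions, text, path = NULL) {
  out <- character(0)
  if (nrow(predictions)) {
    if (any(predictions$label == "NONE")) {
      stop_eatree("cannot write NONE as a trigger annotation", "eatree_label_error")
    }
    key <- paste(predictions$label, predictions$char_start, predictions$char_end)
    if (anyDuplicated(key)) {
      warning("duplicate prediction spans deduplicated")
      predictions <- predictions[!duplicated(key), , drop = FALSE]
    }
    o <- order(predictions$char_start, predictions$char_end)
    predictions <- predictions[o, , drop = FALSE]
    surface <- substr(rep(text, nrow(predictions)),
                      predictions$char_start + 1L, predictions$char_end)
    out <- sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(predictions)),
                   predictions$label, predictions$char_start,
                   predictions$char_end, surface)
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Assemble a corpus document
#'
#' @param doc_id document identifier.
#' @param text raw document text.
#' @param trees list of [dep_tree()] whose token offsets index into `text`.
#' @param pas named list of [pas_graph()] keyed by sentence id (may omit
#'   sentences).
#' @param triggers,entities annotation data.frames as from [read_standoff()].
#' @return an object of class `trigger_document`.
#' @export
trigger_document <- function(doc_id, text, trees, pas = list(),
                             triggers = NULL, entities = NULL) {
  empty <- data.frame(annotation_id = character(0), label = character(0),
                      char_start = integer(0), char_end = integer(0),
                      stringsAsFactors = FALSE)
  structure(list(doc_id = doc_id, text = text, trees = trees, pas = pas,
                 triggers = triggers %||% empty, entities = entities %||% empty),
            class = "trigger_document")
}

#' Per-token gold labels for one document
#'
#' Projects the document's trigger annotations onto tokens: every token a
#' multi-token annotation covers receives the annotation's label (prediction
#' spans are later recovered by merging adjacent same-label tokens).
#'
#' @param doc a [trigger_document()].
#' @param labels a [label_set()].
#' @return list (one per sentence) of integer vectors indexing into `labels`
#'   (1 = NONE).
#' @export
token_labels <- function(doc, labels) {
  out <- lapply(doc$trees, function(tr) rep(1L, n_tokens(tr)))
  if (nrow(doc$triggers) == 0L) return(out)
  for (r in seq_len(nrow(doc$triggers))) {
    lab <- match(doc$triggers$label[r], labels)
    if (is.na(lab)) {
      stop_eatree(sprintf("annotation label %s not in label set", doc$triggers$label[r]),
                  "eatree_label_error")
    }
    for (si in seq_along(doc$trees)) {
      idx <- align_span(doc$trees[[si]]$tokens, doc$triggers$char_start[r],
                        doc$triggers$char_end[r], lenient = TRUE)
      if (length(idx)) out[[si]][idx] <- lab
    }
  }
  out
}

#' Write a corpus to a directory
#'
#' One `<doc_id>.txt` / `.conll` / `.pas` / `.ann` quadruple per document
#' (entities and triggers share the `.ann` file).
#'
#' @param corpus list of [trigger_document()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in corpus) {
    base <- file.path(dir, doc$doc_id)
    writeLines(doc$text, paste0(base, ".txt"))
    write_conll(doc$trees, paste0(base, ".conll"))
    write_pas(doc$pas, paste0(base, ".pas"))
    ann <- rbind(doc$entities, doc$triggers)
    lines <- character(0)
    if (nrow(ann)) {
      surface <- substr(rep(doc$text, nrow(ann)), ann$char_start + 1L, ann$char_end)
      lines <- sprintf("%s\t%s %d %d\t%s", ann$annotation_id, ann$label,
                       ann$char_start, ann$char_end, surface)
    }
    writeLines(lines, paste0(base, ".ann"))
  }
  invisible(dir)
}

#' Read a corpus directory written by [write_corpus()]
#'
#' @param dir directory containing `.txt`/`.conll`/`.pas`/`.ann` quadruples.
#' @param labels a [label_set()] used to split T-lines into triggers and
#'   entities.
#' @param strict passed to [read_standoff()].
#' @return list of [trigger_document()].
#' @export
read_corpus <- function(dir, labels, strict = TRUE) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(tp) {
    base <- sub("\\.txt$", "", tp)
    trees <- read_conll(paste0(base, ".conll"))
    nt <- vapply(trees, n_tokens, integer(1))
    names(nt) <- vapply(trees, function(t) t$sentence_id, character(1))
    pas <- if (file.exists(paste0(base, ".pas"))) read_pas(paste0(base, ".pas"), nt)
           else list()
    ## sentences with no PAS edges still get an (edgeless) graph
    for (sid in names(nt)) {
      if (is.null(pas[[sid]])) pas[[sid]] <- pas_graph(sid, NULL, nt[[sid]])
    }
    so <- read_standoff(tp, if (file.exists(paste0(base, ".ann")))
                              paste0(base, ".ann") else character(0),
                        labels, strict = strict)
    trigger_document(basename(base), so$text, trees, pas[names(nt)],
                     triggers = so$triggers, entities = so$entities)
  })
}
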