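## JSON (de)serialization of trained models — text-only, so models survive
## being shipped alongside plain-text corpora.

#' Save a model as JSON
#'
#' @param model a [trigger_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  ser <- list(
    d_x = model$d_x, d_h = model$d_h, labels = as.character(model$labels),
    ablation = unclass(model$ablation), K = model$K, slope = model$slope,
    rho_gate = model$rho_gate,
    flat = as.numeric(flatten_params(model$params))
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON file.
#' @return a [trigger_model()].
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- trigger_model(ser$d_x, ser$d_h, label_set(setdiff(ser$labels, "NONE")),
                         ablation = do.call(ablation_config, as.list(ser$ablation)),
                         K = ser$K, slope = ser$slope, rho_gate = ser$rho_gate)
  model$params <- unflatten_params(ser$flat, model$params)
  model
}

#' Write an embedding table as TSV
#'
#' One line per word: the key followed by its components, tab-separated.
#'
#' @param table an [embedding_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(table, path) {
  lines <- vapply(names(table$vectors), function(w) {
    paste(c(w, format(table$vectors[[w]], digits = 17, scientific = TRUE,
                      trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(sprintf("#dim\t%d\t%d", table$dim, table$seed), lines), path)
  invisible(path)
}

#' Read an embedding table written by [write_embeddings()]
#'
#' @param path TSV file.
#' @return an [embedding_table()].
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  d <- as.integer(hdr[2]); seed <- as.integer(hdr[3])
  vecs <- list()
  for (ln in lines[-1]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    vecs[[parts[1]]] <- as.numeric(parts[-1])
  }
  embedding_table(d, vecs, seed = seed)
}
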