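# Shared TSV helpers. All knowledge-base and pipeline artifacts are plain
# tab-separated text with a header row so every stage is independently
# inspectable.

read_tsv <- function(path, ...) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv <- function(x, path, row_names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

# Matrix writers keep genes in rows, samples in columns, with a leading
# gene_id column so round-trips preserve dimnames.
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

match_arg1 <- function(value, choices, field) {
  if (length(value) != 1L || !value %in% choices) {
    stop(sprintf("field '%s' must be one of: %s (got '%s')", field,
                 paste(choices, collapse = ", "),
                 paste(value, collapse = ",")), call. = FALSE)
  }
  value
}
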