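# Minimal OBO reader: enough of the format (Term stanzas with id, name,
# is_a, obsolete flags) to resolve process names for the regulation
# deriver. Regulation triples are primarily supplied as explicit TSV; this
# deriver is a convenience for users starting from a GO release.

#' Read a GO OBO file (terms only)
#'
#' Parses `[Term]` stanzas and returns term identifiers, names, parent
#' (`is_a`) links and obsolete flags. Everything else in the file is
#' ignored.
#'
#' @param path Path to an OBO file.
#' @return A list with `terms` (data frame: `id`, `name`, `obsolete`) and
#'   `is_a` (named list of parent term ids).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (!length(starts)) {
    stop("malformed OBO: no [Term] stanza found in ", path, call. = FALSE)
  }
  stanza_of <- findInterval(seq_along(lines), starts)
  ids <- character(length(starts)); nms <- character(length(starts))
  obs <- logical(length(starts)); is_a <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[stanza_of == i]
    # stanza ends at the next header of any kind
    hdr <- grep("^\\[", block)
    if (length(hdr) > 1L) block <- block[seq_len(hdr[2] - 1L)]
    get <- function(key) sub(paste0("^", key, ": *"), "",
                             grep(paste0("^", key, ":"), block, value = TRUE))
    id <- get("id"); nm <- get("name")
    if (length(id) != 1L) {
      stop("malformed OBO: [Term] stanza ", i, " has ", length(id),
           " id lines", call. = FALSE)
    }
    ids[i] <- id
    nms[i] <- if (length(nm)) nm[1] else NA_character_
    obs[i] <- any(grepl("^is_obsolete: *true", block))
    parents <- get("is_a")
    is_a[[i]] <- sub(" *!.*$", "", parents)
  }
  names(is_a) <- ids
  list(terms = data.frame(id = ids, name = nms, obsolete = obs,
                          stringsAsFactors = FALSE),
       is_a = is_a)
}

#' Derive regulation triples from GO annotations
#'
#' A gene annotated to a term named `"positive regulation of X"` is taken
#' to positively regulate the process named exactly `X` (and symmetrically
#' for negative regulation); the regulated process id is resolved by exact
#' name match within the OBO. Annotations to non-regulation terms emit no
#' triple — direct triples for those are supplied via TSV instead.
#'
#' @param obo Object returned by [read_obo()].
#' @param annotations Data frame with columns `gene_id`, `term_id` mapping
#'   genes to GO term accessions.
#' @return Regulation data frame (`gene_id`, `process_id`, `process_name`,
#'   `direction`), deduplicated, with attribute `n_skipped` counting
#'   regulation-style annotations whose regulated term name could not be
#'   resolved.
#' @export
derive_regulations_from_obo <- function(obo, annotations) {
  stopifnot(is.list(obo), !is.null(obo$terms))
  for (col in c("gene_id", "term_id")) {
    if (!col %in% names(annotations)) {
      stop("annotation table lacks column '", col, "'", call. = FALSE)
    }
  }
  terms <- obo$terms[!obo$terms$obsolete, , drop = FALSE]
  name_of <- stats::setNames(terms$name, terms$id)
  id_of <- stats::setNames(terms$id, terms$name)

  ann_names <- name_of[annotations$term_id]
  m <- regmatches(ann_names,
                  regexec("^(positive|negative) regulation of (.+)$", ann_names))
  out <- list(); skipped <- 0L
  for (i in seq_along(m)) {
    parts <- m[[i]]
    if (length(parts) != 3L) next   # not a regulation term (or unknown id)
    target_id <- id_of[parts[3]]
    if (is.na(target_id)) { skipped <- skipped + 1L; next }
    out[[length(out) + 1L]] <- data.frame(
      gene_id = annotations$gene_id[i], process_id = unname(target_id),
      process_name = parts[3], direction = parts[2],
      stringsAsFactors = FALSE)
  }
  reg <- if (length(out)) unique(do.call(rbind, out)) else empty_regulations()
  rownames(reg) <- NULL
  attr(reg, "n_skipped") <- skipped
  reg
}
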