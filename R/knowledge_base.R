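#' Construct a study (a ranked gene list)
#'
#' A study is the atom of the knowledge base: one ranked list of genes
#' produced by a single statistical analysis of one molecular data type
#' (in-house) or by one curated literature source. Rank 1 is always the
#' strongest evidence. Tied or gapped input ranks are resolved to a dense
#' permutation 1..N by average input rank, ties broken by gene identifier,
#' so that downstream normalized scores are well defined.
#'
#' @param study_id Study identifier.
#' @param gene_ids Character vector of gene identifiers (opaque strings; no
#'   symbol mapping is performed).
#' @param ranks Integer-ish vector of input ranks, parallel to `gene_ids`.
#'   Ties and gaps are allowed and resolved; `NA` is not.
#' @param source `"in_house"` (analysis of raw data) or `"curated"`
#'   (literature-derived).
#' @param data_type Free-text label for the measured quantity, e.g.
#'   `"expression fold-change"` or `"CNA gain frequency"`.
#' @param direction_tag Interpretation of high rank: `"activating"`,
#'   `"inactivating"`, `"survival"` or `"other"`.
#' @param reverse Set `TRUE` for sources that count rank N as the strongest
#'   evidence; ranks are flipped to the internal convention at load.
#' @param empty Internal flag marking a study whose inclusion criteria left
#'   no genes.
#' @return An object of class `kb_study` with elements `study_id`, `source`,
#'   `data_type`, `direction_tag`, `ranks` (named integer vector, a
#'   permutation of 1..N) and `N`.
#' @examples
#' s <- study("s1", c("TP53", "ERBB2", "FGFR3"), c(2, 1, 3))
#' s$ranks
#' @export
study <- function(study_id, gene_ids, ranks,
                  source = c("curated", "in_house"),
                  data_type = "unspecified",
                  direction_tag = c("other", "activating", "inactivating", "survival"),
                  reverse = FALSE, empty = FALSE) {
  source <- match.arg(source)
  direction_tag <- match.arg(direction_tag)
  stopifnot(is.character(study_id), length(study_id) == 1L)
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != length(ranks)) {
    stop("gene_ids and ranks must have equal length", call. = FALSE)
  }
  if (anyNA(ranks) || (length(ranks) && !is.numeric(ranks))) {
    stop("ranks must be numeric and non-missing in study '", study_id, "'",
         call. = FALSE)
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop("gene(s) ", paste(dup, collapse = ", "),
         " appear more than once in study '", study_id, "'", call. = FALSE)
  }
  n <- length(gene_ids)
  if (n == 0L && !empty) {
    stop("study '", study_id, "' has no genes; use empty = TRUE for an ",
         "intentionally empty study", call. = FALSE)
  }
  if (reverse) ranks <- max(ranks) - ranks + 1
  # dense unique ranks: order by input rank (average-rank semantics for
  # ties come free from a stable order), then lexicographic gene id
  dense <- integer(n)
  dense[order(ranks, gene_ids)] <- seq_len(n)
  names(dense) <- gene_ids
  dense <- sort(dense)
  structure(list(study_id = study_id, source = source, data_type = data_type,
                 direction_tag = direction_tag, ranks = dense, N = n,
                 empty = empty || n == 0L),
            class = "kb_study")
}

#' @export
print.kb_study <- function(x, ...) {
  cat(sprintf("<study '%s'> %s / %s / %s, %d ranked gene(s)\n",
              x$study_id, x$source, x$data_type, x$direction_tag, x$N))
  invisible(x)
}

#' Assemble a knowledge base
#'
#' The knowledge base is gene-centric: it stores per-study gene ranks,
#' named study sets, gene-to-GO-process regulation triples with direction,
#' and drug/gene-target pairs. All cross-references are validated at
#' construction.
#'
#' @param studies List of [study()] objects.
#' @param study_sets Named list; each element a character vector of study
#'   identifiers. Conventional set names are `"activating"`,
#'   `"inactivating"` and `"survival"`.
#' @param regulations Data frame with columns `gene_id`, `process_id`,
#'   `process_name`, `direction` (`"positive"`/`"negative"`). Triples must
#'   be unique.
#' @param drug_targets Data frame with columns `drug_id`, `drug_name`,
#'   `gene_id`, `action` (`"inhibitor"`, `"activator"`, `"unknown"`),
#'   `source_db`. (drug, gene) pairs must be unique; a missing/empty
#'   `action` defaults to `"unknown"`.
#' @return An object of class `knowledge_base` with the validated
#'   components plus `gene_universe`, the union of all per-study gene sets.
#' @export
knowledge_base <- function(studies, study_sets = list(),
                           regulations = empty_regulations(),
                           drug_targets = empty_drug_targets()) {
  if (!length(studies)) stop("at least one study is required", call. = FALSE)
  if (!all(vapply(studies, inherits, logical(1), "kb_study"))) {
    stop("studies must be a list of objects created by study()", call. = FALSE)
  }
  ids <- vapply(studies, `[[`, character(1), "study_id")
  if (anyDuplicated(ids)) {
    stop("duplicate study_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(studies) <- ids

  study_sets <- lapply(study_sets, as.character)
  for (set in names(study_sets)) {
    members <- study_sets[[set]]
    if (!length(members)) {
      stop("study set '", set, "' is empty", call. = FALSE)
    }
    if (anyDuplicated(members)) {
      stop("study set '", set, "' lists a study twice", call. = FALSE)
    }
    missing <- setdiff(members, ids)
    if (length(missing)) {
      stop("study set '", set, "' references unknown study id(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  regulations <- validate_regulations(regulations)
  drug_targets <- validate_drug_targets(drug_targets)

  universe <- sort(unique(unlist(lapply(studies, function(s) names(s$ranks)),
                                 use.names = FALSE)))
  structure(list(studies = studies, study_sets = study_sets,
                 regulations = regulations, drug_targets = drug_targets,
                 gene_universe = universe),
            class = "knowledge_base")
}

empty_regulations <- function() {
  data.frame(gene_id = character(), process_id = character(),
             process_name = character(), direction = character(),
             stringsAsFactors = FALSE)
}

empty_drug_targets <- function() {
  data.frame(drug_id = character(), drug_name = character(),
             gene_id = character(), action = character(),
             source_db = character(), stringsAsFactors = FALSE)
}

validate_regulations <- function(reg) {
  req <- c("gene_id", "process_id", "direction")
  missing <- setdiff(req, names(reg))
  if (length(missing)) {
    stop("regulation table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(reg$process_name)) reg$process_name <- reg$process_id
  reg <- reg[, c("gene_id", "process_id", "process_name", "direction")]
  bad <- !reg$direction %in% c("positive", "negative")
  if (any(bad)) {
    stop("regulation direction must be 'positive' or 'negative'; offending row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  key <- paste(reg$gene_id, reg$process_id, reg$direction)
  if (anyDuplicated(key)) {
    stop("duplicate (gene, process, direction) regulation triple(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  reg[order(reg$process_id, reg$gene_id, reg$direction), , drop = FALSE]
}

validate_drug_targets <- function(dt) {
  req <- c("drug_id", "gene_id")
  missing <- setdiff(req, names(dt))
  if (length(missing)) {
    stop("drug-target table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(dt$drug_name)) dt$drug_name <- dt$drug_id
  if (is.null(dt$source_db)) dt$source_db <- NA_character_
  if (is.null(dt$action)) dt$action <- "unknown"
  dt$action[is.na(dt$action) | dt$action == ""] <- "unknown"
  dt <- dt[, c("drug_id", "drug_name", "gene_id", "action", "source_db")]
  bad <- !dt$action %in% c("inhibitor", "activator", "unknown")
  if (any(bad)) {
    stop("drug action must be inhibitor/activator/unknown; offending row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  key <- paste(dt$drug_id, dt$gene_id)
  if (anyDuplicated(key)) {
    stop("duplicate (drug, gene) target pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  dt[order(dt$drug_id, dt$gene_id), , drop = FALSE]
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf(paste0("<knowledge_base> %d studies, %d study set(s), ",
                     "%d regulation triple(s), %d drug-target pair(s), ",
                     "%d gene(s) in universe\n"),
              length(x$studies), length(x$study_sets), nrow(x$regulations),
              nrow(x$drug_targets), length(x$gene_universe)))
  for (set in names(x$study_sets)) {
    cat(sprintf("  set '%s': %s\n", set,
                paste(x$study_sets[[set]], collapse = ", ")))
  }
  invisible(x)
}

#' Load a knowledge base from TSV files
#'
#' Reads the flat-file dialect of the knowledge base. Study tables carry
#' either pre-assigned ranks (columns `study_id`, `gene_id`, `rank`) or raw
#' per-gene statistics (`study_id`, `gene_id`, `p_value`, `effect`), in
#' which case each study is built with [build_study_from_stats()] using
#' `q_threshold`. Optional per-study metadata columns `source`, `data_type`,
#' `direction_tag` and `reverse` are honoured when present (constant within
#' a study).
#'
#' @param studies Character vector of study TSV paths, or a directory whose
#'   `*.tsv` files are all read.
#' @param study_sets Path to a TSV with columns `set_id`, `study_id`
#'   (optional).
#' @param regulations Path to a regulation TSV (`gene_id`, `process_id`,
#'   `process_name`, `direction`) (optional).
#' @param drugs Path to a drug-target TSV (`drug_id`, `drug_name`,
#'   `gene_id`, `action`, `source_db`) (optional; an empty table yields a
#'   valid knowledge base with zero drugs).
#' @param q_threshold BY-adjusted q-value cut-off used when a study table
#'   supplies raw statistics instead of ranks.
#' @return A [knowledge_base()] object.
#' @seealso [write_knowledge_base()] for the inverse operation.
#' @export
load_knowledge_base <- function(studies, study_sets = NULL,
                                regulations = NULL, drugs = NULL,
                                q_threshold = 0.001) {
  if (length(studies) == 1L && dir.exists(studies)) {
    studies <- sort(list.files(studies, pattern = "\\.tsv$", full.names = TRUE))
    if (!length(studies)) stop("no .tsv study files found", call. = FALSE)
  }
  study_objs <- list()
  for (path in studies) {
    tab <- read_tsv(path)
    if (!all(c("study_id", "gene_id") %in% names(tab))) {
      stop("study file ", path, " lacks study_id/gene_id columns", call. = FALSE)
    }
    for (sid in unique(tab$study_id)) {
      rows <- tab[tab$study_id == sid, , drop = FALSE]
      meta <- list(
        source = if ("source" %in% names(rows)) rows$source[1] else "curated",
        data_type = if ("data_type" %in% names(rows)) rows$data_type[1] else "unspecified",
        direction_tag = if ("direction_tag" %in% names(rows)) rows$direction_tag[1] else "other",
        reverse = if ("reverse" %in% names(rows)) isTRUE(as.logical(rows$reverse[1])) else FALSE
      )
      if ("rank" %in% names(rows)) {
        s <- study(sid, rows$gene_id, rows$rank, source = meta$source,
                   data_type = meta$data_type,
                   direction_tag = meta$direction_tag, reverse = meta$reverse)
      } else if (all(c("p_value", "effect") %in% names(rows))) {
        s <- build_study_from_stats(rows, study_id = sid,
                                    q_threshold = q_threshold,
                                    source = meta$source,
                                    data_type = meta$data_type,
                                    direction_tag = meta$direction_tag)
      } else {
        stop("study file ", path, " needs either a 'rank' column or ",
             "'p_value' + 'effect' columns", call. = FALSE)
      }
      if (s$study_id %in% names(study_objs)) {
        stop("study '", s$study_id, "' defined in more than one file",
             call. = FALSE)
      }
      study_objs[[s$study_id]] <- s
    }
  }

  sets <- list()
  if (!is.null(study_sets)) {
    st <- read_tsv(study_sets)
    if (!all(c("set_id", "study_id") %in% names(st))) {
      stop("study-set file needs set_id and study_id columns", call. = FALSE)
    }
    sets <- split(st$study_id, st$set_id)
  }
  reg <- if (is.null(regulations)) empty_regulations() else read_tsv(regulations)
  dt <- if (is.null(drugs)) empty_drug_targets() else {
    d <- read_tsv(drugs)
    if (nrow(d) == 0L) empty_drug_targets() else d
  }
  knowledge_base(study_objs, sets, reg, dt)
}

#' Write a knowledge base to TSV files
#'
#' Emits `studies.tsv` (long form, one row per gene rank, with per-study
#' metadata columns), `study_sets.tsv`, `regulations.tsv` and
#' `drug_targets.tsv` into `dir`. [load_knowledge_base()] on the result
#' reproduces the same knowledge base (order-insensitive equality).
#'
#' @param kb A [knowledge_base()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_knowledge_base <- function(kb, dir) {
  stopifnot(inherits(kb, "knowledge_base"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(kb$studies, function(s) {
    data.frame(study_id = s$study_id, gene_id = names(s$ranks),
               rank = unname(s$ranks), source = s$source,
               data_type = s$data_type, direction_tag = s$direction_tag,
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), file.path(dir, "studies.tsv"))
  sets <- data.frame(
    set_id = rep(names(kb$study_sets), lengths(kb$study_sets)),
    study_id = unlist(kb$study_sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv(sets, file.path(dir, "study_sets.tsv"))
  write_tsv(kb$regulations, file.path(dir, "regulations.tsv"))
  write_tsv(kb$drug_targets, file.path(dir, "drug_targets.tsv"))
  invisible(dir)
}

#' Read back a knowledge base written by [write_knowledge_base()]
#'
#' @param dir Directory produced by [write_knowledge_base()].
#' @return A [knowledge_base()] object.
#' @export
read_knowledge_base <- function(dir) {
  sets_path <- file.path(dir, "study_sets.tsv")
  sets <- if (file.exists(sets_path) && nrow(read_tsv(sets_path)) > 0) sets_path else NULL
  load_knowledge_base(file.path(dir, "studies.tsv"),
                      study_sets = sets,
                      regulations = file.path(dir, "regulations.tsv"),
                      drugs = file.path(dir, "drug_targets.tsv"))
}

#' Build a study from per-gene test statistics
#'
#' Implements the inclusion rule used for in-house expression studies:
#' raw p-values are adjusted with the Benjamini-Yekutieli procedure (valid
#' under arbitrary dependence), genes with adjusted q at or below
#' `q_threshold` are retained, and survivors are ranked by descending
#' absolute effect size (rank 1 = largest). Ties are broken by ascending
#' raw p-value, then by gene identifier.
#'
#' @param table Data frame with one row per gene; needs `gene_id`, a raw
#'   p-value column and an effect-size column.
#' @param study_id Identifier for the resulting study.
#' @param q_threshold Maximum BY-adjusted q for inclusion (default 0.001,
#'   the differential-expression criterion used to populate the
#'   knowledge base).
#' @param effect_column,p_column Column names holding the effect statistic
#'   and the raw p-value.
#' @inheritParams study
#' @return A [study()] object; when no gene survives the threshold an
#'   empty-flagged study is returned with a warning.
#' @examples
#' tab <- data.frame(gene_id = c("a", "b", "c"),
#'                   p_value = c(1e-5, 2e-4, 0.5),
#'                   effect  = c(2, -4, 8))
#' build_study_from_stats(tab, "de_study", q_threshold = 0.05)$ranks
#' @export
build_study_from_stats <- function(table, study_id,
                                   q_threshold = 0.001,
                                   effect_column = "effect",
                                   p_column = "p_value",
                                   source = "in_house",
                                   data_type = "expression fold-change",
                                   direction_tag = "other") {
  for (col in c("gene_id", p_column, effect_column)) {
    if (!col %in% names(table)) {
      stop("statistics table lacks column '", col, "'", call. = FALSE)
    }
  }
  p <- table[[p_column]]
  eff <- table[[effect_column]]
  if (!is.numeric(p) || anyNA(p)) {
    stop("p-value column '", p_column, "' must be numeric and non-missing",
         call. = FALSE)
  }
  if (!is.numeric(eff)) {
    stop("effect column '", effect_column, "' must be numeric", call. = FALSE)
  }
  q <- stats::p.adjust(p, method = "BY")
  keep <- q <= q_threshold
  if (!any(keep)) {
    warning("no gene passes q <= ", q_threshold, " in study '", study_id,
            "'; returning an empty study", call. = FALSE)
    return(study(study_id, character(), integer(), source = source,
                 data_type = data_type, direction_tag = direction_tag,
                 empty = TRUE))
  }
  g <- as.character(table$gene_id)[keep]
  eff <- eff[keep]
  p <- p[keep]
  ord <- order(-abs(eff), p, g)
  ranks <- integer(length(g))
  ranks[ord] <- seq_along(g)
  study(study_id, g, ranks, source = source, data_type = data_type,
        direction_tag = direction_tag)
}
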