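#' Harmonic mean of p-values
#'
#' `H = n / sum(1/p)`. Always between the minimum and maximum of `p`, with
#' equality iff all values agree; crucially, it is independent of `n` when
#' all p-values are equal, which is what de-biases genes that regulate
#' many (highly connected) processes.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return The harmonic mean.
#' @export
harmonic_mean_p <- function(p) {
  if (!length(p)) stop("empty p-value vector", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  length(p) / sum(1 / p)
}

#' Recalibrate one gene through its GO processes
#'
#' Replaces a gene's K-rank with the harmonic mean of the permutation
#' p-values of the processes it regulates, excluding ambiguous processes —
#' those the gene is annotated to regulate in both directions. The
#' reported score is `-log10(H)` so that larger means more
#' cancer-essential.
#'
#' @param gene Gene identifier.
#' @param regulations Regulation table (as in a [knowledge_base()]).
#' @param go_results Process scores from [score_all_processes()].
#' @return One-row data frame (`gene_id`, `harmonic_mean_p`, `score`,
#'   `n_processes_used`, `n_processes_ambiguous`), or `NULL` when no
#'   unambiguously regulated process carries a p-value (the gene is
#'   unscorable).
#' @examples
#' reg <- data.frame(gene_id = "g", process_id = c("GO:1", "GO:2"),
#'                   process_name = c("GO:1", "GO:2"),
#'                   direction = c("positive", "negative"))
#' go <- data.frame(process_id = c("GO:1", "GO:2"), p_value = c(0.1, 0.001))
#' recalibrate_gene("g", reg, go)   # H = 2 / (1/0.1 + 1/0.001)
#' @export
recalibrate_gene <- function(gene, regulations, go_results) {
  mine <- regulations[regulations$gene_id == gene, , drop = FALSE]
  if (!nrow(mine)) return(NULL)
  dirs <- split(mine$direction, mine$process_id)
  ambiguous <- names(dirs)[vapply(dirs, function(d)
    all(c("positive", "negative") %in% d), logical(1))]
  usable <- setdiff(names(dirs), ambiguous)
  pv <- go_results$p_value[match(usable, go_results$process_id)]
  keep <- !is.na(pv)
  if (!any(keep)) return(NULL)
  H <- harmonic_mean_p(pv[keep])
  data.frame(gene_id = gene, harmonic_mean_p = H, score = -log10(H),
             n_processes_used = sum(keep),
             n_processes_ambiguous = length(ambiguous),
             stringsAsFactors = FALSE)
}

#' Recalibrate all genes
#'
#' Applies [recalibrate_gene()] to every gene appearing in the regulation
#' table.
#'
#' @param kb A [knowledge_base()].
#' @param go_results Process scores from [score_all_processes()].
#' @return Data frame of recalibrated ranks, ordered by decreasing score;
#'   attribute `unscorable` lists genes that regulate processes but could
#'   not be scored.
#' @export
recalibrate_genes <- function(kb, go_results) {
  stopifnot(inherits(kb, "knowledge_base"))
  genes <- sort(unique(kb$regulations$gene_id))
  rows <- lapply(genes, recalibrate_gene,
                 regulations = kb$regulations, go_results = go_results)
  ok <- !vapply(rows, is.null, logical(1))
  out <- if (any(ok)) do.call(rbind, rows[ok]) else {
    data.frame(gene_id = character(), harmonic_mean_p = numeric(),
               score = numeric(), n_processes_used = integer(),
               n_processes_ambiguous = integer(), stringsAsFactors = FALSE)
  }
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unscorable") <- genes[!ok]
  out
}

default_mode_map <- function() {
  c(inhibitor = "active", activator = "inactive", unknown = "active")
}

#' Prioritize drugs in a query cohort
#'
#' Ranks every drug with at least one altered, recalibrated target in the
#' activity matrix. For a drug `d`, the eligible altered-target set `A_d`
#' contains its targets that (i) have a recalibrated score, (ii) are
#' altered in the activity matrix, and (iii) hold the status the drug's
#' mode of action requires (`active` for inhibitors — the default when the
#' action is unknown — `inactive` for activators) in at least one sample.
#' The priority score is
#' `D_d = sum over g in A_d of score_g * f_g / n_targets(d)`,
#' where `f_g` is the fraction of samples with the required status and
#' `n_targets(d)` the drug's total number of known targets. Dividing by
#' all known targets penalizes diffuse polypharmacology; `score_g` carries
#' knowledge-base relevance; `f_g` carries measured activity in the
#' cohort. Drugs with `A_d` empty are omitted.
#'
#' @param kb A [knowledge_base()] supplying drug-target pairs.
#' @param recal Recalibrated gene table from [recalibrate_genes()].
#' @param am Activity matrix from [build_activity_matrix()].
#' @param mode_map Named map from drug action to required target status.
#' @param drug_score `"per_total_targets"` (default: divide by all known
#'   targets) or `"per_altered_targets"` (divide by `|A_d|`).
#' @return Data frame of class `drug_scores`, ordered by decreasing score
#'   (ties: more altered targets, then drug id), with columns `drug_id`,
#'   `drug_name`, `score`, `n_targets`, `n_altered_targets`,
#'   `n_sensitive_samples`; attributes `sensitive` (named list of sample
#'   sets) and `per_target` (named list of per-target detail frames).
#' @export
prioritize_drugs <- function(kb, recal, am,
                             mode_map = default_mode_map(),
                             drug_score = c("per_total_targets",
                                            "per_altered_targets")) {
  stopifnot(inherits(kb, "knowledge_base"), inherits(am, "activity_matrix"))
  drug_score <- match.arg(drug_score)
  dt <- kb$drug_targets
  empty <- data.frame(drug_id = character(), drug_name = character(),
                      score = numeric(), n_targets = integer(),
                      n_altered_targets = integer(),
                      n_sensitive_samples = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("drug_scores", "data.frame")
  attr(empty, "sensitive") <- list(); attr(empty, "per_target") <- list()
  if (!nrow(dt)) return(empty)
  if (!length(am$samples) || !length(am$genes)) {
    warning("empty activity matrix; no drug can be scored", call. = FALSE)
    return(empty)
  }
  score_of <- stats::setNames(recal$score, recal$gene_id)
  altered <- rowSums(am$status != "unchanged") > 0

  rows <- list(); sens <- list(); detail <- list()
  for (d in unique(dt$drug_id)) {
    tg <- dt[dt$drug_id == d, , drop = FALSE]
    req <- unname(mode_map[tg$action])
    elig <- tg$gene_id %in% names(score_of) &
      tg$gene_id %in% am$genes & altered[tg$gene_id] %in% TRUE
    f <- numeric(nrow(tg)); f[] <- 0
    for (j in which(elig)) {
      f[j] <- mean(am$status[tg$gene_id[j], ] == req[j])
    }
    in_A <- elig & f > 0
    if (!any(in_A)) next
    denom <- if (drug_score == "per_total_targets") nrow(tg) else sum(in_A)
    D <- sum(score_of[tg$gene_id[in_A]] * f[in_A]) / denom
    s_samples <- sort(unique(unlist(lapply(which(in_A), function(j)
      am$samples[am$status[tg$gene_id[j], ] == req[j]]))))
    rows[[d]] <- data.frame(
      drug_id = d, drug_name = tg$drug_name[1], score = D,
      n_targets = nrow(tg), n_altered_targets = sum(in_A),
      n_sensitive_samples = length(s_samples), stringsAsFactors = FALSE)
    sens[[d]] <- s_samples
    detail[[d]] <- data.frame(
      gene_id = tg$gene_id[in_A],
      gene_score = unname(score_of[tg$gene_id[in_A]]),
      alteration_fraction = f[in_A], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("no drug has an altered, scored target", call. = FALSE)
    return(empty)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$score, -out$n_altered_targets, out$drug_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("drug_scores", "data.frame")
  attr(out, "sensitive") <- sens[out$drug_id]
  attr(out, "per_target") <- detail[out$drug_id]
  out
}

#' @export
print.drug_scores <- function(x, n = 10, ...) {
  cat(sprintf("<drug_scores> %d drug(s) with >=1 altered target\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat("  ... and", nrow(x) - n, "more\n")
  invisible(x)
}

#' Predicted-sensitive samples of a drug
#'
#' A sample is sensitive to a drug when at least one of the drug's altered
#' targets holds the status the drug's mode of action requires (`active`
#' for inhibitors). The set is the union over the drug's altered targets
#' of the samples with the required status.
#'
#' @param drug Drug identifier present in the knowledge base.
#' @param kb A [knowledge_base()].
#' @param am Activity matrix from [build_activity_matrix()].
#' @param mode_map Named map from drug action to required target status.
#' @return Sorted character vector of sample ids.
#' @export
sensitive_samples <- function(drug, kb, am, mode_map = default_mode_map()) {
  stopifnot(inherits(kb, "knowledge_base"), inherits(am, "activity_matrix"))
  tg <- kb$drug_targets[kb$drug_targets$drug_id == drug, , drop = FALSE]
  if (!nrow(tg)) stop("unknown drug '", drug, "'", call. = FALSE)
  req <- unname(mode_map[tg$action])
  hits <- character(0)
  for (j in seq_len(nrow(tg))) {
    g <- tg$gene_id[j]
    if (!g %in% am$genes) next
    if (!any(am$status[g, ] != "unchanged")) next
    hits <- c(hits, am$samples[am$status[g, ] == req[j]])
  }
  sort(unique(hits))
}

#' Categorical stratification report
#'
#' Builds the sample-by-row table behind an oncoprint-style categorical
#' heat map: one row per drug (sensitive / insensitive), one row per
#' requested gene (its activity status) and one row per annotation column.
#' Samples are ordered by sensitivity to the first drug, then by the
#' annotation columns, then by sample id, so repeated calls are stable.
#'
#' @param am Activity matrix.
#' @param sensitive Named list of per-drug sensitive sample sets (e.g.
#'   `attr(prioritize_drugs(...), "sensitive")` or from
#'   [sensitive_samples()]).
#' @param genes Genes whose activity status rows are included.
#' @param annotations Optional data frame of per-sample labels; rownames
#'   (or a `sample_id` column) identify samples.
#' @return Character matrix, rows = drugs + genes + annotations, columns =
#'   samples in display order.
#' @export
render_stratification <- function(am, sensitive = list(),
                                  genes = character(),
                                  annotations = NULL) {
  stopifnot(inherits(am, "activity_matrix"))
  missing_g <- setdiff(genes, am$genes)
  if (length(missing_g)) {
    stop("unknown gene(s): ", paste(missing_g, collapse = ", "), call. = FALSE)
  }
  samples <- am$samples
  ann <- NULL
  if (!is.null(annotations)) {
    ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
    if ("sample_id" %in% names(ann)) {
      rownames(ann) <- ann$sample_id
      ann$sample_id <- NULL
    }
    unknown <- setdiff(samples, rownames(ann))
    if (length(unknown)) {
      stop("annotations missing for sample(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    ann <- ann[samples, , drop = FALSE]
  }
  rows <- list()
  for (d in names(sensitive)) {
    rows[[d]] <- ifelse(samples %in% sensitive[[d]], "sensitive", "insensitive")
  }
  for (g in genes) rows[[g]] <- am$status[g, samples]
  if (!is.null(ann)) for (a in names(ann)) rows[[a]] <- as.character(ann[[a]])
  if (!length(rows)) stop("nothing to render", call. = FALSE)
  m <- do.call(rbind, rows)
  colnames(m) <- samples
  keys <- list()
  if (length(sensitive)) keys$first_drug <- m[1, ] != "sensitive"
  if (!is.null(ann)) for (a in names(ann)) keys[[a]] <- as.character(ann[[a]])
  keys$sample <- samples
  ord <- do.call(order, unname(keys))
  m[, ord, drop = FALSE]
}
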