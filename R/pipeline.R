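#' Validate a pipeline run configuration
#'
#' @param study_set Study set feeding K-rank computation and recalibration
#'   (default `"activating"`; inhibitors act on activated targets).
#' @param B Permutations per process (default 10000).
#' @param seed Integer seed; required whenever `B > 0`.
#' @param krank_denominator `"set_size"` or `"support"`; see
#'   [compute_kranks()].
#' @param drug_score `"per_total_targets"` or `"per_altered_targets"`; see
#'   [prioritize_drugs()].
#' @param discretize Optional list for continuous expression input:
#'   `list(method = "zscore"|"quantile", z_cut =, q =)`.
#' @param paths Named list of input/output locations used by
#'   [run_pipeline()]: `kb` (knowledge-base directory), `query` (query TSV
#'   directory) and `out` (run directory).
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(study_set = "activating", B = 10000, seed = NULL,
                       krank_denominator = "set_size",
                       drug_score = "per_total_targets",
                       discretize = NULL, paths = list()) {
  match_arg1(krank_denominator, c("set_size", "support"), "krank_denominator")
  match_arg1(drug_score, c("per_total_targets", "per_altered_targets"),
             "drug_score")
  if (!is.null(discretize)) {
    match_arg1(discretize$method %||% "zscore", c("zscore", "quantile"),
               "discretize$method")
  }
  if (B > 0 && is.null(seed)) {
    stop("field 'seed' is required when B > 0", call. = FALSE)
  }
  structure(list(study_set = study_set, B = as.integer(B),
                 seed = if (!is.null(seed)) as.integer(seed),
                 krank_denominator = krank_denominator,
                 drug_score = drug_score, discretize = discretize,
                 paths = paths),
            class = "run_config")
}

#' Run the full prioritization pipeline
#'
#' Chains every stage on in-memory objects: K-ranks for the chosen study
#' set, process essentiality scores, the activity matrix, harmonic-mean
#' recalibration and drug prioritization. This is the package's main
#' entry point; [run_pipeline()] is the file-based wrapper around it.
#'
#' @param kb A [knowledge_base()].
#' @param query A [query_dataset()].
#' @param study_set,B,seed,krank_denominator,drug_score See [run_config()].
#' @return An object of class `goprio` holding `kranks`, `go_scores`,
#'   `activity`, `recalibrated`, `drugs` (a `drug_scores` frame with the
#'   per-drug sensitive sample sets in its attributes) and `config`.
#' @examples
#' spec <- fixture_spec(n_genes = 60, n_samples = 20, seed = 42)
#' fit <- goprio(generate_knowledge_base(spec), generate_query_dataset(spec),
#'               B = 200, seed = 42)
#' fit
#' head(summary(fit)$drugs)
#' @export
goprio <- function(kb, query, study_set = "activating", B = 10000, seed,
                   krank_denominator = c("set_size", "support"),
                   drug_score = c("per_total_targets", "per_altered_targets")) {
  stopifnot(inherits(kb, "knowledge_base"), inherits(query, "query_dataset"))
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  krank_denominator <- match.arg(krank_denominator)
  drug_score <- match.arg(drug_score)
  if (!study_set %in% names(kb$study_sets)) {
    stop("unknown study_set '", study_set, "'; available: ",
         paste(names(kb$study_sets), collapse = ", "), call. = FALSE)
  }
  kranks <- compute_kranks(kb, study_set, denominator = krank_denominator)
  go_scores <- score_all_processes(kb, kranks, B = B, seed = seed)
  am <- build_activity_matrix(query)
  recal <- recalibrate_genes(kb, go_scores)
  drugs <- prioritize_drugs(kb, recal, am, drug_score = drug_score)
  structure(list(kranks = kranks, go_scores = go_scores, activity = am,
                 recalibrated = recal, drugs = drugs,
                 config = list(study_set = study_set, B = B, seed = seed,
                               krank_denominator = krank_denominator,
                               drug_score = drug_score)),
            class = "goprio")
}

#' @export
print.goprio <- function(x, ...) {
  cat("Drug prioritization run\n")
  cat(sprintf("  study set: %s (K-ranks for %d genes)\n",
              x$config$study_set, nrow(x$kranks)))
  cat(sprintf("  processes scored: %d (B = %d, seed = %d)\n",
              nrow(x$go_scores), x$config$B, x$config$seed))
  cat(sprintf("  cohort: %d samples, %d genes in activity matrix\n",
              length(x$activity$samples), length(x$activity$genes)))
  cat(sprintf("  drugs scored: %d\n", nrow(x$drugs)))
  if (nrow(x$drugs)) {
    top <- x$drugs[1, ]
    cat(sprintf("  top drug: %s (score %.3f, %d sensitive sample(s))\n",
                top$drug_name, top$score, top$n_sensitive_samples))
  }
  invisible(x)
}

#' @export
summary.goprio <- function(object, n = 10, ...) {
  go <- object$go_scores
  go <- go[order(go$p_value, -go$observed_score, go$process_id), ]
  structure(list(drugs = utils::head(as.data.frame(object$drugs), n),
                 processes = utils::head(go, n),
                 n_drugs = nrow(object$drugs),
                 n_processes = nrow(object$go_scores),
                 config = object$config),
            class = "summary.goprio")
}

#' @export
print.summary.goprio <- function(x, ...) {
  cat(sprintf("Top processes (of %d scored):\n", x$n_processes))
  print(x$processes, row.names = FALSE)
  cat(sprintf("\nTop drugs (of %d scored):\n", x$n_drugs))
  print(x$drugs, row.names = FALSE)
  invisible(x)
}

#' Plot the sample stratification of the top drugs
#'
#' Draws the oncoprint-style categorical heat map of
#' [render_stratification()]: per-drug sensitivity rows over the activity
#' status of the drugs' target genes, samples ordered by sensitivity to
#' the highest-scoring drug.
#'
#' @param x A [goprio()] result.
#' @param drugs Drug ids to show (default: top 3).
#' @param genes Extra genes whose status rows are added (default: the
#'   shown drugs' altered targets).
#' @param ... Unused.
#' @return Invisibly, the rendered character matrix.
#' @export
plot.goprio <- function(x, drugs = NULL, genes = NULL, ...) {
  if (!nrow(x$drugs)) stop("no drug was scored; nothing to plot", call. = FALSE)
  drugs <- drugs %||% utils::head(x$drugs$drug_id, 3)
  sens <- attr(x$drugs, "sensitive")[drugs]
  detail <- attr(x$drugs, "per_target")[drugs]
  genes <- genes %||% unique(unlist(lapply(detail, `[[`, "gene_id")))
  m <- render_stratification(x$activity, sensitive = sens, genes = genes)
  pal <- c(sensitive = "#1b7837", insensitive = "grey85",
           active = "#d73027", inactive = "#4575b4", unchanged = "grey95")
  lv <- names(pal)
  z <- matrix(match(m, lv), nrow(m), ncol(m))
  op <- graphics::par(mar = c(2, 8, 2, 1)); on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                  t(z[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = pal, zlim = c(1, length(lv)),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Sample stratification")
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 2, cex.axis = 0.7, tick = FALSE)
  invisible(m)
}

#' Run the pipeline from files to a run directory
#'
#' File-based front end over [goprio()]: reads the knowledge base and
#' query cohort from `config$paths`, executes all stages, and writes every
#' intermediate TSV (`kranks.tsv`, `go_scores.tsv`, `activity.tsv` with
#' provenance, `recalibrated.tsv`, `drugs.tsv`, per-drug sensitive-sample
#' lists under `sensitive/`) plus `manifest.json` recording the config,
#' seed, package version, per-file row counts and md5 checksums. Runs are
#' idempotent for a fixed seed.
#'
#' @param config A [run_config()] whose `paths` name `kb`, `query` and
#'   `out`. If `query` contains a continuous `expression_values.tsv` and
#'   `config$discretize` is set, expression is discretized first.
#' @return The `goprio` result, invisibly; side effect: the populated run
#'   directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  paths <- config$paths
  for (p in c("kb", "query", "out")) {
    if (is.null(paths[[p]])) {
      stop("config$paths$", p, " is required", call. = FALSE)
    }
  }
  stage <- "load knowledge base"
  res <- tryCatch({
    kb <- read_knowledge_base(paths$kb)
    stage <- "load query data"
    cont <- file.path(paths$query, "expression_values.tsv")
    if (!is.null(config$discretize) && file.exists(cont)) {
      vals <- read_matrix_tsv(cont)
      storage.mode(vals) <- "double"
      d <- config$discretize
      expr <- discretize_expression(vals, method = d$method %||% "zscore",
                                    z_cut = d$z_cut %||% 2, q = d$q %||% 0.1)
      grab <- function(f) {
        p <- file.path(paths$query, f)
        if (file.exists(p)) read_matrix_tsv(p) else NULL
      }
      query <- query_dataset(expression = expr, cna = grab("cna.tsv"),
                             mutation = grab("mutation.tsv"))
    } else {
      query <- read_query_dataset(paths$query)
    }
    stage <- "score"
    goprio(kb, query, study_set = config$study_set, B = config$B,
           seed = config$seed, krank_denominator = config$krank_denominator,
           drug_score = config$drug_score)
  }, error = function(e) {
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  out <- paths$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_tsv(res$kranks, file.path(out, "kranks.tsv"))
  write_tsv(res$go_scores, file.path(out, "go_scores.tsv"))
  write_activity_matrix(res$activity, file.path(out, "activity.tsv"))
  write_tsv(res$recalibrated, file.path(out, "recalibrated.tsv"))
  write_tsv(as.data.frame(res$drugs), file.path(out, "drugs.tsv"))
  sdir <- file.path(out, "sensitive")
  dir.create(sdir, showWarnings = FALSE)
  sens <- attr(res$drugs, "sensitive")
  for (d in names(sens)) {
    write_tsv(data.frame(sample_id = sens[[d]], stringsAsFactors = FALSE),
              file.path(sdir, paste0(d, ".tsv")))
  }
  files <- c("kranks.tsv", "go_scores.tsv", "activity.tsv",
             "recalibrated.tsv", "drugs.tsv")
  manifest <- list(
    config = config[c("study_set", "B", "seed", "krank_denominator",
                      "drug_score")],
    package_version = as.character(utils::packageVersion("goprio")),
    row_counts = lapply(stats::setNames(files, files), function(f)
      nrow(read_tsv(file.path(out, f)))),
    checksums = as.list(tools::md5sum(file.path(out, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
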