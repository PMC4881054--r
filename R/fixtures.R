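#' Specify a synthetic fixture
#'
#' Describes a self-contained synthetic knowledge base and query cohort
#' with planted signal, emulating the statistical structure of the real
#' inputs (multi-study rank tables, a small process ontology, a
#' drug-target table, a discretized tumor cohort) without any download.
#' A set of planted genes receives top-decile ranks in every study, the
#' planted process is regulated exactly by the planted genes, and the
#' planted drug targets a subset of them; the query cohort activates the
#' planted genes in `activation_fraction` of samples.
#'
#' @param n_genes Genes in the universe (default 100).
#' @param n_studies_per_set Studies generated for each of the three
#'   default study sets (default 3).
#' @param n_processes GO-like processes (default 20); the first is the
#'   planted one.
#' @param genes_per_process Integer range (length 2) of regulators per
#'   background process (default 5..15).
#' @param n_drugs Drugs (default 10); the first is the planted one.
#' @param targets_per_drug Integer range of targets per drug (default 1..3).
#' @param n_samples Samples in the query cohort (default 50).
#' @param n_planted Number of planted genes (default 10; must fit in the
#'   top decile of a study).
#' @param activation_fraction Fraction of samples in which each planted
#'   gene is made active-consistent (default 0.4, matching the sensitive
#'   fractions reported for real tumor cohorts).
#' @param noise_rate Per-cell rate of uniform status flips in background
#'   genes (default 0.02).
#' @param plant_signal Set `FALSE` for a negative control: planted genes
#'   get background ranks (no knowledge-base signal) while the planted
#'   process/drug wiring is kept.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 100, n_studies_per_set = 3,
                         n_processes = 20, genes_per_process = c(5, 15),
                         n_drugs = 10, targets_per_drug = c(1, 3),
                         n_samples = 50, n_planted = 10,
                         activation_fraction = 0.4, noise_rate = 0.02,
                         plant_signal = TRUE, seed = 1) {
  counts <- c(n_genes = n_genes, n_studies_per_set = n_studies_per_set,
              n_processes = n_processes, n_drugs = n_drugs,
              n_samples = n_samples, n_planted = n_planted)
  if (any(counts < 1)) {
    stop("all fixture counts must be positive; offending: ",
         paste(names(counts)[counts < 1], collapse = ", "), call. = FALSE)
  }
  if (activation_fraction < 0 || activation_fraction > 1) {
    stop("activation_fraction must lie in [0, 1]", call. = FALSE)
  }
  top_decile <- floor(n_genes / 10)
  if (n_planted > top_decile) {
    stop("planted set (", n_planted, ") exceeds top-decile capacity (",
         top_decile, ") of a study", call. = FALSE)
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  structure(list(
    n_genes = n_genes, n_studies_per_set = n_studies_per_set,
    n_processes = n_processes, genes_per_process = genes_per_process,
    n_drugs = n_drugs, targets_per_drug = targets_per_drug,
    n_samples = n_samples,
    genes = genes, planted_genes = genes[seq_len(n_planted)],
    planted_process = "GO:0000001", planted_drug = "D0001",
    activation_fraction = activation_fraction, noise_rate = noise_rate,
    plant_signal = plant_signal, seed = as.integer(seed)),
    class = "fixture_spec")
}

#' Generate the synthetic knowledge base
#'
#' Produces three study sets (`activating`, `inactivating`, `survival`)
#' of `n_studies_per_set` studies each, every study ranking all genes.
#' Planted genes draw their ranks uniformly from the top decile of each
#' study (unless `plant_signal = FALSE`); background genes fill the
#' remaining ranks uniformly at random. The planted process is regulated
#' exactly by the planted genes (each in a single, unambiguous direction);
#' background processes draw their regulators from background genes. The
#' planted drug (an inhibitor) targets a subset of the planted genes;
#' background drugs target background genes.
#'
#' @param spec A [fixture_spec()].
#' @return A [knowledge_base()] object; regeneration with the same spec is
#'   identical.
#' @export
generate_knowledge_base <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  genes <- spec$genes
  planted <- spec$planted_genes
  background <- setdiff(genes, planted)
  N <- spec$n_genes
  top <- floor(N / 10)

  studies <- list()
  set_tags <- c(activating = "activating", inactivating = "inactivating",
                survival = "survival")
  study_sets <- list()
  for (set in names(set_tags)) {
    ids <- sprintf("%s_%02d", set, seq_len(spec$n_studies_per_set))
    study_sets[[set]] <- ids
    for (sid in ids) {
      if (spec$plant_signal) {
        planted_ranks <- sample(seq_len(top), length(planted))
        rest <- sample(setdiff(seq_len(N), planted_ranks))
        ranks <- c(planted_ranks, rest)
        g <- c(planted, background)
      } else {
        ranks <- sample(seq_len(N))
        g <- genes
      }
      studies[[sid]] <- study(sid, g, ranks, source = "in_house",
                              data_type = "synthetic rank",
                              direction_tag = set_tags[[set]])
    }
  }

  procs <- sprintf("GO:%07d", seq_len(spec$n_processes))
  reg_rows <- list()
  dirs <- rep(c("positive", "negative"), length.out = length(planted))
  reg_rows[[1]] <- data.frame(
    gene_id = planted, process_id = spec$planted_process,
    process_name = "planted process", direction = dirs,
    stringsAsFactors = FALSE)
  for (i in seq_along(procs)[-1]) {
    k <- sample(spec$genes_per_process[1]:spec$genes_per_process[2], 1)
    members <- sample(background, min(k, length(background)))
    reg_rows[[i]] <- data.frame(
      gene_id = members, process_id = procs[i],
      process_name = paste("background process", i),
      direction = sample(c("positive", "negative"), length(members),
                         replace = TRUE),
      stringsAsFactors = FALSE)
  }

  drug_rows <- list()
  n_planted_targets <- min(sample(spec$targets_per_drug[1]:spec$targets_per_drug[2], 1) + 1,
                           length(planted))
  drug_rows[[1]] <- data.frame(
    drug_id = spec$planted_drug, drug_name = "planteddrug",
    gene_id = sample(planted, n_planted_targets), action = "inhibitor",
    source_db = "synthetic", stringsAsFactors = FALSE)
  if (spec$n_drugs > 1) {
    for (i in 2:spec$n_drugs) {
      k <- sample(spec$targets_per_drug[1]:spec$targets_per_drug[2], 1)
      drug_rows[[i]] <- data.frame(
        drug_id = sprintf("D%04d", i), drug_name = sprintf("drug%04d", i),
        gene_id = sample(background, k),
        action = sample(c("inhibitor", "unknown"), k, replace = TRUE),
        source_db = "synthetic", stringsAsFactors = FALSE)
    }
  }

  knowledge_base(studies, study_sets,
                 regulations = do.call(rbind, reg_rows),
                 drug_targets = do.call(rbind, drug_rows))
}

#' Generate the synthetic query cohort
#'
#' Planted genes are made active-consistent — expression `up` and/or
#' copy-number `amplified` — in `activation_fraction` of the samples;
#' every background cell is unchanged except for uniform noise flips at
#' `noise_rate` per cell and layer (expression to up/down, copy number to
#' amplified/deleted, mutation to activating/inactivating). Uses an RNG
#' stream offset from the spec seed so the cohort is independent of the
#' knowledge-base draw but still fully determined by the spec.
#'
#' @param spec A [fixture_spec()].
#' @return A [query_dataset()] covering all genes of the fixture universe.
#' @export
generate_query_dataset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1000003L)
  genes <- spec$genes
  samples <- sprintf("s%04d", seq_len(spec$n_samples))
  n <- length(genes); m <- length(samples)
  dimn <- list(genes, samples)
  expr <- matrix("unchanged", n, m, dimnames = dimn)
  cna <- matrix("neutral", n, m, dimnames = dimn)
  mut <- matrix("none", n, m, dimnames = dimn)

  flip <- function(mat, states) {
    hit <- matrix(stats::runif(n * m) < spec$noise_rate, n, m)
    mat[hit] <- sample(states, sum(hit), replace = TRUE)
    mat
  }
  expr <- flip(expr, c("up", "down"))
  cna <- flip(cna, c("amplified", "deleted"))
  mut <- flip(mut, c("activating", "inactivating"))

  n_on <- if (spec$plant_signal) round(spec$activation_fraction * m) else 0L
  for (g in spec$planted_genes) {
    on <- sample(samples, n_on)
    use_expr <- stats::runif(length(on)) < 0.8
    use_cna <- stats::runif(length(on)) < 0.6
    use_expr[!use_expr & !use_cna] <- TRUE
    expr[g, on[use_expr]] <- "up"
    cna[g, on[use_cna]] <- "amplified"
    # activation must not be masked by a noise flip in another layer
    cna[g, on][cna[g, on] == "deleted"] <- "neutral"
    mut[g, on][mut[g, on] == "inactivating"] <- "none"
  }
  query_dataset(expression = expr, cna = cna, mutation = mut)
}

#' Write a complete synthetic fixture to disk
#'
#' Writes the knowledge base (via [write_knowledge_base()]) and the query
#' cohort (`expression.tsv`, `cna.tsv`, `mutation.tsv`) in the exact TSV
#' dialects the loaders read, so tests exercise the real readers.
#' Deterministic per spec: repeated calls produce byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
simulate_fixture <- function(spec, dir) {
  kb <- generate_knowledge_base(spec)
  q <- generate_query_dataset(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_knowledge_base(kb, file.path(dir, "kb"))
  write_matrix_tsv(q$expression, file.path(dir, "expression.tsv"))
  write_matrix_tsv(q$cna, file.path(dir, "cna.tsv"))
  write_matrix_tsv(q$mutation, file.path(dir, "mutation.tsv"))
  invisible(dir)
}

#' Read a query cohort written by [simulate_fixture()]
#'
#' @param dir Directory containing `expression.tsv`, `cna.tsv`,
#'   `mutation.tsv` (each optional).
#' @return A [query_dataset()].
#' @export
read_query_dataset <- function(dir) {
  grab <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read_matrix_tsv(p) else NULL
  }
  query_dataset(expression = grab("expression.tsv"), cna = grab("cna.tsv"),
                mutation = grab("mutation.tsv"))
}
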