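EXPR_STATES <- c("up", "down", "unchanged", "missing")
CNA_STATES  <- c("amplified", "deleted", "neutral", "missing")
MUT_STATES  <- c("activating", "inactivating", "none", "missing")
ACTIVITY_STATES <- c("active", "inactive", "unchanged")

#' Assemble a query data set
#'
#' A query data set holds the per-sample molecular status of the cohort in
#' which drugs are to be prioritized: expression status
#' (`up`/`down`/`unchanged`/`missing`), copy-number status
#' (`amplified`/`deleted`/`neutral`/`missing`) and mutation status
#' (`activating`/`inactivating`/`none`/`missing`), each a gene-by-sample
#' character matrix. Layers may cover different gene sets (a gene absent
#' from a layer is treated as `missing` there) but must agree on samples.
#'
#' @param expression,cna,mutation Character matrices (genes in rows,
#'   samples in columns) or `NULL` for an absent layer. At least one layer
#'   is required.
#' @return An object of class `query_dataset` with elements `expression`,
#'   `cna`, `mutation` and `samples`.
#' @export
query_dataset <- function(expression = NULL, cna = NULL, mutation = NULL) {
  layers <- list(expression = expression, cna = cna, mutation = mutation)
  layers <- Filter(Negate(is.null), layers)
  if (!length(layers)) stop("at least one data layer is required", call. = FALSE)
  allowed <- list(expression = EXPR_STATES, cna = CNA_STATES,
                  mutation = MUT_STATES)
  sample_sets <- lapply(layers, colnames)
  ref <- sample_sets[[1]]
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      stop("layer '", nm, "' needs gene rownames and sample colnames",
           call. = FALSE)
    }
    if (!identical(colnames(m), ref)) {
      extra <- setdiff(colnames(m), ref)
      miss <- setdiff(ref, colnames(m))
      stop("sample sets differ across layers ('", nm, "' vs '",
           names(layers)[1], "'): extra = {",
           paste(extra, collapse = ", "), "}, missing = {",
           paste(miss, collapse = ", "), "}", call. = FALSE)
    }
    bad <- !m %in% allowed[[nm]]
    if (any(bad)) {
      stop("layer '", nm, "' contains invalid status value(s): ",
           paste(unique(m[bad]), collapse = ", "), call. = FALSE)
    }
  }
  structure(c(lapply(c(expression = "expression", cna = "cna",
                       mutation = "mutation"),
                     function(nm) layers[[nm]]),
              list(samples = ref)),
            class = "query_dataset")
}

#' @export
print.query_dataset <- function(x, ...) {
  n_genes <- length(unique(unlist(lapply(
    x[c("expression", "cna", "mutation")],
    function(m) if (!is.null(m)) rownames(m)))))
  layers <- names(Filter(Negate(is.null),
                         x[c("expression", "cna", "mutation")]))
  cat(sprintf("<query_dataset> %d gene(s) x %d sample(s); layers: %s\n",
              n_genes, length(x$samples), paste(layers, collapse = ", ")))
  invisible(x)
}

#' Discretize continuous expression to up/down/unchanged
#'
#' Per-gene discretization of a continuous expression matrix. The default
#' `zscore` method computes a robust z-score against the per-gene median
#' and MAD (scaled by 1.4826 for normal consistency); samples with
#' `z >= z_cut` are `up`, `z <= -z_cut` are `down`. When the MAD of a gene
#' is zero but its spread is not, a mean / population-sd z-score is used
#' instead; genes with no spread at all are left all `unchanged` with a
#' warning. The `quantile` method marks the upper and lower `q` fraction
#' of each gene's values.
#'
#' @param values Numeric gene-by-sample matrix.
#' @param method `"zscore"` (default) or `"quantile"`.
#' @param z_cut Robust z-score threshold (default 2).
#' @param q Tail fraction for the quantile method (default 0.1).
#' @return Character matrix of `up`/`down`/`unchanged`, same dimnames.
#' @export
discretize_expression <- function(values, method = c("zscore", "quantile"),
                                  z_cut = 2, q = 0.1) {
  method <- match.arg(method)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  out <- matrix("unchanged", nrow(values), ncol(values),
                dimnames = dimnames(values))
  flat <- character(0)
  for (i in seq_len(nrow(values))) {
    x <- values[i, ]
    if (method == "zscore") {
      s <- stats::mad(x)          # includes the 1.4826 consistency constant
      if (s == 0) {
        # MAD degenerates when a majority of samples share one value;
        # fall back to a population-sd z-score before declaring the gene flat
        s <- sqrt(mean((x - mean(x))^2))
        if (is.na(s) || s == 0) {
          flat <- c(flat, rownames(values)[i] %||% as.character(i))
          next
        }
        z <- (x - mean(x)) / s
      } else {
        z <- (x - stats::median(x)) / s
      }
      out[i, z >= z_cut] <- "up"
      out[i, z <= -z_cut] <- "down"
    } else {
      lo <- stats::quantile(x, q, names = FALSE)
      hi <- stats::quantile(x, 1 - q, names = FALSE)
      out[i, x > hi] <- "up"
      out[i, x < lo] <- "down"
    }
  }
  if (length(flat)) {
    warning("gene(s) with zero spread left all-unchanged: ",
            paste(flat, collapse = ", "), call. = FALSE)
  }
  out
}

#' Convert long-form mutation calls to a status matrix
#'
#' @param calls Data frame with columns `gene_id`, `sample_id`, `effect`
#'   (`activating`/`inactivating`).
#' @param samples Character vector fixing the sample order of the matrix.
#' @return Gene-by-sample character matrix over the mutation states, with
#'   `none` where no call was made.
#' @export
mutation_calls_to_matrix <- function(calls, samples) {
  for (col in c("gene_id", "sample_id", "effect")) {
    if (!col %in% names(calls)) {
      stop("mutation call table lacks column '", col, "'", call. = FALSE)
    }
  }
  bad <- !calls$effect %in% c("activating", "inactivating")
  if (any(bad)) {
    stop("mutation effect must be activating/inactivating; offending row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(calls$sample_id, samples)
  if (length(unknown)) {
    stop("mutation calls reference unknown sample(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  genes <- sort(unique(calls$gene_id))
  m <- matrix("none", length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(calls$gene_id, calls$sample_id)] <- calls$effect
  m
}

#' Build the ternary activity matrix
#'
#' Fuses the three evidence layers of a [query_dataset()] into a single
#' gene-by-sample status in `{active, inactive, unchanged}` using a fixed
#' precedence of rules:
#'
#' 1. a mutation call wins outright (`activating` -> active,
#'    `inactivating` -> inactive);
#' 2. otherwise an altered copy-number state wins (`amplified` -> active,
#'    `deleted` -> inactive) — genomic alterations are more stable and
#'    reproducible across studies than expression changes, so they
#'    override a conflicting expression status and also apply when
#'    expression is silent or missing;
#' 3. otherwise expression decides (`up` -> active, `down` -> inactive);
#' 4. otherwise the gene is `unchanged` in that sample.
#'
#' A layer that is `missing`/`none`/`neutral` for a cell simply defers to
#' the next rule. The companion provenance matrix records which layer
#' decided each cell.
#'
#' @param q A [query_dataset()].
#' @return Object of class `activity_matrix`: list with character matrices
#'   `status` and `provenance` (values `expression`, `cna`, `mutation`,
#'   `default`), plus `genes` and `samples`.
#' @export
build_activity_matrix <- function(q) {
  stopifnot(inherits(q, "query_dataset"))
  layers <- q[c("expression", "cna", "mutation")]
  genes <- sort(unique(unlist(lapply(layers, function(m)
    if (!is.null(m)) rownames(m)))))
  samples <- q$samples
  expand <- function(m, fill) {
    full <- matrix(fill, length(genes), length(samples),
                   dimnames = list(genes, samples))
    if (!is.null(m)) full[rownames(m), ] <- m
    full
  }
  expr <- expand(q$expression, "missing")
  cna <- expand(q$cna, "missing")
  mut <- expand(q$mutation, "missing")

  status <- matrix("unchanged", length(genes), length(samples),
                   dimnames = list(genes, samples))
  prov <- matrix("default", length(genes), length(samples),
                 dimnames = list(genes, samples))
  # apply in reverse precedence so later layers overwrite earlier ones
  status[expr == "up"] <- "active";   prov[expr == "up"] <- "expression"
  status[expr == "down"] <- "inactive"; prov[expr == "down"] <- "expression"
  status[cna == "amplified"] <- "active"; prov[cna == "amplified"] <- "cna"
  status[cna == "deleted"] <- "inactive"; prov[cna == "deleted"] <- "cna"
  status[mut == "activating"] <- "active"; prov[mut == "activating"] <- "mutation"
  status[mut == "inactivating"] <- "inactive"; prov[mut == "inactivating"] <- "mutation"

  structure(list(status = status, provenance = prov, genes = genes,
                 samples = samples),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  tab <- table(factor(x$status, levels = ACTIVITY_STATES))
  cat(sprintf("<activity_matrix> %d gene(s) x %d sample(s): %s\n",
              length(x$genes), length(x$samples),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Samples in which a gene holds a given status
#'
#' The sample stratification of the cohort with respect to one gene is
#' read directly off the activity matrix.
#'
#' @param am An [build_activity_matrix()] result.
#' @param gene Gene identifier (must be present in `am`).
#' @param status One of `active`, `inactive`, `unchanged`.
#' @return Character vector of sample ids (possibly empty).
#' @export
stratify_by_gene <- function(am, gene, status) {
  stopifnot(inherits(am, "activity_matrix"))
  if (!gene %in% am$genes) {
    stop("gene '", gene, "' is not in the activity matrix", call. = FALSE)
  }
  status <- match_arg1(status, ACTIVITY_STATES, "status")
  am$samples[am$status[gene, ] == status]
}

#' Write / read an activity matrix as TSV
#'
#' `write_activity_matrix()` writes `status` to `path` and the provenance
#' matrix alongside it (suffix `.provenance.tsv`).
#'
#' @param am An `activity_matrix`.
#' @param path Output TSV path for the status matrix.
#' @return `path`, invisibly.
#' @export
write_activity_matrix <- function(am, path) {
  stopifnot(inherits(am, "activity_matrix"))
  write_matrix_tsv(am$status, path)
  write_matrix_tsv(am$provenance, sub("\\.tsv$", ".provenance.tsv", path))
  invisible(path)
}

#' @rdname write_activity_matrix
#' @export
read_activity_matrix <- function(path) {
  status <- read_matrix_tsv(path)
  prov_path <- sub("\\.tsv$", ".provenance.tsv", path)
  prov <- if (file.exists(prov_path)) read_matrix_tsv(prov_path) else {
    matrix("default", nrow(status), ncol(status), dimnames = dimnames(status))
  }
  structure(list(status = status, provenance = prov,
                 genes = rownames(status), samples = colnames(status)),
            class = "activity_matrix")
}
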