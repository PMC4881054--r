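# Independent oracles, written straight from textbook definitions or by
# exhaustive enumeration. They deliberately share no code with the package
# internals they check.

# Benjamini-Yekutieli step-up adjustment, from the definition:
# q_(i) = min_{j >= i} ( m * c(m) / j * p_(j) ), c(m) = sum_{k<=m} 1/k, capped at 1.
by_adjust_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  ps <- p[ord]
  raw <- cm * m / seq_len(m) * ps
  adj <- rev(cummin(rev(raw)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exact permutation p-value by exhaustive enumeration of all size-k
# subsets of the K-rank universe (no pseudocount).
exact_perm_p <- function(T_obs, k, vals) {
  sums <- utils::combn(vals, k, sum)
  tol <- 1e-9 * max(1, abs(T_obs))
  sum(sums >= T_obs - tol) / length(sums)
}

# Straight-line recomputation of drug scores and sensitive-sample sets
# from first principles (loops over samples, no vectorized shortcuts).
brute_drug_scores <- function(drug_targets, recal, status_matrix,
                              mode_map = c(inhibitor = "active",
                                           activator = "inactive",
                                           unknown = "active"),
                              variant = "per_total_targets") {
  samples <- colnames(status_matrix)
  out <- list()
  for (d in unique(drug_targets$drug_id)) {
    tg <- drug_targets[drug_targets$drug_id == d, , drop = FALSE]
    contributions <- numeric(0)
    n_altered <- 0L
    sens <- character(0)
    for (j in seq_len(nrow(tg))) {
      g <- tg$gene_id[j]
      if (!g %in% recal$gene_id) next
      if (!g %in% rownames(status_matrix)) next
      any_alt <- FALSE
      for (s in samples) if (status_matrix[g, s] != "unchanged") any_alt <- TRUE
      if (!any_alt) next
      req <- mode_map[[tg$action[j]]]
      n_req <- 0L
      hit <- character(0)
      for (s in samples) {
        if (status_matrix[g, s] == req) { n_req <- n_req + 1L; hit <- c(hit, s) }
      }
      if (n_req == 0L) next
      n_altered <- n_altered + 1L
      f <- n_req / length(samples)
      sc <- recal$score[recal$gene_id == g]
      contributions <- c(contributions, sc * f)
      sens <- c(sens, hit)
    }
    if (n_altered == 0L) next
    denom <- if (variant == "per_total_targets") nrow(tg) else n_altered
    out[[d]] <- list(drug_id = d, score = sum(contributions) / denom,
                     n_altered_targets = n_altered,
                     sensitive = sort(unique(sens)))
  }
  out
}

# Independent per-cell evaluation of the activity rules, written as plain
# if/else directly from the documented precedence.
activity_cell_oracle <- function(expr, cna, mut) {
  if (mut == "activating") return(c("active", "mutation"))
  if (mut == "inactivating") return(c("inactive", "mutation"))
  if (cna == "amplified") return(c("active", "cna"))
  if (cna == "deleted") return(c("inactive", "cna"))
  if (expr == "up") return(c("active", "expression"))
  if (expr == "down") return(c("inactive", "expression"))
  c("unchanged", "default")
}
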