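#' Normalized per-study rank score
#'
#' Maps a gene's rank within one study to a score in (0, 1]:
#' `u = (N - r + 1) / N`, so the top-ranked gene scores exactly 1 and the
#' bottom-ranked gene scores `1/N`. This is the per-study building block of
#' the K-rank.
#'
#' @param r Integer rank(s), 1 = strongest evidence.
#' @param N Study size (total ranked genes), recycled against `r`.
#' @return Numeric vector of scores in (0, 1].
#' @examples
#' per_study_score(1, 10)   # 1.0
#' per_study_score(3, 4)    # 0.5
#' @export
per_study_score <- function(r, N) {
  if (!is.numeric(r) || !is.numeric(N)) {
    stop("r and N must be numeric", call. = FALSE)
  }
  bad <- r < 1 | r > N | r != floor(r)
  if (any(bad)) {
    stop("rank r must be an integer in 1..N (offending r = ",
         paste(r[bad], collapse = ", "), ", N = ",
         paste(rep_len(N, length(r))[bad], collapse = ", "), ")",
         call. = FALSE)
  }
  (N - r + 1) / N
}

#' Compute gene K-ranks for a study set
#'
#' The K-rank is the multi-study cancer-essentiality score of a gene
#' within a study set: the sum of its normalized per-study scores
#' ([per_study_score()]) over the studies that rank it, divided by the
#' number of studies in the set. Dividing by the full set size (the
#' default) rewards recurrence across studies: a gene ranked well in two
#' studies outranks a gene ranked equally well in only one. Genes absent
#' from every study of the set receive no K-rank at all (they failed every
#' study's inclusion criteria, which is not evidence of irrelevance at
#' rank N).
#'
#' @param kb A [knowledge_base()].
#' @param set_id Name of a study set defined in `kb`.
#' @param denominator `"set_size"` (divide by the total number of studies
#'   in the set; default) or `"support"` (divide by the number of studies
#'   ranking the gene, i.e. a plain mean over supporting studies).
#' @return Data frame with columns `gene_id`, `set_id`, `krank` (in
#'   (0, 1]), `n_support`, ordered by decreasing `krank` then `gene_id`.
#' @examples
#' s1 <- study("a", c("g1", "g2"), 1:2)
#' s2 <- study("b", c("g1", "g3"), c(2, 1))
#' kb <- knowledge_base(list(s1, s2), list(activating = c("a", "b")))
#' compute_kranks(kb, "activating")
#' @export
compute_kranks <- function(kb, set_id,
                           denominator = c("set_size", "support")) {
  stopifnot(inherits(kb, "knowledge_base"))
  denominator <- match.arg(denominator)
  if (!set_id %in% names(kb$study_sets)) {
    stop("unknown study set '", set_id, "'; available: ",
         paste(names(kb$study_sets), collapse = ", "), call. = FALSE)
  }
  members <- kb$study_sets[[set_id]]
  studies <- kb$studies[members]
  studies <- studies[!vapply(studies, `[[`, logical(1), "empty")]
  n_set <- length(members)

  u_sum <- numeric(0); support <- integer(0)
  for (s in studies) {
    u <- per_study_score(unname(s$ranks), s$N)
    g <- names(s$ranks)
    new <- setdiff(g, names(u_sum))
    if (length(new)) {
      u_sum[new] <- 0
      support[new] <- 0L
    }
    u_sum[g] <- u_sum[g] + u
    support[g] <- support[g] + 1L
  }
  if (!length(u_sum)) {
    return(data.frame(gene_id = character(), set_id = character(),
                      krank = numeric(), n_support = integer(),
                      stringsAsFactors = FALSE))
  }
  denom <- if (denominator == "set_size") n_set else support
  k <- u_sum / denom
  out <- data.frame(gene_id = names(u_sum), set_id = set_id,
                    krank = unname(k), n_support = unname(support),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$krank, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
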