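test_that("the harmonic mean reproduces hand-computed values and bounds", {
  # equal p-values: H equals the common value, score = -log10(H)
  r_equal <- recalibrate_gene(
    "g", data.frame(gene_id = "g", process_id = paste0("GO:", 1:3),
                    process_name = "x", direction = "positive"),
    data.frame(process_id = paste0("GO:", 1:3), p_value = rep(0.01, 3)))
  expect_equal(r_equal$harmonic_mean_p, 0.01)
  expect_equal(r_equal$score, 2.0)

  # worked value 2 / (1/0.1 + 1/0.001)
  r2 <- recalibrate_gene(
    "g", data.frame(gene_id = "g", process_id = c("GO:1", "GO:2"),
                    process_name = "x", direction = c("positive", "negative")),
    data.frame(process_id = c("GO:1", "GO:2"), p_value = c(0.1, 0.001)))
  expect_equal(r2$harmonic_mean_p, 2 / (1 / 0.1 + 1 / 0.001),
               tolerance = 1e-12)

  withr::local_seed(31)
  for (i in 1:50) {
    p <- stats::runif(sample(1:20, 1), min = 1e-6)
    H <- harmonic_mean_p(p)
    expect_gte(H, min(p) - 1e-15)
    expect_lte(H, max(p) + 1e-15)
  }
  expect_error(harmonic_mean_p(c(0.5, 0)), "\\(0, 1]")
  expect_error(harmonic_mean_p(numeric(0)), "empty")
})

test_that("process-count independence: 2 vs 200 equal-p processes give identical H", {
  go <- function(n, p) data.frame(process_id = sprintf("GO:%04d", 1:n),
                                  p_value = rep(p, n))
  reg <- function(g, n) data.frame(gene_id = g,
                                   process_id = sprintf("GO:%04d", 1:n),
                                   process_name = "x",
                                   direction = "positive")
  r_small <- recalibrate_gene("a", reg("a", 2), go(2, 0.01))
  r_big <- recalibrate_gene("b", reg("b", 200), go(200, 0.01))
  expect_identical(r_small$harmonic_mean_p, r_big$harmonic_mean_p)
  expect_identical(r_small$score, r_big$score)
})

test_that("ambiguously regulated processes are excluded from the harmonic mean", {
  # one process regulated in both directions, one in a single direction
  reg <- data.frame(
    gene_id = "g",
    process_id = c("GO:1", "GO:1", "GO:2"),
    process_name = "x",
    direction = c("positive", "negative", "positive"))
  go <- data.frame(process_id = c("GO:1", "GO:2"), p_value = c(1e-9, 0.25))
  r <- recalibrate_gene("g", reg, go)
  expect_equal(r$harmonic_mean_p, 0.25)
  expect_equal(r$n_processes_used, 1L)
  expect_equal(r$n_processes_ambiguous, 1L)

  # 9 positive + 8 negative with no overlap -> all 17 used
  reg17 <- data.frame(
    gene_id = "g",
    process_id = sprintf("GO:%02d", 1:17),
    process_name = "x",
    direction = rep(c("positive", "negative"), c(9, 8)))
  go17 <- data.frame(process_id = sprintf("GO:%02d", 1:17),
                     p_value = stats::runif(17, 0.01, 0.99))
  expect_equal(recalibrate_gene("g", reg17, go17)$n_processes_used, 17L)
})

test_that("genes with no usable process are reported unscorable", {
  reg <- data.frame(gene_id = "g", process_id = c("GO:1", "GO:1"),
                    process_name = "x",
                    direction = c("positive", "negative"))
  go <- data.frame(process_id = "GO:1", p_value = 0.01)
  expect_null(recalibrate_gene("g", reg, go))
  kb <- tiny_kb()
  kb$regulations <- reg
  out <- recalibrate_genes(kb, go)
  expect_equal(nrow(out), 0)
  expect_identical(attr(out, "unscorable"), "g")
})

test_that("the drug score follows the documented formula on a worked case", {
  # drug with 2 targets, one altered with score 3.0 and f = 0.5
  samples <- paste0("s", 1:4)
  status <- matrix("unchanged", 2, 4,
                   dimnames = list(c("t1", "t2"), samples))
  status["t1", c("s1", "s2")] <- "active"
  am <- structure(list(status = status, provenance = status,
                       genes = rownames(status), samples = samples),
                  class = "activity_matrix")
  kb <- tiny_kb()
  kb$drug_targets <- data.frame(
    drug_id = "D", drug_name = "dee", gene_id = c("t1", "t2"),
    action = "inhibitor", source_db = "x")
  recal <- data.frame(gene_id = "t1", harmonic_mean_p = 0.001, score = 3.0,
                      n_processes_used = 1L, n_processes_ambiguous = 0L)
  out <- prioritize_drugs(kb, recal, am)
  expect_equal(out$score, 3.0 * 0.5 / 2)
  expect_equal(out$n_targets, 2L)
  expect_equal(out$n_altered_targets, 1L)
  expect_identical(attr(out, "sensitive")$D, c("s1", "s2"))
  # the per-altered-targets variant divides by |A_d| instead
  out2 <- prioritize_drugs(kb, recal, am, drug_score = "per_altered_targets")
  expect_equal(out2$score, 3.0 * 0.5)
})

test_that("drugs without altered scored targets are omitted; ties break by drug id", {
  samples <- paste0("s", 1:4)
  status <- matrix("unchanged", 2, 4,
                   dimnames = list(c("t1", "t2"), samples))
  status["t1", "s1"] <- "active"
  am <- structure(list(status = status, provenance = status,
                       genes = rownames(status), samples = samples),
                  class = "activity_matrix")
  kb <- tiny_kb()
  kb$drug_targets <- data.frame(
    drug_id = c("Dzz", "Daa", "Dnone"), drug_name = c("z", "a", "n"),
    gene_id = c("t1", "t1", "t2"), action = "inhibitor", source_db = "x")
  recal <- data.frame(gene_id = c("t1", "t2"),
                      harmonic_mean_p = c(0.01, 0.01),
                      score = c(2, 2), n_processes_used = 1L,
                      n_processes_ambiguous = 0L)
  out <- prioritize_drugs(kb, recal, am)
  # t2 is unaltered, so Dnone ("at least one altered gene target") drops out
  expect_identical(out$drug_id, c("Daa", "Dzz"))
  expect_equal(out$score[1], out$score[2])
  # identical eligible target sets give identical sensitive sets
  expect_identical(attr(out, "sensitive")$Daa, attr(out, "sensitive")$Dzz)
})

test_that("empty drug tables and empty activity matrices give empty rankings", {
  kb <- tiny_kb()
  kb$drug_targets <- kb$drug_targets[0, ]
  am <- build_activity_matrix(tiny_query())
  recal <- data.frame(gene_id = "g1", harmonic_mean_p = 0.01, score = 2,
                      n_processes_used = 1L, n_processes_ambiguous = 0L)
  expect_equal(nrow(prioritize_drugs(kb, recal, am)), 0)

  kb2 <- tiny_kb()
  empty_am <- structure(list(status = matrix(character(), 0, 0),
                             provenance = matrix(character(), 0, 0),
                             genes = character(), samples = character()),
                        class = "activity_matrix")
  expect_warning(out <- prioritize_drugs(kb2, recal, empty_am), "empty")
  expect_equal(nrow(out), 0)
})

test_that("sensitive samples are the union over altered targets of required-status samples", {
  samples <- paste0("s", 1:4)
  status <- matrix("unchanged", 3, 4,
                   dimnames = list(c("t1", "t2", "t3"), samples))
  status["t1", "s1"] <- "active"
  status["t2", "s2"] <- "active"
  status["t3", "s3"] <- "inactive"
  am <- structure(list(status = status, provenance = status,
                       genes = rownames(status), samples = samples),
                  class = "activity_matrix")
  kb <- tiny_kb()
  kb$drug_targets <- data.frame(
    drug_id = c("D1", "D1", "D2"), drug_name = "d",
    gene_id = c("t1", "t2", "t3"),
    action = c("inhibitor", "inhibitor", "activator"), source_db = "x")
  expect_identical(sensitive_samples("D1", kb, am), c("s1", "s2"))
  # activator semantics require the inactive status
  expect_identical(sensitive_samples("D2", kb, am), "s3")
  expect_error(sensitive_samples("ghost", kb, am), "unknown drug")
})

test_that("prioritization matches the brute-force oracle on random instances", {
  withr::local_seed(47)
  for (i in 1:20) {
    n_drugs <- sample(1:5, 1); n_genes <- sample(2:6, 1)
    n_samples <- sample(2:4, 1)
    genes <- sprintf("g%d", 1:n_genes)
    samples <- sprintf("s%d", 1:n_samples)
    status <- matrix(sample(c("active", "inactive", "unchanged"),
                            n_genes * n_samples, replace = TRUE),
                     n_genes, n_samples, dimnames = list(genes, samples))
    am <- structure(list(status = status, provenance = status,
                         genes = genes, samples = samples),
                    class = "activity_matrix")
    dt <- do.call(rbind, lapply(seq_len(n_drugs), function(d) {
      k <- sample(seq_len(n_genes), sample(seq_len(min(3, n_genes)), 1))
      data.frame(drug_id = sprintf("D%d", d), drug_name = sprintf("D%d", d),
                 gene_id = genes[k],
                 action = sample(c("inhibitor", "activator", "unknown"),
                                 length(k), replace = TRUE),
                 source_db = "x")
    }))
    scored <- genes[stats::runif(n_genes) < 0.8]
    recal <- data.frame(gene_id = scored,
                        harmonic_mean_p = stats::runif(length(scored)),
                        score = stats::runif(length(scored), 0, 4),
                        n_processes_used = rep(1L, length(scored)),
                        n_processes_ambiguous = rep(0L, length(scored)))
    kb <- tiny_kb(); kb$drug_targets <- dt
    for (variant in c("per_total_targets", "per_altered_targets")) {
      want <- brute_drug_scores(dt, recal, status, variant = variant)
      got <- if (length(want)) prioritize_drugs(kb, recal, am, drug_score = variant) else
        suppressWarnings(prioritize_drugs(kb, recal, am, drug_score = variant))
      expect_setequal(got$drug_id, names(want) %||% character(0))
      for (d in got$drug_id) {
        expect_identical(got$score[got$drug_id == d], want[[d]]$score)
        expect_identical(got$n_altered_targets[got$drug_id == d],
                         want[[d]]$n_altered_targets)
        expect_identical(attr(got, "sensitive")[[d]], want[[d]]$sensitive)
      }
    }
  }
})

test_that("lowering a used process p never lowers a targeting drug's score", {
  kb <- tiny_kb()
  am <- build_activity_matrix(tiny_query())
  go_hi <- data.frame(process_id = c("GO:0000001", "GO:0000002"),
                      p_value = c(0.2, 0.3))
  go_lo <- go_hi; go_lo$p_value[1] <- 0.002
  d_hi <- prioritize_drugs(kb, recalibrate_genes(kb, go_hi), am)
  d_lo <- prioritize_drugs(kb, recalibrate_genes(kb, go_lo), am)
  for (d in d_hi$drug_id) {
    expect_gte(d_lo$score[d_lo$drug_id == d], d_hi$score[d_hi$drug_id == d])
  }
})

test_that("the stratification report has the documented shape and stable order", {
  am <- build_activity_matrix(tiny_query())
  sens <- list(D1 = c("s2", "s4"))
  m <- render_stratification(am, sensitive = sens, genes = c("g1", "g2"))
  expect_equal(dim(m), c(3, 4))
  expect_identical(rownames(m), c("D1", "g1", "g2"))
  # sensitive samples come first, then sample id
  expect_identical(colnames(m), c("s2", "s4", "s1", "s3"))
  expect_identical(m, render_stratification(am, sensitive = sens,
                                            genes = c("g1", "g2")))
  # annotations add rows and participate in the ordering
  ann <- data.frame(sample_id = paste0("s", 1:4),
                    subtype = c("lumA", "lumB", "lumA", "basal"))
  m2 <- render_stratification(am, sensitive = sens, genes = "g1",
                              annotations = ann)
  expect_equal(dim(m2), c(3, 4))
  expect_identical(rownames(m2), c("D1", "g1", "subtype"))
  expect_identical(colnames(m2), c("s4", "s2", "s1", "s3"))
  # no annotations supplied: annotation rows are simply absent
  expect_equal(nrow(render_stratification(am, sensitive = sens)), 1)
  expect_error(render_stratification(am, sensitive = sens, genes = "ghost"),
               "ghost")
  ann_bad <- ann[1:2, ]
  expect_error(render_stratification(am, sensitive = sens,
                                     annotations = ann_bad), "missing")
})
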