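test_that("a knowledge base loads from TSV files with the expected shape", {
  dir <- write_tiny_kb_files(withr::local_tempdir())
  kb <- load_knowledge_base(file.path(dir, "studies.tsv"),
                            study_sets = file.path(dir, "sets.tsv"),
                            regulations = file.path(dir, "regulations.tsv"),
                            drugs = file.path(dir, "drugs.tsv"))
  expect_length(kb$studies, 2)
  expect_identical(kb$gene_universe, paste0("g", 1:6))
  expect_identical(kb$study_sets$activating, c("sA", "sB"))
  expect_equal(nrow(kb$regulations), 2)
  expect_equal(nrow(kb$drug_targets), 1)
})

test_that("invariant violations are rejected with informative errors", {
  expect_error(study("dup", c("g1", "g1"), 1:2), "g1.*dup")
  dir <- withr::local_tempdir()
  utils::write.table(
    data.frame(study_id = "sX", gene_id = c("g1", "g1"), rank = 1:2),
    file.path(dir, "studies.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  expect_error(load_knowledge_base(file.path(dir, "studies.tsv")),
               "g1.*sX")
  # dangling study reference in a set
  s <- study("sA", "g1", 1)
  expect_error(knowledge_base(list(s), list(activating = c("sA", "ghost"))),
               "ghost")
  expect_error(load_knowledge_base("/no/such/file.tsv"), "not found")
})

test_that("an empty drug-target file yields a valid KB with zero drugs", {
  dir <- write_tiny_kb_files(withr::local_tempdir())
  utils::write.table(empty_drug_targets <- data.frame(
    drug_id = character(), drug_name = character(), gene_id = character(),
    action = character(), source_db = character()),
    file.path(dir, "drugs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  kb <- load_knowledge_base(file.path(dir, "studies.tsv"),
                            drugs = file.path(dir, "drugs.tsv"))
  expect_equal(nrow(kb$drug_targets), 0)
})

test_that("curated rank ties resolve to a dense permutation, lexicographic last", {
  s <- study("tied", c("b", "a", "c", "d"), c(2, 2, 1, 5))
  expect_identical(sort(unname(s$ranks)), 1:4)
  expect_identical(unname(s$ranks[c("c", "a", "b", "d")]), c(1L, 2L, 3L, 4L))
  # reversed sources flip so rank 1 is strongest
  r <- study("rev", c("x", "y", "z"), c(1, 2, 3), reverse = TRUE)
  expect_identical(unname(r$ranks[c("z", "y", "x")]), c(1L, 2L, 3L))
})

test_that("write/load round-trips reproduce studies, ranks and triples", {
  kb <- tiny_kb()
  dir <- withr::local_tempdir()
  write_knowledge_base(kb, dir)
  kb2 <- read_knowledge_base(dir)
  expect_identical(sort(names(kb2$studies)), sort(names(kb$studies)))
  for (sid in names(kb$studies)) {
    expect_identical(kb2$studies[[sid]]$ranks, kb$studies[[sid]]$ranks)
    expect_identical(kb2$studies[[sid]]$source, kb$studies[[sid]]$source)
  }
  expect_identical(kb2$study_sets, kb$study_sets)
  expect_identical(kb2$regulations, kb$regulations)
  expect_identical(kb2$drug_targets, kb$drug_targets)
  expect_identical(kb2$gene_universe, kb$gene_universe)
})

test_that("BY-filtered study building matches the hand-evaluated adjustment", {
  p <- c(0.001, 0.01, 0.2, 0.5, 0.9)
  # hand oracle: H_5 = 1 + 1/2 + ... + 1/5
  q_oracle <- by_adjust_oracle(p)
  expect_equal(sum(1 / (1:5)), 2.2833, tolerance = 1e-4)
  tab <- data.frame(gene_id = paste0("g", 1:5), p_value = p,
                    effect = c(1, 2, 3, 4, 5))
  s <- build_study_from_stats(tab, "by_test", q_threshold = 0.05)
  expect_identical(sort(names(s$ranks)),
                   sort(tab$gene_id[q_oracle <= 0.05]))
})

test_that("survivors are ranked by |effect|, ties by raw p then gene id", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    p_value = c(1e-6, 1e-6, 1e-6),
                    effect = c(4, 2, 8))
  s <- build_study_from_stats(tab, "ranked", q_threshold = 0.05)
  expect_identical(unname(s$ranks[c("a", "b", "c")]), c(2L, 3L, 1L))
  # |effect| tie broken by smaller raw p
  tab2 <- data.frame(gene_id = c("a", "b"), p_value = c(0.01, 0.001),
                     effect = c(-3, 3))
  s2 <- build_study_from_stats(tab2, "tied", q_threshold = 0.5)
  expect_identical(unname(s2$ranks[c("b", "a")]), c(1L, 2L))
})

test_that("study building is invariant under sign-preserving monotone effect transforms", {
  withr::local_seed(11)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    tab <- data.frame(gene_id = sprintf("g%02d", 1:n),
                      p_value = stats::runif(n, 1e-6, 0.2),
                      effect = stats::rnorm(n))
    base <- build_study_from_stats(tab, "s", q_threshold = 0.9)
    for (f in list(function(x) 2 * x, function(x) x^3)) {
      tab2 <- tab; tab2$effect <- f(tab$effect)
      expect_identical(build_study_from_stats(tab2, "s", q_threshold = 0.9)$ranks,
                       base$ranks)
    }
  }
})

test_that("zero survivors give an empty-flagged study with a warning", {
  tab <- data.frame(gene_id = c("a", "b"), p_value = c(0.5, 0.9),
                    effect = c(1, 2))
  expect_warning(s <- build_study_from_stats(tab, "none", q_threshold = 0.001),
                 "empty")
  expect_true(s$empty)
  expect_equal(s$N, 0)
  expect_error(build_study_from_stats(
    data.frame(gene_id = "a", p_value = "x", effect = 1), "bad"),
    "numeric")
})

test_that("BY adjustment agrees with the textbook implementation", {
  withr::local_seed(42)
  for (i in 1:25) {
    p <- stats::runif(sample(1:100, 1))
    expect_lt(max(abs(stats::p.adjust(p, method = "BY") -
                        by_adjust_oracle(p))), 1e-12)
  }
})
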