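# Small in-code fixtures shared across test files.

tiny_kb <- function() {
  s1 <- study("expr_brca", paste0("g", 1:10), 1:10, source = "in_house",
              data_type = "expression fold-change",
              direction_tag = "activating")
  s2 <- study("cgc_act", paste0("g", c(1, 3, 5, 7)), c(2, 1, 3, 4),
              source = "curated", data_type = "census class",
              direction_tag = "activating")
  reg <- data.frame(
    gene_id = c("g1", "g2", "g1", "g3", "g4"),
    process_id = c("GO:0000001", "GO:0000001", "GO:0000002", "GO:0000002",
                   "GO:0000002"),
    process_name = c("proc one", "proc one", "proc two", "proc two",
                     "proc two"),
    direction = c("positive", "negative", "negative", "positive", "positive"),
    stringsAsFactors = FALSE)
  drugs <- data.frame(
    drug_id = c("DB1", "DB1", "DB2"),
    drug_name = c("drug one", "drug one", "drug two"),
    gene_id = c("g1", "g2", "g3"),
    action = c("inhibitor", "inhibitor", "activator"),
    source_db = "test", stringsAsFactors = FALSE)
  knowledge_base(list(s1, s2),
                 list(activating = c("expr_brca", "cgc_act")),
                 regulations = reg, drug_targets = drugs)
}

# A 2x2 query over four samples exercising all three layers.
tiny_query <- function() {
  samples <- paste0("s", 1:4)
  genes <- paste0("g", 1:3)
  expr <- matrix("unchanged", 3, 4, dimnames = list(genes, samples))
  cna <- matrix("neutral", 3, 4, dimnames = list(genes, samples))
  mut <- matrix("none", 3, 4, dimnames = list(genes, samples))
  expr["g1", c("s1", "s3")] <- "up"
  expr["g2", "s2"] <- "down"
  cna["g2", "s2"] <- "amplified"
  mut["g3", "s4"] <- "inactivating"
  query_dataset(expression = expr, cna = cna, mutation = mut)
}

write_tiny_kb_files <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  studies <- rbind(
    data.frame(study_id = "sA", gene_id = paste0("g", 1:4), rank = 1:4),
    data.frame(study_id = "sB", gene_id = paste0("g", 3:6), rank = 1:4))
  utils::write.table(studies, file.path(dir, "studies.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(set_id = "activating", study_id = c("sA", "sB")),
    file.path(dir, "sets.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = c("g1", "g2"), process_id = "GO:0000009",
               process_name = "p9", direction = c("positive", "negative")),
    file.path(dir, "regulations.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(drug_id = "D1", drug_name = "dee", gene_id = "g1",
               action = "inhibitor", source_db = "db"),
    file.path(dir, "drugs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  dir
}
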