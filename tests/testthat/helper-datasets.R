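# Build a small dataset from a compact spec: one element per fact, gene ids
# given in order, error categories as in the record schema ("none" = clean).
toy_dataset <- function(genes, categories = rep("none", length(genes)),
                        label = "toy") {
  stopifnot(length(genes) == length(categories))
  initial <- ifelse(categories == "none", "correct", "error")
  final <- ifelse(categories == "factual", "error", "correct")
  validation_dataset(
    tibble::tibble(
      gene_id = genes,
      fact_text = sprintf("fact %d", seq_along(genes)),
      fact_type = "other",
      initial_score = initial,
      final_score = final,
      error_category = categories,
      citations = sprintf("PMID:%d", seq_along(genes)),
      validator_id = "v1",
      comment = ""
    ),
    database_label = label
  )
}

# Random clustered dataset for property-style tests; call under a fixed seed.
random_dataset <- function(max_genes = 8, cap = 5, p_error = 0.2) {
  n_genes <- sample.int(max_genes, 1)
  sizes <- sample.int(cap, n_genes, replace = TRUE)
  genes <- rep(sprintf("g%02d", seq_len(n_genes)), sizes)
  categories <- ifelse(runif(length(genes)) < p_error, "factual", "none")
  toy_dataset(genes, categories)
}

# Unresolved raw scoring table (validator verdicts only, no curator pass).
raw_scoring_tibble <- function(genes, verdicts) {
  tibble::tibble(
    gene_id = genes,
    fact_text = sprintf("fact %d", seq_along(genes)),
    fact_type = "other",
    initial_score = verdicts
  )
}
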