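#' Configure the synthetic validation-protocol generator
#'
#' @description
#' The generator emulates the two-stage sampling design of a curation
#' audit: genes are drawn at random, up to `cap` literature-supported facts
#' are checked per gene, and each checked fact passes through two noisy
#' stages — curation (the fact may be factually wrong, or true but
#' miscited) and validation (the validator may miss a real error or flag a
#' correct fact).
#'
#' Each fact receives a hidden truth label:
#' `factual` (probability `p_factual`), `citation` (`p_citation`: the fact
#' is true but its citation is wrong or incomplete) or `correct`. The
#' validator scores truth-`correct` facts as errors with probability
#' `p_validator_fp`, and misses either kind of real discrepancy with
#' probability `p_validator_fn`. Curator re-analysis then resolves every
#' reported error from the hidden truth: detected factual errors stay
#' final errors; detected citation discrepancies become `citation_metadata`
#' downgrades; false alarms become `validator_mistake`. Discrepancies the
#' validator missed were never reported, so they remain final-correct —
#' exactly as an audit that can only re-analyse reported errors would
#' behave.
#'
#' Defaults mirror the per-fact rates observed across the EcoCyc and CGD
#' audits (about 1.5% factual, 0.6% citation-metadata, 1.1% validator
#' false alarms, no measured validator miss rate).
#'
#' @param n_genes number of genes sampled (default 200, giving roughly 600
#'   facts under the default facts-per-gene law — the scale of one audit).
#' @param facts_per_gene_law probability weights over cluster sizes
#'   `1..cap` (default uniform).
#' @param cap maximum facts checked per gene (default 5).
#' @param p_factual probability a curated fact is factually wrong.
#' @param p_citation probability a fact is true but miscited.
#' @param p_validator_fp probability a correct fact is scored `No`.
#' @param p_validator_fn probability a wrong/miscited fact is scored `Yes`.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param database_label label for generated datasets.
#' @param n_validators validators to rotate `validator_id` over (default 4).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_genes = 200,
                             facts_per_gene_law = rep(1 / 5, 5),
                             cap = 5,
                             p_factual = 0.015,
                             p_citation = 0.006,
                             p_validator_fp = 0.011,
                             p_validator_fn = 0,
                             seed = NULL,
                             database_label = "synthetic",
                             n_validators = 4) {
  probs <- c(p_factual, p_citation, p_validator_fp, p_validator_fn)
  if (any(probs < 0 | probs > 1)) {
    abort_modaudit("probabilities must lie in [0, 1]", "modaudit_state_error")
  }
  if (p_factual + p_citation > 1) {
    abort_modaudit(
      "p_factual + p_citation must not exceed 1", "modaudit_state_error"
    )
  }
  if (length(facts_per_gene_law) != cap || any(facts_per_gene_law < 0) ||
      sum(facts_per_gene_law) <= 0) {
    abort_modaudit(
      sprintf("facts_per_gene_law must be %d non-negative weights", cap),
      class = "modaudit_state_error"
    )
  }
  if (n_genes < 1) {
    abort_modaudit("n_genes must be at least 1", "modaudit_state_error")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      facts_per_gene_law = facts_per_gene_law / sum(facts_per_gene_law),
      cap = as.integer(cap),
      p_factual = p_factual, p_citation = p_citation,
      p_validator_fp = p_validator_fp, p_validator_fn = p_validator_fn,
      seed = seed, database_label = database_label,
      n_validators = as.integer(n_validators)
    ),
    class = "generator_config"
  )
}

fact_types <- c("GO-term", "kinetic-parameter", "phenotype", "interaction", "other")

#' Generate a synthetic validation dataset
#'
#' Simulates one full audit under a [generator_config()]; see that help
#' page for the observation model. The hidden per-fact truth labels
#' (`"factual"`, `"citation"`, `"correct"`) are attached as attribute
#' `truth` — they are what the audit is trying to estimate and are not
#' part of the record schema, so they do not survive [write_validation()].
#'
#' @param config a [generator_config()].
#' @return A resolved [validation_dataset()] that always passes
#'   [validate_dataset()]; deterministic for a fixed `seed`.
#' @examples
#' d <- generate_dataset(generator_config(n_genes = 20, seed = 42))
#' summarize_rates(d)
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  build <- function() {
    sizes <- sample.int(
      config$cap, config$n_genes, replace = TRUE,
      prob = config$facts_per_gene_law
    )
    n <- sum(sizes)
    gene <- rep(sprintf("g%05d", seq_len(config$n_genes)), sizes)
    u <- runif(n)
    truth <- ifelse(
      u < config$p_factual, "factual",
      ifelse(u < config$p_factual + config$p_citation, "citation", "correct")
    )
    flagged <- ifelse(
      truth == "correct",
      runif(n) < config$p_validator_fp, # false alarm
      runif(n) >= config$p_validator_fn # real discrepancy, not missed
    )
    initial <- ifelse(flagged, "error", "correct")
    final <- ifelse(flagged & truth == "factual", "error", "correct")
    category <- rep("none", n)
    category[flagged & truth == "factual"] <- "factual"
    category[flagged & truth == "citation"] <- "citation_metadata"
    category[flagged & truth == "correct"] <- "validator_mistake"
    rec <- tibble::tibble(
      gene_id = gene,
      fact_text = sprintf("assertion %d about %s", seq_len(n), gene),
      fact_type = sample(fact_types, n, replace = TRUE),
      initial_score = initial,
      final_score = final,
      error_category = category,
      citations = sprintf("PMID:%d", 100000 + seq_len(n)),
      validator_id = rep(
        sprintf("%s-v%d", config$database_label,
                rep_len(seq_len(config$n_validators), config$n_genes)),
        sizes
      ),
      comment = ""
    )
    list(records = rec, truth = truth)
  }
  out <- if (is.null(config$seed)) build() else withr::with_seed(config$seed, build())
  ds <- validation_dataset(out$records, database_label = config$database_label)
  attr(ds, "truth") <- out$truth
  ds
}

study_marginals <- list(
  ecocyc = list(
    label = "EcoCyc", n_facts = 358L, factual = 5L,
    citation_metadata = 2L, validator_mistake = 1L, n_validators = 4L
  ),
  cgd = list(
    label = "CGD", n_facts = 275L, factual = 5L,
    citation_metadata = 2L, validator_mistake = 6L, n_validators = 4L
  )
)

#' Reconstruct the published audit marginals
#'
#' Builds a dataset with exactly the marginal counts reported for the
#' EcoCyc and CGD curation audits: EcoCyc — 358 facts, 8 initial errors
#' (5 factual, 2 citation-metadata, 1 validator mistake), 5 final; CGD —
#' 275 facts, 13 initial errors (5 factual, 2 citation-metadata, 6
#' validator mistakes), 5 final. The published record-level data (which
#' genes carried which facts) are not reproduced: this is a synthetic
#' reconstruction of the marginals only, under a chosen cluster layout.
#'
#' * `"singleton"` layout: one fact per gene. In this layout the
#'   gene-cluster bootstrap reduces to an iid fact bootstrap, which is the
#'   layout under which the published confidence intervals are reproduced
#'   and cross-checked against [binomial_oracle()].
#' * `"capped"` layout: cluster sizes drawn uniformly from `1..5`
#'   (truncated so the fact total is exact). Marginal counts are still
#'   exact for every seed; only the clustering — and hence the bootstrap
#'   spread — varies.
#'
#' Error facts are always placed in distinct genes.
#'
#' @param database `"ecocyc"` or `"cgd"`.
#' @param layout `"singleton"` or `"capped"`.
#' @param seed RNG seed for the capped layout's cluster sizes; ignored for
#'   singleton, which is fully deterministic.
#' @return A resolved [validation_dataset()].
#' @examples
#' summarize_rates(study_fixture("ecocyc")) # rate_final 1.40
#' @export
study_fixture <- function(database = c("ecocyc", "cgd"),
                          layout = c("singleton", "capped"),
                          seed = NULL) {
  database <- match.arg(database)
  layout <- match.arg(layout)
  m <- study_marginals[[database]]
  sizes <- if (layout == "singleton") {
    rep(1L, m$n_facts)
  } else {
    draw <- function() {
      s <- integer(0)
      while (sum(s) < m$n_facts) {
        s <- c(s, sample.int(5L, 64L, replace = TRUE))
      }
      j <- which.max(cumsum(s) >= m$n_facts)
      s <- s[seq_len(j)]
      s[j] <- s[j] - (sum(s) - m$n_facts)
      s[s > 0]
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  n_genes <- length(sizes)
  n_err_genes <- m$factual + m$citation_metadata + m$validator_mistake
  stopifnot(n_genes >= n_err_genes)
  gene_ids <- sprintf("%s-g%04d", m$label, seq_len(n_genes))
  gene <- rep(gene_ids, sizes)
  n <- m$n_facts

  # one error per gene, first fact of the cluster, genes 1..n_err_genes
  first_rows <- match(gene_ids, gene)
  category <- rep("none", n)
  err_cat <- c(
    rep("factual", m$factual),
    rep("citation_metadata", m$citation_metadata),
    rep("validator_mistake", m$validator_mistake)
  )
  category[first_rows[seq_len(n_err_genes)]] <- err_cat
  initial <- ifelse(category == "none", "correct", "error")
  final <- ifelse(category == "factual", "error", "correct")

  validation_dataset(
    tibble::tibble(
      gene_id = gene,
      fact_text = sprintf("curated assertion %d on %s", seq_len(n), gene),
      fact_type = rep_len(fact_types, n),
      initial_score = initial,
      final_score = final,
      error_category = category,
      citations = sprintf("PMID:%d", 200000 + seq_len(n)),
      validator_id = rep(
        sprintf("%s-v%d", m$label, rep_len(seq_len(m$n_validators), n_genes)),
        sizes
      ),
      comment = ""
    ),
    database_label = m$label
  )
}
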