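#' Curator rescoring of reported errors
#'
#' @description
#' In the validation protocol, every `No` verdict is re-analysed by a
#' database curator before final error counts are struck. Re-analysis
#' recognises three outcomes, encoded as correction categories:
#'
#' * `validator_mistake` — the fact was present in the cited publication
#'   after all; the record becomes final-correct.
#' * `citation_metadata` — the fact is true but the cited publication was
#'   wrong or the citation list incomplete; true elsewhere in the
#'   literature, so it is not counted as a final database error. The
#'   record becomes final-correct with this category.
#' * `confirmed_factual` — re-analysis upholds the error; the record
#'   becomes a final `error` with category `factual`.
#'
#' Corrections are explicit inputs, not heuristics: the re-analysis itself
#' was human judgment, and this function only encodes its bookkeeping.
#' Reported errors not addressed by any correction remain `unresolved` and
#' block rate computation downstream.
#'
#' @param dataset a [validation_dataset()].
#' @param corrections a data frame with columns `gene_id`, `fact_index`
#'   (1-based position within the gene's cluster), `category` (one of the
#'   three above) and optional `rationale`; see [read_corrections()].
#' @return The rescored dataset. Initially-correct records are never
#'   touched, and cluster structure and fact count are unchanged.
#'   Applying the same corrections twice is a no-op.
#' @examples
#' d <- study_fixture("ecocyc")
#' d2 <- apply_corrections(d, corrections_frame())  # empty list: identity
#' identical(d$records, d2$records)
#' @export
apply_corrections <- function(dataset, corrections) {
  stopifnot(inherits(dataset, "validation_dataset"))
  corrections <- tibble::as_tibble(corrections)
  needed <- c("gene_id", "fact_index", "category")
  missing <- setdiff(needed, names(corrections))
  if (length(missing) > 0) {
    abort_modaudit(
      sprintf("corrections missing column(s): %s", paste(missing, collapse = ", ")),
      class = "modaudit_schema_error"
    )
  }
  rec <- dataset$records
  cl <- cluster_index(rec)
  for (i in seq_len(nrow(corrections))) {
    gene <- corrections$gene_id[i]
    idx <- as.integer(corrections$fact_index[i])
    category <- corrections$category[i]
    if (!category %in% c("validator_mistake", "citation_metadata", "confirmed_factual")) {
      abort_modaudit(
        sprintf("correction %d: unknown category '%s'", i, category),
        class = "modaudit_addressing_error"
      )
    }
    # first cluster for the gene (datasets are deduplicated before rescoring)
    gene_rows <- which(rec$gene_id == gene & cl == cl[match(gene, rec$gene_id)])
    if (length(gene_rows) == 0) {
      abort_modaudit(
        sprintf("correction %d targets unknown gene '%s'", i, gene),
        class = "modaudit_addressing_error"
      )
    }
    if (is.na(idx) || idx < 1 || idx > length(gene_rows)) {
      abort_modaudit(
        sprintf(
          "correction %d: gene '%s' has %d fact(s), no fact_index %s",
          i, gene, length(gene_rows), corrections$fact_index[i]
        ),
        class = "modaudit_addressing_error"
      )
    }
    row <- gene_rows[idx]
    if (rec$initial_score[row] != "error") {
      abort_modaudit(
        sprintf(
          "correction %d targets gene '%s' fact %d, which was scored correct initially",
          i, gene, idx
        ),
        class = "modaudit_addressing_error"
      )
    }
    if (category == "confirmed_factual") {
      rec$final_score[row] <- "error"
      rec$error_category[row] <- "factual"
    } else {
      rec$final_score[row] <- "correct"
      rec$error_category[row] <- category
    }
    if ("rationale" %in% names(corrections) && nzchar(corrections$rationale[i] %||% "")) {
      rec$comment[row] <- trimws(paste(rec$comment[row], corrections$rationale[i]))
    }
  }
  dataset$records <- rec
  dataset
}

#' Read a corrections table
#'
#' @param path TSV/CSV file with columns `gene_id`, `fact_index`,
#'   `category`, `rationale`.
#' @param delim delimiter; guessed from the extension by default.
#' @return A tibble of corrections for [apply_corrections()].
#' @export
read_corrections <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort_modaudit(sprintf("file not found: %s", path), "modaudit_io_error")
  }
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      fact_index = readr::col_integer(), .default = readr::col_character()
    )
  )
}

#' An empty corrections table
#'
#' @return A zero-row tibble with the corrections schema.
#' @export
corrections_frame <- function() {
  tibble::tibble(
    gene_id = character(0), fact_index = integer(0),
    category = character(0), rationale = character(0)
  )
}

#' Tabulate error categories
#'
#' Counts records by `error_category` on a fully resolved dataset. By
#' construction `errors_initial = factual + validator_mistake +
#' citation_metadata` and `errors_final = factual`.
#'
#' @param dataset a resolved [validation_dataset()].
#' @return A one-row tibble: `database`, `n_facts`, `errors_initial`,
#'   `errors_final`, `factual`, `validator_mistake`, `citation_metadata`.
#' @export
tabulate_categories <- function(dataset) {
  stopifnot(inherits(dataset, "validation_dataset"))
  stop_if_unresolved(dataset, "tabulate_categories")
  rec <- dataset$records
  tibble::tibble(
    database = dataset$database_label,
    n_facts = nrow(rec),
    errors_initial = sum(rec$initial_score == "error"),
    errors_final = sum(rec$final_score == "error"),
    factual = sum(rec$error_category == "factual"),
    validator_mistake = sum(rec$error_category == "validator_mistake"),
    citation_metadata = sum(rec$error_category == "citation_metadata")
  )
}
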