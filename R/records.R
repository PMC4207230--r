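#' @title Validation record datasets
#'
#' @description
#' A validation dataset holds one row per checked fact, in the order the
#' facts were scored. Facts are grouped into *gene clusters*: maximal runs
#' of consecutive rows sharing a `gene_id`. The cluster, not the fact, is
#' the sampling unit of the study design (a validator picks a random gene,
#' then checks up to `cap` facts on its page), and it is the unit the
#' gene-cluster bootstrap resamples.
#'
#' Required record columns (all character):
#' \describe{
#'   \item{gene_id}{gene identifier the fact was taken from}
#'   \item{fact_text}{the curated assertion that was checked}
#'   \item{fact_type}{e.g. `GO-term`, `kinetic-parameter`, `phenotype`,
#'     `interaction`, `other`}
#'   \item{initial_score}{validator verdict: `correct` (fact found in the
#'     cited publication) or `error` (not found); `Yes`/`No` are accepted
#'     case-insensitively and normalized}
#'   \item{final_score}{status after curator re-analysis: `correct`,
#'     `error`, or `unresolved` (reported error not yet re-analysed)}
#'   \item{error_category}{`none`, `factual` (a true database error),
#'     `validator_mistake` (the fact was in the publication after all), or
#'     `citation_metadata` (fact true, citation wrong/incomplete)}
#'   \item{citations}{semicolon-separated publication identifiers}
#'   \item{validator_id}{who scored the fact}
#'   \item{comment}{free text}
#' }
#'
#' @param records a data frame with at least `gene_id`, `fact_text`,
#'   `fact_type` and `initial_score`; missing optional columns are filled
#'   with defaults and scores are normalized.
#' @param database_label label for the audited database (e.g. `"EcoCyc"`).
#' @return An object of class `validation_dataset`: a list with elements
#'   `database_label` and `records` (a tibble).
#' @examples
#' d <- validation_dataset(
#'   tibble::tibble(
#'     gene_id = c("trpA", "trpA", "ynk1"),
#'     fact_text = c("requires PLP", "Km 0.3 mM", "cytosolic"),
#'     fact_type = c("other", "kinetic-parameter", "GO-term"),
#'     initial_score = c("Yes", "Yes", "No")
#'   ),
#'   database_label = "demo"
#' )
#' n_facts(d)
#' @export
validation_dataset <- function(records, database_label = "unlabeled") {
  records <- tibble::as_tibble(records)
  required <- c("gene_id", "fact_text", "fact_type", "initial_score")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort_modaudit(
      sprintf("required column(s) missing: %s", paste(missing, collapse = ", ")),
      class = "modaudit_schema_error"
    )
  }
  optional <- c(
    final_score = NA_character_, error_category = NA_character_,
    citations = "", validator_id = "", comment = ""
  )
  for (col in names(optional)) {
    if (!col %in% names(records)) records[[col]] <- optional[[col]]
  }
  records <- normalize_scores(records)
  records <- records[, c(required, names(optional))]
  structure(
    list(database_label = database_label, records = records),
    class = "validation_dataset"
  )
}

#' @export
print.validation_dataset <- function(x, ...) {
  cl <- cluster_index(x$records)
  cat(sprintf(
    "<validation_dataset> %s: %d facts in %d gene clusters\n",
    x$database_label, nrow(x$records),
    if (nrow(x$records) == 0) 0L else max(cl)
  ))
  init <- sum(x$records$initial_score == "error")
  fin <- sum(x$records$final_score == "error")
  unres <- sum(x$records$final_score == "unresolved")
  cat(sprintf(
    "  initial errors: %d | final errors: %d | unresolved: %d\n",
    init, fin, unres
  ))
  invisible(x)
}

#' Number of facts in a dataset
#'
#' @param dataset a `validation_dataset`.
#' @return Integer count of validation records.
#' @export
n_facts <- function(dataset) {
  stopifnot(inherits(dataset, "validation_dataset"))
  nrow(dataset$records)
}

# Run-length cluster ids: consecutive rows with the same gene form a cluster.
cluster_index <- function(records) {
  if (nrow(records) == 0) return(integer(0))
  r <- rle(records$gene_id)
  rep.int(seq_along(r$lengths), r$lengths)
}

score_vocab <- list(
  initial = c(
    yes = "correct", y = "correct", correct = "correct",
    no = "error", n = "error", error = "error"
  ),
  final = c(
    yes = "correct", y = "correct", correct = "correct",
    no = "error", n = "error", error = "error",
    unresolved = "unresolved"
  ),
  category = c(
    none = "none", factual = "factual",
    validator_mistake = "validator_mistake",
    citation_metadata = "citation_metadata"
  )
)

normalize_one <- function(x, vocab, column) {
  key <- tolower(trimws(x))
  out <- unname(vocab[key])
  bad <- which(!is.na(x) & nzchar(key) & is.na(out))
  if (length(bad) > 0) {
    abort_modaudit(
      sprintf(
        "unparseable %s value '%s' at data row %d (file line %d)",
        column, x[bad[1]], bad[1], bad[1] + 1L
      ),
      class = "modaudit_parse_error"
    )
  }
  out
}

normalize_scores <- function(records) {
  records$initial_score <-
    normalize_one(records$initial_score, score_vocab$initial, "initial_score")
  if (anyNA(records$initial_score)) {
    bad <- which(is.na(records$initial_score))[1]
    abort_modaudit(
      sprintf(
        "missing initial_score at data row %d (file line %d)", bad, bad + 1L
      ),
      class = "modaudit_parse_error"
    )
  }
  fin <- normalize_one(records$final_score, score_vocab$final, "final_score")
  # blank final score: initially-correct facts are final-correct; reported
  # errors await curator re-analysis
  blank <- is.na(fin)
  fin[blank] <- ifelse(
    records$initial_score[blank] == "correct", "correct", "unresolved"
  )
  records$final_score <- fin
  cat_ <- normalize_one(
    records$error_category, score_vocab$category, "error_category"
  )
  blank <- is.na(cat_)
  cat_[blank] <- ifelse(records$final_score[blank] == "error", "factual", "none")
  records$error_category <- cat_
  records
}

record_columns <- c(
  "gene_id", "fact_text", "fact_type", "initial_score", "final_score",
  "error_category", "citations", "validator_id", "comment"
)

#' Read a validation dataset from delimited text
#'
#' Reads a TSV or CSV scoring table (one row per checked fact) into a
#' [validation_dataset()]. Rows are kept in file order; consecutive rows
#' with the same `gene_id` form a gene cluster. `Yes`/`No` verdicts are
#' normalized to `correct`/`error`; a blank `final_score` on a reported
#' error is read as `unresolved`. Columns beyond the standard schema are
#' preserved by folding them into `comment` as `name=value` pairs.
#'
#' @param path file to read.
#' @param delim field delimiter; default guesses `","` for `.csv`, tab
#'   otherwise.
#' @param database_label label for the dataset; defaults to the file name
#'   without extension.
#' @return A `validation_dataset`.
#' @seealso [write_validation()] for the inverse; the pair round-trips any
#'   valid dataset field-for-field.
#' @export
read_validation <- function(path, delim = NULL, database_label = NULL) {
  if (!file.exists(path)) {
    abort_modaudit(sprintf("file not found: %s", path), "modaudit_io_error")
  }
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE, na = character()
  )
  required <- c("gene_id", "fact_text", "fact_type", "initial_score")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_modaudit(
      sprintf(
        "required column(s) missing from %s: %s",
        path, paste(missing, collapse = ", ")
      ),
      class = "modaudit_schema_error"
    )
  }
  extra <- setdiff(names(raw), record_columns)
  if (length(extra) > 0) {
    if (!"comment" %in% names(raw)) raw$comment <- ""
    for (col in extra) {
      tag <- ifelse(nzchar(raw[[col]]), paste0(col, "=", raw[[col]]), "")
      raw$comment <- trimws(paste(raw$comment, tag))
    }
    raw <- raw[, setdiff(names(raw), extra)]
  }
  validation_dataset(
    raw,
    database_label = database_label %||% sub("\\.[^.]*$", "", basename(path))
  )
}

#' Write a validation dataset to delimited text
#'
#' @param dataset a `validation_dataset`.
#' @param path file to write (`.csv` gets commas, anything else tabs unless
#'   `delim` is given).
#' @param delim field delimiter override.
#' @return `path`, invisibly.
#' @export
write_validation <- function(dataset, path, delim = NULL) {
  stopifnot(inherits(dataset, "validation_dataset"))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(dataset$records, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Drop duplicated gene clusters
#'
#' The study's gene sampler can return the same gene more than once; the
#' protocol removes such duplications before analysis. The first cluster
#' for each `gene_id` is kept with all its records; any later cluster with
#' an already-seen `gene_id` is dropped entirely. The operation is
#' idempotent and order-stable.
#'
#' @param dataset a `validation_dataset`.
#' @return The deduplicated dataset, with attribute `dropped_genes`: the
#'   unique gene ids whose later clusters were removed (empty if none).
#' @export
dedupe_genes <- function(dataset) {
  stopifnot(inherits(dataset, "validation_dataset"))
  rec <- dataset$records
  cl <- cluster_index(rec)
  if (length(cl) == 0) {
    attr(dataset, "dropped_genes") <- character(0)
    return(dataset)
  }
  first_rows <- !duplicated(cl)
  cluster_gene <- rec$gene_id[first_rows]
  keep_cluster <- !duplicated(cluster_gene)
  dropped <- unique(cluster_gene[!keep_cluster])
  dataset$records <- rec[keep_cluster[cl], ]
  attr(dataset, "dropped_genes") <- dropped
  dataset
}

#' Check dataset integrity
#'
#' Returns human-readable descriptions of every violated invariant rather
#' than raising: scores outside the vocabulary, an initially-correct fact
#' marked as a final error, a final error not categorized `factual` (or
#' vice versa), a downgrade category on a final error, clusters longer than
#' the per-gene cap, and gene ids split across non-adjacent clusters
#' (un-deduplicated data).
#'
#' @param dataset a `validation_dataset`.
#' @param cap maximum facts per gene allowed by the protocol (default 5).
#' @return Character vector of violation descriptions; `character(0)` if
#'   the dataset is clean.
#' @export
validate_dataset <- function(dataset, cap = 5) {
  stopifnot(inherits(dataset, "validation_dataset"))
  rec <- dataset$records
  out <- character(0)
  say <- function(rows, fmt) {
    if (length(rows) > 0) {
      sprintf(fmt, rows, rec$gene_id[rows])
    } else {
      character(0)
    }
  }
  bad <- which(!rec$initial_score %in% c("correct", "error"))
  out <- c(out, say(bad, "row %d (gene %s): initial_score outside {correct, error}"))
  bad <- which(!rec$final_score %in% c("correct", "error", "unresolved"))
  out <- c(out, say(bad, "row %d (gene %s): final_score outside {correct, error, unresolved}"))
  bad <- which(!rec$error_category %in% score_vocab$category)
  out <- c(out, say(bad, "row %d (gene %s): unknown error_category"))

  bad <- which(
    rec$initial_score == "correct" &
      (rec$final_score != "correct" | rec$error_category != "none")
  )
  out <- c(out, say(
    bad, "row %d (gene %s): initially-correct fact must stay correct with category 'none'"
  ))
  bad <- which(xor(rec$final_score == "error", rec$error_category == "factual"))
  out <- c(out, say(
    bad, "row %d (gene %s): final_score 'error' and category 'factual' must coincide"
  ))
  bad <- which(
    rec$error_category %in% c("validator_mistake", "citation_metadata") &
      rec$final_score != "correct"
  )
  out <- c(out, say(
    bad, "row %d (gene %s): a downgraded error must be final-correct"
  ))

  cl <- cluster_index(rec)
  if (length(cl) > 0) {
    sizes <- tabulate(cl)
    big <- which(sizes > cap)
    if (length(big) > 0) {
      genes <- rec$gene_id[!duplicated(cl)][big]
      out <- c(out, sprintf(
        "cluster %d (gene %s): %d facts exceeds the per-gene cap of %d",
        big, genes, sizes[big], cap
      ))
    }
    cluster_gene <- rec$gene_id[!duplicated(cl)]
    dup <- unique(cluster_gene[duplicated(cluster_gene)])
    if (length(dup) > 0) {
      out <- c(out, sprintf(
        "gene %s appears in more than one cluster (run dedupe_genes)", dup
      ))
    }
  }
  out
}

# TRUE when no reported error still awaits curator re-analysis.
is_resolved <- function(dataset) {
  !any(dataset$records$final_score == "unresolved")
}

stop_if_unresolved <- function(dataset, what) {
  n <- sum(dataset$records$final_score == "unresolved")
  if (n > 0) {
    abort_modaudit(
      sprintf(
        "%s requires a resolved dataset: %d record(s) in '%s' are unresolved (apply corrections first)",
        what, n, dataset$database_label
      ),
      class = "modaudit_state_error"
    )
  }
  invisible(dataset)
}
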