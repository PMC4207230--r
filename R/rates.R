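#' Error rate of a validated fact set
#'
#' The error rate is the fraction of checked database assertions that are
#' not supported by their cited publication, expressed as a percent:
#' `100 * errors / facts`. Because the study measures false-positive
#' assertions, this is the complement of curation precision
#' (`precision% = 100 - error rate`).
#'
#' @param errors number of facts in error.
#' @param facts number of facts checked; must be positive.
#' @return The rate as a percent, unrounded. Round only at presentation
#'   ([round_half_up()] to 2 decimals is the package convention).
#' @examples
#' round_half_up(error_rate(5, 358))  # 1.40
#' round_half_up(error_rate(10, 633)) # 1.58
#' @export
error_rate <- function(errors, facts) {
  if (any(facts <= 0)) {
    abort_modaudit(
      "error rate undefined for zero facts checked",
      class = "modaudit_state_error"
    )
  }
  if (any(errors < 0 | errors > facts)) {
    abort_modaudit(
      "errors must lie in [0, facts]",
      class = "modaudit_state_error"
    )
  }
  100 * errors / facts
}

#' Summarize error rates per database and pooled
#'
#' Produces the study's headline summary: one row per database plus a
#' pooled row. Pooled counts are sums; the pooled rate is computed from
#' pooled counts (`100 * sum(errors) / sum(facts)`), never by averaging
#' per-database rates. Rates are rounded half-up to 2 decimals; note that
#' for ratios whose third decimal is ≥ 5 this can differ by 0.01 from a
#' truncated display (13/275 = 4.7273 prints 4.73 here).
#'
#' @param datasets a `validation_dataset` or list of them, all resolved.
#' @param pooled_label label for the pooled row (default `"pooled"`).
#' @return A tibble with columns `database`, `n_validators`,
#'   `facts_checked`, `errors_initial`, `errors_final`, `rate_initial`,
#'   `rate_final`; the last row is the pooled summary.
#' @examples
#' summarize_rates(list(study_fixture("ecocyc"), study_fixture("cgd")))
#' @export
summarize_rates <- function(datasets, pooled_label = "pooled") {
  if (inherits(datasets, "validation_dataset")) datasets <- list(datasets)
  if (length(datasets) == 0) {
    abort_modaudit("no datasets to summarize", class = "modaudit_state_error")
  }
  rows <- lapply(datasets, function(d) {
    stopifnot(inherits(d, "validation_dataset"))
    stop_if_unresolved(d, "summarize_rates")
    counts <- tabulate_categories(d)
    ids <- unique(d$records$validator_id)
    tibble::tibble(
      database = d$database_label,
      n_validators = length(ids[nzchar(ids)]),
      facts_checked = counts$n_facts,
      errors_initial = counts$errors_initial,
      errors_final = counts$errors_final
    )
  })
  per_db <- dplyr::bind_rows(rows)
  all_ids <- unlist(lapply(datasets, function(d) unique(d$records$validator_id)))
  pooled <- tibble::tibble(
    database = pooled_label,
    n_validators = length(unique(all_ids[nzchar(all_ids)])),
    facts_checked = sum(per_db$facts_checked),
    errors_initial = sum(per_db$errors_initial),
    errors_final = sum(per_db$errors_final)
  )
  out <- dplyr::bind_rows(per_db, pooled)
  out$rate_initial <- round_half_up(error_rate(out$errors_initial, out$facts_checked))
  out$rate_final <- round_half_up(error_rate(out$errors_final, out$facts_checked))
  out
}

#' Render a rate summary as text
#'
#' @param summary output of [summarize_rates()].
#' @param format `"tsv"` or `"markdown"`.
#' @return A character vector of lines.
#' @export
format_rate_table <- function(summary, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  labels <- c(
    database = "Database", n_validators = "Validators",
    facts_checked = "Facts checked",
    errors_initial = "Facts in error: initial",
    errors_final = "Facts in error: final",
    rate_initial = "Error rate: initial",
    rate_final = "Error rate: final"
  )
  vals <- summary
  vals$rate_initial <- sprintf("%.2f%%", vals$rate_initial)
  vals$rate_final <- sprintf("%.2f%%", vals$rate_final)
  cells <- rbind(
    unname(labels),
    t(vapply(seq_len(nrow(vals)), function(i) {
      vapply(names(labels), function(col) as.character(vals[[col]][i]), "")
    }, character(length(labels))))
  )
  if (format == "tsv") {
    apply(cells, 1, paste, collapse = "\t")
  } else {
    width <- apply(nchar(cells), 2, max)
    pad <- function(row) {
      padded <- mapply(
        function(s, w) formatC(s, width = w, flag = "-"), row, width
      )
      paste0("| ", paste(padded, collapse = " | "), " |")
    }
    c(
      pad(cells[1, ]),
      pad(strrep("-", width)),
      apply(cells[-1, , drop = FALSE], 1, pad)
    )
  }
}
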