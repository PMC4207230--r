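#' Configure the gene-cluster bootstrap
#'
#' @description
#' Uncertainty in the reported error rate cannot be assessed with textbook
#' binomial formulas because facts were not sampled uniformly: the protocol
#' first samples genes, then checks a variable number of facts per gene, so
#' facts within a gene are not independent draws. The bootstrap therefore
#' mimics the sampling design itself: each replicate draws genes uniformly
#' with replacement from those seen during validation, each drawn gene
#' contributes *all* of its validated facts, and drawing stops once the
#' replicate holds at least the original number of facts. The last gene is
#' truncated so every replicate has exactly the original fact count.
#'
#' @param n_replicates number of bootstrap replicates (default 10000).
#' @param ci_levels two quantile probabilities for the percentile interval
#'   (default `c(0.025, 0.975)`, a 95% CI).
#' @param seed RNG seed for reproducibility; `NULL` uses the current RNG
#'   state.
#' @param truncation_policy how the overshooting final gene is cut back:
#'   `"prefix"` keeps its facts in stored order up to the quota
#'   (deterministic given the gene draws); `"random_subset"` keeps a
#'   uniform random subset of the required size.
#' @param statistic `"final_rate"` (error rate after curator rescoring, the
#'   reported quantity) or `"initial_rate"` (raw validator verdicts).
#' @return A `bootstrap_config` list.
#' @seealso [run_bootstrap()]
#' @export
bootstrap_config <- function(n_replicates = 10000,
                             ci_levels = c(0.025, 0.975),
                             seed = NULL,
                             truncation_policy = c("prefix", "random_subset"),
                             statistic = c("final_rate", "initial_rate")) {
  truncation_policy <- match.arg(truncation_policy)
  statistic <- match.arg(statistic)
  if (n_replicates < 1) {
    abort_modaudit("n_replicates must be at least 1", "modaudit_state_error")
  }
  if (length(ci_levels) != 2 || !all(ci_levels > 0 & ci_levels < 1) ||
      ci_levels[1] >= ci_levels[2]) {
    abort_modaudit(
      "ci_levels must be two probabilities with 0 < lower < upper < 1",
      class = "modaudit_state_error"
    )
  }
  structure(
    list(
      n_replicates = as.integer(n_replicates), ci_levels = ci_levels,
      seed = seed, truncation_policy = truncation_policy,
      statistic = statistic
    ),
    class = "bootstrap_config"
  )
}

# Per-cluster summaries used by the resampler: sizes, row indices, and
# cumulative error counts over each cluster's stored fact order.
cluster_table <- function(dataset, statistic = "final_rate") {
  rec <- dataset$records
  cl <- cluster_index(rec)
  err <- if (statistic == "initial_rate") {
    rec$initial_score == "error"
  } else {
    rec$final_score == "error"
  }
  rows <- split(seq_len(nrow(rec)), cl)
  list(
    sizes = lengths(rows),
    rows = rows,
    # prefix_err[[i]][m + 1] = errors among the first m facts of cluster i
    prefix_err = lapply(rows, function(r) c(0L, cumsum(err[r]))),
    total_err = vapply(rows, function(r) sum(err[r]), 0L)
  )
}

# Draw one replicate's gene sequence and return the cut point. Consumes one
# sample.int() call; guaranteed to reach the quota because the block size
# assumes every draw contributes only the smallest cluster.
draw_genes <- function(ct, quota) {
  n_clusters <- length(ct$sizes)
  block <- ceiling(quota / min(ct$sizes))
  g <- sample.int(n_clusters, block, replace = TRUE)
  cum <- cumsum(ct$sizes[g])
  j <- which.max(cum >= quota)
  list(
    genes = g[seq_len(j)],
    keep_last = quota - (if (j > 1) cum[j - 1] else 0L)
  )
}

# Error count of one replicate, consuming RNG in documented order: the gene
# block draw, then (random_subset policy only, and only when the last gene
# is actually truncated) one subset draw.
replicate_errors <- function(ct, quota, policy) {
  d <- draw_genes(ct, quota)
  j <- length(d$genes)
  last <- d$genes[j]
  full <- sum(ct$total_err[d$genes[-j]])
  if (d$keep_last == ct$sizes[last]) {
    full + ct$total_err[last]
  } else if (policy == "prefix") {
    full + ct$prefix_err[[last]][d$keep_last + 1L]
  } else {
    kept <- sample(seq_len(ct$sizes[last]), d$keep_last)
    errs <- diff(ct$prefix_err[[last]])
    full + sum(errs[kept])
  }
}

#' Draw one bootstrap replicate of validation records
#'
#' Single resampling step of the gene-cluster bootstrap: genes drawn
#' uniformly with replacement, each contributing all its facts, truncated
#' at the original fact count. Uses (and advances) the current RNG state;
#' seed management belongs to [run_bootstrap()].
#'
#' @param dataset a resolved, non-empty [validation_dataset()].
#' @param truncation_policy `"prefix"` or `"random_subset"`; see
#'   [bootstrap_config()].
#' @return A tibble of resampled records with exactly `n_facts(dataset)`
#'   rows; genes may appear multiple times.
#' @export
resample_once <- function(dataset, truncation_policy = c("prefix", "random_subset")) {
  truncation_policy <- match.arg(truncation_policy)
  stopifnot(inherits(dataset, "validation_dataset"))
  if (n_facts(dataset) == 0) {
    abort_modaudit("cannot resample an empty dataset", "modaudit_state_error")
  }
  stop_if_unresolved(dataset, "resample_once")
  ct <- cluster_table(dataset)
  d <- draw_genes(ct, n_facts(dataset))
  j <- length(d$genes)
  rows <- ct$rows[d$genes]
  last <- d$genes[j]
  rows[[j]] <- if (d$keep_last == ct$sizes[last] ||
                   truncation_policy == "prefix") {
    ct$rows[[last]][seq_len(d$keep_last)]
  } else {
    ct$rows[[last]][sort(sample(seq_len(ct$sizes[last]), d$keep_last))]
  }
  dataset$records[unlist(rows), ]
}

#' Run the gene-cluster bootstrap
#'
#' Generates `n_replicates` resampled fact sets (see [resample_once()]),
#' computes the error rate of each, and summarizes the bootstrap
#' distribution: its sample standard deviation (an estimate of the
#' standard error of the reported rate) and an empirical percentile
#' confidence interval. Quantiles use the inverse-ECDF definition
#' (`type = 1`), so interval endpoints are always realized replicate
#' values; with discrete error counts this makes the endpoints insensitive
#' to interpolation at 10000 replicates.
#'
#' @param dataset a resolved, non-empty [validation_dataset()].
#' @param config a [bootstrap_config()].
#' @return A `bootstrap_result` list: `point_estimate`, `replicate_rates`
#'   (percent, length `n_replicates`), `sd`, `ci` (named by level),
#'   `n_facts`, `seed`, `config`. Identical seeds give identical results.
#' @examples
#' d <- study_fixture("ecocyc")
#' b <- run_bootstrap(d, bootstrap_config(n_replicates = 500, seed = 1))
#' round_half_up(b$ci)
#' @export
run_bootstrap <- function(dataset, config = bootstrap_config()) {
  stopifnot(inherits(dataset, "validation_dataset"),
            inherits(config, "bootstrap_config"))
  if (n_facts(dataset) == 0) {
    abort_modaudit("cannot bootstrap an empty dataset", "modaudit_state_error")
  }
  stop_if_unresolved(dataset, "run_bootstrap")
  ct <- cluster_table(dataset, config$statistic)
  quota <- n_facts(dataset)
  run <- function() {
    vapply(
      seq_len(config$n_replicates),
      function(i) replicate_errors(ct, quota, config$truncation_policy),
      numeric(1)
    )
  }
  errs <- if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
  rates <- 100 * errs / quota
  ci <- quantile(rates, probs = config$ci_levels, type = 1, names = FALSE)
  point <- error_rate(
    if (config$statistic == "initial_rate") {
      sum(dataset$records$initial_score == "error")
    } else {
      sum(dataset$records$final_score == "error")
    },
    quota
  )
  structure(
    list(
      database_label = dataset$database_label,
      point_estimate = point,
      replicate_rates = rates,
      sd = sd(rates),
      ci = stats::setNames(ci, paste0(100 * config$ci_levels, "%")),
      n_facts = quota,
      seed = config$seed,
      config = config
    ),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> %s: %s of %d facts\n",
    x$database_label, x$config$statistic, x$n_facts
  ))
  cat(sprintf(
    "  point %.2f%% | bootstrap SD %.2f%% | CI [%s] (%.2f%%, %.2f%%) | %d replicates | seed %s\n",
    round_half_up(x$point_estimate), round_half_up(x$sd),
    paste(names(x$ci), collapse = ", "),
    round_half_up(x$ci[1]), round_half_up(x$ci[2]),
    x$config$n_replicates,
    if (is.null(x$seed)) "none" else format(x$seed)
  ))
  invisible(x)
}

#' Exact binomial quantiles of an error rate
#'
#' Independent reference for the singleton-gene limit of the cluster
#' bootstrap: when every gene contributes exactly one fact, a bootstrap
#' replicate is an iid resample of facts, so its error count is
#' `Binomial(n, k/n)` and the percentile CI endpoints converge to the exact
#' binomial quantiles divided by `n`.
#'
#' @param n number of facts.
#' @param k number of facts in error (`0 <= k <= n`).
#' @param levels quantile probabilities (default `c(0.025, 0.975)`).
#' @return Named numeric vector of rates (percent), unrounded.
#' @examples
#' round_half_up(binomial_oracle(358, 5)) # 0.28, 2.79
#' round_half_up(binomial_oracle(275, 5)) # 0.36, 3.64
#' @export
binomial_oracle <- function(n, k, levels = c(0.025, 0.975)) {
  stopifnot(n > 0, k >= 0, k <= n)
  q <- qbinom(levels, size = n, prob = k / n)
  stats::setNames(100 * q / n, paste0(100 * levels, "%"))
}
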