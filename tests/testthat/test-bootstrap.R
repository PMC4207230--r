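test_that("bootstrap_config validates its inputs", {
  cfg <- bootstrap_config()
  expect_equal(cfg$n_replicates, 10000L)
  expect_equal(cfg$ci_levels, c(0.025, 0.975))
  expect_equal(cfg$truncation_policy, "prefix")
  expect_error(bootstrap_config(n_replicates = 0), class = "modaudit_state_error")
  expect_error(bootstrap_config(ci_levels = c(0.975, 0.025)),
               class = "modaudit_state_error")
  expect_error(bootstrap_config(ci_levels = c(0, 0.9)),
               class = "modaudit_state_error")
})

test_that("every replicate has exactly the original fact count", {
  withr::with_seed(31, {
    for (i in 1:60) {
      d <- random_dataset()
      for (policy in c("prefix", "random_subset")) {
        expect_equal(nrow(resample_once(d, policy)), n_facts(d))
      }
    }
  })
})

test_that("degenerate datasets resample predictably", {
  one_gene <- toy_dataset(rep("A", 3), c("factual", "none", "none"))
  withr::with_seed(1, {
    for (i in 1:5) {
      rep_ <- resample_once(one_gene)
      expect_equal(rep_$gene_id, rep("A", 3))
      expect_equal(sum(rep_$final_score == "error"), 1)
    }
  })
  b <- run_bootstrap(one_gene, bootstrap_config(n_replicates = 200, seed = 2))
  expect_equal(b$sd, 0)
  expect_equal(unname(b$ci), rep(b$point_estimate, 2))

  clean <- toy_dataset(c("A", "A", "B", "C"))
  b0 <- run_bootstrap(clean, bootstrap_config(n_replicates = 200, seed = 3))
  expect_equal(b0$sd, 0)
  expect_equal(unname(b0$ci), c(0, 0))

  expect_error(resample_once(toy_dataset(character(0))),
               class = "modaudit_state_error")
  expect_error(run_bootstrap(toy_dataset(character(0))),
               class = "modaudit_state_error")
})

test_that("two size-3 clusters truncate to exactly 5 of 6 facts", {
  d <- toy_dataset(rep(c("A", "B"), each = 3))
  d$records <- d$records[-6, ] # sizes {3, 2}, n_facts 5: truncation must occur
  withr::with_seed(13, {
    for (i in 1:20) {
      rep_ <- resample_once(d)
      expect_equal(nrow(rep_), 5)
      # prefix policy: within each gene, a fact can only appear if every
      # earlier-stored fact of that gene appears at least as often
      for (g in unique(rep_$gene_id)) {
        stored <- d$records$fact_text[d$records$gene_id == g]
        counts <- vapply(stored, function(f) {
          sum(rep_$gene_id == g & rep_$fact_text == f)
        }, 0L)
        expect_true(all(diff(counts) <= 0))
      }
    }
  })
})

test_that("a fixed seed gives bit-identical bootstrap results", {
  d <- study_fixture("cgd", "capped", seed = 9)
  for (policy in c("prefix", "random_subset")) {
    cfg <- bootstrap_config(n_replicates = 300, seed = 17,
                            truncation_policy = policy)
    a <- run_bootstrap(d, cfg)
    b <- run_bootstrap(d, cfg)
    expect_identical(a$replicate_rates, b$replicate_rates)
    expect_identical(a$ci, b$ci)
    expect_identical(a$sd, b$sd)
  }
  # different seeds explore different replicates
  a <- run_bootstrap(d, bootstrap_config(n_replicates = 300, seed = 17))
  c_ <- run_bootstrap(d, bootstrap_config(n_replicates = 300, seed = 18))
  expect_false(identical(a$replicate_rates, c_$replicate_rates))
})

test_that("binomial oracle matches its closed-form CDF definition", {
  # smallest x with P(Binom(n, k/n) <= x) >= level, via direct summation
  cdf_quantile <- function(n, k, level) {
    p <- k / n
    cdf <- cumsum(dbinom(0:n, n, p))
    (which(cdf >= level)[1] - 1)
  }
  for (case in list(c(358, 5), c(275, 5), c(100, 0), c(50, 3))) {
    n <- case[1]; k <- case[2]
    expected <- 100 * c(
      cdf_quantile(n, k, 0.025), cdf_quantile(n, k, 0.975)
    ) / n
    expect_equal(unname(binomial_oracle(n, k)), expected)
  }
  expect_equal(unname(round_half_up(binomial_oracle(358, 5))), c(0.28, 2.79))
  expect_equal(unname(round_half_up(binomial_oracle(275, 5))), c(0.36, 3.64))
  expect_equal(unname(binomial_oracle(100, 0)), c(0, 0))
})

test_that("singleton-gene bootstrap agrees with the exact binomial oracle", {
  # with one fact per gene the cluster bootstrap is an iid fact bootstrap
  d <- study_fixture("ecocyc", "singleton")
  b <- run_bootstrap(d, bootstrap_config(n_replicates = 4000, seed = 21))
  expect_equal(round_half_up(b$ci), round_half_up(binomial_oracle(358, 5)),
               ignore_attr = TRUE)
})

test_that("initial-rate statistic bootstraps the raw verdicts", {
  d <- study_fixture("ecocyc")
  b <- run_bootstrap(d, bootstrap_config(
    n_replicates = 500, seed = 4, statistic = "initial_rate"
  ))
  expect_equal(b$point_estimate, error_rate(8, 358))
  expect_gt(mean(b$replicate_rates), error_rate(5, 358))
})

test_that("the bootstrap distribution is centred on the point estimate", {
  withr::with_seed(41, {
    for (i in 1:5) {
      d <- random_dataset(max_genes = 12, p_error = 0.15)
      if (sum(d$records$final_score == "error") == 0) next
      b <- run_bootstrap(d, bootstrap_config(n_replicates = 2000, seed = i))
      mc_se <- b$sd / sqrt(b$config$n_replicates)
      expect_lt(
        abs(mean(b$replicate_rates) - b$point_estimate),
        3 * max(mc_se, 1e-8)
      )
    }
  })
})

test_that("replicating clusters k-fold does not increase the bootstrap SD", {
  base <- study_fixture("cgd", "capped", seed = 2)
  sd_for <- function(d, seed) {
    run_bootstrap(d, bootstrap_config(n_replicates = 2000, seed = seed))$sd
  }
  sd1 <- sd_for(base, 101)
  for (k in c(2, 4)) {
    big <- base
    reps <- lapply(seq_len(k), function(j) {
      r <- base$records
      r$gene_id <- paste0(r$gene_id, "-copy", j)
      r
    })
    big$records <- do.call(rbind, reps)
    sdk <- sd_for(big, 101 + k)
    mc_se <- sd1 / sqrt(2 * (2000 - 1))
    expect_lte(sdk, sd1 + 2 * mc_se)
  }
})
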