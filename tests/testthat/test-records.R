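test_that("reading groups facts into gene clusters in file order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(
    raw_scoring_tibble(c("A", "A", "B"), c("Yes", "yes", "YES")), path,
    progress = FALSE
  )
  d <- read_validation(path)
  expect_s3_class(d, "validation_dataset")
  expect_equal(n_facts(d), 3)
  expect_equal(max(modaudit:::cluster_index(d$records)), 2)
  # Yes/No vocabulary is normalized case-insensitively
  expect_equal(unique(d$records$initial_score), "correct")
  expect_equal(unique(d$records$final_score), "correct")
})

test_that("a header-only file reads as an empty dataset", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(raw_scoring_tibble(character(0), character(0)), path,
                   progress = FALSE)
  d <- read_validation(path)
  expect_equal(n_facts(d), 0)
  expect_equal(length(modaudit:::cluster_index(d$records)), 0)
  expect_equal(validate_dataset(d), character(0))
})

test_that("schema and parse failures name the column and the row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  bad <- raw_scoring_tibble("A", "Yes")
  readr::write_tsv(bad[, setdiff(names(bad), "initial_score")], path,
                   progress = FALSE)
  expect_error(
    read_validation(path),
    "initial_score", class = "modaudit_schema_error"
  )

  readr::write_tsv(raw_scoring_tibble(c("A", "B"), c("Yes", "maybe")), path,
                   progress = FALSE)
  expect_error(
    read_validation(path),
    "row 2 \\(file line 3\\)", class = "modaudit_parse_error"
  )
})

test_that("blank final scores resolve to correct or unresolved by initial verdict", {
  d <- validation_dataset(raw_scoring_tibble(c("A", "B"), c("Yes", "No")))
  expect_equal(d$records$final_score, c("correct", "unresolved"))
  expect_equal(d$records$error_category, c("none", "none"))
})

test_that("write/read round-trips datasets field-for-field", {
  cases <- list(
    study_fixture("ecocyc"),
    study_fixture("cgd", "capped", seed = 7),
    toy_dataset(c("A", "A", "B"), c("none", "factual", "citation_metadata")),
    # embedded delimiters must be quoted, not split
    validation_dataset(tibble::tibble(
      gene_id = "A", fact_text = "Km = 0.3 mM, pH 7.5\ttabbed",
      fact_type = "kinetic-parameter", initial_score = "Yes"
    )),
    toy_dataset(character(0))
  )
  for (ext in c(".tsv", ".csv")) {
    for (d in cases) {
      path <- withr::local_tempfile(fileext = ext)
      write_validation(d, path)
      back <- read_validation(path, database_label = d$database_label)
      expect_equal(back$records, d$records)
      expect_equal(n_facts(back), n_facts(d))
    }
  }
})

test_that("unknown extra columns are preserved as comment metadata", {
  path <- withr::local_tempfile(fileext = ".tsv")
  extra <- raw_scoring_tibble("A", "Yes")
  extra$curator_note <- "double-checked"
  readr::write_tsv(extra, path, progress = FALSE)
  d <- read_validation(path)
  expect_match(d$records$comment, "curator_note=double-checked")
})

test_that("dedupe keeps the first cluster per gene and drops later ones whole", {
  d <- toy_dataset(c("A", "A", "B", "A", "A", "A"))
  out <- dedupe_genes(d)
  expect_equal(out$records$gene_id, c("A", "A", "B"))
  expect_equal(attr(out, "dropped_genes"), "A")

  clean <- toy_dataset(c("A", "B", "C"))
  expect_equal(dedupe_genes(clean)$records, clean$records)
  expect_equal(attr(dedupe_genes(clean), "dropped_genes"), character(0))

  same <- toy_dataset(c("A", "A", "A", "A"))
  # three singleton repeats of one gene collapse to the first cluster only
  split_runs <- toy_dataset(c("A", "A"))
  split_runs$records <- rbind(split_runs$records, toy_dataset("B")$records,
                              toy_dataset("A")$records)
  expect_equal(dedupe_genes(split_runs)$records$gene_id, c("A", "A", "B"))
  expect_equal(n_facts(dedupe_genes(same)), 4) # one contiguous run, no dupes
})

test_that("dedupe is idempotent and conserves kept facts", {
  withr::with_seed(11, {
    for (i in 1:20) {
      d <- random_dataset()
      # inject duplicate clusters: a separator gene keeps the duplicated
      # runs non-adjacent (adjacent same-gene rows merge into one cluster)
      sep <- toy_dataset("zz-sep")$records
      dup <- d
      dup$records <- rbind(d$records, sep, d$records)
      once <- dedupe_genes(dup)
      twice <- dedupe_genes(once)
      expect_equal(twice$records, once$records)
      expect_equal(once$records, rbind(d$records, sep))
    }
  })
})

test_that("validate_dataset reports invariant breaches and clean data as empty", {
  d <- toy_dataset(c("A", "B"), c("none", "factual"))
  expect_equal(validate_dataset(d), character(0))

  broken <- d
  broken$records$final_score[1] <- "error" # initially correct, final error
  v <- validate_dataset(broken)
  expect_length(v, 2) # breaks initial⇒final and final⇔factual
  expect_match(v[1], "initially-correct")

  downgrade <- toy_dataset("A", "validator_mistake")
  downgrade$records$final_score <- "error"
  expect_true(any(grepl("downgraded", validate_dataset(downgrade))))

  big <- toy_dataset(rep("A", 6))
  expect_match(validate_dataset(big, cap = 5), "exceeds the per-gene cap")
  expect_equal(validate_dataset(big, cap = 6), character(0))

  undeduped <- toy_dataset(c("A", "B", "A"))
  expect_match(validate_dataset(undeduped), "more than one cluster")
})

test_that("generated and fixture datasets always validate cleanly", {
  withr::with_seed(5, {
    for (i in 1:10) {
      expect_equal(validate_dataset(random_dataset()), character(0))
    }
  })
  expect_equal(validate_dataset(generate_dataset(
    generator_config(n_genes = 100, seed = 3)
  )), character(0))
  expect_equal(validate_dataset(study_fixture("ecocyc")), character(0))
  expect_equal(validate_dataset(study_fixture("cgd", "capped", seed = 1)),
               character(0))
})
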