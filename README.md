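# modaudit

Curation accuracy auditing for model organism databases (MODs).

Biological databases such as EcoCyc and the *Candida* Genome Database are
built by biocuration — scientists reading publications and transcribing
facts into gene pages. `modaudit` implements the statistics of auditing
that process: external validators check whether randomly sampled facts are
actually supported by their cited publications, a curator re-analyses every
reported error, and the package turns the resulting records into error-rate
estimates with honest uncertainty.

The quantity estimated is the **false-positive assertion rate**

> r = 100 · (facts not supported by their cited publication) / (facts checked),

the complement of curation precision. Because the audit samples *genes*
first and then up to five facts per gene, facts are not independent draws,
and a textbook binomial interval for r would be wrong. Uncertainty is
instead quantified with a **gene-cluster bootstrap**: each of 10 000
replicates draws genes uniformly with replacement from those seen during
validation, each drawn gene contributes all its validated facts, and the
replicate is truncated to exactly the original fact count n. The bootstrap
SD estimates the standard error of r; the 2.5th/97.5th percentiles give a
95% CI. In the singleton-gene limit the scheme reduces to an iid fact
bootstrap, and the package ships an exact Binomial(n, k/n) quantile oracle
(`binomial_oracle()`) as an independent cross-check.

The package covers the full pipeline:

| Stage | Functions |
| ----- | --------- |
| Records & I/O | `read_validation()`, `write_validation()`, `dedupe_genes()`, `validate_dataset()` |
| Curator rescoring | `apply_corrections()`, `tabulate_categories()` |
| Rates | `error_rate()`, `summarize_rates()` |
| Uncertainty | `run_bootstrap()`, `resample_once()`, `binomial_oracle()` |
| Simulation | `generate_dataset()`, `study_fixture()` |
| End to end | `run_pipeline()`, CLI at `inst/cli/audit.R` |

See `vignettes/curation-audit-methods.Rmd` for the model, its assumptions
and the numerical choices.

## Worked example

Reconstructions of the two published audits (EcoCyc: 358 facts, 8 reported
errors of which 5 held up; CGD: 275 facts, 13 reported, 5 held up) are built
in; `summarize_rates()` produces the audit summary:

```r
library(modaudit)
s <- summarize_rates(list(study_fixture("ecocyc"), study_fixture("cgd")))
writeLines(format_rate_table(s, "markdown"))
```

```
| Database | Validators | Facts checked | Facts in error: initial | Facts in error: final | Error rate: initial | Error rate: final |
| -------- | ---------- | ------------- | ----------------------- | --------------------- | ------------------- | ----------------- |
| EcoCyc   | 4          | 358           | 8                       | 5                     | 2.23%               | 1.40%             |
| CGD      | 4          | 275           | 13                      | 5                     | 4.73%               | 1.82%             |
| pooled   | 8          | 633           | 21                      | 10                    | 3.32%               | 1.58%             |
```

The *initial* rate counts every validator `No`; the *final* rate counts
only errors that survived curator re-analysis (validator mistakes and
citation-metadata problems are downgraded). The pooled final rate, 10
errors in 633 facts = 1.58%, is computed from pooled counts, not averaged
rates. (13/275 rounds half-up to 4.73; displays that truncate show 4.72.)

Uncertainty for one database:

```r
b <- run_bootstrap(study_fixture("ecocyc"), bootstrap_config(seed = 20260920))
b
#> <bootstrap_result> EcoCyc: final_rate of 358 facts
#>   point 1.40% | bootstrap SD 0.62% | CI [2.5%, 97.5%] (0.28%, 2.79%) | 10000 replicates | seed 20260920

round_half_up(binomial_oracle(358, 5))
#>  2.5% 97.5%
#>  0.28  2.79
```

So the EcoCyc error rate is 1.40% with standard error ≈ 0.62% and 95% CI
(0.28%, 2.79%) — and in this singleton-gene reconstruction the bootstrap
endpoints coincide with the exact binomial quantiles, as they should.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/audit.R fixture ecocyc -o ecocyc.tsv
Rscript inst/cli/audit.R bootstrap ecocyc.tsv --replicates 10000 --seed 1
Rscript inst/cli/audit.R run --config run.yaml
```

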