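---
title: "Estimating biocuration error rates with a gene-cluster bootstrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating biocuration error rates with a gene-cluster bootstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modaudit)
```

## The problem

Model organism databases (MODs) such as EcoCyc (for *Escherichia coli*) and
the *Candida* Genome Database (CGD) are built by biocuration: Ph.D-level
scientists read publications and transcribe facts — GO term assignments,
kinetic constants, phenotypes, interactions — into structured gene pages.
How often is a curated fact *not actually supported* by the publication it
cites? Such false-positive assertions are the error type modaudit measures;
their rate is the complement of curation precision. Errors of omission
(facts the curator should have captured but did not) and errors of
specificity are a different measurement problem and are out of scope.

The measurement design is a two-stage audit:

1. a web service picks genes at random;
2. a validator — a scientist outside the database's own team — chooses up
   to five literature-supported facts on each gene page, retrieves the
   cited publication, and scores the fact `Yes` (found) or `No` (not
   found);
3. a database curator re-analyses every reported `No` with the validator.

Stage 3 exists because validators themselves make mistakes, and because a
`No` is sometimes a citation problem rather than a factual one. modaudit
encodes the bookkeeping of this design: the record schema, the rescoring
taxonomy, the rate summaries, and — the statistically interesting part — an
uncertainty estimate that respects the gene-level sampling.

## The record model

One row per checked fact. Rows are ordered; consecutive rows sharing a
`gene_id` form a *gene cluster*, the sampling unit. Three invariants tie the
two scoring passes together, and `validate_dataset()` enforces them:

* an initially-correct fact is final-correct with category `none` (the
  curator pass only re-examines reported errors);
* `final_score == "error"` exactly when `error_category == "factual"`;
* a downgraded error (`validator_mistake` or `citation_metadata`) is
  final-correct.

A reported error that no correction has addressed yet is `unresolved`; every
rate computation refuses unresolved data rather than guessing, mirroring the
fact that the audit resolved every reported error before counting. Duplicate
genes from the random sampler are removed by `dedupe_genes()` with a
first-cluster-wins rule — the protocol only says duplicates were removed, so
the package picks the deterministic, order-stable option. Corrections are an
explicit input table, never a heuristic: the re-analysis itself was human
judgment, and the package refuses to imitate it.

## Rates

`error_rate(errors, facts)` is `100 * errors / facts`, kept unrounded until
presentation. `summarize_rates()` adds a pooled row whose counts are sums
and whose rate is computed from the pooled counts — pooling rates by
averaging would weight a small audit equally with a large one.

Presentation rounding is half-up to two decimals (`round_half_up()`), which
reproduces the published 1.40, 1.82, 2.23 and 1.58. One caveat worth
flagging: 13/275 = 4.7273 rounds half-up to 4.73, while the published table
shows 4.72 (apparent truncation). The package keeps a single consistent
rounding rule and documents the disagreement rather than special-casing it.

## The gene-cluster bootstrap

A textbook binomial interval for the error rate would assume facts were
sampled independently and uniformly. They were not: genes were sampled, and
each gene contributed a variable number of facts, which are correlated (one
publication often supports several facts on the same page, and one curator
wrote them). Enumerating all facts in a database to sample them uniformly
would be prohibitively expensive, which is exactly why the audit sampled
genes. The bootstrap therefore mimics the design:

* draw genes uniformly **with replacement** from the genes seen during
  validation;
* each drawn gene contributes **all** of its validated facts;
* stop when the replicate reaches the original fact count `n`; if the last
  gene overshoots, cut it back so the replicate has exactly `n` facts.

Each of the (default 10 000) replicates yields an error rate; the sample
standard deviation of those rates estimates the standard error of the
reported rate, and the 2.5th/97.5th empirical percentiles give a 95%
confidence interval.

Numerical choices, all of which matter for bit-reproducibility:

* **Truncation.** How to cut back the overshooting final gene is not
  dictated by the design. The default `prefix` policy keeps that gene's
  facts in stored order up to the quota, which is fully deterministic given
  the gene draws; `random_subset` draws a uniform subset instead. At the
  audit's counts the CI endpoints and SD are insensitive to the choice; both
  policies conserve the replicate size exactly, a property the test suite
  checks over a thousand randomized datasets.
* **Quantiles.** Inverse-ECDF (`type = 1`), so endpoints are realized
  replicate values. With discrete error counts and 10 000 replicates the
  interpolation scheme does not move the endpoints at two decimals, but the
  definition is fixed so results are bit-stable.
* **SD.** Sample standard deviation with the `n_replicates - 1` denominator.
* **RNG order.** One seeded generator, consumed as: the replicate's gene
  block draw, then (only under `random_subset`, and only when truncation
  actually occurs) one subset draw. A fixed seed gives a bit-identical
  `bootstrap_result`.
* **Degenerate inputs.** An empty dataset is an error; a single-gene dataset
  has a point-mass bootstrap distribution (SD 0), which is the honest
  answer; an all-correct dataset gives SD 0 and CI (0, 0).

### An exact oracle for the singleton limit

When every cluster has exactly one fact, "resample genes with all their
facts" collapses to an iid resample of facts, so a replicate's error count
is exactly Binomial(`n`, `k/n`). `binomial_oracle()` computes those
quantiles in closed form, giving an independent check of the whole
resampling path:

```{r oracle}
round_half_up(binomial_oracle(358, 5))  # EcoCyc singleton reconstruction
round_half_up(binomial_oracle(275, 5))  # CGD singleton reconstruction
```

The test suite requires the bootstrap CI to agree with these endpoints at
two decimals on singleton reconstructions of both audits — a check that is
robust to the seed, because the binomial quantile indices sit far from the
replicate-count boundaries.

## The synthetic generator

`generate_dataset()` simulates the whole audit so the pipeline can be tested
without any database access. Each fact gets a hidden truth label — factually
wrong (`p_factual`), true but miscited (`p_citation`), or correct — and the
validator observes it noisily: real discrepancies are missed with
`p_validator_fn`, correct facts are flagged with `p_validator_fp`. Curator
re-analysis then resolves every *reported* error from the hidden truth.
A discrepancy the validator missed stays final-correct: an audit can only
re-analyse what was reported, so `p_validator_fn > 0` biases the estimated
rate downward — a real limitation of the design, reproduced deliberately.

Defaults are fixed once, at the per-fact rates observed across the two
audits pooled: `p_factual = 0.015` (≈10/633 final errors),
`p_citation = 0.006` (≈4/633 citation-metadata downgrades),
`p_validator_fp = 0.011` (≈7/633 validator mistakes), and
`p_validator_fn = 0` because the audit design cannot measure a validator
miss rate. Cluster sizes are uniform on 1..5: the protocol caps facts per
gene at five but reports no size distribution. `n_genes = 200` gives about
600 facts, one audit's scale.

`study_fixture()` reconstructs the published marginal counts exactly —
EcoCyc: 358 facts, 8 initial errors (5 factual, 2 citation-metadata,
1 validator mistake); CGD: 275 facts, 13 initial (5 factual, 2
citation-metadata, 6 validator mistakes) — in either a `singleton` or a
`capped` layout, with error facts always in distinct genes. The record-level
data behind the published audits (which genes carried how many facts, and
where the errors sat) are not public, so these are synthetic
reconstructions of marginals only. Consequences:

* rates and, in the singleton layout, CI endpoints and the EcoCyc SD are
  reproduced exactly, because they depend only on the marginals;
* the published CGD bootstrap SD of 0.78% depends on the real cluster
  layout; under the capped synthetic layout the package claims only a band
  (the test suite checks 0.70–0.90%), and the observed value lands near
  0.79%.

What the generator does *not* emulate: publication text, shared citations
across facts, validator familiarity bias (a validator fluent in GO both
picks and catches more GO facts), or any dependence of error probability on
fact type. Passing tests therefore show the pipeline's arithmetic and the
bootstrap's sampling theory are right under the stated model — not that real
curation errors are homogeneous Bernoulli events.

## Test scale and verification

The test suite verifies, among other properties: round-trip I/O identity;
dedupe idempotence; rescoring monotonicity (final ≤ initial errors);
replicate size conservation across 1 000 randomized clustered datasets;
bootstrap centering within 3 Monte-Carlo standard errors of the point
estimate; that k-fold cluster replication does not inflate the bootstrap SD;
fixed-seed determinism of the full pipeline at the byte level; and parameter
recovery — a generated audit with `p_factual = 0.015` and ~10^5 facts
recovers the rate within 3 binomial standard errors, and across 200
simulated audits of ~510 facts the 95% bootstrap interval (1 000 replicates
each) covers the true rate at least 90% of the time. These problem sizes
are the package's chosen compromise between Monte-Carlo resolution and test
runtime; the headline bootstrap checks always use the full 10 000
replicates.

## Known limitations

* The error-rate model treats a fact as atomic; partially supported facts
  must be scored by the validator one way or the other.
* First-cluster-wins deduplication discards any facts checked under a
  duplicated gene's later cluster; whether the original audit re-used or
  discarded them is not recorded.
* The bootstrap quantifies sampling variability only. Validator selection
  bias within a gene page is not correctable from the recorded data.
* Percentile intervals are reported as published; no BCa or studentized
  variants are provided.
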