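---
title: "Integrating promoter methylation with expression to call cancer driver genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating promoter methylation with expression to call cancer driver genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdriver)
```

# The model

`methdriver` predicts cancer driver genes by demanding that two
independent lines of evidence agree: an expression-level argument that a
gene *behaves* like an oncogene (OCG) or tumor suppressor (TSG), and a
methylation-level argument that a promoter mechanism exists which could
*cause* that behavior. The biological premise is the classical one:
promoter hypomethylation can activate a gene, promoter hypermethylation
can silence it. An over-expressed gene driving proliferation is only
called a driver here if some tumors have lost methylation at its
promoter CpGs and those same tumors are the ones over-expressing it.

## Expression layer

Tumor and normal samples are compared per gene with a Wilcoxon rank-sum
test on log2 expression, BH-corrected; genes with `fdr <= 0.05` and
`|log2FC| >= 1` are the DEGs. These defaults are the field's
conventional cutoffs and are arguments of `run_dea()`. The built-in test
is deliberately nonparametric — it makes no count-model assumptions and
works on any sensibly normalised log-scale matrix — and `load_dea()`
accepts external tables (e.g. from a negative-binomial DEA) whenever
fidelity to an existing analysis matters.

A mutual-information network then links each DEG to its putative
targets. MI is estimated by equal-frequency discretization into
`B = max(2, floor(sqrt(n)))` bins and computed on tumor samples only:
the network should reflect the regulatory state in which drivers act
(`samples = "all"` is available). Per regulator, edges must exceed the
`1 - alpha` quantile (default `alpha = 0.05`) of MI values from 100
seeded permutations of the regulator against cycling target genes.
Because equal-frequency binning gives every gene identical marginals,
the permutation null is exchangeable across targets, which is what makes
the cycling scheme a valid per-regulator null at modest cost.

Each regulator is scored against two process signatures — one
cancer-growing (proliferation), one cancer-blocking (apoptosis) — as
`z = sum(s_i) / sqrt(m)` over the m regulon targets inside the
signature, `s_i = +1` for targets whose fold-change direction matches
the direction expected under process activation and `-1` otherwise.
This signed-concordance z is a reconstruction of the classical upstream
regulator score; the MI edge weights are retained in the network output
but intentionally not used in z, which keeps the score testable by hand
and insensitive to the MI estimator's scale. Mediators are called
symmetrically at `|z| >= t = 1`: OCG-like means pushing growth up and
blocking down, TSG-like the mirror. Only the sign semantics are
inherent to the method; `t` is a tuning key.

## Methylation layer

Tumor beta values of each promoter CpG are modelled as a mixture of up
to three beta components, `Beta(mu * phi, (1 - mu) * phi)` — enough to
represent a normal-like plus a hypo- and a hypermethylated
subpopulation. The EM fit uses:

* deterministic initialisation by splitting the sorted values into K
  equal blocks (no random restarts, so fits are reproducible without a
  seed);
* a method-of-moments M-step for (mu, phi) on responsibility-weighted
  moments. This is simpler and, at cohort scale, more robust than
  Newton iterations on digamma functions; its theoretical cost is that
  a moment update is not guaranteed to increase the likelihood, so each
  update is accepted only if the log-likelihood does not decrease —
  otherwise the previous parameters are kept and iteration stops. The
  recorded log-likelihood trace is therefore non-decreasing by
  construction, which the tests assert for every fitted probe;
* convergence at a log-likelihood gain below 1e-6 or 500 iterations;
* model choice by BIC = -2 logL + (3K - 1) log n; a component whose
  weight collapses below 0.01 invalidates that K and selection falls
  back to the smaller model.

Beta values are clamped to [1e-3, 1 - 1e-3] on input because the beta
likelihood is undefined at the boundaries; clamping rather than
dropping preserves sample counts, and the reader reports how many
values were affected. Values outside [-0.01, 1.01] abort: they indicate
M-values or another scale error, which silent clamping would mask.

Per component, `dm = mu - mean(normal betas)` is the differential
methylation value. `|dm| >= dm_min = 0.10` calls a component abnormal;
0.10 on the beta scale is the established convention of the
methylation-mixture literature for a biologically meaningful shift, and
it is a config key. Mixtures are fitted on tumors only; normals serve
solely as the reference mean. This asymmetry matches the question being
asked (which tumors deviate, and in which direction?) rather than a
symmetric two-group decomposition. Samples are assigned to components
by maximum responsibility — a hard assignment, chosen because the
downstream comparison groups must be auditable sample lists rather than
fractional weights.

A CpG with abnormal components is paired with each gene its manifest
maps it to (promoter rows only by default; probes mapping to several
genes contribute one pair per gene, since no cross-gene arbitration is
defensible from first principles). The gene's tumor expression is
compared between abnormal-component and normal-like-component samples
by rank-sum test; when no normal-like component exists — all tumors are
abnormal — the comparison falls back to normal-tissue expression.
Groups below 3 samples are skipped. BH correction runs across all
tested pairs (one global family; the alternative of per-gene families
would make significance depend on manifest density), and pairs with
`fdr <= 0.05` are *functional*.

## Integration

Functional CpGs are counted per mediator. The gene-level state is Hypo
or Hyper only when all non-dual functional CpGs agree; genes with both
kinds are Mixed, genes with only dual CpGs are Dual-only. Dual CpGs —
hypomethylated in some patients, hypermethylated in others — are
counted and reported but never determine the gene state and never
support agreement: a state that points both ways cannot corroborate a
single mechanism. The rule table (see `classify_evidence()`) then
yields Agreement, Conflicting, Mixed or NoEvidence; only agreement
genes become drivers. The Mixed exclusion generalises the "same state
in all associated CpGs" requirement to the driver call itself, which is
the conservative reading. By construction the four categories partition
the mediators — an invariant asserted on every run.

# The synthetic cohort generator

`simulate_cohort()` plants methylation-driven drivers in a paired
cohort so that every stage has a ground truth. Defaults: 30 tumors, 20
normals, 10 hypomethylation-activated OCGs, 10
hypermethylation-silenced TSGs, 200 null genes, beta shift
`delta_meth = 0.4`, expression shift `delta_expr = 2` (log2),
expression noise sd 0.5, beta precision 20, one promoter CpG per gene,
and 4 signature targets per driver per process.

Two design choices deserve explanation:

* **Epigenetic subtype structure.** All OCGs share one affected tumor
  subgroup and all TSGs another, with the two subgroups overlapping at
  the product expectation so the two classes are uncorrelated across
  tumors. This mirrors coherent methylator phenotypes (CIMP-like
  subtypes) rather than gene-private events. It is also what makes the
  planted truth recoverable in principle: with per-gene random
  subgroups, random overlaps among 20 drivers create genuine
  cross-driver correlations whose retained network edges land on
  signature genes with random signs and wash out the concordance
  z-scores — a property of small cohorts, not of the method.
* **Effect sizes sized by power, not tuned.** The affected fraction is
  0.7, so a planted driver's marginal fold change is
  `0.7 * delta_expr = 1.4` against a standard error of about 0.14 —
  comfortably past the DEG cutoff of 1 — and the abnormal mixture
  component holds 21 of 30 tumors, well above the minimum group size
  of the association test. A fraction near 0.5 would put the expected
  fold change exactly on the DEG boundary and make recovery a coin
  flip by construction.

The generator emulates: bimodal tumor methylation with a clean normal
reference, sample-level coupling between the abnormal methylation group
and the expression shift (the assumption the association test relies
on), and co-regulation of signature targets. It does **not** emulate
tumor purity gradients, copy-number confounding, probe
cross-hybridisation, realistic 450K probe geography, or correlated
noise between genes. Passing the planted-recovery tests therefore shows
the machinery is correct and well-calibrated under its own assumptions;
it does not certify performance on real cohorts, where those
confounders dominate the error budget.

A deliberate property of the defaults: the co-regulated signature
targets are themselves called mediators by the expression layer (they
behave exactly like drivers at the expression level) but carry no
methylation mechanism, so the methylation layer strips them. This
reproduces, inside the simulation, the precision-over-sensitivity trade
the integration is designed to deliver, and the tests assert that
direction rather than any tuned magnitude.

# Evaluation choices

Precision and sensitivity are `100 * TP / (TP + FP)` and
`100 * TP / (TP + FN)` against a census list restricted to the gene
universe. The universe is all genes entering the DEA — the set the
pipeline could in principle have predicted from — not the genome; FN
and the Fisher table change with this choice, and a custom universe can
be supplied. The Fisher p-value is computed by direct hypergeometric
enumeration (two-sided, summing tables no more probable than the
observed one) and is tested against the independent conditional exact
implementation in base R to 1e-10. The odds ratio is the sample
`(a d)/(b c)` with the Haldane–Anscombe +0.5 applied when any cell is
zero — closed-form and oracle-testable, but numerically different from
the conditional-MLE odds ratio a base-R `fisher.test()` reports, which
should be kept in mind when comparing against publications that used
the latter.

# Problem sizes and runtime

The default simulated cohort (380 genes, 380 probes, 50 samples) runs
the full pipeline in well under a minute of mixture fitting plus a few
seconds for the network; the repeated-simulation checks (50 mixture
recoveries, 20 null cohorts) keep the whole reproduction script in the
single-digit minutes on one core. These sizes were chosen as the
smallest at which every stage — including the permutation null and BH
across thousands of pairs — operates in its intended regime.

# Known limitations

* The URA score and the MI thresholding are reconstructions of
  classical designs, not ports of any specific implementation;
  `load_dea()` / `load_pra()` exist precisely so results from original
  implementations can be substituted stage by stage.
* Beta-mixture fits are deterministic but the moment M-step can stop
  short of the exact maximum-likelihood solution; with cohort-scale n
  the difference is far below `dm_min`.
* A gene's driver call depends on the probe manifest: missing promoter
  annotations silently reduce evidence to NoEvidence. The manifest is
  therefore an explicit, validated input rather than a bundled default.
* Dual-methylation biology (context-dependent gain and loss at one CpG)
  is detected and reported but deliberately contributes no driver
  evidence.
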