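---
title: "Multi-omics evidence levels: model, screens, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics evidence levels: model, screens, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A single differential-expression screen of tumors against matched normals is
noisy: one measurement modality, one statistic, one list. The idea behind
this package is to treat a gene's *hyperactivation* in tumors as a claim that
can accumulate evidence across five independent measurement modalities:

* **GE** — the gene is more highly expressed in tumors than in paired
  normals;
* **CN** — the gene sits in regions of somatic copy-number gain;
* **ME** — the gene's promoter methylation (beta value) is depressed in
  tumors, on two independent array platforms;
* **MR** — the gene is a predicted target of a miRNA that is downregulated
  in tumors (loss of repression);
* **GM** — the gene is mutated significantly more often in the case cohort
  than in the disease-wide background cohort.

Genes called in GE are then stratified into nested evidence **levels**:
Level 1 is GE alone; Level *k* (for *k* = 2..5) is GE plus support from at
least *k* − 1 of the other four modalities. The level sets are nested by
construction — every Level-3 gene is also a Level-2 and Level-1 member — and
the package reports both nested membership counts (the canonical output) and
exact highest-level assignments. The motivating use case is a
triple-negative breast cancer (TNBC) cohort against matched normal tissue,
which is what the synthetic study generator emulates, but nothing in the
pipeline is specific to that disease.

## The five screens

All thresholds live in one object, `threshold_config()`, whose defaults are
the canonical screen settings:

| screen | effect | test | call rule |
|---|---|---|---|
| GE | fold = mean(tumor)/mean(normal) over complete pairs | Wilcoxon signed-rank on paired differences | fold ≥ 2 and BH q ≤ 0.05 |
| CN | fold of mean linear copy numbers | Wilcoxon signed-rank, paired | fold ≥ 1.2 and q ≤ 0.05 |
| ME | Δβ = mean(normal) − mean(tumor), per platform | Wilcoxon rank-sum, unpaired | Δβ ≥ 0.05 and q ≤ 0.05 on *both* platforms |
| MR | fold = mean(normal)/mean(tumor) per miRNA | Welch t on log2(x+1) | fold ≥ 2 and q ≤ 0.05; MR gene set = union of targets of called miRNAs |
| GM | sample odds ratio of the case-vs-background 2×2 table | Fisher exact | raw p < 0.05 and OR > 1 |

Choices worth spelling out:

* **Fold change is a ratio of group means**, not a mean of per-pair ratios.
  A "two-fold mean difference" reads naturally as a difference of means, and
  per-pair ratios are unstable when the normal-tissue value is near zero.
* **Copy-number folds are computed on linear copies.** SEG segment means are
  log2(copy/2) ratios; they are converted to linear copy `2 * 2^value`
  before gene-level averaging, because a 1.2-fold threshold is only
  meaningful on the linear scale (copy-number folds in paired tumor/normal
  designs are small — rarely above 1.5).
* **Gene-level copy number is a length-weighted average** of the linear
  copies of overlapping segments, weights equal to the overlapping base
  count. An unweighted mean is available (`cn_weighted = FALSE`); the two
  differ only when a gene spans unequal overlaps. Genes with no covering
  segment are imputed at the neutral diploid value 2 and flagged — "nocnv"
  segment files omit copy-neutral regions, so absence of a segment is not
  evidence of anything. `imputed_fraction()` lets users drop imputed-heavy
  genes.
* **Hypomethylation direction is normal minus tumor** (a positive Δβ means
  the gene is *less* methylated in tumors, i.e. de-repressed), and the ME
  call requires the effect and significance on both platforms
  independently — an intersection, not a meta-analysis.
* **The miRNA t test runs on log2(x+1) values** (variance stabilization for
  count-like abundance data) while the fold threshold applies to the
  untransformed group-mean ratio. The Welch form is the default; a pooled
  Student form is available via `t_variant = "student"`.
* **The mutation screen uses raw p, no FDR**, which is conventional for
  small frequently-mutated gene panels; `gm_use_fdr = TRUE` additionally
  reports q without changing the call. The background cohort *contains* the
  case samples by default — that is the convention under which a
  "78% of 54 cases vs 31% of 992 tumors" comparison is arithmetically
  consistent — and the effect reported is the sample odds ratio
  `a·d/(b·c)`, not a conditional MLE. Silent variants are excluded from the
  mutation matrix by default (`classification_filter = "non_silent"`);
  the choice is explicit because variant-class filtering is rarely stated
  in published screens.

## The statistical kernel

The rank tests and the Fisher test are implemented in-package rather than
delegated, because genome-wide screening needs conventions that the standard
implementations do not provide together: exact enumeration in the presence
of ties, and flagged degenerate outcomes instead of errors on constant
features (a screen over 2,000 genes must not abort because one gene is
constant). Base R's `wilcox.test`, `t.test`, `fisher.test`, `p.adjust` and
`phyper` are used as independent cross-checks in the test suite.

* **Signed-rank**: zero differences are dropped (the classic Wilcoxon
  convention); the exact null distribution of the positive-rank sum is built
  by a generating-function convolution over doubled (possibly tied) ranks
  when the number of non-zero differences is ≤ 25, otherwise a
  continuity-corrected normal approximation with the tie-aware variance
  Σr²/4. All-zero input returns p = 1, flagged degenerate.
* **Rank-sum**: exact by subset-sum enumeration over doubled ranks whenever
  the combined sample size is ≤ 20 — ties included, which is stronger than
  the usual "exact only without ties" — otherwise the tie-corrected,
  continuity-corrected normal approximation.
* **Two-sided p-values** for both rank tests use the `2·min(P≤, P≥)` rule,
  capped at 1.
* **Fisher's test** reports the two-sided point-probability p (the sum of
  hypergeometric outcome probabilities no larger than the observed one, the
  most common convention, with a 1e−7 relative slack against floating-point
  ties) and the sample odds ratio, +Inf when `b·c = 0` with `a·d > 0`.
* **BH q-values** delegate to `stats::p.adjust("BH")` over the non-missing
  entries; missing p-values propagate as missing and are excluded from the
  number of tests m. Note that BH is *not* idempotent as a map (re-adjusting
  an adjusted vector can increase values, e.g. p = (0.04, 1) → q = (0.08, 1)
  → (0.16, 1)); what is stable under re-application is the ranking, and that
  is what the test suite asserts.
* **Exact vs approximate agreement**: at the cut-over sizes the two paths
  agree within 10% relative p in the moderate-p regime (p ≥ 0.05). In the
  far tail the relative error of any normal approximation exceeds that, but
  the absolute error is tiny and the calls the two paths imply agree; the
  tests check exactly this split.
* **Degenerate two-sample t**: both groups zero-variance returns a flagged
  p of 1 (equal means) or 0 (unequal means), again so screens never abort.

Gene-set overlap enrichment is the textbook hypergeometric upper tail
P(X ≥ overlap) per set, BH across sets, against a universe that should be
the genes actually tested in the GE screen (that is what `run_pipeline()`
uses); the default reporting filter, FDR < 1e−10, matches the stringency
customary for large curated collections.

## The synthetic study generator

`generate_study()` produces a complete, seeded multi-omics study plus a
ground-truth table, so every pipeline stage is testable without any data
download. The default cohort shapes mirror the motivating TNBC study: 55
expression pairs, 53 copy-number pairs, 32/27 and 23/47 methylation groups
on two platforms, 53/103 miRNA groups, and a 54-sample case MAF inside a
992-sample background cohort.

Distributional choices:

* **Expression / miRNA**: log-normal; per-feature baseline log2 mean ~
  Normal(8, 2²), within-group log2 noise sd 0.5, planted tumor means
  multiplied by the planted fold (4 by default).
* **Copy number**: a toy genome (10 kb genes, 10 kb spacing, 200 genes per
  chromosome) with one segment per gene per sample; planted genes carry
  linear copy 3 in tumor samples (1.5-fold), everything else is neutral
  diploid; segment log2 values get Gaussian noise (sd 0.2). One segment per
  gene keeps per-gene noise independent across genes — a single
  whole-chromosome segment would make all genes on a chromosome share one
  noise draw and break the independence the FDR calibration relies on.
  With segment noise set to 0, re-deriving gene copies through
  `map_segments_to_genes()` reproduces the planted values exactly.
* **Methylation**: per-gene normal-tissue mean β ~ Uniform(0.3, 0.7) shared
  across the two platforms, 2–5 probes per gene per platform with small
  probe offsets (sd 0.02), values Beta-distributed with precision 30;
  planted genes are depressed by Δβ = 0.2 in tumors.
* **Mutations**: qualifying (non-Silent) calls are Bernoulli per gene and
  sample — planted genes at 0.4 in cases vs 0.05 in the rest of the
  background, non-planted genes at a passenger rate of 0.0015 everywhere.
  The passenger rate matters: the GM screen uses raw p < 0.05, so its
  false-discovery proportion is governed by how often a quiet gene collects
  2–3 case mutations by chance. An exact enumeration of the per-null-gene
  false-call probability (Binomial case/background counts through the
  Fisher decision rule) gives ≈0.013 at a passenger rate of 0.01 — an FDP
  near 0.20 against 100 planted genes — versus ≈0.003 at 0.0015, an FDP
  around 0.05. The chosen 0.0015 is also the realistic order for breast
  cancer exomes: ~30 qualifying calls per sample spread over a ~20,000-gene
  exome. A small extra Silent-call rate (0.001) exists purely to exercise
  the variant-class filter.
* **Planted blocks** occupy deterministic gene-index ranges: 25 genes with
  triple evidence (GE+CN+ME, the genes expected to reach Level 3), 25
  GE+CN, 25 GE+ME, 25 GE-only, 50 CN-only, 50 ME-only, 100 miRNA-target
  genes wired 10-per-miRNA to 10 planted downregulated miRNAs (plus 50
  decoy miRNAs wired to null genes), and 100 mutation-enriched genes.
* All randomness flows from the single mandatory seed through one child
  seed per modality, so modalities are independently reproducible.

**What passing tests show, and what they do not.** The generator plants
clean, block-structured effects with independent Gaussian/Beta/Bernoulli
noise. Real tumor cohorts have correlated genes, batch structure,
copy-number segments spanning many genes, probe-level artifacts, subclonal
mutations and impure tissue. Recovering 100% of planted effects here
demonstrates that the pipeline's statistics, thresholds and plumbing are
correct and calibrated — not that real-cohort gene lists would reach any
particular sensitivity.

## Calibration and problem sizes

The test suite runs, among others:

* kernel oracle equivalence: 1,000 random small instances against
  exhaustive sign/labeling/hypergeometric enumeration;
* segment mapping against a per-base brute-force oracle on 200 random toy
  genomes (≤ 1 kb — small enough for the per-base walk, with multi-segment,
  partially covering, multi-chromosome layouts);
* parameter recovery on the full-size reference study (2,000 genes,
  cohort shapes as above): ≥ 90% sensitivity and FDP ≤ 0.10 per screen,
  ≥ 80% of triple-planted genes reaching Level ≥ 3;
* null calibration on 50 all-null studies (500 genes, reduced cohorts:
  20/20 pairs, 12/12 and 10/16 beta groups, 20/40 miRNA groups): the
  fraction of runs with any GE/CN/ME/MR call at FDR 0.05 must be ≤ 0.10 per
  screen. Because a call requires the effect-size floor *and* the q cut,
  the observed any-call fraction is essentially zero — under the global
  null a fold of 2 is ~10 standard errors away at these sample sizes.

These sizes were chosen to exercise the full study design at the modest end
of its realistic range while keeping the whole suite comfortably
re-runnable on a laptop.

## Degenerate inputs and tie-breaks

* Genes with fewer than 3 usable pairs, zero mean normal value, or
  identical tumor/normal values in every pair are reported `tested = FALSE`
  and excluded from the BH m of the paired screens (an all-imputed
  copy-number gene is the canonical case). The unpaired miRNA screen keeps
  constant features as tested with degenerate p = 1 — they carry
  information (no difference), unlike an unmeasurable paired gene.
* Writers are byte-deterministic: fixed column order, rows sorted (screen
  tables by q, then p, then feature ID), data matrices at 15 significant
  digits (so write-then-read is the identity at realistic precision),
  result tables at 6.
* Chromosome names are matched verbatim; a SEG/gene-model mismatch yields
  all-imputed copies plus one warning, never an error.
* Gene identifiers are matched by exact symbol across modalities; no alias
  database is shipped.

## Limitations

* The ME screen's platform intersection is conservative by design; a gene
  measured on only one platform can never be ME-called.
* The MR modality inherits every limitation of the supplied target map;
  the package consumes a map, it does not predict targets.
* The GM screen's raw-p rule is faithful to common practice but anti-
  conservative over large gene panels; `gm_use_fdr` exists for users who
  want the adjusted view.
* Level assignment requires GE membership — a gene with copy gain,
  hypomethylation and mutation evidence but no expression call has no
  level, by construction.
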