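---
title: "Evaluating and combining genotype imputation runs"
author: "imputeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and combining genotype imputation runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(imputeval))
```

## The problem

Genotype imputation infers untyped genotypes from a phased haplotype
reference panel, emitting for each genotype a trio of posterior
probabilities $(p_0, p_1, p_2)$ for carrying 0, 1 or 2 copies of the
alternate allele.  Two practical questions recur whenever a cohort can be
imputed in more than one way — for instance against a large public panel
reachable only through an imputation server, versus a smaller
population-matched panel held in house:

1. *How accurate is each run*, overall and for which individuals, which
   variants, which genomic regions and which allele-frequency classes?
2. *Can two runs be combined* into something at least as good as the
   better of the two, given that the panels themselves cannot be merged?

This package implements the measurement side of that comparison: the
chance-corrected Imputation Quality Score (IQS), a per-genotype
most-confident-vote merge of two runs, switch-error-rate estimation from
repeated phasings, and aggregation of identity-by-descent (IBD) sharing
between sample groups, which explains *where* a population-matched panel
helps.  A simulator generates all the inputs with known ground truth, so
every claim the package makes is testable without access to cohort data.

## The Imputation Quality Score

Genotype concordance alone flatters imputation of rare variants: calling
everyone homozygous reference is already almost always "correct".  The
IQS removes that baseline.  Truth genotypes $j$ and imputed probability
mass $k$ are cross-tabulated into a $3 \times 3$ table whose cell
$n_{jk}$ accumulates, over all genotypes with truth $j$, the posterior
probability assigned to genotype $k$ (fractional, posterior-weighted
counts).  With row and column margins $r_j$ and $c_k$ of a table with
total $N$,

$$P_o = \frac{\sum_j n_{jj}}{N}, \qquad
  P_c = \frac{\sum_j r_j c_j}{N^2}, \qquad
  \mathrm{IQS} = \frac{P_o - P_c}{1 - P_c},$$

i.e. Cohen's kappa of the truth-vs-imputed table.  A perfect run scores
1; a run carrying no information beyond the genotype frequencies scores
0.  Two readings of "concordance with the posterior probabilities" are
possible — fractional posterior weighting versus concordance of the
best-guess genotype — and the package defaults to the fractional reading
while providing a hard-call mode (`mode = "hardcall"`) as a cross-check,
because the two answer slightly different questions: the fractional
score rewards calibrated uncertainty, the hard-call score equals the
probability that the best guess is right.

Three numerical decisions matter in practice:

* **Undefined scores are flagged, not coerced.**  When $1 - P_c$
  vanishes (below $10^{-12}$; e.g. a monomorphic stratum predicted
  monomorphic) the score is reported as undefined.  Replacing it by 0 or
  1 would bias per-region summaries, so summaries drop undefined strata
  and report how many were dropped.
* **Missing trios are excluded, never imputed as uniform.**  A
  fabricated $(1/3, 1/3, 1/3)$ entry would dilute $P_o$ and $P_c$
  together and quietly shrink every score toward its chance level.
* **MAF comes from the truth set.**  The rare/common split (threshold
  0.01 by default) always uses minor allele frequencies computed from
  the truth genotypes, never from imputed dosages, which are biased
  exactly where imputation fails.

Stratification pools tables, and pooling is exact: the table of a merged
stratum is the cell-wise sum of its parts.  Per-individual scores pool
all of one sample's genotypes (the axis on which geographic gradients of
imputation quality appear); per-variant scores pool across samples;
region scores assign a genotype to every region containing its position,
so overlapping regions deliberately double-count.

## The most-confident-vote merge

When two runs impute the same genotype, the merge retains the trio whose
maximum probability is larger — but only if it is larger by more than a
margin $\delta$; otherwise a designated priority run wins:

$$\text{retain } A \iff p_{max}^{A} > p_{max}^{B} + \delta,$$

with $\delta = 0.05$ and priority to $B$ by default.  The margin exists
because different imputation programs scale their posteriors slightly
differently, so hair-thin differences in $p_{max}$ carry no signal;
$\delta$ is an empirical knob, which is why both it and the priority side
are configurable rather than fixed.  Selection is per genotype, not per
variant: two individuals at the same site may draw from different
sources.  The retained trio is copied verbatim — blending probabilities
is out of scope by design, since a blend would no longer be the output of
either calibrated run.  Variants imputed by only one run pass through
unchanged, so the merged run covers the union of the two variant sets.

Each genotype is also labelled **Accord** (both runs name the same most
likely genotype) or **Discord**.  Agreement between two runs driven by
different panels is strong evidence of correctness, so the Accord
correct-call fraction should far exceed the Discord one; within Discord,
a confidence-based choice should beat either source provided the
posteriors are calibrated.  Argmax ties inside a trio are broken toward
the smaller genotype code, a fixed rule chosen purely for
reproducibility.

Variant identity across runs is the exact (chrom, pos, ref, alt) tuple.
Strand flips are never attempted (unresolvable for A/T and C/G
variants); reconciling ref/alt-swapped records — reversing the trio to
$(p_2, p_1, p_0)$ — is available but off by default, because silent
allele relabelling is the most dangerous failure mode of cross-run
matching.

## Switch error rate by seed consensus

True haplotypes are rarely known, so phasing accuracy is approximated by
stability: the phasing is run $K = 21$ times with different random
seeds, and for each pair of *adjacent heterozygous sites* of an
individual the relative orientation ("same" when the alternate alleles
sit on one haplotype) voted by the majority of seeds is taken as
correct.  Each replicate's switch error rate (SER) is its disagreement
fraction with that consensus, and the per-individual estimate is the
mean over replicates.  $K$ must be odd so the majority is unique; the
orientation convention counts a long-range switch once, at its boundary.
The approximation degrades as the true per-pair switch probability
approaches 0.5 — the consensus then carries no information — which is
why the simulator refuses $s \ge 0.5$ outright.  In the tested regime
($s \le 0.05$, $K = 21$, thousands of pairs) the consensus matches the
generating orientation for more than 99.9% of pairs and the estimator
recovers $s$ within Monte-Carlo error.

## IBD sharing aggregation

To explain where a population-matched panel helps, pairwise IBD segments
between target individuals and reference individuals are aggregated into
a target-group × reference-cluster matrix of mean total shared length in
cM, split at 3 cM into long segments (recent common ancestry, the ones
that carry rare alleles) and short ones.  Two deliberately distinct
semantics coexist:

* **Totals are sums.**  Overlapping segments to different cluster
  members all count — the quantity is total sharing, not coverage.
  Individuals with no segments contribute zeros to their group mean;
  dropping them would inflate exactly the cells with the least sharing.
* **Masks are unions.**  For dosage stratification, an individual's long
  segments with a reference group are merged into intervals, and
  truth-heterozygous genotypes are tabulated by imputed dosage
  ($p_1 + 2 p_2$, equal to 1 for a perfect heterozygote) inside versus
  outside the mask.

Genetic lengths are read from the segment file and never recomputed from
a genetic map; a file without a length column is a configuration error.

## What the simulator does and does not emulate

The generator exists so that every contract above can be exercised with
known truth.  Its defaults define the benchmark conditions:

* **Truth genotypes** are drawn i.i.d. under Hardy–Weinberg equilibrium
  per variant, with no linkage disequilibrium.  Every statistic in the
  package is genotype-wise, so LD would add realism without adding
  discrimination; LD-aware simulation is a non-goal.
* **Posteriors** realise a per-genotype correctness probability $a$ that
  may depend on the imputation strategy, the variant's MAF bin and the
  sample's group.  Miscalls draw the wrong genotype proportional to the
  HWE priors of the two alternatives, which makes a chance-level
  strategy score IQS = 0 by construction.  Calibration is a switch:
  calibrated runs emit $p_{max} = a$ (the premise under which
  confidence-based selection is the right rule), and an uncalibrated
  mode emits a fixed over- or under-confident $p_{max}$ so that tests can
  probe what the merge does when that premise fails.
* **The two-strategy scenario** (3000 variants, half with MAF in
  0.002–0.009 and half in 0.05–0.5; two groups of 60 samples) encodes a
  local panel-matched strategy that is most accurate on rare variants of
  group-1 samples but restricted to variants reaching minor allele count
  5 in an emulated reference panel of 850 individuals (panel allele
  counts drawn binomially at the true frequency), against a public-panel
  strategy that imputes every variant and is more accurate for group-2
  samples and common variants.  Accuracies were chosen so that pairwise
  confidence gaps are either zero or larger than $\delta$, keeping the
  scenario's expected behaviour analysable.
* **Phasing replicates** flip each adjacent-pair orientation
  independently with probability $s$ per replicate.  **IBD segments**
  are Poisson per pair with group-level rates, lengths 1 cM plus an
  exponential tail (mean 4 cM), spans placed uniformly with 1 cM ≈ 1 Mb.

Passing tests on these inputs demonstrate the correctness of the
bookkeeping and the qualitative structure of the comparisons — they do
not demonstrate performance on real cohorts, where LD, panel phasing
errors, batch effects and miscalibrated posteriors all interact.

## Problem sizes and determinism

The shipped tests and the benchmark command run at desk scale: the
scenario at 3000 variants × 120 samples, switch-rate recovery at 200
individuals × 2000 het pairs × 21 replicates for each
$s \in \{0.005, 0.02, 0.05\}$, sharing matrices from a few thousand
segments.  Every simulator takes an explicit seed and is bit-reproducible
under it; the benchmark manifest records the seed, the configuration and
an MD5 checksum of every output file, so a run can be verified byte for
byte.

## A worked example

```{r example}
sc <- simulateScenario(nVariants = 600, nPerGroup = 20, seed = 7)
mg <- mergeRuns(sc$runA, sc$runB, hybridConfig(delta = 0.05))
keys <- intersect(rownames(sc$runA), rownames(sc$runB))
tr <- sc$truth[keys, ]

perA <- iqsStratified(sc$runA[keys, ], tr, "individual")
perH <- iqsStratified(mg$merged[keys, ], tr, "individual")
summary(perH$iqs - perA$iqs)

acc <- accordSplitIqs(sc$runA, sc$runB, mg, sc$truth)
c(accord = mean(acc$accord_correct),
  discord_merged = mean(acc$discord_correct_merged, na.rm = TRUE))
```

## Known limitations

* No BCF support, no liftover between genome builds, and no attempt to
  normalise indel representations; keys must match exactly (or by the
  opt-in ref/alt swap).
* The merge is pairwise.  Combining more than two runs is possible by
  chaining, but the chain order matters near the margin $\delta$ and is
  left to the user.
* Per-variant quality scores (RSQ-style) are read as metadata and used
  only for filtering; the package never recomputes them.
* The IQS of pooled strata is not a weighted mean of per-stratum scores
  (kappa is not linear); only the tables pool exactly.
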