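---
title: "Methods: fine-mapping a regulatory risk locus with finelocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-mapping a regulatory risk locus with finelocus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finelocus)
```

# The problem

Genome-wide association studies localise disease risk to haplotype blocks,
not to variants. Turning a block into a mechanism requires (i) statistical
fine-mapping — dense (typically imputed) genotypes, stringent quality
control, and conditional analysis to count independent signals — and (ii)
functional triage — overlap with regulatory chromatin, evolutionary
conservation, transcription-factor motif disruption, chromatin contact
structure, and an expression consequence in the relevant tissue.
`finelocus` implements that whole arc for a single locus, modelled on the
B-cell leukemia risk interval on chromosome 15 where a common intronic
variant in a super-enhancer alters a RELA (NF-κB p65) binding site and
lowers expression of the pro-apoptotic gene *BMF*.

# Statistical models

## Case-control association

Two tests are computed per variant. The Cochran–Armitage trend test uses
the 2×3 case/control-by-genotype table with additive scores $w = (0,1,2)$:

$$\chi^2 \;=\;
\frac{N\,\big[N\sum_j w_j r_j - R\sum_j w_j n_j\big]^2}
     {R\,(N-R)\,\big[N\sum_j w_j^2 n_j - (\sum_j w_j n_j)^2\big]},$$

on one degree of freedom, where $r_j$ are case counts per genotype class,
$n_j$ column totals, $R$ total cases and $N$ total samples. When genotype
probabilities are available the class counts are *expected* counts (sums of
per-sample probability triples by phenotype), the standard treatment of
imputed data; the formula accepts non-integer counts unchanged. A table
whose score variance is zero (a monomorphic variant) is reported as
$\chi^2 = 0$, $p = 1$ with a degeneracy flag rather than an error, so a
scan never aborts mid-locus.

The logistic model $\mathrm{logit}\,P(\text{case}) = \beta_0 + \beta d$
(dose $d \in [0,2]$, optional covariates) supplies the effect size: the
per-allele log-odds $\beta$, $\mathrm{OR} = e^\beta$, and a Wald p. The fit
is Newton–Raphson on the Bernoulli log-likelihood with step-halving,
declared converged when the largest score component falls below $10^{-8}$
(at most 25 iterations). Separation is detected — saturated fitted
probabilities or $|\beta| > 15$ — and flagged as non-convergence instead of
being reported as a finite estimate. The trend statistic equals the score
test of this model at the null, an identity the test suite asserts to
$10^{-6}$ relative.

"Conditional logistic regression" here means ordinary
(unconditional-likelihood) logistic regression with the lead SNP's dose as
a covariate: the modelled study has unmatched cases and controls, so there
are no strata to condition on. Variants whose dose correlates with the
lead beyond $|r| > 0.999$ are flagged collinear and excluded from the
conditional scan rather than fitted.

## Imputation quality

The information score is the IMPUTE-style ratio-of-variances measure. With
per-sample triples $(p_{AA}, p_{AB}, p_{BB})$, $e_i = p_{AB} + 2p_{BB}$,
$f_i = p_{AB} + 4p_{BB}$ and $\hat\theta = \sum_i e_i / 2N$:

$$I_s \;=\; 1 - \frac{\sum_i (f_i - e_i^2)}{2N\,\hat\theta(1-\hat\theta)}.$$

Hard calls give exactly 1; values below 0 (possible in finite samples) are
clamped to 0; $\hat\theta \in \{0, 1\}$ yields 0 with a degeneracy flag.
The filter retains $I_s \ge 0.80$, and the association filter additionally
requires MAF $> 0.01$ (strict) and trend $p < 5\times10^{-7}$ (strict),
exactly the printed conventions.

## Linkage disequilibrium

From phased haplotypes, $D = f_{AB} - p_A p_B$,
$r^2 = D^2 / (p_A q_A p_B q_B)$ and $D' = |D|/D_{max}$ are direct counts.
From unphased genotypes the four haplotype frequencies are estimated by the
Excoffier–Slatkin EM: all cells of the 3×3 genotype table are phase-known
except the double heterozygote, whose cis/trans split is re-estimated each
iteration from the current frequencies. The EM is initialised at linkage
equilibrium — for two loci the likelihood is well-behaved and a single
start suffices — and stops when the largest frequency change drops below
$10^{-8}$ (cap 1000 iterations, convergence flagged). The observed-data
log-likelihood trace is retained and is non-decreasing, which the tests
assert. Proxy selection is strict $r^2 > 0.2$, sorted by descending $r^2$
with ties broken by genomic position for determinism.

## Motif disruption

JASPAR count matrices are regularised with a pseudocount (default 0.25)
and scored as $\log_2(p_{b,\ell} / 0.25)$ against a uniform background —
the background, log base and pseudocount are all arguments. Scanning
scores every window on both strands (minus strand via the
reverse-complemented matrix); windows containing `N` are skipped; best-hit
ties resolve to the plus strand, then the leftmost window. The
allele-specific disruption score considers *only* windows covering the
variant base — disruption semantics, not global best-hit semantics — and
reports $\Delta = \text{best}_{ref} - \text{best}_{alt}$, positive when
the alternate allele weakens the motif. On the packaged enhancer context
the risk allele scores strictly below the protective allele, matching the
gel-shift asymmetry the design emulates.

## 4C contact profiles

The fragment map cuts the sequence at the first base of every primary-site
occurrence (a DpnII-style enzyme cleaving 5′ of GATC; the cut model is
fixed and documented), yielding a gapless partition. A fragment is *blind*
when it fully contains no secondary-site (HindIII, AAGCTT) occurrence;
classification is at whole-fragment level, with no fragment-end sub-model.
Read processing: mapping quality < 30 dropped, duplicate 5′ positions
collapsed to unique events, masked intervals and a viewpoint exclusion
zone (default radius 1,500 bp) removed, then each read assigned to the
fragment containing its 5′ position. Reads outside the map are counted and
reported, not fatal. Profiles distribute each fragment's count over 100-bp
bins in proportion to overlap (signal-conserving), keep blind and
non-blind channels separate, and are smoothed with a 5-kb centred running
mean in which masked bins contribute to neither numerator nor denominator;
a bin whose entire window is masked is absent (NA). No cross-class
normalisation is applied between blind and non-blind channels; the
channels are reported separately plus summed.

## cis-eQTL and splicing

Genes with TSS within 1 Mb of the SNP are tested by OLS of expression on
dose with a two-sided t test, and Benjamini–Hochberg adjustment across the
tested genes only. No expression normalisation is performed — the package
consumes array-scale values that are already normalised, and an exclusion
list handles samples with somatic copy-number loss over the locus. The
splicing check counts reads carrying k-mers (default k = 31, an
implementer choice; the modelled analysis does not state k) unique to one
junction sequence, on either strand, and compares per-sample counts
between the two homozygote classes with Student's t test.

# The synthetic locus

`locus_design()` fixes the study conditions; `write_fixture_locus()`
materialises them. Defaults and their sources:

| parameter | default | why |
|---|---|---|
| locus span | chr15:40,379,030–40,532,514 | the conditional-analysis interval of the modelled study |
| causal OR | 1.35 per allele | the study's lead-SNP effect |
| causal RAF | 0.35 | not printed in the study; a common-variant value chosen once and flagged as an implementer choice |
| proxies | 3 at r² = 0.98, 0.95, 0.91 | four risk SNPs behaving as one signal; the published companion SNP sits at 0.91, taken as the weakest |
| cases/controls | 1,920 / 5,199 | the two scans combined (517 + 1,403 cases; 2,698 + 2,501 controls) |
| disease model | logistic, baseline risk 0.001 | rare-disease regime in which the per-allele OR matches the sampling enrichment and closed-form checks hold |
| genotype certainty | 0.98 (two background SNPs at 0.45) | keeps the risk SNPs above the info filter while exercising it |
| expression effect | −0.3 units/allele, σ = 1, n = 426 | places the target-gene dose p near the printed order of magnitude at the study's cohort size |
| 4C | decay exponent 1, fold 5 enrichment at the super-enhancer's distal end, 10-kb mask | a standard contact-decay law with the loop-anchor enrichment the experiment observed |

Haplotypes are generated by solving the two-locus frequencies analytically
for each (causal, other) pair — positive D, feasibility checked against
$r^2_{max}$ with an explicit error naming the attainable maximum — with
non-causal columns conditionally independent given the causal allele.
Proxies therefore correlate with each other only through the causal SNP,
matching the single-underlying-variant architecture. Cohorts are sampled
with replacement from a pool of 20,000 haplotypes; batches repeat until
the case and control quotas are met exactly, with a draw cap that turns an
unreachable quota into an error reporting attained counts.

Two generator details depart from the most literal reading of the design.
Genotype uncertainty is deterministic: the stated rule (mass `certainty`
on the truth, remainder split equally) has no residual randomness, so no
seed is taken. And 4C read 5′ ends are jittered uniformly within 75 bp of
a fragment end rather than placed exactly on it: exact-end placement would
let the unique-position collapse erase the very count law
(counts ∝ distance$^{-\gamma}$ × fold) the simulation is meant to realise.

What the replica does *not* emulate: recombination maps or coalescent
ancestry (LD is pairwise only), population stratification, batch effects,
genotyping error beyond the symmetric uncertainty model, overdispersed 4C
counts (sampling is multinomial), and correlated expression structure.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative assumptions — not robustness to the
messiness of real cohorts.

# Numerical choices and degenerate inputs

* Coordinates: variant positions are 1-based (VCF convention); all
  BED/bedGraph intervals are 0-based half-open. A variant at 1-based
  position $P$ overlaps $[s, e)$ iff $s \le P-1 < e$; the conversion is
  applied internally and is self-inverse.
* Monomorphic variants: trend test degenerates to $p = 1$ with a flag;
  LD and eQTL raise explicit errors (the quantities are undefined).
* bedGraph overlapping intervals are rejected as a dialect violation, with
  the offending chromosome named; malformed BED lines are rejected with
  their line number.
* Profile bedGraph output is rounded to 6 decimal places; candidate
  reports embed the config hash and seed in `#` header lines so a report
  is reproducible byte-for-byte from its configuration.
* The fixture's `config.json` stores `outdir = "."`; readers resolve it
  against the config file's location, keeping fixture directories
  relocatable and the generated file set byte-identical across runs.

# Problem sizes in the test suite

The suite regenerates everything programmatically. Replicated checks use
sizes chosen to keep Monte-Carlo error well inside the asserted
tolerances: 200 cohort replicates at the full 1,920/5,199 design for
odds-ratio recovery (tolerance 0.03 on the mean), 100 replicates for
trend-test power and for the conditional-scan property, 100 EM replicates
of 5,000 genotype pairs for LD recovery (tolerance 0.03), and 500
global-null expression replicates (20 genes × 426 samples) for
false-discovery control. Haplotype-frequency convergence is tested at
$n = 10^5$ with tolerance 0.02.

# Limitations

Single-locus by design: no genome-wide scanning data structures, no
meta-analysis, no reference-panel handling (the replica stands in for the
panel), no multi-locus phasing, no trans-chromosomal 4C, and no survival
or clinical-covariate modelling. The conditional analysis assumes at most
additive, unmatched sampling; matched designs would need true conditional
likelihoods. The evidence ranking is deliberately transparent — three
binary criteria with exposed thresholds — rather than a probabilistic
fine-mapping posterior.
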