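# finelocus

Post-GWAS fine-mapping and regulatory-mechanism analysis for a single
disease risk locus, written for statistical geneticists and regulatory
genomicists who want to go from "a GWAS hit lives here" to "this specific
variant plausibly acts through this enhancer, this transcription-factor
motif and this target gene". The package is modelled on the chronic
lymphocytic leukemia (CLL) risk locus at 15q15.1, where a common variant in
an intronic B-cell super-enhancer alters an NF-κB (RELA) binding motif and
dampens expression of the pro-apoptotic gene *BMF* — but every stage is
generic over its inputs.

Because the real cohort genotypes live in controlled-access archives, the
package ships a synthetic-locus generator that reproduces the statistical
structure the analyses assume (one causal SNP plus high-LD proxies,
imputation uncertainty, enhancer/conservation/motif context, 4C
distance-decay contacts, an allelic dose effect on one gene). The entire
pipeline runs end-to-end on that replica, so everything here is testable
without any download.

## What it computes

**Association and QC.** Per-variant case-control association by the
Cochran–Armitage trend test,
χ² = N·[N·Σⱼwⱼrⱼ − R·Σⱼwⱼnⱼ]² / (R(N−R)·[N·Σⱼwⱼ²nⱼ − (Σⱼwⱼnⱼ)²]) with
additive scores w = (0,1,2), and by Newton–Raphson logistic regression of
phenotype on allele dose (per-allele log-odds β, OR = e^β, Wald p).
Imputed variants carry the IMPUTE-style information score
Is = 1 − Σᵢ(fᵢ − eᵢ²) / (2N·θ̂(1−θ̂)) and are screened with the
conventional fine-mapping filters (MAF > 0.01, Is ≥ 0.80, p < 5×10⁻⁷).
Conditional analysis re-tests every variant with the lead SNP's dose as a
covariate.

**Linkage disequilibrium.** Two-locus haplotype frequencies from unphased
genotypes by the Excoffier–Slatkin EM algorithm (resolving double
heterozygotes), giving D, r² = D²/(p_A q_A p_B q_B) and D′; proxies of the
lead are selected at r² > 0.2.

**Regulatory annotation.** Variants are overlaid on BED interval tracks
(DNase, H3K4me1/3, H3K27ac, super-enhancer, chromatin contact domain) and
bedGraph conservation channels (phastCons, GERP), then ranked by a
three-criterion evidence count: conservation, active-enhancer context, and
motif disruption.

**Motif disruption.** JASPAR-format count matrices become PWMs
(pseudocount-regularised, log₂ odds against a uniform background); both
strands are scanned and the allele-specific disruption score is
Δ = best_ref − best_alt over the motif windows covering the variant.

**4C-seq contact profile.** A DpnII/HindIII restriction-fragment map is
built from the genome sequence, mapped reads are filtered (mapping quality
≥ 30), de-duplicated and allocated to blind/non-blind fragments, binned at
100 bp and smoothed with a 5-kb running mean over unmasked bins.

**cis-eQTL.** For genes with TSS within 1 Mb of the SNP, expression is
regressed on allele dose; p-values are Benjamini–Hochberg adjusted across
tested genes. Spearman correlation and junction k-mer counting cover the
expression-correlation and splicing checks.

## Worked example

```r
library(finelocus)

design  <- locus_design(seed = 42)              # the default study replica
write_fixture_locus(design, "bmf_locus")        # all inputs + config.json
config  <- read_pipeline_config("bmf_locus/config.json")
res     <- run_pipeline(config)

res$survivors[, c("variant_id", "or_", "p_trend", "maf", "info")]
#>    variant_id  or_  p_trend   maf  info
#> 1 sim_proxy_1 1.32 1.86e-11 0.372 0.924
#> 2 sim_proxy_2 1.34 2.16e-12 0.369 0.923
#> 3  sim_causal 1.33 7.62e-12 0.370 0.923
#> 4 sim_proxy_3 1.33 9.35e-12 0.369 0.923
```

Four variants survive the MAF/info/significance filters — the simulated
causal SNP and its three high-LD proxies, each with an estimated per-allele
OR near the generating 1.35. Evidence integration separates them:

```r
res$report[, c("variant_id", "rank", "evidence_count", "conserved",
               "active_enhancer", "motif_disrupting", "p_conditional")]
#>    variant_id rank evidence_count conserved active_enhancer motif_disrupting p_conditional
#> 1  sim_causal    1              3      TRUE            TRUE             TRUE         0.990
#> 2 sim_proxy_3    2              1     FALSE           FALSE             TRUE         0.452
#> 3 sim_proxy_2    3              0     FALSE           FALSE            FALSE            NA
#> 4 sim_proxy_1    4              0     FALSE           FALSE            FALSE         0.796
```

Only the causal variant combines conservation (phastCons 1.00, GERP 4.81),
an active enhancer (DNase + H3K27ac + H3K4me1) and a disrupted RELA-like
motif, so it ranks first; conditioning on the lead leaves no residual
signal anywhere (all conditional p ≫ 0.01; the lead's own entry is NA).
The eQTL stage recovers the expression effect of the risk allele on the
target gene:

```r
res$eqtl[res$eqtl$gene_id == "BMF", ]
#>   gene_id      tss   n   beta     se        p        q
#> 1     BMF 40435000 426 -0.327 0.0696 3.42e-06 3.42e-05
```

i.e. each copy of the risk allele lowers *BMF* expression by ≈0.33 units
(generating truth −0.3), q ≪ 0.05, while no null gene is a stable hit. The
4C stage writes per-channel bedGraphs under `bmf_locus/results/`; the
smoothed contact maximum away from the viewpoint falls in the simulated
enriched interval at the super-enhancer's distal end.

The same stages are available from the shell:

```sh
Rscript inst/cli/finelocus.R simulate --seed 42 --out bmf_locus
Rscript inst/cli/finelocus.R run --config bmf_locus/config.json
```

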