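---
title: "Methods: the dgvar filter cascade, LOH model and interaction tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dgvar filter cascade, LOH model and interaction tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgvar)
library(dplyr)
```

This vignette explains the models and procedures the package
implements, the parameters that matter and their defaults, the design
choices made where the design was genuinely open, and what the
synthetic cohort does and does not emulate. Everything quantitative
below is computed by the package's own tests or the acceptance script;
nothing here is an empirical claim beyond what those compute.

## The deleterious-variant cascade

A germline call survives to pDGV (putative deleterious germline
variant) status iff it passes all of:

| filter | retained region (`wcm` profile) | rationale |
|---|---|---|
| site quality | ≥ 50 (Phred-like VCF QUAL) | sequencing noise |
| read depth | ≥ 10× | genotype confidence |
| VAF | ≥ 0.35 | sub-heterozygous VAF suggests CHIP, a blood clone masquerading as germline |
| SNV cluster | not ≥ 3 SNVs in any 10 bp window | read misalignment produces dense substitution clusters |
| population AF | ≤ 0.01 | common SNPs are not deleterious drivers |
| classification | ClinVar P/LP (cancer or unknown condition) **or** truncating in a TSG with ExAC inbreeding + VQSR pass | restricts to highly damaging events |
| cohort recurrence | carried by ≤ 5% of patients | platform artifacts recur across a sequencing cohort |
| exclusion list | not listed | declarative stand-in for manual review |

Boundary semantics: the filters are stated as removal conditions
("lower than 50", "less than 35%", "more than 1%", "more than 5%"), so
the implementation keeps the exact complement — every boundary value is
retained. A second profile, `spark` (quality ≥ 30, depth ≥ 8, VAF ≥
0.20, no cluster rule), mirrors the laxer pre-filtering used for
population-scale control cohorts called with a different pipeline.

Open choices resolved here:

* **Multiallelic sites** are decomposed at read time into one record
  per alt allele, with VAF = that allele's AD over the site's total
  AD. The convention is applied uniformly; no other stage needs to
  know about multiallelics.
* **Transcript choice**: the effect on the canonical transcript
  (longest CDS) drives truncation calls when annotated, falling back
  to the reported effect otherwise.
* **ClinVar vs. TSG routes are an OR** by default: a
  ClinVar-pathogenic variant outside the TSG list is still a pDGV.
  TSG membership of all pDGVs is an observation, not a constraint; a
  `restrict_to_tsg` switch makes the conjunction available.
* **Benign beats truncating**: a benign/likely-benign ClinVar
  assertion discards the variant even if it truncates a TSG, because
  the benign screen runs before the TSG screen.
* **The VAF floor applies to indels as well as SNVs**; only the
  cluster rule is substitution-specific.
* **Recurrence counts patients**, not aliquots, and is evaluated on
  the raw input cohort. Note the rule is fraction-based: in cohorts of
  fewer than 20 patients a single carrier already exceeds 5%, so the
  cascade is only meaningful at the cohort sizes it was designed for.
* **Rare synonymous variants** (the burden-test denominator) pass the
  identical QC gates; their rarity condition is strict (< 1%), as
  stated for that variant class, while the deleterious cascade retains
  ≤ 1%.

Every input call receives a full pass/fail trace; removals are
attributed to the first failing filter in cascade order, which makes
the per-stage counts conserve: input = output + Σ per-reason removals.

## Burden enrichment

Alternative alleles (1 per het, 2 per hom-alt) of pDGVs and of rare
synonymous variants are counted over a gene panel — the union of genes
harboring a pDGV in any contributing cohort — separately for a cancer
and a control cohort, forming a 2×2 table. The test is the exact
conditional two-sided Fisher test. Two odds ratios are reported: the
sample cross-product (a·d)/(b·c), Haldane-corrected (+0.5 per cell)
when a cell is zero, and the conditional-MLE estimate that
`fisher.test` returns; the cross-product is primary because it matches
the CI construction (Wald interval on the log cross-product OR).
Ethnicity matching is a subset operation on a manifest label before
counting.

Calibration is checked by simulation: independent Poisson allele
counts with a true rate ratio of 2 at realistic magnitudes (cancer
pDGV ≈ 60 alleles against a ~10× larger control), 500 replicates; the
95% CI covers the truth at the nominal rate within Monte-Carlo error.

The CADD comparison contrasts pDGV Phred scores with a seeded random
background of up to 20 truncating non-TSG variants per patient. The
groups are independent and of very different sizes, so the unpaired
Wilcoxon rank-sum test is used; a paired signed-rank test would be
mathematically inapplicable here and is reserved for the paired
primary/metastatic comparison.

## LOH with purity correction

At every pDGV locus, read counts are forced in every tumor of the
patient (re-genotyping without re-calling), giving a raw tumor VAF.
The purity correction divides by tumor purity and clamps:

corrected = min(1, max(0, VAF / purity)),

and LOH is called when corrected tumor VAF / normal VAF ≥ 1.6
(boundary inclusive). The normal VAF is never purity-corrected —
purity is a property of tumor tissue only. QC excludes tumors with
purity < 0.5 (CLONET estimate when available, else pathology review,
else excluded) and loci with < 10 reads. Background controls are
truncating variants in non-TSGs with normal VAF in [0.35, 0.80] — by
definition LOH concerns heterozygous loci.

A property of this crude correction worth stating explicitly: for a
het locus **without** LOH, the corrected VAF is ≈ 0.5/purity, so the
ratio is ≈ 1/purity and crosses 1.6 whenever purity ≤ 0.625. The
correction therefore buys near-perfect sensitivity at every purity the
QC admits (the corrected VAF of a true LOH locus saturates at 1, and
the package's calibration tests show sensitivity ≥ 0.95 at purities
0.5–0.9 and depth 85×) at the cost of a false-positive rate that is
only controlled at high purity (≤ 0.05 at purity 0.9, but large below
~0.65). The tests assert exactly this behavior rather than a
calibration the formula cannot deliver; users who need specificity at
low purity should raise the QC purity cutoff.

Deepening LOH across serial tumors is a two-sided Wilcoxon signed-rank
test on paired (primary, metastatic) corrected VAFs at shared loci;
zero differences are dropped. Ties in |difference| get average ranks,
and for n ≤ 25 the null distribution of the rank sum over all 2^n sign
assignments is computed exactly by convolution over doubled ranks (the
standard exact algorithm breaks under ties, and the normal
approximation is poor at these n). The TSG vs. non-TSG corrected-VAF
distributions are compared with a two-sided Kolmogorov–Smirnov test,
exact for small tie-free samples.

## Somatic consensus

Four callers' normalized VCFs are merged by (tumor, locus, allele);
variants supported by ≥ 2 callers survive (indels can only come from
the two indel-capable callers, so a two-caller indel consensus is
attainable). The five post-consensus criteria (tumor depth ≥ 10, alt
reads ≥ 3, tumor VAF ≥ 5%, normal VAF ≤ 1%, dbSNP-unless-COSMIC,
artifact blacklist) commute, and the tests check order-invariance and
equivalence with a brute-force pairwise-intersection union. Depth
criteria are applied to the tumor sample. When callers disagree on
evidence fields, values come from a fixed caller priority
(mutect2 > strelka > varscan > somaticsniper) for determinism.

## Pathway-level interactions

Per tumor, the patient's pDGV genes are combined with the tumor's
qualifying somatic genes — truncating mutations or copy-number losses
in TSGs, non-truncating mutations in oncogenes (a truncated oncogene
is not activated). Each pathway is tested for over-representation of
the combined set by the upper-tail hypergeometric probability against
a gene universe defaulting to all genes in the annotation table; a
pathway with p < 0.05 (strict) containing at least one germline and
one somatic gene is an interaction. Pathways with identical gene sets
(the same pathway from different source databases) are merged first.
No multiple-testing correction is applied at the stated threshold, by
design; a BH option exists (`adjust = "BH"`). The curated
"cancer-associated pathway" selection is a declarative allow-list
defaulting to all pathways. The descriptive pathway score
log10(1000·g/(G·P) + 1) is monotone in the obvious directions and zero
when the pathway holds no affected gene.

The private-interaction fraction is computed over tumors of patients
with ≥ 2 analyzed tumors (a single-tumor patient cannot have a private
vs. shared distinction); a switch widens the denominator to all tumors.

## The synthetic cohort

The generator's defaults are the study conditions the rest of the
package is calibrated against: 40 patients, negative-binomial read
depth with mean 85× (dispersion 25), about one deleterious plant per
patient (Poisson), per-patient backgrounds of 8 common SNPs (AF
0.015–0.5), 8 rare synonymous variants, 25 truncating non-TSG variants
(so the 20-per-patient CADD background is always samplable), 3
QC decoys each violating exactly one rule (quality, depth, or an
explicit 3-SNVs-in-10-bp cluster), 0.5 expected CHIP-like plants (VAF
drawn in 0.08–0.30), and 2 platform artifacts each planted in ≥ 7.5%
of patients. Tumors: one primary each, half the patients add a
metastasis; purity uniform on 0.5–0.95 with 10% of tumors drawn low
(0.2–0.45) to exercise QC; LOH probability 0.5 per (pDGV, tumor) with
+0.25 in metastases; copy-neutral and deletion models equally likely.
Somatic layer: 8 true variants per tumor, caller sensitivity 0.9 each,
2 private false positives per caller per tumor, and deliberate
in-trans plants (rate 0.4) that put a somatic truncating TSG hit into
a pathway shared with a germline pDGV gene, since such co-occurrence
is vanishingly rare under a uniform null. Pathways are 25 random gene
sets of 8–20 genes over a 400-gene model (30% TSG, 15% oncogene);
small sets keep two-gene overlaps capable of reaching p < 0.05 in a
400-gene universe, as curated pathway databases do.

Allele models: a het locus without LOH draws alt reads Binomial(depth,
0.5); copy-neutral LOH at purity p uses q = (1+p)/2 (tumor cells two
alt copies of two, admixed normal one of two); hemizygous deletion of
the reference allele uses q = 1/(2−p) (tumor cells one alt of one
remaining copy, normal cells one of two — both cell populations carry
the germline allele).

Determinism: every component and patient draws from its own RNG
stream keyed by (seed, component, patient), so regeneration is
byte-identical and enlarging the cohort does not perturb existing
patients (platform artifacts are the one deliberately cohort-level
plant). Positions live on a per-patient 50 bp grid inside per-gene
windows, so planted variants never trip the cluster rule by accident
and different patients never collide at identical keys except where
recurrence is planted on purpose.

What the simulation does **not** emulate — and hence what passing
tests do not show about real data: linkage and realistic site-frequency
spectra, subclonal LOH (planted events are clonal, so corrected VAFs
saturate at 1 and the deepening signal is carried by loci switching
LOH state rather than by gradual VAF drift), caller-specific error
profiles beyond a flat sensitivity and false-positive rate, annotation
errors (the annotation table is exact by construction), and biological
pathway structure beyond the planted in-trans interactions.

## Problem sizes and numerical choices

The shipped tests run the cascade on 40-patient cohorts (~1,900
calls, a few seconds), Fisher enumeration over all 2×2 tables with
n ≤ 30, hypergeometric checks for universes up to 50 genes, exact
KS/signed-rank enumeration at n ≤ 8, 500-replicate CI-calibration and
LOH-calibration simulations at depth 85, and a 1,000-variant consensus
recall check — sizes chosen so a complete run stays in the minutes
range on one core while keeping Monte-Carlo error well inside the
asserted bands. Exact enumeration limits: sign-flip convolution up to
n = 25 (beyond that, tie-corrected normal approximation with
continuity correction); `ks.test`'s exact small-sample p when
applicable. Degenerate inputs are defined rather than left to error:
empty call sets propagate as empty tibbles, all-zero paired
differences report p = 1 with a warning, degenerate Fisher margins
report p = 1 with the OR flagged undefined, and a missing or
non-positive purity excludes the observation with a message.
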