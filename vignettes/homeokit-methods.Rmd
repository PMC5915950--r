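---
title: "Methods: homoeolog-resolved transcriptome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homoeolog-resolved transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeokit)
```

## The problem

An allopolyploid species carries two complete subgenomes inherited from
distinct diploid ancestors. Its duplicated genes (homoeologs) need not be
expressed the way a naive average of the two ancestors would predict:
a homoeolog group's total expression can be additive (equal to the
mid-ancestral value, MAV), dominated by one parent's level (expression
level dominance, ELD), or transgressive (outside the parental range); and
within the hybrid the two homoeologs can be expressed evenly or with a
bias that retains, loses, gains, or reverses the ancestral ratio.
Resolving these patterns from RNA-seq requires (i) knowing where the two
ancestral genomes differ, (ii) a reference for the second subgenome in
the first's coordinate system, and (iii) a rule to attribute each hybrid
read to a subgenome. homeokit implements that chain, together with the
statistics that turn counts into category calls.

## The pipeline and its model

### Homoeologous SNP map

Variant calls are pileup-style records (contig, position, variant base,
depth, variant frequency). A call is **homogenic** when depth ≥ 8 and the
variant frequency is ≥ 0.9 — essentially all of the second ancestor's
reads carry the variant, as expected where that genome differs from the
reference. A call is **heterogenic** when depth ≥ 8 and the frequency
lies in [0.3, 0.7] — the hybrid's two subgenomes contribute the two
alleles at roughly equal coverage. A reference position is a
**homoeologous SNP** when a homogenic ancestor call and a heterogenic
hybrid call agree on contig, position, and variant base. The depth floor
of 8 follows the pileup caller's default; the frequency cutoffs are this
package's defaults (callers in this family do not publish canonical
values) and are configurable via `snp_thresholds()`. Whether a hybrid
frequency window should be applied at all is genuinely open; setting
`het_low = 0, het_high = 1` disables it.

Multi-allelic positions are outside the bi-allelic call model and come
out AMBIGUOUS. Splice-site annotation uses the standard 2-bp window at
intron boundaries, taking precedence over the plain intron label. Coding
effects substitute the alternative allele into its codon (strand-aware)
and translate with the standard genetic code; a first codon ceasing to
be ATG is a start loss, a non-terminal codon becoming a stop is a stop
gain, and the terminal stop becoming a sense codon is a stop loss.

### Virtual second-ancestor genome

The virtual genome replaces each mapped reference allele with the
mapped alternative allele, in place. Contig names, order, and lengths
are unchanged, so every annotation transfers without liftover, and
re-applying the allele-swapped map restores the reference exactly (an
involution the tests exercise byte-for-byte). Records whose reference
allele disagrees with the genome stop the construction by default
(`on_mismatch = "error"`); a lenient mode skips them with a message,
since the behaviour of legacy scripts on such records is unknowable.

### Subgenome read sorting

Each hybrid read aligned against both genomes carries two mismatch
counts (SAM `NM`). The sorter applies the minimal consistent rule:
strictly fewer mismatches wins; an exact tie, or failure to map to
either genome, leaves the read unclassified. A read that maps to only
one genome is taken as evidence for that genome — requiring both-genome
mapping would discard reads spanning indel-divergent regions for no gain
in the ungapped model. Multi-mapped reads keep their lowest-`NM`
alignment per genome; a tie among a read's own alignments drops it to
unclassified for that genome. A configurable `max_nm` cap exists but
defaults off.

### Quantification

Counting uses the exon-union rule: a read increments a gene if its
alignment interval overlaps the exon union of exactly one gene; reads
overlapping none or several genes stay uncounted. RPM is
`1e6 × count / library_size`. A gene is **expressed** in a group when
RPM ≥ 1 in *every* biological replicate (inclusive). The MAV
pseudo-sample for replicate r is the sum of the two ancestors'
replicate-r counts with summed library sizes — the count-space analogue
of averaging expression, chosen (over averaging RPMs) because the
downstream test works on counts; when library sizes match it equals the
RPM mean exactly. The hybrid total is built by the *same* code path from
the two homoeolog columns, which keeps the additivity comparison
internally consistent. Replicates pair by index; the pairing is
arbitrary but fixed.

Sample correlation matrices (for condition comparisons) use Pearson
correlation over genes on `log2(RPM + 1)` by default; raw-scale
correlation is a flag. The log scale is the package's choice — the
field's heatmaps are usually log-scale, but the choice is recorded in
the output rather than silently assumed. Constant profiles yield `NA`
with a warning, never a silent zero.

### The negative-binomial Wald test

Counts are modelled as NB with `Var = mu + phi mu^2`. For a two-group
comparison the test is deliberately explicit and simple:

1. size factors by median-of-ratios over the pair's samples, with a
   geometric-mean reference over genes with all-positive counts;
2. normalized group means `mu_A`, `mu_B`;
3. per-gene dispersion by method of moments with the ANOVA pooled
   within-group variance
   `s² = ((n_A−1)s²_A + (n_B−1)s²_B)/(n_A+n_B−2)`,
   `phi = max((s² − mu)/mu², 1e-8)`;
4. Wald statistic `z = ln((mu_B+c)/(mu_A+c)) / SE` with
   `SE² = (1/n_A)(1/(mu_A+c)+phi) + (1/n_B)(1/(mu_B+c)+phi)` and
   pseudo-count `c = 0.5`; two-sided normal p; BH adjustment.

There is no dispersion shrinkage and no fold-change moderation, so the
numbers will not match shrinkage-based packages; the test is instead
calibrated by simulation (see below). The pooled *within-group* variance
was chosen over pooling all samples around the grand mean: the latter
absorbs the between-group difference into the denominator, which makes
the test conservative under the null (empirically ~0.02 type-I at
nominal 0.05) and increasingly conservative under the alternative. The
pseudo-count keeps the log ratio finite for zero-mean groups; genes with
zero counts in every sample of a pair are skipped, not called equal —
absence of evidence is not evidence of equality. The dispersion floor
(1e-8) only guards against negative moment estimates; the Poisson term
`1/mu` dominates the SE in that regime.

Relations are reported for "first-named group vs second": GT means the
first is significantly higher at FDR ≤ alpha (inclusive, alpha = 0.001
by default), EQ means not significant. All five pairwise tests (hybrid
total vs MAV, vs each ancestor; ancestor vs ancestor; homoeolog vs
homoeolog) use this one convention.

### Category calls

Additivity, from three relations: EQ to MAV is ADDITIVE; otherwise
equal to exactly one ancestor is ELD toward that ancestor; above both is
TRANSGRESSIVE_UP, below both TRANSGRESSIVE_DOWN; everything else —
including the awkward case of differing from MAV while EQ to both
ancestors, which is possible since MAV sits between them — is
OTHER_NONADDITIVE. ELD deliberately requires difference from the *other*
parent; without that requirement a gene equal to both parents would be
"dominated" by both at once. Bias, from two relations (ancestral ratio
vs hybrid homoeolog ratio): (EQ,EQ) no bias; same inequality retained;
inequality vanishing lost; appearing gained; flipping reversed. No bias
and retained bias form the ancestral pattern class. Both taxonomies are
mutually exclusive and exhaustive, verified by enumeration in the tests.

### Divergence dating

Because the virtual genome shares coordinates with the reference, each
gene model splices a homoeologous CDS pair directly. Ka and Ks follow
Nei–Gojobori (1986): per-codon synonymous-site fractions from the
standard genetic code averaged over both sequences (changes to or from
stops count as nonsynonymous); substitution pathways for multi-hit
codons averaged over orderings, skipping pathways through stop codons
(with a fallback to all pathways if every one is blocked); Jukes–Cantor
correction `d = −(3/4) ln(1 − 4p/3)`, with p ≥ 3/4 reported as saturated
(`NA`), never as a number. The trailing stop codon pair is excluded;
codons with an internal stop in either sequence are masked with a
warning. Divergence time is `T = mean(Ks) / (2 lambda)` with the grass
synonymous clock `lambda = 6.1e-9` substitutions/site/year as default;
saturated values are excluded from the mean. The counting method here is
NG86 rather than the Yang–Nielsen-family estimator sometimes used for
this purpose: NG86 is exactly testable against a brute-force enumeration
oracle, and the `method` field leaves room for extensions. Per-gene Ks
values are averaged once across genes (not within and then across
groups).

### Enrichment

Terms annotated to more than 3000 genes are excluded before testing
(inclusive retention at exactly 3000), then each term gets a one-sided
Fisher exact test — the upper hypergeometric tail `P(X ≥ k)` — against
the full annotated population, with BH across the tested terms only.
One-sided is the natural enrichment reading; the tail is computed by
`phyper` and verified against an explicit binomial-coefficient summation
over every 2×2 table with margins ≤ 50.

## The synthetic study: what it emulates, what it does not

The generator (`sim_config()`, `simulate_study()`) stands in for the
archived sequencing data of a real three-species design. Its stated
world:

* **Genomes.** One 200-kb contig; the second ancestor differs at each
  site independently with probability `d = 0.005` (uniform choice among
  the three alternatives, no transition/transversion skew) — the order
  of divergence between closely related congeneric grasses, and enough
  that a 150-bp read spans ≥ 1 SNP about half the time. Two-exon gene
  models (UTRs, split CDS, intron) tile the contig on alternating
  strands; CDS start ATG, end with a stop, no internal stops.
* **Reads.** Ungapped 150-mers drawn uniformly from either genome with
  i.i.d. base errors at `e = 0.002`. No indels — so alignment `NM` is
  exactly a Hamming distance and the sorter can be checked against an
  exact oracle. The oracle aligner places each read at its true locus;
  real-aligner mapping ambiguity is out of scope.
* **SNP calls.** Truth sites emit an ancestor call with frequency in
  [0.93, 1] and a hybrid call in [0.40, 0.60] at depth 20. The paper
  trail for real callers' empirical frequency distributions is thin;
  these ranges are simply the model the homogenic/heterogenic
  definitions imply, which is exactly what a green round-trip test
  establishes — no more.
* **Counts.** Per-gene library fractions are log-normal
  (`meanlog = log(1e-5)`, `sdlog = 1`) over a nominal library of
  `N = 1e6` mapped reads, NB dispersion `phi = 0.05`, three replicates —
  mean counts of a few tens per gene, the regime the package's own
  worked examples use. Planted categories realize the classification
  definitions: additive hybrids sit at the ancestor mean, ELD copies one
  ancestor with the ancestors a fold `F = 4` apart, transgressive genes
  exceed (or undercut) both ancestors by `F`, and the bias plan sets the
  homoeolog ratio relative to the ancestral ratio. The two homoeolog
  pseudo-samples carry `N/2` each — halves of one hybrid library — so
  the hybrid-total and MAV RPMs are directly comparable. A
  `deterministic` count mode emits rounded means for exact assertions.

A green test suite on this world establishes internal correctness —
exact round trips, oracle equivalences, calibration of the test, and
recovery of planted structure. It does **not** establish performance on
real data, where alignment ambiguity, indels, paralogy, coverage bias,
and dispersion trends all exist and are deliberately out of the model.

## Numerical choices, in one place

| Quantity | Value | Why |
|---|---|---|
| call depth floor | 8 | pileup caller default |
| homogenic frequency | ≥ 0.9 | package default, configurable |
| heterogenic window | [0.3, 0.7] | package default, configurable |
| splice-site window | 2 bp | standard convention |
| expressed filter | RPM ≥ 1, all replicates | stated rule, inclusive |
| significance | FDR ≤ 0.001, inclusive | stated rule |
| Wald pseudo-count | 0.5 | finite log-ratios at zero means |
| dispersion floor | 1e-8 | guards negative moment estimates |
| sorter ties | unclassified | minimal consistent 3-group rule |
| large-term cutoff | > 3000 excluded | stated rule, strictly greater |
| clock rate lambda | 6.1e-9 /site/yr | grass synonymous clock |

## Calibration results the tests compute

With the defaults above, the 5000-gene null simulation puts the raw
p < 0.05 fraction at ~0.055 (band [0.03, 0.08] in the acceptance suite);
planted 8-fold changes at means ≥ 50 are detected at FDR ≤ 0.001 with
> 95% power; and in the full category-recovery run (F = 4, phi = 0.02,
means ≥ 100) ~97% of genes receive their planted additivity category and
~98% their planted bias category. One caveat the tests document rather
than hide: per-category recovery is not uniform. An ELD gene whose
hybrid copies the *higher* ancestor sits only `2/(1+1/F)` = 1.6-fold
from the mid-value at F = 4, and at n = 3 that contrast hovers near the
FDR ≤ 0.001 boundary, so that subset recovers at ~87% while all others
exceed 95%. This is a property of the definitions and the stringency,
not of the implementation.

## Known limitations

* No indel or structural-variant handling anywhere; the read model and
  the effect annotator are SNP-only.
* The NB test has no dispersion shrinkage; at n = 3 its per-gene moment
  estimate is noisy, and the type-I behaviour depends on the count
  scale (it is calibrated in the tens-of-counts regime the generator
  states).
* The read counter ignores strandedness and assigns whole reads, not
  fractional overlaps.
* NG86 assumes equal mutability of pathways; lineages with strong
  transition bias will see Ks compressed relative to codon-model
  estimators.
* Enrichment takes annotations as given — no ontology-graph
  propagation.
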