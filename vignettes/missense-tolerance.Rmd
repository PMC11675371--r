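---
title: "Missense tolerance profiling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missense tolerance profiling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senscan)
```

## The problem

Clinical variant repositories (ClinVar-style) and population repositories
(gnomAD-style) describe two different samples of the same protein: variation
observed in affected individuals, and variation the general population
carries without a reported phenotype. Where the two densities diverge along
the residue axis — clinically reported missense variants clustered in a span
that the population leaves sparse — the span is a candidate critical
subdomain. senscan turns that intuition into a reproducible per-residue
statistic and a region caller, together with a truncation-variant pathway
(last-exon NMD rule, haploinsufficiency-tolerance report) for the
complementary question of whether losing one allele of the gene is tolerated
at all.

## The tolerance curve

For each source the input is a deduplicated list of missense positions: one
record per distinct protein-level substitution, so neither allele counts nor
submission counts weight the curve, and two different substitutions at the
same residue count twice. The smoothed density at residue $i$ is

$$\mathrm{raw}(i) = \sum_{p} K(i - p), \qquad
  K(d) \propto e^{-d^2 / 2\sigma^2},\ |d| \le \tfrac{w-1}{2},$$

with the kernel truncated at the window and renormalized to unit sum. The
implementation evaluates this as a convolution of the per-residue count
vector (via `stats::convolve`); the test suite holds it to within $10^{-10}$
of a direct per-residue summation oracle on random instances up to
$L = 2000$.

**Window and sigma.** The window defaults to 31 residues — wide enough that
a handful of neighbouring variants form a contiguous peak, narrow enough to
resolve subdomains of tens of residues. The kernel's standard deviation is
not separately prescribed anywhere authoritative, so the package fixes
$\sigma = (w-1)/6$: the window edge sits at $3\sigma$, retaining
$\approx 99.7\%$ of the untruncated Gaussian's mass, which makes the
truncation numerically irrelevant while keeping the correction below well
defined. Both are user-configurable. The kernel is renormalized *before* the
edge correction; the opposite order differs only by a constant factor that
cancels at the normalization step, so the choice is cosmetic and is recorded
here rather than exposed as an option.

**Edge correction.** Within $(w-1)/2$ residues of either terminus part of
the window hangs over the end of the protein and would contribute false
zeros. Each raw value is divided by the in-range kernel mass
$m(i) = \sum_{t \in [1,L],\,|t-i| \le (w-1)/2} K(t-i)$, the reciprocal form
of scaling up by the out-of-range fraction. The defining property — a
variant at every residue yields a perfectly flat curve up to both termini —
is enforced in the tests at $10^{-10}$. The correction inflates what little
signal exists at the ends, so edge residues are *flagged*, never dropped:
region calls confined to the flagged zone are annotated low-confidence.

**Normalization and delta.** Each curve with a positive maximum is rescaled
to maximum 1; an all-zero curve (a gene with no clinical records, say) is
left at zero rather than divided — this is logged in the object, and the
delta then reduces to the other curve alone. The collapsed profile is
$\Delta(i) = t_{\text{pop}}(i) - t_{\text{clin}}(i)$, the only orientation
under which negative values mark clinically enriched spans.

**Region calling.** Sensitive regions are maximal runs of strictly
$\Delta < 0$, minimum length 1 by default, with no gap merging — the
procedure defines no smoothing of calls beyond the kernel itself, and we do
not add any. No significance test is attached: the statistic is descriptive,
and region boundaries should be read together with the per-region
`min_delta`/`mean_delta` and variant counts that accompany each call.

**Masks.** Some genes carry spans that one database systematically lacks
(e.g. alternatively spliced inserts absent from the population reference
isoform). A mask interval drops the configured source's variants inside the
span and flags the residues in the output and the figures, preventing a
spurious "sensitive" call driven by a bookkeeping artifact rather than
biology.

## Truncations, NMD and haploinsufficiency

Nonsense and frameshift variants are marked at a single CDS nucleotide: the
stop codon's first nucleotide (derived as $3(p-1)+1$ from the protein
position when no nucleotide coordinate is supplied) or the first
inserted/deleted nucleotide when an explicit CDS hint is given. A transcript
is predicted to undergo NMD exactly when that nucleotide falls before the
transcript's last exon; a site at the first nucleotide of the last exon
belongs to the last exon and escapes. Only this last-exon criterion is
implemented — the canonical 50-nt-from-the-last-junction refinement is a
deliberate non-goal, as the simpler rule is what the downstream report is
calibrated against. For frameshifts whose downstream stop would land in a
later exon than the indel itself, the indel position governs, consistent
with the marking rule.

The haploinsufficiency report counts deduplicated truncating variants per
source, split by the rule, and applies an explicitly heuristic,
configurable call: *tolerant* when population before-last-exon truncations
reach 10 and at least triple the clinical before-last-exon count;
*intolerant* when they number at most 5 while any clinical truncation
exists; otherwise *indeterminate*. The defaults reproduce the four
published NLGN worked examples (NLGN1 53 vs 3 → tolerant; NLGN2 64 vs 2 →
tolerant; NLGN3 11-before-last vs 2 → tolerant; NLGN4X 4-before-last vs 6 →
intolerant). For X-linked genes the interpretation is confounded by carrier
sex, and the biology is genuinely ambiguous (female heterozygotes may
tolerate what hemizygous males cannot), so a female-carrier bias — at most
20% of sexed before-last-exon population truncations in males — is surfaced
in the rationale string only, never promoted into the categorical call.

```{r haplo}
fx <- nlgn_truncation_example("NLGN3")
haploinsufficiency_report(fx$clinical, fx$population, fx$transcript)
```

The NLGN examples deserve a caveat: the published analyses report *counts*
(per exon class, per source, per carrier sex), not the underlying variant
positions. `nlgn_truncation_example()` therefore returns synthetic
reconstructions — evenly spaced invented positions on toy transcripts laid
out so every reported count is reproduced exactly. They exercise the
machinery end to end; they are not database records.

## The synthetic generator

`generate_variants()` draws a population background per residue from a
Poisson with a configurable rate, plus Gaussian-shaped clusters
(rounded, clipped to the protein so the implanted $n$ is exact) for either
source, under a single integer seed governing one generator stream.
It emulates the qualitative structure real profiles exhibit — clustered
clinical variants over diffuse population background with optional depleted
windows — and nothing more: no mutational signature, codon usage,
allele-frequency spectrum, or shared-variant correlation between sources.
Passing the recovery test therefore shows the pipeline detects implanted
clusters under Poisson background at the stated rates; it does not certify
performance on real databases, where background density varies along the
protein and the two sources share variants.

The recovery study condition is fixed as: protein length 800, one clinical
cluster of 20 variants at residue 400 (an interior residue, chosen so edge
effects play no role) with sd 5, uniform population background at 0.05
variants/residue, window 31, 100 seeded replicates, success = a called
sensitive region containing the implanted center, required in at least 95
replicates. The generator's defaults are these values.

## Numerical and degenerate-input choices

* FFT round-off from `stats::convolve` is of order $10^{-13}$ over the
  curve; magnitudes below $10^{-15}$ are snapped to zero so that empty
  stretches are exactly zero. The $10^{-10}$ oracle and flatness tolerances
  sit three orders of magnitude above the observed error.
* Strictness of the region threshold: $\Delta < 0$, not $\le$, so exact ties
  (including the all-zero profile) call nothing.
* A window of 1 yields the identity kernel directly; the default
  $\sigma$ formula would degenerate there.
* Variants beyond the protein length are excluded with a warning naming
  them, not an error — transcript-isoform mismatches are common in exports
  and should not abort a batch run.
* Duplicate records at one residue with distinct alternate residues are
  distinct events by design; the generator guarantees distinct alternates
  when it stacks draws on one residue so deduplication never silently
  shrinks a simulated set.
* Reference residues are taken as printed and never validated against a
  protein sequence: published lists occasionally disagree with any single
  isoform's numbering (two different reference residues at one position,
  for instance), and preserving the record as printed is the safer
  default for a tool whose inputs are curated tables.
* Interval conventions: 1-based closed residue coordinates everywhere
  (HGVS convention) except BED output, which is 0-based half-open; the
  writer/reader pair round-trips exactly.

## Problem sizes

The test suite runs the oracle comparison on 50 random instances up to
$L = 2000$ with up to 500 variants, the recovery study at 100 replicates of
$L = 800$, and the exhaustive NMD check over all 333 codons of a toy
three-exon transcript; the whole suite completes in well under a minute on
one CPU, and `scripts/acceptance.R` recomputes the same headline quantities
in a few seconds.

## Known limitations

* No statistical calibration of sensitive regions (no null model, no
  p-values); regions are descriptive summaries of a smoothed difference.
* The two curves are compared only through max-normalization; genes whose
  clinical and population list sizes differ by orders of magnitude will
  have deltas dominated by the sparser curve's kernel shape.
* NMD prediction uses transcript exon structure alone; translation
  reinitiation, 50-nt-rule escape and tissue-specific NMD efficiency are
  out of scope.
* Cross-isoform residue alignment (comparing analogous regions between
  paralogs) is out of scope; profiles are strictly per-gene in one
  transcript's numbering.
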