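# senscan

Residue-level missense-tolerance profiling for single genes, built for
molecular biologists who study rare disease-associated variants (the
motivating case is the neuroligin / *NLGN* gene family in neurodevelopmental
disorders) and want to know *which parts of a protein* are enriched in
clinically reported missense variation relative to the variation the general
population tolerates.

## The method

For one gene, take two deduplicated lists of missense variant positions: a
clinical set C (ClinVar-style, disease-associated) and a population set P
(gnomAD-style, unimpacted individuals). Each distinct protein-level
substitution counts once — never weighted by carrier or submission counts.
For each source *s* and each residue *i* of an *L*-residue protein, compute a
smoothed density ("tolerance value") with a truncated Gaussian window of
width *w* (default 31 residues, σ = (w−1)/6):

    raw_s(i) = Σ_{p ∈ s} K(i − p),      K = unit-sum Gaussian kernel, |i − p| ≤ (w−1)/2

Near the termini part of the window falls outside [1, L] and would
contribute false zeros, so values are divided by the in-range kernel mass
m(i) (edge correction; m(i) = 1 in the interior):

    t_s(i) = raw_s(i) / m(i)

Both curves are rescaled to a common maximum of 1, and the profile is their
difference:

    Δ(i) = t_P(i) / max t_P  −  t_C(i) / max t_C

Maximal runs of Δ < 0 are called **sensitive regions**: spans where
disease-associated missense density exceeds what the population tolerates.
Residues within (w−1)/2 of a terminus are flagged (interpret with caution);
per-gene masks (e.g. splice-insert spans absent from one database) drop a
source's variants and flag the residues.

Separately, nonsense/frameshift variants are classified by the last-exon
nonsense-mediated-decay (NMD) rule — a premature stop before the final exon
of the transcript is predicted to degrade the message — and per-source
early-truncation counts feed a haploinsufficiency-tolerance call
(tolerant / intolerant / indeterminate, with the carrier-sex pattern
reported in the rationale for X-linked genes).

## Worked example

The 11 clinically reported NLGN4X missense variants of the N-terminal
hotspot (p.P81A … p.L114P), bundled in `inst/extdata`, against an empty
population set:

```r
library(senscan)
path <- system.file("extdata", "nlgn_region1_clinvar.csv", package = "senscan")
clin <- read_variant_table(path, dialect = "generic_csv", source = "clinical")
nl4x <- clin[clin$gene == "NLGN4X", ]
prof <- tolerance_profile(nl4x, parse_hgvs_p(character(0)),
                          protein_length = 816, gene = "NLGN4X")
summary(prof)
#> Missense tolerance profile: NLGN4X (816 aa, window 31, sigma 5.00)
#>   clinical variants: 11   population variants: 0
#>   sensitive regions: 1
#>
#> Sensitive regions (delta < 0):
#>  start end min_delta mean_delta n_clinical n_population low_confidence
#>     66 129        -1     -0.488         11            0          FALSE
```

One sensitive region spanning residues 66–129 — the variant cluster (81–114)
plus the half-window reach of the kernel on each side — containing all 11
clinical variants. `plot(prof)` draws the curve overlay (clinical red,
population blue) with the delta panel; `write_curve_tsv()` /
`write_regions_bed()` export the per-residue table and the regions (BED is
0-based half-open; everything else is 1-based closed, as in HGVS).

Truncation analysis on the reconstructed NLGN4X example (printed counts laid
out on a toy transcript):

```r
fx <- nlgn_truncation_example("NLGN4X")
haploinsufficiency_report(fx$clinical, fx$population, fx$transcript)
#> Haploinsufficiency report: NLGN4X
#>   clinical truncations:   6 (6 before last exon, 0 last exon)
#>   population truncations: 5 (4 before last exon, 1 last exon)
#>   call: intolerant
#>   rationale: only 4 population early truncation(s) before the last exon
#>   against 6 clinical truncation(s): haploinsufficiency appears not
#>   tolerated; female-carrier bias: 0 of 4 sexed before-last-exon population
#>   truncations are male, suggesting intolerance in hemizygous males
```

## Command line

A thin Rscript front end wraps the same functions:

```sh
SENSCAN=$(Rscript -e 'cat(system.file("exec", "senscan", package = "senscan"))')
Rscript $SENSCAN simulate --spec spec.json --out sim
Rscript $SENSCAN profile --clinical sim_clinical.csv --population sim_population.csv \
        --gene SYN1 --length 400 --out prof
Rscript $SENSCAN truncations --clinical cl.csv --population po.csv \
        --transcript transcript.json --out report.json
Rscript $SENSCAN exonmap --transcript transcript.json --population po.csv --out map.png
```

Outputs embed a config hash; re-runs with identical inputs and flags are
byte-identical. Accepted HGVS protein notations: `p.X123Y`, `X123Y`,
`p.Xaa123Yaa`, `p.X123*`, `p.X123Ter`, `p.X123fs`, `p.X123Yfs*N`,
`p.Xaa123=`, with one- and three-letter codes canonicalized to one-letter.

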