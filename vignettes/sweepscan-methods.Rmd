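---
title: "Detecting recent positive selection with sweepscan: models, parameters, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recent positive selection with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

A recent selective sweep leaves three distinct footprints in population
sequence data: a distorted site frequency spectrum (excess rare variants and
excess high-frequency derived alleles), unusually long haplotypes around the
selected allele, and — when selection acted in one population only — an
allele-frequency shift concentrated on that population's branch.
`sweepscan` computes one well-established statistic family per footprint
from phased, biallelic SNP genotypes:

* **SFS**: nucleotide diversity $\theta_\pi$, Watterson's $\theta_W$,
  Tajima's $D$, and Fay and Wu's $H$ in sliding windows;
* **haplotype homozygosity**: EHH decay, iHS, and nSL per core SNP, with
  derived-frequency-bin standardization;
* **differentiation**: Hudson's $F_{ST}$ per site and per window
  (ratio of averages), the population branch statistic
  $PBS_A = (T_{AB} + T_{AC} - T_{BC})/2$ with $T = -\ln(1 - F_{ST})$,
  and pairwise LD $r^2$.

Significance is assessed empirically: a value's $p$ is the proportion of the
genome-wide distribution at least as extreme, with top-5%/top-1% cutoff
flags. Input is VCF 4.x with phased `GT` and a 1000 Genomes-style
`AA` (ancestral allele) INFO tag, plus a sample-to-population panel.

## Coordinate and orientation conventions

Positions are 1-based (VCF convention) throughout; scan windows are
half-open `[start, start + window_bp)`, anchored at
`floor(min_pos / step) * step`. Window anchoring is not standardized in the
field; the floor-lattice anchor makes window boundaries reproducible across
subsets of the same chromosome.

Alleles are oriented by `polarize()`: if `AA` equals REF the ALT allele is
derived; if `AA` equals ALT the column is complemented so 1 always codes
the derived allele. The 1000 Genomes dialect encodes low-confidence
ancestral calls in lowercase; matching is case-insensitive by default with
a `strict_uppercase` opt-in, since published pipelines rarely state their
handling. Sites that cannot be oriented are kept as `UNPOLARIZED` and
excluded from derived-allele statistics ($H$, iHS, nSL); Tajima's $D$ and
$\theta_\pi$ are frequency-folded and tolerate them. Missing genotypes are
rejected, never imputed: the intended inputs (fully phased reference panels
and this package's simulator) never produce them, and silent imputation
would corrupt haplotype statistics.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `window_bp` / `step_bp` | 5000 / 1000 | bp | matches the common human whole-genome scan scheme (~1 SNP/kb gives ~5 SNPs per window) |
| `min_snps` | 3 | sites | below this, $D$ and $H$ are reported `NA`; a 1-2 SNP window has no usable spectrum |
| `maf_min` (haplotype tests) | 0.05 | frequency | strict `> 5%`: iHS/nSL are powerless and unstable for rare cores |
| EHH `cutoff` | 0.05 | EHH | integration stops once homozygosity is effectively lost |
| `max_extend_bp` | 1e6 | bp | cap on physical extension |
| `max_gap_bp` | 2e5 | bp | a larger inter-SNP gap aborts the core (assembly gap guard) |
| `gap_scale_bp` | 2e4 | bp | area across a gap $g$ is damped by $20\,\mathrm{kb}/g$ |
| `n_bins` | 100 | bins | equal-width derived-frequency bins for standardization |
| `clamp_eps` | 1e-8 | — | $F_{ST}$ is clamped to $[0, 1-\epsilon]$ before $-\ln(1-F_{ST})$ |

The EHH/iHS defaults mirror the widely used selscan conventions, so scores
are comparable with published scans. MAF filtering is deliberately **not**
applied to the SFS statistics: rare variants are their signal.

`ihs_scan(edge_ok = )` controls the edge policy. By default a core whose
EHH has not fallen below `cutoff` when the data end is skipped
(`EDGE_TRUNCATED`), the usual behaviour on real recombining chromosomes.
On non-recombining simulated loci EHH barely decays, so the default policy
discards essentially every core; `edge_ok = TRUE` (the `--trunc-ok`
analogue) integrates to the data end instead. The test-suite positive
control uses `edge_ok = TRUE` for exactly this reason.

## Estimator choices

**FST.** The paperwork behind many scans says only "pairwise FST".
`sweepscan` uses the Hudson estimator with finite-sample correction,
aggregated across sites as a **ratio of averages**
($\sum$numerators / $\sum$denominators), which is nearly unbiased under
unequal sample sizes; mean-of-ratios is avoided. Raw per-site values are
reported unclamped (negative values are legitimate sampling noise);
clamping to $[0, 1-10^{-8}]$ happens only inside the PBS log transform,
where it is required for finiteness. The identity
$PBS_A + PBS_B = T_{AB}$ is asserted in the tests to $10^{-12}$.
One consequence worth knowing: because negative per-site $F_{ST}$ clamps
to a zero branch length, per-site PBS has a small positive bias under
exchangeability (visible in the symmetric-population test).

**iHS sign.** `unstd = ln(iHH_ancestral / iHH_derived)`: sweeps on the
derived background give negative scores (the Voight convention).

**nSL.** Computed without enumerating haplotype pairs via the tail-sum
identity $E[L] = 1 + \sum_k EHH_{left}(k) + \sum_k EHH_{right}(k)$ in SNP
steps, capped at 100 SNPs per side.

**Empirical p.** "As or more extreme" includes ties, so a member of the
distribution always has $p \ge 1/N$ and no $+1$ correction is needed. The
top-$f$ cutoff is the $\lceil fN \rceil$-th most extreme value; with ties
at the cutoff the flagged set can exceed $fN$ — flags and $p \le f$ agree
exactly only on tie-free data. Tail orientation defaults: $D$, $H$, $\pi$
lower; PBS upper; standardized iHS/nSL two-sided on $|z|$.

## The synthetic-data generator

`simulate_neutral()` is a standard Kingman coalescent under infinite
sites: exponential coalescence times with rate $k(k-1)/2$ in units of $2N$
generations, mutations Poisson with mean $\theta/2 \times$ total branch
length, so $E[S] = \theta a_1(n)$, and $E[\theta_\pi] = E[\theta_W] =
E[\theta_H] = \theta$. `simulate_structured()` draws per-population
frequencies from the Balding-Nichols Beta law, giving
$E[(p_1-p_2)^2] = 2Fp(1-p)$ so the Hudson estimator recovers $F$ directly.
`inject_sweep()` overwrites a chosen fraction of haplotypes with one
template over a span — a star genealogy with exact control of the derived
frequency and the shared-haplotype length. `write_fixture()` emits VCF 4.2
plus panel files that round-trip bit-exactly through `read_vcf()` /
`polarize()` / `read_panel()`.

Defaults were fixed from the conditions the validation suite states:
coalescent calibration at $n = 20$, $\theta = 5$; FST recovery at two
populations, $F = 0.1$, 100 diploids each, 5000 sites; sweep control at
$n = 100$, $\theta = 20$, derived frequency 0.4, span 300 kb. The sweep
locus length (not stated anywhere) is 1 Mb, so the span fits centrally
with room for EHH decay on both sides; the ancestral-frequency law for
structured sites is uniform on $[0.05, 0.95]$, a conventional choice that
avoids near-fixed sites whose Beta draws are numerically degenerate.

### What the generator does *not* emulate — and what a green test means

The coalescent here has **no recombination**. This keeps $E[S]$ analytic
and the simulator fast, but it changes the haplotype landscape profoundly:
every neutral derived clade carries a locus-length shared haplotype, so

* neutral EHH decays only through mutation, never through recombination —
  hence the `edge_ok` policy above;
* iHS/nSL standardization is still internally consistent (bin means 0,
  sd 1; the neutral $|z|>2$ mass matches the Gaussian tail within the
  expected slack), but **the contrast between a true sweep and a young
  neutral clade is far weaker than on recombining data**. A green
  standardization or neutrality test therefore validates the machinery,
  not genome-scale power;
* the copy-based sweep injection demonstrably removes span diversity
  (paired $\Delta\pi < 0$, tested), but it erases rare variants in
  proportion to the pairwise diversity it deletes, so $\theta_W$ falls in
  step with $\theta_\pi$ and windowed Tajima's $D$ is **not** depressed in
  expectation. Real sweeps depress $D$ through the post-sweep excess of
  new rare mutations, a mutational step this injection intentionally lacks.

Both limitations are inherent to the simulator's design (coalescent
without recombination; sweep by haplotype copying), not to the statistics,
which are oracle-verified: $\theta_\pi$ against brute-force pairwise
Hamming distances, EHH against brute-force pair-identity counts, both to
$10^{-12}$; $D$ and $H$ against hand-evaluated closed forms at $n = 4$.
The genome-wide positive-control criterion that presumes recombining-data
power is left failing by design rather than met by weakening it; the
per-component checks above are the meaningful validation at desk scale.

Demography (bottlenecks, growth), genetic maps, and
selection-trajectory sweep simulation are out of scope.

## Degenerate inputs and tie-breaks

* $S = 0$ windows: $D$ is `NA`, never 0; `NA` values are excluded from
  empirical distributions.
* Both populations fixed at a site: the $F_{ST}$ denominator is 0, the
  site is skipped in `pbs_scan()` with a logged count.
* A simulated mutation position colliding with an existing site is
  redrawn (positions are sampled without replacement); an injected focal
  position that is occupied is nudged up by 1 bp.
* Standardization bins with fewer than 2 scores or zero spread leave the
  score `NA` rather than dividing by zero.
* Indels and multiallelic records are excluded on read; the statistics
  here are defined on biallelic SNPs. This is a documented limitation for
  loci where an associated indel matters.

## Known limitations

Autosomal, single-chromosome matrices only; no genetic map (iHS distances
are physical); no recombination or demography in the simulator; BCF and
genotype-likelihood inputs unsupported; empirical p-values require the
caller to supply a genuinely genome-wide background track in replay mode —
the focal locus alone is not a valid null.
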