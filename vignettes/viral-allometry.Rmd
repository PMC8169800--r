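---
title: "Capsid allometry, DNA packing density, and the virion energy budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capsid allometry, DNA packing density, and the virion energy budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virallometry)
```

## The model

Across viruses, capsid volume and genome length are related by a power law

$$V_c = a\,L_g^m, \qquad \log_{10} V_c = A + m \log_{10} L_g,\quad A = \log_{10} a,$$

with the allometric exponent $m$ carrying the biology: $m \approx 1$ means
the capsid grows in proportion to the genome it must house (constant packing
density), while $m \approx 2$ means capsid volume outruns genome length, so
bigger virions are emptier. Group-level fits place icosahedral dsDNA
bacteriophages near $m = 0.95$ ($A = 3.49$) and the giant dsDNA viruses of
protozoa and algae (NCLDVs) near $m = 2.00$ ($A = 1.38$), straddling the
all-virus slope of about $1.13$.

Everything else in the package is a consequence of this law plus elementary
geometry:

* **Packing density.** DNA is modelled as a cylinder of radius 1 nm with a
  0.34 nm rise per base pair, $V_g = 0.34\,\pi\,L_g$ (about 1 nm$^3$ per
  bp). The packing fraction is $V_g / V_c^{\mathrm{inner}}$, where the inner
  volume is the sphere of radius $r_c = R_c - t$ (outer radius minus wall
  thickness). With $r_c \propto L_g^{m/3}$, the density
  $\rho = L_g / r_c^3$ scales as $r_c^{3/m - 3}$: flat for phages
  ($m = 1$), declining as $r_c^{-3/2}$ for NCLDVs ($m = 2$)
  (`density_scaling_exponent()`).

* **Wall stress.** Treating the capsid as a thin-walled spherical pressure
  vessel, the hoop stress is $\sigma = p_c r_c / t$; the capsid stays
  intact while $\sigma < \sigma_u$, the ultimate tensile strength. Because
  pressure increases with packing density, the density scaling above feeds
  directly into the integrity condition: phage pressure is roughly
  size-independent while NCLDV pressure falls with size, which is how very
  large capsids can remain below $\sigma_u$. The functional form of
  $p_c(\rho)$ and the $\sigma_u(r_c)$ curve are inputs, never computed —
  only the stated monotonicities are relied on.

* **Energy budget.** Costs are counted in ATP hydrolysis events per virion.
  Replication from genome length is
  $E_{rep} = 2 L_g (e_d + e_p + e_{od})$ — 94 ATP/bp for a bacterial host,
  110 ATP/bp for a eukaryote. From capsid capacity (genome length
  approximated by inner volume over the bp volume $v_d$) it is
  $E_{rep} = \frac{4\pi r_c^3}{3 v_d}(e_d + e_p + e_{od})$, a pure $r_c^3$
  law; the capacity form is implemented exactly as stated, with no
  additional fill-factor or strand-count factors. Translation of the capsid
  shell is $E_{tl} = \frac{4\pi r_c^2 t}{v_a}(e_a + e_{ea} + e_{oa})$, a
  pure $r_c^2$ law. Equating the two gives the phage crossover radius
  $r_c^{*} = 3 t v_d (e_a + e_{ea} + e_{oa}) / (v_a (e_d + e_p + e_{od}))
  \approx 59.4$ nm: translation dominates smaller phages, replication
  larger ones. For NCLDVs the genome does not fill the capsid, so the
  fitted law is inverted instead,
  $L_g = \left(\frac{4\pi}{3a}\right)^{1/m} r_c^{3/m}$, and with $m = 2$
  the replication cost grows only as $r_c^{3/2}$ — translation dominates
  the NCLDV budget at every size. The ATP cost of the packaging motor
  (~0.5 ATP/bp) is two orders of magnitude below the replication cost and
  is excluded; the budget here is translation + replication only.

## Parameters and defaults

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| $t$ | capsid wall thickness | 3 (phage), 10 (NCLDV), per-record override (e.g. 70 for the multilayer Mimivirus wall) | nm |
| $v_d$ | volume of one base pair | 1 | nm$^3$ |
| $v_a$ | volume of one amino acid | 0.1 | nm$^3$ |
| $e_d, e_p, e_{od}$ | DNA direct / elongation / opportunity cost | 11, 2, 34 (bacterial) or 42 (eukaryote) | ATP per nt |
| $e_a, e_{ea}, e_{oa}$ | amino-acid direct / bond / opportunity cost | 2, 4, 25 (bacterial) or 30 (eukaryote) | ATP per aa |
| fit axes | genome length, capsid volume | kb, nm$^3$ | — |

All of these are visible in one place via `allometry_defaults()`.

The fit-axis convention deserves a note: the intercept $A$ depends on the
unit of $L_g$, and the published group coefficients are only reproduced on
nm$^3$-versus-kb axes (e.g. $a = 10^{1.38}$ with $L_g$ in kb yields
nm$^3$-scale NCLDV volumes, and inverting at $r_c = 100$ nm gives
$L_g \approx 418$ kb). The package therefore fits in (kb, nm$^3$) by
default and records the convention in every `allofit` object; this is a
declared convention of the package, not an observed quantity.

## Curation rules

`read_trait_table()` ingests the canonical CSV/TSV schema; dimensions
reported as `low-high` ranges are resolved to the midpoint, segmented
genomes (`;`-separated) are summed, and `_kb` columns are converted to bp.
`curate()` then applies, in order:

1. **Deduplication** — records with identical capsid dimensions and genome
   length are represented once; the first in input order is retained (a
   deliberate tie-break, flagged in the exclusion report, since duplicates
   may differ in name).
2. **Over-packing filter** — dsDNA icosahedral records whose packing
   fraction exceeds 1 are physically impossible (attributable to capsid
   measurement error) and are removed. The cutoff is strict: exactly 1 is
   retained. Other genome types and shapes pass through untouched, and
   their packing density is never computed — for RNA viruses in particular
   the genome volume cannot be estimated with confidence.

Every removal is logged with its rule in `exclusions()`; counts always
reconcile (output + removals = input).

Dedup keys use the *post-curation* numeric values (midpoints, summed
segments), not raw strings, because the redundancy being removed is of
measured sizes, not of formatting. Enveloped virions use the reported
capsid radius as-is — no envelope correction — and for tailed phages only
head dimensions are stored; tails are never modelled. Icosahedra are
treated as spheres of the reported radius (no triangulation-number
geometry); elongated heads use the spheroid formula with
$a = \mathrm{width}/2$, $c = \mathrm{length}/2$.

## The synthetic generator

`simulate_viruses()` draws genome lengths log-uniformly over the group's
range (phage 10–500 kb, spanning up to the ~498 kb G-phage extreme; NCLDV
100–2500 kb, up to the 2.5 Mb Pandoravirus extreme), applies the group's
power law on log axes with Gaussian noise on $\log_{10} V_c$ (sd 0.3 by
default, which reproduces the observed $R^2 \approx 0.7$ scatter at the
phage geometry), and back-solves each record to an outer radius through
the group's wall thickness. Noise is placed on volume only — genome length
is the OLS predictor and is treated as error-free, matching the fitting
model. A truth table with the noiseless volumes accompanies every draw,
and a single integer seed makes output byte-identical across runs.
`inject_contamination()` adds exact duplicates, range-valued dimensions
and over-packed rewrites in known, disjoint counts so curation can be
tested for exact removal numbers.

What the generator deliberately does **not** emulate: phylogenetic
correlation between records, host-specific measurement error, shape
diversity within a group (all synthetic records are icosahedral), or any
errors-in-variables structure on genome length. Passing tests on synthetic
populations therefore demonstrate the pipeline's statistical correctness
under the model's own assumptions, not the field realism of those
assumptions.

One consequence worth knowing: at the default noise level a realistic
fraction (a few percent) of synthetic phages comes out over-packed and is
curated away — the same phenomenon seen in real data, where a handful of
bacterial viruses exceed fraction 1 and are removed. Tests that need
attributable removal counts use low-noise populations instead.

## Numerical choices and edge cases

* Fits require $\ge 3$ points and strictly positive values (logs must
  exist); groups below the threshold are *reported* as skipped, never
  silently dropped, and a skipped group does not fail a pipeline run.
* The slope p-value is the two-sided t-test on $n - 2$ df — identical to
  the overall F-test in simple regression.
* `hoop_stress()` refuses $t \ge r_c$ and warns when $t > r_c/5$, where
  the thin-wall formula degrades.
* `inner_radius()` refuses $t \ge R_c$ (degenerate capsid), and the
  generator refuses configurations that back-solve to non-physical radii.
* Packing-fraction regressions against radius on noisy populations are
  biased away from $3/m - 3$ because the volume noise enters both axes
  (an errors-in-variables effect); diagnostics that identify the geometric
  exponent use near-noiseless populations.
* The density exponent is implemented as $3/m - 3$, the form consistent
  with both limiting cases ($m=1 \to 0$, $m=2 \to -3/2$).

## Problem sizes

The shipped tests fit populations of 100–400 records, run 500-replicate
recovery studies for bias and CI coverage of the slope, and compare the
OLS path against closed-form normal equations on 1000 random point sets —
sizes chosen so the full suite completes in well under a minute while the
Monte-Carlo standard errors remain far below the tolerances asserted.

## Limitations

* Plain OLS throughout: no phylogenetically independent contrasts, no
  robust or errors-in-variables regression, and no model selection against
  alternatives to the power law.
* Energy costing covers capsid-protein translation and genome replication
  only — no per-gene proteome costs, no lipid membrane synthesis, no
  packaging-motor ATP.
* Mechanics outputs carry whatever pressure unit the caller supplies;
  $\sigma_u$ and $p_c(\rho)$ are user inputs.
* Published per-host exponents can only be re-derived from a real trait
  table in the published schema; the package ships none and performs no
  network retrieval.
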