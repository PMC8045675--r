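---
title: "The MBW activator-inhibitor model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MBW activator-inhibitor model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbwsim)
```

## The biological question

Anthocyanin pigmentation in *Mimulus* petals is switched on by the MBW
complex — an R2R3 MYB (*MYB5a/NEGAN*), a bHLH, and a WD40 protein — which
activates the late biosynthetic genes (LBGs: *DFR*, *ANS*, *UF3GT*) of the
pathway. The complex also activates a single-repeat R3 MYB repressor
(*RTO*), which sequesters the bHLH partner and so shuts the complex down.
This activator–inhibitor loop has two signatures that this package
reproduces computationally:

1. **Fold-change amplification.** An RNAi knockdown that lowers the
   activator transcript a few fold collapses the repressor transcript by an
   order of magnitude, because repressor production responds
   superlinearly to the activator level.
2. **Cryptic spotting.** With the activator nearly cell-autonomous and the
   repressor freely mobile, the loop is a Turing system: depending on the
   basal drive it yields no pigment, semi-regular spots (nectar guides,
   hybrid lobes), or solid color (high-drive lobes), and knockdown can
   carry a solid petal back through the spotted regime to full loss.

## The model

The two species are the activator `a` (MBW complex activity, proxied by
the *MYB5a* transcript) and the inhibitor `i` (*RTO*):

$$\frac{\partial a}{\partial t}
  = f\left(\sigma_a + \frac{\rho_a a^2}{(1+\kappa a^2)\,i}\right)
    - \mu_a a + D_a \nabla^2 a,
\qquad
\frac{\partial i}{\partial t}
  = \sigma_i + \rho_i a^{n} - \mu_i i + D_i \nabla^2 i.$$

This is a Gierer–Meinhardt-type system with basal production rates
$\sigma_a, \sigma_i$, autocatalysis $\rho_a$ saturating at scale
$1/\sqrt{\kappa}$, inhibitor induction with cooperativity $n \ge 1$,
linear decay, and diffusion. The RNAi knockdown factor $f \in (0,1]$
multiplies *total* activator production: RNAi destroys the transcript,
upstream of both the basal and the autocatalytic route. Assumptions worth
stating: the three-protein complex assembly is collapsed into a single
activator variable; repression acts through the $1/i$ divisor rather than
explicit bHLH sequestration kinetics; WD40 is not a dynamic variable (it
appears only as a gene in the transcriptome panel); all dynamics are
deterministic.

### Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `sigma_a` | basal activator production | 0 (well-mixed), 0.05–0.30 (petal zones) | conc/time |
| `sigma_i` | basal inhibitor production | 0 (well-mixed), 0.8 (petal) | conc/time |
| `rho_a` | autocatalysis coefficient | 1 (well-mixed), 0.8 (petal) | conc/time |
| `rho_i` | inhibitor induction | 1 | conc^(1-n)/time |
| `mu_a`, `mu_i` | decay rates | 1, 1 (well-mixed); 1, 2 (petal) | 1/time |
| `kappa` | activator saturation | 0 (well-mixed), 0.3 (petal) | 1/conc^2 |
| `n_coop` | cooperativity of inhibitor induction | 2 | — |
| `D_a`, `D_i` | diffusivities | 0.01, 6 (petal) | length^2/time |
| `f_knockdown` | RNAi factor on activator production | 1 | — |

Time, concentration and length are nondimensional; the activator decay
rate sets the time unit and the petal grid spacing `h = 0.5` sets the
length unit.

## Well-mixed analysis

`steady_state()` reduces the fixed-point problem to one dimension along
the inhibitor nullcline $i(a) = (\sigma_i + \rho_i a^n)/\mu_i$, scans a
logarithmic grid of activator levels (16 decades around the closed-form
scale) for sign changes, polishes each bracket with `uniroot()` to a
residual below $10^{-10}$, and returns the *largest stable* positive root
— the pigmented branch, which is the state compared across knockdown
levels. When no positive root exists the trivial state
$(0, \sigma_i/\mu_i)$ is reported with `trivial_only = TRUE`, which
`knockdown_foldchange()` translates into an infinite fold-down: the
pigment-loss phenotype, not an error.

In the unsaturated, no-basal limit ($\sigma = 0$, $\kappa = 0$, $n = 2$)
the steady state has the closed form
$a^* = f\rho_a\mu_i/(\mu_a\rho_i)$, $i^* = \rho_i {a^*}^2/\mu_i$, so the
fold-downs under knockdown obey $\mathrm{FC}_i = \mathrm{FC}_a^{\,n}$:

```{r foldchange}
knockdown_foldchange(network_params(n_coop = 2), f = c(1, 0.5, 1/3))
```

A threefold activator knockdown with $n=2$ gives a ninefold repressor
collapse; matching the observed 19-fold collapse instead requires
$n = \ln 19/\ln 3 \approx 2.68$. The monotonicity of both steady states
in $f$ — every knockdown lowers the inhibitor — holds for all valid
parameters and is verified over 200 random draws in the test suite.

`integrate_ode()` wraps `deSolve::lsoda` (relative tolerance $10^{-8}$)
for transients; `linear_stability()` evaluates the dispersion relation
$\lambda(k) = \max \mathrm{Re}\,\mathrm{eig}(J - k^2\,\mathrm{diag}(D_a,
D_i))$ and flags Turing instability when the homogeneous state is stable
($\mathrm{tr}\,J < 0$, $\det J > 0$) yet some $k > 0$ grows.

## Petal simulation

`integrate_rd()` uses explicit forward Euler with the 5-point Laplacian
and no-flux (edge-replication) boundaries — the simplest scheme whose
stability bound $dt \le h^2/(4\max(D_a, D_i))$ is checkable; the bound is
enforced and the default step is 90% of it. The initial condition is the
per-zone homogeneous steady state plus seeded uniform noise (default 5%
of the mean — developmental noise large enough to seed patterns within
`t_end = 150` time units). Negative undershoots are clamped at zero; the
continuous model cannot cross zero.

The domain is a 96 × 64 grid (`h = 0.5`) with the proximal third of rows
as nectar guide, a deliberately coarse two-zone petal. The shipped
parameter set (`petal_params()`) was chosen so that the unique
steady-state branch passes through a Turing-unstable band as the basal
activator drive `sigma_a` rises: below the band (drive ≲ 0.1) the petal
stays uniformly unpigmented, inside it (≈ 0.13–0.26) spots form with
wavelength $2\pi/k_{\max} \approx 3.4$ length units, above it (≳ 0.3)
pigmentation is solid. The genotype presets place zones on this axis:
luteus lobe 0.05 < F1 lobe 0.15 < variegatus lobe 0.30, nectar guide 0.18
for all; the RNAi presets knock the variegatus background down to
f = 0.85 (partial: the lobe re-enters the spotted band) and f = 0.15
(strong: both zones lose pigment). The F1 is modelled simply as an
intermediate lobe drive; whether hybrid spotting reflects cis-regulatory
dosage or trans effects is left open, and the presets expose `sigma_a`
directly without committing to a mechanism.

### Phenotype classification

`summarize_pattern()` thresholds the activator field at the midpoint of
its domain-wide range (configurable), then classifies each zone:
*spotted* if the spatial coefficient of variation is ≥ 0.05 **and** at
least one supra-threshold 4-connected component exists; otherwise
*uniform_low*/*uniform_high* by whether the mean clears `uniform_cutoff`
(default 0.5, between the fixture's unpigmented steady states at 0.05–0.25
and its pigmented ones at 0.9–1.2). Spot counts are reported only for
spotted calls. Zone summaries exclude 4 rows on each side of the
guide–lobe boundary: the mobile inhibitor creates a gradient of a few
cells there that belongs to neither zone's interior phenotype, mimicking
a dissection margin. `pigmented_area_fraction` is the supra-threshold
fraction for spotted fields and 0/1 for uniform calls, which makes it
comparable across genotypes whose fields have very different ranges.
There is no quantitative phenotype metric to inherit here; the rule is
documented and every knob is an argument.

## The synthetic transcriptome

`build_panel()` + `generate_counts()` emulate the *downstream product* of
the petal RNA-seq experiment — a genes × samples integer count matrix for
3 wild-type vs 3 RNAi libraries — not the reads. Counts are negative
binomial with mean $\mu_{gs} = \mathrm{depth}_s \cdot \mathrm{baseline}_g
\cdot \mathrm{FC}_g^{[s \in \mathrm{rnai}]}$ and variance
$\mu + \alpha\mu^2$ (default $\alpha = 0.05$; $\alpha = 0$ degenerates to
Poisson). Depth factors are log-normal around 1 (sdlog 0.1). The default
panel: 6 regulators with planted fold-downs MYB5a 3, bHLH1/bHLH2/WD40a
2.5 (midpoint of the observed two-to-threefold range), RTO1 19, RTO2 29
(the assignment of 19 vs 29 to the two homeologs is arbitrary); 30 enzyme
genes split CHS 7, CHI 6, F3H 5, DFR 4, ANS 4, UF3GT 4 (only the total of
30 and the copy enrichment of the early classes are constrained); LBG
copies all 4-fold down and EBG copies cycling {1.5× up, 1.5× down,
unchanged} (qualitative choices reproducing the EBG/LBG dichotomy, not
measured values); and 2,000 null background genes with log-uniform
baselines (10–1,000). Named-gene baselines are log-normal around 1,000
counts and gene lengths uniform on 500–5,000 bases, all drawn with the
panel's own seed so a panel is deterministic given its configuration.

What the generator deliberately does **not** emulate: read-level noise
and mapping ambiguity between homeologs, indirect targets of the
knockdown among background genes (configurable via the effect preset, but
zero by default), correlated library effects, and annotation error.
Passing recovery tests therefore show that the DE stage is calibrated for
honest negative-binomial data at this depth and design — not that it
would survive a real alignment pipeline's artifacts.

## The differential-expression stage

Built from first principles and validated on the generator's known truth:

- **Normalization**: median-of-ratios size factors (geometric-mean
  reference over genes nonzero in every sample), rescaled to unit
  geometric mean; total-count fallback with a warning when no such gene
  exists.
- **Dispersion**: per-gene method-of-moments on normalized counts pooled
  within groups, floored at zero, then shrunk toward the panel mean with
  fixed weight 0.3 — three replicates cannot support a stable per-gene
  estimate, and the shrinkage form is the simplest one that can be stated
  and tested exactly.
- **Test**: Wald statistic on the log2 ratio of normalized group means
  with a delta-method standard error from the NB variance; two-sided
  normal reference; Benjamini–Hochberg adjustment; significance =
  |log2FC| ≥ 1 and adjusted p < 0.05. A pseudocount of 0.5 is engaged
  only when a group mean falls below it: well-covered genes use the pure
  ratio, which keeps log2FC exactly invariant to rescaling any sample's
  column, while zeros remain finite.
- **RPKM** follows its defining identity exactly
  (`count * 1e9 / (length * depth)`), and the segregation statistic is
  the exact binomial test with the minimum-likelihood two-sided
  convention.

Simulation checks in the test suite: BH equals a brute-force step-up
oracle on 1,000 random p-vectors; on all-null data the fraction of genes
with adjusted p < 0.05 stays at or below 0.05 over 20 seeds; each planted
fold in {1.5, 2.5, 3, 4, 19, 29} is recovered within ±20% as the median
over 50 seeds at the default 3 vs 3 design. Problem sizes throughout
(2,036 genes, 50 replicate seeds, 96 × 64 grids, `t_end` = 150) are desk
scale: large enough for the medians and classifications to be stable,
small enough to rerun casually.

## Closing the loop

`compare_model_to_de()` matches the well-mixed model to the DE-estimated
activator fold-down (solving for the `f` that reproduces it) and reports
the predicted inhibitor fold-down next to the observed RTO estimates.
With the default `n_coop = 2` the prediction (about 8-fold at a 2.8-fold
activator knockdown) undershoots the planted 19/29-fold collapses — the
point being that matching them requires stronger cooperativity
(`n_coop ≈ 2.7` for 19-fold), which the comparison makes quantitative.

## Known limitations

- The spatial scheme is first-order in time; patterns are statistically,
  not pointwise, converged at the default step.
- Steady-state root-finding scans 16 decades around a closed-form scale;
  parameter sets whose positive root lies outside that window (extreme
  cooperativity near 1 with large rate ratios) are reported as
  trivial-only rather than found.
- The classification rule's constants (CV 0.05, cutoff 0.5, margin 4
  rows) are calibrated to the shipped fixture's concentration scale;
  re-parameterized models should revisit them.
- The Wald test is anti-conservative for very low counts compared to
  exact NB tests; with the default baselines this regime is rare, and the
  FDR simulations bound the practical effect.
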