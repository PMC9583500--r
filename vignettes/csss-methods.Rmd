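---
title: "Methods: single-cell surprisal analysis and CSSS barcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell surprisal analysis and CSSS barcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csss)
```

## The model

A tumor cell population is treated as a thermodynamic-like system disturbed
away from a balanced steady state by constraints (mutational stress,
irradiation, microenvironment). Each constraint deviates a coordinated subset
of proteins — an *unbalanced process*. For the measured level $X_i(cell)$ of
protein $i$, the model is multiplicative:

$$X_i(cell) = X^o_i(cell)\,
  \exp\Big(-\sum_{\alpha \ge 1} G_{i\alpha}\lambda_\alpha(cell)\Big),$$

where $X^o_i(cell)$ is the reference (steady-state) level, $G_{i\alpha}$ the
weight of protein $i$ in process $\alpha$, and $\lambda_\alpha(cell)$ the
per-cell amplitude of the process. On the log scale this is a plain
factorization. `csss` stores amplitudes so that

$$\ln(X_i(cell) + \mathrm{offset}) = \sum_{\alpha \ge 0}
  G_{i\alpha}\lambda_\alpha(cell)$$

with no minus sign: the stored $\lambda_\alpha$ for $\alpha \ge 1$ is the
negative of the amplitude in the exponent form above. This removes a global
sign trap: all downstream direction logic (is a marker up- or down-regulated
by a process in a cell?) reads off the sign of the stored product
$G_{i\alpha}\lambda_\alpha(cell)$ directly. The $\alpha = 0$ term is the
reference state; `reference_state()` back-transforms it to intensity units.

## Fitting: the covariance route

`fit_surprisal()` computes the SVD of the log matrix
$C = \ln(X + \mathrm{offset})$ through the small $p \times p$ matrix $C^TC$
($p$ = number of markers): its eigenvectors are the $G$ columns, the square
roots of its eigenvalues the importance values (singular values of $C$), and
the amplitudes are the projections $\Lambda = CG$. The $n \times n$
cell-by-cell matrix is never formed, so time and memory are linear in the
number of cells; fitting 500,000 cells on an 11-marker panel is a
millisecond-scale eigenproblem plus one matrix product. With $p$ markers at
most $p - 1$ constraint processes exist (10 for an 11-marker panel), because
one dimension is taken by the reference term.

Numerical choices:

* **Offset.** Cytometry intensities include zeros; the natural log needs a
  positive argument. The default offset is 1 intensity unit, added before the
  log and recorded in the decomposition so results are auditable. Intensities
  are otherwise used raw; any instrument-specific pre-scaling belongs
  upstream.
* **Rank.** The numerical rank is the number of eigenvalues of $C^TC$ at
  least $10^{-12}$ times the largest. The floor is applied to eigenvalues,
  not singular values: machine-epsilon eigenvalue noise surfaces as
  $\sqrt{\epsilon}$-scale singular values, which a singular-value floor would
  miscount as signal. Rank deficiency (a constant or duplicated marker
  column, identical cells) reduces the number of processes with a warning.
* **Sign convention.** Each eigenvector's sign is ambiguous; `csss` flips
  every $G$ column so its largest-magnitude entry is positive, with
  amplitudes flipped to match. Barcodes are therefore reproducible across
  platforms and BLAS libraries.
* **Ties.** Degenerate eigenvalues (relative gap below $10^{-10}$) keep the
  eigen-solver's column order after the sign fix.
* **Ordering.** Processes are ordered strictly by decreasing singular value.
  The expectation that low-index processes appear in more cells is an
  emergent property of that ordering, not enforced.

One identifiability point worth knowing: the factorization does not center
the data, so any *population-mean* process activity is absorbed into the
reference term. If a process is active in a large fraction of cells with one
sign (say, a 21% subpopulation with strongly induced Her2), the fitted
reference level of the affected markers shifts accordingly. The reference
state equals the "baseline" of a generative model only when process
amplitudes average out to about zero over the pooled population. Relatedly,
the constraint axes themselves are identified only up to rotation when
planted amplitudes are correlated across cells; this drives the design of
the synthetic generator below.

## Amplitude thresholds: reading the sigmoid tails

A process is not active in every cell. Sorting $\lambda_\alpha(cell)$ over
all cells gives a sigmoid-shaped curve: a broad body of inactive cells and,
where the process is genuinely active in a subpopulation, a tail that breaks
away from the body. `compute_thresholds()` turns that visual rule into an
algorithm. Thresholds are always computed on the pooled population (all
conditions together): per-condition thresholds would move the ruler between
the groups being compared and confound abundance changes. Activity is
two-sided; the lower tail is "active in the negative sense" (the amplitude
sign encodes how a cell is oriented with respect to the process).

The default `knee` method processes each half of the sorted curve (median
outward, on a grid of up to 512 quantile points):

1. **Locate** a candidate cut at the first prominent local maximum of the
   distance to the chord spanning the half (prominence: at least 0.75 of the
   half's global maximum distance, scanning outward from the median). Taking
   the *first* prominent bend rather than the global one matters when a
   carrier cluster overlaps the body: the global maximum can sit inside the
   cluster rather than at its onset.
2. **Refine** by a one-dimensional two-means iteration (the cut moves to the
   midpoint of the means on either side until stable), which centers the cut
   in the gap between body and cluster.
3. **Gate**: the side is accepted as a genuine tail only if the cells beyond
   the cut are well separated from the body,
   $\big(\mathrm{median}(tail) - \mathrm{median}(body)\big) /
   \big(\mathrm{IQR}(body)/1.349\big) \ge$ `min_separation` (default 4).
   Otherwise the side activates no cells.

The gate is what makes the method usable on a full decomposition, where many
amplitude columns are pure noise. A smooth unimodal curve always has *some*
bend — on a Gaussian column the chord rule alone would "find" a tail of
roughly 5–16% of cells on every side of every process, which fragments every
real subpopulation into spurious barcode variants. The default
`min_separation = 4` was calibrated on the separation statistic's sampling
distribution: Gaussian halves score about 2.5–3.3, Student-$t_5$ about 3.0,
a moderately skewed log-normal about 3.4, while a planted carrier cluster
three noise-SDs out scores 4.4 and a well-separated cluster 20+. Heavier
tails than these can exceed the gate, which is acceptable behavior: genuinely
extreme cells are what the tail rule is after.

Degenerate halves (normalized chord distance below `lin_tol = 0.05`, e.g. a
uniform/linear ramp) have no knee at all; those fall back to the `quantile`
rule with a warning. The `quantile` method (cuts at the `tail_fraction` and
`1 - tail_fraction` quantiles, default 0.05) is also available outright as a
fully reproducible, assumption-free fallback. Both methods log the realized
active-cell fraction per process and side. Whatever the method, the central
interval is widened to the quartiles if it would ever hold less than half
the cells.

## Barcodes and subpopulations

`assign_barcodes()` writes, per cell, a ternary digit per process: `+` above
the upper cut, `-` below the lower cut, `0` otherwise. The default mode is
*signed* because process direction is biology (Her2 induced is a different
phenotype from Her2 repressed); *binary* mode (`abs`) reproduces the
active/inactive barcode presentation. Cells sharing a barcode form a
subpopulation: `tabulate_subpopulations()` counts them per condition.
Letter labels a, b, c, … follow descending pooled abundance (ties broken
lexicographically by barcode string). The all-zero barcode is the
steady-state bulk, labeled `ss`; it is a real row in the table but is never
flagged dominant, since "subpopulation" here means cells defined by at least
one active process. The dominance flag uses the >1% rule
(`abundance_floor = 0.01`) evaluated per condition (`any_condition`), so a
subpopulation that is undetectable at baseline but expands after treatment
is still flagged. Rare barcodes are retained unflagged, never dropped.

`compare_conditions()` reports, per barcode, the fold change of fractions,
the absolute change, and a two-sided two-proportion z-test p-value with
Benjamini–Hochberg adjustment across barcodes. When the control fraction is
below the detection floor (default one cell of the control sample), the fold
change is reported as the conservative lower bound
`treated_frac / detection_floor` — never infinity — and the barcode is
flagged *emergent* when the treated fraction clears the abundance floor.
When per-replicate tables are available (e.g. one per flask), a two-sample
Student t-test on per-replicate fractions replaces the z-test; pooled
fractions remain the reported effect sizes. Both pooled and replicate-mean
workflows are thereby supported.

## Process networks

`build_process_network()` exports process $\alpha$ as the set of markers
with $|G_{i\alpha}| \ge$ `g_cut`, each with its exact weight (no rescaling)
and a direction: the sign of the mean of $G_{i\alpha}\lambda_\alpha(cell)$
over a chosen cell subset (cells active on the positive side, the negative
side, or all cells). There is no principled universal weight cutoff, so the
default `1.96 / sqrt(n_markers)` (a loading that stands out of a flat unit
vector) is deliberately visible in the output log and meant to be
overridden. Interaction edges are imported from a pre-downloaded two-column
file and filtered to the node set; no live database access.

## The synthetic generator

`synthetic_spec()` / `generate_cells()` use the decomposition model
generatively:

$$X_{ic} = \exp\Big(\ln b_i + \sum_a G^{planted}_{ia}\lambda_{ac} +
  \varepsilon_{ic}\Big), \qquad \varepsilon_{ic} \sim N(0, \sigma^2).$$

Noise is Gaussian on the log scale (multiplicative on intensities), matching
the model's structure and the right order of magnitude for bright-channel
FACS intensities. Cells belong to planted subpopulations defined by barcodes
over the planted processes; active amplitudes are
$\mathrm{sign} \times A$ with relative jitter (CV 0.1), inactive processes
get small nonzero jitter so sorted-amplitude curves have a realistic sigmoid
body for the knee detector. Subpopulation counts are allocated
*deterministically* from the mixing fractions (largest-remainder rounding);
randomness enters only through amplitudes and noise. The planted fractions
are the study conditions, and multinomial assignment would add ~10% relative
sampling noise to a 0.3% control fraction — exactly the quantity the
fold-change analysis anchors on.

Defaults (units are log-intensity for amplitudes and noise):

| parameter | default | meaning |
|---|---|---|
| `amplitude` | 3 | active-process amplitude; 15 jitter SDs, well past the tail gate |
| `noise_sigma` | 0.05 | per-entry log-scale measurement noise |
| `inactive_sd` | 0.2 | jitter of inactive amplitudes (sigmoid body width) |
| `amplitude_cv` | 0.1 | relative spread of active amplitudes |
| `n_cells` | 30,000/condition | the scale at which subpopulation quantification is performed |

`rt_scenario_spec()` is the reference scenario: an 11-marker surface
oncomarker panel (Her2, EGFR, cMet, MUC1, E-cadherin, EpCAM, CD44, CD24,
PD-L1, AXL, vimentin), baselines spanning 60–900 intensity units, four
planted processes (a stemness-like axis, an immune-evasion axis, Her2/EGFR
co-induction, and cMet/MUC1 up with E-cadherin down), and eight planted
subpopulations above the 1% floor in at least one condition — among them a
process-3-only subpopulation expanding 0.3% → 21% (70-fold) after treatment,
a process-4-only subpopulation emerging from zero to 1.5%, and one
contracting 9.9% → 4.9%.

Two generator design constraints come straight from identifiability:
planted subpopulations each carry a *single* process, and each process has
carriers on both amplitude signs in roughly balancing proportions. Planted
amplitudes are then uncorrelated across cells with near-zero means, which is
the regime where the eigendecomposition can recover the planted axes at all;
co-occurring processes (cells carrying two processes at once) or strongly
one-sided activity rotate the recoverable axes away from the planted ones.
Planted weight vectors are unit-norm, mutually orthogonal, and orthogonalized
against the log-baseline direction (`orthogonal_processes()`), so they live
in the constraint subspace rather than tilting the reference term.

What the generator does **not** emulate: spectral spillover and
compensation artifacts, autofluorescence, debris/doublets, heavy-tailed or
cell-size-correlated noise, gating effects, or non-orthogonal/correlated
process structure. Passing the recovery tests therefore demonstrates that
the chain of estimators is correct and numerically stable under the model's
own assumptions — not that real cytometry data satisfies those assumptions.
On real panels the practical safeguards are the threshold audit log
(realized active fractions per process), the quantile fallback, and the
barcode table keeping rare variants visible.

## Problem sizes and determinism

The test suite exercises the full chain at 30,000 cells per condition (the
scenario's native scale) for the recovery checks, 50,000 cells for the
reconstruction identity, and 200 cells for the direct-SVD cross-check;
routine per-module tests run on 500–5,000 cells to keep the suite fast.
`scripts/acceptance.R` recomputes the headline quantities from scratch at
the native scale. All analysis stages are deterministic by construction;
the only randomness is in the generator (and the PCA baseline is
deterministic too), seeded from a single integer, so a fixed seed gives
bit-identical artifacts.

## Known limitations

* The decomposition is linear on the log scale; processes whose amplitudes
  co-occur in the same cells are recovered as rotated mixtures, and their
  barcodes split or merge accordingly.
* The reference state absorbs population-mean process activity (see above);
  interpret per-marker reference distributions with that in mind when a
  large fraction of cells carries one process with one sign.
* The knee gate is calibrated against unimodal light-tailed amplitude
  distributions; genuinely heavy-tailed amplitude noise will be read as
  activity.
* The two-proportion z-test treats cells as independent draws; with
  replicate structure available, the replicate t-test is the honest test and
  the z-test is descriptive.
* FCS support covers list-mode FCS 3.0/3.1 with a uniform datatype, read
  only; compensation and gating are assumed done upstream.
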