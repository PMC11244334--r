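---
title: "Quantifying adipocyte lineage tracing: methods and model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adipocyte lineage tracing: methods and model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipotrace)
```

## The scientific question

"Dedifferentiated fat" (DFAT) cells are proliferative, fibroblast-like cells
that appear when mature adipocytes are kept in ceiling culture. Whether they
really descend from adipocytes is decided by lineage tracing: in
*Adipoq:Cre* reporter mice, adipocytes and all their descendants switch
irreversibly from tdTomato to GFP (membrane-localised in the mT/mG reporter,
nuclear-localised in nT/nG). If DFAT cells come from adipocytes they must be
GFP-positive; if proliferation markers (EdU incorporated during S phase,
phospho-histone H3 in mitosis) appear only in GFP-negative cells, the
proliferative population must come from contaminating non-adipocyte cells of
the stromal vascular fraction (SVF).

`adipotrace` implements the complete desk side of that experiment: a
synthetic-microscopy generator with exact ground truth, nuclear segmentation
and per-nucleus measurement, ratio gating with per-well replicate
statistics, and the population-composition model that shows why even a tiny
proliferative contamination ends up dominating a weeks-long culture.

## The population-composition model

Two populations share a dish and are observed every 24 h. Both are thinned
by a common daily survival fraction $s$; only the proliferative ("other")
population grows, with doubling time $d$ (hours):

$$A_{n+1} = A_n \cdot s, \qquad
  O_{n+1} = O_n \cdot s \cdot \left(1 + \tfrac{24}{d}\right), \qquad
  F_n = \frac{O_n}{O_n + A_n}\cdot 100.$$

The default survival is $s = 0.99$ per 24 h. The growth factor
$1 + 24/d$ is a linear within-day approximation of doubling; we keep it as
the model's defining recurrence because it is the form the composition
estimates are built on, and expose the exact exponential alternative
$2^{24/d}$ behind `growth = "exponential"` (default off; at $d = 24$ h both
give a daily doubling, at other $d$ the linear factor is slightly larger).

Because both populations share $s$, the composition is independent of
survival — it cancels. That gives the closed form implemented in
`closed_form_fraction()`:

$$F_n = \frac{f_0\, g^n}{f_0\, g^n + (1 - f_0)}, \qquad g = 1 + \frac{24}{d},$$

and the exact algebraic inversion in `minimal_initial_fraction()`,

$$f_0^{\min}(T) = \frac{T}{g^n (1 - T) + T},$$

the smallest seed fraction reaching a target composition $T$ after $n$ days.
The tests cross-check the recurrence against the closed form to $10^{-12}$
relative tolerance over random parameter draws, assert the survival
cancellation, and verify the inversion against bisection on the monotone
closed form.

```{r model}
tr <- simulate_composition(population_model_params(
  survival = 0.99, division_time = 24, adipocyte_0 = 99, other_0 = 1,
  n_days = 26))
tail(tr, 3)
100 * minimal_initial_fraction(0.95, division_time = 24, n_days = 26)
sweep_doubling_times(c(16, 24, 48, 72))
```

With a 24 h doubling time, a 1% proliferative seed exceeds 99.99% of the
population by day 26; even at a 48 h doubling time it passes 99%. The sweep
reproduces the doubling-time dependence as a table and (in the pipeline) a
plot of final percentage versus doubling time.

## What the simulator emulates — and what it does not

`simulate_field()` renders four co-registered channels per field: nuclear
counterstain, GFP, RFP/tdTomato and one marker channel. Its defaults encode
the study conditions the analysis is meant to recover:

* **GFP+ minority.** `frac_gfp_pos = 0.06`: adipocyte-derived cells are a
  ~6% minority of the culture at endpoint.
* **Proliferation restricted to GFP− cells.**
  `p_marker_pos_given_gfp_pos = 0` and `p_marker_pos_given_gfp_neg = 0.04`
  (the short-pulse EdU positivity scale observed in GFP− cells; time-course
  designs can raise it per timepoint).
* **Reporter bimodality.** Foreground intensities are log-normal per
  population (`fg_pos`/`fg_neg` medians, common `sdlog`), which produces the
  log-scale bimodal GFP/Tomato ratio that ratio gating assumes. In
  `nuclear_ratio` mode GFP+ nuclei are GFP-bright/Tomato-dim and GFP−
  nuclei the converse; `membrane` mode instead renders a ~2 px ring at the
  cell boundary and exists to check that nuclear segmentation is robust to
  off-nucleus fluorescence.
* **Noise.** Gaussian read noise (`read_sd = 40` on a 16-bit scale with
  ~200-unit backgrounds and ~3000-unit nuclear foregrounds) plus optional
  Poisson shot noise.

Nuclei are disks (radius $8 \pm 1$ px at the default 10X-like scale) placed
by dart throwing with a minimum centre distance; a configurable
`clump_frac` plants deliberately touching pairs to exercise watershed
splitting. Disks make every downstream oracle analytic: areas are
$\pi r^2$, per-nucleus channel means equal the configured foregrounds
exactly when `sdlog = 0` and noise is off, and the reference label raster is
exact by construction. Cell density per field and nucleus size are free
parameters (the source experiments do not report them); the defaults — 80
cells on a 512×512 field — correspond to a subconfluent 10X field and were
fixed once, before any recovery statistics were examined.

The simulator deliberately omits photobleaching, illumination gradients,
PSF blur, cytoplasm segmentation and time-lapse tracking. Passing recovery
tests on these images therefore validates the *measurement contract*
(detection, mean/integral measurement, gating arithmetic), not performance
on degraded real microscopy; on real data the segmentation parameters and
cutoffs must be tuned per experiment.

Pixel coordinates are 1-based with origin at the top-left, rows = y and
columns = x, matching R's matrix indexing.

## Segmentation and measurement

`segment_nuclei()` follows the standard Hoechst pipeline: median-background
subtraction, Gaussian smoothing (`smoothing_sigma = 2` px), Otsu threshold
(or a fixed value), hole filling, then a distance-transform watershed that
splits touching nuclei (seed neighbourhood `seed_separation = 6` px, about
0.8× the expected radius; ridge tolerance 0.3 px — low enough to separate
nuclei whose centres are 1.5 radii apart, while smooth disk interiors do not
fragment). Objects outside `[min_area, max_area]` = [50, 2000] px² and, by
default, objects touching the border (truncated areas and integrals) are
removed, and labels are renumbered densely. The procedure is deterministic
and idempotent.

`measure_nuclei()` then applies the measurement contract: GFP and RFP are
*averaged* over the nucleus pixels, the marker signal is *integrated*
(summed) over the nucleus, and the reporter ratio is
$(\bar g + \varepsilon)/(\bar r + \varepsilon)$ with
$\varepsilon = 10^{-6} \times$ the larger of the two channel maxima — a
guard against division by zero that is negligible (< 0.1%) for any real
signal.

## Gating and statistics

`gate_cells()` applies one fixed pair of cutoffs to every record of an
experiment — constancy across samples is enforced by the single
`gate_config` per run. Gating is strictly greater-than; ties fall negative
(the convention had to be fixed somewhere, and the conservative side avoids
inflating the rare positive class). Cutoffs are ideally chosen manually
from the ratio/marker density plots; `suggest_cutoff()` automates the
obvious choice by finding the valley of a kernel-smoothed log10 histogram
between the two dominant modes (or log-domain Otsu), erring out on unimodal
input rather than guessing.

Replicate statistics operate on biological replicates (wells or mice),
never on single cells: per-well fractions from `summarize_wells()` (with
zero-denominator fractions flagged `NA`, never silently 0) feed
`mean_sem()` and `two_sample_t_test()`. "Student" is interpreted as the
pooled-variance test (Welch available via `var_equal = FALSE`); degenerate
zero-variance inputs return defined values (equal means: $t = 0$, $p = 1$)
instead of erroring. `timecourse_table()` reshapes well summaries into the
long (timepoint × condition × population) table used for EdU time courses.

## Numerical and design choices

* **Problem sizes in the test-suite studies**: segmentation recovery uses
  20 seeded 384×384 fields of 40 nuclei; gating recovery uses 20 seeds of
  1000 cells (cell-table level — gating needs no pixels); the end-to-end
  run uses 3 wells of 80 cells. These sizes give binomial error bars well
  inside the asserted bounds while keeping a full run in seconds.
* **Seeding**: every stochastic step derives from one integer seed; the
  pipeline fans a global seed out to per-stage seeds by a fixed affine map,
  so stages are independently reproducible and identical configurations
  reproduce outputs byte for byte.
* **Overlapping nuclei** in the ground-truth raster are resolved by
  assigning contested pixels to the nearest centre.
* **Label maps** are written as 16-bit TIFF (≤ 65535 nuclei per field);
  images round-trip integer-exactly.
* **Degenerate inputs**: blank images segment to an empty label map; empty
  well groups summarise to `n_total = 0` with undefined fractions; an
  unreachable placement density fails with the achievable density named.

## Known limitations

* Equivalence with the original study's per-cell values is not claimable:
  its segmentation/measurement settings (via an external MATLAB package)
  and manual cutoffs are unpublished, and its raw images are not consumed
  here. What is reproduced is the measurement contract and the model
  arithmetic, validated against synthetic ground truth.
* The per-replicate values behind the published "average 5.7% GFP+" are not
  printed anywhere, so that exact number cannot be recomputed; the pooled
  27/440 = 6.14% arithmetic is asserted instead, and the simulator's 6%
  default stands in for the population it describes.
* The composition model is deterministic; it estimates expected
  composition, not the variance of small founder populations (no stochastic
  birth–death variant).
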