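---
title: "Combining partial phase sets in reciprocal space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining partial phase sets in reciprocal space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasemerge)
```

## The problem

Fragment-based molecular replacement places small, generic model fragments
(a polyalanine helix, a few beta strands) in the unit cell and tries to
expand the resulting rudimentary phases into a full structure.  A single
correctly placed fragment rarely carries enough signal to be recognised:
runs produce hundreds to thousands of partial solutions, only a minority of
them correct, and placement scores often cannot tell the two populations
apart.  Each partial solution implies a set of phases
$\{\varphi_h\}$ over the measured reflections $h$.  All correct solutions
approximate the *same* true phase set (up to an origin ambiguity), so
averaging consistent solutions raises the signal-to-noise ratio, while
wrong solutions scatter incoherently.  `phasemerge` implements this
programme: compare phase sets under the origin shifts the space group
allows, cluster the mutually consistent ones, and merge each cluster into
an averaged phase set with per-reflection figures of merit.

## Metrics

Two phase sets indexed over the same reflections are compared by the
**weighted mean phase difference**

$$\mathrm{wMPD} = \frac{\sum_h w_h\,\Delta\varphi_h}{\sum_h w_h},
\qquad \Delta\varphi_h = \min(|\varphi_{1h}-\varphi_{2h}| \bmod 360^\circ,\;
360^\circ - |\varphi_{1h}-\varphi_{2h}| \bmod 360^\circ),$$

with weights $w_h = m_{1h} m_{2h} F_{1h} F_{2h}$ (figure-of-merit product
times amplitude product; when both sets carry the same observed amplitudes
this is the familiar $m_1 m_2 F^2$ weighting).  The wMPD is $0^\circ$ for
identical sets and $90^\circ$ in expectation for unrelated sets — the
weights scale each term but not the uniform distribution of
$\Delta\varphi$, so the $90^\circ$ noise floor holds for any amplitude
distribution.  The **map correlation coefficient** is evaluated in
reciprocal space as

$$\mathrm{mapCC} = \frac{\sum_h m_{1h} F_{1h}\, m_{2h} F_{2h}
\cos\Delta\varphi_h}{\bigl(\sum_h (m_{1h}F_{1h})^2\bigr)^{1/2}
\bigl(\sum_h (m_{2h}F_{2h})^2\bigr)^{1/2}},$$

which by Parseval's theorem equals the Pearson correlation of the two
fom-weighted electron-density maps (the $F_{000}$ term is excluded, so the
maps have zero mean); the test suite verifies this against a gridded
real-space synthesis.  A wMPD against the *true* phases is called a wMPE
(weighted mean phase error); solutions with wMPE below $80^\circ$ are
flagged as nonrandom.

## Origin shifts

Two descriptions of the same structure may sit on different permitted
origins, changing every phase by $360\,(h \cdot t)$ without touching any
amplitude.  For nonpolar groups the permitted shifts form a small discrete
group (e.g. $\{0,\tfrac12\}^3$ in $P2_12_12_1$, the quarter-diagonal cycle
$\{0,\tfrac14,\tfrac12,\tfrac34\}\,(1,1,1)$ in $F23$ and $F222$); along
polar axes the origin is continuously free ($b$ in $P2_1$ and $C2$, $c$ in
$P6_3$, all three axes in $P1$).  The package hard-codes these tables for
P1, P2~1~, C2, P2~1~2~1~2~1~, C222~1~, F222, F23 and P6~3~; the test suite
validates every entry with a brute-force oracle (translate a random
structure by the tabulated shift, recompute structure factors, demand
amplitude invariance and the phase rule $\varphi' = \varphi - 360\,h\cdot
t$) and checks closure under addition.  For centred lattices one
representative per coset of the centring translations is stored.
Enantiomorph (hand-flip) alternatives and re-indexing are deliberately not
searched; only pure origin translations.

Sign convention: `apply_origin_shift(ps, t)` re-expresses phases after
moving the *origin* by $+t$, i.e. $\varphi' = (\varphi - 360\,h\cdot t)
\bmod 360$.

## Shift search algorithms

* **discrete** (nonpolar groups): evaluate the wMPD at every tabulated
  shift, keep the minimum.  Ties break toward the first entry in canonical
  table order.
* **sparse** (single polar axis): for each discrete candidate, estimate
  the polar component from the weighted circular mean of the phase
  differences on the layer with polar index 1 (where the phase offset is
  exactly $360\,t_{\mathrm{polar}}$), then refine against all reflections
  by golden-section minimisation of the wMPD.  If the layer is empty the
  caller falls back to the FFT search.
* **fft** (any polar group): build $G_h = w_h e^{i(\varphi_{1h} -
  \varphi_{2h})}$, accumulate onto a grid over the polar indices (64
  points per axis by default; aliasing $h \bmod N$ is exact on the grid),
  and evaluate the translation function $T(t) = \mathrm{Re}\sum_h G_h
  e^{2\pi i h\cdot t}$ by FFT.  The argmax is polished by golden-section
  refinement of the wMPD within one grid cell per axis (tolerance
  $10^{-5}$ fractional, two coordinate sweeps when several axes are
  free).

The automatic rule uses FFT in P1 (three coupled polar axes make the
layer-1 estimate structurally unreliable there) and sparse in other polar
groups, falling back to FFT when layer-1 reflections are missing.  The
test suite checks the three routes against a dense-grid scan oracle on
noisy pairs and requires agreement on at least 95% of cases, and exact
shift recovery to 0.002 fractional on constructed pairs.

## Referential clustering and merging

`phase_cluster()` seeds a cluster with the first (best-scored) solution as
reference.  Each cycle compares every remaining set to the current
reference at its best shift, admits those with wMPD at or below the
tolerance, and rebuilds the reference as the weighted average; by default
three cycles are run, with early exit when the membership stops changing.
Admitted members enter the average with weight
$\omega_j = (\mathrm{tol} - \mathrm{wMPD}_j)/\mathrm{tol}$ — linear in
similarity, chosen for transparency over cosine alternatives — while the
reference keeps $\omega = 1$.  Per reflection the combined phase is the
argument of $\sum_j \omega_j m_{jh} e^{i\varphi_{jh}}$ and the combined
figure of merit is its modulus divided by $\sum_j \omega_j$, so identical
copies preserve their fom and antipodal phases cancel to fom 0.
Amplitudes are copied from the reference; member amplitudes may differ
(calculated amplitudes of partial models do) and only enter through the
comparison weights.

The default tolerance is $60^\circ$, a compromise that admits genuinely
overlapping solutions while keeping the $90^\circ$ noise floor at a safe
distance.  For combining fragments of different structural nature (helices
with strands), whose mutual wMPD approaches the noise floor because they
cover different parts of the structure, a higher threshold around
$83^\circ$ is needed, and the package exposes it.

## Orchestration

`phasemerge()` sorts solutions by their CC (else LLG) scores, compares at a
coarse resolution — 4.0 Å by default, 3.5 Å in P1 where origin
determination is unconstrained in all three directions and more
error-prone — and clusters in two phases: while the pool exceeds
`minchunk` (default `2 * n_cores`), parallel rounds compare contiguous
chunks against one common reference through forked workers, aggregating in
chunk order; the admission decision depends only on the (set, reference)
pair, so membership is identical to a single-core run for any chunking,
which the tests assert for 1, 2 and 4 cores.  Below `minchunk` a
sequential pass walks the remaining list, advancing the reference past
entries that attract no member.  Final clusters are re-merged at full
resolution using the recorded shifts; weights keep their comparison-stage
values (recomputing them at full resolution could push a member past the
tolerance and make its weight negative), and the full-resolution wMPD is
reported alongside.

With several groups of solutions (e.g. one per rotation cluster, or
several monomers in the asymmetric unit), the two-step protocol clusters
within groups at the base tolerance and then runs one pass across the
round-1 merged sets at $87^\circ$, letting complementary clusters join.
The second round considers round-1 clusters only, not unclustered
singletons: singletons had their chance to join a reference in round 1,
and re-admitting them at $87^\circ$ would mostly import noise.

## The CC matrix and its embedding

`pairwise_mapcc()` computes the best-shift mapCC for every unordered pair
(shifted to a common origin first — the raw CC of two sets on different
origins is meaningless) and `write_cc_input()` emits the plain "i j cc"
text format read by external CC-analysis programs.  `cc_embed()`
eigendecomposes the CC matrix, clips negative eigenvalues, and scales the
top eigenvectors so that dot products approximate the CCs.  Mutually
consistent solutions then receive vectors of norm approaching 1 while
mutually inconsistent ones land near the origin — the test suite checks
this separation with a rank-sum test at $p < 0.01$ on a 30-solution
landscape.

## The synthetic generator

`make_toy_structure()` draws point atoms (unit scattering weights, no B
factors — phase relationships, not amplitude realism, drive every
algorithm here) uniformly in the cell, rejecting configurations with
symmetry-expanded contacts under 0.5 Å.  `make_partial_solution()` builds
a solution from an atom subset with coordinate jitter, optional truth-
phasor blending, wrapped Gaussian phase noise, a resolution-dependent fom
model $\exp(-2\pi^2\sigma_{\mathrm{eff}}^2/d^2)$, and a random allowed
origin shift (recorded as the shift that maps the solution back onto the
model origin).  `make_landscape()` assembles correct solutions around a
ground-truth model and wrong solutions from freshly drawn unrelated
structures of the same size — which reproduces the $\approx 90^\circ$
wMPE noise floor without modelling the placement program — and attaches
overlapping CC/LLG-style scores (correct $\sim N(30, 6)$, wrong
$\sim N(22, 6)$) so that score-based discrimination is imperfect by
construction.

Two generator choices deserve emphasis.  First, the default toy cells are
sized so that the 4.0 Å comparison shell contains roughly 150–250 unique
reflections per group: the admission test compares a chance minimum over
up to eight origin shifts against the 60° tolerance, and with only a few
dozen effective reflections that minimum starts dipping below 60° for
unrelated sets (real data sets carry thousands of reflections, so this is
the realistic regime, scaled down).  Second, phases of *disjoint* atom
subsets are exactly uncorrelated under direct summation, so the
complementary-fragment regime — distinct fragment types clustering just
below the noise floor — cannot arise from subsets alone; in real
pipelines the correlation is created by density modification pulling
every solution toward the true map.  The `dm_pull` parameter emulates
that pull by blending a fraction of the true phasor into each correct
solution; the heterogeneous fixtures use `dm_pull = 0.3` with 20° phase
noise, which puts cross-family wMPDs between the 60° and 83° thresholds.

What the generator does **not** emulate: scattering-factor and solvent
effects on amplitudes, the non-independence of real solutions (overlapping
fragments from one library produce correlated wrong solutions; our wrong
solutions are independent), rotation-cluster structure, and the density
modification/autotracing steps that ultimately validate a cluster.
Passing tests therefore demonstrate the correctness of the comparison,
search, clustering and merging machinery under a controlled noise model —
not end-to-end structure solution on real diffraction data.

## Benchmark problem sizes and degenerate inputs

The packaged test suite runs landscapes of 10 correct plus 20 wrong
solutions over 20 seeds (clustering), 50 ten-member landscapes at 40°
phase noise (signal-increase check), 100 shift-recovery pairs per space
group, and 10,000-reflection sets for the analytic limits — sizes chosen
to make the statistical assertions stable at desk scale.  Degenerate
inputs are rejected loudly rather than silently repaired: comparisons
between differently indexed sets, all-zero weights, empty phase sets,
out-of-range figures of merit, and unsupported space groups all raise
typed errors.

## Known limitations

Eight space groups are tabulated; other settings (different unique axes,
rhombohedral/hexagonal choices) and the remaining 222 groups are out of
scope, as are MTZ/CIF reflection formats, anomalous data and
hand-flip/re-indexing searches.  The CC-matrix module prepares input for —
but does not reimplement — the external least-squares vector refinement;
`cc_embed()` provides only its eigenvector initialisation stage.
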