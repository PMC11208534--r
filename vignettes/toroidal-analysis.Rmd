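---
title: "Detecting toroidal population structure in grid cell recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting toroidal population structure in grid cell recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gridtorus)
```

# The problem

Grid cells in the medial entorhinal cortex fire on a hexagonal lattice of
spatial locations. A *module* — a subpopulation sharing lattice scale and
orientation — encodes position as a point on a two-dimensional torus: two
periodic coordinates, one per lattice axis. When the animal forages in an
open arena this toroidal structure can be read off the spatial tuning, but in
minimal experiments (head-fixed wheel running, virtual-reality tracks, sleep)
there is no 2-D behavioral covariate to reveal it. `gridtorus` implements a
covariate-free pipeline that discovers modules and their toroidal state space
from the population activity alone:

1. spike/event times → smoothed firing rates (Gaussian kernels, square-root
   transform);
2. neurons → ensembles, by agglomerative clustering of time-lagged
   cross-correlations;
3. population vectors → a whitened point cloud, reduced by a radial then a
   fuzzy (density-based) downsampling;
4. persistent cohomology of the Rips filtration (cosine metric, Z~47~
   coefficients) with a time-roll shuffle null: a module shows the torus
   signature of one prominent component, two significant 1-D holes and one
   2-D void;
5. the two dominant 1-cocycles → circle-valued coordinates on the landmarks,
   extrapolated in time via per-neuron activity distributions on the torus;
6. toroidal rate maps, classified against analytic heat-kernel models of a
   hexagonal versus square torus; and
7. cross-session alignment, phase-conservation statistics, trajectory
   unwrapping and per-trial toroidal path lengths.

Because the pipeline's validity cannot be established on desk-scale
recordings, the package ships three continuous attractor network (CAN)
simulators as a first-class synthetic data source, and the test suite
establishes every structural claim on them.

# The simulators and what they emulate

`simulateInhibitorySheet` integrates rectified rate dynamics on a 56 × 44
periodic sheet with purely inhibitory, direction-shifted connectivity,

$$f_{t+1} = f_t + \tfrac{1}{\rho}\left(-f_t + [\,J + f_t W + \gamma\, s
\cos(\phi - \bar\phi)\,]_+\right),$$

with defaults $J = 1$, $\gamma = 0.15$, shift $l = 2$, radius $R = 20$,
$W_0 = -0.01$, $\rho = 10$, a 2 ms step and 2000 stabilization iterations
from a random state. The weight kernel is not uniquely determined by these
constants alone; we adopt the convention standard for this model class:
$W_{ji} = W_0$ when the periodic sheet distance from unit $i$ to unit $j$'s
position shifted by $l$ along $j$'s preferred direction is at most $R$, with
preferred directions tiled E/N/W/S in 2 × 2 blocks. Output rates are
resampled at 10 ms and floored at $10^{-4}$. Units develop hexagonal spatial
firing; the rest state settles toward a fixed point, with a slow residual
relaxation along the (neutral) translation modes of the bump lattice, so the
strict sub-$10^{-6}$-per-step stationarity is reached a few thousand
iterations after the nominal 2000-step stabilization.

`simulateTwistedTorus` implements the divisive-normalization attractor on a
20 × 20 sheet whose metric is the minimum over the seven periodic copies of
the twisted torus (offsets $(0,0), (\pm 1, 0), (\pm\tfrac12,
\pm\tfrac{\sqrt3}{2})$):

$$w_{ij} = I e^{-d_{tri}(c_i, c_j + v)^2 / \sigma^2} - T,\qquad
b = a + \tfrac{N_{ref}}{N}\, a\,W,\qquad
a' = \big[(1 - \tau)\, b + \tau\, b / \langle b\rangle\big]_+,$$

with the model's published constants $I = 0.3$, $\sigma = 0.24$, $T = 0.05$,
$\tau = 0.8$ and a velocity gain `gridGain = 0.06`. Two implementation
choices are ours and documented as such: the recurrent drive is normalized
by network size (reference 90 units) so the constants remain stable on the
20 × 20 sheet, and the velocity input is expressed per 10 ms reference frame
so the spatial grid scale does not depend on the integration step. With a
random walk in a 1 m arena the defaults give a grid period of about one
sixth of the arena and drag the activity bump around the torus several times
per session. `simulateSquareTorus` is the untwisted variant (ordinary
unit-torus distance, 10 × 10 sheet): the negative control with square
periodicity.

Each simulator records the true bump phase per frame — on the twisted torus
in the dual-lattice circle coordinates $u = 2\pi(x - y/\sqrt3)$,
$v = 2\pi\,2y/\sqrt3$, which are single-valued on the quotient — so decoded
coordinates can be scored against ground truth up to the discrete symmetry
group of the torus.

What the simulators do *not* emulate: spiking noise (rates are noiseless),
heterogeneous tuning widths, conjunctive head-direction tuning, slow drift
and remapping, and realistic firing-rate statistics. A pipeline that passes
on them is therefore validated for geometry and bookkeeping, not for
robustness to every artifact of real recordings; the preprocessing defaults
(kernel widths, speed filter) follow the values used on real Neuropixels
data.

# Parameters that matter

`parameterProfile()` bundles the tunables. Units are seconds, centimeters
per second and whitened-coordinate distances:

* `sigmaSmooth` (60 ms) / `dtTopology` (10–50 ms): rate kernel and sample
  step for topology; `sigmaCluster` (0.3 s) / `dtCluster` (30–100 ms) for
  clustering, where slower co-modulation is the signal.
* `d` (6–8): whitened PCA dimensions. Too small truncates the torus; too
  large admits noise directions that inflate spurious bars.
* `eps`: radial-downsampling radius. It thins dense regions while keeping
  outliers, leaving 30–50 % of points on real data (a clean simulated
  manifold shrinks much further).
* `kappa`, `m`: fuzzy-downsampling neighborhood and landmark count. `m`
  bounds the Rips computation (cubic-ish in `m` at `maxdim = 2`); 600–2200
  is practical.
* `rhoCluster` (given "in r", i.e. correlation-distance units) and `tauMax`:
  the clustering cut and the maximal cross-correlation lag. Ensembles below
  19 neurons are disregarded — too few cells to interpret toroidal
  structure.
* `speedMin` (5 cm/s): immobility filter.

The simulation profile used throughout the tests and the acceptance script
is `d = 6`, `eps = 0.4`, `kappa = 300`, `m = 450`, `speedMin = 5` on a 50 s,
5000-frame random walk; the resulting clouds carry 300–400 landmarks into
persistence, which keeps a full run with a 20-shuffle null in the
single-digit minutes on one core. These sizes are the package's study
conditions for the simulators; per-dataset profiles for real recordings are
read from YAML.

# Numerical choices

**Persistence.** No persistent-homology backend exists as an R package in
this stack, and representative cocycles are load-bearing for the decoding,
so the package authors a Rips persistent-cohomology engine (in C++):
coboundary reduction in reverse filtration order with clearing and the
emergent-pair shortcut, arbitrary prime field (default Z~47~, chosen as
unlikely to divide torsion), implicit column storage, and dim-1
representative cocycles taken from the reduction's V-columns. The filtration
is truncated at the enclosing radius, where the complex cones off and all
finite features have died. Correctness is pinned by a test oracle: an
independent brute-force boundary-matrix reduction over Z~2~, compared
bar-for-bar on small clouds, plus the canonical circle and flat-torus
signatures and a Z~2~/Z~47~ agreement check.

**Circular coordinates.** For a chosen H^1^ bar the stored cocycle is lifted
to integers in $[-23, 23]$, restricted to the 1-skeleton at
$\tau = b + 0.99\,(d - b)$ (edges above $\tau$ belong to no triangle at
$\tau$, so the restriction is still a cocycle), and harmonically smoothed by
unweighted least squares on the graph Laplacian (dense solve, one pinned
vertex per component; edge weighting is a documented option we do not use).
Angles are read off the potential modulo 1. Orientation and origin are gauge
freedoms; `alignToReferenceAngle` and `alignTori` fix them against a
reference.

**Extrapolation.** Landmark angles weighted by a neuron's activity give a
16-bin circular distribution per neuron and torus axis (one-bin Gaussian
circular smoothing); at each time point the distributions are summed with
instantaneous-activity weights, and the decoded angle is the circular mass
center. The per-neuron (rather than per-landmark) reading is what allows a
torus found in one session to decode another session of the same cells.
Times with zero total weight are masked. Decoded-coordinate agreement is
scored with a resultant-based circular association,
$\max(R(a-b), R(a+b))$; moment-based circular correlations degenerate when
the marginals are uniform on the circle, which decoded torus coordinates
are by construction.

**Toroidal maps and hexagonal classification.** Toroidal rate maps use 12°
bins; to respect the 60° axis geometry each row is sheared by half its
vertical position, tiled 3 × 3, Gaussian-smoothed (width 2 bins), and the
middle tile is extracted and unsheared. Unvisited bins take the mean of
visited bins before smoothing; all bin summaries are occupancy-weighted
means. Peak phases (circular mass centers on 16² unsmoothed bins) and observed
10²-bin landmark maps feed the heat-kernel classification: truncated lattice
sums with $t = 0.1$, $k, l \in \{-1, 0, 1\}$, hexagonal quadratic form
$\tfrac{2}{\sqrt3}(u^2 + uv + v^2)$ versus square $u^2 + v^2$, both axis
orientations of the hexagonal kernel tested (reversal is taken relative to
the peak so the modeled field stays centered on it). An ensemble is
hexagonal when the median unit correlation exceeds 0.6 and the square
median. The 15° shear some analyses apply for display is excluded from all
numerical maps.

**Alignment group.** The hexagonal torus admits three axes 60/120° apart and
the decoded basis is arbitrary, so `alignTori` enumerates all 2 × 2 integer
matrices with entries in $\{-1, 0, 1\}$ and determinant $\pm 1$ — a finite
superset of the 12-element point group that covers both lattice-sign
conventions (e.g. $(\theta_1, \theta_1 + \theta_2)$) — fits per-axis offsets
by circular means after 200 ms smoothing, and keeps the combination with the
smallest mean angular difference. Recovery of planted transforms is exact on
noiseless data.

**Degenerate inputs.** Zero-variance neurons are dropped (with a warning)
before z-scoring; all-zero correlogram pairs score 1 ("no evidence of
coupling"); duplicate-dominated membership scales take the zero limit;
antipodally balanced activity flags a degenerate peak; zero-weight time
points are masked, and masked gaps split unwrapped trajectories into
segments.

# Shuffle null and significance

Each neuron's rate series is circularly rolled by an independent uniform
offset, the topology tail (whitening → downsampling → persistence) is rerun,
and the maximum finite lifetime per dimension is recorded; the threshold is
the 99th percentile over shuffles (the reference analysis uses 100 shuffles;
the simulation tests use 20, which only affects the percentile's estimation
error, not its location). The infinite H^0^ bar is excluded from thresholds
and always counted significant. Shuffles rerun topology on the fixed
ensemble; refitting the clustering per shuffle is a documented switch we do
not take, matching the pipeline's application of the shuffle to the
already-selected population.

# Known limitations

* Persistence beyond dimension 2 is supported by the engine but unused:
  cubic growth in landmarks makes H^3+ impractical, and more neurons would
  be needed to interpret it.
* The harmonic coordinate at $\tau$ close to the bar's death can warp on
  highly regular point sets (the Rips complex of a near-perfect circle
  passes through odd-sphere regimes near filling scales); the `tau` argument
  exposes the scale per bar.
* `classifyTorus` margins are small when tuning fields are broad relative to
  the $t = 0.1$ kernel, as with the divisive-normalization simulator's wide
  bump; on such data the median-correlation rule sits closer to its 0.6
  floor than real grid ensembles do.
* The fuzzy membership distance is read as the plain Euclidean distance
  (no nearest-neighbor shift), and directed memberships are supported on the
  $\kappa$-neighborhood where the scale is solved — without that restriction
  an isolated point's adaptively large scale would hand it the *largest*
  total membership and the selection would favor outliers, the opposite of
  the method's purpose. The alternative directed membership sometimes written
  $\exp(-d(x,y)/\sigma_y)$ is treated as exposition and not used.
* File-based input is CSV/JSON/YAML; no HDF5 or NWB ingestion.

# Reproducing the structural results

`scripts/acceptance.R --seed <s> --out <path>` regenerates, from fresh
simulations: the significant-bar counts of the twisted-torus module (the
torus signature 1/2/1), the hexagonal and square median correlations for
both simulators, the per-axis circular correlation between decoded
coordinates and the true bump phase, the shuffle-null clean fraction on
noise data, and the planted-structure recoveries (ensembles, torus
transforms, phase-conservation P). The test suite asserts the same claims
with `testthat`.
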