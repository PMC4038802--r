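---
title: "Processing MicroED still-diffraction tilt series"
author: "microedr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing MicroED still-diffraction tilt series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microedr)
```

## The problem

MicroED collects electron-diffraction patterns from three-dimensional
protein microcrystals held static in a transmission electron microscope:
one still pattern, tilt the stage, another still, and so on across a
limited angular range. The result is a set of still exposures rather than
the oscillation images X-ray integration programs expect, and mainstream
packages struggle with the combination of a nearly flat Ewald sphere,
imprecise stage angles and zero oscillation. `microedr` implements a
complete, self-contained processing chain for such data: beam-center
determination, reconstruction of each spot's three-dimensional
reciprocal-space position, unit-cell determination, still-pattern spot
prediction and Miller indexing, iterative refinement, background-subtracted
intensity integration, and merging of symmetry-equivalent measurements
under point group 422 into a plain-text reflection file suitable for
conversion to MTZ and molecular replacement.

All geometry is done in detector pixel units. The two instrument constants
are the electron wavelength $\lambda$ (Å) and the camera constant $c$
(px·Å), which maps reciprocal ångström to pixels: a reflection at
resolution $d$ lands at radius $c/d$ pixels from the beam center.

## Geometry: lifting spots onto the Ewald sphere

A picked spot at detector offset $(x, y)$ from the beam center is the
intersection of a reciprocal-lattice point with the Ewald sphere of radius
$1/\lambda$ (in pixels, $R = c/\lambda$). Because $R$ is five orders of
magnitude larger than the pattern radius, the sphere is nearly — but not
exactly — flat. The out-of-plane depth of the sphere at in-plane radius
$r$ is the sagitta

$$ z(r) \;=\; c\left[\frac{1}{\lambda} -
   \sqrt{\frac{1}{\lambda^2} - \frac{r^2}{c^2}}\right]
   \;\approx\; \frac{\lambda r^2}{2c}, $$

about 12 px at 2 Å resolution for typical 200 kV constants — ignoring it
visibly corrupts the reconstruction, so the exact form is used throughout
(`ewald_z()`; the small-angle form is retained for documentation and
testing). The corresponding in-plane displacement is below a pixel at the
same resolution and is ignored. The laboratory-frame vector of a spot on an
image tilted by $\theta$ is then

$$ \mathbf v = R(\theta)\,(x - x_c,\; y - y_c,\; z(r))^{\mathsf T}, $$

with $R(\theta)$ a right-handed rotation about the tilt axis
(`spot_to_v()`). The axis direction on the detector varies by microscope
and is a configuration parameter (default: the image $y$ axis). The $z$
sign convention (positive toward the sphere center) is arbitrary but fixed;
flipping it globally leaves all pairwise distances invariant, which the
tests assert. The beam center itself comes from user-picked Friedel pairs
— mates $hkl$ and $\bar h\bar k\bar l$ are symmetric about it, so it is
estimated as the mean of pair midpoints (`beam_center_from_friedel()`).

## Unit-cell lengths from the distance distribution

With a few hundred spots picked across several tilts, the pairwise
distances $d = |\mathbf v_a - \mathbf v_b|$ concentrate at
reciprocal-cell lengths and their integer combinations: for two spots with
adjacent indices, $d$ equals a cell edge. `pairwise_distances()` histograms
all pairs (1 px bins by default) and detects local maxima with a
prominence floor (5 % of the tallest bin). Both parameters are exposed;
the defaults make the step deterministic while keeping the user in the
loop, because the assignment of peaks to cell edges is genuinely
ambiguous: equal axes share one peak, and integer combinations can fall
arbitrarily close to a true edge. In the package's default demonstration
cell (reciprocal lengths 55, 55 and 112 px, emulating tetragonal lysozyme)
the doubled short axis, $2a^* = 110$ px, lies 1.8 % from $c^* = 112$ px and
the two merge into one histogram peak at realistic pick noise. This is
expected behaviour, not failure: `candidate_lengths()` only ranks peaks,
`predict_cross_peaks()` prints the expected positions
$|m\,\mathbf u + p\,\mathbf w|$ for each axis pair under the full
triclinic metric for comparison with the observed distribution, and the
accepted lengths are an explicit input to the next stage. The final,
precise lengths come out of vector refinement, which resolves the 110/112
blend correctly.

## Unit-cell vectors from difference-vector clustering

Difference vectors between all picked spots are filtered to those whose
norm matches an accepted cell length within a relative tolerance (5 %
default), assigned to the nearest of four fixed reference directions
($\langle 100\rangle$, $\langle 010\rangle$, $\langle 001\rangle$,
$\langle 110\rangle$, sign-agnostic), and greedily clustered. A member
joins a group when it is within 8° of the group's running mean *and*
within 5 % of its mean norm; anti-parallel members are flipped by
multiplication with $-1$ (a member is flipped when its dot product with
the running mean is negative). The norm gate is a deliberate robustness
addition: after length filtering, a $2a^*$ difference vector passes the
filter against a $c$ axis of similar length yet is parallel to $a^*$, and
angle-only clustering would average 55 px and 110 px vectors into
nonsense. Groups are scored by member count, and `select_cell_vectors()`
ranks group triples by total score subject to the norms matching the
accepted lengths and the pairwise angles matching the accepted cell angles
(sign-agnostic), breaking ties deterministically by total angular then
length deviation. The winner is relabelled to the target-length slots and
made right-handed. All candidate triples are reported for user override.

## Indexing still patterns

The chosen basis rows form the unit-cell matrix $B$; a reciprocal position
maps to fractional indices via $B^{-1}$. Two user-chosen reference spots
per image — bright reflections believed to be exactly bisected by the
sphere, ideally with visible neighbours on both sides — are indexed by
rounding, with the rounding residual reported as a quality metric (worse
than 0.3 per component triggers a warning). Their integer cross product
$\mathbf q = \mathbf h_1 \times \mathbf h_2$ is normal to the central
reciprocal plane the still samples. An index $\mathbf h$ is predicted when

$$ \frac{|\mathbf h \cdot \mathbf q|}{|\mathbf q|} \le L, $$

with $L$ the Laue-zone threshold (default 0.15), and its detector position
follows from $\mathbf h B$ and the inverse tilt projection. Raising $L$
widens the predicted zones monotonically — the prediction sets are nested,
which the tests assert — capturing more reflections at the price of more
partials and false positives. Because $\mathbf h \cdot \mathbf q$ is an
integer, the physical zone width scales with the *reduced* magnitude of
$\mathbf q$: reference pairs drawn from different Laue bands produce
high-index normals, physically narrow zones and visibly poor prediction.
Reference quality is the single most important user input, and the
synthetic pick generator emulates a careful user by choosing, per image,
the bright on-sphere pair whose reduced check vector is lowest-order.

## Refinement

Each predicted spot is mass-centered: a square box (default edge 10 px) is
summed by rows and columns and the center moves to the argmax of each.
Ties resolve toward the current center — making a featureless box a fixed
point — then to the lowest index. The pass runs twice; a second-pass move
beyond `max_shift` (default 2 px) discards the spot, preventing it from
walking to a neighbouring Miller index. Survivors must then beat a
spot-to-background contrast threshold: with a circle inscribed in the box,
$\mathrm{ratio} = (\bar I_{\mathrm{circle}} - \bar I_{\mathrm{bg}}) /
\bar I_{\mathrm{bg}}$, where the background is the square-minus-circle
region. At refinement the threshold is high (10 %) because only clean,
fully-excited reflections should steer the cell.

The kept spots — more numerous and better centered than the original hand
picks — are lifted to reciprocal space and the grouping pipeline above is
rerun with the current basis as target (`recalculate_vectors()`). A
least-squares polish is then applied by default: spots are indexed by
rounding under the grouped basis and $B$ is refit as
$\arg\min_B \sum_i \lVert \mathbf v_i - \mathbf h_i B\rVert^2$. The polish
exists because averaged difference vectors inherit a selection bias
peculiar to still tilt series: a pair of reflections one cell apart along
$c^*$ is only co-observed when both members sit near the sphere at
accessible tilts, which, within a limited ±20° range, anti-correlates
their Ewald offsets and stretches the apparent $c^*$ by 1–2 %. The
per-spot least-squares fit involves no pair conditioning and removes the
bias (to below 0.5 % on the default synthetic conditions); it is standard
practice in autoindexing and can be disabled with `polish = FALSE` to
obtain the plain grouped result. Prediction–refinement–recalculation
iterates until the basis change drops below 0.2° and 0.5 % per vector
(defaults), with a cap of 10 iterations and a cycle detector for the
pixel-quantisation limit cycle the deterministic update map can enter.

## Intensity measurement and merging

The final indexing is *not* mass centered — at this stage accuracy is
sufficient, and recentering risks attributing intensity to a neighbouring
index. For each predicted spot the mean background (same box-minus-circle
definition) is subtracted from every pixel in the circle and the remainder
summed. A much lower contrast threshold (0.5 %) admits weak spots; at
typical background levels this deliberately admits some empty boxes, whose
near-zero intensities are handled by merging.

Still exposures record mostly partial intensities. Following the
max-only strategy, the largest measurement in each symmetry orbit is taken
to best represent the complete reflection and the rest are discarded
(`merge_maxonly()`), which precludes $R_{\mathrm{merge}}$;
`merge_threshold()` instead keeps measurements within a fractional cutoff
of the orbit maximum (cutoff 1.0 reproduces max-only), merges by the mean
of the kept values, and reports
$R_{\mathrm{merge}} = \sum |I_i - \langle I\rangle| / \sum I_i$. Orbits
are those of Laue group 4/mmm (the 8 rotations of point group 422 plus
Friedel inversion; 16 operations); other symmetries are out of scope. The
canonical orbit representative is the lexicographically greatest member
with $h \ge k \ge 0$, $l \ge 0$ when one exists, else the lexicographic
maximum. $F = \sqrt{\max(I, 0)}$; for single observations
$\sigma_I = \sqrt I$ and $\sigma_F = \sqrt F$; for multiplicities of two
or more, $\sigma_I$ is the sample standard deviation (an extension — the
source rule only covers single observations) and $\sigma_F = \sigma_I/2F$.
Systematic absences are not removed: they are space-group information, and
space-group assignment is left to downstream tools. The output is a text
file with columns `h k l I F SigI SigF`.

## The synthetic-data generator

`simulate_tilt_series()` renders ground-truth datasets so that every stage
is testable without instrument data. For each tilt it enumerates the
reciprocal lattice, computes each point's exact distance from the Ewald
sphere surface, attenuates the point's full intensity by a Gaussian in
that distance (the partiality model, width 1.5 px by default), and renders
surviving spots as pixel-integrated Gaussians (PSF σ = 1.5 px) over a
Poisson background (mean 50 counts) with a circular beamstop shadow,
writing 16-bit TIFFs, a YAML dataset config and a tab-separated truth
table. The simulator deliberately implements its own rotation and
sphere-distance code, so agreement between simulation and analysis is a
genuine round trip rather than a shared-code tautology.

The default conditions emulate the pixel regime of tetragonal lysozyme on
a 200 kV instrument: reciprocal cell 55 × 55 × 112 px (camera constant
4345 px·Å puts the real cell near 79 × 79 × 39 Å), 20 stills from −20° to
+20°, 1024² rasters, log-normal full intensities (median 2×10⁴ counts),
300 picks with 0.3 px jitter, and two reference picks per image chosen as
described above. `make_pick_files()` samples distinct Miller indices,
brightness-weighted, as a careful user avoids re-picking the same
low-angle reflection on several patterns.

What the simulator does not model: dynamical scattering, radiation-damage
decay, detector point spread beyond a Gaussian, tilt-angle readout error,
and spot-position shifts of partially excited reflections. Passing the
recovery tests therefore demonstrates the geometric and statistical
machinery, not robustness to every artefact of real data.

## Numerical choices and limitations

* Histogram bin width 1 px; peak prominence floor 5 % of the tallest bin.
* Angular clustering tolerance 8°, length tolerances 5 %; Laue threshold
  0.15; box edge 10 px; walk limit 2 px; contrast thresholds 0.10
  (refinement) and 0.005 (measurement); merge cutoff 1.0. All are function
  arguments.
* Convergence: 0.2° and 0.5 % per basis vector, at most 10 iterations.
* Degenerate inputs: flat mass-centering boxes are fixed points; zero
  background means flag the measurement instead of dividing by zero;
  degenerate refined sets keep the previous basis with a warning; empty
  prediction sets warn about reference quality.
* A recovered basis is reported up to a valid lattice relabeling — for a
  tetragonal cell the $a^*/b^*$ choice and signs are conventions, and
  `index_transform()` maps between two equivalent indexings.
* Problem sizes in the test-suite: the end-to-end checks run the full
  default conditions above (one simulation, ~1 100 rendered reflections);
  unit tests use a compact 512 px orthorhombic series. These sizes were
  chosen as the smallest that exercise all three reciprocal axes of each
  cell.
* The cell-determination stages assume the accepted lengths are roughly
  right (they verify them against distribution peaks within 5 %); de novo
  determination of a wholly unknown cell benefits from independent
  verification, and Fourier-transform based autoindexing as found in
  mainstream integration packages remains the stronger tool for that job.
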