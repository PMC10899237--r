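---
title: "ocuprost: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ocuprost: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented by `ocuprost`, the
assumptions behind each stage, the parameters a user may want to touch,
and the numerical and design choices made where the procedure left
room. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Shape representation and correspondence

Every prosthesis shape is reduced to 838 corresponding landmarks on a
fixed 1672-triangle topology. The correspondence procedure exploits the
fact that an aligned prosthesis is "two-and-a-half dimensional": any
line parallel to the z axis crosses its surface at most twice, so front
and back orthographic depth maps capture the full geometry. From the
origin, 48 radial lines (7.5° increments) are marched to the silhouette
of the projection; points at fixed fractional distances along each line
form rings, and sparser rings skip angles evenly.

The exact ring fractions and skip pattern are this package's own
versioned scheme (v1, `correspondence_rings()`):

* front: centre + rings of 4 / 16 / 48 / 48 / 48 points at fractions
  0.16–0.90, plus a 24-point outline ring at fraction 1.0 — 189 points,
  with the limbus always on the third ring;
* back: centre + a 24-point inner ring + thirteen 48-point rings —
  649 points.

Any scheme with these ring counts closes into 1672 triangles with
2508 edges and Euler characteristic 2; the triangulation itself is a
deterministic angle-merge between adjacent rings. Depth values are
sampled bilinearly at 512×512 px over 32×32 mm (0.0625 mm pitch); at
invalid-pixel boundaries sampling falls back to the nearest valid pixel,
and gaps wider than 2 px raise an error (a hole in the projection means
the shape violates the two-crossings assumption).

One consequence of the depth-map formulation: the silhouette radius per
direction is pixel-quantized, so on a perfectly axisymmetric shape the
ring z values agree only to sampling tolerance (about 2 pixel pitches),
not exactly. The property tests use that tolerance.

### Alignment

Scans carry four hand-marked limbus points (nasal, superior, inferior,
temporal). Alignment translates by minus their centroid and rotates
them onto the +x/+y/−y/−x directions. The least-squares solution of the
marker equation is not guaranteed orthogonal, so we project it to the
nearest rotation (orthogonal Procrustes, SVD with det = +1): downstream
stages assume a rigid transform. Left-eye scans are mirrored across the
y–z plane after alignment, with triangle winding flipped, so that every
training shape fits a right socket.

## 2. The statistical shape model

PCA by SVD on the n×2514 matrix of centred, flattened landmarks. No
Procrustes size normalization: rotation is already canonical, and size
correlates with shape, which the prediction should exploit. Variances
divide by n−1 (the σ scale depends on this; it cancels in S(S⁻¹(·))).
Sign convention: each mode's largest-magnitude component is made
positive, and ties in singular values keep input order, so models are
reproducible. k is the smallest mode count reaching the 98 % variance
target (applied to variances, not standard deviations). An all-identical
training set yields a flagged zero-variance model with k = 1 and σ = 0;
synthesizing a nonzero coordinate on a zero-σ mode is an error rather
than silently a no-op.

Model quality is measured as in the SSM literature: replication (mean
per-vertex distance of training shapes to their own projection),
generalization (leave-one-out) and specificity (mean distance from
shapes sampled with standard-normal coordinates to the nearest training
shape; 10000 samples by default, seeded). The clinical-scale reference for
these metrics — an SSM trained on 173 manually manufactured prostheses —
sits at 0.27 / 0.31 / 1.10 mm with k = 17; that scan collection is
proprietary, so the values are documented here as non-reproducible
reference points only. Our
suite evaluates the metrics on synthetic families where the expected
ordering (replication ≤ generalization; tight families more specific
than dispersed ones) is checked instead.

## 3. Socket extraction

Slices are thresholded with `(max(B, 25) − 25)/230`, then denoised and
downsampled ×4 per axis. The cascade is median(5) → 2×2 median pool →
median(3) → 2×2 median pool; pooling truncates trailing remainder
pixels, which is what makes 2145×1877 come out as exactly 536×469. The
edge volume thresholds the size-5 Sobel second depth-derivative of the
max-pooled slice (masked to nonzero median pixels) at −0.05; the 1-D
derivative taps are (1, 0, −2, 0, 1) with the cross-direction smoothing
(1, 4, 6, 4, 1)/16 normalized to unit sum so the threshold applies to
[0, 1] data.

Window tracing: first edge hit per column, masked to depths below
median + 0.75τ (τ = window thickness in voxels), then 8 iterations of
plane-fit-and-reselect with a 0.5τ inlier band; the posterior surface
starts 0.5τ deeper, refines 4 times, and its mask is closed by a median
filter and morphological opening. Socket tracing starts 10 voxels below
the posterior window (scaled with depth resolution for desk-scale
volumes), finds the global maximum z₁, the steepest-rise position z₂
relative to the start, and takes the surface z₃ as the last zero-valued
voxel before z₂ — this skips detached speckle blobs, which have a
shallower rise. A 5×5 neighbourhood median rejects columns deviating
more than 0.5 mm. If the surviving mask covers less than 32 mm² the
extraction aborts with a typed condition.

Three corrections are applied to the traced point cloud:

1. refraction at the tilted window — a thin-window model bends the beam
   by Snell's law (index 1.5) and corrects only the in-plane
   displacement `d (tan θi − tan θt)`; the net depth bias of the glass
   path is the empirically calibrated −0.35·d (mm), applied as a depth
   *decrease* (surfaces seen through the conformer appear deeper);
2. a z shift placing the fitted anterior plane at the origin plus the
   window's 1.8 mm offset below the iris plane;
3. a 6° rotation about the y axis for the gaze/optical-axis mismatch.
   The rotation axis for this correction is underdetermined; y (nasal–temporal
   gaze deviation) is the natural choice and the synthetic generator
   emulates the same convention.

Depth maps store depth in mm measured from the iris plane, positive
into the socket, so the prosthesis back surface compares directly. At
full scale the 256×256 regrid is dense and pixel area equals traced
area; desk-scale volumes undersample the grid, so the physically
meaningful `area_traced_mm2` (traced columns × column footprint) is kept
alongside.

## 4. Shape fitting

The energy and its weights are given in the README. Numerical choices:

* Z_z rasterizes the 1672 landmark triangles at the depth-map grid in
  C++; this is non-smooth, so gradients use forward finite differences
  (step 10⁻³ per coordinate) inside L-BFGS-B rather than a custom
  differentiable renderer. Socket pixels the projection misses
  contribute with depth 0 (the iris plane), giving the optimizer a
  coverage signal.
* Coarse-to-fine: modes unlock three at a time; locked modes stay
  pinned at their *target* values (not zero), and previously unlocked
  coordinates remain free. A stage's result is kept only if it does not
  worsen the energy, so E(x_f) ≤ E(x_t) always.
* The fallback triggers when any |x_i| ≥ 3 − 10⁻⁶ and reruns the
  schedule with (θ, z) appended, bounded by ±30° / ±2.5 mm.

One analytic property of the fallback deserves a note. With the
distance term normalized by the mask size and w_dist = w_ext = 10000,
the rigid-z subproblem for a pure residual depth shift dz is
`min_z w_dist (dz − z)² + w_ext z²`, whose optimum is
`z* = dz·w_dist/(w_dist + w_ext) = dz/2`; any absorption of the shift
by shape modes lowers it further. A 1 mm alignment error therefore
yields a recovered z well below 1 mm by construction — the fallback
restores *fit quality*, not a calibrated shift estimate. The test suite
asserts the derivable behaviour (fallback triggering, bounds, positive
partial recovery); the acceptance suite records the stricter nominal
expectation, which this analysis shows cannot follow from the stated
weights.

## 5. Post-processing

Cornea renormalization replaces the front region through the limbus
ring with the mean shape's cornea, scaled so the apex sits exactly
2.5 mm above the origin and the limbus ring diameter equals the
measured iris diameter (valid range 8–14 mm); the two rings beyond the
limbus blend the residual displacement with cosine weights (0.75, 0.25)
and the posterior surface is untouched bit for bit.

Subdivision is Loop with a volume-increasing modification: odd and even
vertices are first placed by the standard stencils; each vertex's
displacement is then decomposed along the interpolated vertex normal of
the unrefined mesh, and any inward component is reflected to the
outside. Two rounds multiply the face count by 16 (1672 → 26 752) and
strictly increase the enclosed volume.

Predicted shapes are enlarged 5 % by radial scaling about the origin
with a cosine falloff to 1.0 over a 2 mm band outside the limbus (no
falloff profile is prescribed beyond "locally varying, sparing the
cornea"),
and receive a clear coat between 0.1 and 0.5 mm, thicker in the
lid-contact latitudes and near the equatorial edge — the lid-region map is a
parametric stand-in for the hand-drawn maps of clinical practice. Reconstructed shapes (rebuilt from a scan of an
existing prosthesis, never projected through the SSM, so out-of-span
detail survives) skip the enlargement and get a uniform 0.2 mm coat.
Shapes whose bounding box strictly exceeds 30×29×20 mm are rejected.

## 6. Colour and appearance

The camera characterization is a 3×3 linear map to CIEXYZ followed by
CIELAB conversion (D50, 2° observer) and a 3×7 root-polynomial
correction on (L, a, b, √(La), √(Lb), √(ab), 1). CIELAB components can
be negative, which the usual non-negative root-polynomial convention
does not cover; we use the signed root sign(x)·√|x|, which is odd and
continuous. The corrected Lab *replaces* the input of the correction
stage (the alternative residual-additive reading fits the same least
squares but reports differently). Training uses 24 colour-checker + 24
iris + 15 sclera patches; on a synthetic camera with a known mixing
matrix the recovery is exact to numerical precision, which the
acceptance suite verifies.

The raw-image chain is demosaic (bilinear, documented; RGB input
bypasses the stage), NLM
denoise (h = 15 on the 8-bit scale; patch radius 1, search radius 5 —
a compact C++ implementation), dark-frame subtraction, flat fielding
`w̄ (I′ ⊘ W)`, characterization, light NLM (h = 1.5 in Lab units).
Specular highlights are masked where the raw capture saturates
(≥ 4095/4096, the 12-bit ceiling) or lightness deviates more than 10
L* from the 15×15 neighbourhood median, dilated 3×3 twice, and filled
by Laplacian diffusion inpainting. The lightness rule necessarily fires
on true region edges too; the mask semantics follow the stated rule
deliberately.

Iris segmentation runs the Daugman integro-differential operator on the
chroma-minus-lightness image over a 4-level pyramid (factors 8, 4, 2,
1, each refining ±4 px), then refines the circle to a constant-area
ellipse over axis ratios 1 → 0.85 (step 0.01) and angles 0–175° (step
5°), maximizing the contrast between bands just outside (1.03×) and
inside (0.97×) the boundary; because the circular stage tends to lock
onto the minor axis of an elliptical limbus, the refinement also
searches a small radius range and a ±4 px centre window, keeping the
area at πr² for the refined radius. Unwrapping samples the pupil–limbus
annulus bilinearly into a 4096×1024 angle×radius texture (limbus at the
top); contrast is stretched 1.5× about the per-row mean, the global
mean lightness is restored exactly, and the pupil-side rows are set to
pure black.

Sclera segmentation blurs the image (median kernels 5 and 3,
alternating, 10 passes each), extracts seeds from the central
horizontal cross-section (darkest pixel = pupil, brightest left/right =
sclera, derivative extrema in between = iris, image border = skin), and
grows a marker-based watershed by immersion on the gradient magnitude —
labels flood lowest gradient levels first so boundaries settle on
ridges. The sclera mask is refined by L* ≥ 50, removal of a dilated
iris mask, and a vein filter (C* > 8 with hue in [345°, 60°], the wrap
handled as h ≥ 345 or h ≤ 60). The palette is k-means (k = 9,
k-means++ initialization, seeded); stain weights are min-max-normalized
cluster lightnesses and the base colour their weighted mean — staining
darkens, so light clusters dominate the base. If all cluster
lightnesses coincide the weights are undefined; we fall back to uniform
weights and the plain mean.

Staining uses 3-octave 3D Perlin gradient noise sampled on a cylinder
so the texture's u borders match seamlessly. Each colour's field is
standardized; the pixelwise maximum is thresholded at the 10 %
quantile, which pins total coverage at 90 % exactly, and stained pixels
take the colour of the largest field — exchangeable fields make the
per-colour areas approximately equal (the suite checks a 2× bound; at
1024×512 the relative spread is ~±20 %).

The vein network grows in a dimensionless 2:1 domain (u = azimuth,
v = 0 fornix → v = 1 limbus edge): 10 seed positions near the fornix
border, 15 recipes (5 per layer) controlling thickness, depth, step
length, lifetime, branching, straightness and decay. All three tables
(seeds, recipes, profiles) are versioned stand-in defaults; in clinical
practice such tables are hand-authored from photographs. A vein stops at its step
limit, below a quarter of its initial thickness (a *relative* rule, so
the global thickness multiplier th rescales the network without
touching the random stream), or at the limbus (v ≥ 0.95). Branches
start at randomly chosen nodes with 0.6× the node thickness, the
parent's depth and a random next-layer recipe; br scales all branching
rates, and br = 0 yields a pure layer-1 network. Rendering sweeps a
21-sample colour/alpha cross-section profile along quadratic B-splines
(sliding 3-node windows, i.e. 4 knots per local segment; 2-node veins
degrade to a line), with a sinusoidal perpendicular offset and a depth
buffer so shallower veins win crossings; profiles are selected by the
weighted squared distance to the recipe's (thickness, depth) with a 5×
weight on thickness.

## 7. Synthetic fixtures: what they do and do not show

The generators emulate: the manufactured-size envelope of prosthesis
shapes (a 5-parameter shell family — outline semi-axes, back depth,
back bump, cornea height — so ~5 PCA modes dominate); marker points at
exact mesh vertices; OCT volumes with bright window planes (optionally
tilted), the acquisition distortions the extraction corrects (inverse
refraction shift, +0.35 d bias, window offset, inverse gaze rotation)
and multiplicative speckle; eye photographs with known region maps,
stain colours, veins and highlight positions.

They do not emulate: real OCT speckle statistics or signal decay,
eyelid occlusion of the iris, reflections other than point highlights,
camera noise correlations, or anatomical vein topology. Passing tests
therefore demonstrate algorithmic correctness against the stated model
of the data, not clinical performance. Desk-scale problem sizes are
used throughout the suite (64-slice volumes at quarter resolution with
the same mm extents, 256 px photographs, 20–50 training shapes); the
single full-resolution path exercised end to end is the 2145×1877 slice
cascade, whose output size is resolution-defining.

## 8. Known limitations

* The ring scheme, frustum wall slope (30°), clear-coat weight map,
  vein tables and sclera UV mapping are documented defaults of this
  package, standing in for hand-authored equivalents in clinical
  practice.
* The watershed seeds come from a single central cross-section; eyes
  with the pupil far off-centre can defeat seed extraction (a typed
  error is raised).
* Printer-side colour management (optical printer model, CLUT/ICC
  generation) is out of scope; textures are exported as sRGB with a
  documented Bradford-adapted D50→D65 conversion, which a print
  pipeline would replace with its own device transform.
* The fallback's recovered rigid shift is structurally attenuated (see
  §4); treating it as a measurement of the alignment error would be a
  misreading of the energy.
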