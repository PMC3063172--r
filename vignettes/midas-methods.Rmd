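---
title: "Detecting cerebral microbleeds as an extra tissue class: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cerebral microbleeds as an extra tissue class: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cerebral microbleeds (CMBs) are small (2--10 mm), rounded deposits of
haemosiderin that appear as well-defined hypointense lesions on
gradient-recalled echo (GRE) T2\*-weighted MRI. They matter clinically —
multiple lobar CMBs are a marker of cerebral amyloid angiopathy and of
intracerebral haemorrhage risk — but manual rating is slow and only
moderately reproducible, and standard clinical acquisitions are hostile
territory for automated detection: 1.5 T, thick slices (5 mm plus a 1.5 mm
gap against 0.938 mm in-plane resolution), poor grey/white contrast on T2\*,
and many dark mimics (vessel flow voids, calcification, air--bone
susceptibility artefacts at the skull base).

`midas` implements a detection pipeline built around one idea: instead of
searching an intensity map for dark blobs, *model the microbleeds as an
explicit tissue class* inside a prior-weighted Gaussian-mixture segmentation,
give that class a deliberately uninformative spatial prior, and let the
segmentation decide voxel by voxel whether "abnormally dark tissue" explains
the data better than any normal class.

## The model

A T2\* volume, resampled to a 1.5 mm isotropic working grid, is modelled by
six tissue classes: combined grey+white matter (GWM; T2\* cannot usefully
separate the two at this resolution), CSF, CMB, a dark peri-cerebral "skull"
class, "scalp", and background ("other"). Class $k$ has a spatial prior
$\pi_k(x)$ (probability maps summing to one at every voxel) and an intensity
model that is a mixture of $n_k$ Gaussians; the per-class counts are
(3, 2, 2, 3, 2, 4). With a multiplicative bias field $b(x)$, the
responsibility of Gaussian $j$ of class $k$ at voxel $x$ with intensity
$y(x)$ is

$$ r_{kj}(x) \propto \pi_k(x)\, w_{kj}\,
   \mathcal{N}\!\left(y(x)/b(x);\ \mu_{kj}, \sigma^2_{kj}\right), $$

optimised by EM. Two empirical constraints anchor the classes to the T2\*
histogram (CSF bright, parenchyma intermediate, microbleeds dark):

* every CSF mean must exceed the posterior-weighted GWM mean, and
* every CMB mean must stay below **50%** of the posterior-weighted GWM mean.

They are enforced by projection (clipping) after each M-step. The spatial
priors are the only spatial regularisation; there is no Markov random field,
and the model is monospectral (T2\* only).

### The flat empirical prior and the two passes

Because CMBs can occur anywhere in the brain, the CMB class starts from a
*flat empirical prior*: 0.1 inside the brain mask, zero outside. The first
segmentation pass therefore behaves like a rejection class: it collects
everything too dark to be normal tissue, including mimics. The first-pass
CMB posterior is then cleaned by a fixed morphological cascade:

1. binarise at probability **0.2** (inclusive),
2. label 26-connected components,
3. size filter: discard components of fewer than **2 voxels** (a single
   working-grid voxel is 0.003375 cm^3, and even a full acquisition voxel,
   0.938 × 0.938 × 6.5 mm^3 = 0.0057 cm^3, is below the 0.006 cm^3
   single-voxel bound) and components larger than **0.675 cm^3** (a
   two-slice-high cylinder of 8 mm diameter — macrobleed territory),
4. remove voxels with skull posterior ≥ 0.5 (air--bone hypointensities),
5. remove voxels with CSF posterior > 0.5 *and their nearest neighbours*
   (6-connected dilation; vessels in sulci, ventricle rims),
6. discard whole components that touch the control-derived artefact mask.

The surviving posterior values become the subject-specific CMB prior of a
second segmentation pass; where the cleaned map is zero the new CMB prior is
a hard zero, so the second pass can reconsider candidate territory but can
never invent new territory. Its CMB posterior, thresholded at **0.5** and
re-filtered with the same size bounds, is the final detection map. Every
discarded candidate carries exactly one machine-readable reason
(`too_small`, `too_large`, `skull`, `csf_neighbour`, `artefact_mask`,
`manual`), so the rapid manual-editing workflow is an audit-trail edit, not
a re-run.

### The artefact mask

Running the identical pipeline on control subjects with no microbleeds and
taking the union of everything it "detects" yields a map of recurrent
false-positive territory — dominated by air--bone interfaces near the
inferior temporal and orbitofrontal regions and the posterior fossa.
Patient components overlapping this mask are discarded whole. The mask is
union-monotone by construction: adding a control can only grow it, and
growing it can only reduce the surviving component count.

## Numerical choices

**EM.** Initialisation is deterministic: class means start at
prior-weighted intensity quantiles, except the CMB Gaussians, which start at
the 2nd and 10th percentiles of the in-brain intensities. Convergence is a
relative log-likelihood change below 1e-5 (maximum 100 iterations). The
variance floor is $(0.01\,R)^2$ with $R$ the in-brain intensity range, with
an additional scale-relative numerical floor $(10^{-6}\max|y|)^2$ so that
floating-point cancellation cannot differentiate components of a degenerate
(e.g. constant) input; on such inputs the constraint projection is skipped —
there is no contrast to constrain — and the posteriors reduce exactly to the
renormalised priors.

**Constraint projection and variances.** In the first pass the M-step is
standard and the means are clipped afterwards (margin $10^{-3}$ relative).
This keeps the CMB Gaussians tight around genuinely dark intensities and the
candidate map selective. Used naively in the second pass, the same scheme
can starve the CMB class: partial-volumed lesions on 6.5 mm slices sit at
60--90% of the GWM mean, the clipped mean cannot follow them, and a variance
computed about the *unclipped* mean collapses until the class loses all
mass. The second pass therefore uses the constrained maximum-likelihood
update — the second moment about the *projected* mean — which is the
optimal variance given the mean constraint and keeps a clipped component
broad enough to hold the voxels it explains. The CMB class is also
re-initialised from the data in the second pass (its prior support has
changed); the other five classes warm-start from the first pass. After the
final E-step the projection is iterated to a fixed point, so the returned
model satisfies the constraints *exactly* against its own posteriors.

**Bias field.** The multiplicative field is $\exp$ of a 3rd-order 3D
polynomial (20 coefficients) in coordinates scaled to $[-1,1]$, mean-centred
over the brain. It is re-estimated every third EM iteration by weighted
least squares of the log-residual $\log y - \sum_{kj} r_{kj}\log\mu_{kj}$,
with Gauss--Newton precision weights $\sum_{kj} r_{kj}\mu_{kj}^2/\sigma^2_{kj}$
and MAD-based trimming of outlying residuals (partial-volume voxels at
tissue boundaries leave large, spatially structured residuals that would
otherwise bend the polynomial). Updates stop once a refit moves the
log-field by less than 1e-3, after which the EM trace is strictly monotone
and the usual tolerance applies. The log-likelihood trace records every
projection and bias event; monotonicity is asserted in the tests between
event-free iterations.

**Alignment.** The full nonlinear unified normalisation of the original
framework is out of scope; `align_to_template()` estimates a 12-parameter
affine by normalised mutual information (32-bin joint histogram), with
coarse axis-wise translation/rotation sweeps followed by two-resolution
Nelder--Mead. Phantom-based tests run pre-aligned, and an externally
computed transform can be supplied to `run_midas()`. Masks are resampled
nearest-neighbour; probability maps linearly with per-voxel renormalisation;
intensities linearly.

## The phantom generator

All tests run against a seedable synthetic head: nested ellipsoids (scalp
shell, dark skull shell, 3.5 mm subarachnoid CSF rim, parenchyma,
ventricles) on the clinical acquisition grid (0.938 × 0.938 × 6.5 mm voxels;
the 5 mm excitation plus 1.5 mm gap is modelled as one 6.5 mm cell, matching
how the acquisition's voxel volume is quoted). Default mean intensities
(arbitrary units) are GWM 100, CSF 180, skull 30, scalp 140, background 5 —
reproducing the clinical histogram ordering. Microbleeds are spheres whose
voxel occupancies are computed by sub-voxel supersampling; intensities are
scaled toward `intensity_fraction` (default 0.3, a free choice — no
published value exists for CMB contrast on these acquisitions — kept
configurable) in proportion to occupancy. A voxel joins the ground-truth
mask at occupancy ≥ 0.5; lesions with no such voxel are recorded as
sub-voxel, which genuinely happens to lesions under ~6 mm centred in the
inter-slice gap — the same thick-slice partial-volume mechanism that causes
real missed microbleeds. Noise is additive Gaussian (at clinical T2* SNR
the Rician correction is immaterial and closed-form recovery checks stay
exact); the bias field is a random low-order polynomial with a known
maximum deviation. Mimic primitives (inferior edge band for air--bone
artefact, bright-walled dark tube for a flow void, >10 mm dark blob for a
macrobleed) emulate the three recurrent false-positive types.

What the phantom does *not* emulate: cortical folding, susceptibility
physics, k-space artefacts, anatomically realistic priors (tests build
priors by smoothing the phantom's own label map with an 8 mm kernel, which
is cleaner than a real population template). Passing phantom tests
therefore demonstrates the machinery — constraint handling, the two-pass
prior refinement, the morphology, the bookkeeping — not clinical
performance; the original clinical agreement numbers (Kappa 0.43→0.65,
ICC 0.71→0.87) require the 30-patient dataset, which is not public, and are
deliberately not claimed.

## Study conditions used by the shipped checks

The acceptance script (`scripts/acceptance.R`) and the acceptance tests
generate 20 phantoms (seeds 1--20), each bearing 2--5 lobar microbleeds of
diameter 4--8 mm at intensity fraction 0.3, with noise at 5% of the GWM mean
and a 10% bias amplitude, on the default 154 × 154 × 22 acquisition grid
(~96^3 working grid at 1.5 mm). A subject counts as positive when at least
one lobar component survives both passes; the script reports the resulting
patient-level sensitivity — the desk-scale analogue of screening for
patients with multiple lobar microbleeds. Unit tests use smaller grids of
the same geometry; the parameter-recovery checks use a 120 × 120 × 17 grid
where boundary partial volume does not dominate the brain interior.

## Agreement statistics

`cohen_kappa()` implements $\kappa = (p_o - p_e)/(1 - p_e)$ with the
convention $\kappa = 1$ for identical constant raters; the theoretical
"expected agreement 1 with disagreement" case is unreachable for binary
ratings but guarded with a flagged `NaN`. Interpretation bands are
<0.2 poor, 0.2--0.4 fair, 0.4--0.6 moderate, 0.6--0.8 good, >0.8 excellent,
with exact cut-points assigned upward. `icc_counts()` is the two-way
random-effects, absolute-agreement, single-measure ICC(2,1) — the standard
choice for method-versus-reference count agreement; the source cites only
"ICC", so the variant is a documented assumption, cross-checked in the
tests against an independent ANOVA-based computation. Detection-to-reference
matching is greedy nearest-centroid, one-to-one, within 5 mm by default;
on small instances it is tested against an exhaustive assignment oracle.

## Known limitations

* Affine-only alignment; no nonlinear warp estimation.
* Monospectral by design; no multispectral extension.
* The region contract is a user-supplied 3-code label volume
  (lobar / deep / infratentorial), assigned to components by centroid.
* The second pass confirms or rejects vetted territory; a lesion that never
  reaches 0.2 posterior in pass 1 is unrecoverable downstream.
* Runtime is logged in every report but never asserted; it is
  hardware-dependent.
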