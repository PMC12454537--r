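---
title: "Reconstructing bipennate muscle architecture: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing bipennate muscle architecture: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A bipennate muscle such as the m. rectus femoris inserts its fibres
obliquely into both sides of a thin internal tendon sheet, the anterior
aponeurosis. Continuum-mechanical simulations of such a muscle need two
internal structures that standard imaging does not deliver directly: the
geometry of the aponeurosis and a smooth per-element fibre orientation
field. Diffusion-tensor tractography yields fibre streamlines, but they
are noisy, irregular at boundaries, and unusable directly as a finite
element fibre field. This package implements a reconstruction chain
around that difficulty:

1. **Aponeurosis detection.** Streamlines are converted into per-voxel
   maps. Because fibres of both muscle halves insert into the sheet, the
   sheet is a *sink* of the oriented streamline field: it accumulates a
   large positive discrete divergence and, because many distinct fibres
   converge there, a high fibre density. The detector thresholds both
   maps jointly inside a region of interest, removes small islands by
   connected-component filtering and keeps the largest component.
2. **Thermal fibre fields.** A smooth stand-in fibre field is obtained
   by solving steady-state heat conduction on a tagged tetrahedral mesh
   of the muscle-tendon-aponeurosis complex and taking unit heat-flux
   directions. Fixed temperatures at the two tendon end faces alone give
   a fusiform (near-axial) field; power-law temperature ramps on the
   muscle surface and on a strip along the aponeurosis's central axis
   turn it into the feather pattern of a pennate muscle.
3. **Boundary-condition identification.** The ramp exponents and the
   outlet temperature are not observable; they are identified by fitting
   the flux directions to a reference fibre field (mapped tractography,
   or a synthetic ground truth) by minimising the mean per-element
   cosine distance over a trusted sub-region, using a space-filling
   design, an RBF metamodel and simulated annealing.
4. **Mechanical comparison.** A transversely isotropic hyperelastic
   model with passive and active fibre stress drives a quasi-static FE
   solver, so that two candidate fibre architectures can be compared in
   what matters mechanically: passive force-displacement behaviour and
   isometric force production.

No subject data ship with the package. All claims are validated on a
synthetic bipennate phantom with known ground truth, generated by the
package itself.

# Voxel fields from streamlines

Streamlines live in world millimetres. For every voxel a sphere of
diameter 2.625 mm (matching the in-plane voxel size, so the sphere fits
inside the anisotropic 2.625 x 2.625 x 6.25 mm voxel) is centred at the
voxel centre. The density `K(V)` counts *distinct* streamlines with a
resampled point inside the sphere; the resampling step of 0.5 mm
guarantees that no sphere can be jumped over. Per fibre and voxel the
representative direction is the normalised chord between its first and
last in-sphere samples -- robust to the resampling density -- and the
voxel orientation is the arithmetic mean of these unit vectors,
sign-flipped as a whole so its component along the principal muscle axis
`e2` is non-negative. The mean is deliberately not re-normalised; its
magnitude is a coherence measure.

The discrete divergence is endpoint-based: each streamline is first
oriented so its end-to-end chord has a non-negative `e2` component (the
same convention as the orientation sign rule), and each voxel counts
entering minus leaving streamlines. For any polyline that net count
equals "endpoint inside minus start point inside", which is how it is
computed; pass-through fibres contribute exactly zero and the global sum
over voxels telescopes to the difference between endpoint and
start-point counts. A central-difference divergence of the averaged
orientation field is also available (`mode = "fd"`) but the endpoint
mode is the detector default: it is exact, integer-valued and does not
amplify orientation noise.

## Detection thresholds

The canonical thresholds -- divergence above 3.0 and density above 600,
islands below 10 voxels removed -- belong to an acquisition with on the
order of 1e5 tracks. Both thresholds scale with track count, so the
detector also accepts a density *quantile* (default 0.75 over
fibre-carrying RoI voxels) instead of an absolute density. Strict
inequalities are used throughout ("exceed"). Connectivity is 26
(vertex-adjacent) by default with 6 available; ties between equally
large components are broken towards the component containing the
smallest flat voxel index, making detection deterministic. The RoI
excludes posterior voxels; for the synthetic phantom it is the
half-space one voxel posterior of the sheet's posterior edge.

# The synthetic phantom

The generator produces a fusiform solid of revolution (smooth sine-based
radius profile, flat circular tendon end faces) with an embedded planar
mid-sheet starting at 40% of the muscle span and reaching the distal
tendon, attached to the anterior surface and free elsewhere. Defaults
are sized like a lean adult rectus femoris at desk scale: total length
150 mm with 15 mm tendons at both ends, belly radius 15 mm, end radius
6 mm, sheet thickness 2 mm, pennation 15 degrees. The mesh is a
structured hexahedral grid on the normalised cross-section square mapped
by the elliptical square-to-disk map, split into six tetrahedra per
hexahedron with a consistent diagonal (conforming by construction); a
dedicated thin element column carries the sheet, so the aponeurosis is a
volumetric thin region, not a shell. The temperature boundary set of the
sheet is a strip along its central axis (half its width by default),
mirroring how such boundary conditions are applied in practice.

Synthetic streamlines emulate what tractography produces rather than
what fibres anatomically are: seeds are drawn uniformly in the muscle
volume and integrated in both directions of the analytic pennate field
(0.5 mm explicit steps), with per-step Gaussian angular noise about a
random perpendicular axis. Tracks terminate at the muscle boundary; on
the sheet side they run on for a random 2-10 mm inside the sheet (where
the field is axial) before terminating, as tracks following the local
diffusion direction of an aponeurosis do. This termination model is what
makes the sheet both a divergence sink *and* a density maximum; with
dead-stop termination the sheet would paradoxically be density-poor,
because the per-voxel sphere would see only track tails.

What the phantom does not emulate: fat infiltration, shading artefacts,
partial-volume effects at the muscle boundary, a posterior aponeurosis,
and anatomically curved fibre trajectories. Passing the detection test
on the phantom therefore demonstrates the method's logic (sink + density
conjunction, island filtering, largest component), not its robustness to
every artefact of real DTI data.

# Thermal fibre generation

Only flux *directions* matter, so the conductivity is fixed at 1 and
temperatures are dimensionless; the steady-state equation is a pure
Laplace problem, discretised with Galerkin linear tetrahedra and solved
by sparse Cholesky factorisation (ample below about 2e5 nodes, the mesh
sizes this package targets; the factorisation is cached so the
design-of-experiments loop pays one triangular solve per candidate).
The relative residual tolerance is 1e-10.

Boundary values: `T0 = 1` on the inlet (proximal tendon end face), `T1`
on the outlet, and power-law ramps `T0 * n^alpha` on the muscle surface
(`alpha1`) and the aponeurosis strip (`alpha2`), where `n` is the
normalised axial coordinate over each set's own axial range, equal to 1
at the set's proximal end so the ramps meet `T0` continuously on the
proximal side (a switch reverses the convention). `0^0` is taken as 1 so
that `alpha = 0` degenerates to a constant ramp rather than a
discontinuity at the admissible-range boundary. Where face sets share
nodes the precedence is inlet > outlet > aponeurosis > muscle. Element
fibre vectors are unit fluxes, sign-aligned to `e2`; elements with
numerically zero flux are flagged invalid and excluded from objective
averages.

# Boundary-condition identification

The design space follows the canonical parameter table: `T1` in
[-200, -1] (negative values have no physical meaning -- they only
steepen the axial gradient), `alpha1` and `alpha2` in [0, 20], start
point (-100, 5, 10), and the feasibility constraint
`alpha2 - alpha1 >= 0`, which makes the flux incline *towards* the
aponeurosis. The objective is the arithmetic mean of per-element cosine
distances over the sub-region (the printed formula is an arithmetic
mean even where the surrounding text says "geometrical"); the companion
angle `acos(1 - y)` is reported in degrees.

The sub-region excludes muscle elements whose centroid lies within 3 mm
of the exterior surface (exact point-triangle distances against the
surface triangulation) and the distal 10% of the axial extent -- the
regions where a tractography reference is least trustworthy.

The design is a maximin Latin hypercube over the full box (N = 200 by
default, the canonical design size); the constraint restricts only the
optimiser, so the metamodel is informed on both sides of it. The
metamodel is an RBF interpolant (multiquadric kernel plus linear tail,
inputs scaled to the unit box). Two numerical choices matter here and
were fixed by a small calibration study on synthetic thermal-objective
responses, before being frozen:

* the exponent axes are warped by a square root before fitting, because
  an exponent acts on `n^alpha` fastest near zero -- the stretch
  equalises the metamodel's resolution where the response has a cliff;
* the kernel width is 0.6 in unit-box units, which balances smoothing
  against the conditioning of the interpolation system for 100-200
  design points in three dimensions. (For very smooth responses, such
  as polynomial test functions, larger widths are better; the width is
  a plain argument.)

Optimisation runs seeded simulated annealing on the metamodel (geometric
cooling 0.95, step scaling towards 40% acceptance, 5 restarts, proposals
projected onto the feasible set), followed by a multi-start constrained
Nelder-Mead polish -- started from the annealed optimum and the best
feasible design points -- on the *simulator* objective by default, so the
final coefficients are not limited by metamodel bias. Hold-out R^2 (20
fresh seeded designs) and Saltelli-type first-order sensitivity indices
of the metamodel are reported with every fit. On the synthetic phantom
the loop recovers known exponents to about 1e-4 and ranks `T1` last in
sensitivity (well under 1%), consistent with the near-invariance of flux
directions to the outlet temperature.

# Mechanics

The constitutive model is a quasi-compressible Mooney-Rivlin matrix
(`C1`, `C2`, bulk penalty `k (J - 1)^2 / 2`), a passive fibre stress
`(C3 / L^2)(L^C4 - 1) a0 (x) a0` active above unit fibre stretch, and an
active fibre stress `alpha sigma_max / L^2 exp(-|(L/L_opt - 1)/DW|^nu)`
with ascending/descending branch constants, where `L` is the fibre
stretch `sqrt(I4)`. Three interpretation points deserve note:

* The printed material table assigns the activation factor gamma = 0 to
  muscle and gamma = 1 to tendon, which read literally would activate
  exactly the non-contractile tissue. The package scales activation by
  1 in muscle and 0 in tendon/aponeurosis and keeps the printed values
  as `gamma_printed` for traceability.
* The applied initial fibre stretch of the isometric protocol enters as
  an additive shift of the stretch *seen by the fibre stress laws*
  (`L = sqrt(I4) + (L_ini_app - 1)`), applied to muscle tissue only.
  This realises "pre-stretch as an internal load": at zero deformation
  the fibre laws see exactly `L_ini_app`, and a passive analysis
  (shift 0) reduces to the plain `sqrt(I4)`.
* The various stretch symbols of the piecewise fibre laws are read as
  one quantity, the (shifted) fibre stretch.

The FE solver is total-Lagrangian on linear tetrahedra (as in the
reference workflow; their locking tendency under near-incompressibility
is acknowledged and mitigated by the finite bulk modulus). Element
tangents are central finite differences of the exact element internal
force, assembled sparsely. On the descending limb of the force-length
relation the material stiffness is negative and the structural tangent
can become indefinite or singular -- the quasi-static path genuinely
passes limit points during activation. The Newton iteration is therefore
pseudo-transient: a Levenberg-damped step `(K + mu D) du = -r` whose
damping grows on rejected or element-inverting steps and relaxes with
the residual ratio after good ones, with moderate residual growth
accepted while damping is active (the discrete analogue of riding over a
fold with implicit dynamics). Load stepping is incremental with
recursive bisection of failed increments; the converged relative
residual tolerance is 1e-8.

Load case 1 (passive stretch) fixes the proximal tendon end face and
ramps nodal forces summing to 5 N along the axis on the distal end face,
reporting the mean axial distal-face displacement. Load case 2
(isometric contraction) fixes both tendon ends, equilibrates the applied
pre-stretch (1.10/1.25/1.35 are the standard levels), then ramps the
activation from 0 to 1, reporting the proximal reaction (tension
positive, equal to the transmitted axial force). On the phantom, a
steeper fibre field (10 degrees pennation) produces a strictly smaller
passive end displacement and a strictly larger isometric reaction than a
flatter one (25 degrees) -- the expected directions of effect -- and
volume changes stay below 5% under the default bulk modulus.

# Comparing fields

Fibre orientations are sign-ambiguous, so both fields are aligned to
`e2` before comparison. The relative inclination per element is
`90deg - angle(normalised difference, e2)`: positive where the first
field is steeper, negative where it is flatter. Where two vectors are
numerically identical the difference direction is undefined; such
elements are set to 0, flagged, and excluded from spread summaries. In a
deformed configuration both vectors are pushed forward with the element
deformation gradient and re-normalised first; uniform scalings cancel.
Under increasing axial stretch both fields converge towards the loading
axis, so the spread of the inclination narrows -- the mechanism behind
the drop of inclination spread at moderate loads, reproduced on
synthetic fields in the test suite.

# Study sizes and numerical defaults

All scales were chosen once as the package's study conditions: detection
uses 2000 tracks at 3 degrees angular noise on the default phantom;
boundary-condition identification uses the default 5 mm mesh (about
7.5k elements) with 200 designs and 20 hold-out points; mesh-sensitivity
comparison uses target edge lengths 2.2 mm vs 1.6 mm (about 87k vs 201k
elements, the same refinement ratio as consecutive reference mesh
levels) with nearest-centroid pairing over the interior sub-region;
mechanics comparisons run on an 8 mm mesh (about 3.2k elements) with 10
load steps. Degenerate inputs error early (empty sub-regions, degenerate
ramp ranges, inverted elements, missing face sets); every stochastic
stage takes one explicit integer seed and is bit-reproducible.

# Known limitations

* The aponeurosis detector assumes one dominant anterior sheet; a
  posterior aponeurosis is out of scope (its fibres would form a second
  sink and could be found by re-running with a complementary RoI).
* The phantom's pennation is planar (no azimuthal twist or curvature),
  so detection and recovery results bound the method's behaviour on
  clean geometry only.
* Thermal fibre fields converge at first order near the Dirichlet edge
  of the aponeurosis strip (a mixed boundary singularity); the interior
  field is stable under refinement but boundary-layer elements should
  not be interpreted quantitatively -- the same reason the fitting
  sub-region excludes the surface layer.
* Linear tetrahedra are overly stiff under near-incompressibility; the
  FE comparisons are meaningful as *paired* contrasts (same mesh, two
  fields), not as absolute force predictions.
* The active model is a homogeneous activation scaling; no fatigue,
  no recruitment heterogeneity, no biophysical coupling.
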