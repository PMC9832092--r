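---
title: "Models and numerical methods in tavsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in tavsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

tavsim assembles four desk-scale model families used in transcatheter
aortic valve replacement (TAVR) analysis: a fiber-reinforced hyperelastic
description of valve tissue with biaxial fitting, a closed-loop
reduced-order circulation with a lumped aortic-valve surrogate, a
beam--spring model of a self-expanding stent frame, and a small 2D
immersed-boundary fluid--structure solver that demonstrates the coupling
concepts (regularized-delta transfer, implicit contact) that full 3D
simulations of these devices rely on. This vignette records the models,
their assumptions, the tunable parameters, and the numerical choices,
including those the package made where several reasonable designs exist.

## Tissue model

Leaflet and pericardial tissue is modelled as a nearly incompressible
fiber-reinforced hyperelastic solid. With deformation gradient $F$,
$J=\det F$, $\bar F=J^{-1/3}F$ and $\bar C=\bar F^T\bar F$, the strain
energy splits into isochoric and volumetric parts
$\Psi = W(\bar F) + U(J)$, with

$$W = C_{10}\{\exp[C_{01}(\bar I_1-3)]-1\}
 + \frac{k_1}{2k_2}\sum_{i=1,2}\{\exp[k_2(\bar I^{\*}_{4,i}-1)^2]-1\},
 \qquad U = \beta\,[J\ln J - J + 1],$$

where $\bar I_1=\mathrm{tr}\,\bar C$ and
$\bar I^{\*}_{4,i}=\max(f_{i0}\cdot\bar C f_{i0},\,1)$ is the tension-only
squared stretch of fiber family $i$. Two equally weighted families at
$\pm\theta$ about a mean in-plane direction provide a simple account of
fiber dispersion. The first Piola--Kirchhoff stress is the analytic
gradient $P=\partial\Psi/\partial F$, including the isochoric projection
from the $\bar F$ dependence and the volumetric term
$\beta J\ln J\,F^{-T}$; every release is checked against central finite
differences of the energy at randomized deformations (relative error
$\le 10^{-6}$).

Units are mixed in the conventional reporting of these constants
($C_{10}$ in kPa; $k_1$, $\beta$ in MPa). The package standardizes on kPa
internally and converts at the constructor and in the JSON schema, whose
keys are unit-suffixed (`C10_kPa`, `k1_MPa`, ...).

Two shipped parameter sets cover healthy native aortic leaflet tissue
(mean fiber direction commissure-to-commissure; $C_{10}=0.1463$ kPa,
$C_{01}=26.21$, $k_1=0.007072$ MPa, $k_2=147.5$, $\theta=26.21^\circ$,
$\beta=141$ MPa) and glutaraldehyde-fixed porcine pericardium
($C_{10}=15.14$ kPa, $C_{01}=13.48$, $k_1=0.1526$ MPa, $k_2=107.3$,
$\theta=7.81^\circ$, $\beta=5.84$ MPa). A severely stenotic native valve
is emulated by multiplying $C_{10}$ by $10^3$
(`stenotic_stiffening()`). For the pericardial components we follow the
convention that the *leaflets* carry the 45° mean fiber direction (the
skirt is aligned with the flow axis); published descriptions are not
fully consistent on which component carries the 45° orientation, and the
choice is exposed through `mean_fiber_deg` rather than hard-coded.

Numerical guard: the exponentials are continued linearly beyond argument
50 (a $C^1$ guard), so fitting can explore extreme $k_2$ without overflow
while stress and energy remain consistent derivatives of one another;
guarded evaluations are flagged.

### Biaxial response and fitting

Planar biaxial tests are reduced with exact incompressibility
($\lambda_3 = 1/\lambda_1\lambda_2$, so $U$ vanishes) and plane stress
($\sigma_{33}=0$ via a pressure-like multiplier). A consequence is that
$\beta$ is not identifiable from biaxial data; it is configured, never
fitted. The mean fiber direction is treated as specimen-mounting
information and held fixed.

`fit_hgo()` minimizes weighted least squares over the stacked
$(\sigma_{11},\sigma_{22})$ residuals by Levenberg--Marquardt with a fixed
8-point log-spaced multi-start on $(k_1,k_2)$, positivity enforced by
log-reparameterization and $\theta\in(0,90^\circ)$ by a logistic map. The
default weighting is *relative* ($1/(|\sigma|+\delta)$): over a stretch
grid reaching 1.25 the exponential model's stresses span roughly twenty
decades, and unweighted least squares cannot resolve the soft isotropic
response that identifies $C_{10}$ at double precision. With noise-free
synthetic data the fit recovers both shipped parameter rows to machine
precision; with 5% multiplicative noise at 400 grid points, $k_2$ is
recovered essentially exactly while $C_{10}$ typically lands within
2--8% (its estimate trades off against $C_{01}$, with occasional larger
excursions at unlucky noise draws).

The synthetic generator (`generate_biaxial_dataset()`) evaluates the
plane-stress response on a 20x20 grid of stretch pairs in $[1.0, 1.25]$
(a physiologic loading range for these tissues) and adds additive or
multiplicative Gaussian noise. It emulates the *shape* of equibiaxial
tensile protocols; it does not emulate actuator coupling, shear
misalignment, hysteresis or preconditioning of real experiments, so
passing recovery tests demonstrates identifiability of the model from
clean protocol data, not robustness to every experimental artifact.

## Closed-loop circulation

The upstream left heart is a time-varying elastance model. Chamber
pressures follow $P = E(t)\,\hat V$ where $\hat V = C(t)P$ is the
volume-like state, and the balances

$$\frac{d(C_{LA}P_{LA})}{dt} = Q_{vein}-Q_{MV},\qquad
  \frac{d(C_{LV}P_{LV})}{dt} = Q_{MV}-Q_{LVOT},\qquad
  C\frac{dP_{Wk}}{dt} = Q_{Ao}-\frac{P_{Wk}}{R_p}$$

are integrated exactly in $\hat V$ (the design choice of state variable
avoids differentiating $C(t)$). The mitral valve is a diode of resistance
$R_{MV}$; the outflow tract adds $R_{LVOT}$; downstream loading is a
three-element Windkessel ($R_c$, $R_p$, $C$) with
$P_{Ao}=P_{Wk}+Q_{Ao}R_c$. Elastances use the two-Hill waveform

$$E(t)=k\frac{g_1}{1+g_1}\frac{1}{1+g_2}+E_{min},\qquad
 g_i=(t/\tau_i)^{m_i},$$

with $k$ normalized numerically on a $10^5$-point grid (cached) so the
waveform maximum is exactly $E_{max}$. The atrial waveform is the same
shape delayed by $0.85\,T$; the opposite sign convention is available as
a configuration switch (`la_shift_mode = "advance"`).

All default constants are the shipped calibration
(`inst/extdata/circulation_default.json`): $Q_{vein}=5.8$ L/min,
$R_{MV}=0.005$, $R_{LVOT}=0.0043$, $R_c=0.042$, $R_p=0.9046$
mmHg s/mL, $C=1.9504$ mL/mmHg, $T=0.8512$ s, LV elastance
$(\tau_1,\tau_2)=(0.0725,0.4503)\,T$, $(m_1,m_2)=(2.7463,21.5683)$,
$E\in[0.01,0.1191]$, LA elastance $(0.1150,0.1882)\,T$, $(1.32,13.1)$,
$E\in[0.08,0.17]$ mmHg/mL.

### The aortic valve surrogate

A resolved 3D fluid--structure valve is outside this package's scope; in
its place sits a lagged diode plus Gorlin orifice
(`valve_surrogate()`): open flow solves
$(Q/51.6\,EOA)^2+(R_{LVOT}+R_c)Q = P_{LV}-P_{Wk}$ in closed form, with
$EOA$ the effective orifice area (default 1.50 cm², the reported
effective area of the modelled 26 mm device). Both valve states are
*lagged*: updated once per step from the previous step's pressures, with
no event location — deliberately mirroring the simplification used when
such reduced models drive full FSI simulations.

### Integration, convergence, and metrics

Integration is classical fixed-step RK4, default $dt=10^{-4}$ s (snapped
so a period is an integer number of steps), initial conditions
$P_{Wk}=80$, $P_{LA}=10$, $P_{LV}=8$ mmHg, up to 20 cycles with
convergence declared when the aortic pressure trace changes by less than
0.5 mmHg (max norm) between consecutive cycles. Runs are bitwise
deterministic.

`cycle_metrics()` computes, over the final cycle: stroke volume
$SV=\int Q_{LVOT}\,dt$; cardiac output $CO=60\,SV/T$ (definitional — note
that published SV/CO pairs are sometimes mutually inconsistent at the
0.5% level, so both cannot be matched simultaneously); systole defined as
samples with $Q_{LVOT}>0$ (no alternative definition is standard for
this surrogate); mean systolic gradient
$\overline{P_{LVOT}-P_{Ao}}$; peak diastolic gradient
$\max(P_{Ao}-P_{LVOT})$ over closed-valve samples; and
$EOA = Q_{rms}/(51.6\sqrt{\overline{\Delta P}})$, a Gorlin-type reading
of the simplified continuity equation using systolic RMS flow (the
specific flow statistic is an interpretation; RMS makes the formula
exactly self-consistent with the orifice law).

Two properties of this system are worth knowing when comparing against
resolved-valve results. First, at periodic steady state mass balance pins
$SV$ to $Q_{vein}T = 82.3$ mL regardless of the valve. Second, the
surrogate has no inertance: flow stops as soon as the driving pressure
reverses, so ejection is shorter (about 0.29 s here) than for a resolved
valve with fluid momentum (about 0.36 s for the same stroke volume), and
the systolic RMS flow — hence the mean systolic gradient
$(Q_{rms}/51.6\,EOA)^2$ — is correspondingly higher, by roughly 30% for
these parameters. The computed EOA, by contrast, is exactly the
configured orifice area, because the continuity formula inverts the
orifice law. These are intrinsic scale-down effects of the lumped
surrogate, not tunables; the package reports the metrics as computed.

`prescribed_flow_experiment()` drives several valve surrogates with one
flow waveform (as in pre/post-intervention comparisons on a common
systolic flow); `synth_flow_waveform()` supplies a half-sine ejection
pulse with exact stroke volume, standing in for measured patient
waveforms that are not redistributable. The shipped comparison config
uses effective areas of 3.63 (healthy), 0.76 (stenotic) and 1.32 cm²
(post-TAVR), which reproduces the severalfold ordering of mean gradients
across the three states; matching absolute published gradients would
require the measured waveform.

## Stent frame

The self-expanding frame is an idealized diamond-cell cylindrical
lattice (the CT-derived geometry of a real device is not available to
this package): `n_rows + 1` rings of `n_circumferential` nodes with
alternating half-cell offsets, diagonal springs forming the diamonds,
hoop springs along each ring, and discrete-curvature beams along the
axial zigzag chains and around the rings. Rest lengths and rest
curvature magnitudes come from the generated geometry, so the nominal
26 mm configuration is exactly force-free.

The beam energy penalizes $(|d|-|d_0|)^2$ for the second difference
$d = x_a-2x_b+x_c$ — magnitude-based rather than vector-based, which
keeps the elastic energy invariant under rigid motions (a vector-valued
rest curvature is not). Because magnitude-only bending admits folded
("petaled") ring configurations as spurious minima, the rings carry hoop
springs as well; with them, release from any crimp depth relaxes back to
the reference shape (diameter recovered within 1%, endpoint independent
of crimp depth).

Crimping follows the kinematics of a radial crimper contracting at
50.0 cm/s; nodes outside the crimper radius feel a stiff radial penalty
of 3.0x10^8 dyne/cm (the tether stiffness used for such crimping devices,
here realized as a barrier because contact in this package is not
fluid-mediated). The penetration past the commanded radius is bounded by
the tether compliance (elastic force / 3x10^8, well under 10 µm here).
Dynamics are overdamped first-order with explicit Euler at the stability
bound $dt = \gamma/4k_{max}$; only equilibria and quasi-static paths are
of interest. Energy decreases monotonically whenever the crimper is
static, and the shipped demo crimps the 26 mm frame to 17.25 Fr
(5.75 mm), the capsule scale of clinical delivery systems.

The spring and beam constants of real frames are not published in
sufficient detail for this idealization; defaults
($k=2\times10^5$ dyne/cm springs, $10^6$ beams, damping
$2\times10^4$ dyne s/cm) are chosen so stored crimp energy re-expands
the frame on a ~0.1 s timescale, are exposed in the constructor, and are
not device measurements. No quantitative claim rests on absolute stent
forces. Nitinol's temperature-dependent superelasticity, sheath removal,
and contact with anatomy are out of scope. Diameters are measured about
the lattice's fixed z-axis (no axis refitting) as twice the maximum
radial node distance; 1 Fr = 1/3 mm.

## 2D immersed-boundary solver

The fluid is blood-like ($\rho=1$ g/cm³, $\mu=3.5$ cP), discretized on a
periodic square MAC (staggered) grid. Each step performs explicit
centered advection, a semi-implicit (backward Euler) viscous solve, and
an exact FFT pressure projection using the 5-point Laplacian's
eigenvalues; the post-step discrete divergence is zero to round-off
(the Taylor--Green benchmark decays at the closed-form rate within 1% at
64² and $dt=10^{-3}$ s). A CFL monitor aborts with a suggested step when
advective CFL exceeds 0.5.

Structures are point sets carrying the same spring/beam/tether library
as the stent module. Coupling uses the classical 4-point regularized
delta kernel (pluggable; the kernel identities — partition of unity,
vanishing first moment, compact support — are tested at $10^{-12}$).
`ib_spread()` and `ib_interp()` are exact adjoints up to the mesh volume
factor, and spreading conserves total force. Structure points move with
the interpolated velocity through a midpoint (RK2) update, which
markedly improves enclosed-volume conservation over a forward-Euler
move: the pressurized elastic ring (ellipse relaxing to a circle of the
same enclosed area) drifts less than 1% in area over 1 s at 64², with the
equilibrium radius converging to the area-conserving circle at first
order under grid refinement.

The leaflet demonstrator builds a channel from rows of stiff tether
points inside the periodic box (the 2D transposition of treating vessel
walls as nearly rigid penalty structures), spans it with two elastic
leaflets meeting at the centerline, and imposes a pressure difference as
a uniform body force. Two known immersed-boundary artifacts matter for
interpretation. First, the effective no-slip plane of a tether-point
wall sits a fraction of a mesh width inside the point row, so the
absolute open-channel flux under-predicts plane Poiseuille flow by an
O(h) width effect (about 20% at 64²); the *curvature* of the velocity
profile, which is offset-independent, matches the Poiseuille value
$-f/\mu$ to better than 1%, and that is the closed-form check the tests
use for the flow itself. Second, a closed immersed interface leaks
slightly; with the default stiffnesses the blocked-channel flux is about
3% of the open-channel flux (the ≤5% seal criterion), and the opposing
leaflet tips never interpenetrate — contact emerges implicitly from both
leaflets moving in the one background velocity field, with no contact
algorithm. That is precisely the mechanism by which full-scale immersed
FSI keeps a closed valve sealed under diastolic load, demonstrated here
at desk scale. Demo parameters (0.5 cm box, ~0.003 mmHg driving
pressure, 1e4/5e3 dyne-scale leaflet stiffnesses) are chosen so the flow
stays deep in the laminar regime, the startup transient completes within
0.5 s, and explicit coupling is stable at $dt=10^{-4}$ s; they are demo
choices, not physiologic claims.

## Problem sizes and determinism

The shipped defaults are sized for a single desktop CPU: circulation
runs integrate up to 20 cycles at $dt=10^{-4}$ s (~170k steps, seconds);
tight mass-balance checks use $dt=5\times10^{-4}$ s over up to 80
cycles; fits take ~400-point datasets through 8 multi-starts; IB demos
use 64² grids for up to 1 s of simulated time (the most expensive,
~2 min including the open-channel reference). Every stochastic step
(noise generation, randomized property tests) is seeded; identical
configurations give byte-identical outputs.

## Known limitations

* The circulation surrogate has no inertance and no regurgitant or
  closing backflow volume; diastolic LV pressures are set entirely by the
  minimum elastance (very compliant here), so diastolic transvalvular
  gradients read higher than a resolved model with the same aortic
  pressures would give against a stiffer filling ventricle.
* The stent lattice is idealized, its stiffnesses are not device
  parameters, and stent--anatomy contact is absent.
* The IB solver is 2D, uniform-grid, periodic-domain only; wall shear
  stresses are unresolved by construction, and no claim transfers
  quantitatively to 3D.
* $\beta$ and the flexural behavior of pericardium are taken as given;
  fitting exercises biaxial data only.
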