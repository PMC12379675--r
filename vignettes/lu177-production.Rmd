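---
title: "Modelling accelerator production of lutetium-177: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling accelerator production of lutetium-177: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radyield)
```

radyield models the production of radionuclides by light-ion beams on thin
enriched targets. Its reference application is carrier-free ¹⁷⁷Lu from
10 mA, 18 MeV deuterons on 99 % enriched [¹⁷⁶Yb]Yb₂O₃: the dominant route is
¹⁷⁶Yb(d,p)¹⁷⁷Yb followed by the 1.911 h beta decay into ¹⁷⁷gLu, with a
smaller direct (d,n) contribution and a handful of contaminant channels
(¹⁷⁷ᵐLu, ¹⁷⁶ᵐLu, ¹⁷⁴ᵍ⁺ᵐLu, plus stable ¹⁷⁵Lu and quasi-stable ¹⁷⁶ᵍLu that
only matter as carrier mass). This vignette explains the model stage by
stage, states every assumption and tunable parameter, and records the
numerical and design choices that were genuinely open.

## Stopping power and ranges

The electronic stopping power is the compact Bethe–Bloch form

$$S(E) = \frac{\omega z^2}{\beta^2}\,\ln(\kappa\beta^2),\qquad
\omega = 4\pi n_e m_e c^2 r_e^2,\quad \kappa = \frac{2 m_e c^2}{\langle I\rangle},$$

with shell and density-effect corrections omitted — they are sub-percent for
deuterons between a few and twenty MeV, and the compact logarithm keeps the
range integral analytic enough to calibrate transparently. The neglected
bracket terms ($-\beta^2 - \ln(1-\beta^2) \approx \beta^4/2$) amount to
about $2\times10^{-5}$ relative at 10 MeV; a unit test pins the compact form
at $10^{-10}$ against a literal re-evaluation and separately measures that
gap. $\beta^2$ is always computed relativistically from the kinetic energy
and the ion rest mass, $\beta^2 = 1 - (m_0c^2/(E+m_0c^2))^2$; at these
energies the nonrelativistic shortcut would bias ranges by close to a
percent for no saving.

Compound mean excitation potentials come from Bragg's rule,
$\ln\langle I\rangle = \sum_i N_iZ_i\ln I_i / \sum_i N_iZ_i$, with
per-element values I(Yb) = 684 eV and I(O) = 95 eV giving 512.4 eV for the
oxide. The rule is exact for one component and bounded by the component
values in general — both are property-tested.

**Low-energy cutoff.** The logarithm changes sign at
$\kappa\beta^2 = 1$, so the model is integrated only above the energy where
$\kappa\beta^2 = e$ (1.279 MeV for deuterons in Yb₂O₃, 1.708 MeV in Yb
metal). Below the cutoff the particle still travels a short distance;
`csda_range()` approximates it by constant-stopping continuation,
$R_{\rm sub} = E_{\min}/S(E_{\min})$, about 15 µm in the oxide and 37 µm in
the metal. Setting this residual to zero instead (the `subcutoff = "zero"`
switch) leaves the full 17.9 MeV ranges 2–3.5 % below the reference values
0.49/0.75 mm, while with the continuation both land within 1 %. Interval
quantities — slab thicknesses, residual energies, thin-target averages — are
unaffected either way, because the constant cancels in range differences.

**Isotopic molar masses.** A 99 % enriched target is essentially pure
¹⁷⁶Yb, so the packaged scenario materials use the isotopic molar mass
(175.9426 g/mol; M(Yb₂O₃) = 399.88 g/mol) rather than the natural-abundance
173.045. This is not cosmetic: the electron density, and with it every
thickness, scales with $\rho/M$, and only the enriched masses reproduce the
published design thicknesses (0.359 mm oxide, 0.541 mm metal for 18→8 MeV)
and rate table within a percent; natural masses leave all of them 2–3 %
short. `material()` takes per-element molar-mass overrides, so either
convention is one argument away.

Ranges use `stats::integrate` (adaptive, absolute tolerance well below the
10⁻³ mm at which thicknesses are quoted); a 1 keV fixed-step marching oracle
agrees to 0.1 % across 2–20 MeV in both materials. `residual_energy()`
inverts $R(E)-R(E_T)=T$ by bracketed root-finding polished with one Newton
step in range space, verified to 10⁻⁹ mm.

## Excitation functions and averaged cross sections

Excitation functions are tables interpolated piecewise-linearly; below the
first node the cross section is zero, above the last node the package
refuses to extrapolate — an activation integral must never invent cross
section. The thin-target averaged cross section weights by the inverse
stopping power,

$$\langle\sigma\rangle_T = \frac{1}{T}\int_{E_T}^{E}\frac{\sigma(E')}{S(E')}\,dE',
\qquad T = R(E)-R(E_T),$$

and reduces to the full range average when $E_T$ reaches the cutoff (tested
to 10⁻⁹ relative). Integrals are evaluated segment-wise between the σ-grid
nodes with 7-point Gauss–Legendre quadrature — the integrand is smooth
inside each segment and kinked at the nodes, so this converges essentially
to machine precision and matches a brute-force 1 keV trapezoid oracle to
10⁻⁶. Using the same segment rule for numerator and denominator makes the
average of a constant curve exactly that constant.

The energy-weighted approximation
$\int\sigma E\,dE/\int E\,dE$ (the "material-independent" shortcut, kept as
`mode = "approximate"`) rests on treating the logarithm in $S$ as constant.
Over the cross-section support (5–18 MeV) that is fair, but over the full
tracking window from the 1.28 MeV cutoff the logarithm grows from 1 to 3.6,
so the two modes differ by ~9 % at 17.9 MeV on the (d,p) curve; the package
documents and tests this at its measured size rather than pretending the
near-equality is tighter than it is. The precise 1/S-weighted form is the
default everywhere.

## The fixture excitation library

The experimental and evaluated σ(E) tables behind the reference study are
external databases and are not shipped. Instead `yb176_xs_library()` returns
smooth parametric stand-ins — threshold-damped split-Gaussian forms
$\sigma(E) = A\,(1-e^{-(E-E_{th})/d})\,e^{-(E-E_p)^2/2w^2}$ with different
left/right widths, and a saturating form for the non-elastic aggregate —
whose constants were calibrated once, against this package's own quadrature,
and committed:

* the (d,p) curve has its threshold at 5 MeV, its peak of 230 mb at
  12.5 MeV, and reproduces the three design-study averages
  $\langle\sigma\rangle_T$(16→6, 18→8, 20→10 MeV) = 167.4/175.4/167.9 mb to
  better than 1.6 % (the family saturates there; the calibration tolerance
  is ±3 %);
* every contaminant reaction is scaled so its production rate in the
  reference scenario reproduces the published rate table essentially
  exactly;
* the non-elastic curve and the two nucleon-retaining channels
  ((d,d′), (d,n+p)) are scaled so the (d,anything) rate and the composed
  burn-up rate ($\sigma^* = \sigma^{non} - \sigma_{d,d'} - \sigma_{d,np}$,
  grids unified by interpolation, negatives clipped with a warning) match
  their published values, for both the oxide and the metal target.

What the fixtures emulate is therefore the *integral* behaviour of the real
curves under this scenario; what they do not emulate is the fine structure
of the measured excitation functions, their uncertainties, or their
behaviour outside the calibrated window. Passing tests demonstrate the
formalism and the calibration, not the nuclear data themselves; users with
real tables (EXFOR, TENDL exports) should load them through
`read_excitation_csv()`, which round-trips losslessly with the writer.

## Rates, figures of merit, burn-up

With a mono-energetic beam equal in area to the target face, the
per-reaction rate is $\Gamma = \eta\,\epsilon\,(J/q)\,T\,N\,
\langle\sigma\rangle_T$: η the enrichment (multiplying the atom count, not
redefining molar mass), ε the line transmission (0.985), $J/q$ the particle
current, N the Yb atom number density (two atoms per oxide formula unit).
The area cancels between flux and target face, so doubling the radius at
fixed current changes nothing — a tested invariant. `beam_flux()` exposes
both conventions (with and without ε); the quoted bare flux on target is
1.99×10¹⁶ d/cm²/s. Angular path-length enhancement from imperfect
collimation is not modelled; it makes the thin-target rate a slight
underestimate.

`figures_of_merit()` tabulates the optimiser's ranking keys: ΔE/T
(proportional to the heat load), $T\langle\sigma\rangle_T$ (to the
production rate) and $T\langle\sigma\rangle_T/E$ (production per unit beam
energy). On the three candidate intervals the 18→8 MeV design maximises the
efficiency key while 20→10 maximises raw production — the reason the
reference accelerator stops at 18 MeV.

Target burn-up uses the composed σ*: the rate is the same formula with σ*
in place of σ, and depletion follows
$N(t) = N_0 e^{-\phi\langle\sigma\rangle^* t}$. For the reference target the
burn-up rate is 6.07×10¹³ reactions/s and 10 % depletion takes 61.7 days of
continuous beam, which is why recycling the target is economic.

## Decay-chain inventories

Chains are strictly linear (no branching): the ¹⁷⁷ᵐLu decay branch into
¹⁷⁷ᵍLu is ignored (its feed is three orders below the direct activities
involved), and each contaminant is produced by its own single-step route.
During irradiation a constant source Γ into the first member gives the
closed form

$$N_n(t) = \frac{\Gamma}{\lambda_n}\sum_{j=1}^{n}(1-e^{-\lambda_jt})
\prod_{k\ne j}\frac{\lambda_k}{\lambda_k-\lambda_j},$$

evaluated with `expm1` so quasi-stable nuclides (¹⁷⁶ᵍLu, t½ = 3.76×10¹⁰ y)
lose no precision; truly stable members are only allowed at the chain end,
where they act as sinks filled by atom conservation (and conservation,
Γt = chain total, is tested to 10⁻⁹). After shutdown the state decays with
precursor in-growth by the matching closed form. Both phases are checked
against an independent stiff-ODE oracle at 10⁻⁸ relative on the reference
chains and on 100 randomised chains (up to four members, decay constants
spread over six decades); the test sizes keep the whole suite inside a few
minutes on one core. When two decay constants coincide to better than 10⁻⁹
relative the closed form is numerically singular, and the package itself
switches to the stiff integrator — correctness over closed-form purity.

**Half-life fixture.** Two half-lives are consistency-adjusted: ¹⁷⁶ᵐLu is
entered as 3.664 h and ¹⁷⁴ᵐLu as 142.2 d. The commonly quoted alternatives
(3.66 d, 120.9 d) are inconsistent with the reference inventory tables this
network is validated against — the ¹⁷⁶ᵐLu saturation inventory
(0.172×10¹⁸ atoms at a 9.02×10¹² atoms/s rate) and its 1.03 GBq activity
48 h after shutdown pin the half-life to hours, and the ¹⁷⁴ᵐLu activity
implies ≈142 d. Both adjustments are flagged in `nuclide_data()`'s `note`
column. One published atom count (¹⁷⁴ᵍLu, "0.02×10¹⁸") is internally
inconsistent with its own mass and activity by a factor ten and is treated
as a typo; mass and activity are the validated quantities.

Reports derive mass $NM/N_A$, activity $\lambda N$, radionuclidic purity
(activity share within the reported set, summing to 100 %) and two specific
activities: per summed radionuclide mass, and per total element mass
including stable carriers — the second is the clinically limiting figure
(598 GBq/mg for the 5-day reference schedule, versus 3.75 TBq/mg on the
radionuclide basis).

## The scenario layer

`run_scenario()` executes the whole pipeline from one YAML file and is
bit-deterministic; the packaged `lu177_reference.yaml` encodes the reference
design (18→8 MeV, 10 mA, ε = 0.985, η = 0.99, r = 1 cm, 5 d + 48 h). Rates
can come from the fixture library (`rates.source: fixtures`, the default)
or from the packaged published rate table (`reference`), selected per
reaction by dataset — the mixed default mirrors the reference yield tables,
which use the experimental rates where they exist and the evaluated ones
elsewhere (¹⁷⁷ᵐLu, ¹⁷⁶ᵍLu, ¹⁷⁵Lu). Timelines are evaluated on a configurable
grid (25 points per phase by default — closed forms make each point cheap).
A zero-duration irradiation returns an empty inventory and suppresses the
purity table rather than reporting 0/0.

## Known limitations

* No lateral/longitudinal straggling, nuclear stopping, or Monte Carlo
  transport: the thin-target, mono-energetic-beam idealisation throughout.
* Shell and density corrections omitted; the stopping model is not meant
  below the validity cutoff or for heavy ions.
* Fixture cross sections are calibrated stand-ins, not nuclear data; no
  uncertainty propagation.
* Chains are linear; branching decay networks and gamma dose modelling are
  out of scope.
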