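---
title: "Coarse-grained membrane-protein unfolding and force-curve analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained membrane-protein unfolding and force-curve analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(photopull)
```

photopull combines two computational halves of a single scientific problem:
why the same membrane protein unfolds differently in membranes of different
hydrophobicity. The first half is a structure-based (Gō-type) coarse-grained
model of mechanical unfolding with an implicit membrane; the second half is
the analysis pipeline that turns single-molecule force-spectroscopy (SMFS)
force–distance curves into contour-length statistics that can be compared
across membranes. A reweighting module connects membrane hydrophobicity (a
proxy for cholesterol content) to the conformational equilibrium between the
inactive and active receptor states.

## The coarse-grained model

Each residue is a bead at its native Cα position. The potential is a sum of
five terms:

* **Backbone**: harmonic tethers between consecutive beads,
  $V^{BB} = \sum_i k_{BB}(r_{i,i+1} - d_0)^2$ with $d_0 = 3.8$ Å and
  $k_{BB} = 33.34\,\varepsilon/\text{Å}^2$. The spring constant is the
  smallest that remains stable at the 15 fs timestep label (see *Units*).
* **Native contacts**: Lennard-Jones wells
  $4\varepsilon[(\sigma_{ij}/r_{ij})^{12} - (\sigma_{ij}/r_{ij})^6]$ over the
  native contact map, with $\sigma_{ij}$ the native Cα–Cα distance. The well
  minimum therefore sits slightly outside the native separation
  ($2^{1/6}\sigma_{ij}$); we keep this literal convention.
* **Non-native repulsion**: a truncated, shifted LJ
  ($\sigma_0 = 5$ Å, cut at $d_{cut} = 5.61 \approx 2^{1/6}\sigma_0$ Å) on
  all non-adjacent, non-native pairs.
* **Chirality**: $k_{CHIR} C_i^2\,\Theta(-C_i C_i^{NAT})$ penalises internal
  beads whose instantaneous chirality (normalised triple product of three
  consecutive virtual bonds) opposes the native sign. $\Theta$ is the
  standard Heaviside step (1 for positive argument, 0 otherwise). A literal
  step that returns −1 instead of 0 would *reward* correct-handed segments
  and destabilise straight chains; that reading is available behind
  `ff_params(theta_literal = TRUE)` for sensitivity checks only.
* **Membrane slab**: hydrophobic residues in native membrane contact pay 0
  inside $[z_{min}, z_{max}]$ ($-17.034$ to $15.896$ Å), a linear 3 Å ramp
  at each border, and $\varepsilon_{membr}$ outside; hydrophilic contact
  residues feel the same profile times −1. $\varepsilon_{membr}$ is the one
  free parameter of the model: a larger value describes a more hydrophobic
  (cholesterol-rich) membrane. Membrane-contact flags are assigned once from
  the native structure (Cα z within the slab extended by the ramp) and do
  not change during unfolding; the flag-based reading keeps the potential a
  function of the native topology only.

Contacts for atomistic structures use the enlarged van der Waals overlap
criterion: residues i, j (|j − i| ≥ 2) interact natively if any heavy-atom
pair sits closer than 1.244 times the sum of the atoms' radii. The radii are
a Tsai-style table keyed by atom class (sp3 C 1.88, aromatic CH 1.76, sp2 C
without H 1.61, N 1.64, carbonyl O 1.42, hydroxyl O 1.46, S/Se 1.77 Å),
overridable per call. Hydrophobicity is the Kyte–Doolittle scale split at
zero (strictly positive = hydrophobic); disulfide bridges are ordinarily
represented implicitly through the contact map, with `add_cross_link()`
available to pin a specific pair explicitly.

## Units and the integrator

Internally everything is expressed in Å, ε and unit bead mass, which fixes
the reduced time unit $\tau = \sqrt{m\,\text{Å}^2/\varepsilon}$. The
conventional calibration $\sqrt{m\sigma^2/\varepsilon} \approx 3$ ps with
$\sigma = 5$ Å puts $\tau$ at roughly 600 fs, and that is the default
`fs_per_tau`. Under this calibration the femtosecond-labelled constants
(dt = 15 fs, γ = 8.14×10⁻⁴ fs⁻¹, v_pull = 2.035×10⁻⁶ Å/fs) are mutually
consistent: the backbone oscillation satisfies ω·dt ≈ 0.2, i.e. the quoted
spring constant is indeed at the edge of stability for the quoted timestep,
and the products γ·dt and v·dt — which carry the physics — are independent
of the calibration altogether.

The Langevin equation $m\ddot r = -\gamma\dot r + F_c + \sqrt{2\gamma k_BT}\,\xi$
is integrated with the BBK discretisation of velocity Verlet; one Gaussian
random force per time label is shared between the second half-kick of a step
and the first half-kick of the next, which reproduces equipartition to
within the discretisation error (the suite checks ⟨KE⟩/dof = 0.26 ± 0.02 ε
at $k_BT = 0.52$). With γ = 0 and T = 0 the scheme reduces to plain velocity
Verlet and conserves energy (drift < 10⁻² ε over 10⁴ steps on a 50-bead
fixture built at an exact potential minimum). Random numbers come from a
bundled xoshiro256++/ziggurat generator so trajectories are bit-reproducible
for a fixed seed across platforms. Forces at the non-differentiable membrane
ramp corners take the one-sided derivative from inside the ramp; the
potential is continuous so the impulse error is bounded by the timestep.

Pulling attaches a harmonic spring (default k = 0.2 ε/Å², chosen soft enough
to resolve individual ruptures; it is echoed in the trace attributes) to the
C-terminal bead and moves its outer end along +z at constant velocity while
the N-terminal bead is fixed. The recorded force is the spring extension
times k; the native-contact fraction Q and the contiguous unfolded stretch
from the pulled terminus (a residue is "unfolded" once all of its native
contacts exceed 1.5 σ) are recorded alongside. Runs stop at full detachment,
tolerating a residual 1% of contacts because pairs whose 1.5 σ exceeds the
stretched-chain spacing can never register as broken.

Event detection smooths the recorded force with a running mean and reports
running maxima terminated by a drop exceeding a fraction of the peak height
(0.3), a multiple of the thermal force noise (3), and a fraction of the
trace-wide maximum (0.25, the "major peak" floor); a peak must also rise by
the same threshold above the valley preceding it, which prevents the decay
shoulder of a rupture from being counted twice.

## The synthetic structure

No experimental membrane-protein structure ships with the package (the
deliverable is text-only and built offline), so structure-scale work runs on
`synthetic_tm_bundle()`: an idealised 348-residue, seven-transmembrane
helical bundle with ideal helix geometry (1.5 Å rise, 100°/residue, 2.3 Å Cα
radius), helix axes on an 11 Å circle (adjacent axis spacing ≈ 9.5 Å,
realistic packing), circular-arc loops relaxed to 3.8 Å spacing without
clashes, straight terminal tails leaving the membrane on opposite faces, and
a segment-wise sequence draw that makes helices hydrophobic-rich and loops
polar-rich. Because an idealised Cα trace has no heavy atoms, its native
contacts use a Cα distance cutoff (8.5 Å, |j − i| ≥ 3). The cutoff was fixed
by two construction requirements stated before any end-to-end testing: the
fold must be stable at the working temperature (Q ≈ 0.9 at $k_BT = 0.52$)
and melt 20–40% above it, mirroring the design rule that the working
temperature sits below the melting point by a comfortable margin. Pairs with
|j − i| = 2 are excluded because their separation is fixed by backbone
geometry (7.6 Å in a stretched chain, within 1.5 σ of their native ~5.4 Å),
so they can never register as broken and would contaminate both Q and the
unfolded-stretch count; the same screen removes any pair whose rupture
distance exceeds 95% of its stretched-chain separation.

What the stand-in does *not* reproduce is the tertiary detail of any real
receptor: its melting transition is broader than a natural fold's, its
unfolding temperature is its own (the scan in the test suite localises the
Q = 0.5 crossing near 0.7 ε rather than any literature value), and its
event-by-event unfolding pathway is that of a symmetric bundle. Conclusions
that depend on the real fold — the printed unfolding temperature of the
visual pigment, or exact major-event counts at specific membrane strengths —
cannot be checked against it and are not asserted; the monotone response of
unfolding force and event count to $\varepsilon_{membr}$, which is the
mechanistic claim, is.

Desk-scale settings used by the test suite: melting scan over
$k_BT \in [0.5, 0.9]$ with 2 replicas of 3×10⁵ steps per temperature;
pulling sweep over $\varepsilon_{membr} \in \{4.03, 5.64, 7.25, 10\}$ with 2
replicas each at 10× the production pulling velocity (at this speed the
friction on the moving, unfolded part of the chain adds ≲ 1 ε/Å of baseline,
small against 3–7 ε/Å rupture forces; much larger multiples would bury the
sawtooth in drag).

## The force-curve pipeline

Force–distance curves are modelled point-by-point with the Marko–Siggia
worm-like chain, $F = (k_BT/p)\,[1/(4(1 - x/L_c)^2) - 1/4 + x/L_c]$ with
persistence length p = 0.4 nm and $k_BT$ = 4.114 pN·nm (25 °C). The
interpolation formula itself is the standard choice in the SMFS literature
(the analysis tradition the pipeline follows does not print one). Inversion
to contour length solves the cubic in $u = 1 - x/L_c$ by vectorised
bisection; the roundtrip is exact to < 0.1 nm.

The pipeline stages are:

1. **Peak detection** (`detect_fd_peaks`): Savitzky–Golay smoothing
   (7 points), the same rise/drop sawtooth detector as the simulator
   (absolute drop 20 pN ≈ 5 SD of the smoothed noise at the default
   10 pN noise level), least-squares WLC fit of each rising edge above a
   10 pN noise floor, rupture force read off the denoised trace, and
   collapse of residual double-detections within 5 nm.
2. **Filtering** (`filter_curves`): every retained peak ≥ 35 pN and the
   final peak inside a configurable contour-length window — (0, 200) nm
   selects rhodopsin-length molecules (~550 aa at 0.364 nm/aa), while
   (200, 300) nm selects CNG-channel-length curves; a single fixed 200 nm
   cap would discard the entire closed-state CNG dataset, whose detachment
   sits at 273 nm.
3. **Clustering** (`cluster_curves`): per-curve force-weighted F–Lc
   histograms on a common grid; pairwise similarity is the maximum overlap
   (sum of binwise minima of unit-normalised histograms) over integer bin
   shifts within ±5 nm, the stated bound on unspecific attachment-offset
   variability; average-linkage hierarchical clustering cut at similarity
   0.4. Clustering always uses ≥ 3 nm bins even when the reporting bins are
   finer (0.8 nm bins spread the mass too thinly for overlap to be
   informative). Each member's best alignment shift against the cluster
   reference is kept and re-centred to zero mean, so the arbitrary offset of
   the reference curve does not bias downstream positions.
4. **Peak statistics** (`peak_statistics`): alignment-corrected peak
   positions pooled per cluster are partitioned at the valleys between the
   modes of their histogram — modes closer than 6 nm, or separated by a
   valley shallower than 60% of the smaller mode, are treated as one peak
   group. A plain sorted-gap rule was tried first and split wide single
   clouds while merging everything when stray mis-fits bridged the gaps;
   the valley-depth rule reflects how such peak tables are actually read
   off published histograms. Per group the report carries mean ± SD contour
   length (nm and residues), occurrence probability (fraction of member
   curves showing the peak; groups below 10% occurrence are dropped as
   unreproducible) and rupture-force statistics.

Residue conversion divides $L_c$ by 0.4 nm/aa by default; the bundled
rhodopsin templates use 0.36 nm/aa because the published
contour-length-to-residue conversions for that protein imply it (e.g. 86 nm
at 240 aa), while the CNG templates use 0.4 (276 nm at 690 aa). Both values
appear in `wlc_params(residue_nm = )` and in every template.

## The synthetic SMFS generator

`generate_curve()` draws, per curve: one Bernoulli inclusion per template
peak, a Gaussian position jitter per peak (the published per-peak SDs), a
truncated-Gaussian rupture force (floor 35 pN, matching the filter threshold
so synthetic data exercises the filter boundary), a uniform ±5 nm attachment
offset, white Gaussian force noise (10 pN) and a small random linear
baseline drift. Force follows the WLC toward each included peak and drops to
the baseline instantaneously, as observed sawtooths do. The dataset
generator records a ground-truth manifest for recovery scoring and is
byte-reproducible for a fixed seed. Five templates parameterised from
published peak tables ship with the package (`smfs_templates()`), covering
the closed- and open-state CNG channel and rhodopsin pulled from discs and
the plasma membrane.

Two honest limitations of the closed loop, measured on synthetic data:
recovered group means carry a ~1% low bias (WLC fits of noisy rising edges
are slightly short), comfortably inside the two-bin-width recovery
tolerance; and measured rupture forces track the realised ones only at the
dataset level (mean deviation below one noise SD) — per-group force means
can deviate by up to ~15 pN because the detachment sampling grid truncates
steep force rises and weak ruptures near the detection floor are
preferentially missed. Real instrument effects beyond white noise, drift and
attachment offset (1/f noise, hydrodynamic artefacts, multiple tethers) are
not emulated, so passing recovery tests bounds algorithmic error, not
instrumental error.

## Ensemble reweighting

`generate_ensemble()` emulates the post-processed output of an atomistic
simulation of the inactive receptor: a broad inter-helix angle distribution
(truncated Gaussian, mode 2.72 rad, SD 0.18 rad — "broad" at the scale where
0.18 rad of helix rotation is a large structural change), hydrophobic
transmembrane SASA concave in the angle and peaking at the mode, hydrophilic
SASA anti-correlated. SASA itself is computed by a Shrake–Rupley
implementation (960 golden-spiral points, 1.4 Å probe) validated against an
independent random-direction sampling oracle to < 2%.

Reweighting multiplies each frame by
$w \propto \exp[g(c)\,(A_{HPHOB} - A_{ref})]$, the minimal Boltzmann form in
which a more hydrophobic membrane favours conformations exposing more
hydrophobic surface: $g(c)$ is a transfer free-energy coefficient per unit
area (kBT/Å²), zero at zero cholesterol and monotone in the cholesterol
fraction. The bundled `illustrative_cholesterol_model()` (linear to
0.01 kBT/Å² at 50% cholesterol) is an order-of-magnitude placeholder
generated in code, not a literature calibration — users with a measured
partition-coefficient curve should supply their own `cholesterol_model()`.
The normalised active/inactive population ratio
$[P_c(meta)/P_c(rhod)]/[P_0(meta)/P_0(rhod)]$ equals 1 at c = 0 by
construction and declines with c whenever the active-state range of the
angle exposes less hydrophobic area; on the bundled synthetic ensemble it
falls to ≈ 0.2 at 50% cholesterol, the qualitative behaviour (direction and
order of magnitude) expected of a cholesterol-rich membrane suppressing
receptor activation. The state split is user-supplied (default: threshold
2.4 rad); `state_split_threshold()` locates the valley automatically only
for genuinely bimodal distributions.

## Numerical choices and degenerate inputs

* WLC inversion: 80 bisection iterations, unique root guaranteed on (0, 1);
  non-positive forces or extensions return NA and are counted in the QC
  attributes.
* Non-native pairs use a neighbour list with a 2 Å skin, rebuilt when any
  bead has moved half the skin.
* `melting_scan` interpolates the first downward crossing of mean Q through
  0.5 and errors with advice when the grid does not bracket the transition.
* Empty curves, non-numeric rows and unit mismatches in curve files are
  skipped with warnings; the batch continues.
* All-empty histograms, single-curve clustering, zero-mass states at c = 0
  and chains without Cα atoms raise errors naming the offender.

## Known limitations

The membrane is a static implicit slab: no lipid rearrangement, no membrane
deformation by the extracted chain, no electrostatics or solvent. Forces
from the simulator are reported in reduced units (ε/Å); the package
deliberately does not fix a pN conversion because the energy scale ε is not
pinned experimentally. The synthetic bundle supports every qualitative
study the simulator is designed for, but quantitative anchors tied to a
specific experimental fold require supplying that structure as an oriented
PDB file to `parse_structure()`/`cg_topology()`.
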