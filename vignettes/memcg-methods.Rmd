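---
title: "The memcg model: assumptions, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The memcg model: assumptions, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memcg)
```

## The representation

`memcg` models a membrane protein at one united particle per side chain
plus explicit backbone atoms (N, CA, C, O, and the amide H when the input
provides one). The united particle sits at the geometric centroid of the
side-chain heavy atoms (CB included); when an input residue has only CB,
the particle is CB itself, and glycine carries no particle. The centroid
choice is a design decision of this package: it is reproducible,
rotation-covariant, and requires no rotamer assignment. Hydrogens never
enter the mapping.

Residues are classified as nonpolar (ALA, VAL, LEU, ILE, PHE, MET, TRP,
PRO, GLY), polar (SER, THR, ASN, GLN, TYR, CYS) or ionizable (ASP, GLU,
LYS, ARG, HIS) — the standard biochemical partition, fully configurable
(`energy_config(residue_class = ...)`, e.g. to treat HIS as polar).
Intrinsic water pKa defaults are the textbook values ASP 3.9, GLU 4.3,
HIS 6.5, LYS 10.5, ARG 12.5; only *differences* between the
environment-shifted and water pKa enter the energy, so a consistent table
matters more than any individual entry. Chain termini are not ionizable
by default (`termini_ionizable = TRUE` adds them with pKa 8.0 / 3.6);
keeping the site count minimal makes exact enumeration available more
often.

The membrane is a cubic lattice of particles (spacing 3 Å) filling a slab
of half-thickness 15 Å — a 30 Å hydrophobic core, the usual
implicit-membrane dimension — laterally covering the protein's bounding
box plus a 15 Å margin, with nodes closer than 2.5 Å to any protein
particle removed. The lattice is anchored at the coordinate origin and at
the slab center, so rebuilding a grid for a translated-by-a-lattice-vector
protein yields a congruent environment; this is what makes the
two-distant-copies extensivity check exact. The grid is built once per
conformation frame and frozen for every energy and Monte Carlo evaluation
of that frame; membrane thickness fluctuations, curvature and head-group
chemistry are out of scope.

## The energy function

The folding free energy of one conformation is

$$G = c_1 G^{vdw}_{side} + c_2 G^{solv}_{main} + c_3 G^{HB}_{main}
      + G^{elec}_{side} + G^{polar}_{side} + G^{hyd}_{side}
      + G^{elec}_{main-side} + G^{vdw}_{main-side}$$

with $c_2 = 0.25$ and $c_3 = 0.15$; $c_1$ defaults to 0.10 and is a
package choice, not an externally fixed constant. The returned
`energy_breakdown` always satisfies this identity to $10^{-9}$, which the
test suite asserts on randomized structures.

**Electrostatics.** The side-chain electrostatic term is

$$G^{elec}_{side} = -2.3RT \sum_i \langle Q_i\rangle
  \left(pK_{a,i}^{intr} - pK_{a,i}^{w}\right)
  + \Delta G_{Qdev} + \Delta G_{QQ}^{fold} - \Delta G_{QQ}^{unfold}$$

where $\langle Q_i\rangle$ is the ensemble-average charge of site $i$ and
$\Delta G_{QQ}^{fold}$ is the ensemble-average screened Coulomb energy
between charged sites, $k q_i q_j / (\varepsilon_{eff}\, r_{ij})$ with
$k = 332.0637$ kcal·Å/(mol·e²) and a uniform effective dielectric
$\varepsilon_{eff} = 40$ — the large effective dielectric that
coarse-grained charge–charge screening calls for; its exact value is a
configuration parameter. The unfolded reference places all charges at
their water pKa at infinite separation, so $\Delta G_{QQ}^{unfold} = 0$
and any constant reference cancels in conformational differences, which
are the quantities this package is for. $\Delta G_{Qdev}$, the correction
for the scaled-down protonation change on unfolding, has no published
functional form and defaults to a configurable constant 0.

**Self-energy and intrinsic pKa.** Charging a site in a low-dielectric
environment costs

$$\Delta G_{self,i} = |q_i|\left[a_{np}\min(N^{np}_i, N_{sat})
  + a_{p}\min(N^{p}_i, N_{sat}) + a_{mem}\min(N^{mem}_i, N_{sat})\right]$$

where the $N_i$ count nonpolar side particles, polar side particles and
membrane particles within the 10 Å neighbor cutoff of the site. The
linear-with-saturation form (slopes 0.05, −0.05, 0.20 kcal/mol per
neighbor; $N_{sat} = 20$) is the simplest potential with the right
monotonicity: membrane burial penalizes charge most, polar surroundings
relieve it. The intrinsic pKa is the water value shifted by
$\Delta G_{self}/(2.3RT)$ — up for acids (harder to ionize when
desolvated), down for bases. Smooth per-count tables can be supplied via
the configuration where continuous derivatives matter.

**A note on the 2.3 factor.** The conversion between pKa units and
energy uses the factor 2.3 as conventionally written, not
$\ln 10 = 2.3026$. Titration curves are therefore sigmoids in
$e^{2.3x}$ rather than $10^x$: indistinguishable at the half-charge
point (so apparent pKa values are unaffected) and within $10^{-3}$
charge units elsewhere. The tests assert the exact $e^{2.3x}$ closed
form and the base-10 form at the appropriate tolerance.

**Packing terms.** Polar–polar side-particle contacts within the cutoff
contribute $k_{polar} = -0.1$ kcal/mol each; nonpolar–nonpolar contacts
$-k_{hyd} = -0.1$ kcal/mol each, plus $-0.1$ kcal/mol once per nonpolar
side particle in contact with the membrane (hydrophobic matching at the
contact-count level). Van der Waals interactions use a 6–12 potential
with per-residue-type united-particle radii, well depth 0.1 kcal/mol, and
a $+10$ kcal/mol per-pair cap so that unrelaxed morph frames with clashes
yield finite, comparable energies. Backbone hydrogen bonds contribute
$-1$ kcal/mol scaled by a linear switch from 1 at donor-N/acceptor-O
distance ≤ 3.0 Å to 0 at ≥ 3.5 Å, over pairs at least three residues
apart in sequence. Backbone desolvation charges $k_{solv} = 0.5$ kcal/mol
for each amide N or O whose surrounding particle count (protein particles
of other residues plus membrane particles within 6 Å) exceeds 10. The
backbone/side-chain coupling uses backbone partial charges C +0.4,
O −0.4, N −0.2, H +0.2 against charged side particles, and the same
capped 6–12 against backbone heavy atoms.

**One cutoff convention.** Every pair term — packing, hydrogen-bond
candidate enumeration aside, backbone coupling, *and* the charge–charge
Coulomb sums — uses the same 10 Å cutoff with the count-at-boundary
convention (a distance exactly equal to the cutoff counts, implemented
with a $10^{-9}$ Å² tolerance on squared distances so that rigid
rotations cannot flip boundary cases). Cutting the Coulomb sum is what
makes the energy exactly extensive: two copies of a structure separated
by more than the cutoff decouple in every term, including the titration
ensemble. Distances below 2 Å in Coulomb terms are clamped to 2 Å as a
clash guard for morph frames.

## Charge-state determination

At fixed pH the charge configuration energy is

$$\Delta G^{m}_{elec} = -2.3RT\sum_i q_i^{(m)}
  \left(pK_{a,i}^{intr} - pH\right) + \Delta G_{QQ}^{(m)}$$

evaluated with the instantaneous configuration charges $q_i^{(m)} \in
\{0, \pm 1\}$ — the standard reading for a per-move energy; using
pre-averaged charges inside a move energy would make the Metropolis
criterion circular. Sampling uses two move types: bulk exchange (one site
toggles charged/neutral, trading a proton with the solvent) and pair
proton transfer (a proton moves from a protonated site — neutral acid or
charged base — to a deprotonated one, conserving the total proton count).
Bulk moves alone guarantee ergodicity; pair moves (20% of attempts by
default) accelerate strongly coupled site pairs. A move is accepted when
the energy decreases or by the Metropolis criterion at 300 K. One sweep
attempts one move per site; defaults are 2 000 burn-in and 20 000
production sweeps, and the chain is bit-reproducible given the seed.

For 16 sites or fewer the package enumerates all $2^n$ configurations and
Boltzmann-averages exactly. This enumeration is both the default route in
`total_energy()` (making small-system profiles deterministic, with zero
error bars) and the oracle against which the sampler is validated: on
random 8–12-site systems in a 20 Å box with water pKa drawn from [3, 11],
$10^5$ production sweeps reproduce every exact mean charge to within
0.02. Apparent pKa values are read off titration curves as the pH where
$|\langle Q_i\rangle|$ crosses 0.5, by monotone linear interpolation on
the pH grid.

## Pathways, barriers, mutations

Intermediates between residue-matched end states are generated by linear
Cartesian morphing (frame $k$ at $t = k/(n-1)$; 21 frames by default, a
resolution at which the fixtures' energy features are well sampled);
residues missing from one end state are carried from the nearer end.
Morphing replaces biased-dynamics intermediate generation entirely — this
package makes no attempt at transition-state search, and morph frames are
not equilibrium structures, which is precisely why the repulsive caps and
clamps above exist. An optional bounded steepest-descent relaxation moves
side particles downhill on the side-chain pair surface (numerical
gradient, 0.1 Å displacement cap per particle per step, backtracking so
the energy never increases, backbone fixed). The descent surface keeps
the full repulsive wall rather than the capped potential: the cap's
plateau has zero gradient and would leave clashes unresolved.

Per-frame free energies are averaged over Monte Carlo seeds (three by
default in the pipeline), with the standard deviation over seeds as the
error bar — zero whenever the exact route is taken. The barrier is
$\max_k G_k - G_1$ with the earliest-maximum tie-break; the reaction
energy difference is $G_1 - G_n$, positive when the final state is more
stable. Two identities follow algebraically and are asserted in the
tests: reversing the path negates the reaction energy difference, and
forward minus reverse barrier equals its negative. Multi-state pathways
chain pairwise legs with shared junction frames and energies that are
*not* re-zeroed between legs. Mutational scans recompute the profile per
mutant — both end states mutated, same morphing schedule, same seeds — so
that every difference from wild type is attributable to the mutation.

## The synthetic generators, and what they do not show

`make_helix()` builds ideal α-helices: CA atoms on a cylinder (rise
1.5 Å, twist 100°, radius 2.3 Å) with N, C, O placed by fixed offsets in
each residue's local helical frame. The offsets are named constants,
fitted once against an ideal-geometry backbone so that bond lengths stay
near ideal values, the (i, i+4) donor–acceptor N–O distance lands at
2.95 Å (inside the hydrogen-bond window), and all other
sequence-separated N–O pairs stay beyond the 3.5 Å switch-off — an
n-residue helix therefore has exactly n−4 backbone hydrogen bonds, a
property the tests count by brute-force distance scan.

`make_two_state_bundle()` arranges parallel helices on a circle and tilts
one of them about its midpoint (rotation axis radial, so the helix ends
swing tangentially along the bundle surface) — a localized single-helix
motion between two otherwise identical states, the canonical motif of
channel-gating conformational changes. `make_titration_system()` builds
enumerable charge clusters whose backbone stubs are parked far outside
every cutoff, so the titration ensemble is determined purely by the site
geometry — the ground truth for the oracle tests.

`make_barrier_fixture()` is the analytic mutation-scan fixture: a
glycine-rich helix carrying one lysine translates along the membrane
normal from 30 Å above the slab to 30 Å below, so linear morphing takes
the charged site through the slab center exactly mid-path, where its
membrane neighbor count — hence its self-energy and pKa shift — peaks.
A tilt cannot produce this geometry (the z-coordinate of a linearly
morphed tilted particle is monotone along the path), which is why the
fixture translates. Neutralizing the lysine (K→S) removes the mid-path
electrostatic penalty and must lower the barrier; mutating an isoleucine
on a static helix placed beyond every cutoff must leave the barrier
unchanged to numerical precision. Both directions are asserted.

Passing on these generators shows that the machinery — mapping, grid,
titration, energy bookkeeping, morphing, barrier algebra — is internally
correct and deterministic. It does not show that the energy function's
absolute scale is realistic for experimental structures: the packing,
solvation and hydrogen-bond constants here are simple declared forms, not
a fitted force field, and real activation barriers additionally depend on
relaxed intermediates that morphing does not provide. Absolute kcal/mol
values for real proteins are therefore not reproduction targets of this
package; conformational *differences* and their qualitative responses to
mutations are.

## Numerical conventions collected

- Gas constant 0.0019872 kcal/(mol K); temperature 300 K; 2.3RT =
  1.371168 kcal/mol.
- Count-at-boundary cutoffs everywhere, with a 1e-9 Å² tolerance on
  squared distances.
- Coulomb distances clamped from below at 2 Å; 6–12 pairs capped at +10
  kcal/mol; the relaxation surface is uncapped.
- Degenerate-coordinate guard: no two particles within 0.01 Å.
- Exact enumeration whenever a conformation has ≤ 16 ionizable sites;
  `mc_config(mode = )` overrides.
- Earliest-index tie-break for the barrier maximum.
- Residue identity is (chain, author residue number, insertion code);
  coordinates are Å throughout.
- Mutation to glycine drops the side particle; the reverse mutation
  rebuilds a pseudo-particle along the local pseudo-CB direction, so
  only non-glycine mutation round-trips restore a structure exactly.
- Problem sizes in the shipped tests and acceptance script — helices of
  8–20 residues, bundles of four 18-residue helices, 21-frame profiles,
  20 random titration systems of 8–12 sites at 10^5 sweeps — were chosen
  so every property is exercised at full stated tolerance while the
  whole suite stays interactive.

## Known limitations

- No transition-state search, kinetics, or rates; barriers come from
  morphed frames only.
- No explicit ligands, ions or lipids; profiles are computed on protein
  conformations alone.
- No tautomers for histidine, no coupled conformational–protonation
  sampling within a frame, no explicit protons.
- The membrane is a rigid slab lattice: no thickness fluctuation, phase
  behaviour or curvature.
- Homology modeling, loop building and mmCIF input are out of scope;
  input is fixed-column PDB, first model, altloc A/blank.
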