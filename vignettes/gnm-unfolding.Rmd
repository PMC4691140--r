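---
title: "Network dynamics and iterative unfolding of Fab-like proteins"
author: "gnmunfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network dynamics and iterative unfolding of Fab-like proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`gnmunfold` treats a protein as an isotropic elastic network over its
C-alpha sites: every residue pair whose separation $R_{ij}$ does not
exceed a cutoff $r_c$ is joined by a harmonic spring of uniform force
constant $\gamma$. The network is fully described by the Kirchhoff
(connectivity) matrix $\Gamma$ — the graph Laplacian of the contact map:
$\Gamma_{ij} = -1$ for a contact, $0$ otherwise, and
$\Gamma_{ii} = -\sum_{j \ne i}\Gamma_{ij}$. Thermal fluctuations around
the native structure follow from the pseudoinverse:

* cross-correlations
  $\langle \Delta R_i \cdot \Delta R_j \rangle = (k_BT/\gamma)\,[\Gamma^{-1}]_{ij}$,
* per-residue mean-square fluctuation (MSF)
  $\langle (\Delta R_i)^2 \rangle = (k_BT/\gamma)\,[\Gamma^{-1}]_{ii}$,
* Debye–Waller B-factors $B_i = \tfrac{8\pi^2}{3}\langle (\Delta R_i)^2 \rangle$,
* the mean-square fluctuation of the internal distance (MSFID)
  $\langle (\Delta R_{ij})^2 \rangle = \tfrac{3 k_BT}{\gamma}
  \left([\Gamma^{-1}]_{ii} + [\Gamma^{-1}]_{jj} - 2[\Gamma^{-1}]_{ji}\right)$.

$\Gamma$ is singular; its pseudoinverse is taken over the non-zero
eigenmodes of `decompose()`. MSF measures the *mobility* of a residue,
MSFID the *flexibility* of a residue pairing: a pair with large distance
fluctuation is loosely coupled regardless of how mobile each partner is.
Up to the spring constant, MSFID per $3k_BT/\gamma$ is exactly the
effective resistance between the two nodes when each contact is a unit
resistor — a fact the test suite exploits for hand-computable instances.

The model's central assumption is that the native structure sits at the
energy minimum and only native contacts matter. That makes it
inappropriate for misfolded or non-native states, and everything below
inherits that limitation.

### Prefactor conventions

MSF and cross-correlations carry the prefactor $k_BT/\gamma$; MSFID
carries $3k_BT/\gamma$, the isotropic-space convention for a
vector-distance fluctuation. The package works in units where
$k_BT = 1$, so temperature and spring constant enter every statistic
only through $\gamma$ (in $k_BT/\text{Å}^2$). Every rank-based result —
mode shapes, flexibility orderings, the unfolding sequence and its
jumps — is invariant to both prefactors; only absolute scales (B-factors
in Å²) depend on them.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cutoff_rc` | 7.3 Å | contact distance (inclusive boundary) for $\Gamma$ |
| `gamma` | fitted | uniform spring constant, $k_BT/\text{Å}^2$ |
| `k_slowest` | 6 | slow modes kept for the collective-mobility profile |
| `zero_tolerance` | $10^{-9}\lambda_{max}$ | relative eigenvalue threshold flagging rigid-body (zero) modes |
| `min_jump_size` | 20 | contacts breaking at one temperature to count as a cooperative jump |
| `T0_kelvin` | 300 K | physical temperature assigned to the first rupture |

$\gamma$ is fitted by `fit_gamma()`, by default so the *mean* theoretical
B-factor matches the mean experimental one; "normalizing" does not pin
down an estimator, so a least-squares scale is available as
`method = "lsq"`. The Pearson correlation between the two series is
scale-free and reported alongside. The relative zero-mode threshold is
chosen to stay robust on the progressively fragmenting networks the
unfolding simulator produces, where zero modes multiply as components
split off.

The six-slowest-mode restriction applies to the mobility profile only;
MSFID maps and the unfolding engine use all non-zero modes, since the
distance-fluctuation formula is stated for the full pseudoinverse.

## The iterative unfolding simulator

`unfold()` mimics slow heating: contacts are expected to break in a
fluctuation-dependent manner, so at each step the engine

1. eigen-solves the current $\Gamma$,
2. computes MSFID for every live breakable contact over all non-zero
   modes,
3. ruptures the contact with the largest MSFID, and
4. rebuilds $\Gamma$ and repeats until no breakable contact remains.

Re-solving after every rupture is what captures nonlinear softening: as
a domain loses contacts its remaining pairs fluctuate more, which
accelerates its collapse. Backbone-adjacent pairs (consecutive sites of
one chain) model covalent links: they stay in $\Gamma$ permanently and
are never rupture candidates, so chains cannot disperse. Ties in the
maximal MSFID (within a relative $10^{-9}$) are broken by the
lexicographically smallest pair — symmetric synthetic networks do
produce exact degeneracies and a deterministic rule keeps trajectories
replayable bit for bit. There is no randomness anywhere in the engine.

### Reduced temperatures — a reconstruction

The temperature axis is derived, not simulated. A contact is assumed to
break when its distance fluctuation reaches a fixed critical value;
MSFID is linear in $T$, so the breaking temperature of the $k$-th
ruptured pair is inversely proportional to its per-$k_BT$ fluctuation:
$T_k/T_0 = m_1/m_k$, normalized to the first rupture. The reported
curve is the running maximum of this raw sequence: whenever a rupture
*raises* the next maximal MSFID above the current record, the following
events happen below the running maximum and are read as a cooperative
cascade at constant temperature. Maximal runs of at least
`min_jump_size` events at one reported temperature are the jumps
`detect_jumps()` returns. This mapping is a reconstruction adopted by
this package; alternative monotonizations would shift melt temperatures
but not the rupture order, which depends only on the greedy rule.

`melting_summary()` assigns each annotated domain the temperature of the
jump that ruptures the plurality of its internal contacts (not the first
or last rupture — the cooperative transition is the melting event), in
Kelvin via `T0_kelvin`, and orders domains by the median rupture step of
their internal contacts. A domain whose contacts all break outside any
jump falls back to the reported temperature at its median rupture step.

## What the synthetic generators emulate

All tests and the acceptance script run on generated structures with
planted ground truth:

* `make_linear_chain()` — collinear chains whose Kirchhoff spectrum has
  the closed form $\lambda_k = 4\sin^2(k\pi/2N)$; the analytic oracle.
* `make_two_domain_network()` — two compact lattice-snake globules
  bridged by an extended linker. The weak domain is dilated about its
  centroid until only the requested fraction of its internal
  non-adjacent contacts survives, so the 7.3 Å rule remains the single
  source of topology; seeded jitter differentiates realizations. The
  planted prediction is that the weak domain's internal contacts finish
  rupturing first.
* `make_beta_sandwich()` / `make_synthetic_fab()` — idealized stacked
  four-strand sheets (4.8 Å rise, 5.0 Å inter-strand — fixture choices,
  not measurements) assembled into a two-chain, four-domain Fab-like
  structure whose constant-like domains are dilated by a small factor,
  planting the looser packing that real Fab constant domains show.
* `make_pseudo_experimental_bfactors()` — model B-factors at a known
  $\gamma$ plus seeded Gaussian noise scaled to the mean B-factor,
  clipped at a small positive floor.

Every generator is a pure function of its arguments including the seed
(RNG state is saved and restored), so fixtures are bit-reproducible.

These generators emulate contact topology, packing-density contrasts and
noisy observables. They do **not** emulate real side-chain packing,
hydrogen bonding, sequence effects, disulfides, or crystallographic
artifacts (lattice contacts, TLS refinement) that shape real B-factor
columns. Passing tests therefore demonstrate that the machinery is
correct and that planted topological signal is recovered — not that any
particular real protein will show a given correlation or melt
temperature.

## Numerical choices

* Eigenvalues ascend; each eigenvector's first entry above $10^{-8}$ in
  magnitude is made positive, so decompositions are reproducible across
  platforms.
* The mode-space pseudoinverse is symmetrized, making MSFID exactly
  symmetric and the clipped negatives (order machine epsilon) harmless.
* MSFID between sites in different connected components is reported as
  `Inf`: they share no modes and their relative fluctuation is
  unbounded. Such pairs are never rupture candidates (they hold no
  contact by construction).
* Structures with fewer than two sites, subsets containing zero modes,
  non-positive experimental B-factor means and snapshot requests beyond
  the final contact count raise immediate, named errors or warnings.

## Problem sizes

The shipped analyses use a 250-site synthetic Fab (646 native contacts,
~400 breakable), 28–47-site two-domain benchmarks for the
planted-recovery studies (100 realizations), a ~150-site structure for
spring-constant recovery (200 noise draws), and chains up to $N = 50$
for the spectral closed form — sizes at which a full eigensolve per
rupture step is comfortable on a single core while preserving every
qualitative regime (multi-domain cooperativity, fragmentation, noise).

## Known limitations

* The temperature mapping is a model-internal reconstruction (above);
  absolute melt temperatures should be read as comparative, not
  calorimetric.
* A uniform spring constant ignores residue-specific interactions;
  computed melt temperatures on real proteins run high for this reason.
* The greedy, one-contact-per-step rupture is quasi-static: kinetics,
  refolding and non-native contacts are out of scope.
* Isotropic network theory yields magnitudes, not directions, of motion.
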