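---
title: "Spin-adapted CI, stochastic RDM sampling, and Heisenberg mapping with gugaci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spin-adapted CI, stochastic RDM sampling, and Heisenberg mapping with gugaci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gugaci)
```

## The problem

Magnetic clusters — iron–sulfur cubanes being the canonical example — have
many near-degenerate electronic states that differ in their *total spin*.
Getting their energetics, exchange couplings, and local spin structure right
requires solving the electronic Hamiltonian *within a fixed total-spin
sector*: a determinant-based expansion mixes spin sectors, converges slowly
when spin states are nearly degenerate, and contaminates spin-dependent
observables. `gugaci` is a desk-scale toolkit for this problem. It

1. builds spin-adapted many-electron bases (configuration state functions,
   CSFs) with the graphical unitary group approach (GUGA),
2. evaluates the spin-free Hamiltonian and arbitrary unitary-group
   generator operators over that basis,
3. solves sectors either exactly or with a stochastic FCIQMC projector,
4. samples unbiased spin-free one- and two-body reduced density matrices
   (RDMs) from two-replica walker dynamics,
5. computes local spin and spin–spin correlation observables from those
   RDMs, and
6. maps computed spin ladders onto bilinear/biquadratic Heisenberg models.

"Desk scale" is a design commitment, not an apology: every stochastic
estimate in this package can be checked against exact diagonalization on
the same sector, and the test suite does exactly that.

## The spin-adapted basis

A CSF is encoded by its *step vector* $d_k \in \{0, u, d, 2\}$ over spatial
orbitals: empty, singly occupied coupling the cumulative spin up by 1/2,
singly occupied coupling down by 1/2, or doubly occupied. A step vector is
valid when the cumulative spin $S_k$ never becomes negative and ends at the
sector's total spin. All CSFs of a sector $(n, N, S)$ form the paths of a
directed graph (the distinct row table, DRT) whose nodes are Paldus rows
$(a, b, c)$ with $b = 2S_k$; per-node path counts give an $O(n)$ bijection
between CSFs and lexicographic indices (ordering $0 < u < d < 2$, orbital 1
most significant — a convention, fixed and documented).

```{r basis}
space <- spin_space(6, 6, 0)     # 6 orbitals, 6 electrons, singlet
drt <- build_drt(space)
drt$dim                           # 175 = Weyl-Paldus count
head(enumerate_csfs(drt), 3)
```

Spin is stored internally as the integer $2S$, so half-integer bookkeeping
is exact. The basis takes the orbital order as given: localization or
site-ordering of orbitals is the caller's responsibility, and all
orbital-resolved observables are representation-dependent in exactly that
sense.

## Generators and Hamiltonians

The spin-free Hamiltonian is
$\hat H = \sum_{ij} t_{ij} \hat E_{ij} + \tfrac12 \sum_{ijkl} V_{ijkl}
\hat e_{ij,kl}$ with $\hat E_{ij} = \sum_\sigma
a^\dagger_{i\sigma} a_{j\sigma}$ and $\hat e_{ij,kl} = \hat E_{ij} \hat
E_{kl} - \delta_{jk} \hat E_{il}$; $V$ uses chemists' $(ij|kl)$ notation
with 8-fold symmetry, matching FCIDUMP practice.

Coupling coefficients $\langle \mu'|\hat E_{ij}|\mu\rangle$ between CSFs
depend only on the step values inside the orbital window $[i, j]$ and on
the cumulative spin entering it. `gugaci` exploits this locality directly:
the window is contracted in its determinant expansion with the entering
spin supplied by a ferromagnetic stack of spectator $u$-steps. Because
$\hat E_{ij}$ is an SU(2) scalar, this windowed evaluation is exact — the
genealogical coupling above the window commutes with the operator, and the
fermionic phases of fully paired electrons below it cancel. Two-body
operators are assembled from one-body matrix products per the defining
identity. The per-level segment-value product form is mathematically
equivalent; the windowed contraction was chosen because it is compact,
exact by construction, and validated wholesale against the sparse
generator matrices (the test suite compares the two routes on thousands of
random pairs, and checks the generator commutation relations and
$\hat S^2 = S(S+1)\,\mathbb 1$ — the defining property of spin adaptation —
to machine precision).

Everything downstream (exact CASCI, the FCIQMC engine, the RDM tables) is
built from these matrices. An independent determinant-basis oracle in the
test suite (its own bitstring operators, its own $S^2$ projector, no shared
code) confirms that CSF-sector spectra coincide with determinant-basis
spectra.

## The stochastic eigensolver

FCIQMC propagates walker weights $c_\mu$ in imaginary time,
$c(\tau + \Delta\tau) = [1 - \Delta\tau(\hat H - S)]\, c(\tau)$, with three
per-iteration steps:

* **Spawning** samples the off-diagonal part: each occupied parent makes
  $N_\text{att} = \lceil |c_\mu| \rceil$ attempts; a child $\nu$ drawn with
  probability $p_\text{gen}(\nu|\mu)$ receives weight $-\Delta\tau
  H_{\nu\mu} c_\mu / (N_\text{att}\, p_\text{gen})$ per attempt. The
  sampler uses the *exact-column* distribution $p_\text{gen} \propto
  |H_{\nu\mu}|$, which is the optimal importance function; at desk scale
  the Hamiltonian column is available, so the large-$n$ branching-tree
  walk over the Shavitt graph is not needed (stable dynamics require
  $\Delta\tau |H_{\nu\mu}| / p_\text{gen} \le 1$; violations are counted
  and reported as *blooms*, never silently ignored).
* **Death/cloning** applies the diagonal factor
  $1 - \Delta\tau (H_{\mu\mu} - S)$ deterministically.
* **Annihilation** sums signed spawned weights per CSF and applies a
  stochastic kill threshold $\kappa = 1$ (an entry with $|c| < \kappa$
  survives as $\pm\kappa$ with probability $|c|/\kappa$ — magnitude
  preserving in expectation, real walker weights).

The shift $S$ is the population control: after the walker number first
reaches its target (checked at shift-update boundaries), one undamped
correction from the interval-averaged growth puts $S$ near the ground
energy, and thereafter $S \leftarrow S - \frac{\zeta}{A\Delta\tau}
\ln\frac{N_w(\tau)}{N_w(\tau - A\Delta\tau)}$ with defaults $\zeta = 0.05$,
$A = 10$ iterations. The undamped entry correction matters: jumping on a
single iteration's growth is noisy enough to destabilize the population.

A *semistochastic* core — the $N_D$ lowest-diagonal CSFs — is propagated
exactly (its block matrix applied each iteration, spawning within the core
suppressed, core weights exempt from the kill threshold). With the core
equal to the full space the dynamics become exact power iteration with
zero stochastic variance, a limit the tests assert to round-off.

```{r fciqmc, eval = FALSE}
ints <- hubbard_model(6, t = 1, U = 4, topology = "ring")
run <- run_fciqmc(ints, spin_space(6, 6, 0),
                  n_iterations = 2000, dtau = 0.01, target_walkers = 500,
                  seeds = c(7, 11), rdm = TRUE, n_core = 20)
glance(run)
autoplot(run)
```

Defaults, with units: `dtau` (hartree$^{-1}$) must satisfy the stability
contract for the sector's spectral range; `target_walkers` sets the
statistical resolution (variance $\sim 1/N_w$); `burnin = 0.2` discards
the growth phase from every estimator and from RDM accumulation (the
sampling window must be an equilibrium window for unbiasedness);
`kill_threshold = 1`; the projected-energy reference is the
largest-weight CSF at the end of burn-in, fixed thereafter (the estimator
bias depends on this choice, so it is pinned and recorded). Seeds are
explicit; identical configuration and seeds give bit-identical
trajectories.

## Two-replica RDM sampling

The spin-free RDMs $\gamma_{ij} = \langle \hat E_{ij} \rangle$ and
$\Gamma_{ij,kl} = \langle \hat e_{ij,kl} \rangle$ (no $\tfrac12$ prefactor;
the $\tfrac12$ lives in the energy contraction) are sampled from two
statistically independent replicas $A$ and $B$ with distinct seeded RNG
streams. Products $c^A_\mu c^B_\nu$ are unbiased where a single replica's
$c_\mu^2$ carries a strictly positive variance bias — the package ships a
diagnostic `single_replica_rdm` mode that exposes this bias, and the test
suite demonstrates it on an asymmetric two-orbital model.

Three accumulation channels partition the $(\mu, \nu)$ pairs exactly once:

* **Diagonal** ($\mu = \nu$), accumulated explicitly every iteration:
  $\gamma_{ii}$ from occupations, $\Gamma_{ii,kk}$ from occupation
  products, and the exchange diagonals $\Gamma_{ij,ji} =
  \langle\mu|\hat e_{ij,ji}|\mu\rangle$ from genuine coupling
  coefficients.
* **Stochastic off-diagonal**, harvested from the spawn stream: each spawn
  record carries the parent, its coefficient, the attempt count, and the
  generation probability of its route; the pair contributes
  $c^A_\mu c^B_\nu \langle\nu|\hat e_r|\mu\rangle / (N_\text{att}\,
  p(\text{route}))$ to every index route $r$ of the pair. With the
  exact-column sampler there is exactly one generation event per sampled
  child, so the recorded route probability is the child probability and
  all routes of the pair are credited together — the per-route-probability
  bookkeeping that prevents double counting in the general case
  degenerates gracefully. Exchange-type CSF pairs (identical occupations,
  different open-shell coupling) have multiple non-unique $(i,j)$ routes
  $\hat e_{ij,ji}$; each is credited with its own coefficient, which the
  tests verify route by route against the operator matrices.
* **Core-exact**: all ordered pairs of distinct core CSFs contribute
  deterministically each iteration (they never appear in the spawn
  stream, so nothing is counted twice — the full-core limit reproduces
  exact RDMs entrywise to $10^{-9}$ in the tests).

One subtlety is support: a pure $|H|$-proportional sampler never visits
pairs whose Hamiltonian element vanishes but whose generator coupling does
not, which would silently bias those $\Gamma$ entries. When RDM sampling is
enabled, the child distribution therefore mixes in a small floor
(`rdm_floor`, default 0.05, as a fraction of the column's maximum $|H|$)
over all generator-connected children. Spawned weights still divide by the
exact total $p_\text{gen}$, so the dynamics remain unbiased; the floor only
widens the sampled support.

Finalization normalizes by the accumulated replica overlap
$\sum_\tau \sum_\mu c^A_\mu c^B_\mu$ (so $\mathrm{tr}\,\gamma = N$ holds
*exactly*, not just in expectation), averages $\Gamma$ with its
$\hat e_{ij,kl} = \hat e_{kl,ij}$ and hermitian images, and reports the
invariant checks — trace, the partial trace
$\sum_k \Gamma_{ij,kk} = (N-1)\gamma_{ij}$, and $\langle \hat S^2\rangle$
against $S(S+1)$ — on the result object. Spin purity of sampled RDMs is
structural (every walker lives in the target sector), and the tests
confirm $\langle \hat S^2 \rangle = S(S+1)$ to $10^{-10}$ even on noisy
runs.

Implementation note: all pair contributions are precomputed once per
sector as sparse (pair $\times$ RDM-slot) tables built from the generator
matrices, so a whole iteration's off-diagonal accumulation reduces to a
scalar-factor update per sampled pair, and finalization to one sparse
cross-product. The route enumeration by step-vector analysis
(`identify_excitation()`) is kept as an independent cross-check of those
tables.

## Spin observables from RDMs

From the operator identities $\hat e_{pq,qp} = -\tfrac12 \hat e_{pp,qq} -
2\, \hat{\mathbf S}_p \cdot \hat{\mathbf S}_q$ (for $p \ne q$) and
$\hat{\mathbf S}_p^2 = \tfrac34 (\hat n_p - \hat e_{pp,pp})$:

$$\langle \hat{\mathbf S}_p \cdot \hat{\mathbf S}_q \rangle =
  -\tfrac12 \Gamma_{pq,qp} - \tfrac14 \Gamma_{pp,qq}, \qquad
  \langle \hat{\mathbf S}_p^2 \rangle = \tfrac34 (\gamma_{pp} -
  \Gamma_{pp,pp}).$$

`local_spin()` sums these over a fragment, `fragment_spin_sum()` over
unions of disjoint fragments, `correlation_profile()` returns the
orbital-resolved vector from a reference orbital. Closed-shell or empty
orbitals report zero (they carry no spin); two ferromagnetically coupled
singly occupied orbitals give $+1/4$; an open-shell singlet pair gives
$-3/4$; a fragment of five ferromagnetically coupled singly occupied
orbitals gives the maximal $\tfrac52 \cdot \tfrac72 = 8.75$. These formulas
were derived independently and are pinned by a determinant-basis operator
oracle in the tests (tolerance $10^{-9}$); any published variant of the
same identities must agree with that oracle or one of the two is wrong.

All of these are representation-dependent quantities — they depend on the
orbital basis. The tests fix the orbital basis explicitly, and users
comparing against localized-orbital results must do the same.

## Heisenberg mapping

For two spin centers $A, B$ the bilinear/biquadratic Heisenberg model
$\hat H = J\, \hat{\mathbf S}_A \cdot \hat{\mathbf S}_B + J' (\hat{\mathbf
S}_A \cdot \hat{\mathbf S}_B)^2$ has the ladder $E(S) = J x + J' x^2$ with
$x(S) = \tfrac12 [S(S+1) - S_A(S_A+1) - S_B(S_B+1)]$. The sign convention
is $J > 0$ antiferromagnetic (singlet ground state). This closed form is
*defined into* the package by an oracle test: `model_energies()` must
reproduce the exact two-site spectra of `heisenberg_exact()` for random
$(J, J', S_A, S_B)$ draws at $10^{-9}$, which protects against every
plausible sign or factor-of-two slip.

`fit_ladder()` performs ordinary least squares on spin *gaps* relative to
the lowest-$S$ state (removing the constant term, as one does when fitting
computed spin ladders), and reports the relative average error per state

$$\omega = \frac{100}{N_\text{states}} \sum_{S \ne S_\text{ref}}
  \frac{|E^C_S - E^M_S|}{\Delta E^C_\text{max}} \;\; [\%],$$

where $E^C$ are the computed gaps, $E^M$ the model gaps,
$\Delta E^C_\text{max}$ the computed lowest-to-highest-spin gap, and
$N_\text{states}$ the number of non-reference states. The number of states
entering $\omega$ is therefore whatever the supplied ladder contains — for
a two-center $S = 0 \ldots 5$ ladder that is five states; for a four-center
cluster the caller decides how many sectors to include simply by passing
them.

`complete_graph_ladder()` provides the equal-coupling closed form
$E(S) = \tfrac{J}{2} [S(S+1) - n\, s(s+1)]$ for $n$ equal spins $s$ on a
complete graph, cross-checked against exact diagonalization at reduced
site spin.

```{r fit}
lad <- model_energies(0:5, J = 1.44e-3)      # a synthetic bilinear ladder
fit <- fit_ladder(lad)
glance(fit)
```

Degenerate eigenmanifolds deserve a warning: for the antiferromagnetic
equal-coupling tetramer the whole $S = 0$ manifold is degenerate, so
individual eigenvectors returned by a diagonalizer are arbitrary within
it. The package's observables on such manifolds are only quoted where
they are provably constant on the manifold (as
$\langle(\hat{\mathbf S}_A + \hat{\mathbf S}_B + \hat{\mathbf S}_C)^2\rangle
= \langle(\hat{\mathbf S}_\text{tot} - \hat{\mathbf S}_D)^2\rangle$ is for
singlets), or on symmetry-resolved states built explicitly by
Clebsch–Gordan coupling (`pair_coupled_state()`).

## What the model builders emulate — and what they do not

The package's fixture generators stand in for ab initio integrals:

* `hubbard_model()` — chains/rings with hopping $-t$ and on-site $U$; the
  standard correlated-electron benchmark with closed-form limits (the
  dimer singlet at $U/2 - \sqrt{U^2/4 + 4t^2}$, the $4t^2/U$
  superexchange limit).
* `exchange_cluster_model()` — the magnetic-cluster regime in caricature:
  each center carries several orbitals with on-site $U$ and a
  ferromagnetic intra-center exchange $K$ (Hund coupling), adjacent
  centers couple through weak hopping. At half filling this produces
  exactly the physics the analysis chain targets: local high-spin centers
  ($\langle \hat{\mathbf S}_A^2 \rangle \to 2$ for a two-orbital center)
  antiferromagnetically coupled into a Heisenberg-like ladder.

What they deliberately do not contain: real molecular integrals, ligand
orbitals and charge-transfer physics, orbital relaxation (the CASSCF
step), scalar-relativistic effects. Passing tests therefore demonstrate
that the machinery — basis, operators, stochastic sampling, observables,
fitting — is correct on systems where exact answers exist; they do not by
themselves validate chemical conclusions about any particular cluster,
whose integrals the user must supply via FCIDUMP.

## Numerical choices and limitations

* Exact diagonalization is dense below 1500 basis states, then a Lanczos
  with full reorthogonalization; sectors beyond `max_dim` (default
  $2\times10^5$) are refused with a pointer to the stochastic engine.
* The test suite runs sectors up to $(6, 6, 0)$ (dimension 175) for
  stochastic physics, dimension counts up to $(10, 10, 0)$ (19404), and
  spin models up to the $6^4 = 1296$-dimensional spin-5/2 tetramer —
  sizes chosen so exact oracles stay cheap while every code path is
  exercised.
* The sampled-RDM energy is a ratio estimator; its $O(1/N_w)$ bias is far
  below the statistical error at the shipped defaults but is the expected
  first deviation if runs are pushed to very small populations.
* The RDM accumulation window opens only after burn-in; there is no
  automatic equilibration detection.
* Orbital indices are 1-based everywhere in user-facing structures and
  files (FCIDUMP convention).
* Serialization of DRTs, CSF lists, RDMs, trajectories, and fit reports
  is plain text (CSV/JSON) with documented layouts; `write_rdms()` /
  `read_rdms()` round-trip losslessly at double precision.
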