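---
title: "Statistical mechanics of protein folding with virtual linkers: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical mechanics of protein folding with virtual linkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsmel)
```

## The model and its assumptions

The WSME (Wako–Saitô–Muñoz–Eaton) family describes a protein as a chain of
Ising-like residues, $m_k \in \{0,1\}$ (native / unfolded), stabilized only
by native contacts, with a contact $(i,j)$ contributing its energy
$\varepsilon_{i,j}$ only when *every* intervening residue is native:
$H(\{m\}) = \sum_{i<j} \varepsilon_{i,j}\, m_{i,j}$ with
$m_{i,j} = \prod_{k=i}^{j} m_k$. Each native residue pays an entropic price
$S_i < 0$, and a free-energy landscape over the order parameter
$n = N^{-1}\sum_i m_i$ follows from the restricted partition function
$Z(n) = \mathrm{Tr}_n\, e^{-(H - T\sum_i S_i m_i)/k_BT}$.

Two assumptions define the family: (1) only native contacts stabilize; (2)
contacts require a continuous native stretch. Assumption (2) forbids a
discontinuous domain (say, the N- and C-terminal halves of a chain packing
together) from folding before the region between them — which is exactly what
multidomain proteins are observed to do. The linker extension relaxes (2)
minimally: for an eligible contact $(u,v)$, an ensemble component is added in
which residues connected *through the linker* also interact,

$$m^{(u,v)}_{i,j} = \Big(\prod_{\min(i,u) \le k \le \max(u,i)} m_k\Big)
                   \Big(\prod_{\min(v,j) \le k \le \max(j,v)} m_k\Big),$$

and a contact counts when it is connected through the main chain *or*
through the linker (the ceiling of the averaged indicator sum in the model's
Hamiltonians is exactly this logical OR; the package asserts the equivalence
exhaustively in its tests). The component pays a ring-closure entropy and
gains the linker contact energy; the full partition function is the ensemble

$$Z_L(n) = Z(n) + \sum_{(u,v)} \big[Z^{(u,v)}(n) - Z(n)\big]
           \exp\!\big(S'^{(u,v)}(n)/k_B\big).$$

Model variants differ only in their inputs: the **uniform-contact** model
($e_{i,j} = -1$ inside a 4 Å heavy-atom cutoff), the **weighted** model
($e_{i,j}$ from a normalized residue-pair energy matrix), the full **linker
ensemble**, the **oxidative-disulfide** variant (−40 kcal/mol added to the
raw energy of each Cys–Cys pair, so the disulfide enters the linker ensemble
as an overwhelmingly favourable linker), and the **disulfide-intact** variant
(each disulfide is a *mandatory* linker with no entropy penalty; its five
surrounding contact weights are removed from the Hamiltonian because the
covalent bond, not the contact energy, holds the ring closed).

## Parameters, units, defaults

| parameter | meaning | unit | default |
|---|---|---|---|
| $\varepsilon$ | global contact-energy scale | kcal/mol per unit weight | 1 (fit per protein) |
| $e_{i,j}$ | contact weight, $|e|\le 1$ after normalization | — | from map/table |
| $S_i$ | entropy cost of fixing residue $i$ | cal/(mol·K) | −2.0 / −2.5 / −3.5 by variant |
| $a$ | Cα–Cα virtual bond | Å | 3.8 |
| $A$ | persistence length | Å | 20 |
| $h_{S'}$ | ring-entropy scale | — | 1 (fit over 0.5–2.0) |
| linker threshold | raw-energy eligibility | kcal/mol | −0.6 (strictly below) |
| disulfide bonus | raw-energy increment | kcal/mol | −40 |
| $\eta$ scale | Φ perturbation, fraction of $|\varepsilon_{i,j}|$ | — | 0.1 |
| $A$ (1D kinetics) | attempt frequency | s⁻¹ | $10^7$ |
| $A_0$, $A(n)=A_0/(1+5n^2)$ | scheme prefactor with internal friction | s⁻¹ | $10^7$ |

All energies are kcal/mol, entropies cal/(mol·K), with the gas constant
$R = 1.987$ cal/(mol·K) as the per-mole Boltzmann constant — one constants
table (`wsme_constants()`) enforces the conventions.

The ring-closure entropy of a loop of $L$ virtual bonds whose ends sit $r$
apart is the Gaussian-chain form
$s'(L) = -\tfrac{3}{2} k_B [\ln L + (r^2-a^2)/(2AaL)]$, and the penalty at
order parameter $n$ is its hypergeometric average over how many of the
spanned residues are native. $r$ is taken as the native Cα–Cα distance of
the linker endpoints (implied but not stated by the source formulation;
recorded as a choice).

## Exact evaluation

`restricted_partition()` and friends evaluate the generating-function product
of stretch transfer matrices as a dynamic program over decompositions of the
chain into maximal native stretches. A stretch $i..j$ carries
$w_{i,j} = \exp[-(\sum_{i\le k<l\le j}\varepsilon_{k,l} -
T\sum_k S_k)/k_BT]\,\lambda^{j-i+1}$; the $\lambda$ bookkeeping is a dense
polynomial over integer native counts (an index pair for 2D landscapes), and
extracting coefficient $k$ yields $Z(k/N)$ exactly. With a linker $(u,v)$ the
sum is organized around the stretch containing $v$; every stretch containing
$u$ is multiplied by the Boltzmann factor of *all* cross-contacts between the
two stretches, which is what the linker physically switches on. Two linkers
(the disulfide-intact case) enumerate the joint placement of both
$v$-stretches; a bridge shared by both linkers is counted once.

Numerical choices:

* **Log-domain arithmetic everywhere.** A single −40 kcal/mol disulfide gives
  Boltzmann factors of order $e^{68}$; chains of them overflow doubles.
  All polynomial coefficients are stored as log-magnitudes with log-sum-exp
  accumulation (C++), and the ensemble combinations — whose differences
  $Z^{(u,v)}-Z$ can be negative term-by-term — run in signed log arithmetic
  in R. A negative *resulting* bin is a hard error, never clamped: with
  physically sensible inputs it cannot occur, so it signals
  misconfiguration.
* **Bins are integer native counts.** $n = k/N$ exists only at the
  presentation layer; no floating-point order-parameter comparisons occur.
* **Oracle equivalence is the binding contract.** A brute-force $2^N$
  enumeration (pure R, deliberately primitive, guarded at $N \le 22$)
  defines the microstate semantics; the test suite holds the transfer-matrix
  route to relative $10^{-9}$ against it over randomized instances with 0–2
  linkers, 1D and 2D axes, disulfide bonuses and Φ perturbations
  (observed agreement is ~$10^{-14}$).
* $s'(L)$ **clamp.** The penalty average can request $s'(0)$ (all spanned
  residues native), where $\ln L$ diverges; the argument is clamped to
  $L = 1$ — one virtual bond is the physical minimum loop, and the clamp is
  continuous with the $L=1$ case.
* **The linker gain $\varepsilon'^{(u,v)}$ is a state-independent constant**
  in the exponent of the linked component, exactly as the model defines it —
  including in the all-unfolded bin. The $Z^{(u,v)}-Z$ subtraction largely
  compensates, but the all-unfolded bin of $Z_L$ is *not* exactly 1 once
  linkers carry energy; the free-energy gauge (F = 0 at the unfolded bin) is
  applied after the fact. For strongly boosted disulfide linkers this
  convention makes the unfolded bin itself disulfide-bonded — which is the
  correct physics for oxidative folding, where the bond can pre-form in the
  unfolded state.
* **Perturbation masking.** Read literally, the source perturbation
  equations leave $\eta$ unmasked inside the linked Hamiltonian *and* add
  the masked-neighbourhood $\eta$ again as the constant
  $\Delta\varepsilon'$, double-counting $\eta$ at the linker pairs; that
  breaks the first-order identity between $\Phi^{SS}$ and contact occupancy.
  The package masks $\eta$ exactly as $\varepsilon$ is masked, with
  $\Delta\varepsilon'$ (the sum of $\eta$ over the five masked pairs, which
  reproduces every printed case of the source's case analysis including
  boundaries) carrying those terms once. Both evaluation routes share the
  convention.

## Landscapes, pathways, Φ values

`free_energy()` gauges $F = -k_BT\ln Z$ to zero at the all-unfolded bin;
zero bins become $+\infty$ with a warning. Basins are local minima (strict,
4-neighbourhood in 2D); saddles are minimax points over 4-connected paths,
found by flooding the landscape in order of increasing $F$ and recording the
first cell where two catchments merge — a reproducible, oracle-checkable
stand-in for pathways that the source only draws. The **dominant pathway**
is the unfolded→native staircase (each step adds one native residue, so
$n_\mathrm{pathway} = (k_1+k_2)/N$ never decreases) minimizing the maximum
$F$; ties break by lower path integral of $F$, then toward the axis-1 step.
The monotone restriction matches how cross-sections along a folding pathway
are conventionally plotted; both the staircase DP and the saddle flooding
are verified against exhaustive path enumeration on small grids.

Φ values perturb all attractive contacts of one residue at once by
$\eta_{i,j} = 0.1|\varepsilon_{i,j}|$ (repulsive contacts untouched) and
normalize the free-energy response along the pathway so that
$\Phi_{th}(0) = 0$ and $\Phi_{th}(1) = 1$ exactly — the package asserts the
endpoints to $10^{-9}$ before clamping negatives to zero. A residue with no
attractive contacts has no defined response: it is reported **missing**
(`NA`), not zero, because zero would be a biological claim the computation
cannot support. $\Phi^{SS}$ perturbs a single Cys–Cys contact and is, to
first order in $\eta$, the thermal probability that the contact is formed
in the linker ensemble (where "formed" includes formation through the
linker); the suite checks that the discrepancy is $O(\eta)$ and halves when
$\eta$ is halved.

## Kinetics and thermodynamics

The 1D master equation uses hopping rates
$k_{n\to n\pm 1/N} = A\,e^{-(F(n\pm 1/N)-F(n))/2k_BT}$ on the landscape
grid; the macroscopic folding rate is the smallest nonzero eigenvalue
magnitude of the generator, computed on the detailed-balance-symmetrized
matrix (same spectrum, symmetric eigenproblem). The stationary distribution
is $\propto e^{-F/k_BT}$ to $10^{-8}$ by construction — asserted, not
assumed. Stability is the difference of basin minima (lowest-$n$ basin =
unfolded, highest-$n$ = native); a single-basin landscape has no two-state
stability and errors rather than guessing.

The named four-state scheme (U, I₁, I₂, N with U↔I₁, I₁↔I₂, I₁↔N, I₂↔N)
reads its barriers from the 2D landscape's minimax saddles
($\Delta F^\ddagger$ = saddle minus source-basin minimum — the source states
the dependence but not the discretization, so the minimax saddle is this
package's reproducible choice, as is using the saddle's
$n_\mathrm{pathway}$ in the internal-friction prefactor $A(n^\ddagger)$).
Populations come from the eigendecomposition of the generator (Runge–Kutta
fallback for defective generators, logged); the irreversible five-state form
splits the native state by pathway of arrival and its terminal split is
validated against a $10^6$-molecule jump-chain simulation. Domain-level
structure formation over time is the population-weighted sum of per-state
domain-averaged Φ values.

Heat capacity is $C(T) = \frac{d}{dT}(k_BT^2\, d\ln Z/dT)$, evaluated as
$k_B(2T\,[\ln Z]' + T^2[\ln Z]'')$ with second-order central differences on
a uniform grid — interior points only, so a 5-point grid yields 3 values;
the default step is 1 K. The temperature-dependent contact scale
$\varepsilon(T) = \varepsilon_f + p(1-T/T_f) - q[(1-T/T_f) +
(T/T_f)\ln(T/T_f)]$ satisfies $\varepsilon(T_f) = \varepsilon_f$ identically.
The bundled example constants for a lysozyme-like system
(`lysozyme_example_constants()`: $\varepsilon_f = 1.783$, $p = -0.307$,
$q = 11.3$, $T_f = 293$ K, $T_m = 350$ K, baseline 8 kcal/(mol·K), the four
disulfide pairs and the α/β domain residue sets) are shipped as documented
inputs, never hard-coded into any computation.

Parameter fitting scans $h_{S'}$ over 0.5–2.0 in steps of 0.1 and, for each
value, minimizes over $\varepsilon$ the squared mismatch of
$\Delta G_{NU}/k_BT$ (plus $\ln^2(k_f/k_f^{exp})$ when a rate target exists)
by bracketed scalar search (tolerance $10^{-4}$, coarse pre-scan to verify
the bracket). The full per-grid-point table is returned: selecting among
near-minimal pairs by Φ correlation requires experimental data and is the
caller's decision.

## What the synthetic fixtures emulate — and what they do not

`make_toy_model()` generates Cα-only chains on lattice-like paths whose
geometry is consistent with the designed contacts: a **hairpin** (ladder of
cross-strand contacts), a **discontinuous domain** (terminal blocks in
contact across an inert middle block — the headline scenario: the test suite
asserts that the blocks-folded/middle-unfolded basin is > 1 k_BT more stable
with linkers than without), and a seeded **compact** self-avoiding walk
(clustered contacts; the two-state instances used for parameter recovery).
Raw energies are uniform in [−3, −0.5] kcal/mol — the range where some pairs
clear the −0.6 linker threshold and none dominates, which is what
force-field-derived residue-pair energies look like after removing
neighbours.

The fixtures deliberately do **not** emulate: realistic secondary-structure
contact statistics, sequence-dependent entropy costs, many-contact dense
maps of real proteins (fixture N ≤ 30), or force-field energetics. A green
suite therefore establishes that the *mathematics* — partition functions,
ensembles, landscapes, kinetics — is implemented exactly and
self-consistently; it does not establish predictive accuracy for any real
protein, which depends on user-supplied energies and the fitted
$(\varepsilon, h_{S'})$.

## Known limitations

* More than two simultaneous linkers are served only by the enumeration
  oracle ($N \le 22$); the transfer-matrix route stops at two, which covers
  the disulfide-intact ensemble (one virtual + one mandatory linker per
  term). Multi-linker transfer matrices add substantial complexity for
  little benefit — the per-disulfide ensemble is the practical formulation.
* The linked transfer-matrix evaluation recomputes modified prefixes per
  stretch placement; it is polynomial in $N$ and instant at fixture scale,
  but hundreds of residues with hundreds of linkers (a real multidomain
  protein) would want the memoization of unchanged stretch weights across
  placements, plus parallelism over linkers.
* Only single chains; no non-native contacts (so no off-pathway
  misfolding); disulfides are native-pair only; experimental-Φ curation is
  out of scope.
* `fit_parameters()` recovers parameters cleanly on two-state synthetic
  targets; on landscapes without two basins the stability target is
  undefined, and the function reports the failure rather than substituting
  a different observable.
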