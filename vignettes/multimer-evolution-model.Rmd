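---
title: "A statistical-physics model of multimer and fibril evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A statistical-physics model of multimer and fibril evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multimerevo)
```

## The model

Most cellular proteins function as parts of multimeric complexes. Two copies
of the same protein can bind head-to-head through an *isologous* interface,
giving closed dimers, or head-to-tail through a *heterologous* interface,
which is open-ended and can grow into fibrils of unbounded length. This
package implements a minimal model of that competition and couples it to a
population-genetics description of how the interface sequences evolve.

A protein carries two opposing binding surfaces, A and B, each a 4x4 array
of amino acids (32 surface residues in total; nonsurface residues play no
role). When two faces meet, 16 pairwise amino-acid contacts form, and the
interface energy is the sum of their contact energies taken from a 20x20
statistical potential in kT units (the packaged default is the
Betancourt-Thirumalai transform of the Miyazawa-Jernigan contact energies,
whose threonine-referenced entries take both signs; its grand mean is
slightly negative). Four relative rotations of the two faces are possible,
and the interface energy $E_{AA}$, $E_{BB}$ or $E_{AB}$ is the **minimum**
over the four rotations. Faces are labelled canonically so that
$E_{AA} \le E_{BB}$.

The minimum-over-rotations rule carries real physics: in an isologous
interface every off-diagonal contact pair occurs twice, so the fixed-rotation
energy distribution has twice the variance of a heterologous interface, and
its minimum over four rotations therefore reaches lower. This is why
$\langle E_{AA}\rangle < \langle E_{AB}\rangle < \langle E_{BB}\rangle$ even
for purely random sequences.

### Aggregation equilibrium

Each interface type contributes a statistical weight
$a_{ij} = e^{-\beta E_{ij}}/\omega$, where $\omega$ is the number of
orientational configurations of one subunit relative to its neighbour
($\omega = 24$ for a cubic object on a cubic lattice). Linear aggregates are
generated by the 2x2 transfer matrix over the exposed-face state of a
growing chain, with eigenvalues
$\lambda_\pm = a_{AB} \pm \sqrt{a_{AA}a_{BB}}$ and amplitudes
$A_\pm = (a_{AA} + a_{BB} \pm 2\sqrt{a_{AA}a_{BB}})/(4\sqrt{a_{AA}a_{BB}})$.
The equilibrium concentration of $n$-chains is
$C_n/c_0 = (c/c_0)^n\,(A_+\lambda_+^{\,n-1} - A_-\lambda_-^{\,n-1})$, and the
free monomer concentration $c$ solves the mass balance
$$\frac{\phi}{c_0} = \frac{A_+\,c/c_0}{(1-\lambda_+ c/c_0)^2}
                   - \frac{A_-\,c/c_0}{(1-\lambda_- c/c_0)^2},$$
which has exactly one root in $0 < c < \min(\phi,\, c_0/\lambda_+)$ because
the right-hand side is monotone increasing there. The phenotype of a
sequence at concentration $\phi$ is the partition of subunits into monomers
($P_1$), dimers ($P_2$, with the closed-AA-dimer part
$P_2^\ast = P_2\, a_{AA}/(a_{AA}+a_{BB}+2a_{AB})$), fibrils
($P_{fib} = 1 - P_1 - P_2$, all aggregates of three or more) and oriented
fibrils ($P_{ori}$, fibrils whose interfaces are all heterologous).

### Evolution

Sequences evolve under strong-selection weak-mutation (SSWM) dynamics: at
most one mutation segregates at a time, and the stationary frequency of a
sequence is its mutational frequency reweighted by $e^{2N_e s}$. Mutation
replaces residue $i$ by $j$ at rate $u\pi_j$ (uniform $\pi_j = 0.05$ by
default). Fitness is $w = 1 + s$ with $s$ a function of the phenotype at
the fitness concentration: $s = 0$ (neutral), $\sigma P_2^\ast$ (dimer
selection), $\pm\sigma P_{fib}$ (selection for/against fibrils) or
$\sigma P_{ori}$ (oriented fibrils). A Metropolis chain samples this
distribution: each generation replicates the whole sequence with per-site
mutation, accepts the descendant with probability
$\min(1, e^{2N_e\sigma\,\Delta\text{score}})$, and on rejection records a
second copy of the parent. Only the product $N_e\sigma$ matters, so it is
the user-facing knob.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `phi` | 0.01 M | total subunit concentration; 0.01 M is typical of the most abundant cellular enzymes, for which aggregation matters most |
| `omega` | 24 | rotational-entropy penalty per interface; smaller values mean more aggregation at a given concentration |
| `c0` | 1 M | reference concentration fixing the concentration units |
| `u` | 0.05 | per-site proposal rate; affects only mixing speed, not stationary frequencies |
| `Ne_sigma` | 25 | compound selection strength $N_e\sigma$ |
| `generations`, `burn_in` | 300000, 5000 | chain length and equilibration prefix |

Energies are consumed in kT units throughout, so `beta` is numerically 1 and
kept only for clarity.

## Numerical choices

* The monomer solve is a 200-step bisection on the bracketing interval
  $(0, \min(\phi, c_0/\lambda_+))$, run in compiled code; the interval
  shrinks below double resolution, so the root is exact to machine precision
  and the residual mass balance is far below the 1e-9 documented tolerance.
* $P_{fib}$ is the exact complement $1 - P_1 - P_2$, never a truncated sum.
* The oriented-fibril tail $\sum_{n\ge3} n x^n$ with $x = a_{AB}c/c_0 < 1$
  is evaluated as $x^3(3-2x)/(1-x)^2$, an exact rearrangement that avoids
  the catastrophic cancellation of the naive
  $x/(1-x)^2 - x - 2x^2$ form at small $x$.
* Relabelling ties ($E_{AA} = E_{BB}$ exactly, which happens with a
  two-decimal potential) keep the input face order. Tied sequences are the
  one place where surface statistics are not invariant to the order in
  which the two faces are written.
* The contact pairing used for the four rotations is the mirror map
  $(r,c)\mapsto(5-r,c)$ at 0 degrees, $(c,r)$ at 90, $(r,5-c)$ at 180 and
  $(5-c,5-r)$ at 270. Each map is an involution, as physical face-to-face
  contact requires; 0/180 have no fixed points, 90 fixes the main diagonal
  (positions 1, 6, 11, 16) and 270 the anti-diagonal. The anti-diagonal
  choice at 270 is the unique one consistent with mirror contact geometry,
  although any four-fixed-point alternative would only relabel positions.
* The Metropolis chain runs in compiled code on R's seeded RNG stream with
  a documented draw order (32 site uniforms, a residue draw per mutating
  site, then an acceptance uniform only when the fitness exponent is
  negative), so `metropolis_step()` in R replays a compiled chain
  bit-for-bit — the test suite uses this as a cross-validation of the two
  implementations.

## What the generator emulates, and what it does not

The neutral ensemble (`random_sequence_sample()`) is i.i.d. by construction,
which is exactly the SSWM neutral stationary distribution — a neutral chain
is just a slower way of sampling it. The packaged study conditions are those
of the aggregation analyses this model was built for: $\phi = 0.01$ M,
$\omega = 24$, uniform $\pi$, $N_e\sigma = 25$, chains of $3\times10^5$
generations with $5\times10^3$ discarded. Propensity analyses here default
to $10^6$ neutral sequences, which leaves the sampling error of the
per-amino-acid frequencies (320 residues per face per $10^3$ sequences) far
below the effects being measured; correlations move by well under 0.01
between $10^5$ and $10^6$ sequences.

Passing tests on this model say nothing about real 3-D interface geometry:
there is no structure, solvent, charge screening, or atomic detail, surfaces
are flat 4x4 lattices, and contact energies are a knowledge-based potential
derived from globular protein cores. The model's value is that its
*relative* amino-acid propensities (S_int, S_iso) correlate strongly with
propensity scales measured on real structures, and those scales enter only
as optional user-supplied tables, never as fitted inputs.

## Known limitations

* Phenotypes are equilibrium quantities; there is no nucleation or growth
  kinetics.
* The SSWM approximation ignores clonal interference; no explicit
  population is simulated.
* Mutation acts on amino acids directly, with no codon structure.
* $\langle P_{ori}\rangle$ under plain fibril selection mixes slowly: the
  fitness is indifferent between oriented and alternating fibrils, so the
  chain drifts between the two fibril architectures and this observable
  carries the largest chain-to-chain variability of the reported summaries.
  The full 3e5-generation default is deliberate for this quantity.

## A worked session

```{r example, eval = FALSE}
library(multimerevo)
params <- physical_params(phi = 0.01, omega = 24)

# a fibril-forming energy triple
ph <- phenotype(interface_energies(-9.08, -8.67, -5.68), params)
ph$P_fib # ~0.60

# neutral ensemble means
enc <- random_sequence_sample(50000, seed = 1)
pt <- phenotype_table(ensemble_interface_energies(enc), params)
colMeans(pt[, c("P2_star", "P_fib")]) # ~0.042, ~0.0035

# selection for dimers
ch <- run_mcmc(selection_scheme("dimer", Ne_sigma = 25), seed = 1)
chain_summary(ch)

# interface propensities vs matrix predictors
si <- s_int(surface_frequencies(random_sequence_sample(1e6, seed = 2)))
pearson_with_pvalue(si, matrix_predictors()$B_ave) # r ~ -0.97
```
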