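---
title: "Descriptor-based screening of molecular composites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor-based screening of molecular composites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdftscreen)
```

## The problem

When two bioactive molecules are joined into a non-covalent composite -
here an isoflavone (genistein) and a tropane alkaloid (L-hyoscyamine),
candidates for a combined functional-food additive - many plausible binding
poses exist, and only a few are worth carrying into synthesis and in vitro
work. cdftscreen implements the desk-scale screening layer that sits on top
of quantum-chemistry output: it consumes *summaries* of electronic-structure
calculations (state energies, orbital energies, atomic charges,
thermochemistry blocks) and molecular structures (SMILES), computes the
standard conceptual-DFT and rule-based ADME descriptors, and ranks candidate
poses by configurable multi-criteria screening. It never runs quantum
chemistry itself; the contract is the documented QM-summary schema
(`?read_qm_summary`).

## Models and conventions

### Global reactivity indices

Vertical ionization potential and electron affinity come from total
energies of the ionic states at the neutral geometry,

$$\mathrm{IP} = E(N{-}1) - E(N), \qquad \mathrm{EA} = E(N) - E(N{+}1),$$

not from Koopmans-theorem orbital energies (orbital relaxation is not
negligible at this scale). From these, electronegativity
$\chi = (\mathrm{IP} + \mathrm{EA})/2$, chemical potential $\mu = -\chi$,
hardness $\eta$, softness $S = 1/\eta$, electrophilicity
$\omega = \chi^2 / 2\eta$ and nucleophilicity $\varepsilon = 1/\omega$.

Two hardness conventions circulate in the literature,
$\eta = \mathrm{IP} - \mathrm{EA}$ and the halved
$\eta = (\mathrm{IP} - \mathrm{EA})/2$. The package defaults to the
*difference* convention because it is the one under which the bundled
reference tables are internally consistent
(hyoscyamine: $7.93 - (-0.35) = 8.28$ eV, the printed value); the halved
variant is selectable via `convention = "halved"`. Negative electron
affinities (unbound anions) are legitimate inputs and are never clamped.
The reciprocal identities $S\eta = 1$ and $\omega\varepsilon = 1$ are exact
for computed values and are enforced by property tests at $10^{-12}$.

### Condensed Fukui functions and the dual descriptor

Per-atom reactivity uses charge differences across the $N{-}1$, $N$,
$N{+}1$ states at fixed geometry:

$$f_k^- = q_k(N{-}1) - q_k(N), \qquad f_k^+ = q_k(N) - q_k(N{+}1),
\qquad f_k^0 = \tfrac{1}{2}(f_k^- + f_k^+),$$

with the condensed dual descriptor $\mathrm{CDD} = f^+ - f^-$: positive
values mark nucleophilic-attack-prone sites, negative values
electrophilic-attack-prone sites. A caution on signs: sources frequently
state these formulas for electron *populations* $p = Z - q$ while printing
partial *charges*; the two conventions differ by a global sign. This
package's convention is the one stated above on charges - it is
algebraically identical to the population form (a test proves this with
explicit $Z$) and it reproduces every cell of the bundled reference tables
within 0.002 e.

Site flagging uses a threshold `tau` on the CDD, default 0.05 e. No
published threshold exists; 0.05 e is where the handful of chemically
discussed sites in the reference tables separates from the background of
3-decimal rounding noise (the strongest discussed sites have |CDD| of
0.059-0.173 e; the background sits below 0.045 e). Weaker sites of interest
(e.g. a secondary electrophilic carbon with CDD $-0.028$ e) fall below any
sensible threshold and are recovered by *ranking* (`top_sites()`) rather
than flagging; this mirrors how such tables are read in practice.

### Composite energetics and thermochemistry

Binding energy is the fragment decomposition
$\mathrm{BE} = E_\mathrm{complex} - \sum E_\mathrm{fragments}$ over
neutral-state totals. Every record carries a mandatory theory-level tag and
binding-energy operations refuse to mix tags: a BE formed from energies at
different levels is the single most tempting wrong number this kind of
data offers (the bundled dataset exists at two levels precisely because
its parents were re-optimized at the composites' level).

The thermochemistry block carries ZPE, H, G, Cv and S as printed by
quantum-chemistry codes. `entropy_from_hg()` recomputes
$S = (H - G)/T$ as a consistency check; at the default
$T = 298.15\,$K the six bundled poses agree with their printed entropies
to better than 0.1 cal mol$^{-1}$ K$^{-1}$, which is also what validates
the temperature choice (the source states no temperature; the H/G/S triple
is only consistent near standard conditions). Negative recomputed
entropies warn rather than error, keeping the checker usable on arbitrary
data. All energies are stored in eV; the single constants table
`unit_constants` (CODATA hartree, thermochemical calorie) is the only
conversion source.

Pose contacts are classified geometrically: H...O/N contacts at or below
2.5 angstrom count as hydrogen bonds, anything at or below 3.6 angstrom as
van der Waals, else none. These are conventional geometric criteria for
moderate hydrogen bonds and van der Waals separations; under them the four
bundled poses with short H...O contacts (1.67-1.77 angstrom) classify as
hydrogen-bonded and the two long C...O contacts (3.15, 3.23 angstrom) do
not, consistent with the source's isosurface analysis. Both cutoffs are
arguments, not constants.

### Rule-based ADME layer

The ADME layer computes only what published deterministic rules define:
Ertl fragment-additive TPSA (the N/O contribution set, embedded as a
SMARTS-to-contribution table in `ertl_tpsa_table()`), Wildman-Crippen
atomic logP, Lipinski and Veber filters, and the Martin bioavailability
rule table (anions by TPSA bands 0.85/0.56/0.11; everything else 0.55 with
at most one Lipinski violation, 0.17 otherwise). SMILES parsing, SMARTS
matching and the Crippen logP evaluation are delegated to Open Babel via
ChemmineOB; the TPSA typing itself is this package's, and the test suite
cross-checks it against Open Babel's independent Ertl implementation on a
mixed panel (exact agreement, including fused heteroaromatics).

Two deliberate restrictions. First, the S/P extension of the TPSA table is
omitted - no molecule in scope contains them - and polar S/P atoms raise an
unsupported-fragment error rather than silently contributing zero. Second,
machine-learned or consensus endpoints (P-glycoprotein substrate calls, GI
absorption class, solubility class, consensus logP, synthetic
accessibility) are consumed as supplied flags (`adme_flags()`) and labelled
as such in the profile's provenance field; the package never imitates
them. A representational caveat inherited from all fragment schemes:
charge-separated drawings (e.g. nitro as N$^+$-O$^-$) are typed as drawn,
so tautomer/resonance normalization is the caller's responsibility.

### Screening engine

Screening is hard filters, then min-max normalization per criterion (best
candidate 1, worst 0, direction applied; constant columns map to 0.5 for
everyone, keeping them weight-neutral), then a weighted total with weights
renormalized over the active criteria, a deterministic ranking (ties break
on ascending pose id), a Pareto front (dominance checked on the directed
raw values), and a top-k selection. Candidates are sorted by pose id before
anything happens, so reports are invariant to input order and
byte-identical across runs. Min-max normalization also makes the ranking
invariant under positive affine rescaling of any raw criterion column,
which the suite tests.

The default configuration (`default_criteria()`) encodes the reference
study's stated preferences - gap up, binding energy down, dipole up,
entropy down, heat capacity up, TPSA down, logP up - with weights
(0.20, 0.20, 0.10, 0.15, 0.05, 0.15, 0.15) *calibrated to reproduce that
study's two-winner verdict*. This is labelled honestly: the source selects
narratively, not algorithmically, and even argues both directions for the
dipole in different places (the engine exposes `dipole_direction` rather
than resolving that tension). The weights are a reusable default, not an
objective utility function.

## The synthetic-data generator

`gen_molecule()` builds records whose descriptors are known exactly by
construction: ion-state energies offset from the neutral total by the
target IP/EA; orbital energies separated by the target gap; neutral
charges as a zero-sum transformation of uniform noise; ion-state charges
offset by the target Fukui profiles, so the charge-difference convention
recovers them identically; and $G = H - TS$ built from the target entropy.
Defaults mirror the magnitudes of the reference parents (IP near 7.6 eV,
EA near 0.35 eV, gap 4.4 eV, 30 atoms, S near 235 cal mol$^{-1}$ K$^{-1}$).
A single integer seed drives every draw.

What the generator emulates is the *algebraic structure* the descriptors
consume - three-state energy triples, charge closure, thermodynamic
consistency, known binding energies assembled fragment-by-fragment - not
electron densities or geometries. Passing recovery tests therefore
demonstrates that the descriptor algebra is implemented correctly and is
stable under table-style rounding (`round_to_printed()`, half-away-from-zero);
it says nothing about the quality of any upstream quantum chemistry.
Recovery of IP/EA from synthetic records is asserted at $10^{-9}$ rather
than machine epsilon: the targets are differences of $\sim 10^4$ eV
totals, so cancellation leaves a few times $10^{-12}$ eV of noise.

## The bundled reference dataset

`reference_bundle()` ships the transcribed input and result tables of a
published screening of six genistein/L-hyoscyamine composite poses: parent
three-state energetics and 30/44-atom Hirshfeld charge tables at
APFD/6-311++G(d,p); parent and composite totals, orbitals, dipoles and
thermochemistry at B3LYP/6-31G; pose contact geometries; and the supplied
ADME panel. Printed derived values ride alongside so every derivation can
be checked against its published counterpart, which is what the acceptance
tests do: global indices within 0.01 eV, every Fukui cell within 0.002 e,
band gaps and binding energies to $10^{-6}$ eV, entropies to 0.1
cal mol$^{-1}$ K$^{-1}$, parent TPSA to 0.01 angstrom$^2$, and the
hard-filter / Pareto / top-2 outcome exactly.

Two transcription artifacts are preserved rather than corrected, and
documented: the parents' APFD totals are printed only to integer hartree,
so their ion-state energies are reconstructed from the printed vertical
IP/EA; and the published hyoscyamine anion-state charge column closes to
$-0.91$ instead of $-1$ (its printed $f^+$ column itself sums to 0.911), so
that record validates under a relaxed tolerance and the deviation is
asserted as a known value in the tests. One pose's pre-optimization contact
length (1.065 angstrom for a C...O contact) is chemically odd but
transcribed as printed.

## Worked example

```{r example, eval = FALSE}
bundle <- reference_bundle()

# global reactivity of the parents
global_indices_table(bundle$parents_apfd)

# local reactivity: flagged attack sites
ft <- fukui_table(bundle$parents_apfd$genistein, tau = 0.05)
flagged_sites(ft, "nucleophilic_site")   # atoms 3, 9, 12

# composite energetics and the screening verdict
en <- energetics_table(bundle$composites)
report <- screen(reference_candidates(bundle))
report$selected                          # "04" "02"
```

## Numerical choices, sizes, limitations

* Tolerances against printed values follow the table precision:
  $\pm 0.01$ for 2-decimal cells, $\pm 0.005$ for 3-decimal, $10^{-6}$ for
  full-precision energies (`tolerance_level()`); charge-sum closure allows
  $\pm 0.02$ for 30-44 atom tables of 3-decimal charges.
* Property suites run 50-seed synthetic batches and 50-candidate Pareto
  comparisons against a brute-force dominance oracle; these sizes exercise
  every code path in seconds and are plenty for exact-recovery checks,
  whose failure modes are not size-dependent.
* Serialization uses 17 significant digits, so summary files and reports
  round-trip doubles bit-exactly.
* Out of scope by design: running or parsing electronic-structure
  calculations (delegate Gaussian-log parsing to cclib or similar and feed
  the summary schema), 3-D geometry and grid analyses (electrostatic
  potential maps, reduced-density-gradient isosurfaces, QTAIM critical
  points), Hirshfeld charge computation (needs densities), and any
  machine-learned ADME endpoint.
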