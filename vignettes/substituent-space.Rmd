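---
title: "Mapping substituent space: extraction, properties and Craig-plot navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping substituent space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(substispace)
```

## The problem

Bioisosteric replacement — swapping a substituent for another of similar
size and physicochemical profile — is a routine move in lead optimization.
Doing it systematically requires (i) knowing which substituents actually
occur in bioactive molecules and how often, and (ii) placing them in a
property space where proximity means interchangeability. The classic such
space is the Craig plot: hydrophobicity (the Hansch–Fujita $\pi$ constant)
on one axis, electronics (the Hammett $\sigma$ constant) on the other.
Because experimental constants exist for only a fraction of the groups seen
in real corpora, both parameters must be estimated in silico.

`substispace` implements that pipeline end to end: rule-based substituent
extraction from SMILES corpora, $\pi$ and $\sigma$ estimation from a
substituted-benzene probe, root-atom/attachment classification, frequency
statistics, and query/selection utilities with Craig-plot export.

## Fragmentation model

A bond is *chemically activated* (breakable) when it is a single, acyclic,
non-aromatic bond between two heavy atoms and at least one of these holds:

* its endpoints differ in ring membership (ring–nonring bond);
* one endpoint is carbon, the other a heteroatom;
* either endpoint carries a double or triple bond to a third atom
  (carbonyls, nitriles, vinyls, sulfonyls, ...).

Aromatic bonds never count as "multiple" for the adjacency rule: attachment
to an aromatic ring is already captured by the ring–nonring rule, and a
bond linking two aromatic rings (biphenyl) is deliberately not cut. Bonds
between two heteroatoms (N–N, O–S, ...) are only cut under an optional
switch (`cut_hetero_hetero`), off by default, because the quoted rules do
not cover them.

Each breakable bond is cut one at a time; *both* fragments are candidate
substituents (this is what lets a chlorine atom report the halogen-side
attachment class), and a fragment is kept when it has at most 12 heavy
atoms (`max_heavy`). Every occurrence records the attachment context: the
atom on the other fragment, categorized as aliphatic C, aromatic c,
carbonyl carbon `C(=O)*` (which takes precedence over plain carbon),
nitrogen `N,n` (aromatic and aliphatic merged, mirroring the usual
presentation), O, S, halogen X, or other. Hydrogens are never extracted as
substituents — only heavy–heavy bonds are cut — but `[*][H]` is a legal
input to the property functions.

Aggregation distinguishes `molecule_frequency` (distinct molecules
containing the substituent — the sense in which a group is "present in 50
or more molecules") from `occurrence_count` (every cut counted, the
weighting used for classification tables). Fragment identity is canonical
SMILES of the attachment-marked fragment; canonicalization is delegated to
Open Babel, and one fixed aromaticity perception (Open Babel's) is used
throughout, since the aliphatic/aromatic split of the class grammar depends
on it.

```{r frag-example, eval = FALSE}
extract_substituents("CC(=O)c1ccccc1", "acetophenone")
#> four occurrences: methyl (attached to carbonyl carbon), acetyl
#> (attached to aromatic c), benzoyl (attached to aliphatic C) and phenyl
#> (attached to carbonyl carbon)
```

## Classification grammar

The level-1 class is the root atom (the substituent atom bonded to the
skeleton): `R-C`, `R-c`, `R-N`, `R-n`, `R-O`, `R-S`, with halogens pooled
as `R-X`; lowercase means aromatic. The level-2 class appends the root's
heavy neighbours with their bond annotation (`=O` carbonyl first, then
`-`/`=`/`#`/`:` bonds), neighbours ordered by the fixed precedence
C, c, N, n, O, S, X, and all but the last wrapped in parentheses:
`R-C(=O)-N`, `R-c(:c):c`, `R-N(-C)-C`. One conventional override renders
mixed aromatic shells heteroatom-first (`R-c(:n):c` for pyridin-2-yl), as
the class strings are conventionally printed. ASCII hyphens are used
throughout. A depth-3 renderer (`level2_class(x, depth = 3)`) expands one
further shell and yields chain patterns like `R-C-C-O`; depth 2 is the
default class key. Aromatic oxygen is merged into the `O` attachment
category (no separate "o" class is distinguished).

## Hydrophobicity: $\pi$

$\pi$ is defined against the benzene scaffold, matching both the probe
used for $\sigma$ and the aromatic context of the classic scale:

$$\pi(R) = \log P(\mathrm{C_6H_5R}) - \log P(\mathrm{C_6H_6})$$

with $\log P$ from the Wildman–Crippen atom-contribution scheme (Open
Babel's implementation). Two consequences are exact by construction:
$\pi(\mathrm{H}) = 0$, and every catalog $\pi$ equals the whole-molecule
logP difference of its probe — both are asserted as regression tests.
Atom-contribution logP is least reliable for strongly hydrogen-bonding
groups (sulfones, primary amides), which it systematically overestimates;
rank orders within a chemical family are much more trustworthy than
absolute values across families.

## Electronics: the $\sigma$-compatible descriptor

The electronic parameter is built from partial atomic charges of the same
mono-substituted benzene probe. The descriptor is

$$d(R) = \left[q(\mathrm{C}_{para}) + q(\mathrm{H}_{para})\right]_{\mathrm{C_6H_5R}}
       - \left[q(\mathrm{C}_{para}) + q(\mathrm{H}_{para})\right]_{\mathrm{C_6H_6}}$$

so $d(\mathrm{H}) = 0$ identically and electron-withdrawing groups give
$d > 0$. The para position is used because the $\sigma$-para scale has the
larger span (the nitro/dimethylamino gap is about 1.5 $\sigma$-para units
versus about 1.0 in $\sigma$-meta) and therefore separates substituents
better; $\sigma$-meta is out of scope.

The charge model has two coupled parts:

* **$\sigma$-framework**: partial equalization of orbital electronegativity
  (PEOE), the iterative Gasteiger–Marsili scheme with the published
  quadratic electronegativity coefficients per element/hybridization,
  damping $2^{-n}$ per sweep, a 200-sweep cap and a $10^{-6}$ convergence
  tolerance on the largest charge move (the damping makes convergence
  strictly geometric; non-convergence is an error, not a warning). Formal
  charges seed the iteration.
* **$\pi$-system**: simple Hückel theory with standard heteroatom
  parameters ($\alpha + h\beta$ Coulomb, $k\beta$ resonance integrals).
  One-electron centres are multiply bonded or pyridine-type aromatic atoms;
  two-electron centres are conjugated lone-pair donors, including
  pyrrole-type ring heteroatoms and halogens. Saturated carbons attached to
  the $\pi$ system enter as two-electron hyperconjugative pseudo-centres
  (the heteroatom model of the methyl group).

A pure equalization model cannot rank donors correctly: the dimethylamino
nitrogen is more electronegative than carbon, so on $\sigma$ charges alone
it *withdraws* density, while experimentally it is the strongest common
donor. Resonance must therefore be carried by an explicit $\pi$ term — the
classic two-part treatment of substituted benzenes. Induction flows back
into the $\pi$ problem through the $\omega$-technique: every $\pi$ centre's
Coulomb integral is shifted by $\omega\,q_\sigma$ with the customary
$\omega = 1.4$. This one mechanism is what keeps CF$_3$ from behaving like
a methyl group (its pseudo-methyl orbital is pulled far down by the
positive $\sigma$ charge of the carbon) and keeps the halogens net
acceptors (ring polarization outweighs their weak lone-pair donation).

Two parameter choices were made inside the literature spread rather than at
its centre, on qualitative-chemistry grounds: the pseudo-methyl well is
deep ($h = 3.0$), so hyperconjugative donation is weaker than any true
lone-pair donation (otherwise methyl would out-donate methoxy, inverting
the experimental order), and the heavier halogens share $h = 2.0$ with
decreasing $k$ (0.4, 0.3, 0.25 for Cl, Br, I). Degenerate frontier
orbitals are filled evenly, so the occupation is deterministic for every
electron count. Everything in the descriptor is seedless and pure:
repeated calls are bit-identical.

The descriptor is mapped onto the experimental scale by ordinary least
squares against measured $\sigma$-para values. The package ships a
28-entry table of textbook constants (`inst/extdata/`); on it the
calibration reaches $r^2 \approx 0.72$ with a positive slope near 11. The
known limitations are the resonance-only transmission of OCF$_3$ and
acetamido (predicted mildly donating, experimentally neutral-to-accepting)
and the compressed span of strong acceptors. The canonical donor/acceptor
ladder NO$_2$ > CN > Cl > H > CH$_3$ > OCH$_3$ > NMe$_2$ is strictly
decreasing in the descriptor, which is the property bioisosteric ranking
actually relies on.

## Navigator semantics

The interactive tool this package backs is a scatter plot; nearest-
neighbour and diversity semantics had to be fixed explicitly. Distances
are Euclidean in (π, σ) with per-axis standardization by the catalog
standard deviation (π spans several log units, σ about two, so raw
distances would be π-dominated; `scaling = "raw"` is available). Ties
break toward the more frequent — i.e. more synthetically accessible —
substituent, then lexicographically. `diverse_selection()` maximizes the
minimum pairwise distance: exactly (enumeration) when the number of
candidate subsets is at most 500, by greedy farthest-point selection
seeded at the most frequent substituent otherwise. Quadrant assignment is
sign-based with exact zeros reported as `boundary`. The Craig-plot
renderer writes a machine-readable sidecar TSV next to the figure; the
sidecar, not the pixels, is the contract for any downstream UI, and the
point-size encoding of frequency is monotone (log-scaled) but otherwise
unconstrained.

## Synthetic corpora

Real substituent statistics come from corpora of hundreds of thousands of
bioactive molecules; the package instead ships a seeded generator that
reproduces the one statistical feature the statistics modules depend on: a
long-tail (power-law) substituent frequency distribution. A pool of
distinct substituents receives Zipf weights $w_r \propto r^{-s}$ with
$s = 1.5$ by default (rank-1 mass ≈ 38%, a head-heaviness comparable to
how the most common groups dominate bioactive corpora; $s$ must exceed 1).
The head of the ranking is the fixed built-in vocabulary — halogens,
alkyls, methoxy, nitro, cyano, trifluoromethyl, amines, acyls, sulfonyl,
phenyl — because the identity of the most ubiquitous groups in drug-like
molecules is not in doubt; the seed shuffles only the combinatorial tail
(chain-extended variants). Keeping phenyl out of the head's top ranks also
keeps the planted-group recovery rate seed-independent: a phenyl planted
on an aromatic scaffold fuses into a biphenyl linkage that the
fragmentation rules correctly refuse to cut.

Each molecule is one of six ring scaffolds (benzene, pyridine, pyrimidine,
thiophene, cyclohexane, piperidine) with 1–3 pool substituents planted on
distinct hydrogen-bearing ring positions; activities are log-uniform over
0.01–100 µM, so roughly three quarters of molecules pass the usual 10 µM
bioactivity cutoff. A manifest records every planting, giving ground truth
for recovery and singleton statistics. What the generator does *not*
emulate: scaffold diversity and fused ring systems, correlated
substituent co-occurrence, stereochemistry, tautomerism, and any relation
between structure and activity. Tests passing on these corpora therefore
validate the *procedures* (extraction completeness, counting, statistics,
ranking) — not any empirical claim about real corpora.

## Problem sizes and numerical choices

The test suite works at deliberately modest sizes chosen to exercise every
code path: oracle-vs-implementation fragmentation equivalence on 200
molecules, long-tail statistics on a 2,000-molecule corpus with a
120-substituent pool, and the full command-line pipeline on 500 molecules.
The acceptance script reuses the 2,000-molecule setting. Degenerate inputs
are defined, not accidental: an empty corpus yields an empty catalog; a
molecule with no breakable bond yields no occurrences; a catalog with a
single substituent aggregates to a one-row, 100% table; a calibration on
identical descriptors is a hard error (degenerate fit), as is a
zero-size corpus in `frequency_summary()`. Salts keep their largest
covalent component; charged substituents (carboxylate, ammonium, nitro)
are retained as drawn, with no neutralization pass. Stereo descriptors are
not normalized and are lost on fragment canonicalization — stereoisomeric
substituents merge, which matches the resolution of the class grammar and
of the property models, neither of which is stereo-aware.

## Worked example

```{r example, eval = FALSE}
corp <- generate_corpus(corpus_config(seed = 1, n_molecules = 500))
catalog <- fragment_corpus(corp, min_molecule_freq = 5)
catalog <- annotate_catalog(common_substituents(catalog))
frequency_summary(catalog)
nearest_bioisosteres(catalog, "[*]Cl", k = 5)
render_craig_plot(catalog, "craig.png")
```

The same pipeline is scriptable from a shell through
`inst/cli/substispace.R` (`fixtures`, `extract`, `annotate`, `classify`,
`stats`, `query`, `plot`).
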