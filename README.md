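# substispace

Substituent extraction, in-silico property estimation and Craig-plot
navigation for bioisosteric design.

## What it does, and for whom

Medicinal and computational chemists optimizing a lead compound routinely
swap one substituent for a *bioisostere* — a group of similar size and
physicochemical profile expected to preserve activity while fixing
something else (solubility, metabolism, synthesis). Doing this
systematically needs two things: a catalog of the substituents that
actually occur in bioactive molecules, with their frequencies, and a
property space in which "close" means "interchangeable". The classic such
space is the **Craig plot**: Hansch–Fujita hydrophobicity π on one axis,
Hammett electronics σ on the other.

`substispace` builds both from any SMILES corpus:

* **Extraction** — every *chemically activated* bond (single, acyclic:
  ring–nonring, carbon–heteroatom, or adjacent to a multiple bond) is cut
  one at a time; both fragments with ≤ 12 heavy atoms are collected as
  attachment-marked substituents (`[*]C(=O)N`, ...), with the attachment
  context (aliphatic/aromatic carbon, carbonyl carbon, N, O, S, halogen)
  recorded per occurrence.
* **π** — `π(R) = logP(C6H5R) − logP(C6H6)` by Wildman–Crippen atom
  contributions, so π(H) = 0 exactly.
* **σ** — a σ-para-compatible descriptor from partial charges of the same
  substituted-benzene probe: PEOE (Gasteiger–Marsili) σ charges plus
  simple-Hückel π charges with ω-technique coupling, read at the ring
  carbon para to the substituent and mapped onto the experimental scale by
  a linear calibration (a 28-entry table of textbook σ-para/π constants is
  shipped).
* **Classification & statistics** — root-atom classes (`R-C`, `R-c`,
  `R-N`, ... `R-X`), second-shell patterns (`R-C(=O)-N`, `R-c(:n):c`),
  occurrence-weighted attachment profiles, and long-tail (singleton,
  power-law) frequency summaries.
* **Navigation** — filters by class/attachment/size/frequency/property
  ranges, k-nearest-neighbour bioisostere search, max-min diversity
  selection, and Craig-plot export (figure + machine-readable sidecar
  TSV).
* **Synthetic corpora** — a seeded generator plants Zipf-weighted
  substituents on ring scaffolds with a ground-truth manifest, so the
  whole pipeline is testable offline.

Molecular parsing, aromaticity perception, canonical SMILES and
atom-contribution logP are delegated to Open Babel through `ChemmineOB`.

## Worked example

```r
library(substispace)

corp    <- generate_corpus(corpus_config(seed = 1, n_molecules = 500))
catalog <- fragment_corpus(corp, min_molecule_freq = 5)
frequency_summary(catalog)
#> Substituent frequency summary
#>   corpus size        : 500 molecules
#>   unique substituents: 875
#>   total occurrences  : 2668
#>   singletons         : 699 (79.9%)
#>   present in > 1%    : 40
```

875 distinct substituents were extracted from 500 molecules; as in real
corpora, most (79.9%) are singletons seen in a single molecule, while 40
groups occur in more than 1% of the corpus. Annotating the common slice
and asking for chlorine's neighbours:

```r
common <- annotate_catalog(common_substituents(catalog))
nearest_bioisosteres(common, "[*]Cl", k = 5)[, c("smiles", "pi", "sigma",
                                                 "distance")]
#>         smiles    pi  sigma distance
#> 1           *I 0.605 0.1028   0.0698
#> 2          *Br 0.763 0.0951   0.1413
#> 3 *c1cnc(nc1)C 0.765 0.1444   0.2161
#> 4    *c1cncnc1 0.457 0.1710   0.3520
#> 5 *c1ccnc(n1)C 0.765 0.1983   0.3597
```

The top hits for chlorine are iodine and bromine — the textbook halogen
bioisosteres — followed by mildly electron-poor heteroaryls of similar
hydrophobicity. `render_craig_plot(common, "craig.png")` writes the
figure and a `craig.tsv` sidecar with the plotted coordinates.

The same pipeline runs from a shell:

```sh
S=$(Rscript -e 'cat(system.file("cli", "substispace.R",
                                package = "substispace"))')
Rscript $S fixtures --seed 1 --n 500 --out corpus.smi
Rscript $S extract  --in corpus.smi --max-atoms 12 --min-freq 5 --out cat.tsv
Rscript $S annotate --catalog cat.tsv --out annotated.tsv
Rscript $S query    --catalog annotated.tsv --root R-O --sigma-max -0.1 \
                    --out donors.tsv
Rscript $S plot     --catalog annotated.tsv --out craig.png
```

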