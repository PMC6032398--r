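# cellumod — comparative analysis of modular GH9 cellulases

Green microalgae (*Chlamydomonas*, *Gonium*, *Volvox*) secrete cellulases of
glycosyl hydrolase family 9 (GH9) that are **modular**: one or two catalytic
domains (CD) joined by proline/serine-rich linkers to novel cysteine-rich
carbohydrate-binding modules (CBM), sometimes with Ig-like or unassignable
domains. `cellumod` is an R package plus a small analysis workflow for the
sequence-level side of that biology, aimed at anyone annotating modular
cellulases or validating such annotations against simulations:

* **Pattern engine** — a full PROSITE-syntax parser/scanner
  (`parse_prosite()`, `scan_pattern()`), reporting *all* match coordinates of
  variable-length patterns, with the GH9 Region I/II patterns, the
  algal-specific Region II insertion `P-T-[PTA]-[YSG]` and the CBM18 Hevein
  motif shipped in `inst/extdata/gh9_patterns.tsv`.
* **Region annotation** — `find_regions()` groups Region I–III matches into
  catalytic-domain occurrences (handling double-CD proteins), flags canonical
  triads, assigns catalytic roles (the DAGD motif's supporting D and
  catalytic base D, the Region III acid E and nucleophile D) and detects the
  insertion.
* **Segmentation** — `annotate_architecture()` tiles a protein into
  CD / linker / CBM / unknown segments: linkers classified P/S-rich,
  P/S/T-rich or non-P/S/T by composition; CBMs detected as cysteine-rich
  windows with spacing-based 6-C/4-C/2-C motif classes and a two-family hint
  (`algal_A` / `algal_B`).
* **Comparative stage** — percent-identity matrices over BLOSUM62 affine-gap
  global alignments (identity = identical pairs / shorter sequence × 100),
  neighbor-joining trees on `d = 100 − identity` with column-resampling
  bootstrap support, and group-cohesion checks (`nj_tree()`,
  `bootstrap_support()`, `group_cohesion()`).
* **qPCR stage** — efficiency-corrected relative quantities
  `rq = E^(Cq_cal − Cq)`, geNorm stability `M`, geometric-mean normalization
  factors, NRQs and two-group Student's t-tests on log2(NRQ)
  (`nrq_analysis()`).
* **Synthetic data** — `make_protein()` renders eight modular architecture
  blueprints with ground-truth segment maps, `evolve_on_tree()` produces
  aligned families, `make_cq_dataset()` plants known fold changes; every
  output is fully determined by its seed.

## Worked example

The four numbered scripts under `analysis/` run the whole study on synthetic
inputs (`Rscript analysis/01_simulate.R` … `04_qpcr.R`), writing tables under
`results/`. Step 2 annotates the simulated eight-protein panel:

```
recovered domain architectures:
  Cr9B       CD-linker-CBM
  Cr9C       CD-linker-?
  Cr9D       ?-CD-linker-CBM
  Gp51466    CD-linker-CBM
  Gp51468    CD-linker-CD-linker-CBM
  Gp44756    CD-linker-CBM
  Vc2952174  CD-linker-CBM-linker-CBM
  Vc2958622  CD-linker-CBM
9 canonical Region I-II-III triads across 8 proteins
Region II insertion detected in 7 of 9 catalytic domains
```

Every blueprint is recovered: the double-CD protein shows two canonical
region triads, the Ig-like domain surfaces as a trailing `?` (it is
undetectable from sequence patterns, by design), and the insertion is found
in exactly the seven algal CDs that carry it. Step 3 reports the two-clade
family staying cohesive with full bootstrap support, and step 4 runs the
expression analysis:

```
geNorm chose references: eef1, rpl23 (elimination order: tubA1 > tbpA)
target comparison (treated vs control):
  cel51466  fold change 1.99, p = 0.0000 *
  cel51468  fold change 2.14, p = 0.0000 *
  cel44756  fold change 1.17, p = 0.1112
```

The two planted 2× upregulations are recovered as significant; the third
target's small planted trend stays below significance — the qualitative
pattern observed for the three studied cellulases.

In code, the same stages are three calls:

```r
library(cellumod)
rec  <- make_protein("Gp51468", seed = 1)      # two CDs, two linkers, one CBM
arch <- annotate_architecture(rec)
arch$architecture_string
#> [1] "CD-linker-CD-linker-CBM"
```

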