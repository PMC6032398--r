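---
title: "Analysing modular GH9 cellulases with cellumod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing modular GH9 cellulases with cellumod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellumod)
```

## The biological problem

Glycosyl hydrolase family 9 (GH9) cellulases are inverting enzymes with an
(α/α)~6~-barrel catalytic domain (CD). In green microalgae these enzymes are
modular: one or two CDs joined by low-complexity linkers to C-terminal
cysteine-rich carbohydrate-binding modules (CBMs), occasionally with an
Ig-like or otherwise unassignable domain. `cellumod` implements the sequence
side of a comparative analysis of such proteins:

1. a PROSITE pattern engine and annotation of the three conserved catalytic
   regions of the CD, including the catalytic residues of the DAGD motif and
   the algal-specific four-residue Region II insertion;
2. segmentation of a protein into CD / linker / CBM / unknown stretches, with
   composition-based linker classes and spacing-based CBM motif classes;
3. pairwise percent identity, neighbor-joining (NJ) trees with bootstrap
   support, and group-cohesion checks;
4. multi-reference-gene qPCR analysis (geNorm stability, efficiency-corrected
   normalized relative quantities, two-group Student's t-tests);
5. a synthetic-data generator that emits all of the above inputs with known
   ground truth.

The numbered scripts under `analysis/` run these stages in order and write
their tables under `results/`.

## Pattern engine

`parse_prosite()` supports the standard hyphen-separated PROSITE dialect and
the subscript dialect used in printed motif tables (`X_5-7_`, which
normalizes to `x(5,7)`). `scan_pattern()` reports **all** distinct
`(start, end)` pairs, not only a greedy/shortest match per start: downstream
region picking needs the full set, and whether overlapping variable-length
alternatives should collapse into one hit is not specified by the scanning
conventions we follow, so we keep everything and deduplicate by coordinates.
Coordinates are 1-based inclusive throughout, matching ScanProsite reports.

Two deliberate choices:

* An `X` in a *subject* sequence is an unknown residue: it satisfies
  wildcards and residue classes, but never a negated class. This is the
  conservative reading — an unknown residue might be anything, so it cannot
  be guaranteed to avoid the excluded set.
* Wildcard elements may carry a zero minimum repeat (`x(0,12)`), which the
  Region III stand-in pattern needs; residue-class elements must consume at
  least one residue.

The scanner is validated against a brute-force oracle that enumerates every
substring and every wildcard-length assignment by direct recursion; the test
suite checks exact match-set equality on hundreds of random (pattern,
sequence) pairs.

## Region annotation

Regions I and II use the published GH9 patterns. No community pattern exists
for Region III (its consensus is only shown graphically in the source
literature), so the packaged `region3` pattern is a **declared stand-in**,
`E-x(0,12)-D`, anchored on the two residues that matter functionally: the
invariant catalytic acid E and the downstream nucleophile-aligning D. It is
configurable; the synthetic generator uses the same configured default so
round-trip tests are self-consistent.

Matches are grouped greedily left-to-right into CD occurrences (leftmost
Region I, then the leftmost Region II after it, then the leftmost Region III
after that), which naturally handles double-CD proteins; an occurrence is
*canonical* when all three regions appear in order within `max_triad_span`
(default 450 aa, a typical GH9 CD size — the literature gives no fixed CD
length). Leftmost-match tie-breaking keeps the annotation deterministic.

Catalytic roles follow the region biology: in Region I, pattern element 7
(the N-terminal D of DAGD) is the supporting residue and element 10 the
catalytic base — recorded as `non_canonical_base` when the sequence carries
something other than D there, as in some angiosperm and sea-squirt enzymes;
in Region III the anchors are the acid and the nucleophile. Region II has no
catalytic roles; it is screened (span ± 6 aa) for the `P-T-[PTA]-[YSG]`
insertion instead.

## Segmentation thresholds

The source descriptions of linkers and CBMs are qualitative ("P/S-rich",
"high percentage of cysteine residues"), so the quantitative thresholds here
are this package's own, chosen once so that the described exemplars separate
cleanly, and all configurable via `pipeline_config()`:

| parameter | default | meaning |
|---|---|---|
| `ps_rich_min` | 0.40 | min fP+fS for a P/S-rich linker (with fT < 0.10) |
| `pst_rich_min` | 0.45 | min fP+fS+fT for a P/S/T-rich linker (fT ≥ 0.10) |
| `min_linker_len` | 8 aa | shortest stretch labelled LINKER |
| `max_linker_len` | 50 aa | linker/unknown split of a C-terminal stretch |
| `cbm_min_cys`, `cbm_min_cys_frac` | 8, 0.08 | cysteine thresholds of a CBM window |
| `cbm_min_len`, `cbm_max_len` | 50, 130 aa | CBM window bounds |
| `cd_pad_left`, `cd_pad_right` | 30, 60 aa | CD span around the region triad |

CBM motif classes are **spacing-based approximations**: the residue content
of the reported motifs is only available graphically, so we classify by
cysteine-cluster geometry — `sixC` (≥ 6 C within 25 aa), `fourC` (≥ 4 C
within 18 aa), `twoC` (a C-x(0,8)-C pair) — and hint the family accordingly:
both `sixC` and `fourC` present → `algal_A` (the family proposed for Cr9B,
Gp51466, Gp51468, Vc2958622); `twoC` only → `algal_B` (Cr9D, Gp44756,
Vc2952174).

Architecture assembly places CDs first (region triads padded by the CD
margins; CD claims take priority over CBM claims), CBMs next, then labels
inter-domain stretches ≥ 8 aa as classified linkers. Flanking stretches need
one asymmetric rule, because Ig-like and unknown domains are *not*
detectable from sequence patterns and deliberately surface as UNKNOWN: in
these enzymes all linkers sit C-terminal to the CD, between CD and accessory
modules, so a C-terminal flanking stretch is split into a domain-adjacent
LINKER (up to `max_linker_len`) plus a trailing UNKNOWN, whereas an
N-terminal flanking stretch is wholly UNKNOWN. This renders the two special
architectures correctly — `CD-linker-?` for a protein with a trailing
Ig-like domain and `?-CD-linker-CBM` for one with an unknown N-terminus —
without pretending to detect what the method cannot see. In the rendered
architecture string, terminal UNKNOWN stretches shorter than 10 aa are
considered boundary slack and omitted.

## Comparative analysis

Percent identity is *identical aligned pairs ÷ length of the shorter
sequence × 100* (configurable to aligned columns): alignment-program
identity conventions differ, and since the original CD truncations were
manual, exact reproduction of any published identity table is out of reach —
the comparative stage therefore validates **properties** (symmetry, additive
recovery, monotone decay with divergence, group cohesion) rather than
specific percentages. Alignment is global with BLOSUM62 and affine gaps
(open 10, extend 0.5; a gap run of length L costs open + L·ext); the
implementation is checked against exhaustive alignment-path enumeration on
tiny pairs.

Tree inference is Saitou–Nei neighbor joining on `d = 100 − identity`
(optionally Poisson-corrected), an explicit distance-based stand-in for
maximum-likelihood inference: it exercises the same claim — sequences
cluster by taxonomic group — at a fraction of the cost, and NJ is exact on
additive distances, which the tests verify against a quartet (four-point)
oracle. Negative NJ branch lengths are clamped to zero with the deficit
recorded. Bootstrap support resamples alignment columns with replacement
(default 100 replicates, the usual reporting convention), rebuilds the NJ
tree per replicate, and reports the fraction of replicates containing each
original bipartition. `group_cohesion()` asks whether a group's leaves form
one side of some bipartition of the unrooted tree.

## qPCR model

With per-gene amplification efficiency $E_g \in (1, 2]$ and quantification
cycles $Cq$, the efficiency-corrected relative quantity is

$$rq(s,g) = E_g^{\,\overline{Cq}_g - Cq(s,g)},$$

with the calibrator $\overline{Cq}_g$ the gene's mean over all samples
(qbase convention; a control-group-mean calibrator is available). geNorm
stability is

$$M_j = \frac{1}{|K|-1}\sum_{k \ne j} \mathrm{sd}_s\!\left[\log_2 \frac{rq(s,j)}{rq(s,k)}\right],$$

with iterative elimination of the highest-M candidate down to two chosen
references — the study design this emulates used exactly two references, so
the pairwise-variation cutoff for keeping more than two is not implemented.
The normalization factor is the geometric mean of the chosen references' rq,
and $NRQ = rq / NF$ exactly. Fold change is the ratio of NRQ group means;
the test is a two-sided two-sample Student's t-test on $\log_2 NRQ$
(equal-variance by default — the measurement error is multiplicative on the
linear scale, hence approximately additive and homoscedastic on the log
scale; a Welch variant is available). NRQ is scale-invariant: shifting all
Cq of any single gene by a constant changes neither fold changes nor
p-values, which the suite asserts to machine precision.

## What the generator emulates — and what it does not

The generator is construction-first, so ground truth is unambiguous:

* **CDs**: Regions I–III instantiated from their patterns (one residue drawn
  uniformly per class position; algal CDs pin the characteristic DAGD
  tetrad), joined by background spacers (30–60 aa), with a 30-aa head and
  60-aa tail matching the CD padding of the detector. The insertion is
  realised inside Region II's `x(1,5)` stretch, so the region pattern still
  matches; insertion-free CDs are re-drawn if an insertion-like motif arises
  by chance.
* **Linkers**: 20–40 aa (typical reported linker lengths are 20–50),
  composition built from exact counts — P/S-rich at fP+fS = 0.60, P/S/T-rich
  at fP+fS+fT = 0.55 with fT = 0.20, non-P/S/T with zero P/S/T (mirroring
  described linkers "lacking P, S and T") — so the class is guaranteed, not
  merely likely.
* **CBMs**: 10–16 cysteines (the reported range), laid out as explicit
  clusters/pairs per family; segment lengths stay within the detector's
  50–130 aa window by construction. An odd total in a pairs-only family is
  realised as pairs plus one isolated cysteine placed ≥ 9 residues from any
  other, which adds no motif class.
* **Background** (spacers, unknown domains): uniform over the 20 amino acids
  minus C and E, with P/S/T down-weighted 4-fold. Excluding C keeps cysteine
  ground truth unambiguous; excluding E keeps the Region III acid anchor
  unique (the generated E–D gap also excludes D so the recorded anchor is
  the leftmost pattern match); down-weighting P/S/T keeps spacers from
  drifting into linker classes.
* **Families**: per-site substitution along tree branches with uniform
  replacement among the other 19 residues, no indels (leaves stay aligned).
* **Cq tables**: $Cq(s,g) = base_g - \mathrm{effect}(s,g)/\log_2 E_g +
  \mathcal{N}(0, \sigma_g)$, four stable reference candidates (eef1, rpl23,
  tbpA, tubA1; E = 2), planted log2 fold changes of 1, 1 and 0.15 on the
  three targets (two clear upregulations plus one sub-significant trend,
  the qualitative expression pattern of the three studied cellulases),
  σ = 0.15 cycles, six samples per group.

Because spacers are composition-controlled and indel-free, passing the
closed-loop tests demonstrates the *internal consistency* of detector and
generator under realistic signal geometry — it does **not** show that the
thresholds are optimal for real proteomes, where low-complexity regions,
compositional drift, indels and undetectable domains (Ig-like folds,
signal peptides) blur every boundary the generator keeps crisp. The
comparative stage likewise makes no claim of reproducing published identity
percentages or tree topologies, which depend on the original accessions,
manual CD truncation and ML inference.

## Numerical and degenerate-input choices

* Leftmost-match tie-breaks everywhere; all outputs are deterministic
  functions of (input, configuration, seed), and every TSV/Newick output
  carries the package version and configuration hash in a comment header.
* Empty sequences scan to zero matches (not an error); an empty FASTA is an
  ingest error.
* Variation-profile fractions are exact counts over all rows, so residue
  fractions plus the gap fraction sum to 1; consensus ties below threshold
  render `x`, gap-majority columns render `-`.
* Zero within-group variance on the log scale flags the comparison
  `degenerate` with an undefined p-value rather than fabricating one.
* NJ negative branch lengths are clamped at zero, with the clamped total
  kept as an attribute.

## Problem sizes used in the validation suite

The shipped tests run the oracle-equivalence check on 500 random
pattern/sequence pairs (≤ 60 aa), the closed-loop architecture recovery on
all eight blueprints × 50 seeds, NJ recovery on 100 random additive
matrices (4–8 taxa) plus a 100-seed two-clade cohesion study with one
100-replicate bootstrap, and the t-test calibration on 1000 simulated null
datasets. These sizes give stable pass/fail behaviour for the properties
being checked while keeping the whole suite in the low minutes on one CPU.

## Known limitations

* Region III is a stand-in pattern, not a community consensus.
* CBM motif classes are cysteine-spacing approximations; no claim is made
  about non-cysteine motif residues, and Hevein-domain family assignment
  goes no further than pattern matching.
* Ig-like and other accessory domains are reported as UNKNOWN, never
  identified.
* The NJ + bootstrap stage is a stand-in for ML tree inference.
* Primer-efficiency estimation from dilution series and amplification-curve
  processing are out of scope; efficiencies are inputs.
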