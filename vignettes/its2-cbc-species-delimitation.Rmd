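---
title: "ITS-2 barcode species delimitation and V4 haplotype networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ITS-2 barcode species delimitation and V4 haplotype networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(its2cbc)
```

## The problem

Marine coccoid green algae (ulvophytes such as *Chlorocystis*,
*Desmochloris* and *Sykidion*) are morphologically plastic: vegetative cells
of different species can be indistinguishable under the microscope, and
species boundaries drawn from cell shape have repeatedly collapsed under
molecular data. A practical alternative delimits species from the ribosomal
operon itself:

1. the **secondary structure of ITS-2** is highly conserved within species;
   its conserved base pairs can be read as a short species barcode, and
   changes in those pairs between strains carry taxonomic signal;
2. the **hypervariable V4 region of the SSU (18S) rRNA** distinguishes the
   resulting species in environmental sequence data, supports
   clade-diagnostic characters on its secondary structure, and yields
   haplotype networks that display geographic and habitat structure.

`its2cbc` implements this pipeline end to end, from file formats to species
partitions and annotated networks, plus a generator of synthetic datasets
with planted ground truth so that every stage is testable without any
external downloads.

## The ITS-2 number-code barcode

ITS-2 in these taxa folds into three helices (I–III; helix IV is absent).
Only the terminal loops of helices I and II vary freely; the base pairs of
the remaining structure are the **conserved core**. Each core pair is
encoded by one of eight states:

| code | pair | | code | pair |
|------|------|-|------|------|
| 1 | A–U | | 5 | G•U |
| 2 | U–A | | 6 | U•G |
| 3 | G–C | | 7 | mismatch (any other two bases) |
| 4 | C–G | | 8 | deletion, single or unpaired bases |

The per-strain vector of codes is the barcode (`encode_barcode()`, rendered
as a digit string by `barcode_string()`). Comparing two barcodes column by
column (`compare_barcodes()`) classifies every change:

* **CBC** (compensatory base change): both strands differ and both columns
  keep one of the six pairing states — e.g. A–U → G–C;
* **HCBC** (hemi-CBC): exactly one strand differs, pairing kept — e.g.
  A–U → G•U;
* **mismatch / indel changes**: code 7 or 8 involved;
* **identical** (gap-vs-gap counts as identical);
* **ambiguous**: an IUPAC degeneracy code is present. Ambiguous columns are
  excluded from CBC/HCBC counts and from the variable-position count and are
  reported separately — the conservative reading, since a degenerate base
  could hide either state.

Variable-position counting (`count_variable_positions()`) uses base
identity, not code identity: two different mismatch pairs both carry code 7
but still differ, and the display that motivates the barcode prints the
bases alongside the codes.

## The delimitation rule

Candidate lineages come from a phylogenetic analysis; species status is then
decided from barcode evidence (`delimit_species()`):

* a single **CBC** between two lineages keeps them distinct regardless of
  tree support;
* lineages separated **only by HCBCs** stay distinct only when both carry
  high lineage support — bootstrap ≥ 70% or, when posterior probabilities
  are supplied, posterior ≥ 0.95 (`analysis_config()`);
* lineages separated by neither (identical barcodes, or HCBC-only without
  support) merge, by transitive closure.

Two design points were genuinely open and are resolved as follows. First,
the support rule for an HCBC-only split requires *both* lineages to be
supported: a split is an edge between two clades, and an unsupported clade
on either side means the data do not place that boundary reliably. Either
the bootstrap or the posterior criterion suffices, since the two scores
come from different analyses and published practice accepts a clade that
any rigorous analysis supports strongly. Second, between-lineage CBC/HCBC
counts are the *minimum* over all cross-lineage strain pairs: a change must
separate every member pair before it counts as separating evidence,
otherwise within-species variation could manufacture a split.

## Conserved columns and structures

Structures arrive as dot-bracket strings (`read_vienna()`,
`pairing_from_dotbracket()`); thermodynamic folding is out of scope — the
field folds with dedicated programs and the fold is an input here, which
keeps results reproducible. For strain sets folded per strain, the conserved
core is the set of columns paired in *every* strain with a consistent
partner (`conserved_columns()`); alternatively `transfer_structure()`
transfers one reference structure across an alignment column by column
(homology transfer), which is how code 8 (a gap under a conserved pair)
arises naturally.

Helix annotation (`annotate_helices()`) decomposes the pairing into maximal
stacked stems. Two stacked pairs make a stem and interior bulges up to 3 nt
per side do not split one — a conventional stem decomposition; the
three-helix model then labels stems I, II, III in 5′→3′ order of their
opening strands, and terminal-loop positions of helices I and II are
excluded from the barcode (the `exclude_loops` argument makes this
configurable). More than three qualifying stems is an error that asks for a
template override rather than silently inventing a helix IV. All coordinates
are 1-based inclusive, in code and in reports, following R convention.

## Lineage trees

The package's in-repo route to supported lineages is deliberately modest:
uncorrected p-distances (`p_distance_matrix()`, gaps and ambiguity codes
excluded pairwise), neighbor joining (`nj_tree()`, delegated to
`ape::nj`), and a nonparametric bootstrap over alignment columns
(`bootstrap_supports()`, seed-reproducible). Maximum-likelihood and Bayesian
inference are *not* reimplemented — those are external-program computations —
but their support values can be attached to any tree via a bipartition table
(`import_supports()`), so externally inferred trees plug straight into the
threshold logic.

`supported_lineages()` reads clades off the supported bipartitions: each
internal edge at or above the support threshold contributes the side not
containing the declared outgroup (without an outgroup, the smaller side;
equal halves resolve towards the side holding the lexicographically smallest
strain — the tie-break matters only for perfectly balanced splits and is
documented because the lineage set depends on it). Maximal supported clades
become lineages and the remaining strains become singletons, so lineages
always partition the strain set; singleton lineages carry support 100, as a
terminal split is present in every replicate.

## V4 region, template and diagnostic characters

The V4 secondary structure is described by a helix template naming the E23
helices (E23_1–E23_14) with 1-based spans on an ungapped reference
(`read_v4_template()`). The package ships a **synthetic example template**
(`v4_template_synthetic()`, `inst/extdata/v4_template_synthetic.tsv`): the
E23 nomenclature is standard but published figures print no machine-readable
coordinates, so the shipped template is a constructed stand-in that realizes
the helix layout (including the E23_10/E23_11 hairpins nested inside E23_9)
for testing and examples. Real analyses should supply a template curated for
their reference strain.

`extract_v4()` slices the region out of an SSU alignment through the
reference row's gaps; `annotate_v4()` labels every column with its helix or
with `spacer(X-Y)` naming the flanking helices. Diagnostic characters for a
clade are then:

* **NHS** (non-homoplasious synapomorphy, `find_nhs()`): a column where all
  clade members share one unambiguous state absent outside the clade. With a
  tree supplied, single origin is verified by requiring parsimony score 1
  for the presence/absence character. Columns paired in the template are
  excluded by default, because diagnostic changes at paired columns are the
  domain of the pair classifier. Size-one clades yield autapomorphies,
  flagged rather than suppressed.
* **paired-column CBC/HCBC** (`find_pair_synapomorphies()`): template pairs
  where the clade's uniform base pair differs from every outside pair,
  classified against the outside *majority* pair with the same rules as the
  barcode comparison; a polymorphic outside is flagged, never silently
  classified. Suspected sequencing artifacts (singleton mismatch-creating
  states) are the user's call: nothing is auto-removed.

## Statistical-parsimony networks

V4 sequences collapse into haplotypes carrying their samples' habitat and
geography metadata (`collapse_haplotypes()`; multiplicities are conserved by
construction). The **connection limit** (`parsimony_limit()`) is the largest
number of steps `j` between two haplotypes of length `L` for which the
probability that the `j` observed differences arose without homoplasy is at
least the confidence level (0.95 by default). The estimator models per-site
mutation counts as Poisson with rate `lambda = -log(1 - j/L)` — the rate at
which the expected fraction of visibly changed sites equals the observed
`j/L` — giving

```
P(j) = ( lambda * exp(-lambda) / (1 - exp(-lambda)) )^j
```

the probability that every observed difference received exactly one hit
given at least one. A single step is always connectable (the limit is at
least 1, even at confidence 1.0). This closed form is the package's own
documented rendering of the statistical-parsimony criterion; its frozen
values over a length × confidence grid are pinned in the test suite against
an independent numeric evaluation.

`build_network()` connects haplotype pairs in order of increasing mutational
distance up to the limit, skipping pairs already connected — a
minimum-spanning construction whose total step count is provably minimal per
component (the tests verify this against exhaustive enumeration on small
instances). Ties resolve by higher multiplicity, then lexicographic ids.
Distances above 1 are realized through inferred median nodes (multiplicity
0) inserted greedily along a deterministic mutational path, so every edge in
the final graph is a single step; an intermediate that coincides with an
existing node is reused rather than duplicated. Indels count as a fifth
character state, one step per contiguous gap run. The limit constrains
*direct connections*: as in actual statistical-parsimony practice, a chain
of within-limit links may span more than the limit end to end, while pairs
beyond the limit are never joined directly and isolated haplotypes remain
their own components.

Environmental queries are assigned by `assign_query()`: full coverage of
the reference region and identity strictly greater than 97% by default,
both configurable. Equal-length comparisons are positional; shorter queries
are slid ungapped along the reference and their coverage is the fraction of
the region they span, which is what makes a half-region fragment
unassignable regardless of identity.

## The synthetic-data generator

`generate_its2_dataset()` plants a star species tree: an ancestor barcode
drawn from codes 1–6, and per species a private set of CBCs and HCBCs at
fresh core columns (both strands substituted for a CBC, one for an HCBC,
pairing kept in all cases). Between species *i* and *j* the planted counts
are therefore exactly the sums of the two branches' counts, every species
has genuine shared-derived characters on its own branch, and the recorded
truth object carries the per-pair counts, the partition and the total
variable-position count. Free variation is confined to the helix I/II
terminal loops at a configurable noise rate, so core counts are exact, not
statistical. Lineage support values are drawn from 90–100, emulating the
strongly supported clades that motivate the delimitation rule; the
tree-based route to supports is exercised separately on strong-signal data.
Infeasible parameter combinations (more planted changes than core columns)
are errors, not silent truncation.

`generate_v4_dataset()` gives each species a block of private substitutions
one wider than the parsimony limit — so between-species distances always
exceed the limit — and chains haplotypes within species at exactly
`steps_between` fresh substitutions per link. `generate_v4_diagnostics_dataset()`
plants exact NHS/CBC/HCBC counts for a clade on a template-structured
alignment, optionally inside a named spacer. A single integer seed governs
all draws; identical seeds give byte-identical outputs.

What the generator does *not* emulate: substitution-model evolution along
branch lengths, rate heterogeneity, alignment error, intra-individual
polymorphism, or chimeric reads. Passing tests therefore demonstrate that
the machinery recovers exactly what its definitions promise on clean,
planted data — they do not certify performance on noisy real alignments,
where structure curation and alignment quality dominate.

## Problem sizes and numerical choices

The bundled analyses and tests run at the scale of the motivating study:
strain sets of 4–17, a conserved core of 40 base pairs, V4 sequences of
360 nt, bootstrap with 30–100 replicates, and networks of up to a dozen
haplotypes — sizes chosen to mirror the study design while keeping every
check exact. Deterministic tie-breaks are documented where output depends
on them (NJ delegated to `ape`'s deterministic implementation; network edge
order; lineage naming by lexicographically smallest strain). Degenerate
inputs fail loudly: empty FASTA, duplicate ids, pseudoknotted dot-brackets,
unequal barcode lengths, lineages without support values, strains without
barcodes.

## Known limitations

* RNA folding, ML/Bayesian tree inference and remote database searches are
  out of scope by design; structures, trees-with-support and candidate
  query sequences are inputs.
* The shipped V4 template is synthetic; order-level conclusions on real
  data require a curated template for the actual reference strain.
* The parsimony-limit estimator is a documented closed form with the
  canonical qualitative behaviour (monotone in length, limit 1 at full
  confidence); absolute limits from other implementations of the criterion
  may differ by a step or two at a given length.
* Median-node insertion is a greedy approximation of the original
  agglomerative procedure; it preserves the minimum total step count but
  the placement of inferred intermediates along equal-length paths is a
  deterministic convention (columns mutate left to right).
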