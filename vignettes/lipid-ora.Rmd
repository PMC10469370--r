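---
title: "Structure-aware over-representation analysis of lipidomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-aware over-representation analysis of lipidomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidenrich)
```

## The problem and the model

A lipidomics experiment typically ends with two lists: the full lipidome
detected in the study (the *reference*, or codomain) and a shorter list of
lipids that changed under some condition (the *query*). Over-representation
analysis asks, for every structural characteristic observed in the
reference, whether the query carries it more often than chance would
predict. What distinguishes a lipidomic ORA from the transcriptomic
original is that lipids have no useful pathway database — but their
*names* are a structured ontology in themselves. Shorthand nomenclature
encodes resolution explicitly: `"/"` between chains means the sn positions
are known, `"_"` means they are not; `(5,8,10,14)` locates double bonds;
`9Z` adds their geometry; `;O` and `;OH` count and name oxygen
modifications. The package's parser maps each name onto one of eight
nomenclature levels (CATEGORY < CLASS < SPECIES < MOLECULAR_SPECIES <
SN_POSITION < STRUCTURE_DEFINED < FULL_STRUCTURE < COMPLETE_STRUCTURE)
and extracts every structural feature the level supports.

Each feature becomes a **term**, identified by a classifier
(CATEGORY, CLASS, TOTAL_C, TOTAL_DB, TOTAL_O, CHAIN, CHAIN_AT_SN, C_GROUP,
DB_GROUP, BOND_TYPE, DB_POSITION, MODIFICATION), a value (e.g. `20:4`,
`sn-2:20:4`, `polyunsaturated`), the minimum level a lipid must reach to
be evaluable for it, and an optional conditioning category or class
("Acyls 16:1 within Glycerophosphocholines [GP01]"). For a term with
query membership count $a$ out of a query universe of $a+b$ and reference
count $c$ out of $c+d$, the package reports the sample odds ratio
$\mathrm{OR} = ad/bc$ and an exact p-value: Fisher's exact test under the
conditional hypergeometric distribution (two-sided by default), or the
hypergeometric upper tail $P(X \ge a)$, which is identical to the
one-sided ("greater") Fisher test. The two lists are treated as two
independent groups with the counts exactly as supplied; the reference is
*not* reduced by its overlap with the query. This convention is what makes
the printed odds ratios of the demo table exact cross-product ratios, and
it matches the common usage where the query is a subset of the reference.

Assumptions worth stating: membership is presence/absence (abundances are
never used); lipids are treated as independent draws, which is optimistic
when many query lipids are modification variants of one backbone; and a
term is tested only if at least one query lipid carries it (reference-only
terms carry no interpretive value and would inflate the correction
family; a flag restores them for strict users).

## Universes and level eligibility

A species-level name like `PC 36:4` cannot be evaluated for a chain term —
its chains are unknown. Two universe conventions are therefore
implemented. The default, `universe = "fixed"`, keeps the full list sizes
(restricted to the conditioning class for conditioned terms) as the
denominators of every term and lets eligibility act on the numerators
only; this is the convention under which the demo table's counts
(13/68 against 18/556 and the class-conditioned 11/26 against 14/148) are
arithmetically consistent, and it keeps denominators comparable across
levels. The alternative, `universe = "evaluable"`, counts only lipids
resolved deeply enough for the term, which is the stricter
conditional-sampling view. Both are tested; the default follows the
printed table.

## Multiple testing and the correction family

Bonferroni, Holm, and Benjamini–Hochberg corrections are available
(`stats::p.adjust` underneath). The subtler choice is the *family*: the
term universe mixes families of very different sizes (a handful of class
terms, dozens of chain terms, conditioned variants of each), and a single
global family lets the large families dilute the small ones — the set-size
effect. `family_scope` therefore offers `"all_terms"` (one family; the
default, and the conservative choice for a first screen), `"per_level"`,
and `"per_classifier"` (one family per classifier × level, so each
structural family is corrected for its own size). The demo reproduction
in the tests and the acceptance script uses `"per_classifier"`, the
per-family correction this hierarchical term system calls for; with one
global family of 150+ terms the weakest of the seven demo terms
(p ≈ 1.2e-4) cannot clear an adjusted threshold of 0.001, which is
precisely the set-size effect the per-family scope corrects. Adjusted
p-values are reported per term, `significant` means adjusted p < alpha,
and `alpha = 1` disables the threshold entirely (useful for exporting the
full ranked table).

## Intersections and Very Important Lipids

Significant terms overlap heavily — a lipid carrying `20:4` at sn-2 also
carries `20:4` unpositioned, and its conditioned variants. The package
condenses the result with *exclusive* UpSet semantics: each query lipid
belongs to exactly one intersection record, the one given by its full
membership profile over the retained terms, so records partition the
covered lipids and the joint structure is exact rather than pairwise.
(Inclusive counts are recoverable from the long-format export.) At most
`max_terms = 13` terms are retained, best-adjusted-p first, because the
number of possible profiles grows as $2^m$; ties at the cap break by
label for determinism. A lipid's *degree* is the number of retained
significant terms it belongs to, and the Very Important Lipids are all
lipids achieving the maximum degree — ties are kept, never truncated,
since the VIL set is a scientific statement, not a top-k list. Degree
counts distinct terms, not distinct intersections.

## The synthetic generator and the demo fixture

`generate_lipidome()` emulates the presence/absence skeleton of an LC–MS
mammalian lipidome: a class mixture over PC/PE/PG/PS/TG/Cer, chains drawn
from a frequency pool of sixteen common fatty acyls, a level mixture
(15% species, 55% molecular species, 22% sn-resolved, 8%
structure-defined), sparse `;O`/`;OH` modifications (10% of lipids), and
methylene-interrupted double-bond positions where the level calls for
them. Names are drawn until canonically distinct, so realized list sizes
equal the spec. Planted terms force a chain composition into an exact
number of lipids on each side. What the generator does **not** emulate:
abundances and missingness, correlated co-occurrence of modifications
with particular backbones, ether-lipid prevalence, and isotope/adduct
artifacts. Passing tests on generated data therefore demonstrate the
statistical machinery under a known truth, not performance on any real
instrument output.

`demo4_fixture()` is different: a fully deterministic 68/556 query/
reference pair, query ⊂ reference, built so that seven term memberships
hit fixed printed counts exactly (recounted through the parser at
construction; construction aborts on any disagreement) and so that the
thirteen sn-2-20:4 query lipids share one term profile (the "green
cluster", all 36:4 backbones with 16:0 at sn-1). All further joint
structure is a fixture choice: background pairs are mirrored
proportionally between query and reference so that every term covering
only part of the green cluster stays far from significance (raw two-sided
p > 0.004 throughout, against a demo threshold of 0.001 on the
*adjusted* p). Because the query is all-glycerophospholipid by
construction, the GP category term is genuinely significant and joins the
cluster profile; it contains every query lipid and so never splits any
intersection.

## Numerical choices

* Two-sided Fisher p-values sum all outcome probabilities at most the
  observed one, with a `1 + 1e-7` relative tie tolerance — the standard
  guard against float-equality pathologies in exact tests; one-sided
  tails come from `phyper` directly.
* Odds ratios are computed in double precision from integer counts
  (exact up to 2^53); `b·c = 0` with `a·d > 0` reports `Inf`, both zero
  reports `NaN` with the p-value still defined.
* Mixed-level names (positions with `"_"`, or positions on only some
  unsaturated chains of an sn-resolved name, or partial geometry) are
  coerced down to the closest valid level and flagged, never rejected;
  within-chain inconsistencies (three positions on a 2-double-bond chain)
  are errors.
* A name with geometry on every double bond reaches FULL_STRUCTURE only
  if it carries no unlocated oxygens; unpositioned modifications cap the
  level at STRUCTURE_DEFINED. Modification *positions* and stereo
  annotations are out of scope throughout, so COMPLETE_STRUCTURE is never
  assigned.
* Canonical molecular-species names order chains sphingoid first, then
  ether chains, then by carbons/double bonds/oxygens; sn-resolved names
  keep their stated order. Parsing a canonical name reproduces the same
  representation (round-trip property, tested on a 200-name panel).
* Per-level tree radii default to 1..8; branch lengths are radius
  differences so a radial drawing rings the levels. The spacing is an
  aesthetic choice, not a measured quantity.
* Report bundles fix member timestamps, so identical inputs produce
  byte-identical tar archives.

## Design decisions

* The analysis entry point is a single fitting-style function,
  `lipid_ora()`, returning a classed object with `print`/`summary`/
  `plot`/`as.data.frame` methods, in the style of R's modelling
  functions; the stage functions (`parse_batch`, `enumerate_terms`,
  `membership`, `build_membership`, …) remain exported for pipelines.
* Chain-at-sn terms are keyed by (sn index, composition) but displayed
  rolled up ("Acyls 20:4" at SN POSITION level), matching how such
  results are read — the sn detail lives in the term value.
* Bond-type terms classify a glycerolipid as ester, ether-O (alkyl), or
  ether-P (alkenyl); sphingoid-based lipids are skipped for this
  classifier rather than forced into an amide pseudo-class.
* Tabular exports are CSV; the bundle archive is POSIX tar written by R
  itself. The interactive viewers that usually accompany this kind of
  analysis (clickable UpSet plots, network sessions) are replaced by
  their data exports: an UpSet long table and node/edge tables.
* Problem sizes in the test suite — 1000 random tables for the exact-test
  oracles, 200 null seeds and 100 planted seeds at 68/556 for the
  statistical checks — were chosen as the smallest sizes at which the
  binomial noise on the measured rates is well below the margins being
  asserted.

## Known limitations

The grammar is a curated subset: ~20 headgroups covering common
glycerophospholipids (with lyso and ether variants), glycerolipids,
sphingolipids, free fatty acids and steryl esters. Other dialects
(LIPID MAPS full names, SwissLipids, HMDB identifiers) are recognised as
grammar selectors but not implemented. Mass or formula computation,
adduct mass handling and isotope labels are out of scope; adduct suffixes
are stripped textually. Multiple class categorisation (one lipid, several
LIPID MAPS classes) is not modelled — each headgroup maps to one class.
Positions of modifications and enantiomers are deliberately not
interpreted: the search space they open grows far faster than the
information they add for set-level statistics.
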