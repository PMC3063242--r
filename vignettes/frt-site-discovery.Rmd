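---
title: "Rule-based discovery and classification of FRT-like sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based discovery and classification of FRT-like sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frtscan)
library(dplyr)
```

## The problem and the model

Flp recombinase acts on *FRT*, a 34-bp site made of two 13-bp inverted
Flp-binding elements around an 8-bp asymmetric spacer. Evolved Flp
variants can be made to act on genomic sequences that merely resemble
*FRT*, which turns every sufficiently FRT-like stretch of a genome into
a potential recombination target — and every *near*-identical stretch
into a potential off-target. `frtscan` finds, classifies and compares
these sequences with a deterministic rule model rather than a
probabilistic one (a PWM or HMM would also be natural here; the rule
model has the advantage that every rejection names the rule it broke,
and its thresholds correspond directly to mutational and
variant-evolvability observations).

The window anatomy is fixed: characters 1–13 are the left element
(positions −13…−1), 14–21 the spacer (s1…s8), 22–34 the right element
(positions 1…13). The default consensus is wild-type *FRT* with
degeneracy only where Flp variants are known to tolerate it: position
1 ∈ {A,G} (so −1 ∈ {C,T}) and ±2 ∈ {A,T}. We considered extending the
degeneracy further out but kept it at ±1/±2 only, since that is the
extent the functional data support; `load_consensus()` accepts any
IUPAC string per element, so a user with different evidence can relax
or tighten any position.

## Acceptance rules and their order

A window is accepted iff all of the following hold, evaluated in a
fixed order so `failure_reason` is deterministic (spacer first — it is
the cheapest and most selective filter — then composition, then
proximal-8 rules, then element rules):

1. only A/C/G/T after case folding (`non_acgt`);
2. spacer starts with T, ends with A, has ≤ 4 G/C bases
   (`spacer_ends`, `spacer_gc`);
3. no single-base run longer than 4 anywhere in the 34-mer
   (`homopolymer`);
4. proximal-8 region (−4…−1, 1…4): ≥ 5 matches
   (`proximal8_count`), no two adjacent mismatches within the same
   4-bp segment (`consecutive_mismatch_in_segment`), not both −1 and 1
   mismatched (`both_proximal_mismatch`), no G at −1 or C at 1
   (`forbidden_base_pm1`);
5. elements: a match at −7 or 7 (`position7`), ≥ 5 matches in at least
   one element (`element_matches`), and a run of ≥ 6 consecutive
   matches (`consecutive_run`).

All thresholds are `frt_consensus` fields with the defaults above,
overridable from YAML. Three parameter choices deserve comment:

* **The consecutive-run rule is ambiguous in prose** ("at least 6
  consecutive matches within both of its binding elements" can mean a
  run in at least one element, or in each). We evaluate the run per
  element and compare the *maximum* to the threshold, because the
  strict per-element reading would be close to unsatisfiable for
  class-5 sites, which have mismatches in both elements by
  construction. The strict reading remains available as
  `run_in_each_element: true`.
* **Score weights default to 1.0 at all 26 positions**, making the
  weighted score equal the overall match count. Position-specific
  weights are supported (`weights:` map in the config) but scores only
  annotate hits — they never gate acceptance — so the default is the
  neutral choice.
* **Non-ACGT windows are rejected, not errored.** Genome assemblies
  contain `N` runs and soft-masked lowercase; masking must not abort a
  scan, and lowercase is case-folded and scanned normally because
  FRT-like sites sit heavily in repeats.

Because the default allowed sets are reverse-complement symmetric and
every rule maps onto itself under reverse complement (G at −1 ↔ C at
+1, segment adjacency maps across the spacer, the spacer T…A maps to
itself), acceptance is reverse-complement closed. The scanner
therefore reads only the forward strand and still finds every
reverse-orientation site; tests assert closure on random windows and
whole synthetic genomes.

## Scanning and coordinates

`scan_contig()` evaluates every window in bounded chunks (default
10,000 bp with a 33-bp carry-over, the minimal overlap that makes
chunked output identical to whole-string output; the equivalence is
asserted by test rather than assumed). Internally the chunk becomes an
integer matrix with one row per window, so all rules are vectorised
matrix arithmetic — a 1-Mb contig takes a few seconds in plain R and
memory stays bounded regardless of contig size.

Genome runs take a directory of FASTA contigs plus a *manifest* (TSV:
`chromosome`, `order`, `contig_id`, `length`) declaring per-chromosome
contig order. Cumulative offsets place each hit on the linear
chromosome (`chrom_linear_pos`). We chose a manifest over hard-coding
contig filenames so any assembly layout works. Coordinates are 0-based
half-open internally and in BED exports, 1-based inclusive in TSV
reports — the two conventions genomics tooling expects.

Windows that would straddle a contig boundary are not scannable from
contig files; the synthetic-data generator therefore keeps planted
features clear of split points and derives its truth table per contig.

## Duplicates, classes, subclasses, spacers

Exact duplicates are pooled on the canonical 34-mer (lexicographic
minimum of the window and its reverse complement): groups of ≥ 2 form
the duplicated pool, singletons the unique pool, and
|hits| = |unique| + Σ copy\_number is asserted on every run. Duplicate
detection keeps only canonical keys in memory, never the genome.

Subclass identity is the proximal-8 sequence encoded base-by-base in
the order −4,−3,−2,−1,1,2,3,4 with A=1, T=2, G=3, C=4, taking the
lower of the forward code and the code of the reverse-complemented
site. A degenerate palindromic proximal-8 region is its own canonical
form (a fixed point, not an error). For classes 7–5 the subclass
distinguishes the concrete base at every proximal-8 position —
consistent with class 8 splitting by degenerate-base identity rather
than collapsing to one "all-match" bucket.

`enumerate_subclasses(k)` builds the theoretical catalogue by
enumerating all 4^8 = 65,536 proximal-8 sequences, applying only the
proximal-8-local rules (spacer and element rules cannot constrain the
proximal-8 pattern), and collapsing reverse-complement pairs. Under
the default consensus this yields **10** perfect-match subclasses
(2×2×2×2 degeneracy = 16 concrete patterns, 4 of them palindromic:
(16−4)/2 + 4 = 10) and 120 / 558 / 696 subclasses for classes 7 / 6 /
5. The original genome-wide human study that introduced this
classification reported 116 / 528 / 672 for the lower classes; its
published rule description does not fully determine those counts, so
we report our enumeration alongside that reference point rather than
forcing agreement, and the catalogue is exported with the rule set
that produced it.

Within a subclass, `group_spacers()` buckets sites on the canonical
spacer (lexicographic minimum over orientations), reading each
spacer in the site's canonical orientation first so that "same
subclass + same canonical spacer ⇒ recombination-compatible" is
orientation-consistent; comparing spacers in raw contig orientation
would split a site from its flipped twin, but that mode is available
(`raw_orientation = TRUE`) for comparison.

## Homology search

`identity_count()` is strict positionwise identity on the fixed-length
34-mer — no gaps, by design: recombinase sites do not align with
indels. Both orientations of the subject are compared and the maximum
taken (an as-stored mode exists behind `both_orientations = FALSE`).
`elements_only` mode excludes the spacer, useful because spacers can
be swapped experimentally while binding elements cannot.
`find_homologs()` excludes the query's own genomic copy by coordinate,
never by sequence: exact duplicates of the query elsewhere are
precisely the off-targets worth reporting. `subclass_report()` lists
the query's whole subclass regardless of threshold, since subclass
members share the functionally critical proximal-8 region and are the
first candidates for counter-selection targets.

## The synthetic-data generator

`simulate_genome()` emulates the aspects of real assemblies the
pipeline is sensitive to: multi-contig chromosomes with declared order,
background of configurable GC content, planted sites of chosen class
and orientation, and repeat families (a unit containing a site, copied
with optional per-copy point mutations). It does **not** emulate real
genome composition beyond GC — no CpG structure, no true repeat-family
phylogenies, no masking. Consequently i.i.d. background at mammalian
GC (~0.41) yields roughly one FRT-like site per ~18 kb, sparser than
the ~1 per 4–5 kb observed in the human genome, whose AT-rich tracts
and repeats enrich for sites. Passing tests on these fixtures
demonstrates correctness of the rules, coordinates, duplicate
structure and orientation handling — not that real-genome site
densities will be reproduced.

Ground truth is defined by a full scan of every generated contig (via
the same public rule set, and cross-checked in the test suite against
two independently written brute-force checkers, one in R and one in
Python), because random background legitimately contains FRT-like
sites: defining truth as "the planted list" would miscount those as
false positives. All randomness flows from the single `seed`.

```{r example}
genome <- simulate_genome(
  tibble::tibble(name = "chr1", length = 30000L, gc = 0.40),
  planted_sites = tibble::tibble(chromosome = "chr1", position = 5000L,
                                 class = 8L),
  seed = 20, dir = file.path(tempdir(), "vignette-demo"))
scan <- scan_genome(genome$dir, genome$manifest)
glance(scan)
tidy(scan) |> select(chrom_linear_pos, class, subclass_code, spacer)
```

## Numerical and degenerate-input choices

* Codes fit exactly in 32-bit integers (maximum 44,444,444), so
  subclass keys are plain R integers.
* Contigs shorter than 34 bp scan to an empty hit table; empty hit
  tables write header-only files.
* Overlapping occurrences of a site and its reverse complement at
  different offsets are distinct hits: distinct offsets, distinct
  windows. A fully palindromic accepted window is its own canonical
  form and simply counts once per offset.
* Rejection sampling in `random_site()` is capped (default 200
  tries); exhausting the cap signals an inconsistent rule model rather
  than looping forever.
* Problem sizes in the test suite — 10,000-window oracle comparisons,
  a 1-Mb genome for the full cross-implementation scan, 80–150-kb
  genomes for orientation and recovery checks — were chosen so the
  whole suite exercises every pathway at genome-like scale while
  completing in about two minutes.

## Known limitations

* The rule model is binary; it does not estimate recombination
  efficiency, and scores are annotations, not predictions.
* Homology is ungapped by construction.
* The generator's background is i.i.d.; conclusions about real-genome
  site *density* should come from scanning real assemblies (the
  scanner streams arbitrarily large contig sets in bounded memory).
* The theoretical subclass counts for classes 7–5 depend on exactly
  which proximal-8 rules are applied; alternative historical rule sets
  may partition them differently (see above).
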