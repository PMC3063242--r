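# frtscan

Genome-wide discovery, classification and comparison of **FRT-like
sequences** — degenerate pseudo-sites for Flp recombinase — in R.

The Flp/*FRT* system catalyzes precise site-specific recombination, but
only at *FRT* sites, which normally must be pre-inserted into the
genome. Directed evolution can produce Flp variants that instead
recombine pre-existing genomic sequences resembling *FRT*. Planning
such experiments needs a map of every FRT-like sequence a genome
already contains: where the candidate targets are, which ones share the
recognition features that let a single Flp variant act on both, and
which near-identical sites should serve as counter-selection targets to
keep the evolved variant specific. `frtscan` builds that map. It is
aimed at genome engineers choosing target and counter-selection sites,
and at anyone scanning genomes for spacer-constrained inverted-repeat
motifs under rule-based (rather than probabilistic) models.

## The site model

A minimal *FRT* site is 34 bp: two 13-bp inverted Flp-binding elements
(positions −13…−1 and 1…13) flanking an 8-bp asymmetric spacer
(s1…s8). The consensus allows A or G at position 1 (hence C or T at
−1) and A or T at positions ±2; all other element positions are fixed
at wild type. A 34-nt window is accepted as FRT-like iff:

* **spacer**: T at s1, A at s8, GC content ≤ 50% (≤ 4 of 8 bases);
* **proximal-8 region** (positions −4…−1, 1…4, the critical
  recognition determinants): ≥ 5 matches to consensus, no two adjacent
  mismatches within the same 4-bp segment, not both −1 and 1
  mismatched, no G at −1 and no C at 1;
* **elements**: a match at position −7 or 7, ≥ 5 matches within at
  least one element, and ≥ 6 consecutive matches within an element;
* **composition**: only A/C/G/T, no homopolymer run longer than 4.

The rule set is reverse-complement symmetric, so a single-strand scan
finds sites in either orientation. Accepted sites carry three
annotation scores (overall, weighted, consecutive matches), are
partitioned into *unique* and *exactly duplicated* pools (duplicates
keyed on the canonical 34-mer, i.e. orientation-independent), and are
classified by **class** (proximal-8 match count, 8…5) and **subclass**:
the proximal-8 bases encoded as an 8-digit number (A=1, T=2, G=3, C=4),
taking the lower of the forward and reverse-complement readings so a
site and its mirror image share one identity. Within a subclass, sites
whose spacers are identical in either orientation can in principle
recombine with each other and are grouped. A positionwise identity
search (optionally restricted to the 26 element positions) ranks
counter-selection candidates for any query site.

## Worked example

```r
library(frtscan)
library(dplyr)

# A seeded 50-kb fixture genome: two planted sites (class 8 and 6) and a
# repeat family carrying one site copied three times verbatim.
genome <- simulate_genome(
  tibble::tibble(name = "chr1", length = 50000L, gc = 0.40),
  planted_sites   = tibble::tibble(chromosome = "chr1",
                                   position = c(5000L, 12000L),
                                   class = c(8L, 6L)),
  repeat_families = tibble::tibble(chromosome = "chr1", copies = 3L,
                                   mutation_rate = 0),
  seed = 20, dir = file.path(tempdir(), "demo"))

scan <- scan_genome(genome$dir, genome$manifest)
scan
#> <frt_scan>
#>   50,000 bases scanned across 1 chromosome(s), 1 contig(s)
#>   7 FRT-like sites: 4 unique, 3 in 1 exact-duplicate group(s)
```

Seven sites: the two plants, the three verbatim repeat copies (pooled
into one duplicate group with `copy_number` 3), and two sites the
AT-rich random background produced on its own — random DNA at 40% GC
legitimately contains FRT-like sequences, which is why the generator's
truth table comes from a full scan, not the planted list.

```r
tidy(scan) |> count(class)
#> # A tibble: 2 × 2
#>   class     n
#>   <int> <int>
#> 1     6     2
#> 2     8     5

find_homologs(tidy(scan), frt_wildtype(), threshold = 20) |>
  select(rank, identity, chrom_linear_pos, class, subclass_code) |> head(3)
#> # A tibble: 3 × 5
#>    rank identity chrom_linear_pos class subclass_code
#>   <int>    <int>            <int> <int>         <int>
#> 1     1       27            20825     8      12123212
#> 2     2       27            31980     8      12123212
#> 3     3       27            40741     8      12123212
```

The top homologs of wild-type *FRT* here are the three repeat copies:
27 of 34 bases identical, perfect proximal-8 match (class 8) — exactly
the kind of off-target a counter-selection strategy must cover.

Single windows evaluate directly; the wild-type site is a perfect
class-8 hit whose canonical subclass code is 12143112 (the minimum of
its forward reading 12243212 and flipped reading 12143112):

```r
evaluate_window(frt_wildtype()) |>
  select(accepted, class, subclass_code, overall_score)
#> # A tibble: 1 × 4
#>   accepted class subclass_code overall_score
#>   <lgl>    <int>         <int>         <int>
#> 1 TRUE         8      12143112            26
```

`enumerate_subclasses(k)` gives the theoretical proximal-8 catalogue
(10 canonical subclasses for class 8), and the `inst/scripts/frtscan`
front-end exposes the pipeline as shell subcommands
(`scan → sort → spacers`, plus `compare`, `enumerate`, `simulate`).

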