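---
title: "How g4cr finds and quantifies G-quadruplex-containing regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How g4cr finds and quantifies G-quadruplex-containing regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4cr)
```

## The structural model

`g4cr` considers intramolecular, three-tetrad G-quadruplexes only: four
ordered tracts contributing three core guanines each (12 core G in
total), joined by three loops of 1–7 nt, with at most one bulge of 1–3
non-G residues extruded from inside a single tract (between its first and
second, or second and third, core guanine). Bulged guanines are excluded
because the variant with that G in the core is always more stable; loops,
by contrast, may freely contain guanines. Two-tetrad cores, four-or-more
tetrad cores, hairpin-stabilised long loops, topology (parallel /
antiparallel / hybrid) and inter-quadruplex stacking are all outside the
model, so the isomer counts reported here are a conservative lower bound
on the true conformational diversity of a locus.

## Stability scoring

Each candidate structure is ranked by

$$T_m^{est} = a - b\,\log_{10}(L_1 L_2 L_3) - d\,N_b - f\,(L_b - N_b)$$

with `a = 89.9`, `b = 19.2`, `d = 20`, `f = 8.5` (all °C) and a retention
threshold of 50 °C. The logarithmic loop term reflects the entropic cost
of loop closure (approximately linear in log loop length in published
melting series); the intercept `a` is, by construction, the score of the
minimal `(G3T)3G3` layout, which is why base-10 logarithms are the only
choice consistent with that reading. The bulge penalties are the merged
values of two potassium-concentration-specific fits (d = 20.5 and 19.4,
f = 8.5 in both); the salt-specific intercepts and slopes are recorded in
the package source for documentation but never used for scoring. The
score is a *ranking* statistic tied to plausible melting temperatures,
not a thermodynamic prediction — no salt, pH or crowding corrections are
attempted, and refitting the constants is deliberately out of scope.

Threshold comparisons are plain floating-point `>=` against the printed
constants, with no epsilon. The two borderline families come out as
intended: a loop product of 120 scores 49.98 °C and is excluded
(product 119 scores 50.05 °C and is kept), and the best possible
two-bulge configuration scores exactly 49.9 °C, which is why the
enumeration never needs to consider more than one bulge.

## Mask enumeration and scanning

All admissible layouts are enumerated as numeric mask rows — core 1,
loop 0, bulge 13 — giving `7^3 * (8*3 + 1) = 8575` masks, 699 of which
pass the threshold (widths 15–28 columns; the unfiltered widths span
15–36). The value 13 makes the dot product against a 0/1 guanine
indicator window diagnostic: exactly 12 means "all cores are G and no
bulge column is G"; below 12 a core is missing; 13 or more means a bulged
guanine, which is rejected.

Scanning is restricted to candidate segments obtained by deleting every
non-G run longer than the maximum loop length and trimming to G
boundaries; segments with fewer than 12 guanines cannot host a core and
are dropped. Since every mask begins and ends with a core column, no
match can cross a deleted run, so this restriction is lossless. Masks are
grouped by width and each group is applied to all windows of a candidate
with one matrix multiplication.

Distinct (mask, offset) placements always yield distinct core sets, so
the scanner performs no deduplication; this bijection, and the
correctness of the whole scanning path, are enforced in the test suite by
comparison against `oracle_enumerate()`, a brute-force enumerator that
works directly on tract placements and shares no code with the mask
machinery.

One worked subtlety: for the candidate segment `GGGTGGGAGTGGGGTGGG` both
routes find **five** isomers — the two G-register isomers of the `GGGG`
run, one isomer recruiting the isolated G via a single-residue bulge
(cores at the segment's 9th, 11th and 12th residues), and two further
isomers using the bulged tract `G,G,(A),G` across the `A` with either
register of the `GGGG` run. Sketches of this example sometimes miss the
last two; the enumerator settles the count.

## Regions and polymorphism statistics

Matches from one sequence and strand are assembled into G4-containing
regions (G4CRs) as connected components of footprint overlap — footprint
meaning the whole interval including loops and bulges, since the defining
property of a G4CR is that *every* residue can take part in at least one
stable structure in some role. Per region:

* `n_tot` is the number of member isomers (distinct 12-G core sets);
* `n_tand` is the maximum number of members with pairwise disjoint
  footprints, computed by the earliest-footprint-end greedy rule, which
  is provably optimal for interval scheduling (and is cross-checked
  against exhaustive maximum-independent-set search in the tests);
* the multiplicity of each position is the number of member cores using
  it, so the track always sums to `12 * n_tot`;
* ties for the most stable isomer are all reported (`n_max_tm`), never
  broken arbitrarily; output ordering is by start then mask id.

G-content is computed on the scanned strand only (C residues of the
source when scanning the reverse complement); strand-level results are
never merged at region level. Coordinates are 0-based half-open
throughout, including BED output; the TSV writers state this in their
header comments.

## Promoter analyses

Windows of −1999..+2000 around each TSS (offset 0 = the TSS base, 4000
positions) are cut from a genome and oriented along transcription, so
minus-strand genes are reverse-complemented. Both window strands are
scanned separately ("coding" = the oriented window, "noncoding" = its
reverse complement mapped back to window offsets). Regions are classified
by nearest-rank quantiles (edges at the 50th, 75th and 99th percentiles;
ties fall into the lower bin), and the positional distribution of a class
is the per-offset fraction of windows in which the offset lies inside a
class member, normalised to sum to 1 over the window so common and rare
classes are comparable. Two conventions were genuinely open and are
resolved as follows:

* truncated windows (contig edges) contribute only at offsets they
  actually cover, and the per-offset denominator is the number of
  covering windows, not all windows — flagged in the output;
* classes with no members are reported as zero vectors with an
  `empty_classes` attribute rather than being normalised (0/0).

The enrichment ratio compares mean probability over offsets −200..0 to
−1500..−1300; a flat profile gives 1 and an empty far window is reported
as `Inf` with a flag. The null model is a per-window mononucleotide
shuffle — the reference shuffle order is not specified by convention, and
the mononucleotide version is the weakest (hence most conservative for
detecting clustering) composition-preserving null; it is seedable and the
seed is the caller's to record. Promoter tables can be deduplicated to
each gene's first promoter for region statistics (gene identity = id
minus a trailing `_<n>` suffix), while positional analyses conventionally
use all promoters; the two modes coincide when every gene has one
promoter.

## Synthetic data and what the tests do (and do not) show

The generator plants G-tract islands of chosen tract lengths and spacers
into i.i.d. random backgrounds of chosen GC content, with an optional
8-nt non-G buffer so background guanines cannot extend the island across
the 7-nt loop limit. It emulates controlled quadruplex content and
placement, *not* real promoter base composition: no CpG islands, repeats,
or dinucleotide structure. Passing tests therefore demonstrate
algorithmic correctness (scanner = enumerator, conservation identities,
mirror symmetry, determinism), not biological recall on genomes. Test
problem sizes are deliberately desk-scale: the scanner/enumerator
equivalence runs on 500 random sequences of 20–40 nt (half at symmetric
mixed GC, half G-skewed so that a substantial fraction actually contains
quadruplexes), and promoter machinery is exercised on synthetic
multi-kilobase contigs with planted islands. Genome-scale summaries
(median region length, TSS enrichment folds, per-gene incidence on real
promoter databases) require external genome and promoter downloads and
are intentionally not asserted anywhere in the package.

## Numerical and degenerate-input choices

* Loop lengths below 1 are an error (the log of zero is never evaluated).
* `Tm_est` values are kept at full precision internally; tables round to
  one decimal only at presentation time.
* Empty sequences are an error; sequences without candidates return
  empty, typed tibbles. IUPAC ambiguity codes count as non-G: they may
  sit in loops or bulges but never in cores, and matches whose footprint
  contains any non-ACGT character carry an `ambiguous` flag.
* Positional probabilities are checked to sum to 1 within 1e-9 whenever a
  class is populated.

## Known limitations

The isomer catalogue is conservative by design (three tetrads, loops
≤ 7, one bulge ≤ 3, no bulged G); regions formed by structures outside
the model (e.g. long hairpin loops) are under-segmented or missed.
Isomer counts treat all stable isomers equally — no Boltzmann weighting
of relative populations is attempted. The brute-force enumerator refuses
sequences beyond 60 nt by default to guard against combinatorial blowup;
it is a correctness referee, not a production scanner.
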