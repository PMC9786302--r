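# g4cr

Identification and polymorphism analysis of G-quadruplex-containing
regions (G4CRs) in DNA.

## The problem

Intramolecular G-quadruplexes (G4s) are four-stranded structures formed
when four tracts of guanines assemble into three stacked G-tetrads. G-rich
promoter DNA usually contains *more* guanines than one core can use, so a
single locus folds into an ensemble of structural isomers: G-register
shifts within long tracts, "spare-tire" substitution of whole tracts, and
bulged variants. Most motif scanners collapse this ensemble to one hit;
`g4cr` instead treats the **G4-containing region** — a maximal stretch in
which every residue can participate in at least one stable G4 (as core,
loop or bulge) — as the unit of analysis, and quantifies how polymorphic
each region is. It is aimed at genomics and nucleic-acid biophysics
researchers who want per-region and per-residue measures of G4 structural
heterogeneity, e.g. around transcription start sites.

## The model

A putative G4 is four ordered tracts of three core guanines, connected by
loops of 1–7 nt, with at most one bulge of 1–3 non-G residues inside one
tract. Its stability is ranked by an empirical melting-temperature
estimate

```
Tm_est(L1, L2, L3, Nb, Lb) = a − b·log10(L1·L2·L3) − d·Nb − f·(Lb − Nb)
```

with defaults `a = 89.9`, `b = 19.2`, `d = 20`, `f = 8.5` (°C) fitted to
published melting data; a structure is kept when `Tm_est ≥ 50 °C`. Two or
more bulges can never reach that threshold (best case 49.9 °C), which is
why the enumeration stops at one.

All admissible core/loop/bulge layouts are enumerated as numeric masks
(core = 1, loop = 0, bulge = 13): `7³ × (8·3 + 1) = 8575` layouts, of
which 699 are stable. A sequence is encoded as a 0/1 guanine indicator,
split into G-dense candidate segments (no non-G run longer than 7, at
least 12 G), and every mask is slid across every segment; a window whose
dot product with a mask row equals exactly 12 is one stable isomer
(distinct set of 12 core guanines). Overlapping isomer footprints are
merged into G4CRs, for which the package reports:

* `n_tot` — number of distinct isomers (distinct 12-G core sets),
* `n_tand` — maximum number of isomers with disjoint footprints
  (simultaneously foldable tandem G4s),
* per-guanine folding **multiplicity** (Σ multiplicity = 12 · `n_tot`),
* `max_tm` and the isomers tied for it.

## Worked example

The Pu27 region of the human *MYC* promoter (two GGG tracts, three GGGG
tracts):

```r
library(g4cr)
fit <- g4_analyze(c(pu27 = "TGGGGAGGGTGGGGAGGGTGGGGAAGG"))
fit
#> <g4_analysis> 1 sequence(s): 46 isomer(s) in 1 region(s); 699 stable masks, threshold 50.0 degC
#> # A tibble: 1 × 10
#>   seq_id strand start   end length g_content n_tot n_tand max_tm n_max_tm
#>   <chr>  <chr>  <int> <int>  <int>     <dbl> <int>  <int>  <dbl>    <int>
#> 1 pu27   +          1    23     22     0.818    46      1   84.1        4

fit$regions$multiplicity[[1]]
#> [1] 15 35 38 27  0 36 34 31  0 21 39 39 21  0 31 34 36  0 27 38 35 15
```

One G4CR of 22 nt (0-based half-open interval [1, 23), i.e. excluding the
leading T and trailing AGG, which no stable isomer can recruit) that folds
into 46 distinct isomers, only one at a time (`n_tand = 1`). The most
stable isomers score 84.1 °C (loop-length product 2, no bulge; four
isomers tie, `n_max_tm = 4`),
and the multiplicity track shows which guanines the ensemble relies on
most (39 of 46 isomers use the central Gs; the outermost tract guanines
take part in only 15). `tidy(fit)`, `glance(fit)` and `autoplot(fit)` give
the region table, a one-row summary and the multiplicity plot.

For promoter sets: `extract_windows()` cuts −1999..+2000 windows around
each TSS, `scan_windows()` scans coding and template strands,
`classify_regions()` bins regions by length/G-content/`n_tot`/`n_tand`
quantiles (bottom 50%, 50–75%, 76–99%, top 1%), and
`positional_distribution()` / `enrichment_ratio()` quantify TSS
clustering; `shuffle_windows()` provides the composition-preserving null.
A command-line wrapper for batch use ships in `inst/scripts/g4cr`
(subcommands `motifs`, `scan`, `promoters`, `shuffle`).

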