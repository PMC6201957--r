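# spacerclust

Marker comparison for fungal ITS metabarcoding: how much do analyses built
on the full internal transcribed spacer (ITS), the ITS1 spacer, or the
ITS2 spacer disagree — on the *same* underlying reads?

Fungal community surveys cluster reads into OTUs at an identity threshold
(conventionally 97%) and assign taxonomy from the cluster representatives.
Because short-read platforms capture only one spacer, the choice between
ITS1 and ITS2 silently changes OTU counts, richness estimates, and
taxonomic calls. `spacerclust` is for people who want that effect
quantified under controlled conditions: it simulates fungal communities
with known taxonomy and known ITS1/5.8S/ITS2 decomposition, runs the full
marker-comparison pipeline on them, and measures the disagreement.

The core statistic is the cross-clustering **commonality**

    A = (Σᵢ mᵢ) / N

between two OTU sets built from the same reads: `N` reads in database 1,
and for each of its OTUs, `mᵢ` the reads it shares with the database-2 OTU
containing its representative sequence. `A(c, c) = 1`; a database 2 that
splits database 1's clusters drives `A` down; both directions of every
pair are reported (the statistic is asymmetric), plus their mean.

What the package provides, end to end:

* a synthetic-community generator (taxonomy → genus ancestors → species
  references → per-copy intraspecific variants → barcoded 454-style reads
  with a quality model) whose every stage has exact ground truth;
* anchor-motif extraction of ITS1/ITS2 from full-length spacers (the role
  profile-HMM scanners play in production pipelines), exactly testable on
  the generator's ground truth;
* greedy centroid OTU clustering (UCLUST-style first-hit assignment) at
  configurable identity thresholds, on a semi-global alignment identity
  with free terminal gaps — implemented in C++ and property-tested against
  a plain-R brute-force oracle;
* bias-corrected Chao1, Shannon diversity, Bray–Curtis/UPGMA sample
  dendrograms;
* commonality, species-per-OTU, taxonomic self-return / species-agreement
  rates, rank-level classified/unclassified composition;
* exact small-sample tests (permutation Mann–Whitney U, Fisher's exact)
  for group comparisons;
* two orchestrated studies: `run_insilico_comparison()` (database-style)
  and `run_amplicon_comparison()` (multi-sample read survey), both writing
  a complete TSV/FASTA/newick bundle with a JSON manifest.

## Worked example

```r
library(spacerclust)

spec   <- default_community_spec(seed = 1)   # 5 genera × 10 species × 20 copies
report <- run_insilico_comparison(spec, thresholds = 0.97)

dplyr::select(report$otu_counts, region, n_otus)
#> # A tibble: 3 × 2
#>   region n_otus
#>   <chr>   <int>
#> 1 ITS        56
#> 2 ITS1      293
#> 3 ITS2       67

dplyr::select(report$commonality, db1, db2, A)[1:6, ]
#> # A tibble: 6 × 3
#>   db1   db2       A
#>   <chr> <chr> <dbl>
#> 1 ITS   ITS1  0.529
#> 2 ITS   ITS2  0.750
#> 3 ITS1  ITS   0.915
#> 4 ITS1  ITS2  0.804
#> 5 ITS2  ITS   0.702
#> 6 ITS2  ITS1  0.412
```

Read: at 97% identity the faster-evolving ITS1 shatters the 50-species
community into 293 OTUs where ITS2 gives 67 and the full ITS 56; the
full-length clustering agrees better with ITS2 (`A(ITS→ITS2) = 0.75`)
than with ITS1 (`A(ITS→ITS1) = 0.53`), and the two spacers agree worst of
all in the ITS2→ITS1 direction (0.41) — the in-silico incarnation of the
field observation that single-spacer surveys, especially ITS1, overstate
richness and scatter clusters.

`report$species_per_otu`, `report$diversity`, `report$taxonomy$rates` and
`report$metrics` hold the species-lumping curves, Chao1/Shannon values,
self-return/species-agreement rates and the length/GC tables;
`plot_commonality()`, `plot_species_per_otu()` and `autoplot()` draw them.

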