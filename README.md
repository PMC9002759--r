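# awbox

Motif analysis of the **AW box**, the 14-bp cis-regulatory element bound by
the WRINKLED1 (WRI1) transcription factor upstream of plant fatty-acid
biosynthesis genes — scanning, position matrices, forbidden-base analysis
and WRI1-bindability classification, with sunflower as the worked system.

## The problem

WRI1, an AP2/EREBP transcription factor, activates the genes of plastidial
fatty-acid synthesis by binding the AW box

```
C N T N G N N N N N N N C G
1 2 3 4 5 6 7 8 9 ...  13 14
  N1  N2  N3 N4 N5 N6 N7 N8 N9
```

with fixed bases at positions 1, 3, 5 and 13–14 and nine variable
N positions. Presence of the motif alone does not predict binding: in
electrophoretic mobility shift assays (EMSA) on sunflower promoters, only
18 of 52 canonical boxes analysed were clearly bound. Binding is

* **position-sensitive** — active boxes sit close to the translation
  initiation site (TIS, the ATG), usually inside the 5′-UTR; and
* **sequence-sensitive** — among bound boxes certain bases never occur at
  certain N positions ("forbidden" bases: G at N1/N2/N8/N9, A at N4, C at
  N3/N6), and N2/N6 are strongly biased toward C/A.

This package turns that analysis into a reusable, tested pipeline: a
signed no-zero TIS coordinate system (−1 abuts +1; +1 is the A of the
ATG), strand-aware scanning for canonical boxes and for 15-bp "extra
base" variants (which WRI1 can also bind), PFM/PPM/PWM construction from
a bound training set, forbidden-base/bias reports, derivation of the
degenerate consensus `CHTCGWKWAYWYCG`, a rule-based bindability
classifier, the complete labelled sunflower box inventory as a packaged
fixture, and a seeded synthetic promoter generator for end-to-end
validation.

## Worked example

```r
library(awbox)

## scan a promoter: the FATA1 box embedded in flanking sequence
scanAWBox("AAAAACCTCGTGCATATCGAAAAA", tisIndex = 24)
#>   gene_id local_start local_end tis_start tis_end strand   variant
#> 1     seq           5        19       -19      -6      + canonical
#>   insertion_offset    matched_seq
#> 1               NA CCTCGTGCATATCG

## the packaged bound set and its forbidden-base analysis
fx  <- loadAWBoxFixtures()           # 79 records; 52 EMSA-tested canonical
pfm <- buildPFM(boundSequences(fx))  # 18 bound motifs
forbiddenAndBias(pfm)
#> ForbiddenReport over 18 bound motifs
#>   N1 forbidden: G       bias: A,C (0.39)
#>   N2 forbidden: G       bias: C (0.72)
#>   N3 forbidden: C       bias: T (0.44)
#>   N4 forbidden: A       bias: T (0.50)
#>   N5 forbidden: -       bias: A,T (0.39)
#>   N6 forbidden: C       bias: A (0.67)
#>   N7 forbidden: -       bias: T (0.39)
#>   N8 forbidden: G       bias: T (0.50)
#>   N9 forbidden: G       bias: C (0.50)

iupacConsensus(buildPPM(pfm, 0))
#> [1] "CHTCGWKWAYWYCG"

## classify a candidate that EMSA showed not to bind
prof <- fitProfile(boundSequences(fx))
predictBinding(prof, "CTTGGAGTACTCCG", tisStart = -277)
#> $label   "not-bindable"
#> $reasons "forbidden base G at N2"
```

The forbidden sets say: a G at N2 (or any other forbidden base at its
position) has never been observed in a box that binds WRI1, so the
candidate is predicted non-binding — with the violated position named.
`runReproduction(outdir)` executes the whole pipeline (matrices,
consensus, classification of all 52 tested boxes) and writes the report
bundle to `outdir`.

## Layout

* `R/` — implementation (S4 classes over Biostrings containers)
* `inst/extdata/awbox_fixtures.tsv` — the labelled AW-box inventory
* `tests/testthat/` — unit, property and acceptance tests
* `vignettes/awbox-methods.Rmd` — the methods vignette (model,
  parameters, design choices, limitations)
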