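---
title: "AW-box analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AW-box analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awbox)
```

# The model

The AW box is the WRI1 binding element `CNTNG(N)7CG`: a 14-mer with five
fixed bases (C1, T3, G5, C13, G14) and nine variable positions N1..N9
(motif slots 2, 4, 6..12). Two empirical regularities govern whether WRI1
actually binds a given box:

1. **Position.** Active boxes lie close to the translation initiation
   site (TIS), typically inside the 5′-UTR; boxes far upstream fail to
   bind even when their sequence is unexceptional.
2. **Sequence at the N positions.** Among boxes that clearly bind in
   EMSA, some bases are never observed at particular N positions. These
   *forbidden* bases (G at N1, N2, N8, N9; A at N4; C at N3, N6 in the
   packaged sunflower training set) predict non-binding, and the N2/N6
   positions carry a strong C/A bias. Nearly every EMSA-negative
   canonical box carries at least one forbidden base; the handful that
   do not are explained by unfavourable base combinations at N2/N6 and
   are reported as such, not hidden inside an accuracy figure.

WRI1 can additionally bind a *non-canonical* box: a 15-mer that matches
the canonical pattern after deletion of one internal "extra" base. The
scanner therefore supports an insertion-tolerant mode, and the
classifier routes such variants past the canonical rule, flagging them
as non-canonical with bound precedent rather than forcing them through
a matrix trained on 14-mers.

# Coordinates

All positions are signed distances from the TIS with **no position 0**:
+1 is the A of the ATG, −1 the base just 5′ of it. Under this convention
the printed arithmetic of assay fragments is exact: a fragment from −272
to +51 is 323 bp, and a 14-bp box starting at −110 ends at −97
(`spanLength()`, `spanEnd()`). Promoter-local indices are 0-based and
half-open; `indexToTis()`/`tisToIndex()` convert and round-trip over
every valid index.

# Scanning

`scanAWBox()` slides a 14-bp window over the sequence (and its reverse
complement for minus-strand hits), matching the five fixed slots;
sequence `N` characters never match any slot — a conservative choice
that avoids phantom hits in ambiguous sequence. Minus-strand hits report
the coordinates of the occupied span on the coding strand, ascending,
with the matched sequence as read on the matched strand; the published
inventories list positions the same way regardless of strand.
Near-palindromic sites legitimately produce a hit on each strand over
the same span; both are reported, and `dedupe = TRUE` collapses
identical spans when a single footprint per site is wanted.

With `maxInsertions = 1` the scanner additionally reports every 15-bp
window that matches after deleting one internal base. Deletions that
would disturb the 5′ C or split the 3′ CG anchor are not considered
(valid offsets 2..13). Runs of identical bases make several deletion
offsets equivalent; the scanner deterministically reports the 5′-most.
Because a designed probe may designate a *specific* base as the
insertion (the extra-base probe mutated in the published mutagenesis
series designates probe position 4), `substituteInsertedBase()` takes
the offset explicitly and `insertionOffsets()` enumerates the valid
choices.

The distance gate (`distanceGate()`) is inclusive, with a default of
500 bp — the selection window within which boxes were chosen for the
binding assays; 200 bp is the stricter literature bound for active boxes
and is available by argument. The 5′-UTR condition applies only when the
promoter carries a UTR annotation.

# The packaged inventory and the bound training set

`inst/extdata/awbox_fixtures.tsv` transcribes the published sunflower
AW-box inventory: 79 records (74 natural canonical boxes, two
extra-base boxes, three mutagenesis probes), of which 52 canonical
boxes were analysed by EMSA — 18 bound, 25 unbound, 9 smears. Smears
(weak/unstable binding) are a distinct label, held out of the training
set, which contains only sequences that clearly bound.

Two reconstruction choices deserve record:

* **The 18th bound member.** The main text enumerates 17 clearly-bound
  natural boxes; the definitive roster lives in a figure whose binding
  colours are not machine-readable here. This package adopts the KAR1
  *mut A/C* probe (`CTTCGATTATATCG`, a canonical 14-mer that produced a
  visible shift) as the 18th member. Counting the two canonical KAR1
  mutant probes among the EMSA-analysed canonical motifs is also the
  only reading that reaches exactly 52 tested; the resulting set
  reproduces every published forbidden base, the N2/N6 bias and the
  printed consensus. The record is flagged `provisional-18th` in the
  fixture file.
* **Recomputed ends.** A few printed spans are inconsistent with their
  sequence length under the no-zero convention (they would be 15, 20 or
  54 bp wide for a 14-mer). The fixture keeps the printed start and
  recomputes the end as `spanEnd(start, nchar(seq))`; such rows are
  flagged `end-recomputed`. Rows whose tested/untested status is not
  stated in the running text are flagged `tested-inferred`.

# Matrices and the consensus

`buildPFM()` tallies raw counts over the 14 slots; column sums conserve
the number of sequences. **Forbidden-base detection always uses raw
counts** — the zeros are the signal, and a pseudocount would erase them.
`buildPPM(pfm, pseudocount)` normalises with an optional pseudocount
(`(count + p) / (n + 4p)` per slot), and `buildPWM()` takes log2 odds
against a background composition. The PWM default pseudocount is 0.5,
avoiding −∞ weights; the background defaults to uniform 0.25 and is an
argument, because the genomic base frequencies used to fit the published
weight matrix are not printed in the source analysis and so cannot be
hard-coded responsibly.

`iupacConsensus()` emits, per N slot, the minimal IUPAC code covering
all bases with probability ≥ `includeThreshold`, except that in
`bias-collapse` mode a slot whose top base reaches `collapseThreshold`
collapses to that single base. The defaults are
`includeThreshold = 0.2` and `collapseThreshold = 0.6`. They were chosen
from the structure of the training set, not tuned per slot: with 18
sequences, an inclusion cut of 0.2 keeps bases seen ≥ 4 times and drops
bases seen ≤ 3 times, which is exactly the boundary separating the
minor third bases (3/18) from the codes the published motif prints
(e.g. W rather than D at N3); a collapse cut of 0.6 fires only at the
two genuinely dominant positions (N2 at 0.72, N6 at 0.67) and not at
positions whose top base sits at exactly 0.50. Under these documented
defaults the bound set yields `CHTCGWKWAYWYCG`. Both numbers are
configuration, not constants; `inclusion` mode disables collapsing
entirely, and raising the inclusion threshold can only narrow a slot's
code (a tested monotonicity property).

```{r consensus}
pfm <- buildPFM(boundSequences())
forbiddenAndBias(pfm)
iupacConsensus(buildPPM(pfm, 0))
```

# The classifier

`fitProfile()` stores, per N position, the set of bases observed in
training (the complement of the forbidden set), the N2/N6 bias bases,
the distance-gate parameters and a PWM. The default decision rule is
`strict-forbidden` — reject iff any N position carries a forbidden base
— because that is the published mechanism. `allowed-profile` mode is a
formalisation of "forbidden bases plus bias" that this package defines
(the source analysis states no combined rule): it rejects any base not
in the allowed set, which makes it at least as strict as
strict-forbidden on any input and identical when the profile comes
straight from `fitProfile()`. `pwm-threshold` mode ranks by log-odds
score; it has no anchored default threshold and is provided for
exploratory ranking only. `evaluateProfile()` reports the full
per-record explanation table and confusion counts; it deliberately does
not distil a headline accuracy, since the unbound-without-forbidden-base
exceptions are real and documented. Smear records are never scored.

# The synthetic generator

`simulatePromoters()` emulates what the analysis assumes about real
promoters and nothing more: i.i.d. background at a configurable base
composition with boxes planted at controlled TIS distances and strands
(bound-pool, unbound-pool, explicit, forbidden-decoy, insertion
variants). The TIS sits `tisOffset` bases before the 3′ end (default
51, mirroring the TIS-crossing design of the assay fragments) so
sign-crossing coordinate code is exercised by default. The seed is
mandatory — there is no hidden entropy — and identical configurations
produce byte-identical FASTA and truth files. Background chance hits
are expected (five fixed positions recur roughly once per 4^5 ≈ 1 kb
per strand under uniform composition), so truth-aware evaluation
(`compareToTruth()`) separates planted from incidental hits instead of
asserting zero background matches.

What passing tests on synthetic data do **not** show: real promoters
are not i.i.d. (CpG structure, TATA context, nucleosome positioning and
conservation all shape real motif neighbourhoods), and EMSA labels are
wet-lab measurements that no simulation here reproduces. Synthetic
recall/specificity of 100% is a pipeline smoke test, not a biological
claim.

# Problem sizes and determinism

The test suite runs the scanner-vs-oracle property on dozens of random
sequences up to 200 bp, simulates tens of promoters of 0.4–10 kb, and
reruns the full reproduction pipeline twice to assert byte-identical
outputs; these sizes exercise every code path while keeping the default
suite fast. All randomness flows through explicit seeds; scanning,
matrix construction and classification are deterministic functions of
their inputs.

# Known limitations

* The 18th bound training member is provisional (above); swapping it
  for another candidate would perturb bias probabilities but none of
  the forbidden sets asserted by the tests, which come from the 17
  unambiguous members plus pattern structure.
* The classifier is a rule system, not a binding-affinity model; smears
  sit outside it, and no free-energy or structural modelling of the
  AP2-domain–DNA interface is attempted.
* Consensus derivation reproduces the printed motif under documented
  thresholds; it does not emulate the normalisation of any specific
  external logo/motif tool.
* Scanning targets promoter-scale inputs; genome-scale scanning and
  coordinate liftover are out of scope.
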