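---
title: "Methods: scanning, scoring and dating purine-rich elements at 3' splice sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning, scoring and dating purine-rich elements at 3' splice sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repascan)
```

## The biological question

Acceptor splice sites end in (Y)nNYAG: a polypyrimidine tract for U2AF65,
then the 3' AG for U2AF35, with almost no room between them. A group of
mammalian acceptors nevertheless carries purine-rich sequence — most
strikingly G tracts, runs of three or more guanosines bound by hnRNP H/F —
precisely between the pyrimidine tract and the AG. Such elements weaken
the acceptor and act as intronic splicing silencers, biasing splicing
toward alternative 3' splice sites and intron retention. `repascan`
provides the computational side of that analysis: find the sites, measure
their strength, classify the associated alternative splicing, test the
enrichments, and date the evolutionary emergence of the tracts.

## Coordinates and the acceptor scan

All positions are intron-relative and skip zero: -1 is the last intronic
base (the G of the acceptor AG), +1 the first exonic base. This matches
how the field labels acceptor positions and removes the classic
off-by-one trap; the single conversion point to genomic and BED
coordinates lives in one utility (`pos_to_index()`, `write_sites_bed()`).
GTF input is 1-based closed; BED output is 0-based half-open.

A site is a **purine-rich (REPA) candidate** when

* the acceptor dinucleotide (-2..-1) is `AG`, and
* the A/G fraction over -10..-3 is **strictly** greater than 0.60.

With eight informative positions the strict inequality means 5/8 passes
and 4/8 fails. `N` bases (soft-masked or ambiguous genome sequence is
uppercased, `N` retained) are removed from the denominator; a window that
is all `N` in the interval is undefined and never called.

**G tracts** are maximal runs of G — no sub-runs are reported — searched
over -15..-3: wide enough to catch tracts extending 5' of the tested
interval, while runs are required to lie entirely inside the search
interval, so a run continuing past either boundary (in particular toward
the AG, which a silencer tract cannot invade) is not a tract. Runs of
3-8 Gs are the reported range; longer runs are kept with their true
length and an `over_cap` flag rather than clipped. Per site, histograms
use one representative tract: the 5'-most, with longest-then-most-3' as
the (unreachable for maximal runs, but fixed) tie-break.

Hexamer/pentamer **group labels** (`gtggaa`, `aaataa`, `ggggg`, `ggaaa`,
`gaaaa`) are literal motif matches anywhere in -12..-3, resolved by a
fixed precedence list (longer motifs first, then the G-richer of equal
length); a site matching no motif but carrying a purine at -3 — the
consensus position that should be a pyrimidine — is `nnnrag_like`, and
everything else is `other`. The precedence order is a package decision:
each site must land in exactly one group, and no published tie rule
exists.

## Acceptor strength: a maximum-entropy model

Acceptor strength is scored over 23-nt windows (20 intronic + 3 exonic
bases) as the log-odds, in bits, of the window under two normalized
sequence models:

$$\mathrm{score}(w) = \log_2 P_{\mathrm{signal}}(w) -
  \log_2 P_{\mathrm{background}}(w).$$

Each model is the maximum-entropy distribution subject to marginal
constraints estimated from training sequences. Two constraint sets are
supported:

* `"singleton"` — per-position base marginals. The fit has the closed
  form of the product of (smoothed) marginals, i.e. exactly a position
  weight matrix; this limit is verified in the tests by exhaustive
  enumeration at window length 4.
* singleton + `"adjacent_pair"` (default) — adds the 16 joint marginals
  of every adjacent position pair, a maximum-entropy Markov-1 equivalent
  that captures neighbour dependence while staying exactly tractable.

Empirical targets get Laplace smoothing (+0.5 pseudocount) so every
A/C/G/T window has finite probability and every score is finite. With
pairwise constraints the singleton targets are taken as the margins of
the smoothed pair targets — adjacent smoothed pairs share consistent
margins, so the constraint system is exactly satisfiable; smoothing
singletons separately would leave no distribution satisfying all
constraints at once.

Fitting uses iterative proportional scaling of the clique marginals with
exact inference on the chain (forward-backward over 4 states per
position; the partition function is exact, no sampling). For this
decomposable constraint set an ordered sweep over the cliques converges
essentially immediately; the stopping rule is a maximum marginal
residual below 1e-4 (typically ~1e-16 after one or two sweeps), and
non-convergence is an error carrying the residual. The fit is
deterministic: no random initialization is involved. Normalization and
constraint satisfaction are asserted by brute-force summation over all
sequences at reduced window lengths (4 and 5) in the test suite.

The published acceptor-model parameters from the original
maximum-entropy splice-site framework are **not** bundled: the package
trains on user or synthetic data (and a JSON serialization allows
loading externally fitted parameters). Consequently absolute score
values are not comparable to that service's output; only orderings are
meaningful here, and those are what the tests assert — constitutive
acceptors outscore purine-rich ones under a model trained on generator
output, and inserting a G pentamer at -10..-6 strictly lowers a
constitutive window's score.

Group comparisons use the classic equal-variance two-sample two-tailed
t-test against a reference group, cross-checked in the tests against the
exact permutation distribution on a small example.

## Alternative-splicing classification

Events come from pairwise comparison of the transcripts of each gene:

* **cassette exon** — an internal exon of one transcript absent from the
  other while both flanking splice junctions are shared;
* **alternative 3'SS** — two introns sharing a donor but differing at
  the acceptor; **alternative 5'SS** — the mirror case;
* **retained intron** — an intron of one transcript fully contained
  within a single exon of the other.

Two guards keep the definitions disjoint: an alt-3'/5' candidate is
rejected when a complete exon of either transcript lies between the two
alternative boundaries (that is a skipping junction, not a shifted
splice site), and one genomic region satisfying several definitions is
resolved by the fixed precedence retained_intron > alt_3ss > alt_5ss >
cassette_exon. Events are deduplicated across transcript pairs;
detection is symmetric in transcript order. A site is *alternative* when
an event's defining acceptor equals its acceptor coordinate or the event
interval covers it; a site may carry several types. Establishing AS
status from multi-isoform annotation (rather than from EST/mRNA
alignment in a genome browser) is a deliberate substitution that keeps
the pipeline self-contained; mutually exclusive exons and alternative
first/last exons are not itemized and fall into no event (a documented
limitation).

Type proportions are computed among associated sites, and fold
enrichment divides each type's proportion by a user-supplied reference
proportion (a transcriptome-wide survey distribution, passed as
configuration, since no such survey ships with the package).

## Statistics

`hypergeom_upper(k, K, n, N)` sums P(X >= k) term by term in log space
(log-sum-exp over `dhyper(log = TRUE)` terms), so deep tails keep their
exact value instead of printing 0; p-values below 1e-300 are flagged as
at risk of underflow in double precision. The Fisher right tail on a
2x2 table is the same quantity, and the tests assert both against full
enumeration of all draws for populations up to 12 and against base R.
Positional purine enrichment tests each position's query purine count
within the pooled query+background population. Gene-set enrichment is
the right-tailed Fisher test per set, optionally alongside random query
sets of matched size as an empirical background; no multiple-testing
correction is applied by default (a Benjamini-Hochberg column is behind
a flag), matching the analysis this implements.

## Emergence calls

Ortholog tables give, per gene and species, either an acceptor window
(scanned for a G tract of >= `gmin` Gs, default 3) or a direct 1/0/ND
determination. Clades form a ladder — fish, reptiles, birds (siblings),
marsupials, other mammals — and clade presence is an OR over its
species, because a single species retaining the tract demonstrates
presence in the clade's ancestor while within-clade losses are common.
Under the Dollo assumption (a G tract arises once, may be lost
repeatedly):

* **pre_mammalian** — present in any of birds/reptiles/fish;
* **mammalian_ancestor** — present in a mammalian clade with birds,
  reptiles and fish all determined absent (marsupial absence alongside
  other-mammal presence is secondary loss, still mammalian);
* **absent** / **undetermined** otherwise.

Only rows determined in all five clades enter percentages; the packaged
21-gene vertebrate panel yields 15 complete rows, 13 of them
mammalian-ancestor (86.7%), 2 pre-mammalian, and 4 mammalian rows with
marsupial loss. The panel's within-mammal subcounts depend on how one
reads collapsed clade columns, so the marsupial-level subcount is
reported but not asserted anywhere.

## The synthetic-data generators

`generate_genome()` emulates the features under test and nothing more:

* constitutive acceptors sampled at ~20% A/G over -20..-3 on a
  pyrimidine-dominated background; purine-rich acceptors at ~70% A/G;
* planted tracts with first G in -11..-6 (bimodal, peaks at -10 and -8)
  and run lengths 3..8 dominated by G3-5 (~98.5% of mass), never
  invading the AG;
* a 68% alternative fraction among purine-rich focus acceptors, with an
  event mixture (cassette .16, alt-3' .40, alt-5' .10, retained .34)
  whose retained-intron and alt-3' shares sit at 17x and 1.6x the
  default reference proportions (.02 and .25) — so the fold-enrichment
  machinery can be checked against a planned value;
* genes of 2-6 exons on both strands of two contigs, written as
  FASTA + GTF, byte-identical under a fixed seed.

Two deliberate choices make recovery tests exact rather than
statistical. First, counts are assigned by largest-remainder allocation,
not per-gene coin flips, so planted fractions (REPA fraction,
alternative fraction, event mixture) are recovered exactly. Second,
planted compositions keep a margin around the decision boundary: >= 6/8
purines over -10..-3 for purine-rich sites and <= 4/8 for constitutive
ones. 4/8 is the largest cap that still fails the strict >60% rule
deterministically; a tighter cap would noticeably bias the constitutive
A/G profile below its nominal 20%, which the profile-recovery test pins
down. The purine-rich profile, by contrast, necessarily sits above its
nominal 70% at tract positions, so profile recovery is asserted on the
constitutive side only. Planted tracts are made the only reportable run
in the search range, and alt-3' witnesses get a clean pyrimidine+AG
shifted acceptor, so truth tables are unambiguous.

What the generator does *not* emulate: branch points, real
polypyrimidine-tract length variation, splicing-regulatory grammar
beyond the tested features, expression levels, or read data. Passing
recovery tests therefore demonstrates correctness of the scan,
classifier and caller logic — not performance on the messier composition
spectrum of a real genome, where sites near the 60% boundary genuinely
occur.

`generate_ortholog_sets()` scripts each gene's emergence clade
(deterministic mammalian/pre-mammalian counts), fills clades with
species windows that carry or lack a tract, interrupts tracts with a
single T at the configured per-species loss rate (the wallaby/platypus
pattern), and injects not-determined cells at a configurable rate. With
three species per clade and loss rate 0.2, clade-level false absence is
0.2^3 = 0.008, and the scripted call is recovered for >= 99% of 1000
genes.

## Numerical and degenerate-input choices

* Strict inequality at the 0.60 threshold, as the definition states.
* Truncated windows (intron shorter than the span) are flagged and
  excluded from calls and profiles rather than padded.
* Empty tract lists, empty event sets and zero-REPA runs are ordinary
  results (empty data frames, placeholder report panels), not errors;
  an all-ND emergence table yields an `NA` percentage.
* Profile denominators exclude `N`; positions with no informative base
  are `NA`.
* The hypergeometric lower support bound returns exactly 1 (P(X >= 0)
  and below-support k).
* Pipeline stages run in dependency order; a failing stage leaves the
  completed outputs plus an error manifest naming the stage.

## Problem sizes

The test suite and the acceptance script run at desk scale by design:
synthetic genomes of 40-200 genes (~50-250 kb), 256-1024-sequence
exhaustive enumerations for the maximum-entropy checks, populations up
to N = 12 for the combinatorial statistics oracles, and 1000 simulated
ortholog sets for the emergence caller. These sizes were chosen so every
oracle is exact and the whole suite completes in about a minute; all
generators scale to larger n by configuration.

## Known limitations

* Group labels are literal motifs, not a motif-discovery step; novel
  purine motifs outside the label set land in `other`/`nnnrag_like`.
* Strength scores are model-relative; no bundled pre-trained acceptor
  model, hence no absolute comparability with published score tables.
* The AS classifier sees only annotated isoforms: unannotated events are
  invisible, and "other" AS classes are not itemized.
* The emergence caller works at clade, not species-tree, resolution;
  it cannot distinguish emergence at the base of a clade from multiple
  independent gains inside it (the Dollo assumption forbids the latter).
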