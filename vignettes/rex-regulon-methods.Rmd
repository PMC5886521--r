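---
title: "Methods: operator-site prediction, variant evidence filtering, and fermentation physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: operator-site prediction, variant evidence filtering, and fermentation physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rexreg)
library(dplyr)
```

rexreg implements the computational side of a classic bacterial regulon
study: predicting operators of the redox-sensing repressor Rex in an AT-rich
anaerobe genome, filtering resequencing evidence for secondary mutations,
and the bench calculators (ethanol yield, growth rate, enzyme activity,
qPCR quantification) that turn raw measurements into the numbers such
studies report. This vignette explains each model, its assumptions, the
parameters that matter, and the design decisions taken where the underlying
procedure left room for interpretation.

## The operator model

Rex binds an 18-bp degenerate palindrome: a 5-bp AT-rich arm with template
`WTGWW` (`W` = A or T), an 8-bp AT-rich spacer, and the reverse complement
of the arm. Three tolerances complete the model:

* the spacer may carry **at most one C or G**;
* arm 2 may deviate from the perfect reverse complement by **at most one
  mismatch**, and only in its **last two positions** (arm-2 positions 4
  and 5, i.e. window positions 17-18);
* arm 1 must match its template exactly.

The search syntax writes this as `WTGWW{WWWWWWWW}` followed by the arm-2
back-references `-5-4-3-2-1`; replacing a digit with `N` frees that
position. Three variants (`-5-4-3-2-1`, `-5-4-3-N-1`, `-5-4-3-2-N`)
together express "at most one mismatch in the last two positions", and the
reserved token `"paper-union"` compiles exactly that union:

```{r}
p <- compile_pattern("paper-union")
p
```

Two semantic decisions are worth stating. First, an `N`-freed position that
happens to equal the complement base counts as a *match*, not a mismatch —
so the union is simply "zero or one mismatch at positions 4/5". Second, a
tolerated mismatch may be any of the three alternative bases including C or
G, and the spacer's G/C budget does not interact with arm mismatches: the
two clauses are evaluated independently. Concentrating all tolerance in
arm 2 (arm 1 exact) reproduces each of the 29 published site sequences on
at least one strand, which is the behaviour the acceptance suite locks in.

The accepted set is small enough to materialise — 8 arm-1 realisations x
2,304 admissible spacers x 7 arm-2 variants = 129,024 windows — and
`enumerate_accepted()` builds it by direct product enumeration. It doubles
as the ground-truth oracle in the tests and as the sampling space for the
synthetic-data generator (`sample_accepted_site()` draws uniformly from the
product space, so about 6 of 7 planted sites carry an arm mismatch).

## Scanning and coordinates

`scan_sequence()` tests every window in both orientations and emits one row
per offset: strand `+`, `-`, or `both` (a perfect palindromic window with a
palindromic spacer can match both ways). `forward_seq` always reports the
forward genome strand, because published site tables mix orientations while
printing forward-strand sequence. Coordinates are 0-based half-open
internally — unambiguous arithmetic — and only reports convert to the
1-based convention. Windows containing ambiguity codes are skipped and
counted rather than raising errors, since draft genomes routinely contain
Ns. Circular replicons can be scanned with `circular = TRUE` (windows wrap
across the origin); the default is linear because the published analysis
gives no indication of origin-spanning sites.

## Annotation, the 200-bp filter, and the consensus

A site annotates the nearest downstream gene on either side: the closest
`+`-strand gene starting after the site, or `-`-strand gene ending before
it, provided the site overlaps no gene body at all. The signed distance
follows the reporting convention that *includes the site's own length*: it
is measured from the site boundary farthest from the gene
(`|d| = gene_start - site_start` for a `+` gene). Distances are therefore
always <= -18. The companion figure legend of the original analysis differs
from its table by one or two bp on three sites — a counting-convention
discrepancy the source never resolves — and this package follows the
table's footnote convention throughout.

Filtering is strict in the grammatical sense: sites *more than* 200 bp
upstream are excluded, so |d| = 200 passes. "Function not annotated" is
operationalized as a missing product or membership in a configurable
deny-list (default: `"hypothetical protein"` and the empty string);
functional-category labels are treated as manual curation and only
supported as a user-supplied map, never inferred.

The consensus is a plain threshold consensus over strand-corrected
windows: a column is written as a concrete base when its frequency reaches
the threshold (default 1.0, i.e. unanimity), else `N`. The published
18-column motif emerges from the three adhE/adhA operators:

```{r}
cons <- build_consensus(c("TTGTTAAATGAATAACAA",
                          "TTGTTAATAAATTAACAC",
                          reverse_complement("TAGTTAAATTTATAACAA")),
                        threshold = 1.0)
cons$consensus
```

A 20-column variant of this consensus exists in the source's supporting
material; the 18-column form is implemented because it is the one the text
states and the one the window model produces.

## Structural-variant evidence filtering

Small variants identical to a wild-type call (exact on contig, position,
ref, alt — no fuzzy indel normalisation) are subtracted as reference
errors. Breakpoint records — up to 75 bp of unaligned read tail, given
150-bp reads and a 0.5 minimum mapping fraction — are filtered by two
strict rules: fewer than 10 supporting reads, or less than 20% "not
perfectly matched" reads, eliminates the record; retention is therefore
inclusive at exactly (10, 0.20). The not-perfectly-matched fraction is
taken as given per record; its denominator is not recomputed from reads.

The original workflow identified paired breakpoints by BLASTing their
sequences against known elements. That external search is out of scope
here; instead `pair_breakpoints()` pairs a left and a right breakpoint
when they lie within `max_span` (default 10 kb) and their unaligned tails
share an exact substring of at least `min_overlap` bases (default 15 bp,
directly or reverse-complemented), pairing greedily nearest-first with a
documented lower-coordinate tie-break. The source describes no pairing
algorithm; greedy nearest-first was chosen because it is deterministic,
order-independent given the tie-break, and conservative (each breakpoint
used once).

Coding effects are named in conventional protein notation (`Thr597Lys`,
`Glu454*`, `Lys290fs`, flanking-residue style for in-frame indels) by
translating reference and alternate codons with the standard genetic code;
GTG/TTG initiators are translated as written since the affected residues
in practice lie far from the start. A CDS with an internal stop upstream
of the variant is rejected as an annotation mismatch rather than silently
translated.

## Physiology calculators

**Yield.** The percent theoretical ethanol yield divides ethanol produced
by the stoichiometric maximum for the substrate consumed. Coefficients are
computed from standard atomic weights at full precision and printed to two
decimals at the interface: cellobiose gives 4 x 46.069 / 342.297 =
`r round(theoretical_yield_coeff("cellobiose"), 4)` g/g (printed 0.54), on
the assumption that one glucose equivalent yields at most two ethanol.
Initial product concentrations are assumed baseline-subtracted upstream;
the calculator flags (rather than clips) yields above 100%.

**Growth.** `fit_growth()` estimates the maximal specific growth rate as
the steepest slope of ln(OD600) over sliding windows (default 5 points)
whose log-linear fit reaches r^2 >= 0.98, a sliding-window regression
rather than a parametric growth model because the original analysis names
only its plotting software. The guard keeps lag- and stationary-phase
windows out of the estimate on clean data; on noisy data wider windows and
a lower guard are the right tool (the tests use 80-point windows at 2%
multiplicative noise). Max OD is the maximum of a 3-point running median,
which removes single-point spikes without flattening the plateau.

**Enzyme activity.** One unit is 1 umol product per minute;
`adh_specific_activity()` applies Beer-Lambert inversion with an explicit
extinction coefficient (default 6.22 mM^-1 cm^-1 for NADH/NADPH at 340 nm,
a textbook constant the source does not state) and path length (default
1 cm). Cofactor oxidation enters as a positive slope magnitude.

**qPCR.** Quantification is absolute against a synthetic-template standard
curve — Cq regressed on log10 copies, efficiency `10^(-1/slope) - 1` —
then expressed as a copy ratio to the *recA* reference, averaging replicate
wells on the copy scale. No ddCq mode is provided: with a shared
multi-amplicon template at 1:1:1 the absolute route is exact and simpler.

## The synthetic-data generators

Every stage is exercised against seeded, truth-labeled synthetic inputs, so
the whole pipeline is testable without downloads:

* `gen_genome()` draws an i.i.d. background at 65% AT (a
  Thermoanaerobacterium-like composition), plants accepted windows
  (sampled uniformly from the accepted set, so mismatch handling is
  exercised) alternating strands at evenly spaced loci, and places a gene
  downstream of each site. After planting, the contig is re-scanned and
  accidental background matches are appended to the truth — the one
  deliberate point where a generator uses the pipeline's own scanner, so
  that truth completeness is guaranteed by construction.
* `gen_od_curves()` produces logistic curves sampled every 0.05 h (a
  3-minute plate-reader cycle) from an inoculation OD of 0.002 (a 1% v/v
  transfer of a mid-log culture). Keeping the inoculum two orders below
  the carrying capacity keeps the logistic's early-phase curvature below
  the 1% recovery tolerance of the sliding-window estimator; the tests
  use runs long enough (up to 150 h for mu = 0.06 1/h) for the plateau to
  be reached so max-OD recovery is also meaningful.
* `gen_breakpoint_table()` draws read counts and fractions straddling the
  (10, 0.20) thresholds and always includes exact-boundary rows; labels
  are computed from the same strict rule the filter applies, never stored
  independently of the values.
* `gen_fermentation_table()` and `gen_qpcr()` invert their respective
  calculators exactly at zero noise, so round-trip tests have closed-form
  expected values.

What the generators do *not* emulate: real genomes are not i.i.d. (repeats,
skews, coding bias), real OD curves have lag phases and instrument floors,
real breakpoint fractions are correlated with read counts, and real qPCR
wells share plate effects. Passing the round-trip suite therefore
demonstrates correctness of the calculators and filters under their stated
models, not robustness to every artefact of real data.

## Problem sizes and numerical choices

The test and acceptance runs use a 100-kb genome with 20 planted sites,
500 breakpoint records, five growth rates spanning 0.06-0.38 1/h, 10^5
random windows for the matcher equivalence check, and the full 129,024-set
enumeration — sizes at which every check is exact yet the whole suite runs
in well under a minute. Degenerate inputs are handled explicitly: contigs
shorter than one window scan to an empty result, an all-zero OD series and
a single-level dilution series are errors, a constant OD series fits
mu = 0 with r^2 defined as 1 when residuals vanish, and tie-breaks
(equidistant genes, equidistant breakpoint partners) are deterministic and
documented at the function level.

## Known limitations

Operon structure is not modelled: a site is attached to its nearest gene,
not to everything co-transcribed behind it. The scanner has no scoring —
a window either satisfies the three clauses or it does not — so there is
no ranking among accepted sites and no motif statistics (PWMs,
information content, E-values are out of scope by design). Breakpoint
pairing without external alignment cannot classify the inserted element.
The growth fitter assumes exponential-phase data exist within the sampled
range; it will warn and fall back to the best-fitting window when the
r-squared guard rejects everything.
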