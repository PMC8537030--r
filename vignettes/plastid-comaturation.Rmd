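---
title: "Co-maturation and chronology of plastid transcript processing from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-maturation and chronology of plastid transcript processing from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomat)
```

## The problem

Plastid transcripts are matured by many post-transcriptional steps: C-to-U
editing of specific cytidines, removal of group-II introns, intergenic
cleavage and end processing. Short-read RNA-Seq measures each editing site
or intron in isolation; it cannot say whether two maturation events tend to
co-occur *on the same molecule*. Long, strand-oriented cDNA reads
(nanopore-style) span several events at once, so each read becomes a joint
observation of the maturation state of a whole transcript region. This
package implements that analysis: per-read annotation of maturation
states, pairwise dependency testing, chronology inference from maturation
intermediates, rate quantification, and virtual Northern blots — together
with a kinetic simulator that generates fully aligned synthetic reads with
known ground truth.

## Per-read annotation: three modalities

For every catalogued event, a read is annotated with one of three states:

* **mature** (`M`): the edited base is observed (a `T` where the reference
  has `C` on a plus-strand gene; an `A` where it has `G`, in plus-reference
  coordinates, for a minus-strand gene), or the intron is removed by a
  reference skip whose boundaries match the annotated junctions;
* **immature** (`I`): the genomic base is observed, or the intron is
  retained (the read aligns contiguously across it);
* **not read** (`N`): anything unreliable — the site is deleted in the
  read, outside the aligned span, within `end_margin` (default 5 nt) of an
  alignment end, shows a base that is neither the edited nor the genomic
  one, or the read maps to the opposite strand or another contig.

The `N` state is what makes the analysis robust at a ~4% per-base error
rate: an error at a site usually produces an off-alphabet base or an indel
and the read simply abstains for that event, rather than polluting the
contingency tables. Substitutions that happen to produce the counterpart
base (a third of substitutions at a C/T site) do flip the call; this
residual miscall rate of about `err/3` is measured by the test-suite and
must be kept in mind when interpreting rates of nearly-fixed events.

Splice calling uses two tunable geometric parameters: `junction_tol`
(default 10 nt), the wobble allowed between an observed reference skip and
the annotated intron boundaries — nanopore aligners rarely place junctions
exactly — and `intron_cover_min` (default 0.5), the fraction of the intron
that must be skipped (mature) or covered by aligned blocks (immature).
Reads that span the intron but satisfy neither test (for instance a large
deletion that misses one junction by more than the tolerance) are `N`.

## Dependency testing

For each pair of events, reads informative for both are cross-tabulated
into TT, TF, FT, FF (T = mature, first letter = first event). TF and FT
are the *maturation intermediates*. Under independence the expected count
of each cell is the product of its margins over n; `delta_TF` and
`delta_FT` are observed minus expected. Co-maturation — one event's
completion accelerating the other — depletes both intermediate classes, so
`delta_TF < 0` and `delta_FT < 0` is the expected signature, and the pair
report flags pairs violating it.

Each pair is tested with a two-sided Fisher exact test (the table is small
and margins are fixed by design; the test-suite verifies the p-values
against a brute-force hypergeometric enumeration to 1e-12). P-values are
adjusted with Benjamini–Hochberg within each replicate's family of
detected pairs (those with at least one jointly informative read), and
within the pooled family. A pair is declared dependent only under the
replicate-consensus rule: adjusted p < 0.1 in at least 2 of the 3
biological replicates *and* adjusted p < 0.005 on the pool of all
replicates. Pairs with an empty margin get p = 1 (the table carries no
association information); pairs with no joint read in a replicate count as
not significant there. We test every detected pair without a minimum
coverage threshold — the consensus rule already protects against unstable
small-n significance.

## Chronology from intermediates

For a dependent pair, the more abundant intermediate reveals the preferred
order: if reads mature at A but not B (TF) outnumber the converse, A tends
to mature first. We use the raw pooled TF vs FT counts, not
expectation-normalised quantities — the comparison is between two counts
drawn from the same set of doubly-informative reads, so their ratio is
directly meaningful. Directed edges from all ordered significant pairs of
one transcript are then layered by **longest-path depth**: an event
downstream of two chains gets the later rank, which matches the intuition
that it waits for everything upstream. Events with no significant edge are
reported as processed independently. Cycles, which can arise under noise,
are collapsed into a single rank group and flagged — never silently broken.

Reads covering *all* ranked events of a transcript validate the
chronology: among its intermediates (neither all-mature nor all-immature),
a read is *compatible* if its matured set is a union of complete lowest
ranks plus possibly a subset of the next rank (the prefix rule, which
treats ties within a rank group as unordered). With a per-position error
rate e and k ranked positions, only (1-e)^k of reads are expected
error-free — 81.5% for e = 0.04, k = 5 — so the compatibility fraction of
real data is bounded by sequencing noise even under a perfect chronology;
`error_free_fraction()` computes this bound.

## Rates, coverage, blots

Editing and splicing rates are mature/(mature+immature) over the pooled
replicates; `N` never enters the denominator. Virtual Northern blots take
every primary read on the probe strand overlapping the probe interval by
at least one base (the probe is a selector, not a clip — the histogram
uses full read lengths) and normalise the length histogram so the modal
length has intensity 100. Rendering smooths with a Gaussian (sigma 5 nt)
purely for display; the companion TSV is always the raw histogram.
Strand-specific coverage counts aligned bases (reference skips excluded)
of all reads on the requested strand overlapping the window.

## The simulator

The generator is a per-molecule Gillespie process. Each molecule draws a
transcript and a sampling age; each immature event i matures at rate
`k_i * prod(m_ji)` over already-mature events j. With all multipliers at
1, states are products of independent exponential-clock outcomes; a
multiplier above 1 plants co-maturation (both intermediates depleted) and
a j-before-i order; a chain of strong enhancements with negligible
downstream base rates yields a monotone sequential process whose only
intermediates are prefixes.

The sampling age is **fixed** (deterministic, default 1 time unit) rather
than exponential. This was a genuinely open design point: a shared random
age is a kinetic confounder — old molecules are mature everywhere, young
ones nowhere — which induces positive association between *all* event
pairs even at unit multipliers, making a clean independence control
impossible. Sampling the population at a fixed age makes the independence
case exact while preserving every planted dependence and ordering; the
exponential steady-state age remains available as
`age_distribution = "exponential"` for studying exactly that confounding.

Captured molecules become pre-aligned SAM records: the CIGAR is
constructed from the known transform (N skips for spliced introns, edits
and substitutions as M mismatches, simulated indels as I/D), bypassing any
aligner so tests stay hermetic; a FASTQ export exists for users who want
to run a real aligner. The error model applies, per aligned base, a
deletion (0.7%), substitution to a uniformly chosen other base (3%), or
insertion (0.3%) — about 4% total, the typical nanopore cDNA error rate.
Long-transcript capture bias is a logistic keep-probability
`1/(1+exp((L-L0)/s))` with L0 = 2000 nt and s = 200 nt, reflecting the
depletion of transcripts beyond ~2-2.5 kb in 3'-ligation libraries;
non-captured molecules are either lost entirely or truncated to a
3'-anchored fragment (cDNA synthesis primes at the 3' end), in equal
proportion. All randomness flows from one seed with a fixed offset per
stage (genome, kinetics, sequencing), so stages are independently
reproducible.

## Canned scenarios and calibrations

Four scenarios fix the study conditions used by the test-suite and the
reproduction script (`scripts/acceptance.R`):

* **null**: one 800-nt transcript, 8 editing sites + 2 introns, base rates
  spreading marginals between ~0.39 and ~0.86, all multipliers 1,
  3 replicates x 2000 reads. Expected result: zero network edges.
* **power**: null plus one planted 4-fold enhancement between two editing
  sites. The enhancer's rate is log(2) (marginal exactly 0.5 at the fixed
  unit age) and the enhanced event's base rate is 0.425, chosen once by
  Monte Carlo integration of the two-state kinetic model so that its
  marginal is also ~0.50 under the 4-fold multiplier.
* **chain**: five editing sites maturing strictly sequentially (first at
  rate 1.5; later ones at base rate 1e-12, boosted 2e12-fold by their
  predecessor). The base rate is negligible rather than exactly zero — a
  zero rate can never be enhanced multiplicatively — making out-of-order
  maturation possible in principle but with probability ~1e-12 per
  molecule, i.e. absent at any simulated scale.
* **isoforms**: two co-terminal transcripts of 1100 and 1800 nt at equal
  molarity, error-free and without capture bias, for exact virtual-Northern
  band positions.

Problem sizes in the suite (2000 reads x 3 replicates for network work,
5000 pooled reads for the chain, 40 and 50 seeds for the null and power
batteries) were chosen as the smallest scales at which the binomial
tolerances used by the tests are meaningful.

## What the simulator does and does not emulate

It reproduces the features the pipeline's statistics depend on: binary
maturation states with plantable dependence and order, strand-oriented
full-length reads with ~4% mixed errors, polycistronic co-terminal
isoforms, and long-transcript dropout. It does **not** emulate nanopore
signal-level artefacts (homopolymer compression, systematic miscalls),
polyadenylation, rRNA contamination, transcription in progress, or 5'/3'
end-processing heterogeneity. Passing tests therefore demonstrate the
correctness of the statistical machinery under a faithful abstraction of
the data, not robustness to every artefact of a real flow cell.

## Numerical choices and degenerate inputs

* Fisher p-values use the standard conditional two-sided convention (sum
  of table probabilities not exceeding the observed one, with a 1e-7
  relative tie tolerance).
* `p = 1` for zero-margin tables; `NA` (pair skipped) for empty tables.
* BH families exclude untested (NA) pairs from the family size.
* Rank numbers are re-compacted to be contiguous from 1 after longest-path
  layering; TIE pairs keep both events in the ranked set but contribute no
  edge direction.
* Compatibility is undefined (flagged, `NA`) when no intermediate read
  exists.
* An empty alignment file yields an empty annotation matrix with a
  warning, and empty blot profiles refuse to render but carry an empty
  histogram.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_scenario_power(seed = 42)      # planted e3 -> e7 enhancement
sim <- simulate_dataset(cfg)              # FASTA + catalogue + 3 SAMs
mats <- annotate_dataset(sim)             # read x event state matrices
net <- build_network(mats)                # Fisher + BH + consensus
net$edges                                 # the single planted pair
rates <- maturation_rates(mats)           # pooled M/(M+I) per event
ch <- build_chronology(net, "tA")         # e3 ranked before e7
```

## Known limitations

* The splice caller assumes one intron per catalogued event and does not
  model alternative 5'/3' splice sites; nested or overlapping introns
  would need distinct events.
* Chronologies are per-transcript; dependencies between events on
  different transcript units (which do occur across polycistronic units)
  contribute edges to the network but are not ordered unless the events
  share a `transcript_group`.
* The consensus rule is calibrated for three replicates; with more
  replicates the `min_replicates` threshold should be revisited.
* Rate estimates for nearly-fixed events are biased by the residual
  miscall rate (~1% at 3% substitution error); comparisons between
  conditions are safer than absolute values.
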