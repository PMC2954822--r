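---
title: "Characterizing a Rab GTPase family: methods and design notes"
author: "RabKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a Rab GTPase family: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RabKit)
```

# Scope

RabKit re-implements, as a tested pipeline, the computational procedures used
to characterize a ciliate Rab GTPase family at genome scale: motif-based Rab
identification and Rab/Rab-like discrimination, ORF prediction under the
ciliate nuclear genetic code, reciprocal-best-hit orthology, neighbor-joining
phylogenetics with bootstrap and a multi-method conservation classification,
stage-grid expression-peak detection, and thresholded-mask colocalization.
Because the original raw inputs (a macronuclear genome assembly, GenBank
records, a public microarray database, and microscopy images) are not
required here, every module is exercised on seeded synthetic data whose
ground truth is known, plus a packaged transcription of the published
localization survey table.

# Rab identification and classification

## The motif model

Rab proteins carry five short family-diagnostic motifs (RabF motifs;
defaults IGVDF, KLQIW, RFRSIT, YYRGA, LVYDIT) distributed N- to C-terminally
along the G domain. `scanRabMotifs()` finds, for each motif in turn, the
best ungapped window with at most `maxMismatch` mismatches. Because the
motifs correspond to ordered structural elements, hits must by default occur
at strictly increasing positions (F1 before F2 ... before F5); this ordering
constraint can be switched off.

Two thresholds govern the verdicts and are deliberately permissive in one
direction only:

* `maxMismatch = 2` per motif and `minMotifs = 3` of 5. Real Rabs diverge
  at individual consensus positions, so exact matching would be too strict;
  these defaults were chosen so that an exact consensus always passes while
  a random protein essentially never assembles three ordered near-matches.
  Both are configurable, and the motif library itself can be replaced via a
  plain-text config (`readMotifLibrary()`).
* Family discrimination (`classifyGtpaseFamily()`) scores Rab, Ras, Rho,
  Arf/Sar and Ran motif sets as the sum of best-window matched residues per
  motif. Scores are normalized by each family's maximum attainable score so
  families with different total motif lengths are comparable; the winner
  must reach 40% of its maximum and beat the runner-up strictly (tie
  tolerance zero), otherwise the call is `unknown`. The non-Rab motif sets
  shipped as defaults are consensus windows from canonical family members
  (H-Ras, RhoA, Arf1, Ran); they are placeholders adequate for
  discrimination and are expected to be overridden for serious cross-family
  work.

## Rab-like proteins

Authentic Rabs are prenylated on C-terminal cysteines. `classifyPrenylation()`
tests the final four residues against the anchored pattern set CC, CXC, CCX,
CCXX, CXXX, in that priority order. The window of four and the pattern set
are a design choice: published work states only that Rab-like proteins "lack
the specific C-terminal residues", so we fixed the standard geranylgeranylation
arrangements over the smallest window that contains all of them.
`callRabStatus()` then combines the three signals: non-Rab unless the family
call is Rab with at least `minMotifs` motifs; otherwise Rab when
prenylatable, Rab-like when not.

# Gene calling under the ciliate nuclear code

In the ciliate nuclear code (NCBI translation table 6) UAA and UAG encode
glutamine and UGA is the sole stop. `ciliateGeneticCode()` builds this table
by reassignment from the standard code; the test suite compares it codon by
codon against an independently curated copy of table 6.

`predictOrf()` mirrors manual curation of ciliate gene models: translate the
transcript, UTRs included, in all three forward frames; take the frame whose
translation carries the most RabF motifs; place the start at the nearest
in-frame ATG at or upstream of the first motif ("shortly upstream" read
conservatively as nearest, with an optional distance cap); place the stop at
the first in-frame TGA after the last motif. Transcripts are treated as
intronless mRNAs and the reverse strand is not searched, matching how the
original gene models were curated against transcript evidence.

# Homology

`alignPair()` performs optimal affine-gap alignment (global with end-gap
penalties, or local floored at zero) with BLAST-like defaults (BLOSUM62,
gap open 11, extend 1; a gap of length L costs open + L x extend). The
dynamic programming itself is delegated to Biostrings; RabKit ships an
independent exhaustive-enumeration scorer (`bruteForceAlignScore()`,
implemented as a depth-first walk over alignment paths with no DP table)
purely so the two routes can be checked against each other on short
sequences.

`percentIdentity()` exposes both denominator conventions — all aligned
columns (`gapped`, the default) or only residue-residue columns
(`ungapped`) — because published identity figures rarely state which was
used. `reciprocalBestHits()` reports a pair only when each sequence is the
unique top hit of the other; ties for the top score disqualify the query
rather than being broken arbitrarily, for determinism.

# Phylogenetics

## Trimming, distances, neighbor joining

`trimAlignment()` reproduces the usual preprocessing: remove the C-terminal
hypervariable region, then every column containing a gap. In `auto` mode the
cutoff is the alignment column of the last RabF motif occurrence in any
sequence, capped so no sequence loses more than 80 residues (the upper end
of typical Rab hypervariable tails; the published trimming was manual and
per-sequence, so auto mode is an approximation). Trimming is idempotent.

`computeDistances()` offers the p-distance with pairwise deletion of gaps
and the Poisson correction -ln(1 - p). After gap-column removal the
pairwise-deletion and complete-deletion conventions coincide.

`neighborJoining()` is a native Saitou–Nei implementation with the
Q-criterion. Two behaviours are pinned down that generic implementations
leave unspecified: ties for the minimum Q are broken by the
lexicographically smallest id pair (clusters ranked by their smallest member
id), and negative branch-length estimates are clamped to zero. On additive
matrices the algorithm is exact; the tests verify exact recovery of
topology and all path lengths on randomized additive matrices up to 12
taxa, with `ape::nj` as an independent cross-check.

## Bootstrap, consensus, conservation calls

`bootstrapSupport()` resamples alignment columns with replacement,
rebuilds the NJ tree per replicate, and maps bipartition frequencies (as
percentages) onto the full-data tree — the Phylip/PhyML convention of
annotating the estimate rather than the consensus. Resampling is seeded and
byte-reproducible; the seed and replicate count are recorded on the result.
The default of 100 replicates matches common practice for protein family
surveys. `majorityConsensus()` retains splits present in strictly more than
half of the input trees and labels them with occurrence percentages.

`classifyConservation()` operationalizes a judgement that is usually made
by eye on published figures: for each query and each method's tree, find
the smallest clade with support at or above 50% (the display threshold
used in bootstrap figures) containing the query and at least one other
leaf. A query is *conserved* when that clade contains a non-ciliate
reference in at least 2 of the trees (the "2 of 3 methods" rule);
*lineage-restricted* when in every tree the clade exists and contains only
ciliate-tagged leaves; *divergent* otherwise. Trees are consumed as rooted
Newick representations, as displayed in figures; unlabeled internal nodes
are treated as supported, so externally computed maximum-likelihood or
Bayesian trees without support annotations can still be used. Native
likelihood and Bayesian inference are out of scope: those trees enter as
Newick inputs.

# Expression analysis

The stage grid is fixed: growth at three culture densities (Ll, Lm, Lh),
seven starvation time points (S0, S3, S6, S9, S12, S15, S24) and ten
conjugation points (C0 through C18 at 2 h). The starvation labels follow
the public microarray series the published profiles were drawn from; the
source states only the endpoints and the count.

A *discrete peak* is a stage whose value strictly exceeds
`foldThreshold` (default 2) times the maximum over all other non-excluded
stages of the same condition — the strongest reading of "a >2-fold peak at
a distinct time point", and a scale-free one, so peak calls are invariant
to uniform rescaling of a profile. S0 is excluded by default because the
starvation-onset point coincides with a medium change. The background
threshold for expressed/background calls has no published value and is an
explicit argument.

One property of this definition deserves emphasis. With per-value
multiplicative log-normal noise at coefficient of variation 0.2, a planted
3-fold peak is *not* reliably recovered by the >2-fold rule: detection
requires 3 e1 > 2 max(e2..ek) over the k in-condition comparators, and the
acceptance script measures the resulting sensitivity at roughly 0.7-0.8
(it reaches 0.95 only once the CV drops to about 0.13). This is a property
of the detection rule under noise, not an implementation artifact; the
package reports the measured sensitivity rather than adjusting the rule or
the noise to flatter it.

# Colocalization

`thresholdMask()` keeps pixels strictly above a threshold chosen as a
fraction of the image's dynamic range (default 0.5), an absolute intensity,
or an order-statistic quantile. The range-relative default means a constant
image yields an empty mask — there are no "brightest structures" to keep —
and the strict inequality makes constant regions deterministic. The
published per-image manual thresholds are unrecoverable, so a fixed
fraction is used.

`overlapCoefficients()` implements the intensity-sum overlap: the fraction
of a channel's above-threshold signal residing in pixels above threshold in
both channels. The source describes two non-identical formulas; the
intensity-sum fraction is primary here because only it is guaranteed to lie
in [0, 1] and registers exactly 1.0 for complete overlap, matching the
stated anchor. The mean-intensity-ratio variant is available behind
`method = "mean_ratio"`. `quantifyCells()` applies the per-cell analysis
and refuses a summary over fewer than 4 cells unless forced, reflecting
the minimum cells analyzed per line in practice.

# Synthetic data

The generators are pure functions of (seed, parameters) and each returns
its ground truth:

* `simulateRabGene()` plants the five RabF motifs (or Ras motifs for
  non-Rab) with a class-determined C terminus, then back-translates under
  the ciliate code with uniform synonymous codon choice, random UTRs and an
  in-frame TGA stop. Spacer regions avoid methionine so the planted start
  codon is provably the nearest in-frame ATG upstream of the first motif.
* `simulateFamily()` evolves a random root along a given tree with
  Poisson-distributed substitution events per site and uniform replacement
  among the other 19 residues — a Jukes–Cantor-like model chosen for
  analytic transparency over realism (no WAG matrix, no rate
  heterogeneity, no indels, hence gapless alignments).
* `simulateExpression()` uses constant per-gene baselines with planted
  single-stage fold changes and mean-preserving multiplicative log-normal
  noise.
* `simulateColocImage()` places unit-amplitude Gaussian puncta on a
  separation lattice so puncta never overlap, with a chosen fraction of
  green puncta sharing red centers.

None of these attempt to match real codon usage, AT content, microarray
noise spectra, or microscope point-spread functions. Passing recovery tests
on this data therefore demonstrates correctness of the algorithms under
their stated models, not performance on real genomes or images.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use: 45 simulated proteins for
class recovery and 100 transcripts for ORF recovery (both zero-noise);
100 seeded 8-taxon, 150-site family simulations at rate 1 with pendant
branches of 0.1 and internal branches of 0.05/0.025 substitutions per site
for NJ topology recovery (a moderate-divergence regime); 200 randomized
additive matrices up to 12 taxa for NJ exactness; 500 random pairs up to
length 9 for the alignment oracle and 1000 random sequences for the motif
oracle; 100-gene cohorts for peak sensitivity and false-peak counts; and
96 x 96 images with 12 puncta per channel for colocalization. These sizes
keep the whole suite comfortably within a few minutes on one CPU while
leaving the statistical assertions well-powered.

Other numerical conventions: positions are reported 1-based inclusive
everywhere (internal computation is 0-based half-open); supports and
identities are percentages in [0, 100]; overlap fractions are in [0, 1];
Newick round-trips preserve topology, branch lengths (to 6 decimals) and
support labels.

# Known limitations

* The motif-based family discrimination is not an HMM/PSSM profile search;
  deeply divergent Rabs that a profile method would catch can be missed.
* Auto trimming approximates what was originally a manual, per-sequence
  judgement; the published 167-site master alignment is not reproducible
  without the original sequences and aligner.
* The conservation classifier depends on the rooted representation of the
  input trees and on their support annotations; trees without supports are
  taken at face value.
* Expression analysis performs no normalization or probe-level modeling;
  it consumes already-summarized intensities.
* Colocalization assumes single-plane, background-thresholded image pairs;
  there is no segmentation, deconvolution or z-projection.
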