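---
title: "Screening plant mitochondrial genomes for CMS candidate genes"
author: "MitoCMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening plant mitochondrial genomes for CMS candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MitoCMS)
```

## The biological problem

Cytoplasmic male sterility (CMS) in plants is a maternally inherited
failure of pollen production or anther dehiscence, almost always traced
to a *chimeric* open reading frame in the mitochondrial genome:
recombination between repeated sequences fuses fragments of ancestral
genes into a new ORF whose product is toxic or interferes with
respiration-linked factors (in several rice CMS systems, through
segments that bind the COX11 assembly factor). Nuclear
restorer-of-fertility (Rf) genes silence these ORFs and restore
fertility, which is what makes CMS/Rf pairs the engine of hybrid seed
production.

MitoCMS implements the comparative screen used to nominate such
candidate genes from an assembled mitochondrial genome, plus the
bulked-segregant statistic used to map the corresponding restorer QTL.
The full screen is:

1. **ORF scanning** (`findOrfs`): all maximal ATG-to-stop frames of at
   least 70 codons, on both strands of the circular molecule.
2. **Reference discard** (`runScreen`): ORFs whose locus a fertile
   reference mitogenome carries nearly verbatim (a single local
   alignment hit covering ≥ 95% of the ORF at > 99% identity,
   E ≤ 1e−5) are common to fertile cytoplasm and removed.
3. **Transmembrane filter** (`predictTm`): known CMS proteins are
   membrane-associated; candidates must carry a predicted TM segment.
4. **Mitotype-specific sequences** (`detectMss`): segments of the query
   absent from at least one genome of a panel of sequenced mitogenomes;
   candidates overlapping an MSS are flagged, and the presence/absence
   matrix doubles as input for mitotype clustering (`cseDistance` +
   `upgmaTree`).
5. **Chimera decomposition** (`decomposeChimera`, `liftDomains`): a
   surviving candidate is explained as a mosaic of known parental
   proteins, with breakpoints, indel counts and domain lift-over.

`findRepeats` reports the large (> 1 kb) exact repeats that mediate the
underlying recombination, and the `qtlseq` functions (`snpStats`,
`deltaWindows`, `nullConfidence`, `callQtl`) map the restorer locus
from two-bulk allele counts.

## Worked example on synthetic data

Every stage can be exercised without downloads through the simulators,
which plant known truth:

```{r screen, eval = FALSE}
sim <- simPanel(seed = 13, backboneLen = 3e4, nPanel = 3,
  mssSpec = list(
    list(length = 600, presentIn = 1:3),
    list(length = 700, presentIn = integer(),
         orf = list(aaLength = 90, tm = TRUE)),
    list(length = 400, presentIn = c(2))),
  cleanOrfs = TRUE)
cfg <- screenConfig(sim$query, reference = sim$backbone,
                    panel = sim$panel, requireMssOverlap = TRUE)
report <- runScreen(cfg)
report
#> CandidateReport: 32 ORF(s) scanned, 1 candidate(s)
#>   orf90_9: 8731..9003 strand +1, 90 aa
```

The one surviving candidate is exactly the planted transmembrane ORF
inside the panel-absent insertion; the 30-odd chance ORFs of the shared
backbone are discarded by the reference filter.

## Coordinate conventions

All reported coordinates are 1-based inclusive (GenBank style), so a
reverse-strand gene printed as `259,955–260,893` spans
`260893 − 259955 + 1 = 939` nt — 313 codons including the stop, a
312-aa protein. Circular genomes are stored linearized at an arbitrary
origin; an interval with `end < start` wraps, with length
`(L − start + 1) + end`. Scanning operations (ORFs, repeats) run on the
doubled sequence and deduplicate features whose canonical start lies in
the second copy; alignment treats the linearized sequence directly, so
homology spanning an origin is reported as two hits, which is
immaterial for the coverage profiles that MSS detection consumes.

## The aligner and its parameters

The local aligner is a seed-and-extend design in the ungapped-BLASTN
regime, which is the right regime for near-identical mitogenomes:

* exact word seeds (`wordSize = 11`), `+1/−2` match/mismatch, gap open
  5 / extend 2 (a gap of length *g* costs `open + g·extend`);
* ungapped X-drop extension (`xdrop = 20` raw-score units) from each
  seed, skipping seeds inside an already-extended hit on the same
  diagonal;
* colinear chaining of blocks across indels (diagonal drift ≤
  `band = 32`, unaligned stretch ≤ `maxChainGap = 200` bp); the gap
  regions between chained blocks are aligned exactly with affine DP,
  and chains of up to ~1e6 DP cells are re-aligned in full with local
  affine DP, so on test-sized inputs the reported raw score equals the
  Smith–Waterman optimum (the test suite asserts this against an
  independent DP oracle);
* blocks far below the single-hit significance score are dropped before
  chaining — they are chance word matches, and any real homology they
  sit in is re-captured by the gap DP between retained blocks;
* Karlin–Altschul E-values `E = K·m·n·exp(−λ·S)` with the published
  ungapped constants for `+1/−2` (`λ = 1.28`, `K = 0.46`); hits are
  reported at `E ≤ 1e−5`, the conventional screening cutoff.

Exact parameter parity with any particular BLAST release is not
claimed; the contract is agreement with the decisions made at the
stated thresholds (99% identity, E < 1e−5) on high-identity genomes,
plus DP-oracle score parity at test scale. Overlapping hits are pruned
deterministically: a hit survives only if less than half of its query
span is covered by higher-scoring hits.

`N` never matches anything, in either the aligner or the repeat
finder, and any codon containing `N` terminates an ORF.

## MSS detection thresholds

The method detects segments of the query with no qualifying alignment
in at least one panel genome. The thresholds are explicit because the
upstream literature leaves them unstated: coverage requires identity ≥
0.90 at E ≤ 1e−5; uncovered runs are merged across gaps ≤ 50 bp;
records shorter than 100 bp are dropped (consistent with the smallest
MSS the screen is expected to report, ~108 bp); a genome is scored as
carrying a record when its hits cover ≥ 80% of the record
(`presenceFrac`). "Specific" means absent from **at least one** panel
genome, not unique across all — per-genome grey/white presence patterns
are the object of interest, and a segment can be shared by several
mitotypes. Copy numbers are counted by self-alignment of the query
against each record (occurrences at identity ≥ 0.90 covering ≥ 80% of
the record, outside its own locus); the copy criterion is a package
choice, as the source method does not state one. A segment planted
twice in the query is reported as two records, each with `copies = 2`.

## Mitotype clustering

Each MSS is treated as a biallelic locus with allele frequency 0 or 1
per genome; the Cavalli–Sforza–Edwards chord distance then reduces to
`(2√2/π) ·` (Hamming fraction), averaged over loci. On binary profiles
every reasonable variant of the chord distance is a monotone transform
of the Hamming fraction, so the UPGMA topology is invariant to that
choice — which is why topology, not branch length, is the tested
contract. UPGMA uses proportional (size-weighted) averaging, merge
heights `d/2`, and a deterministic tie-break (lexicographically
smallest pair of cluster labels, clusters labeled by their smallest
member). Note that clustering on presence/absence data groups genomes
by shared absences as well as shared presences.

## Transmembrane calling

TM segments are called by a Kyte–Doolittle sliding window (window 19
residues, threshold 1.6, the classic scale and cutoff): maximal runs of
qualifying windows are merged into segments. This is a deliberate,
declared hydropathy method — a full membrane-topology HMM is out of
scope — and the screen consumes only the presence or absence of at
least one segment, a far more robust contract than helix counts.
Because merged segments may include sub-threshold positions between
qualifying windows, the reported segment mean can in principle dip
slightly below the window threshold; `X` residues score 0.

## Chimera decomposition

Each parent is locally aligned (Smith–Waterman, BLOSUM62, gap open
11 / extend 1) to the candidate, repeatedly with masking so one parent
can contribute several segments. Because similarity-score alignment may
drag low-identity flanking sequence along, each alignment is trimmed to
its maximal-scoring run of columns under +1 per identical column and −4
otherwise (runs below 80% identity cannot sustain a positive score at
these weights); one consequence is that a planted mismatch at the very
terminus of a segment may be trimmed, so recovered segment ends are
exact only up to terminal edits. Segments at identity ≥ 0.85 (the
conventional recombinant threshold; identity counts exact matches over
aligned columns, indels included) enter a greedy maximum-coverage
selection; ties prefer identity-weighted length, then lexicographic
parent id. Junction overlaps between consecutive segments — the
homology that mediated the recombination — are reported as is. Domain
annotations (e.g. COX11-interaction regions) are supplied by the user
as parent-coordinate intervals, never hard-coded, because the
authoritative coordinates exist only as figure annotations in the
source literature; a domain annotated on several parents under one
name is merged across the junction and reports every contributing
parent.

## Repeats

`findRepeats` reports *maximal exact* repeated pairs (direct and
inverted) of at least 1 kb by word anchoring (k = 31) followed by exact
diagonal sweeps; circular genomes are swept on the doubled sequence
with deduplication, and runs truncated at a doubled-sequence boundary
are dropped because the same pair recurs untruncated at an echo
placement. A family of *c* copies yields `choose(c, 2)` pairs; a
union-find over shared loci also assigns family ids, so both the pair
and the family counting conventions are available — the literature's
repeat counts do not state which convention they use.

## QTL-seq statistics

The per-site SNP-index is `alt/(ref+alt)` with a default minimum depth
of 10 per bulk (shallower sites are flagged, not dropped silently);
ΔSNP-index is the bulk difference, smoothed in 2 Mb windows every
50 kb. The windowing is a package default chosen from common QTL-seq
practice — the upstream pipeline's exact windowing is not restated in
the literature — and is configurable. Confidence bands are simulated
under the null of no QTL: each bulk's allele frequency is drawn by
sampling `2 × bulkSize` alleles at frequency 1/2 (F2-equivalent 1:2:1
segregation; a BC1 option exists because the real cross's segregation
ratio is not stated), then read counts binomially at the stated depth;
band quantiles at α = 0.05 and 0.01. Windows are matched to the band
simulated at their rounded median per-SNP depth (the smaller of the two
bulk depths). QTL calls are maximal runs of windows outside the 95%
band, flagged when any window also exceeds the 99% band.

The coverage self-check uses a constant-depth null table so that each
site is compared against the band simulated at exactly its own depth;
with Poisson depths a single-depth band is only an approximation, and
the check would conflate band calibration with depth mismatch.

## What the simulators emulate — and what they do not

`simPanel` builds a uniform-random circular backbone (GC 0.5 by
default) shared by a query and a panel, with mitotype-specific
insertions drawn independently of the backbone (so planted-truth
recovery assertions are sharp), optional duplicate copies, planted
TM-bearing ORFs and planted exact repeats. `simFusion` builds a
candidate protein as an N-terminal region of one parent fused to a
C-terminal region of another, with a configurable homologous junction
overlap and planted indels/substitutions. `simBulkseq` draws bulk
allele counts from a single-locus selection model with Haldane-map
linkage decay (default 4 cM/Mb, a typical rice euchromatic rate; bulks
of 25 individuals, matching the real experimental design; the planted
locus uses fixed-vs-fixed coding so the expected ΔSNP-index at the
locus is 1).

Real mitogenomes are not uniform-random: they carry gene blocks under
selection, nested repeat families, low-complexity tracts and
inter-genome indel polymorphism smaller than the planted insertions.
Passing the planted-truth suites therefore demonstrates correctness of
the detection machinery under clean conditions, not robustness to every
real-data pathology; on real accessions the MSS count, in particular,
is sensitive to the (unstated) upstream thresholds, and exact parity
with published MSS tallies is not asserted. With `cleanOrfs = TRUE`
the panel generator redraws insertion sequences until they contain no
chance ORF above the screen threshold, so end-to-end tests can assert
"exactly the planted ORF survives"; chance ORFs in the shared backbone
are left in place deliberately — the reference-discard stage is
expected to remove them, and does.

## Problem sizes and numerical choices

The shipped test and acceptance runs use: DP-oracle parity on ≤ 200 bp
nucleotide and ≤ 30 aa protein pairs; ORF-scanner brute-force parity on
5 kb genomes; repeat-finder exhaustive parity on ~2 kb; UPGMA naive
parity on 5-taxon matrices; MSS planted-truth recovery on a 6-genome,
100 kb panel with 10 planted segments; fusion recovery at the 312-aa
scale of the motivating chimera; QTL null-band coverage on 2000 SNPs at
10,000 simulations and localization over 20 seeded replicates. These
sizes exercise every code path at mitogenome-representative densities
while keeping the default suite quick. DP tie-breaks prefer diagonal
over up over left; UPGMA ties are broken lexicographically; all
simulators are pure functions of their seed and restore the caller's
RNG state.

## Known limitations

* Alignment is heuristic beyond oracle scale: scores are
  Smith–Waterman-optimal within chained-and-padded regions, not
  globally guaranteed for arbitrarily diverged inputs.
* TM calling is hydropathy-only; no topology or posterior
  probabilities.
* The screen cannot apply the expression (RT-PCR) filter that wet-lab
  work would add; it flags this in the report provenance instead.
* Variant calling from reads is out of scope for the QTL module, which
  starts from allele-count tables (a bcftools one-liner produces them
  from a VCF).
* Degenerate (mismatch-tolerant) repeats are not reported, only exact
  ones.
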