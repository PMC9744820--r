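---
title: "Calling CRISPR off-targets and translocations from tag-insertion enrichment libraries"
author: "peacseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling CRISPR off-targets and translocations from tag-insertion enrichment libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peacseq)
```

## The assay this package models

Cas9 fused to a reverse transcriptase, guided by a pegRNA whose 3'
extension carries a primer-binding site (PBS) and an RT template, cuts the
genome at on- and off-target protospacers and writes a 21-nt DNA tag into
the break. The tag is the enrichment handle: after Tn5 tagmentation
(which embeds a UMI adapter on one side of every fragment), anchored PCR
with a tag-specific primer and a Tn5-adapter primer amplifies the edited
loci. Two sub-libraries exist per sample: forward-primer amplicons reading
from the tag into the genome downstream of the insertion, and
reverse-primer amplicons reading into the upstream genome. A wild-type
library (no editing enzyme) is the background control.

`peacseq` implements the computational half of this assay: read
annotation, deduplication, cut-site calling with three candidate criteria,
RPM-based enrichment scoring, spacer/PAM mismatch search and profiling,
and the detection, classification and scoring of DSB-end joins
(translocations). Because the real datasets require large downloads, the
package ships a first-class simulator that emulates the library
architecture with a per-read ground-truth ledger, and the whole test suite
runs against planted truth.

## Coordinate conventions and core geometry

All internal coordinates are 0-based half-open; SAM records are converted
at the I/O boundary. The blunt Cas9 cut is modeled between protospacer
positions 17 and 18 (3 bp upstream of the PAM) — for a site on the plus
strand with protospacer start $s$, the cut coordinate is $s + 17$; on the
minus strand, $s + 3$.

Each enrichment read pair is anchored at the tag/genome boundary: after
trimming the primer and the remaining tag bases, the 5' end of the
primer-side read maps exactly at the cut. Cluster anchors therefore sit on
the cut coordinate, and forward- and reverse-side evidence for the same
site falls into a single cluster.

## Read preparation and the extension filter

The UMI is the first 10 nt of the Tn5-side mate, followed by a fixed 4-nt
spacer (the adapter geometry is config-driven; these are the defaults).
Primer identification compares each primer against the read 5' end with at
most one mismatch, ties resolved by fewest mismatches, then longest
primer, then declared order.

Every primer is designed to end at least 2 bp before the tag/genome
insertion boundary, so the bases a polymerase copies immediately after the
primer are still tag bases. `verify_extension()` demands an exact match of
the first `min(boundary_offset, min_ext)` bases after the primer against
the expected tag continuation. The window is deliberately exact-match: it
is only 2–6 bases wide, and tolerating a mismatch would defeat its
purpose. The default analysis pair F1/R2 leaves a 4-base window
(`min_ext = 4`), which makes a random genomic continuation pass with
probability $4^{-4} \approx 0.4\%$; the alternative primers F2/R1 with
2-base windows realize the most permissive design allowed by the
"at least 2 bp" rule and are available by configuration.

## The candidate criteria

A cluster of deduplicated, primer-matched reads becomes a candidate site
when:

1. **No control signal** — at most `max_wt` (default 0) deduplicated,
   primer-matched wild-type reads anchor within ±`window` (default 25 bp)
   of the cut. An optional relative mode accepts clusters whose sample/WT
   ratio is at least 1000, for controls with trace background.
2. **Bidirectional verified support** — at least one direction has an
   extension-verified read and the geometric mean
   $\sqrt{f \cdot r}$ of the per-direction extension-verified counts is
   positive. With the default `bidirectional_required = TRUE` this forces
   both directions to be non-zero (which subsumes the first clause); a
   permissive single-direction reading is exposed as a config switch,
   because paired-direction signal tracks at reported sites support the
   strict reading while the criterion's wording also admits the looser
   one.
3. **Strand consistency** — each amplicon side's modal orientation must
   dominate (fraction > 0.5 by default) and the two sides must imply the
   same protospacer orientation: forward amplicons read downstream of the
   cut, reverse amplicons upstream. The threshold is a majority rather
   than unanimity so that genuine sites receiving reverse-oriented tags
   via translocation (model v below) are not discarded.

Deduplication keys on the full paired-end fragment location (chromosome,
strand, both ends), UMI and primer. Keying on the tag-anchored 5' position
alone would make every molecule of a site share a position and leave the
UMI as the only discriminator; including the Tn5 end reflects what "mapped
to the same location" means for paired-end data and keeps the dedup exact.

The enrichment score is
$\mathrm{RPM}(f) + \mathrm{RPM}(r)$, extension-verified counts normalized
per million deduplicated reads of the respective direction — the
denominators are deduplicated library sizes because deduplication precedes
all counting. Sites are ranked by descending score (PEAC-ID). The exact
arithmetic behind the published per-site scores is not spelled out in the
assay's description; this RPM-sum is the package's documented
reconstruction, and the resulting ranking reproduces truth tag-molecule
ordering on simulated data.

The spacer search scans both strands within ±25 bp of the cut for 20-mers
followed by NGG or NAG, returns the minimal-mismatch hit (≤ 7 mismatches
by default), with ties resolved NGG-before-NAG and then by the distance of
the implied cut. All three bounds are exposed in the configuration; none
is stated by the assay description, so defaults follow GUIDE-seq-style
practice.

## Translocations: the five join models

A cut produces three distinguishable ends: the upstream end with a
(possibly partial) tag, the upstream end without tag, and the downstream
end. Joins observed at a *receiver* site are classified as:

* **i** — receiver ends religated with the tag (the intended edit);
* **ii** — receiver ends religated without tag (indel-only);
* **iii** — a distal donor's upstream end joined, without tag;
* **iv** — a donor's downstream end joined;
* **v** — a donor's tag-carrying upstream end joined; the tag then reads
  in reverse orientation relative to the receiver, which is what creates
  forward-amplicon signal *upstream* of the receiver cut — the
  unexpected-upstream signature that `detect_unexpected_signals()` flags.

The assignment of (i) and (ii) to tag-present/tag-absent intra-site joins
is the package's reading of the model figure, which groups them as
intra-site joins without further text. Model (ii) is simulated with 1–3 bp
end-resection deletions: a perfect tag-less religation is indistinguishable
from uncut DNA, so only resected religations are observable as split
reads; the remainder surfaces as contiguous normal-join coverage.

`call_junctions()` consumes nested-PCR/UDiTaS-style reads anchored in the
receiver's upstream flank: the 5' segment must end at a known cut (±5 bp),
the partner segment's breakpoint is matched against the site list, the
donor end is inferred from the partner's orientation relative to the
donor's own strand, and a (≥ 6 nt, ≤ 1 mismatch) tag match in the
inter-segment gap determines tag presence and orientation. Segments
shorter than 20 bp are ignored and audited. Events with fewer than two
supporting reads are reported but flagged low-confidence (no hard
threshold exists in the assay description).

The translocation score is $t/(n + t + c)$ with pseudocount $c = 10$. The
assay's methods text omits the pseudocount while its figure legend states
it; the legend form — the formula the published scores were plotted from —
is the default and $c$ is a config parameter (`pseudocount = 0` recovers
the bare ratio). UDiTaS amplicon reads carry no UMI in the simulated
libraries, so their deduplication is position-based; when UMIs are present
the standard key applies.

## What the simulator emulates — and what it does not

`simulate_library()` draws each molecule's origin (site, model-v junction,
mis-priming artifact, primer-free background), amplicon side (50/50 by
default; the true molar ratio of the two sub-libraries is not published),
tag truncation length, Tn5 fragment length (truncated normal, mean 350 sd
80, floor 80 — tagmentation size selection is not distributed in the
assay description), UMI, and PCR duplicate count, and emits paired FASTQ,
a truth SAM with the error-free intended alignment of every genomic
segment, and a per-read ledger. Planted-site defaults: insertion rate 0.3
(published full-length insertion efficiencies are 11–31%), edit rate
decaying with mismatch count ($0.8\,e^{-0.35\,mm}$, floor 0.05) so that
off-target read counts fall with divergence, as observed.

Tag truncation retains the 5' portion of the tag (reverse transcription
synthesizes from the upstream junction outward): 60% full length, the
remainder uniform over 6–20 retained bases. Consequences the ledger makes
explicit:

* a molecule whose tag is shorter than a primer's annealing region never
  amplifies with that primer (the simulator conditions the truncation draw
  on amplifiability);
* a forward-primer molecule whose tag retains the annealing region but
  not the full verification window amplifies yet *cannot* pass
  verification — these reads are tag-derived but `ext_intact = FALSE` in
  the ledger, and retention statistics are measured over boundary-intact
  reads. Reverse primers verify toward the truncation-free 5' boundary and
  are immune.

Mis-priming loci are genomic positions sharing the primer's eight
3'-terminal bases — the artifact class the extension rule was designed to
remove. Loci whose genome happens to continue with the expected extension
bases are excluded from the pool: reads from them would pass verification
by construction, i.e. they are signal mimics rather than removable
artifacts, and including them would make the ledger's "random priming
implies unverifiable" labeling incoherent. Real libraries can contain such
loci; they are a sensitivity floor of the assay itself, not of this
implementation.

Not modeled: PCR-cycle-level amplification bias, base-quality realism
(flat qualities), chromatin effects on editing, repeats or homology in the
reference (bases are i.i.d.). Passing tests therefore demonstrate
correctness of the pipeline's logic under the declared library
architecture, not robustness to alignment ambiguity in repetitive genomes
— alignment itself is out of scope (the pipeline consumes SAM/BAM from any
aligner; the simulator's truth SAM makes the tests aligner-free).

## Problem sizes and numerical choices

The bundled study fixture is a 100-kb reference hosting the on-target and
six off-targets (1–6 mismatches) under 50,000 read pairs, with a
10,000-pair wild-type control — large enough that every planted site
receives hundreds of molecules per direction while the whole suite runs in
about a minute and a half. Determinism is absolute: all randomness flows
from one integer seed, and every writer is byte-stable, so reruns are
file-for-file identical.

Degenerate inputs are defined rather than accidental: empty libraries
produce empty (header-only) outputs; a cluster with reads in one direction
only fails criterion 2 under the default reading; an unmatched donor
breakpoint yields an event with `donor_id = NA`; join geometries outside
the five models classify as "unassigned" and are never dropped silently.
Ties are deterministic everywhere (modal anchors break toward the smaller
coordinate; equal scores rank by coordinates; equal primer matches follow
declared primer order).

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(list(
  reference = list(length = 60000, gc = 0.5),
  sites = list(n_offtargets = 3, mismatch_counts = c(1, 3, 4)),
  library = list(n_fragments = 6000, random_priming_rate = 0.02),
  seed = 11
))
bundle <- run_simulate(cfg, "sim_out")
res <- run_call(
  ref = "sim_out/reference.fa", spacer = cfg$spacer, tag = tag_design(),
  sample_fq1 = "sim_out/sample_R1.fastq",
  sample_fq2 = "sim_out/sample_R2.fastq",
  sample_sam = "sim_out/sample.sam",
  wt_fq1 = "sim_out/wt_R1.fastq", wt_fq2 = "sim_out/wt_R2.fastq",
  wt_sam = "sim_out/wt.sam", out_dir = "call_out")
res$sites[, c("peac_id", "cut_pos", "peac_score", "n_mismatch")]
```

## Known limitations

* Scores are comparable within a run, not across libraries of different
  depth composition: RPM normalizes depth but not enrichment efficiency.
* The caller assumes one reference sequence per genome file as shipped;
  multi-chromosome support follows the same keys (all operations key on
  `chrom`) but the simulator emits a single chromosome.
* Donor ends can only be classified against a supplied site list;
  junctions to loci outside it are reported with an unknown donor rather
  than classified.
* Indel quantification at called sites and genome-wide structural-variant
  calling are out of scope.
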