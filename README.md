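# peacseq

Off-target and translocation calling for CRISPR editing assays that label
cut sites with a prime-editor-inserted DNA tag and enrich them by anchored
PCR.

## The problem

Cas9 cuts where its guide only partially matches, and simultaneous
double-strand breaks can rejoin across loci as translocations — the more
genotoxic and more easily overlooked outcome. In tag-insertion enrichment
assays, a Cas9–reverse-transcriptase fusion writes a 21-nt tag into every
cut (on- and off-target), Tn5 tagmentation fragments the genome with
UMI-bearing adapters, and tag-specific primers amplify the edited loci
from both sides. The computational task is to turn these libraries into a
ranked list of edited sites and a catalog of DSB-end joins, while removing
two dominant artifacts: PCR duplicates (via UMIs) and random-priming reads
(via the primer-extension check). `peacseq` is aimed at people analyzing
such libraries — and at method developers, since it bundles a full
simulator with per-read ground truth so every stage can be validated
without sequencing data.

## The method

* **Extension filter.** Each enrichment primer ends `b ≥ 2` bases before
  the tag/genome boundary; a read is kept only if the bases immediately 3'
  of the primer exactly equal the remaining tag bases. Mis-primed reads
  continue with genome instead and are rejected.
* **Deduplication.** Reads with the same paired-end location, UMI and
  primer are PCR duplicates; one representative survives.
* **Candidate criteria.** A cluster of tag-anchored reads is a site iff
  (1) the wild-type control shows no signal in its window, (2) the
  geometric mean of per-direction extension-verified counts is positive
  (both directions supported, under the default strict reading), and
  (3) read orientations are consistent upstream and downstream of the cut.
* **Score.** `PEAC score = RPM(ext_fwd) + RPM(ext_rev)`, extension-verified
  deduplicated counts per million deduplicated reads of each direction;
  sites are ranked by descending score (PEAC-ID), and the nearest
  spacer/PAM match (NGG/NAG, minimal mismatches) is reported with
  per-position mismatch profiles and primer-binding-site (PBS) annotation.
* **Translocations.** Split reads anchored upstream of a receiver cut are
  classified into five join models — intra-site religation with (i) or
  without (ii) tag, donor upstream end without tag (iii), donor downstream
  end (iv), donor upstream end with reverse-oriented tag (v; the source of
  "unexpected upstream" enrichment signal) — and scored as
  `t / (n + t + 10)`, junction reads over normal-join reads with a
  pseudocount.

## Worked example

Simulate a 60-kb genome with an on-target and three off-targets (1, 3 and
4 spacer mismatches), 6,000 read pairs plus a wild-type control, then call
sites:

```r
library(peacseq)
cfg <- pipeline_config(list(
  reference = list(length = 60000, gc = 0.5),
  sites = list(n_offtargets = 3, mismatch_counts = c(1, 3, 4)),
  library = list(n_fragments = 6000, random_priming_rate = 0.02),
  seed = 11))
bundle <- run_simulate(cfg, "sim_out")
res <- run_call(
  ref = "sim_out/reference.fa", spacer = cfg$spacer, tag = tag_design(),
  sample_fq1 = "sim_out/sample_R1.fastq",
  sample_fq2 = "sim_out/sample_R2.fastq",
  sample_sam = "sim_out/sample.sam",
  wt_fq1 = "sim_out/wt_R1.fastq", wt_fq2 = "sim_out/wt_R2.fastq",
  wt_sam = "sim_out/wt.sam", out_dir = "call_out")
res$sites[, c("peac_id", "cut_pos", "fwd_count", "rev_count",
              "peac_score", "n_mismatch", "match_strand")]
```

```
 peac_id cut_pos fwd_count rev_count peac_score n_mismatch match_strand
       1   55594      1239      1226   768223.8          0            +
       2   19655       880       900   576852.5          1            -
       3    4222       398       455   267584.7          3            -
       4   44053       356       329   213883.4          4            -
```

All four planted sites (cuts 4222, 19655, 44053, 55594) are recovered at
their exact cut coordinates, ranked by enrichment, with the planted
mismatch counts; the wild-type control and the random-priming reads
produce no calls. `call_out/` additionally holds the BED file, per-side
bedGraph signal tracks, the per-cluster audit log with each criterion's
verdict, and the read rejection log.

## Scope

Alignment is delegated to external tools (the pipeline consumes SAM/BAM;
the simulator emits truth alignments so tests are aligner-free). Indel
quantification at called sites, genome-wide SV calling and epigenetic
co-localization analyses are out of scope. See
`vignettes/peacseq-methods.Rmd` for the model, parameter rationale and
limitations.
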