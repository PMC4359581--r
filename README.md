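# gbskit

Genotyping-by-sequencing (GBS) reduces genome complexity by sequencing
restriction-digest fragments: every fragment starts and ends with the
enzyme's recognition site, and samples are identified by variable-length
*in-line barcodes* ligated directly 5′ of the restriction-site remnant.
Standard Illumina demultiplexing cannot handle in-line barcodes, and the
low sequence diversity of restriction libraries demands barcode sets
designed for the enzyme they will be used with.

`gbskit` is an R toolkit for the whole experimental loop — aimed at
groups designing and processing GBS/RAD experiments:

* **In silico digest** (`digest_genome()`): IUPAC-aware scan of a
  reference genome for cut sites (e.g. ApeKI, `G^CWGC`, where `W = A|T`
  and `^` marks the cut), fragment statistics for one or two enzymes,
  size selection, a BED of predicted sequenced bases, third-enzyme
  screening.
* **Barcode design** (`generate_barcodes()`): random barcodes of length
  8–16 built on Hamming(15,11) codes applied per bit plane of a 2-bit
  nucleotide encoding (A=00, C=01, G=10, T=11). Any two codewords differ
  in ≥ 3 nucleotides and any single substitution is correctable
  (`decode_hamming()`). Shorter barcodes are poly-A padded inside the
  codeword frame, so truncation preserves self-correction. Sets
  additionally guarantee: no internal or junction recognition site, no
  prefix collisions, pairwise *combined distance* (barcode + recognition
  site, degenerate positions conservative) ≥ 3, and per-position base
  balance.
* **Demultiplexing + trimming** (`demultiplex_run()`): assigns reads by
  barcode (+ optional site) within mismatch budgets (defaults 1 + 1),
  trims barcode and site at 5′, trims 3′ read-through (site + common
  adapter in GBS mode; adapter in RAD/inline mode; site +
  reverse-complemented barcode on read 2), and applies a paired-end
  consistency correction that reconciles unequal mate lengths through
  their overlap. Outputs per-sample FASTQ (optionally gzipped) plus a
  statistics table.
* **Barcode discovery** (`discover_barcodes()`): counts candidate
  prefixes of length 6–16 keyed by the enzyme site that follows them —
  for diagnosing undetermined reads.
* **Simulation + evaluation** (`simulate_reads()`, `evaluate_demux()`):
  generates single- or paired-end GBS reads with per-base substitution
  errors (default 1%) and per-read ground truth, and scores
  demultiplexing sensitivity, misassignments per million and trimming
  accuracy against a geometric expected-length oracle.

A command-line interface wraps all of it:
`gbskit digest|barcodes|demux|discover|simulate|evaluate`
(see `inst/scripts/gbskit`; an optional YAML `--config` can hold any
flag set).

## Worked example

```r
library(gbskit)

set <- generate_barcodes(10, "ApeKI", seed = 7)
frags <- random_fragments(500, "ApeKI", min_len = 60, max_len = 200, seed = 3)
sim <- simulate_reads(frags,
                      data.frame(barcode = set$barcodes, enzyme = "ApeKI"),
                      sim_config(reads_per_locus = 4, error_rate = 0.01,
                                 seed = 11),
                      out_dir = "sim")

sheet <- data.frame(sample = sprintf("S%02d", 1:10),
                    barcode = set$barcodes, enzyme = "ApeKI")
dm <- demultiplex_run("sim/reads.R1.fastq", "sim/reads.R2.fastq", sheet,
                      demux_config("gbs", adapter = "AGATCGGAAGAGCG"),
                      out_dir = "demux", collect = TRUE)
evaluate_demux(sim$truth, dm)
#> <demultiplexing evaluation> gbs paired-end
#>   sensitivity: 99.26% (19853 / 20000)
#>   misassigned per million: 0.0
#>   trimming sensitivity: 99.95% (19843 / 19853)
#>   trimming errors per thousand: 0.50
```

Reading the output: of 20,000 simulated pairs carrying 1% per-base
errors, 99.26% were assigned to their true sample (reads with ≥ 2
barcode errors or ≥ 2 site errors exceed the 1+1 mismatch budgets and
land in `undetermined`), none were assigned to a *wrong* sample, and
99.95% of assigned pairs were trimmed to exactly the fragment's interior
length — the mate-consistency correction rescues read 1 whenever its
terminal restriction site is truncated by the read end. Single-end runs
of the same data lose that rescue and trim ~94–96% correctly, the main
argument for paired-end GBS.

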