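---
title: "gbskit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gbskit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbskit)
```

This vignette records how each component of `gbskit` works, which
parameters matter, and why the open design questions were settled the
way they were. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The GBS read model

A GBS library is a complete restriction digest: each sequenced fragment
starts and ends with a match of the enzyme's recognition sequence
(ApeKI: `GCWGC`, cut after the first base, so `G^CWGC`). Library
construction prepends an in-line barcode of 8–16 bp; reading 5′→3′, a
read is

```
barcode | recognition site | insert interior | recognition site | adapter | ...
```

with the 3′ portion present only when the insert is shorter than the
read. Read 2 of a pair is the reverse complement of barcode+fragment
followed by the adapter, so short inserts make mates overlap — the
geometric fact exploited by the pair-consistency correction.

All coordinates in the package are 0-based half-open; BED output follows
the BED standard. Sequences are uppercased on input; base qualities
(Phred+33) are carried through trimming untouched.

### IUPAC conventions

Two matching alphabets are deliberately asymmetric:

* *pattern side* (recognition sequences): degenerate codes expand, `N`
  matches everything;
* *read side* (observed bases): `N` matches nothing and always counts as
  a mismatch. An N-rich read therefore drifts toward `undetermined`
  instead of matching every sample.

## In silico digestion

`find_cut_sites()` scans the top strand with `Biostrings::matchPattern`
(`fixed = "subject"`, so reference `N` runs never spawn cuts),
allows overlapping matches, and — for recognition sequences that are not
their own IUPAC reverse complement — scans the reverse-complement
pattern too, mapping a bottom-strand match to its top-strand cut point
(`match start + site length − cut offset`) and deduplicating by
position. Fragments are the intervals between consecutive cut points and
tile each chromosome exactly; chromosome-end fragments are reported but
never counted sequencable, because they lack one restriction end.

Parameters: `min_fragment`/`max_fragment` (bp, both inclusive; defaults
60/200), `read_length` (bp, default 100) for the predicted-sequenced-
bases BED, `bin_width` (bp, default 10) for the fragment-length
histogram, and `include_full_site`, which widens each fragment frame by
`cut_offset` on the left and `site length − cut_offset` on the right so
the BED (and fragment FASTA) contains complete recognition sites — the
frame the simulator expects.

## Barcode design

Nucleotides carry two bits (A=00, C=01, G=10, T=11); each bit plane of
an 11-symbol data word is encoded independently with binary
Hamming(15,11) (parity at positions 1, 2, 4, 8). Consequences, both
verified exhaustively in the tests: two distinct codewords differ in at
least three nucleotide positions (a nonzero plane difference has weight
≥ 3, and nucleotide differences are the union of plane supports), and a
single nucleotide substitution flips at most one bit per plane, so
per-plane syndrome decoding corrects it.

A barcode of target length $\ell \le 15$ forces the data symbols at
codeword positions $> \ell$ to `A` (poly-A padding) and truncates; since
all parity positions sit at $\le 8$, every $\ell \ge 8$ keeps the full
algebraic guarantee among same-length barcodes, and decoding simply
re-appends the padding. Length 16 (allowed, occasionally useful for
extra diversity) extends a full 15-frame codeword by one random base and
relies on the explicit set-level checks alone — the mapping of a
16-mer onto a (15,11) frame has no algebraic meaning, so the distance
property is enforced by rejection instead.

Set-level constraints, all enforced by rejection sampling and
re-checkable with `validate_barcode_set()`:

* no recognition-site match inside a barcode or spanning the
  barcode–site junction (an accidental site would shift the apparent
  read structure);
* no barcode is an IUPAC-compatible prefix of another barcode's
  barcode+site string (reads are matched left to right; only prefixes
  collide);
* pairwise *combined distance* ≥ 3, where the combined distance appends
  the recognition sequence to both barcodes and counts mismatching
  positions over the common prefix, scoring a degenerate position as a
  match whenever the expansions intersect. This is deliberately the
  worst case: separability is never overestimated, which is why a
  barcode set designed for one enzyme must not be reused with another.

Among valid candidates for each slot the generator prefers the one whose
bases are rarest at their cycle positions, which keeps per-position base
usage balanced — important because restriction libraries are already
low-diversity in early cycles. Generation is deterministic under
`seed` (via `set.seed`). The attempt budget (default 5000 draws per
slot) turns infeasible requests (e.g. hundreds of barcodes at a single
short length) into an informative error rather than a hang.

## Demultiplexing

For each read, every sample's probe (barcode, plus recognition site
outside inline mode) is compared at the read start: barcode positions as
plain characters, site positions IUPAC-aware. A sample is a candidate
when barcode mismatches ≤ `barcode_mismatches` (default 1) and site
mismatches ≤ `enzyme_mismatches` (default 1). The winner has the fewest
barcode mismatches, then the fewest site mismatches, then the longest
barcode; true ties and reads shorter than the probe go to
`undetermined`, untrimmed — they remain usable for barcode discovery.
The defaults match the published GBS practice of one mismatch in each
component.

3′ trimming:

* **gbs**: leftmost position with a complete recognition-site match
  (within the site budget) followed by the first
  $a = \min(|{\rm adapter}|, \text{bases remaining})$ adapter bases at
  ≤ $\lfloor 0.1\,a \rfloor$ mismatches; $a = 0$ (site flush with the
  read end) is allowed. The proportional adapter budget avoids
  over-trimming on short overlaps; 10% mirrors the per-component
  1-in-10 tolerance used elsewhere.
* **rad** / **inline**: adapter-only scan with a minimum overlap of 3
  bases.
* **read 2** (gbs/rad): recognition site followed by the reverse
  complement of the matched barcode (budgets: site budget + barcode
  budget; partial barcode at the read end allowed). Unlike the adapter
  scans, this scan takes the *best-scoring* position (leftmost among
  ties) rather than the leftmost qualifying one: the tail is only
  8–16 bp, so positions within one site mismatch plus one barcode
  mismatch occur by chance at roughly $10^{-3}$ per read, and a
  leftmost rule would let such a decoy pre-empt a later exact junction.
  For the 19+ bp site+adapter scan of read 1 the decoy probability is
  negligible and the conservative leftmost rule stands.

Read 2's 5′ end is handled symmetrically to read 1: a leading
recognition-site match (within budget) is removed unless
`keep_enzyme_5prime`.

**Pair consistency.** Correctly trimmed overlapping mates have equal
lengths. When at least one mate was 3′-trimmed and lengths differ, the
start of the longer read is compared with the reverse complement of the
end of the shorter read over a window of site length + longest barcode
length (mismatch budget: site + barcode budgets). On a match the longer
read is cut to the shorter length; otherwise the longer read is trusted
and the shorter is restored from its untrimmed original, cut to the
longer read's length. This rescues the commonest single-end failure:
read 1 whose terminal site is truncated by the read end is untrimmable
alone, but read 2 — whose 5′ loses only the site, not barcode+site —
still reaches the junction.

## Simulation and evaluation

The simulator draws fragments either from an in silico digest
(full-site frames) or synthesizes them: concrete site expansion +
random insert + concrete site expansion, lengths uniform on
`[min_len, max_len]`; inserts containing an internal recognition match
are redrawn, since a fragment of a complete digest would have been cut
there. Reads are taken from both fragment ends in equal numbers
(`reads_per_locus` must be even), completed with a 14 bp common adapter
and poly-A, at constant quality `I`.

Errors are independent per-base substitutions (default rate 0.01) to a
uniformly random *different* symbol from `{A, C, G, T, N}`. The
independent-Bernoulli reading of "about one error per hundred bases"
matters: it allows two errors in one barcode, which is exactly what
makes a 1-mismatch budget lose reads; an exactly-one-error-per-read
process would be fully correctable and uninformative.

Ground truth (sample, fragment, end, fragment/barcode/site lengths,
barcode-region error count) is carried in both the read ids and a TSV,
so evaluation is independent of read order. The evaluator judges
trimming on read 1 — the read that carries the barcode; pairs count
once — against a *geometric* expected length derived only from fragment
geometry, never from the trimmer: with fragment length $F$, site length
$k$, barcode length $b$ and read length $L$, the available read-1 length
is $L_1 = L - b - k$ ($L - b$ inline) and the expectation is
$\min(F - 2k,\,L_1)$ in gbs mode, $\min(F - k,\,L_1)$ in single-end rad
mode (the adapter scan keeps the terminal site; the paired correction
harmonises rad to the site start, $F - 2k$), and $\min(F,\,L_1)$
inline. Any deviation — over- or under-trimming — counts as incorrect.
Because the expectation is strict geometry, reads whose correct trim
point is undetectable (terminal site truncated at the read end) count
as single-end errors; that is a property of the data, not a scoring
artefact, and it is precisely what the paired-end correction buys back.

Rates reported: sensitivity = correctly assigned / total simulated;
misassignments per million = wrongly assigned / total × 10⁶; trimming
sensitivity = correctly trimmed / correctly assigned; trimming errors
per thousand = incorrectly trimmed / correctly assigned × 10³.

## Problem sizes and numerical choices

The packaged benchmark (tests and `scripts/acceptance.R`) uses 500
fragments × 10 samples × 4 reads per locus = 20,000 pairs of 100 bp at
1% error — large enough that the binomial noise on a ~99% sensitivity
is a few hundredths of a point, small enough to run in seconds. The
zero-noise validation uses 60–80 bp fragments at 100 bp reads so that
every trim point is reachable in every mode and on single reads alone;
with 60–200 bp fragments the truncated-terminal-site geometry makes
single-end trimming inherently imperfect (that shortfall is what the
single-end benchmark quantifies, and it varies a few tenths of a point
with the fragment-length draw). Determinism: every stochastic component
(generator, simulator) takes a seed and is reproducible bit-for-bit;
the demultiplexer is fully deterministic.

Degenerate inputs are defined, not accidental: empty FASTQ files parse
to empty streams; cuts at position 0 or chromosome end produce no empty
fragments; `min == max` size selection is inclusive; a second enzyme
with no matches reduces to the single-enzyme digest.

## What the synthetic data does and does not show

The generator reproduces the structural determinants of demultiplexing
and trimming accuracy — barcode length mix, degenerate restriction
sites at both fragment ends, adapter read-through, mate overlap,
substitution errors including `N` — so tests on it validate the
matching, trimming and pair-correction logic. It does not model
quality-score profiles, indels, PCR duplicates, chimeras, coverage
bias, or partial digestion (internal sites from incomplete cutting).
Passing tests therefore demonstrate algorithmic correctness under the
stated read model, not end-to-end accuracy on any particular instrument
run; on real data, indel errors in the barcode region (not correctable
by a Hamming code) and variable quality will lower sensitivity somewhat.

## Known limitations

* Full recognition sites are matched and trimmed by default; real
  ligation products carry only the post-cut remnant. The enzyme
  annotation file accepts a per-enzyme `remnant` column for such data,
  but the shipped evaluation exercises the full-site convention, which
  is self-consistent with the simulator.
* Barcode matching is Hamming (substitution-only); indel-containing
  barcodes are not recovered.
* Enzymes with interrupted recognition sites (two-part sites with a gap)
  and methylation sensitivity are out of scope.
* The demultiplexer streams in chunks and is single-threaded; the
  vectorised engine processes tens of thousands of reads per second,
  which is adequate for the library sizes GBS produces, but no
  multi-core path is provided.
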