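---
title: "covdepth: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{covdepth: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The statistic

For a set of half-open reference intervals $R = \{[s_j, e_j)\}$ and a set of
filtered alignment records, define per-base depth
$d(i) = \#\{\text{records whose CIGAR aligns a base onto } i\}$.
`covdepth` reports, per target region,

* Covered_site $= \#\{i \in R : d(i) \ge 1\}$,
* Total_depth $= \sum_{i \in R} d(i)$,
* Coverage(%) $= 100\,\cdot\,$Covered_site$/|R|$,
* Mean_depth $=$ Total_depth$/|R|$,

and optionally GC(%) of the reference over $R$.  Only the alignment
position and CIGAR of each record matter; sequence and base qualities are
never consulted (and on the CRAM path never even decoded).

### CIGAR semantics

`M`, `=` and `X` consume reference and increment depth; `D` (deletion) and
`N` (splice/skip) advance the reference cursor without incrementing; `I`,
`S`, `H` and `P` neither advance nor increment.  Two conventions here were
genuinely open and are now fixed:

* **Deletion-spanned bases are not covered.**  A `D` base has no aligned
  read base on it.  This matches the dominant depth-tool convention and the
  samtools-equivalent semantics the package is tested against; if a
  different convention is ever needed it belongs behind an explicit switch,
  not a silent change.
* **`N` behaves exactly like `D`** for the cursor and for counting, which is
  what one wants for spliced long reads: introns are not covered by an
  exon-exon junction read.

Aligned bases falling past the declared chromosome end (possible with
malformed inputs) are discarded with a warning rather than counted or
crashed on.

## Filtering

A record is used iff `bitwAnd(FLAG, mask) == 0` and `MAPQ >= q`.

* `mask` defaults to `0x704` — unmapped `0x4`, secondary `0x100`, QC-fail
  `0x200`, duplicate `0x400`.  The duplicate bit covers *all* duplicates
  (SAM has no optical-only bit).  Supplementary alignments (`0x800`) are not
  excluded by default, because the default exclusion list is exactly those
  four classes; users wanting mosdepth-like behavior can pass `-f 0xF04`.
* **A user-supplied mask replaces the default** instead of OR-ing into it.
  One knob with replace semantics is the least surprising contract and the
  only one that lets a user *reduce* filtering (e.g. `-f 0x4`); it is called
  out in the CLI help because the consequence — passing `-f 0x800` silently
  re-admits duplicates — is easy to miss.
* `q` defaults to 0: no silent data loss.  MAPQ 255 ("unavailable") is kept
  at the value 255 and therefore passes every threshold; excluding it would
  be a policy decision the defaults should not make.

## Blocked depth accumulation

Per-chromosome depth lives in fixed-capacity blocks (default $2^{20}$
positions) materialized only when a read touches them, so memory is bounded
by coverage footprint, not chromosome length — a 10 Mb chromosome with one
read costs one block.  Counts are stored in doubles, which are exact
integers up to $2^{53}$: R has no native 64-bit integer, and 32-bit counts
can genuinely overflow on amplicon data.  Results are invariant to the
block size; the test suite runs the same inputs at block sizes 7, 64 and
$2^{20}$ to stress boundary-spanning reads, and an acceptance property
requires exact agreement with a naive full-array oracle.

## Region modes

* **Chromosome** (default): every `@SQ` entry, plus a `Total` row pooling
  raw counts (never averaging percentages).
* **Windows** (`-w`): tiling `[0, w), [w, 2w), …` truncated at the
  chromosome end, so window lengths sum exactly to the chromosome length —
  a conservation property the acceptance suite checks against chromosome
  totals.
* **BED** (`-b`): taken verbatim, one output row per line, overlapping
  lines included — the user asked for those exact regions.  Validation is
  per-line with line numbers in error messages.
* **Genes** (`-g`): GFF3 or GTF, dialect auto-detected from the attribute
  syntax.  Per gene, CDS features are preferred and exons used only when
  the gene has no CDS — decided *gene by gene*, because a file-global rule
  would compute nothing for non-coding genes in a mixed annotation.
  Intervals are pooled across all transcripts and merged; **touching
  intervals merge** so a shared boundary base is counted once.  Gene
  identity is the GTF `gene_id`, or in GFF3 the `Parent`-chain ancestor
  whose type matches `gene$` (accepting `pseudogene`, `ncRNA_gene`, …).
  Orphan features and features on chromosomes absent from the alignment
  header are skipped with a counted warning; a file yielding zero genes is
  an error.  Strand is ignored throughout — coverage is strand-agnostic.

Internally every coordinate is 0-based half-open; conversion to/from the
1-based closed GFF/GTF convention and the 1-based inclusive report display
happens only at parse/format boundaries.

## Parallel scheduling

With an index and `t > 1` threads, chromosomes are sorted by length
(descending, ties by header order) and greedily assigned to the currently
least-loaded of `min(t, #chroms)` groups, load being summed length.
"Equal-sized groups" is thus read as *load*-balanced rather than
count-balanced: equal counts would leave one worker holding the single
giant chromosome of many real genomes plus as many small ones, defeating
the point of parallelism.  Surplus threads (`t > #chroms`) are assigned
round-robin to chromosomes in descending length order as decoder threads.
Workers share nothing — each opens its own file handle, fetches its
chromosomes via the index, accumulates once and reduces all of that
chromosome's targets (so overlapping regions are never double-fetched) —
and results are reassembled in header order, which is why the report is
byte-identical for every thread count.  Unindexed (e.g. unsorted) files
cannot be region-fetched: they are accepted but streamed once, serially.

## GC content

GC(%) $= 100 (G{+}C)/(A{+}C{+}G{+}T)$, case-insensitive, so soft-masked
sequence is handled transparently.  `N` and other IUPAC ambiguity codes are
excluded from **both** numerator and denominator: counting assembly gaps in
the denominator would depress GC exactly in the regions where CNV pipelines
use it for normalization.  A region with no unambiguous base reports the
sentinel `-`.  GC depends only on the reference, never on alignments, and
the whole-genome Total GC pools raw counts across chromosomes.

## Report format

Tab-separated; two leading `#` lines (coordinate convention, column
header).  Percentages and mean depth are printed with two decimals,
half-up; the integer columns carry full precision so nothing is lost to
rounding.  Output paths ending `.gz` are gzip-compressed.  The exact column
layout is this package's own declared format, covered by round-trip tests —
no byte-compatibility with any other tool's output is claimed.

## The synthetic fixture generator

`sim_config()` / `generate_reference()` / `generate_alignments()` build the
entire test world: random A/C/G/T references (optionally with an N run),
and alignment sets with configurable fractions of duplicate, secondary,
QC-fail, unmapped and low-MAPQ records and per-read indel, splice and
soft-clip events, emitted as SAM, unsorted BAM, sorted+indexed BAM and
indexed CRAM plus a plain-text truth table.  Defaults (~5% duplicates, a
few % secondary/unmapped, 10% MAPQ < 20, bwa-like indel/clip rates, ~8×
depth over a few kb) sketch a small short-read resequencing slice.  The
truth table — not a re-parse of the BAM — feeds the independent per-base
oracle (`oracle_depth()`), so a reader bug cannot cancel itself out of an
equivalence test; a separate test asserts reader output equals the truth
table.

What the generator does **not** emulate: paired-end insert-size structure
and proper pair flags, base qualities and sequencing error profiles,
reference-biased read placement, multi-mapper correlation, or chimeric/
supplementary alignments.  A green equivalence suite therefore establishes
that depth arithmetic, filtering, interval handling and scheduling are
exact under samtools-compatible semantics — not that any biological
conclusion drawn from real data is sound, and not anything about wall-clock
performance.

## Numerical and degenerate-input choices

* Half-up rounding at two decimals via `floor(100x + 0.5)/100`; ties at
  exactly `.005` are astronomically rare in ratios of integers but the rule
  is deterministic either way.
* Scheduler ties (equal loads, equal lengths) break toward the lowest group
  index / earliest header position, keeping plans reproducible.
* Empty chromosome lists, zero-read chromosomes, windows larger than the
  chromosome, genes whose parts abut, and regions at block boundaries all
  have dedicated tests.
* Unmapped records are normalized to `ref_name = NA, pos = -1, mapq = 0`,
  empty CIGAR, and flow through to the filter rather than being dropped by
  the reader — filtering policy lives in exactly one place.

## Known limitations

* The CRAM path shells out to `samtools view` (restricted to
  FLAG/RNAME/POS/MAPQ/CIGAR via `required_fields`); no samtools on the
  PATH means no CRAM support.
* Pure-R accumulation is exact but not fast: throughput is adequate for
  targeted panels and test-scale data, orders of magnitude from compiled
  depth tools on 150 GB inputs.  The contract here is semantics, not speed.
* No per-base output tracks, depth histograms/quantiles, or mate-overlap
  correction; a template-aware mode would need pair information the
  minimal decode deliberately skips.
* One decoder thread per chromosome is recorded in the work plan but the R
  reader cannot currently exploit >1 decompression threads per file; the
  plan field documents intent and keeps the scheduling contract testable.
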