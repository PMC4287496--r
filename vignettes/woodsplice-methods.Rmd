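---
title: "Methods: alternative splicing events, their functional impact, and cross-species conservation"
author: "woodsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alternative splicing events, their functional impact, and cross-species conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`woodsplice` implements a comparative alternative-splicing (AS) analysis for
two bulk transcriptomes, of the kind used to study wood-forming (developing
xylem) tissue in tree species: AS events are called and typed from assembled
transcript models, their consequences for the encoded protein are annotated,
and events shared between two species are identified through orthology and
local sequence homology around the alternative introns. This vignette
documents the model behind each stage, the tunable parameters, the numerical
and design choices, and what the synthetic-data tests do and do not
demonstrate.

## Coordinates and data model

All genomic coordinates are 0-based, half-open `[start, end)` on the forward
genome strand; strand is metadata. mRNA coordinates are 0-based from the 5'
end of the transcript (reverse-complemented for minus-strand genes). With
half-open arithmetic every changed-nucleotide count is a plain interval
length, with no ±1 corrections. GTF input/output converts to and from the
on-disk 1-based inclusive convention at the boundary.

A transcript model is one isoform's ordered exon chain; introns are the gaps
between consecutive exons and must be at least 1 nt. Single-exon transcripts
are retained — they are the natural intron-retaining partner of an IR event.
Transcripts with identical exon chains under one gene carry no AS
information and are deduplicated, keeping the lexicographically smallest id.

## Expression filtering

Weakly expressed isoforms are the dominant source of spurious AS calls in
assembled transcriptomes, so two gates precede event calling:

* **Detection gate** — a transcript must exceed `min_fpkm` (default 0.1
  FPKM) in *both* biological replicates. A flag relaxes this to
  either-replicate, and another applies the gate per gene (all isoforms pass
  when any does) for data sets where detection is reported at gene level.
* **Relative-abundance gate** — a transcript's mean FPKM across the two
  replicates must be at least `min_major_fraction` (default 0.05) of the
  mean FPKM of its gene's most abundant gate-surviving isoform.

The 5% rule is anchored on the mean of the two replicates. Anchoring could
equally be per-replicate; the mean was chosen for symmetry between
replicates, and the choice only matters for isoforms straddling the cutoff
in one replicate. An isoform at exactly 5% survives (strictly weaker
isoforms are removed). Filtering is idempotent and monotone in the cutoff;
both properties are tested. The isoform ratio reported per surviving
transcript is its mean FPKM divided by the gene's top isoform's, in (0, 1].

## Event calling by pairwise splice-chain comparison

Two isoforms of a gene are compared over the genomic overlap of their
spans. The overlap is partitioned at **shared splice sites** — positions
strictly inside the overlap where both isoforms have an exon start, or both
an exon end — and every partition cell whose exonic content differs between
the isoforms becomes exactly one AS event. Typing is by the intron content
of the region, with donor/acceptor named in transcription orientation:

* **IR** — one isoform is continuously exonic across the region while the
  other splices one or more introns there. (Multi-intron retention within
  one region is still a single IR event; with no shared boundary between
  the introns there is no principled place to split it.)
* **ES** — one isoform spans the region with a single intron equal to the
  region; the other carries at least one exon strictly inside it. The
  flanking splice sites are shared by construction of the region bounds.
* **AltA / AltD** — both isoforms have exactly one intron in the region,
  sharing the donor but not the acceptor (AltA) or vice versa (AltD).
* **AltP** — the catch-all for regions where both isoforms carry splice
  sites but none of the patterns above applies; the canonical case is an
  intron shifted at both ends. Complex mixed regions yield a single AltP
  event rather than nested sub-events.

One boundary case deserves a note: a cassette exon lying inside a single
intron of the other isoform, with both flanking sites shared, satisfies the
ES pattern and is typed ES here. Catalogues that reserve "alternative
position" for any internal exon with displaced boundaries would label some
of these differently; with the definitions above the assignment is
deterministic and oracle-testable, which we prioritised.

**Changed length** is the size of the symmetric difference of the two
isoforms' exonic base sets within the region — the nucleotides exonic in one
isoform but intronic or absent in the other. For IR this is the retained
intron length, for ES the skipped exon length, for AltA/AltD the splice-site
shift. The **inclusion isoform** is the one with more exonic sequence in the
region (ties broken by transcript id, which keeps the caller symmetric
under operand order), and the altered interval is mapped to its mRNA
coordinates for downstream feature localization.

Differences that touch transcript termini are not events: comparison is
restricted to the span overlap, and a region containing an intron that
crosses the overlap bound (an alternative first/last exon artifact) is
skipped. The five types are all internal by definition.

Gene-level collection runs all isoform pairs and merges events with
identical type, variable region and alternative intron sets, recording the
supporting pairs. This pairwise-plus-deduplication scheme approximates
multi-isoform event grouping as done by splice-graph tools; it is exactly
testable against a brute-force oracle that compares per-position exonic
indicator vectors, which the test suite runs on 500 seeded random
two-isoform genes (up to 6 exons each).

## Intron features

AT content is computed over unambiguous bases only (IUPAC ambiguity codes
excluded from numerator and denominator). Introns of surviving transcripts
are constitutive unless they participate in an event. Group comparisons use
the two-sided Welch unequal-variance t test; two identical zero-variance
groups return t = 0, p = 1 rather than an error. Junction position
frequency matrices are built over configurable donor/acceptor windows
(default 3 exonic + 6 intronic bases) in transcription orientation;
canonical splice sites give invariant G/T at donor +1/+2 and A/G at
acceptor −2/−1.

## ORF finding and functional impact

Isoforms are translated from the **longest ORF**: all three forward frames
of the (already oriented) mRNA are scanned for ATG-to-stop spans, each span
ending at the first in-frame stop so the protein has no internal stop; the
longest span wins and ties go to the 5'-most start. There is no minimum
length beyond one encoded amino acid (`ATGTAA` is noncoding). Scanning the
reverse strand would be meaningless for oriented mRNA, so it is not done.

Event localization compares the altered mRNA interval with the inclusion
isoform's ORF: strictly upstream is 5'UTR, strictly downstream is 3'UTR,
and *any* overlap — including boundary-spanning intervals — is ORF. The
disjoint three-way classification needs a tie rule and any-overlap is the
conservative one for functional impact. When the exclusion isoform's own
ORF would place the event elsewhere, the row is flagged
(`location_discordant`) rather than silently re-anchored. An ORF-located
event disrupts the reading frame iff its changed length is not a multiple
of 3.

The altered interval maps to protein coordinates by codon arithmetic
(`floor` at the start, `ceiling` at the end, so partially covered codons
count). For frame-disrupting events the affected region is open-ended: all
sequence C-terminal of the shift differs, on **both** proteins — this
matters in the degenerate case where the shift truncates the inclusion
protein at the event itself, leaving its own affected interval empty while
downstream domains of the other isoform are plainly disrupted.

Domain hits (from any HMM search, supplied as a table; a converter for
hmmscan `--domtblout` is included) are filtered at E ≤ 1e-10. A domain is
**modified** when a hit on either isoform's protein overlaps the affected
region by at least one residue; **gain/loss** is counted per family
occurrence, so an isoform keeping one of two copies of a family registers a
loss. Impact tables report both per-event and per-(event, domain) tallies —
summary fractions can be computed either way and the table keeps both
options open.

Domain enrichment among AS-modified genes uses the two-sided Fisher exact
test per family over the universe of genes with at least one domain hit
(this conditions out the background domain census), flagged at raw
p < 0.05 with no multiplicity correction. The exact p values are verified
against full hypergeometric enumeration for every 2×2 table with total ≤ 30
(agreement within 1e-12).

## Orthology and conserved events

Each gene is represented by the longest-ORF protein of its most abundant
surviving isoform. Orthologs are **reciprocal best hits** over all-vs-all
protein local alignment (Smith–Waterman, BLOSUM62, gap open 11 / extend 1),
the standard one-to-one reading of "putative orthologs". Accepted pairs
must satisfy, in both directions: Karlin–Altschul E-value < 1e-50, identity
over aligned columns > 0.4, and aligned span over query length > 0.6.

Homology of exonic sequence is assessed by a built-in six-frame translated
local alignment: every pair of the six translated frames (stops score via
the `*` row of BLOSUM62) is aligned, and the best raw score S becomes
E = K·m·n·e^(−λS) with λ = 0.267, K = 0.041 (the gapped BLOSUM62 11/1
regime) and m, n the translated lengths summed over frames. The search
space is per-comparison, not database-wide, so E-values differ somewhat
from a database `tblastx` run — thresholds here are calibrated to this
statistic, and an adapter can ingest externally computed tabular alignment
results instead. Keeping the aligner in-package makes the whole analysis
runnable and testable without external binaries; its scores are verified
against an independently written quadratic-time Gotoh dynamic program.

For every alternative intron of every event, up to 100 bp of exonic
sequence immediately 5' and 3' of the intron is extracted from the
intron-bearing isoform (the isoform with the longest adjacent exons when
several carry the intron), in transcription orientation; shorter exons give
flagged truncated flanks. An intron pair is **conserved** when
upstream-vs-upstream AND downstream-vs-downstream alignments both reach
E ≤ 1e-5; a cross-species pair of same-type events on an accepted ortholog
pair with a conserved intron is a **conserved AS event**. All matching
event pairs are emitted (genes with several events can appear in more than
one pair), each with its best-supported intron pair; lowering the E-value
cutoff can only shrink the set, and species swap only exchanges roles —
both properties are tested.

## The synthetic data generator

The generator builds two artificial species so that every stage has planted
ground truth. Genes are constructed in transcription-orientation
coordinates as 5'UTR + CDS + 3'UTR with GT–AG introns inserted at chosen
mRNA points, then placed on a chromosome on a random strand (minus-strand
genes are reverse-complemented into the genome). Each AS gene carries a
major isoform and one minor isoform realizing exactly one planted event;
alternative donor/acceptor/position variants re-use intron-interior
sequence with planted GT/AG dinucleotides, so no post-hoc genome edits are
needed and all planted introns are canonical.

Design guarantees rather than probabilistic hopes: 5'UTRs are ATG-free, the
3'UTR begins with a stop codon in all three frames, CDS codons are drawn
from sense codons excluding ATG, and every constructed gene is verified
with the package's own ORF finder — the major isoform's longest ORF must be
the planted CDS and the event must locate to its intended mRNA feature; a
draw violating either is redrawn. ORF-located events are planted in the
second half of the CDS so that a frame-shift-truncated head ORF still
outweighs any downstream fragment. Changed lengths are drawn to cover both
multiples and non-multiples of 3.

Ortholog copies are mutated at 5% per base (splice dinucleotides — including
the planted minor-isoform sites — and start/stop codons protected; coding
substitutions that would create an in-frame stop are reverted), which
leaves protein identity around 0.85, comfortably above the 0.4 orthology
threshold. Shared events keep identical intron placement with 100-bp flanks
mutated at 10% (flank identity ≈ 90%). Species-specific events sit either
on genes whose ortholog partner carries no event (negative controls for
conserved-event precision) or on unpaired genes. Domains are exact peptide
motifs (no methionine, so no in-frame ATG) embedded to overlap or avoid the
event's affected protein region per truth, scanned by an exact-motif
scanner in place of an HMM search; exon-skipping genes carry two copies of
one motif, one inside the skipped exon, so per-copy domain loss is
exercised. Minor-isoform abundances default to 15–80% of the major (well
above the 5% filter); a flag plants an additional isoform at 2% whose event
must vanish after filtering.

What the generator does **not** emulate: realistic codon usage, intron
phase or length distributions, AT-richness of plant introns relative to
exons (sequence is uniform-GC, so AT-content contrasts are null here),
indels between orthologs, incomplete or mis-assembled transcript models,
and shared sequence between paralogs. Perfect recall/precision on synthetic
data therefore demonstrates the correctness of the logic under the stated
model, not expected performance on real assemblies, where filter choices
and assembly quality dominate.

## Problem sizes and determinism

The test suite runs the event caller against its brute-force oracle on 500
seeded random gene structures, recovers 50 planted events per type per
species (recall = precision = 1.0 on type and changed length), checks
frame-disruption consistency for every planted ORF event, enumerates all
2×2 Fisher tables with total ≤ 30, verifies the aligner on 100 seeded
peptide pairs and the ORF finder on 200 seeded sequences up to 2 kb,
recovers 20 shared events against 20 species-specific negatives at 10%
flank divergence, and confirms byte-identical outputs for repeated runs at
a fixed seed. These sizes were chosen to exercise every code path at a few
seconds to a couple of minutes each; all randomness flows from explicit
seeds, and the pipeline itself is a pure function of its inputs.

## Known limitations

* Pairwise event extraction with deduplication can differ from
  splice-graph grouping on genes with many isoforms (a three-isoform
  nested-variant gene may yield two events where a graph tool reports one
  complex event).
* E-values of the built-in translated aligner are per-comparison, not
  database-wide; porting thresholds from database BLAST output is not
  exact.
* Orthology is reciprocal-best-hit on one representative protein per gene:
  no synteny, no many-to-many families, no more than two species.
* Event quantification (PSI), novel junction discovery from reads, and
  transcript assembly are out of scope; the analysis starts from transcript
  models and abundance tables.
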