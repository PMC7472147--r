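---
title: "Virus discovery from shotgun metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virus discovery from shotgun metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viroscout)
```

## The problem

Tissue viromes are dominated by host and bacterial sequence: in a shotgun
library from a clinical or wildlife sample, reads from the viruses of
interest are typically a fraction of a percent of the pool, duplicated by
library PCR, quality-degraded toward their 3' ends, and occasionally run
through into the sequencing adaptor. `viroscout` implements the
computational half of a virus-discovery study as a single auditable
pipeline: aggressive background removal, ensemble de novo assembly tuned
for low and uneven coverage, translated homology classification with an
explicit virus/non-virus arbitration rule, hallmark-motif annotation for
the two small-DNA-virus families most often recovered this way
(parvoviruses and polyomaviruses), and identity-based comparison against
reference proteins.

Because real discovery datasets are large and external, the package ships
a first-class synthetic-data module. Every stage of the pipeline is
exercised, end to end, on seeded synthetic metagenomes whose ground truth
is known exactly, so each claim the pipeline makes (reads removed, genomes
assembled, taxa detected, motifs found) can be checked against a truth
table rather than against another tool's output.

## The synthetic community

`make_genome()` builds genomes from declarative specs. The two canned
viral specs mirror the genome organizations the annotation module targets:

* `parvovirus_like_spec()`: 4,620 bases, linear, two forward-strand ORFs.
  The replication ORF (NS1, 600 aa) carries the Walker A
  (`GxxxxGKT/S` — instance `GPASTGKS`) and Walker B (`uuuuD/ED/E` —
  `VIWIEE`) NTP-binding motifs plus two rolling-circle replication motifs
  (`xuHuHuuux` and `uxxYux-Kxx` — `TKLHTHLILG`, `VLTYTHKQT`). The capsid
  ORF (VP1, 700 aa) carries the phospholipase A2 catalytic `HD` and `D`
  residues and the `YLGPG` calcium-binding loop in its N-terminal region.
* `polyomavirus_like_spec()`: 4,800 bases, circular, four ORFs (VP2, VP1
  on the forward strand, the large T antigen on the reverse strand, and a
  small T ORF that wraps the origin). LT carries the `HPDKGG` DnaJ box,
  an `LXCXE` Rb-binding instance, a Walker A loop (`GPINSGKT`) and the
  `CXXC`/`CLVC`/`CFSC` zinc-binding clusters.

ORF peptides are drawn at random, the motif instances are overwritten
verbatim, and the peptides are reverse-translated with uniform codon
choice — so ORFs are stop-free by construction and every planted motif is
present exactly. Circular genomes are held as linear strings plus a
topology flag; reads and ORFs that cross the origin are built from the
doubled sequence.

`simulate_reads()` emulates a paired-end 2 x 250 run:

* **Qualities** start at Q37 and decline linearly to a floor (default
  Q17), with independent integer jitter (sd 2) per base. The floor was
  chosen once, as a typical tail for long paired-end chemistry: the
  template crosses the Q20 trimming threshold around 85% of the read, so
  quality trimming has real work to do without destroying the data.
* **Substitutions** are independent per base (default 0.2%).
* **Duplicates** are planted by re-emitting an exact fraction (default
  10%) of already-generated pairs byte-for-byte (qualities re-jittered),
  which exercises the positional deduplication key precisely.
* **Adaptor run-through** occurs whenever the sampled insert (default
  mean 350, sd 60) is shorter than the read; the read continues into the
  adaptor and then random sequence.
* A truth table records source genome, source coordinates (including
  origin wrap), and duplicate status for every pair.

What the generator does **not** model: platform-specific error spectra
(it has no indels and no motif-dependent miscalls), optical duplicates,
GC-coverage bias, or chimeric fragments. Tests passing on this generator
therefore demonstrate the pipeline's logic — key handling, thresholds,
graph construction, arbitration — not robustness to every artefact of
real instruments.

`make_protein_db()` builds the labeled search database: viral ORF
peptides diverged to a target identity (default 70%) under per-genome
taxa, host ORF peptides verbatim as `nonvirus` records, and random decoy
peptides under both labels so that best-hit arbitration has genuine
competition.

## Preprocessing

Stages run in a fixed order: deduplication, quality tail trimming,
adaptor clipping, length filtering, background subtraction.

* **Deduplication** keys each read on positions 5–55 from the 5' end
  (1-based, inclusive — 51 bases); reads shorter than the key interval
  are keyed on their full sequence, and grouping is exact string equality
  (an N matches only an N). One copy per group survives; the default
  keeps the first-seen copy for reproducibility, with a seeded
  random-survivor mode available. Deduplication runs on single reads, not
  pair-combined keys, and before trimming (so the key positions refer to
  the raw read).
* **Quality trimming** removes the contiguous 3' tail of bases below
  Phred 20, stopping at the first base at or above the threshold;
  internal low-quality bases are retained.
* **Adaptor clipping** clips from the earliest position where either the
  remaining read suffix exactly equals an adaptor prefix of at least 8
  bases, or the full adaptor matches with at most one mismatch. This is a
  deliberate simplification of general vector screening: the synthetic
  adaptors are known exactly, so BLAST-style scoring categories are
  unnecessary.
* **Subtraction** removes a read iff it has an ungapped alignment of at
  least 60 consecutive bases to a host/bacterial reference (either
  strand) with at most 2 mismatches and no gaps. The implementation seeds
  with exact 20-mers and scans the full diagonal of every seed hit with a
  sliding 60-base window. The seed length is exactly the pigeonhole
  bound: two mismatches split a 60-base window into three segments whose
  longest piece is at least 20 bases, so any qualifying window is
  guaranteed to contain an exact seed and the seeded search is equivalent
  to the exhaustive window scan (asserted against a brute-force oracle in
  the tests). N bases count as mismatches — ambiguous reads are retained
  conservatively.

## Ensemble assembly

Virus genomes in these libraries sit at low, uneven coverage next to
abundant background, which is why a single assembler pass is fragile. The
module combines:

1. **Multi-k de Bruijn assembly** (defaults k = 21, 31, 41, k-mers seen
   fewer than twice dropped). K-mers are strand-canonical (a k-mer and
   its reverse complement collapse onto the lexicographically smaller
   form; odd k avoids palindromes). Unitigs are maximal non-branching
   paths; a perfect cycle — a circular template covered end to end — is
   emitted linearly with a (k-1)-base terminal redundancy. Short
   dead-end spurs hanging off a branching node (tips under 2k bases) are
   clipped in one pass; bubbles are left to the consensus step, since at
   desk scale the multiplicity filter removes almost all error k-mers
   first.
2. **Partitioned sub-assembly**: reads are split at random (seeded) into
   4 partitions, each assembled independently at every k, and all unitigs
   pooled. Different partitions and k values break at different places;
   pooling gives the merger multiple overlapping drafts of the same
   genome. The partitioning criterion is an interpretation (random
   split); with one partition the stage degenerates to plain multi-k
   assembly.
3. **Greedy overlap-layout-consensus merging** over the pooled unitigs
   plus the reads themselves: fragments contained in a longer fragment
   (at 98% identity, either strand) are absorbed; remaining fragments
   merge longest-overlap-first when a suffix/prefix overlap of at least
   35 bases reaches 98% identity, in any relative orientation. Consensus
   over a disagreeing overlap column takes the longer fragment's base.
   Overlap candidates come from exact 16-mer probes at the prefix of the
   incoming fragment (positions 1 and 17), so a single early error
   cannot hide an overlap. The greedy merger keeps no full overlap
   graph; at desk scale, with deterministic ordering (fragments sorted
   by length then sequence), it is adequate and reproducible.
4. **Circularity detection**: a contig whose prefix and suffix share an
   exact terminal repeat of at least 20 bases is collapsed once and
   flagged circular; a repeat extending to half the contig length (for
   example a homopolymer) is ambiguous and left alone. A circular genome
   assembled end to end acquires its terminal redundancy naturally —
   either the k-1 wrap of a de Bruijn cycle or the final uncommitted OLC
   overlap — so the collapsed length equals the true circle length
   exactly when the consensus is error-free.

A contig supported by fewer than two reads is demoted back to a singlet
read; contigs and surviving singlets both proceed to classification, so
a virus present as a single read is still reportable.

The assembler's k values, multiplicity threshold, partition count and
OLC thresholds are package defaults chosen for 250-base reads and
genomes of a few kilobases; all are configurable through
`assembly_params()`.

## Translated classification

Queries (contigs + singlets) are translated in all six frames (standard
code, stops as `*`, trailing partial codons dropped) and searched against
the labeled protein database by exact 4-residue word seeding and ungapped
X-drop extension (drop 15) under BLOSUM62. Stop codons terminate
extension. Raw scores S convert to bit scores `(lambda*S - ln K)/ln 2`
and E-values `K*m*n*exp(-lambda*S)` with m the frame peptide length and n
the database residue count; lambda = 0.3176 and K = 0.134 are the
standard ungapped BLOSUM62 constants. The search space is raw `m*n` with
no finite-size correction — a deliberate simplification, conservative at
desk scale. There is no gapped stage and no low-complexity masking (the
synthetic sequences are complexity-controlled); word length 4 with exact
seeding suffices against desk-scale databases, where neighborhood words
would only add noise.

Classification proceeds in two passes, reproducing the discovery
pipeline's candidate/arbitration logic:

1. A query is a **candidate** iff its best hit against the viral records
   has E < 0.01.
2. Each candidate is re-searched against the **combined** database
   (viral + non-viral); hits with E < 10 are ranked by E-value, ties by
   raw score, residual ties with non-virus preferred, then record id.
   The candidate is retained iff the top hit is viral. The residual
   tie-break toward non-virus is a design choice: the arbitration step
   exists to suppress false viral calls, so an exact tie (the same
   protein under both labels) is resolved to removal. The E < 10 ranking
   window is likewise a documented choice — the arbitration rule itself
   specifies only the ordering.
3. Retained calls are grouped by database taxon; a taxon is flagged as a
   mammalian-virus **detection** iff its best E-value is below 1e-10.

## Annotation

`find_orfs()` reports ATG-initiated, stop-terminated ORFs on both
strands; circular sequences are scanned as a doubled string, ORFs
crossing the origin are reported once with a wrap flag, and ORFs longer
than the genome are rejected. The default minimum of 100 codons reflects
the smallest ORFs the hallmark panels target (polyomavirus small T).

The motif grammar compiles the field's degenerate notation into token
lists: `x`/`X` any residue, `u` uncharged, `-` any residue or none,
`T/S` one position matching either residue. The uncharged class excludes
D, E, K, R and H — histidine is treated as charged, the reading under
which every printed hallmark instance validates; the set is an argument
of `compile_motif()` for users who want histidine uncharged. One
consequence of taking the notation literally: the rolling-circle motif
`xuHuHuuux` matches the documented NS1 region at one residue past the
conventionally quoted 9-mer (the window `KLHTHLILG` inside
`TKLHTHLILG`), because the quoted excerpt itself places a charged K at a
`u` position; the scanner reports the matching window, not the excerpt.
Similarly, `CXXC-CLVC and CFSC` is read as three independent patterns
(`CXXC`, `CLVC`, `CFSC`) — the hyphen is prose, not a gap token; a
spaced-composite reading is scannable with the same machinery but is not
the default.

Hallmark panels: NS1 = Walker A + Walker B + both RCR motifs; VP1 = PLA2
`HD` + catalytic `D` 20–60 residues downstream (a literature-typical
spacing, configurable, since the source notation gives none) + `YLGPG`,
evaluated only in the N-terminal third of the ORF; LT = `HPDKGG` +
`LXCXE` + Walker A + the three zinc-binding patterns. A panel verdict
("consistent with ...") is issued per ORF iff every member hits. Panels
are evaluated on translated ORFs, not all six frames, because hallmark
motifs are properties of named proteins. Note that degenerate panels can
co-fire on long unrelated peptides (the LT ORF satisfies the NS1 panel
with non-negligible probability); the pipeline therefore prefers the
panel-complete ORF with the fewest other complete panels when it selects
the replication protein for demarcation.

Species demarcation follows the ICTV parvovirus rule: a genome is a
new-species candidate iff its NS1-like protein is strictly below 85%
identity to every reference, computed from a full-length (global)
alignment; 85.0% exactly is not a candidate.

## Comparison

Pairwise protein alignment uses affine-gap dynamic programming (BLOSUM62,
gap open 11, extend 1 — standard protein-search defaults; the method
source names none). Percent identity is identical columns over aligned
columns with gap columns excluded. Local identity over the aligned
region is the headline number for homology percentages, since reported
discovery identities derive from local search hits; global identity
backs demarcation. Both are available from `align_pair()`.

Neighbor joining is the package's own Saitou–Nei implementation:
standard Q-criterion, negative branch lengths clamped to zero with the
deficit shifted to the sibling, deterministic label-order tie-breaking,
and a trifurcating root for the unrooted result (an `ape` `phylo`
object). `ape::nj` serves as an independent cross-check in the test
suite, never as the implementation. Maximum-likelihood inference,
bootstrap support and tree figures are out of scope.

## Numerical and degenerate-input choices

* All randomness is seeded; `with_seed()` restores the caller's RNG
  state, and the pipeline derives per-stage sub-seeds from the global
  seed, so identical configs reproduce byte-identical artifacts.
* Zero-length reads after trimming are flagged by their length and
  removed by the length filter (default minimum 50 bases).
* An empty read set after subtraction produces a report with zero
  viruses, not an error.
* A genome shorter than the sampled insert is clamped to a whole-genome
  fragment; genomes shorter than 40% of the read length are skipped with
  a warning.
* Ties everywhere (OLC candidate order, arbitration ranking, NJ joins,
  dedup survivor) break deterministically, by explicit ordering rules.

## Problem sizes

The bundled demonstration community — and the scale at which the
acceptance checks run — is 50,000 pairs of 2 x 250 reads over a 200 kb
host genome, a 100 kb bacterial genome and the two viral genomes at 30x
coverage, with 10% duplicates and 0.2% substitution error. At this size
the full pipeline completes in well under a minute on one CPU; unit
tests use smaller communities of the same shape. These sizes were chosen
so that every stage (including the quadratic OLC merger) stays
comfortably in the regime it was designed for: a subtracted read pool of
a few thousand reads and genomes of a few kilobases.

## Known limitations

* The subtraction contract is the 60-base/2-mismatch/no-gap rule only;
  it is not a general local aligner and will not remove background that
  diverges by indels.
* The greedy OLC has no layout graph and can, in principle, commit to a
  locally-best merge; the partitioned multi-k pool makes this rare at
  desk scale but does not eliminate it.
* E-values use raw `m*n` search space without edge or length
  corrections, so they are conservative for short queries.
* Spliced gene models (VP1/LT isoforms) are not reconstructed; ORFs are
  contiguous.
* The generator's independence assumptions (per-base errors, uniform
  codon choice) make the synthetic task slightly easier than real data;
  see the generator section for what is not modeled.
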