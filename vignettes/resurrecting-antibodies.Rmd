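---
title: "Resurrecting a dominant antibody from degraded-RNA libraries: methods and design"
author: "IgRescue"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the pipeline

A tissue lesion dominated by a single expanded B-cell clone leaves its
antibody's blueprint in the tissue RNA. When that RNA is badly
fragmented — as it is in formalin-fixed, paraffin-embedded (FFPE)
archival material, where most fragments are shorter than 200 nt — no
single read spans an antibody variable region, and standard repertoire
tools that assume intact transcripts fail. IgRescue implements a
two-library strategy around that constraint:

1. A constant-region-primed, template-switch amplicon library
   (**Ig-seq**) reads upstream across the V(D)J junction of every
   expressed chain. It identifies each chain's CDR3 — the clone-defining
   region — and quantifies clonal dominance, but sees nothing upstream
   of the junction.
2. A **whole-transcriptome** fragment library covers the complete
   immunoglobulin transcripts in short, scattered pieces. Individually
   uninformative, these fragments collectively tile the full variable
   region.

The pipeline stitches the two together: the Ig-seq-derived junction of
the dominant heavy and light chain seeds a contig that is extended
3'→5' across the V segment by overlapping transcriptome reads, then
annotated against germline. Every stage operates on explicit,
checkable objects: a `GermlineSet` of annotated reference segments, an
AIRR-style clonotype table, a `RepertoireProfile`, an
`AssembledChain`, and a `ChainAnnotation`.

# Coordinate and anchor conventions

All coordinates are 0-based, half-open internally; human-readable
reports are 1-based. The V anchor is the second conserved cysteine
codon (IMGT position 104); the J anchor is the conserved tryptophan
(heavy) or phenylalanine (light) codon (IMGT 118). The **junction** is
anchor-inclusive (C…W/F); **CDR3** excludes both anchors. These
anchors are the structural guideposts every stage keys on: junction
calling projects them through read-to-germline alignments, seed search
demands the YYC-class motif upstream of the junction cysteine, and
germline validation rejects any reference segment whose anchor codon
fails to translate to C, W-followed-by-G, or an F-G-x-G run.

D segments are not modelled as separate references: the junction
between V and J absorbs all D-derived and non-templated nucleotides.
The procedure keys on junction identity, not D-gene calls, so a D
reference would add alignment ambiguity without changing any output.

# Alignment engine

Read-to-germline comparison uses an affine-gap local
(Smith–Waterman) aligner implemented in C++ (match +2, mismatch −3,
gap open 5, gap extend 2 — the megablast weights). A batch score-only
kernel in linear memory ranks alleles and strands for every read; a
full traceback runs only on the winning pair, yielding the identity
(matches / alignment columns, gaps included), the aligned intervals,
and the position map used to project anchor and CDR coordinates onto
reads and contigs. A 12-mer strand vote pre-screens read orientation;
any read whose vote is weak, or whose chosen orientation scores below
a floor, is scored both ways, so results match the exhaustive search.
Ties are broken deterministically everywhere: score, then identity,
then allele id lexicographically; within a traceback, diagonal over
vertical over horizontal, gap closure over extension; the best cell is
the first maximum in row-major order.

The test suite checks this engine against two independent routes: a
pure-R quadratic DP oracle written for the tests (score, identity and
aligned-column equality, plus decision equality for the 80% filter on
threshold-straddling reads), and `Biostrings::pairwiseAlignment` score
equality on random instances.

# The synthetic-data generator

The generator is first-class, tested code: it defines the statistical
structure the analysis assumes, and emits a `SimTruth` mapping every
read to its clone of origin so pipeline output can be scored exactly.

**Repertoire.** One dominant clone at frequency `dominance` (default
0.6) plus background clones whose frequencies follow a discrete power
law `1/rank^power` (default exponent 1) normalised to the remaining
mass. In the default *paired* mode each B-cell clone contributes one
heavy and one light chain transcript at half the clone's frequency, so
the dominant clone sits at `dominance` within the heavy-chain view and
within the light-chain view alike — the "one H, one L" near-monoclonal
structure the pipeline is designed to detect. The dominant clone is
IgG-switched and kappa by default.

**Transcripts.** Each chain transcript is leader + germline V (up to
the anchor) + junction + germline J (after the anchor) + constant
segment + 3' tail. The 60-nt untemplated leader models the 5'
UTR/leader peptide upstream of the V start; without it no uniformly
sampled fragment would ever cover the first V base and the assembler's
"projected V start reached" stop could never fire. Junctions are
sampled as germline anchor codons flanking random stop-free codons
(36–60 nt heavy, 27–45 nt light), unique per locus.

**Hypermutation.** SHM is drawn per base at `shm_rate` (default 0.02,
a heavily mutated memory/plasma-cell load) over the V and J portions;
the junction is excluded (it is clone-specific already), as are the
YYC motif and the codons flanking segment boundaries — a substitution
in the first V codon or the codons abutting the junction/constant
boundaries sits at a local-alignment edge where no caller can place it
unambiguously, so planting mutations there would make "exact SHM
recovery" an ill-posed target rather than a test of the caller. A
count mode (`dominant_shm_count`) plants an exact number of
amino-acid-changing substitutions in distinct codons for round-trip
tests.

**Fragmentation and damage.** Fragment lengths follow a truncated
log-normal; the default (median 200 nt, sdlog 0.55, truncation at
200/3 and 200×3, symmetric in log space) puts exactly half the mass
above 200 nt — DV200 = 50%, the borderline-usable degradation regime.
Fragments lie fully inside the transcript (standard shearing model).
Formalin damage is strand-asymmetric deamination, C→T and G→A on the
coding strand at a low residual per-base rate (default 0.002), as
after chemical reversal of formalin adducts.

**Libraries.** Ig-seq amplicons are template-switch tail + transcript
down to the constant-region primer site; the shipped primer table
(`inst/extdata/primers_igseq.tsv`) carries the reverse-transcription,
enrichment and indexing pools of the library design, and the toy
constant segments embed the matching sites a few bases into the
segment, as RT-in primers are designed, so amplicon reads retain
enough V context upstream of the junction. Reads are 150 nt, paired
by default, with i.i.d. substitution errors (default 0.5%); qualities
are constant because quality-aware processing is out of scope.
Transcriptome reads sequence each fragment in random orientation,
inward from both ends in paired mode.

What the generator does **not** emulate: PCR chimeras and cycle-wise
amplification noise, UMIs (the modelled protocol has none), indel
sequencing errors (off by default; the platform is
substitution-dominated), quality-score variation, allelic diversity
within a gene (toy alleles are random sequences, far more distinct
than real IMGT alleles), isotype subclasses, and cell-level H/L
pairing noise. Tests passing on this generator therefore demonstrate
algorithmic correctness under the stated statistical model — junction
recovery, frequency calibration, exact reconstruction at realistic
coverage — not robustness to chimeric artefacts or to the much finer
allele distinctions of a real germline database.

# Stage-by-stage parameters

**Junction calling** (`buildClonotypeTable`). Amplicon reads are gated
by their V alignment: identity ≥ 0.85 over ≥ 30 aligned nt (this is
the Ig-seq acceptance gate, deliberately distinct from the
transcriptome 80% filter below; amplicon reads should be
near-germline over their V flank, and 0.85 tolerates the combined SHM
plus error load). J alignments are gated at identity ≥ 0.85 over ≥ 18
nt — the J segment contributes only ~36 nt to a read. Anchors are
then projected through both alignments; a read is rejected with a
tallied reason (`no_v_hit`, `no_j_hit`, `anchor_uncovered`,
`anchor_lost`, `vj_inconsistent`) and accepted + rejected always
equals input. Translation frames come from the V anchor, never from
the read start, because the template-switch chemistry makes read
frames arbitrary. Out-of-frame or stop-containing junctions are
reported but excluded from frequency normalisation: a non-productive
chain cannot be the secreted antibody. Kappa and lambda are profiled
per locus and merged into one "L" view, mirroring how light chains
are read as a single competition.

**Error correction** (`errorCorrectClonotypes`). A clonotype within
`max_mismatches` junction substitutions of a clonotype ≥
`ratio_threshold` times more abundant (same locus/V/J) merges into it,
children processed in ascending count order, iterated to a fixed
point. Defaults: ratio 20, mismatches 2. The mismatch budget is sized
for 150-nt reads at ~0.5% error, where ~3% of junction observations
carry two errors and would otherwise persist as satellite clonotypes
that systematically deflate the dominant clone's frequency; the 20×
ratio gate is what keeps genuinely distinct clonotypes apart, since
co-occurring true clones of comparable abundance can never merge
regardless of distance.

**Clonality** (`profileRepertoire`). The quantile layer partitions
clonotypes by abundance *rank* into five equal-size bins (top 20% of
clonotypes = Q1), remainder clonotypes going to earlier bins — the
repertoire-visualisation convention — rather than by cumulative
frequency. The inner layer reports singleton, doubleton and "3+"
mass. Ranking ties break by junction sequence so profiles are
deterministic and row-order invariant. Both read-based and
corrected-table views can be profiled; the numerical profile is the
contract and the donut SVG is a thin optional rendering.

**The 80% VDJ filter** (`filterVdjReads`). A transcriptome read
enters the assembly pool iff its best local alignment to any V or J
allele reaches identity ≥ 0.80 over ≥ 30 aligned nt. "80% alignment"
admits a second reading — at least 80% of the read aligned — which is
available as `rule = "read_fraction"`; the identity reading is the
default because it is the quantity an aligner reports per hit and the
one under which the filter's behaviour is scale-free in read length.
Retained reads are strand-normalised to the coding strand.

**Seed search** (`findSeeds`). All occurrences of the target junction
within `seed_max_mismatches` (default 0 — the junction is known
exactly from Ig-seq), each required to carry an in-frame YYC-class
motif (`[YF][YF]C`) immediately upstream of the junction cysteine,
sorted exact-first then longest 5' flank first.

**Extension** (`extendContig`). The contig starts as the junction
itself — taking the known-exact Ig-seq junction rather than a whole
seed read keeps single-read errors out of the starting material. Each
iteration collects reads whose suffix overlaps the contig 5' end by ≥
`min_overlap` = 20 nt at ≥ `min_overlap_identity` = 0.95 (one
mismatch per 20), then extends column-wise by majority vote, each read
voting once per column. At most `extend_chunk` = 12 columns are added
before overlaps are re-collected: the live read set thins with depth
within an iteration, and votes taken at residual coverage 1–2 would
turn single read errors into spurious branch stops. Stops: (a) the
projected germline V start is reached — checked by aligning the contig
to the candidate V allele(s) and extrapolating through up to 6
clipped terminal columns, after which the contig is trimmed to the
projected start, and applied as a final override because a
multi-column iteration can legitimately run past the V start into the
untemplated leader; (b) no qualifying overlap (`no_overlap`, reported
at the exact gap edge); (c) a tie or runner-up support ≥ `branch_ratio`
= 0.8 of the winner (`ambiguous_branch`, at the exact divergence
column); (d) `max_iterations` = 10,000. 3' extension runs the same
machinery on the reverse complement, capped at `cap3` = 100 added
columns — enough constant region to call the isotype, which is all the
3' side is for. Mates are treated as independent reads; mate linkage
is not used in assembly.

**Polish.** One round re-maps every pool read to the contig (identity
≥ 0.9 over ≥ 20 columns) and takes a column-wise majority, recording
per-position coverage and agreement. Positions inside the junction are
pinned to the Ig-seq target — the junction is the one region known
independently of the transcriptome reads.

**Annotation** (`annotateChain`). Best-identity V allele over the
contig 5' of the junction (requiring ≥ 60 nt of V context), best J
allele 3' of it. CDR1/CDR2 boundaries are *projected* from the
germline allele's annotated IMGT-style coordinates through the
contig-to-germline alignment — a deliberate substitute for a full IMGT
gap-insertion engine, which is a project of its own and unnecessary
here because boundaries move correctly under indels by projection.
SHM calls compare contig to germline codon-wise outside the junction,
classifying silent versus amino-acid-changing at the codon level with
the frame anchored at the junction cysteine; positions with assembler
coverage < 2 or agreement < 0.7 are *uncallable*, never mutations —
this is what separates sequencing noise from SHM. Isotype comes from
the best-identity constant segment over its leading 60 nt (floor
0.7), or from a majority vote of constant-region reads with a support
fraction when a read pool is supplied.

# Pipeline, configuration, reproducibility

`resurrect()` runs extract → clonality → target selection (the rank-1
H and rank-1 L clonotype by default, overridable) → assemble →
annotate, writing the clonotype TSV, profile JSONs, contig FASTAs
with per-position coverage TSVs, annotation JSON/text reports, the
simulation truth when simulating, and the effective configuration,
whose MD5 stamps the run in `run_info.json`. All randomness descends
from one integer seed through fixed per-stage child streams
(`germline`, `repertoire`, `igseq`, `fragments`, `rnaseq`), so stages
are individually reproducible and reruns are byte-identical. A thin
command-line wrapper (`inst/scripts/resurrect.R`) exposes the same
functions as subcommands; block identity is a sample label only, and
assembly runs per sample with pooling available by concatenating read
sets.

# Problem sizes

The shipped tests and the acceptance script use deliberately compact
instances chosen to exercise every code path at realistic coverage:
20,000 Ig-seq reads over 51 clones for frequency calibration; 2,000
transcriptome fragments (tens-fold coverage of the handful of
simulated transcripts, standing in for the ~10^6-fragment scale of a
real library at equivalent per-locus depth); 20 independent seeds for
noiseless reconstruction; 500 threshold-straddling reads for the
filter-versus-oracle sweep; 200 random tables for the clonality
oracle. These sizes are the package's own validation design; nothing
in the method depends on them.

# Known limitations

- Allele assignment is relative to whichever germline reference the
  user supplies; no allele inference is attempted, and the toy
  reference's alleles are far more mutually distinct than real ones,
  so allele-call accuracy on real data will be lower.
- The assembler is a targeted seed-and-extend consensus machine, not a
  general assembler: co-dominant clones sharing a junction are
  detected as a branch and reported, not phased.
- SHM calls at segment-boundary codons are intrinsically
  alignment-ambiguous and are treated as uncallable territory by the
  generator's design; on real data, mutations in the first V codon or
  at the J–C boundary would likewise be unreliable.
- Isotype resolution stops at class (IgG/IgM/IgA); subclasses would
  need longer constant-region context than the 3' cap retains.
- The damage model is substitution-only; real FFPE artefact spectra
  include crosslink-driven stops and rare indels that the pipeline
  would see as coverage loss rather than miscalls.
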