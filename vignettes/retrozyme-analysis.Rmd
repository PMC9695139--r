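---
title: "Retrozyme discovery and RNA-population analysis with retrozymer"
author: "retrozymer authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrozyme discovery and RNA-population analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrozymer)
library(IRanges)
```

## The biological problem

Retrozymes are nonautonomous LTR retroelements whose long terminal
repeats (LTRs, roughly 300-400 bp) each carry a Type III hammerhead
ribozyme. A genomic retrozyme locus consists of two LTRs flanking a
unique central region (CR) bounded by a primer-binding site (PBS,
complementary to the 3' end of tRNA-Met) and a polypurine tract (PPT),
with a 4-nt target-site duplication (TSD) on either side of the element.
The transcript self-cleaves at the ribozymes, and the unit-length
monomer circularizes; the circle can then be copied RNA-to-RNA by a
rolling-circle mechanism, accumulating replication errors so that much
of the cellular retrozyme RNA population no longer matches any genomic
copy exactly. Because most retrozyme-derived small RNAs are 24 nt long
and LTR-derived, the genomic LTR — which doubles as the promoter — is a
target of RNA-directed DNA methylation and is heavily methylated.

`retrozymer` implements the computational side of this analysis as a
reusable pipeline: genome-wide locus discovery and structural
annotation, strict contig assembly of transcriptome reads, per-read
mismatch classification against the closest genomic copy, small-RNA and
bisulfite-methylation profiling, and seeded simulators that plant every
feature with a ground-truth record so that each stage can be verified
at desk scale.

## Locus discovery and annotation

### Homology scanning

`scanGenome()` is a BLAST-style seed-and-extend search: exact k-mer
seeds (default k = 12) are located on both strands with a `PDict`
lookup, clustered by alignment diagonal, and refined by a local
alignment under match +1, mismatch -2, gap -3 run by the package's own
dynamic-programming kernel. The `evalue_like` statistic is a
Karlin-Altschul-style surrogate computed from the score and the search
space; it ranks and filters hits but is deliberately not calibrated to
any external tool's E-values, which are version-dependent. Default
filters are identity >= 0.70, length >= 50 nt and `evalue_like` <=
1e-10; all are arguments. Externally computed tabular hits (outfmt-6
dialect) can be substituted via `importHits()`, which converts subject
coordinates with `sstart > send` into minus-strand features.

### From hits to loci

`pairLtrs()` pairs same-scaffold, same-strand LTR-sized hits (default
250-450 nt) whose gap is CR-sized (default 100-1500 nt). Chains of
three or more collinear LTR hits with CR-sized gaps are merged into a
single element flagged `tandem`, matching the incomplete tandem copies
expected from genome-integrated rolling-circle products. Unpaired LTR
hits adjacent to a CR-homologous hit become `cr_partial` loci; the rest
are `ltr_fragment`. These are the three completeness classes a genome
survey of this element family encounters.

Hit boundaries are refined before pairing by sliding the full-length
query (ungapped) over a window around each hit and taking the
minimum-mismatch placement. This pins exact element boundaries whenever
a copy diverges from the query by substitutions, which is the dominant
mode for LTR copies of a single family; heavily indel-diverged copies
fall back to the local-alignment boundaries.

Feature calls on each candidate:

* **TSD** — exact 4/4 match of the flanks immediately outside the
  element, no ambiguity codes, no tolerance (`detectTsd()`). Elements at
  scaffold edges return no TSD rather than an error.
* **PBS** — the longest interval inside the first 30 nt of the CR whose
  reverse complement equals a 3'-terminal substring (>= 10 nt) of the
  user-supplied tRNA-Met 3' sequence (`findPbs()`). No tRNA sequence is
  hard-coded: it is an input.
* **PPT** — the longest run with >= 90% purines and length >= 10 within
  the last 40 nt of the CR, ties resolved toward the 3' end
  (`findPpt()`).
* **LTR divergence** — `countLtrMismatches()` aligns the two LTRs
  globally (match +1, mismatch -1, gap -2) and reports substitutions
  plus gap columns, one per column regardless of gap length. This gives
  a reproducible integer "mismatch count" for dating insertions: the
  LTRs are identical at integration, so the count grows with genomic
  age.
* **Groups** — `classifyGroups()` clusters loci by pairwise global CR
  identity with constrained single linkage: clusters merge at identity
  >= 0.80 but never when any cross pair falls below 0.50, because loci
  whose CRs show no significant similarity must not share a group even
  through chaining. Labels are assigned by decreasing cluster size
  ("Group 1" is the largest), ties broken by the smallest member id,
  so labeling is deterministic.

### Hammerhead ribozyme detection

`detectHammerhead()` is a structure descriptor, not a thermodynamic
folding: minimum-free-energy prediction of the full element is out of
scope. The descriptor requires the conserved catalytic core — box 1
`CUGANGA` and box 2 `GAAA` 10-60 nt downstream — and three Watson-Crick
helices of at least 3 consecutive pairs: helix II between the segments
adjacent to the two boxes, helix I between the segment after box 2 and
the segment before the cleavage triplet, and helix III flanking the
catalytic core across the cleavage site (so that, on the circular
monomer, helix III closes the circle). The cleavage site sits
immediately 3' of the NUH triplet (H = A, C or U) closing helix I, per
standard hammerhead chemistry; the first nucleotide of the downstream
product — a G in the constructs used here — is what a 5'-RACE of the
self-processed RNA maps. One substitution at the conserved catalytic
residues is tolerated and reported (`coreIntact = FALSE`) rather than
suppressing the match, since natural loci carry such substitutions and
remain annotatable.

`exciseMonomer()` applies the cleavage convention to a transcript: with
two or more sites, the monomer is the sequence between the first two,
and its length is invariant under rotation of the underlying circle —
a property the test suite checks directly.

### Amplicon logic for circularity

`predictAmplicon()` reproduces the divergent-primer diagnostic for
circular or concatemeric RNA: primer sites are exact matches, and on a
circular template sites are searched on the doubled sequence, so an
outward-facing pair yields a junction-spanning product while the same
pair on the linear template yields nothing. Amplicon length runs from
the first base of the forward site to the last base of the reverse
site, inclusive. Predictions are invariant under rotation of a circular
template.

## The RNA population

### Read classification

`alignReadsToRefs()` aligns each read end-to-end against every
reference, both strands, at every placement (ungapped first; a banded
gapped fallback counts indels as mismatches), doubling the reference
when it is circular so junction-spanning reads align. The best
reference is the minimum-mismatch one, ties going to the lowest
reference id (multi-mapping between groups is otherwise arbitrary, and
the tie rule keeps it deterministic). Reads under 85% identity are
dropped and counted. Mismatch percentages are binned by round-half-up
to whole percent: 0 is "perfect", 1 "1%", 2 "2%", 3-13 "3-13%", above
13 ">13%" — for 100-nt reads one substitution is one percent, so the
bins match the published read-spectrum categories.
`mismatchSpectrum()` turns classifications into bin fractions that sum
to one.

### Strict assembly

Because a genome can carry many near-identical retrozyme copies, the
assembler must never bridge reads from different source RNAs.
`assembleStrict()` therefore (1) forbids any mismatch in an overlap —
merges need an exact overlap of at least 20 nt (the minimum is an
argument; no value is canonical) — and (2) caps contig extension at 25
nt *at the addition of each read*, so a foreign read can never anchor
to a long single-read overhang at a contig end. The cap's unit matters:
a contig-contig merge is legal only when it is realizable as sequential
single-read additions each within the cap. (An earlier draft capped the
total new sequence per merge; that reading makes the greedy result
depend on merge order — two legally built contigs could be forbidden
from joining even though adding the same reads one at a time reaches
the identical contig — and an exhaustive merge-order search finds
strictly fewer contigs. The per-read-addition reading removes the
discrepancy and follows the algorithm's description.)

Merging is greedy — longest overlap first, ties broken by contig ids —
making the output independent of input read order (a property test
shuffles inputs). Every member placement is re-verified against the
final contig with zero mismatches before the object is returned. For
small read sets the test suite compares the greedy contig count against
a memoized exhaustive search over all read-addition orders; the greedy
result matches the optimum on all tested sets, and `contigsVsGenome()`
then measures per-contig best identity against genomic copies, flagging
the exactly-identical ones.

## Small RNAs and methylation

`profileSmallRnas()` keeps reads of 18-30 nt and calls a read
retrozyme-specific only on a full-length exact match to a reference
(either strand, circular doubling); there is no mismatch tolerance, and
inputs are assumed adapter-trimmed. Region assignment (LTR vs CR) is by
majority footprint overlap. `scanMirnaSites()` slides each miRNA's
reverse complement along the doubled element and reports sites with at
most 4 mismatches — a "fewer than five" criterion for candidate
miRNA-binding sites.

`bisulfiteConvert()` converts unmethylated cytosines C to T with a
configurable conversion rate (default 1.0 in simulation; incomplete
conversion is a nuisance parameter, not corrected for in calling).
`callMethylation()` aligns each clone end-to-end to the unconverted
reference, calls each reference-strand cytosine methylated (C),
unmethylated (T) or uncallable (anything else, including gaps), and
labels contexts CpG, CHG, CHH (H = A, C, T) from the reference; only
plus-strand cytosines of the amplicon are called, as appropriate for
sequenced clones of a PCR product. Cytosines within two bases of the 3'
end default to CHH. Clones under 90% identity at non-cytosine positions
are excluded and reported. Pooled and per-context percentages are both
available, since a single pooled figure hides the context structure.

`compareMethylation()` tests the target against a control with a
two-sided Mann-Whitney U on per-clone methylated fractions — the
clone-resolved data structure makes the rank test the natural
distribution-free default; the underlying box-plot style comparison
does not name a test, so this is a documented package choice, with the
exact null used at 10 clones or fewer and cross-checked against an
exact permutation oracle in the tests.

## The simulators and what they emulate

Every simulator is a pure function of its configuration including the
seed, restores the caller's RNG state, and returns a ground-truth
record alongside its output, so parameter recovery can be asserted
exactly.

`simulateGenome()` plants full-length, CR-partial and LTR-fragment
elements in random background DNA (default GC 0.38, a Solanaceae-like
value). Defaults mirror the study conditions: nine full elements in two
groups of 7 and 2, 350-nt LTRs, group-specific CR lengths (600 and 450
nt), planted LTR-LTR substitution counts spanning 0-32 (two loci
identical, the rest graded), 4-nt TSDs, a PBS complementary to the
configured tRNA 3' sequence, a pure-purine PPT, and an intact synthetic
hammerhead cassette in every LTR (a fixture satisfying the descriptor,
not a claim about any natural ribozyme sequence). Incomplete elements
default to 5 CR-partial and 20 LTR-fragment copies, and a quarter of
fragments land on the minus strand. Two choices deserve note:

* Elements are spaced at least ~2.6 kb apart so that LTRs of unrelated
  elements can never satisfy the CR-gap pairing window — the simulator
  controls locus density, which real genomes do not guarantee.
* Planted LTR substitutions are kept at least a few bases apart.
  Clustered substitutions can create shift-ambiguous alignments whose
  optimal mismatch count undercounts the planted edits, making the
  ground truth itself ill-defined; isolated substitutions are always
  scored as mismatches, so the planted count is identifiable.

`simulateReplication()` applies r rounds (drawn from a configurable
distribution; degenerate or truncated-geometric) of per-base
substitution at rate eps per molecule, recording lineages. The expected
per-base divergence is `1 - (1 - eps)^r` up to rare back-substitutions
(second hits reverting a base), which at the rates used here are two
orders of magnitude below the Monte-Carlo error. `simulateReads()`
draws 100-nt single-end reads from uniform circular start positions and
strands, so junction-spanning reads occur at their natural frequency.
`simulateSmallRnas()` draws exact subsequences with an LTR-origin
probability (default 0.816) and a 24-nt-dominated length distribution,
emulating a DCL3-type siRNA library mapped to the element.
`simulateBisulfiteClones()` draws per-clone, per-site methylation
states from per-context rates and applies conversion.

What the simulations do *not* emulate: sequencing errors (a config hook
exists but is off — replication errors are the object of study and
sequencing noise would confound the divergence law), indel
polymorphism between RNA and genome copies, chimeric reads, genomic
repeats other than the planted elements, and CHH/CHG strand asymmetry.
Passing the recovery tests therefore demonstrates correctness of the
algorithms under their stated assumptions, not robustness to every
artifact of real libraries.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout (`IRanges`), converted
  at format boundaries (BED 0-based half-open, BLAST-tabular
  minus-strand encoding).
* Problem sizes in the tests and verification script are chosen for
  desk-scale runs: scaffolds of tens of kilobases, read sets of
  hundreds, a 12-point (eps, r) grid with 150 molecules and 300 reads
  per point, 10,000-read small-RNA libraries and 20-clone bisulfite
  sets. Statistical recoveries are asserted within 3 standard errors
  (or exact 95% binomial CIs), with clustering by source molecule where
  reads are correlated.
* Genome-scale survey tallies reported for the real *N. benthamiana*
  data (hundreds of genomic hits, hundreds of transcriptome contigs and
  their identity spectrum) depend on the genome draft and deposited
  read archives; the package reproduces the procedures, and its
  verification is parameter recovery on simulated data rather than
  re-deriving those archive-bound numbers.
* Degenerate inputs are contracts, not crashes: empty FASTQ files parse
  to empty sets, elements at scaffold edges yield no TSD, sequences
  without the catalytic core yield empty match lists, and a single
  ribozyme site yields no monomer.

## Limitations

The boundary-refinement step assumes substitution-dominated divergence
between family members and the query; indel-rich families would need
the gapped boundaries it falls back to, at some cost in exactness. The
scanner's significance surrogate is a filter, not a calibrated E-value.
The assembler is exact-overlap by design and will fragment data with
sequencing errors — upstream error correction or quality filtering is
assumed, as is adapter trimming for small-RNA libraries. Methylation
calling is plus-strand only and performs no conversion-efficiency
correction.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
res <- runPipeline(list(seed = 4), outdir = "rzk_run")
# writes loci.gff3, contigs.fasta, classifications.tsv,
# mismatch_spectrum.tsv, smallrna_profile.tsv, methylation.tsv and a
# manifest.json recording seed, config hash and package version
length(Filter(function(l) completeness(l) == "full",
              res$annotation$loci))   # 9 planted, 9 recovered
res$comparison$p_value               # LTR vs control methylation
```

Each stage is also callable alone (`scanGenome()`, `annotateGenome()`,
`alignReadsToRefs()`, `assembleStrict()`, `profileSmallRnas()`,
`callMethylation()`, the simulators), consuming and producing plain
files or in-memory objects, so any stage can be rerun independently.
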