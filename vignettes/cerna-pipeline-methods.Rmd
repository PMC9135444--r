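---
title: "Methods: lncRNA discovery and ceRNA network construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA discovery and ceRNA network construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernapipe)
```

# Scope and model

`cernapipe` implements the inference chain that leads from assembled
transcript models and an expression table to a competing-endogenous-RNA
(ceRNA) network: long non-coding RNAs (lncRNAs) that share miRNA binding
sites with mRNAs can titrate those miRNAs away, coupling the expression of
the lncRNA and the mRNA. The pipeline therefore needs, in order:

1. **lncRNA discovery** — filter assembled transcripts, remove anything
   with protein-coding capacity, and classify the survivors by genomic
   context;
2. **differential expression (DE)** between treatment conditions with
   fixed fold-change/p-value screens;
3. **cis targets** (genomic proximity) and **trans targets** (RNA--RNA
   duplex free energy) of the DE lncRNAs;
4. **miRNA interactions** — lncRNAs hosting miRNA precursors, miRNA
   target sites on mRNAs, and endogenous target mimic (eTM) sites on
   lncRNAs, all under a plant-style penalty scoring;
5. **network assembly** — ceRNA triples (lncRNA, miRNA, mRNA) that share
   a miRNA and are concordantly, significantly differentially expressed,
   plus degree-based hub ranking and hypergeometric term enrichment.

The experimental design emulated throughout is a three-condition nitrogen
experiment (nitrate, ammonium nitrate as the reference, ammonium) with
three replicates each; contrasts always compare a treatment against the
reference condition.

# Discovery filters and the coding-potential stand-in

Transcripts are retained when their spliced length is at least 200 nt
**and** their assembler read-coverage fraction is at least 0.5; both
boundaries are kept (exactly 200 nt, or coverage exactly 0.5, passes).
Transcripts with unknown coverage fail the coverage filter, which is the
conservative choice; the filter can be disabled in `run_config()`.

Coding potential is decided by two independent scores combined with a
conjunction: a transcript is non-coding only when *both* scores fall
below their thresholds (defaults $-1$ and $0$).

* The **ORF score** is $4(c - 0.5) + 2\log_2\frac{L+1}{300}$, where $L$
  is the longest ORF in nt (ATG to the first in-frame stop, stop
  included; truncated at the transcript end when no stop follows) and
  $c = L/\text{len}$ its coverage of the transcript. It is monotone in
  $L$: extending the longest ORF never lowers it. The weights and the
  $-1$ default were calibrated on simulated coding transcripts (ORF
  covering ~75% of an ~800-nt mRNA scores about $+3$) versus simulated
  noncoding transcripts (chance ORFs below ~120 nt score below $-2.5$).
* The **hexamer score** is the mean in-frame log2-odds of the hexamers
  (adjacent codon pairs, step 3) in the longest ORF — or the whole
  sequence in frame 1 when no ORF exists — under a position-specific
  codon-usage model against a uniform background. The model favours
  G/C-rich codons, especially at the wobble position, as in plant coding
  sequence; random sequence scores clearly negative, model-sampled CDS
  clearly positive. Sequences shorter than 6 nt score 0.

The conjunction mirrors two-classifier screens in which each classifier
must independently call the transcript non-coding. Because the
thresholds are data-scale choices, `calibrate_coding_thresholds()` can
re-derive both as class-mean midpoints from any labelled (e.g.
simulated) sequence sets.

**Limitation.** These scores are deliberate stand-ins for trained
coding-potential classifiers; they carry no protein homology information,
so a transcript that happens to contain a long, composition-biased chance
ORF can be miscalled coding. On the simulator's output this affects only
genome-derived (sense/antisense) exemplars occasionally, never the
planted interaction lncRNAs.

# Genomic classification

Each candidate gets exactly one of five labels, first match wins:
antisense (exonic overlap, opposite strand), sense (exonic overlap, same
strand), intronic (contained in an annotated intron, either strand),
bidirectional (no gene overlap; transcription start within 1,000 nt of a
gene start in divergent, head-to-head orientation), intergenic
(otherwise). The precedence order and the 1,000-nt promoter window are
design choices that make the five classes mutually exclusive; both are
configurable, and the synthetic generator uses the same window so planted
labels are recoverable by construction. A candidate that overlaps a gene
without touching an exon and without full intron containment falls
through to intergenic.

Intervals are represented as `GenomicRanges` objects throughout (1-based,
closed, the Bioconductor convention), so GFF3/GTF coordinates round-trip
unchanged and all overlap arithmetic is delegated to `IRanges`.

# Differential expression

FPKM is computed as $\text{fragments} \times 10^9 / (\text{length}_{nt}
\times \text{library total})$ when fragment counts are supplied; the
simulator emits FPKM directly. Per contrast, the fold change is
$\log_2\frac{\bar{x}_{\text{trt}} + p}{\bar{x}_{\text{ctl}} + p}$ with
pseudocount $p = 0.1$ guarding zeros, and significance requires
*strictly* $p < 0.05$ and $|\log_2 FC| > 1$ (a fold change of exactly 1,
or p of exactly 0.05, is not significant).

The test is a pooled-variance two-sample t-test on
$\log_2(\text{FPKM} + p)$. At this design's replicate number (3 vs 3)
the pooled test holds its nominal size under the log-normal noise model
(empirical type-I error $\approx 0.05$), whereas the Welch form is
noticeably conservative ($\approx 0.033$) because its Satterthwaite
degrees of freedom collapse at $n = 3$; Welch remains available via
`de_test(..., var_equal = FALSE)` for heteroscedastic data. Transcripts
with zero variance in both groups get $p = 1$ (equal means) or $p = 0$.
No multiple-testing correction enters the screen — the thresholds above
are applied to raw p-values — but a Benjamini–Hochberg FDR column is
emitted for reference. RT-qPCR relative expression is provided as the
closed form $2^{-\Delta\Delta C_t}$.

# Target prediction

**Cis**: every annotated gene on the same chromosome within 100 kb
(inclusive at exactly 100,000 nt; gap measured between closest interval
edges, 0 for overlap; strand ignored) of a DE lncRNA.

**Trans**: the minimum intermolecular duplex free energy between the two
transcripts under a nearest-neighbour stacking model with Watson–Crick
and G:U pairs. The duplex model is a single antiparallel helix optionally
interrupted by one interior loop/bulge with affine cost
(`loop_open` 3.0 + `loop_ext` 0.5 per unpaired base, at most 8 unpaired),
and no intramolecular structure — small enough to verify against
exhaustive structure enumeration, rich enough that a planted 30-bp
complementary stretch scores far below the screening cutoff. Stacking
parameters ship as a plain-text table (`inst/extdata/nn_stacks.tsv`):
Watson–Crick entries follow the standard Turner free energies, G:U
entries are Turner-style approximate values; the table is pluggable, so
the energy scale (and hence the meaning of the unitless $-50$ cutoff) can
be recalibrated. Pairs are retained when energy is strictly below $-50$.
The computation is symmetric in its arguments, reports 0 exactly when no
stabilizing duplex exists, and is invariant to padding either sequence
with non-pairing bases.

# miRNA interactions

**Precursor detection** requires the mature miRNA to occur verbatim
(100% identity, sense orientation — a precursor is transcribed with its
host) in the lncRNA, on the miRNA's annotated chromosome when a
chromosome map is given. Each match is then folded: a window of 150 nt
flank on each side of the match is subjected to base-pair maximization
(Nussinov dynamic programming, Watson–Crick + G:U, minimum hairpin loop
3). The hit passes when at least 60% of mature positions are paired and
all partners lie on one side of the mature span — i.e. the mature sits
in one arm of a stem-loop; a mature straddling the loop apex fails. Pair
maximization is a stand-in for free-energy folding: it is exactly
testable against enumeration, at the cost of ignoring stacking
thermodynamics; the 60%/single-arm/flank-150 thresholds are documented
defaults, all configurable.

**Target and eTM scoring** uses the plant-style zone-resolved penalties:
miRNA positions 2–13 from the 5' end form the strict zone (the cited
tools' convention; the zone bounds are configurable since only the zone
names are standard), where a mismatch or a gap ("missing" position)
costs 1 and a G:U wobble 0.5; outside the zone the penalties halve (0.5,
and 0.25 for G:U — the non-strict wobble penalty is our halving choice,
consistent with the halved mismatch penalty). At most 2 gaps are allowed;
a gap consuming a site base (target bulge) is charged at the next miRNA
position's zone. The minimum-score alignment over all gap placements is
found by dynamic programming and verified against exhaustive alignment
enumeration. A site is accepted when its score is at most 2.5
(inclusive — a site scoring exactly 2.5 passes). Scanning slides every
window of width $|\text{miRNA}| \pm 2$ over the transcript; overlapping
acceptable windows are resolved to minimal-score non-overlapping sites
with deterministic ties (leftmost start, then shortest). eTM prediction
is the same scan over DE lncRNAs; one lncRNA may mimic several miRNAs.

# ceRNA network

A triple (L, m, M) is emitted iff L has an eTM site for m, M has a
target site for m, both L and M are significant in the contrast, and
their directions agree. Triples are contrast-specific — the same
lncRNA–mRNA pair can legitimately appear with opposite directions in
different contrasts — and the pooled table simply concatenates
contrasts. Hubs are ranked by plain degree (distinct miRNA ∪ mRNA
neighbours, lexicographic ties): "most connected" is read literally, and
no other centrality is in scope. Enrichment is an upper-tail
hypergeometric test per term with BH-FDR across terms, against a
user-supplied term→gene map; the background defaults to all expressed
mRNAs.

# The synthetic generator and what passing tests mean

`generate_cerna_dataset()` writes a complete dataset (genome FASTA,
gene annotation GFF3, assembled-transcript GTF with a `cov` attribute,
transcript and mature-miRNA FASTA, FPKM + design tables, a term map) plus
a machine-readable truth bundle. Key construction choices:

* **Geometry.** Three 300-kb chromosomes. Class exemplars are placed to
  satisfy their label by construction (e.g. intronic lncRNAs centred in a
  1.4-kb intron; bidirectional lncRNAs head-to-head 200–800 nt from a
  gene start); cis constructs use gaps of 2, 10, 30, 60 and 95 kb, all
  within the window; features keep ≥ 3 kb clearance otherwise, so no
  unintended class assignment can arise.
* **Sequences.** Coding transcripts are 5'UTR + 201-codon ORF + 3'UTR
  sampled from the same codon-usage model the hexamer score assumes.
  Noncoding sequence is AT-biased (30/20/20/30), and any chance ORF
  longer than 120 nt is interrupted with a stop codon — a transcript
  labelled noncoding must actually lack coding capacity, otherwise the
  planted truth itself would be wrong. Planted content (perfect-
  complement miRNA sites at fixed offsets; 30-nt GC-rich trans
  stretches re-drawn until their duplex energy clears the screen with
  margin, of mixed composition so an insert cannot dominate its host's
  hexamer score; 60-8-60 inverted-repeat precursor hairpins) is
  inserted afterwards, and ORF disruption is re-run around, never
  inside, the planted regions — within a hairpin only the mature miRNA
  copy is untouchable, since a stop codon elsewhere in the stem leaves
  the mature's paired fraction far above the 60% rule.
* **Expression.** $\log_2 \text{FPKM} = \text{baseline} \sim N(4, 1)$
  plus the planted signed effect ($\pm 2$ in the assigned contrast's
  treatment condition) plus $N(0, 0.25)$ noise; 3 conditions × 3
  replicates. At these settings the per-transcript recovery probability
  of a planted effect is effectively 1, which is what makes the 100%
  recovery checks meaningful rather than lucky.
* **Decoys.** Five decoy triples are always emitted, each violating
  exactly one ceRNA condition (discordant directions; lncRNA not DE;
  mRNA not DE; no eTM site; no target site), so the network tests check
  specificity as well as sensitivity.
* **Determinism.** All generator randomness derives from one seed
  (sub-stages use fixed offsets of it); the same seed yields
  byte-identical files.

What the simulator does **not** emulate: read-level noise and alignment
artefacts, isoform complexity, dispersion that varies with expression
level, correlated replicates, and real lncRNA/mRNA sequence families.
Passing the planted-truth tests therefore demonstrates that the
implementation applies its stated rules exactly — not that the rules
themselves would achieve comparable sensitivity on real libraries.

# Numerical and degenerate-input choices

Penalties and energies are compared with absolute tolerance $10^{-9}$ in
the kernels; site selection and hub ranking have deterministic
tie-breaks; empty inputs yield empty, well-typed tables rather than
errors; parsers reject malformed records (duplicate ids, orphan exons,
non-numeric cells) instead of repairing them. T and U are equivalent
everywhere: sequences are canonicalized to the DNA alphabet on ingest,
so mature miRNAs supplied as RNA align against genomic DNA without
special cases.

# Problem sizes used by the test suite

The shipped suite runs the generator at its default size (three 300-kb
chromosomes, 40 genes, 37 lncRNAs, 16 miRNAs), verifies the three
dynamic-programming kernels against brute-force enumeration at the sizes
where enumeration is exact and fast (sites ≤ 24 nt with ≤ 2 gaps, duplex
pairs ≤ 12 nt, folding windows ≤ 24 nt), and calibrates the DE test with
10,000 null transcripts and 200 simulated effect datasets. These sizes
were chosen so every check is exhaustive or statistically stable at
desk scale.
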