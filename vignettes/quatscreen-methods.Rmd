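---
title: "Methods: screening, profiling and quantifying TMA-producing gut bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, profiling and quantifying TMA-producing gut bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Trimethylamine (TMA) is produced by gut bacteria from dietary choline and
carnitine, and its host-oxidized form TMAO is associated with
atherosclerosis. The producers are rare (typically well below 1% of the
community) and phylogenetically scattered, so 16S rRNA surveys cannot
identify them; detection has to go through the pathway genes themselves:
the choline TMA-lyase gene *cutC* (with its activator *cutD*) and the
carnitine oxygenase gene *cntA* (with its reductase *cntB*; *yeaW/X*
homologs are folded into the *cntA* family). quatscreen implements the
computational framework around these genes: building reference databases
from annotated genomes, checking degenerate assay primers, profiling
functional amplicons, and quantifying the pathways in shotgun metagenomes.

## Profile models

Family detection rests on position-specific profile models built from a
seed protein alignment (`build_profile()`). Match columns are alignment
columns with at most 50% gaps; emissions are Henikoff position-weighted
residue counts with +0.5 pseudocounts, expressed as log2-odds bits against
the Robinson-Robinson (BLOSUM62) background; alignment is local Viterbi
over match/insert/delete states with affine penalties (defaults 3/1 bits
for both gap directions). The published workflow's HMM tooling does not
document its weighting or pseudocount settings, so these are package
decisions, kept configurable. Models are refined by the standard
realign-and-rebuild cycle (`refine_profile()`, default 3 cycles), which on
stable seeds converges by the second cycle. Scores are reported in bits;
no e-value calibration is attempted because every downstream rule is a
relative one (score drop, fraction of top score, coverage fraction).

Coverage of an alignment is the fraction of model columns spanned by the
aligned region; sequences under 80% coverage are dropped as partials
before any further screening.

## The multi-parametric genome screen

`build_gene_database()` reproduces the screening logic end to end:

1. score every annotated protein, keep the top N (N is a study-size
   parameter: the published screens kept the top 3,000/10,000 of 67,134
   genomes; our planted-truth fixtures keep the planted family size);
2. collapse identical proteins (`dereplicate()`), carrying all member
   genomes;
3. drop partials (<80% model coverage);
4. check signature residues (e.g. the carnitine oxygenase "bridging"
   glutamate) against model columns — a deletion at the column fails the
   rule;
5. compute each candidate's cophenetic distance to the top-scoring
   sequence on a neighbor-joining tree built from p-distances over shared
   match columns (pairwise deletion of gaps), via `ape::nj()` and
   `ape::cophenetic.phylo()`;
6. test synteny with the partner gene: a partner-model hit scoring at
   least a fraction of the top partner score (51%/26% in the published
   assays), on the same contig, within 10 genes by locus-tag order;
7. set the score cutoff at the largest *relative* drop between
   consecutive sorted scores, taking the median (= mean) of the two
   framing scores. The scan starts at rank 2 so a single outlier top
   score cannot anchor the drop — the published cutoffs sat at an
   "obvious drop", not necessarily the global gap from rank 1. If the
   scores carry no drop the auto mode refuses and demands a manual value.

The optional phylogeny filter mirrors the published *cntA* exclusion of
34 *Bacilli* proteins: that exclusion is narrative in the source, so our
operationalization — exclude above-cutoff candidates whose distance to the
top sequence exceeds a configurable quantile (default 0.95) of
above-cutoff distances *and* whose synteny failed — is a package decision,
logged whenever it fires. Multi-copy genomes are reported (flagging
non-identical copies), never filtered.

The assembled database carries the targets (nucleotide + protein +
optional taxonomy + 90% nucleotide complete-linkage cluster labels) and an
outgroup of top-scoring below-cutoff sequences — 300 unique proteins for
amplicon correction, 500 unique nucleotide sequences for metagenome
search. The outgroup exists so near-miss homologous reads are *captured
and rejected* rather than mis-assigned to targets.

## Degenerate primers

Primer degeneracy is the product over positions of IUPAC set sizes, with
inosine contributing a factor of one (it pairs universally and adds no
synthesis variants). In-silico PCR matches the forward primer on the
template and the reverse primer as its reverse complement, allowing one
mismatch per primer by default; both template orientations are scanned and
product lengths exclude the primers. Products over 5,000 nt are suppressed
as artifacts. Template ambiguity codes count as a match when the two base
sets intersect. The shipped assay primer file reproduces the published
degeneracies 32/16/32/512 for the cutC/cntA pairs; the printed 16S forward
degeneracy (32) conflicts with its printed sequence (which computes to
24), so that primer is shipped but not used as a numeric anchor.

## Amplicon profiling

Reads are merged at the best ungapped overlap (minimum 20 nt, mismatch
fraction at most 0.1, higher-quality base called in the overlap) and
filtered at mean Q25 — the upstream toolchain's exact merge parameters are
unpublished, so this contract is ours. Each merged read is then aligned
against the full reference panel (targets + outgroup) by a
frameshift-aware translated dynamic program: codon states scored with
BLOSUM62, protein-level affine gaps (-11/-1), and frameshift transitions
consuming 2 or 4 nt at -12 per event — the customary defaults of
frameshift-correcting amplicon tools, since the published pipeline ran its
corrector "in default mode". Repair rules: a 4-nt event keeps whichever
nt triple scores best against the aligned reference residue; a 2-nt event
cannot recover the lost base and is repaired to a codon encoding the
reference residue (this is forced by requiring the corrected protein of a
single-deletion read to equal its source fragment). Reads whose best
reference is in the outgroup, or whose corrected frame contains a stop,
are rejected and tallied per sample; samples whose failure rate exceeds
50% are flagged for quality review, mirroring the published exclusion of
one sample in which nearly all reads failed correction.

For clustering, corrected proteins are aligned to the model and
back-translated, giving equal-length codon rows. Pairwise identity is
matches over *shared* columns: columns outside either sequence's aligned
span are missing data (pairwise deletion), gap-gap columns are ignored,
and a residue against an internal gap counts as a difference. Treating
terminal overhangs as missing is what lets full-length references join the
alignment directly — each read-versus-reference comparison is
automatically confined to the amplicon region — and keeps reads with
locally clipped ends from splintering off their population. Clustering is
complete linkage (`stats::hclust` + `cutree` at 1 - cutoff), so every
within-cluster pair meets the identity threshold; merge order is
deterministic, and tied merge decisions (possible because identities are
ratios of small integers) follow hclust's ordering — the tests verify
equivalence with naive agglomeration on tie-free instances. Clusters with
fewer than 5 reads are dropped, tables are rarefied to even depth by
seeded sampling without replacement (`vegan::rrarefy`), and diversity is
summarized across the 99/98/95/90% cutoffs with prevalence bins (<10%,
10-50%, 50-90%, >90% of samples).

Co-occurrence networks use Spearman's rho on midranked relative
abundances over clusters present in at least half the samples; p-values
use the t-approximation (adequate at the study's n = 50; a permutation
test would add nothing but runtime) and q-values are Benjamini-Hochberg
over all tested pairs; edges require rho >= 0.5, p < 0.01 and q < 0.01.
Ordination is Bray-Curtis NMDS via `vegan::metaMDS` under a fixed seed.

## Metagenome quantification

Shotgun reads pass the q30/p50 filter (at least half the bases at Phred
>= 30), are searched with blastn against the target + outgroup nucleotide
panels and the rplB panel, and each read keeps its top hit by e-value
(ties: bitscore, then reference id). Retained hits must cover >= 70 bp at
>= 70% identity; outgroup top-hits are recorded and excluded from
abundance. The published normalization is not written as a formula; ours
is: per gene g, a_g = retained read count / median reference length (bp),
and pathway percent of community = 100 * median(a_gene, a_partner) /
a_rplB, reported only when both pathway genes are observed (the both-genes
rule). Gene-length correction is applied to targets and rplB
symmetrically. Taxonomic binning assigns each read its top-hit reference's
label (90% reference cluster for the choline pathway, genus bin for the
carnitine pathway); per-taxon abundance is the median across the pathway's
two genes of length-normalized counts — the source does not state whether
its medians are taken before or after length correction; we correct first
and keep the order configurable.

## Synthetic fixtures and what they show

Every stage is testable without downloads through seeded generators:
genomes with planted target/partner cassettes (including the boundary
separations 10 and 11), decoy homologs at 50-70% core identity with
scrambled signature residues, a single-copy rplB in every genome; amplicon
reads with per-base substitution/indel planting and recorded error events;
uniformly fragmented metagenomes whose truth carries the analytic expected
percent of community (window counting of read starts overlapping each gene
by at least 70 bp); and abundance matrices with exact rank-tied cluster
pairs. Generators are pure functions of (spec, seed). Deliberately absent:
empirical quality/error models, GC or coverage bias, chimeras, and real
taxonomic structure — passing tests demonstrate the algorithms' contracts
and planted-truth recovery, not performance on real gut communities.

Default test problem sizes are small by design: 25-genome fixtures with 50
decoys for the screen; 20-genome communities at 20x coverage and 150-nt
reads for the estimator (recovery within +-15% relative error is asserted
on the mean over 10 seeds per carrier fraction, since a single seed's read
counts carry several percent of Poisson noise at these depths); 3 samples
by 800 reads for the end-to-end amplicon check.

## Numerical choices and degenerate inputs

Bit scores are doubles; score ties in screening are broken by (genome,
contig, locus) for determinism. The frameshift DP uses integer BLOSUM62
entries and integer penalties so implementation and oracle can be compared
cell-exactly; its traceback preference is fixed (codon > 2-nt > 4-nt
event; match > insert > delete > restart). Empty sequences score -Inf with
coverage 0. Auto cutoff on an all-equal score series is an error, not a
guess. Rarefaction refuses depths above the smallest sample total.
`cooccurrence()` refuses fewer than 4 samples. In-silico PCR on a template
without both sites returns an empty product table, not an error.

## Known limitations

The screen's accuracy on real genomes depends on seed-alignment quality
and on annotation completeness (unannotated ORFs are invisible). The
internal profile engine is deliberately minimal — no e-values, no DNA
models, no glocal mode — and the pluggable contract allows substituting an
external profile-HMM engine where calibrated statistics matter. The
metagenome estimator is read-counting, not assembly; at realistic target
abundances (~0.1% of the community) it needs deep sequencing, and the
package intentionally does not implement gene-targeted assembly. Taxonomy
of references is user-supplied metadata; no classifier is bundled.
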