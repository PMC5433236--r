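# quatscreen

Gene-targeted screening and quantification of trimethylamine (TMA)-producing
gut bacteria.

TMA is produced by intestinal bacteria from dietary quaternary amines —
mainly choline, via the choline TMA-lyase gene *cutC* (with its activator
*cutD*), and carnitine, via the carnitine oxygenase gene *cntA* (with its
reductase *cntB*). Its host-oxidized product TMAO is associated with
atherosclerosis and cardiovascular disease. The producers are rare and
phylogenetically scattered, so taxonomic (16S rRNA) profiling cannot find
them; quantifying the *potential* to make TMA requires assays against the
pathway genes themselves. quatscreen implements the computational framework
for such assays, end to end, for people building or applying functional
gene-targeted assays in microbiome research:

* **Database building** — a multi-parametric screen of annotated genomes:
  profile-model bit score, alignment coverage (≥ 80%), conserved signature
  residues, cophenetic distance to the top-scoring sequence on a
  neighbor-joining tree, and synteny with the partner gene (≤ 10 genes
  apart by locus-tag order); the score cutoff sits at the largest relative
  drop of the sorted score curve, `cutoff = (s_i + s_{i+1}) / 2` over the
  framing pair. The database carries the targets plus a below-cutoff
  *outgroup* (300 unique proteins / 500 unique nucleotide sequences) used
  to capture and reject near-miss homologs downstream.
* **Primer toolkit** — degeneracy arithmetic over IUPAC codes (inosine
  counts 1), in-silico PCR with one mismatch per primer, database coverage,
  and primer trimming.
* **Amplicon profiling** — paired-read merging (mean Q ≥ 25), a
  frameshift-aware translated aligner (BLOSUM62, gap −11/−1, frameshift
  −12) that repairs 1–2 nt slips against the reference panel, stop-codon
  and non-target rejection, codon-aware alignment, complete-linkage
  clustering at 99/98/95/90% nucleotide identity (clusters with < 5 reads
  dropped), seeded rarefaction, diversity and prevalence summaries,
  Spearman/Benjamini–Hochberg co-occurrence networks (ρ ≥ 0.5, p < 0.01,
  q < 0.01, prevalence ≥ 50%), and Bray–Curtis NMDS.
* **Metagenome quantification** — q30/p50 read QC, blastn search against
  the developed references, top-hit filtering at ≥ 70 bp and ≥ 70%
  identity, the both-genes rule, and pathway abundance as
  `100 · median(a_gene, a_partner) / a_rplB` with every gene length-
  corrected (`a_g` = retained reads / median reference length), normalized
  to the universal single-copy gene *rplB*.
* **Synthetic fixtures** — seeded generators for genomes with planted gene
  cassettes and decoy homologs, error-planted amplicon reads, metagenomes
  with analytic ground truth, and abundance matrices with planted
  correlation blocks, so the whole pipeline is testable offline.

## Worked example

Build a gene database from a seeded synthetic community with planted
targets, syntenic partners and decoy homologs, then check the assay
primers:

```r
library(quatscreen)

sim <- sim_genomes(n_genomes = 25, n_targets = 5, n_traps = 2,
                   n_decoys = 50, seed = 11)
res <- build_gene_database(sim$genomes,
                           seed_alignment = sim$target_family$seeds,
                           partner_seed_alignment = sim$partner_family$seeds,
                           top_n = 57, outgroup_protein_n = 30,
                           outgroup_nt_n = 30, gene_name = "cutC-like")
res$db
#> <gene_database> cutC-like: 7 target(s), 30 outgroup reference(s), cutoff 330.125 bits
table(res$candidates$status)
#>
#> below_cutoff       target
#>           50            7

sapply(tma_primers(), degeneracy)
#> cutC_F cutC_R cntA_F cntA_R  16S_F  16S_R
#>     32     16     32    512     24      1
```

The screen put all 7 planted high-scoring genes (5 true targets and 2
"traps" whose partner sits just outside the 10-gene synteny window) above
the automatic cutoff of 330.1 bits and all 50 decoy homologs below it; the
candidate table records the traps as non-syntenous (`partner_found =
FALSE`, `locus_separation = 11`). The degeneracies are the number of
distinct concrete oligonucleotides each degenerate assay primer encodes —
32/16/32/512 for the cutC/cntA pairs. (The shipped 16S forward primer
computes to 24.)

A thin command-line wrapper over the same functions ships in
`inst/scripts/quatscreen` with subcommands `build-db`, `primer-check`,
`profile-amplicons`, `quantify-metagenome` and `simulate`.

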