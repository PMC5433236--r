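# Metagenome quantification: read QC, nucleotide search against the
# developed references (targets + below-threshold outgroup), pathway
# abundance relative to the single-copy gene rplB (gene-length corrected),
# and taxonomic binning of reads via their top-hit reference.

#' Quality-filter shotgun reads
#'
#' Retains reads where at least `min_frac` of bases reach Phred quality
#' `min_q` (the classic q30/p50 rule). FASTA input (no qualities) passes
#' through unchanged.
#'
#' @param reads tibble from [read_reads()].
#' @param min_q per-base quality threshold (default 30).
#' @param min_frac minimum fraction of bases at or above `min_q`
#'   (default 0.5).
#' @return filtered read tibble.
#' @export
qc_reads <- function(reads, min_q = 30, min_frac = 0.5) {
  if (nrow(reads) == 0) return(reads)
  keep <- vapply(reads$qual, function(q) {
    if (is.null(q)) return(TRUE)           # FASTA pass-through
    mean(q >= min_q) >= min_frac
  }, logical(1))
  reads[keep, , drop = FALSE]
}

#' Search reads against a nucleotide reference set
#'
#' Runs a local nucleotide similarity search (blastn) of the reads against
#' the reference panel, keeps each read's top hit by e-value (ties: higher
#' bitscore, then lexicographic reference id), and applies the minimum
#' aligned-length and identity filters. Hits whose top reference belongs
#' to the below-threshold outgroup are recorded but flagged for exclusion
#' from abundance. Pre-computed hits in BLAST tabular (outfmt 6) format
#' are accepted via `hits`.
#'
#' @param reads read tibble (`read_id`, `seq`), or `NULL` when `hits` is
#'   supplied.
#' @param refset tibble with `ref_id`, `nt`, `is_target` (and optionally
#'   `gene`, `taxon`).
#' @param min_len minimum aligned length in bp (default 70).
#' @param min_id minimum identity fraction (default 0.70).
#' @param hits optional pre-computed hit tibble or outfmt-6 file path.
#' @param evalue blastn e-value threshold.
#' @return tibble of retained top hits with `read_id`, `ref_id`,
#'   `identity`, `aligned_length`, `evalue`, `bitscore`, `is_target`.
#' @export
search_reads <- function(reads, refset, min_len = 70, min_id = 0.70,
                         hits = NULL, evalue = 1e-5) {
  if (is.null(refset) || nrow(refset) == 0) stop("empty reference set")
  if (is.null(hits)) {
    hits <- run_blastn(reads, refset, evalue = evalue)
  } else if (is.character(hits)) {
    hits <- read_hit_table(hits)
  }
  if (nrow(hits) == 0) return(dplyr::mutate(hits, is_target = logical(0)))
  top <- hits |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$ref_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  top <- top[top$aligned_length >= min_len & top$identity >= min_id, ]
  top$is_target <- refset$is_target[match(top$ref_id, refset$ref_id)]
  top$is_target[is.na(top$is_target)] <- FALSE
  top
}

run_blastn <- function(reads, refset, evalue = 1e-5) {
  if (!nzchar(Sys.which("makeblastdb")) || !nzchar(Sys.which("blastn")))
    stop("blastn/makeblastdb not found on PATH; supply pre-computed hits")
  td <- tempfile("qsblast")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  db_fa <- file.path(td, "refs.fna")
  q_fa <- file.path(td, "reads.fna")
  out <- file.path(td, "hits.tsv")
  write_fasta(stats::setNames(refset$nt, refset$ref_id), db_fa, "dna")
  write_fasta(stats::setNames(reads$seq, reads$read_id), q_fa, "dna")
  system2("makeblastdb", c("-in", db_fa, "-dbtype", "nucl"),
          stdout = FALSE, stderr = FALSE)
  status <- system2("blastn",
                    c("-task", "blastn", "-query", q_fa, "-db", db_fa,
                      "-outfmt", "6", "-evalue", format(evalue),
                      "-max_target_seqs", "20", "-num_threads", "1",
                      "-out", out),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("blastn exited with status ", status)
  read_hit_table(out)
}

#' Pathway abundance relative to rplB
#'
#' For each gene g the length-normalized abundance is
#' `a_g = retained read count / median reference length (bp)`; the pathway
#' abundance as percent of the community is
#' `100 * median(a_gene1, a_gene2) / a_rplB`. The pathway is reported as
#' detected only when both genes have at least one retained read and rplB
#' was observed.
#'
#' @param hits_gene1,hits_gene2 retained target hits of the pathway's two
#'   genes (from [search_reads()]; outgroup hits are dropped here).
#' @param hits_rplB retained rplB hits.
#' @param ref_lengths named numeric: median reference length in bp for
#'   `gene1`, `gene2`, `rplB`.
#' @param pathway label (e.g. `"cutC/D"`).
#' @param sample_id sample label.
#' @return one-row tibble with per-gene counts and abundances,
#'   `percent_of_community` and `detected`.
#' @export
pathway_abundance <- function(hits_gene1, hits_gene2, hits_rplB, ref_lengths,
                              pathway = "pathway", sample_id = "sample1") {
  cnt <- function(h) {
    if (is.null(h) || nrow(h) == 0) return(0L)
    if ("is_target" %in% names(h)) sum(h$is_target) else nrow(h)
  }
  n1 <- cnt(hits_gene1); n2 <- cnt(hits_gene2); nr <- cnt(hits_rplB)
  a1 <- n1 / ref_lengths[["gene1"]]
  a2 <- n2 / ref_lengths[["gene2"]]
  ar <- nr / ref_lengths[["rplB"]]
  detected <- n1 >= 1 && n2 >= 1 && nr >= 1
  pct <- if (detected) 100 * stats::median(c(a1, a2)) / ar else 0
  tibble::tibble(sample_id = sample_id, pathway = pathway,
                 count_gene1 = n1, count_gene2 = n2, count_rplB = nr,
                 abundance_gene1 = a1, abundance_gene2 = a2,
                 abundance_rplB = ar,
                 percent_of_community = pct, detected = detected)
}

#' Taxonomic profile of pathway reads
#'
#' Each retained read inherits the taxon label (90% reference cluster or
#' genus bin) of its top-hit reference; the per-taxon abundance is the
#' median across the pathway's two genes of the taxon's length-normalized
#' counts, ranked descending.
#'
#' @param hits_gene1,hits_gene2 retained target hit tibbles.
#' @param ref_taxa named character: `ref_id` -> taxon label.
#' @param ref_lengths named numeric with `gene1`, `gene2` median lengths.
#' @return tibble `taxon`, `abundance`, `rel_abundance` (fraction of the
#'   pathway total), ranked.
#' @export
taxon_profile <- function(hits_gene1, hits_gene2, ref_taxa, ref_lengths) {
  per_gene <- function(h, len) {
    if (is.null(h) || nrow(h) == 0)
      return(tibble::tibble(taxon = character(), a = numeric()))
    tx <- unname(ref_taxa[h$ref_id])
    tx[is.na(tx)] <- "unclassified"
    tibble::tibble(taxon = tx) |>
      dplyr::count(.data$taxon) |>
      dplyr::transmute(taxon = .data$taxon, a = .data$n / len)
  }
  g1 <- per_gene(hits_gene1, ref_lengths[["gene1"]])
  g2 <- per_gene(hits_gene2, ref_lengths[["gene2"]])
  taxa <- union(g1$taxon, g2$taxon)
  ab <- vapply(taxa, function(t) {
    stats::median(c(g1$a[match(t, g1$taxon)] %|na|% 0,
                    g2$a[match(t, g2$taxon)] %|na|% 0))
  }, numeric(1))
  out <- tibble::tibble(taxon = taxa, abundance = unname(ab))
  out$rel_abundance <- if (sum(out$abundance) > 0)
    out$abundance / sum(out$abundance) else 0
  dplyr::arrange(out, dplyr::desc(.data$abundance))
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Build an rplB reference set from genomes
#'
#' Screens every genome with an rplB profile model and keeps each genome's
#' best hit at or above `cutoff`; genomes lacking a qualifying hit are
#' listed with a warning.
#'
#' @param genomes list of `genome_record` objects.
#' @param rplB_model `profile_model` for rplB.
#' @param cutoff minimum bit score (default 0: any positive-scoring hit).
#' @return list with `refs` (tibble: `ref_id`, `nt`, `genome_id`,
#'   `is_target`), `median_length` and `missing` (genome ids).
#' @export
rplB_reference_builder <- function(genomes, rplB_model, cutoff = 0) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  refs <- list(); missing <- character(0)
  for (g in genomes) {
    hits <- screen_genomes(g, rplB_model, top_n = 1L)
    if (nrow(hits) == 0 || hits$score[1] < cutoff) {
      missing <- c(missing, g$genome_id)
      next
    }
    refs[[length(refs) + 1]] <- tibble::tibble(
      ref_id = paste0(g$genome_id, "_rplB"), nt = hits$gene_nt[1],
      genome_id = g$genome_id, is_target = TRUE)
  }
  if (length(missing) > 0)
    warning("no rplB found in genome(s): ", paste(missing, collapse = ", "))
  refs <- dplyr::bind_rows(refs)
  list(refs = refs,
       median_length = if (nrow(refs) > 0) stats::median(nchar(refs$nt)) else NA,
       missing = missing)
}

#' Quantify a TMA pathway in a metagenome sample
#'
#' QC, search of reads against the two pathway gene panels and rplB, the
#' both-genes rule, rplB-normalized abundance and the taxonomic profile.
#'
#' @param reads read tibble (FASTQ-derived tibbles are QC'd; FASTA passes
#'   through).
#' @param refset_gene1,refset_gene2 reference tibbles (`ref_id`, `nt`,
#'   `is_target`, optional `taxon`) for the pathway's two genes, each
#'   including its below-threshold outgroup.
#' @param refset_rplB rplB reference tibble.
#' @param pathway label.
#' @param sample_id sample label.
#' @param min_len,min_id retained-hit thresholds (default 70 bp / 0.70).
#' @param min_q,min_frac QC thresholds (default 30 / 0.5).
#' @return list with `abundance` (tibble), `taxa` (tibble), `hits` (list
#'   of retained hits per gene).
#' @export
quantify_metagenome <- function(reads, refset_gene1, refset_gene2,
                                refset_rplB, pathway = "pathway",
                                sample_id = "sample1",
                                min_len = 70, min_id = 0.70,
                                min_q = 30, min_frac = 0.5) {
  reads <- qc_reads(reads, min_q, min_frac)
  # one search over the union panel, then per-gene top-hit selection and
  # filtering (genes are far below the identity floor of one another, so
  # partitioning the union hit list per gene is equivalent to three runs)
  union_refs <- dplyr::bind_rows(
    dplyr::mutate(refset_gene1, .gene = "gene1"),
    dplyr::mutate(refset_gene2, .gene = "gene2"),
    dplyr::mutate(refset_rplB, .gene = "rplB"))
  all_hits <- run_blastn(reads, union_refs)
  per_gene <- function(g, rs) {
    h <- all_hits[all_hits$ref_id %in% rs$ref_id, , drop = FALSE]
    search_reads(NULL, rs, min_len, min_id, hits = h)
  }
  h1 <- per_gene("gene1", refset_gene1)
  h2 <- per_gene("gene2", refset_gene2)
  hr <- per_gene("rplB", refset_rplB)
  t1 <- h1[h1$is_target, , drop = FALSE]
  t2 <- h2[h2$is_target, , drop = FALSE]
  lens <- c(gene1 = stats::median(nchar(refset_gene1$nt[refset_gene1$is_target])),
            gene2 = stats::median(nchar(refset_gene2$nt[refset_gene2$is_target])),
            rplB = stats::median(nchar(refset_rplB$nt)))
  ab <- pathway_abundance(t1, t2, hr, lens, pathway, sample_id)
  taxa <- NULL
  if (!is.null(refset_gene1$taxon)) {
    tax2 <- if ("taxon" %in% names(refset_gene2)) refset_gene2$taxon
            else rep(NA_character_, nrow(refset_gene2))
    ref_taxa <- c(stats::setNames(refset_gene1$taxon, refset_gene1$ref_id),
                  stats::setNames(tax2, refset_gene2$ref_id))
    taxa <- taxon_profile(t1, t2, ref_taxa, lens)
  }
  list(abundance = ab, taxa = taxa,
       hits = list(gene1 = h1, gene2 = h2, rplB = hr))
}
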