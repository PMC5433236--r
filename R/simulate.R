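# Seeded synthetic-data generators. Every generator is a pure function of
# (spec, seed) and returns its ground truth alongside the data, so each
# downstream statistic can be checked without rerunning generation.

sample_protein <- function(L) {
  paste(sample(AA20, L, replace = TRUE, prob = aa_background), collapse = "")
}

# mutate a fraction of residue positions to different residues; positions in
# `protect` are never touched
mutate_protein <- function(protein, rate, protect = integer(0)) {
  res <- strsplit(protein, "")[[1]]
  n <- max(0L, round(rate * length(res)))
  pool <- setdiff(seq_along(res), protect)
  pos <- sample(pool, min(n, length(pool)))
  for (p in pos) res[p] <- sample(setdiff(AA20, res[p]), 1)
  paste(res, collapse = "")
}

# back-translate with uniform choice among synonymous codons (vectorized)
backtranslate_protein <- local({
  flat <- NULL; starts <- NULL; lens <- NULL
  function(protein, code = "11") {
    if (is.null(flat)) {
      gc <- genetic_code_table(code)
      by_aa <- split(names(gc), unname(gc))
      flat <<- unlist(by_aa, use.names = FALSE)
      lens <<- stats::setNames(lengths(by_aa), names(by_aa))
      starts <<- stats::setNames(cumsum(lens) - lens, names(by_aa))
    }
    res <- strsplit(protein, "")[[1]]
    l <- lens[res]; s <- starts[res]
    bad <- is.na(l)
    pick <- ceiling(stats::runif(length(res)) * ifelse(bad, 1, l))
    out <- flat[s + pick]
    out[bad] <- "NNN"
    paste(out, collapse = "")
  }
})

random_dna <- function(L) paste(sample(NT4, L, replace = TRUE), collapse = "")

#' Generate a synthetic protein family
#'
#' An ancestor protein plus seed sequences diverged from it, with an
#' optional conserved signature residue fixed in every family member.
#'
#' @param length ancestor length in residues.
#' @param n_seeds number of seed sequences.
#' @param divergence per-seed fraction of mutated positions.
#' @param signature_col,signature_res optional conserved column and residue.
#' @param seed RNG seed.
#' @return list with `ancestor`, `seeds` (named, ungapped = trivially
#'   aligned), `signature_col`, `signature_res`.
#' @export
sim_gene_family <- function(length = 150, n_seeds = 8, divergence = 0.05,
                            signature_col = NULL, signature_res = "E",
                            seed = 1) {
  withr::with_seed(seed, {
    anc <- sample_protein(length)
    if (!is.null(signature_col)) {
      r <- strsplit(anc, "")[[1]]
      r[signature_col] <- signature_res
      anc <- paste(r, collapse = "")
    }
    protect <- if (is.null(signature_col)) integer(0) else signature_col
    seeds <- stats::setNames(
      vapply(seq_len(n_seeds), function(i)
        mutate_protein(anc, divergence, protect), character(1)),
      sprintf("seed%02d", seq_len(n_seeds)))
    list(ancestor = anc, seeds = seeds, signature_col = signature_col,
         signature_res = signature_res)
  })
}

#' Generate genomes with planted gene cassettes and decoy homologs
#'
#' Builds `n_genomes` single-contig genomes of random coding backbones.
#' Target genes (diverged copies of a family ancestor, signature residue
#' intact) are planted with a syntenic partner gene at locus separations
#' drawn from `separations`; trap genomes carry a target whose partner sits
#' just outside the synteny window (separation `trap_separation`); decoys
#' are family homologs mutated to `decoy_identity` with the signature
#' scrambled and no partner. An rplB-like single-copy gene is planted in
#' every genome.
#'
#' @param n_genomes total genomes.
#' @param n_targets genomes with a true target + syntenic partner.
#' @param n_traps genomes with a target whose partner is at
#'   `trap_separation`.
#' @param n_decoys total decoy genes (distributed over the remaining
#'   genomes).
#' @param decoy_identity range of decoy core identity to the ancestor.
#' @param separations pool of syntenic locus separations (<= window).
#' @param trap_separation separation used for traps (default 11).
#' @param genes_per_genome backbone genes per genome.
#' @param target_length,partner_length,rplB_length family lengths (aa).
#' @param seed RNG seed.
#' @return list with `genomes`, `truth` (tibble), `target_family`,
#'   `partner_family`, `rplB_family`, `signature_rules`.
#' @export
sim_genomes <- function(n_genomes = 25, n_targets = 5, n_traps = 2,
                        n_decoys = 50, decoy_identity = c(0.5, 0.7),
                        separations = c(1, 3, 5, 7, 10),
                        trap_separation = 11, genes_per_genome = 20,
                        target_length = 150, partner_length = 130,
                        rplB_length = 90, seed = 1) {
  fam <- sim_gene_family(target_length, signature_col = round(target_length / 2),
                         signature_res = "E", seed = seed)
  pfam <- sim_gene_family(partner_length, seed = seed + 101)
  rfam <- sim_gene_family(rplB_length, seed = seed + 202)
  sig_col <- fam$signature_col

  withr::with_seed(seed + 500, {
    roles <- rep("background", n_genomes)
    stopifnot(n_targets + n_traps <= n_genomes)
    roles[seq_len(n_targets)] <- "target"
    if (n_traps > 0) roles[n_targets + seq_len(n_traps)] <- "trap"
    decoy_home <- which(roles == "background")
    decoy_counts <- if (length(decoy_home) > 0 && n_decoys > 0)
      tabulate(sample(rep_len(decoy_home, n_decoys)), nbins = n_genomes)
    else integer(n_genomes)

    genomes <- vector("list", n_genomes)
    truth <- list()
    for (gi in seq_len(n_genomes)) {
      gid <- sprintf("G%03d", gi)
      prots <- vapply(seq_len(genes_per_genome), function(i)
        sample_protein(sample(80:150, 1)), character(1))
      labels <- rep("backbone", genes_per_genome)
      # plant rplB
      slot <- sample(genes_per_genome, 1)
      prots[slot] <- mutate_protein(rfam$ancestor, 0.05)
      labels[slot] <- "rplB"
      sep_used <- NA_integer_
      if (roles[gi] %in% c("target", "trap")) {
        sep_used <- if (roles[gi] == "trap") trap_separation
                    else sample(separations, 1)
        free <- which(labels == "backbone")
        ok <- free[(free + sep_used) %in% free]
        if (length(ok) == 0) stop("genome too small for requested separation")
        tpos <- ok[1]
        prots[tpos] <- mutate_protein(fam$ancestor, 0.08, protect = sig_col)
        labels[tpos] <- "target"
        prots[tpos + sep_used] <- mutate_protein(pfam$ancestor, 0.08)
        labels[tpos + sep_used] <- "partner"
      }
      nd <- decoy_counts[gi]
      if (nd > 0) {
        free <- which(labels == "backbone")
        dpos <- sample(free, nd)
        for (p in dpos) {
          idy <- stats::runif(1, decoy_identity[1], decoy_identity[2])
          d <- mutate_protein(fam$ancestor, 1 - idy, protect = sig_col)
          # scramble the signature residue
          r <- strsplit(d, "")[[1]]
          r[sig_col] <- sample(setdiff(AA20, fam$signature_res), 1)
          prots[p] <- paste(r, collapse = "")
          labels[p] <- "decoy"
          truth[[length(truth) + 1]] <- tibble::tibble(
            genome_id = gid, role = "decoy", locus_index = p - 1L,
            identity = idy, locus_separation = NA_integer_,
            protein = prots[p])
        }
      }
      if (roles[gi] %in% c("target", "trap")) {
        tpos <- which(labels == "target")
        truth[[length(truth) + 1]] <- tibble::tibble(
          genome_id = gid, role = roles[gi], locus_index = tpos - 1L,
          identity = 0.92, locus_separation = sep_used,
          protein = prots[tpos])
      }
      # lay genes on one contig with 20-nt spacers; occasional minus strand
      nts <- vapply(prots, backtranslate_protein, character(1))
      strands <- sample(c("+", "-"), genes_per_genome, replace = TRUE,
                        prob = c(0.8, 0.2))
      pos <- 1L
      contig <- character(0)
      feats <- list()
      for (i in seq_len(genes_per_genome)) {
        spacer <- random_dna(20)
        gene_plus <- if (strands[i] == "-") revcomp(nts[i]) else nts[i]
        start <- pos + 20L
        end <- start + nchar(gene_plus) - 1L
        contig <- c(contig, spacer, gene_plus)
        feats[[i]] <- tibble::tibble(
          contig_id = "ctg1", start = start, end = end, strand = strands[i],
          locus_tag = sprintf("%s_%04d", gid, i), protein = prots[i],
          label = labels[i])
        pos <- end + 1L
      }
      feats <- dplyr::bind_rows(feats)
      genomes[[gi]] <- genome_record(gid, c(ctg1 = paste(contig, collapse = "")),
                                     feats[, setdiff(names(feats), "label")])
      genomes[[gi]]$features$label <- feats$label
    }
    sig_rules <- signature_rule(model_column = NA_integer_,
                                allowed_residues = fam$signature_res,
                                label = "conserved bridging residue")
    list(genomes = genomes, truth = dplyr::bind_rows(truth),
         target_family = fam, partner_family = pfam, rplB_family = rfam,
         signature_rules = sig_rules, roles = roles)
  })
}

#' Locate a family signature residue on a built model
#'
#' Maps an ancestor-sequence signature position to the model match column
#' it aligns to, so [signature_rule()] rows can reference model
#' coordinates.
#' @param model `profile_model`.
#' @param family list from [sim_gene_family()].
#' @return integer model column.
#' @export
signature_model_column <- function(model, family) {
  al <- align_to_model(model, c(anc = family$ancestor))
  col <- al$col_of_res[["anc"]][family$signature_col]
  if (col == 0) stop("signature position did not align to a model column")
  col
}

#' Generate amplicon reads from references with controlled error
#'
#' Reads are drawn from the reference sequences at the given population
#' proportions; substitutions and indels are planted per base at the given
#' rates and recorded per read. Qualities are constant Q37.
#'
#' @param refs named character vector of reference amplicon sequences.
#' @param proportions population proportions (recycled across samples).
#' @param n_reads reads per sample.
#' @param sub_rate per-base substitution rate.
#' @param indel_rate per-base indel rate (insert/delete equally likely).
#' @param n_samples number of samples.
#' @param seed RNG seed.
#' @return list with `reads` (tibble: `read_id`, `sample_id`, `ref_id`,
#'   `seq`, `qual`, `n_sub`, `n_indel`) and `truth` (proportions).
#' @export
sim_amplicons <- function(refs, proportions, n_reads = 1000, sub_rate = 0.01,
                          indel_rate = 0.005, n_samples = 1, seed = 1) {
  stopifnot(length(refs) == length(proportions))
  proportions <- proportions / sum(proportions)
  withr::with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_samples)) {
      sid <- sprintf("S%02d", s)
      pick <- sample(names(refs), n_reads, replace = TRUE, prob = proportions)
      for (i in seq_len(n_reads)) {
        base <- strsplit(refs[[pick[i]]], "")[[1]]
        L <- length(base)
        u <- stats::runif(L); v <- stats::runif(L); w <- stats::runif(L)
        is_indel <- u < indel_rate
        is_del <- is_indel & v < 0.5
        is_ins <- is_indel & !is_del
        is_sub <- !is_indel & w < sub_rate
        pieces <- base
        if (any(is_sub)) {
          idx <- which(is_sub)
          shift <- sample.int(3, length(idx), replace = TRUE)
          pieces[idx] <- NT4[((match(base[idx], NT4) - 1L + shift) %% 4L) + 1L]
        }
        if (any(is_ins)) {
          idx <- which(is_ins)
          pieces[idx] <- paste0(sample(NT4, length(idx), replace = TRUE),
                                pieces[idx])
        }
        pieces[is_del] <- ""
        rows[[length(rows) + 1]] <- tibble::tibble(
          read_id = sprintf("%s_r%05d", sid, i), sample_id = sid,
          ref_id = pick[i], seq = paste(pieces, collapse = ""),
          n_sub = sum(is_sub), n_indel = sum(is_indel))
      }
    }
    reads <- dplyr::bind_rows(rows)
    reads$qual <- lapply(nchar(reads$seq), function(L) rep(37L, L))
    list(reads = reads,
         truth = tibble::tibble(ref_id = names(refs),
                                proportion = unname(proportions)))
  })
}

#' Generate shotgun metagenome reads from a genome community
#'
#' Uniform fragmentation of the genomes at the given coverage; reads come
#' from either strand. The truth records, per pathway gene, the analytic
#' expected retained read count (reads overlapping the gene by at least
#' `min_overlap` bp) and the resulting expected percent of community.
#'
#' @param sim a [sim_genomes()] result (its `genomes` and gene labels are
#'   used).
#' @param coverage mean per-base coverage (default 20).
#' @param read_len read length (default 150).
#' @param min_overlap overlap used for the analytic truth (default 70,
#'   matching the retained-hit filter).
#' @param seed RNG seed.
#' @return list with `reads` (tibble) and `truth` (list: per-gene expected
#'   counts, `percent_of_community`).
#' @export
sim_metagenome <- function(sim, coverage = 20, read_len = 150,
                           min_overlap = 70, seed = 1) {
  genomes <- sim$genomes
  lens <- vapply(genomes, function(g) sum(Biostrings::width(g$contigs)),
                 numeric(1))
  withr::with_seed(seed, {
    rows <- list()
    for (gi in seq_along(genomes)) {
      g <- genomes[[gi]]
      L <- lens[gi]
      n <- round(coverage * L / read_len)
      starts <- sample.int(L - read_len + 1L, n, replace = TRUE)
      strands <- sample(c("+", "-"), n, replace = TRUE)
      seqs <- substring(as.character(g$contigs[[1]]), starts,
                        starts + read_len - 1L)
      seqs[strands == "-"] <- revcomp(seqs[strands == "-"])
      rows[[gi]] <- tibble::tibble(
        read_id = sprintf("%s_m%06d", g$genome_id, seq_len(n)),
        genome_id = g$genome_id, seq = seqs)
    }
    reads <- dplyr::bind_rows(rows)
    reads$qual <- vector("list", nrow(reads))

    # analytic expectations: eligible start window per planted gene
    depth_per_start <- nrow(reads) / sum(lens)
    expect_count <- function(label) {
      tot <- 0
      for (g in genomes) {
        f <- g$features[g$features$label == label, ]
        if (nrow(f) == 0) next
        glen <- f$end - f$start + 1
        windows <- pmax(0, glen + read_len - 2 * min_overlap + 1)
        tot <- tot + sum(windows) * depth_per_start
      }
      tot
    }
    med_len <- function(label) {
      l <- unlist(lapply(genomes, function(g) {
        f <- g$features[g$features$label == label, ]
        f$end - f$start + 1
      }))
      stats::median(l)
    }
    e1 <- expect_count("target"); e2 <- expect_count("partner")
    er <- expect_count("rplB")
    a1 <- e1 / med_len("target"); a2 <- e2 / med_len("partner")
    ar <- er / med_len("rplB")
    truth <- list(expected_counts = c(gene1 = e1, gene2 = e2, rplB = er),
                  median_lengths = c(gene1 = med_len("target"),
                                     gene2 = med_len("partner"),
                                     rplB = med_len("rplB")),
                  percent_of_community = 100 * stats::median(c(a1, a2)) / ar)
    list(reads = reads, truth = truth)
  })
}

#' Generate a sample x cluster abundance matrix with planted correlations
#'
#' Log-normal abundances; the designated cluster pairs share their rank
#' structure exactly (Spearman rho = 1), all other clusters are
#' independent. Per-cluster prevalence is controlled by zeroing a random
#' subset of samples.
#'
#' @param n_samples,n_clusters matrix dimensions.
#' @param rho1_pairs list of length-2 integer vectors: cluster index pairs
#'   forced to rho = 1.
#' @param prevalence named or plain numeric vector (recycled) giving each
#'   cluster's detection fraction (default 1).
#' @param meanlog,sdlog log-normal parameters.
#' @param seed RNG seed.
#' @return list with `counts` (integer matrix) and `truth` (planted pairs,
#'   prevalence).
#' @export
sim_abundance_matrix <- function(n_samples = 50, n_clusters = 20,
                                 rho1_pairs = list(), prevalence = 1,
                                 meanlog = 3, sdlog = 1, seed = 1) {
  prevalence <- rep_len(prevalence, n_clusters)
  withr::with_seed(seed, {
    m <- matrix(stats::rlnorm(n_samples * n_clusters, meanlog, sdlog),
                n_samples, n_clusters)
    for (pr in rho1_pairs) {
      # same ranks, fresh marginal scale: sorted independent draws mapped
      # through the source ranks, so the pair stays rank-identical even
      # after integer rounding compresses values
      fresh <- sort(stats::rlnorm(n_samples, meanlog, sdlog))
      m[, pr[2]] <- fresh[rank(m[, pr[1]], ties.method = "first")]
    }
    for (j in seq_len(n_clusters)) {
      if (prevalence[j] < 1) {
        nz <- round((1 - prevalence[j]) * n_samples)
        m[sample(n_samples, nz), j] <- 0
      }
    }
    counts <- matrix(as.integer(round(m)), n_samples, n_clusters,
                     dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                                     sprintf("cl%04d", seq_len(n_clusters))))
    list(counts = counts,
         truth = list(rho1_pairs = rho1_pairs, prevalence = prevalence))
  })
}
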