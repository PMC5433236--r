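# Multi-parametric genome screen: profile score -> dereplication -> coverage
# filter -> signature residues -> phylogenetic distance to the top sequence
# -> synteny with the partner gene -> score cutoff -> database assembly.

#' Screen genomes for a protein family
#'
#' Scores every annotated protein against the profile model and returns the
#' `top_n` by score. Ties are broken by (genome_id, contig_id, locus_index)
#' for determinism; duplicated genome ids are collapsed before scoring.
#'
#' @param genomes list of `genome_record` objects (or a single one).
#' @param model a `profile_model`.
#' @param top_n number of top-scoring proteins to keep.
#' @return tibble of hits: genome/contig/locus fields, `protein`,
#'   `gene_nt`, `score`, sorted descending by score.
#' @export
screen_genomes <- function(genomes, model, top_n) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  genomes <- genomes[!duplicated(ids)]
  feats <- dplyr::bind_rows(lapply(genomes, function(g) g$features))
  if (nrow(feats) == 0 || top_n <= 0)
    return(tibble::tibble(genome_id = character(), contig_id = character(),
                          locus_tag = character(), locus_index = integer(),
                          strand = character(), protein = character(),
                          gene_nt = character(), score = numeric()))
  feats <- feats[!is.na(feats$protein) & nzchar(feats$protein), ]
  feats$score <- score_sequence(model, feats$protein)
  feats <- feats[order(-feats$score, feats$genome_id, feats$contig_id,
                       feats$locus_index), ]
  out <- utils::head(feats, top_n)
  tibble::as_tibble(out[, c("genome_id", "contig_id", "locus_tag",
                            "locus_index", "strand", "protein", "gene_nt",
                            "score")])
}

#' Collapse identical protein sequences
#'
#' Groups hits by exact amino-acid string. The representative member is the
#' hit from the lexicographically smallest genome id; member genomes and
#' per-group counts are carried along.
#'
#' @param hits tibble from [screen_genomes()].
#' @return tibble of unique proteins sorted descending by score, with
#'   `protein_id`, representative fields, `n_members` and
#'   `member_genome_ids` (list column).
#' @export
dereplicate <- function(hits) {
  if (nrow(hits) == 0)
    return(tibble::tibble(protein_id = character(), protein = character(),
                          gene_nt = character(), score = numeric(),
                          n_members = integer(), member_genome_ids = list(),
                          genome_id = character(), contig_id = character(),
                          locus_tag = character(), locus_index = integer()))
  out <- hits |>
    dplyr::group_by(.data$protein) |>
    dplyr::arrange(.data$genome_id, .data$contig_id, .data$locus_index,
                   .by_group = TRUE) |>
    dplyr::summarise(
      score = max(.data$score),
      n_members = dplyr::n(),
      member_genome_ids = list(.data$genome_id),
      genome_id = dplyr::first(.data$genome_id),
      contig_id = dplyr::first(.data$contig_id),
      locus_tag = dplyr::first(.data$locus_tag),
      locus_index = dplyr::first(.data$locus_index),
      gene_nt = dplyr::first(.data$gene_nt),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$genome_id, .data$locus_tag)
  out$protein_id <- sprintf("U%04d", seq_len(nrow(out)))
  dplyr::relocate(out, "protein_id")
}

#' Define a signature-residue rule
#'
#' @param model_column 1-based match-column index in the profile model.
#' @param allowed_residues string of allowed residues (e.g. `"E"`).
#' @param label human-readable label (e.g. `"bridging E205"`).
#' @export
signature_rule <- function(model_column, allowed_residues, label = "") {
  tibble::tibble(model_column = as.integer(model_column),
                 allowed_residues = allowed_residues, label = label)
}

#' Check signature residues against a model alignment
#'
#' A sequence passes a rule iff the residue aligned to the rule's model
#' column is in the allowed set; a deletion (or a column outside the
#' aligned span) fails the rule.
#'
#' @param alignment a `model_alignment` from [align_to_model()].
#' @param rules tibble of [signature_rule()] rows; zero rows pass everything.
#' @return tibble with `sequence_id`, one logical column per rule, and
#'   `residues_ok` (all rules satisfied).
#' @export
check_signatures <- function(alignment, rules) {
  stopifnot(inherits(alignment, "model_alignment"))
  ids <- rownames(alignment$aligned)
  out <- tibble::tibble(sequence_id = ids)
  if (is.null(rules) || nrow(rules) == 0) {
    out$residues_ok <- TRUE
    return(out)
  }
  if (any(rules$model_column > alignment$consensus_length))
    stop("signature rule column exceeds the model consensus length")
  flags <- matrix(FALSE, length(ids), nrow(rules))
  for (r in seq_len(nrow(rules))) {
    allowed <- strsplit(toupper(rules$allowed_residues[r]), "")[[1]]
    res <- alignment$aligned[, rules$model_column[r]]
    flags[, r] <- res %in% allowed
  }
  colnames(flags) <- ifelse(nzchar(rules$label), rules$label,
                            paste0("col", rules$model_column))
  out <- dplyr::bind_cols(out, tibble::as_tibble(flags))
  out$residues_ok <- apply(flags, 1, all)
  out
}

#' Phylogenetic (cophenetic) distance of every sequence to the top sequence
#'
#' Builds a neighbor-joining tree from p-distances over shared match
#' columns and returns the path-length distance from each tip to the tip of
#' `top_id` (default: the highest-scoring sequence). With fewer than three
#' sequences the pairwise p-distance is returned directly.
#'
#' @param alignment a `model_alignment`.
#' @param top_id id of the reference tip; default = best score.
#' @return named numeric vector of distances (0 for the top tip itself).
#' @export
phylo_distance_to_top <- function(alignment, top_id = NULL) {
  stopifnot(inherits(alignment, "model_alignment"))
  ids <- rownames(alignment$aligned)
  if (is.null(top_id))
    top_id <- alignment$records$sequence_id[which.max(alignment$records$score)]
  if (!top_id %in% ids) stop("top_id not present in the alignment")
  n <- length(ids)
  D <- 1 - alignment_identity(alignment$aligned)
  dimnames(D) <- list(ids, ids)
  if (n < 3) return(stats::setNames(D[, top_id], ids))
  tree <- ape::nj(stats::as.dist(D))
  cd <- ape::cophenetic.phylo(tree)
  stats::setNames(cd[ids, top_id], ids)
}

# p-distance-style identity over rows of an aligned protein matrix: gap
# columns are treated as missing (pairwise deletion), so distances are
# computed over shared match columns only
alignment_identity <- function(aligned) {
  codes <- matrix(match(aligned, c(AA20, "-", "X", "*"), nomatch = 23L),
                  nrow = nrow(aligned))
  cpp_pairwise_identity(codes, gapcode = 21L, misscode = 21L)
}

#' Check synteny of a hit with its partner gene
#'
#' Scans the features of the hit's genome for a partner-model hit scoring
#' at least `partner_cutoff`; the pair is syntenous when such a feature
#' lies on the same contig within `max_separation` intervening genes by
#' locus-tag order.
#'
#' @param genome the `genome_record` carrying the hit.
#' @param hit_feature one-row tibble (or list) with `contig_id` and
#'   `locus_index` of the hit.
#' @param partner_model `profile_model` for the partner gene.
#' @param partner_cutoff minimum partner bit score (typically a fraction of
#'   the top partner score; see [partner_cutoff_from_top()]).
#' @param max_separation maximum locus-index separation (default 10).
#' @return list with `partner_found`, `locus_separation` (NA when no
#'   qualifying partner), `same_contig`.
#' @export
check_synteny <- function(genome, hit_feature, partner_model, partner_cutoff,
                          max_separation = 10) {
  feats <- genome$features
  feats <- feats[!(feats$contig_id == hit_feature$contig_id &
                     feats$locus_index == hit_feature$locus_index), ]
  if (nrow(feats) == 0)
    return(list(partner_found = FALSE, locus_separation = NA_integer_,
                same_contig = FALSE))
  feats$pscore <- score_sequence(partner_model, feats$protein)
  qual <- feats[feats$pscore >= partner_cutoff, ]
  if (nrow(qual) == 0)
    return(list(partner_found = FALSE, locus_separation = NA_integer_,
                same_contig = FALSE))
  same <- qual[qual$contig_id == hit_feature$contig_id, ]
  if (nrow(same) == 0)
    return(list(partner_found = FALSE, locus_separation = NA_integer_,
                same_contig = FALSE))
  sep <- min(abs(same$locus_index - hit_feature$locus_index))
  list(partner_found = sep <= max_separation,
       locus_separation = as.integer(sep), same_contig = TRUE)
}

#' Partner-gene score cutoff as a fraction of the top partner score
#'
#' The partner thresholds are expressed relative to the top-scoring partner
#' sequence (e.g. 51% for the cutC activator, 26% for the cntA reductase).
#'
#' @param genomes genomes to screen for the partner gene.
#' @param partner_model partner `profile_model`.
#' @param fraction fraction of the top score.
#' @return bit-score cutoff.
#' @export
partner_cutoff_from_top <- function(genomes, partner_model, fraction) {
  hits <- screen_genomes(genomes, partner_model, top_n = 1L)
  if (nrow(hits) == 0) stop("no partner-gene hits found in the genomes")
  fraction * hits$score[1]
}

#' Detect the score cutoff at the largest relative drop
#'
#' Scans consecutive score pairs within ranks `scan_from` .. N-1 for the
#' largest relative drop (s_i - s_{i+1}) / s_i and returns the median (=
#' mean) of the two framing scores. The top rank is excluded as a drop
#' anchor by default so a single outlier top score cannot define the
#' cutoff.
#'
#' @param scores numeric scores sorted descending (length >= 2).
#' @param mode `"auto"` or `"manual"`.
#' @param value cutoff echoed back in manual mode.
#' @param scan_from first rank considered as the upper frame of a drop.
#' @return cutoff in bits.
#' @export
detect_cutoff <- function(scores, mode = c("auto", "manual"), value = NULL,
                          scan_from = 2L) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    if (is.null(value)) stop("manual mode needs a cutoff value")
    return(value)
  }
  if (length(scores) < 2) stop("need at least 2 scores to detect a cutoff")
  if (is.unsorted(rev(scores))) stop("scores must be sorted descending")
  n <- length(scores)
  from <- max(1L, min(scan_from, n - 1L))
  if (n == 2) from <- 1L
  idx <- from:(n - 1L)
  drops <- (scores[idx] - scores[idx + 1L]) / scores[idx]
  if (all(drops <= 0) || max(drops) == 0)
    stop("no drop detected in the score series; supply a manual cutoff")
  i <- idx[which.max(drops)]
  (scores[i] + scores[i + 1L]) / 2
}

#' Assemble a gene database from an evaluated candidate table
#'
#' Targets are the candidates at or above the cutoff minus any
#' phylogeny-excluded entries; the outgroup holds the top-scoring
#' below-cutoff unique sequences (defaults: 300 for the amplicon/protein
#' set, 500 for the metagenome/nucleotide set). Per-genome copy numbers are
#' reported, flagging genomes with more than one non-identical copy.
#'
#' @param candidates candidate tibble with `protein_id`, `protein`,
#'   `gene_nt`, `score`, `coverage`, `residues_ok`, `phylo_dist_to_top`,
#'   `partner_found`, `member_genome_ids`, `n_members`.
#' @param cutoff bit-score cutoff (see [detect_cutoff()]).
#' @param gene_name database label.
#' @param phylo_filter apply the phylogeny filter: above-cutoff candidates
#'   whose distance to the top sequence exceeds `phylo_quantile` of the
#'   above-cutoff distances *and* whose synteny failed are excluded.
#' @param phylo_quantile quantile defining "distant" (default 0.95).
#' @param outgroup_protein_n,outgroup_nt_n outgroup sizes.
#' @param taxonomy optional named vector protein_id -> taxon label.
#' @param cluster_targets label target references by 90% nucleotide
#'   complete-linkage clusters (needs `model` to align them).
#' @param model profile model used for target clustering.
#' @return a `gene_database`.
#' @export
assemble_database <- function(candidates, cutoff, gene_name = "gene",
                              phylo_filter = FALSE, phylo_quantile = 0.95,
                              outgroup_protein_n = 300, outgroup_nt_n = 500,
                              taxonomy = NULL, cluster_targets = TRUE,
                              model = NULL) {
  cand <- dplyr::arrange(candidates, dplyr::desc(.data$score), .data$protein_id)
  cand$status <- ifelse(cand$score >= cutoff, "target", "below_cutoff")
  above <- cand$status == "target"
  if (phylo_filter && any(above)) {
    qd <- stats::quantile(cand$phylo_dist_to_top[above], phylo_quantile,
                          na.rm = TRUE)
    excl <- above & !is.na(cand$phylo_dist_to_top) &
      cand$phylo_dist_to_top > qd & !cand$partner_found
    cand$status[excl] <- "excluded_by_phylogeny"
    if (any(excl))
      message(sum(excl), " above-cutoff candidate(s) excluded by phylogeny ",
              "(distance > ", signif(qd, 4), " and no syntenic partner)")
  }
  targets <- cand[cand$status == "target", ]
  below <- cand[cand$status != "target", ]
  og_protein <- utils::head(below[!duplicated(below$protein), ],
                            outgroup_protein_n)
  og_nt <- utils::head(below[!duplicated(below$gene_nt), ], outgroup_nt_n)
  if (nrow(og_protein) < outgroup_protein_n || nrow(og_nt) < outgroup_nt_n)
    warning("fewer below-cutoff sequences than requested for the outgroup (",
            nrow(og_protein), " proteins / ", nrow(og_nt), " nt available)")
  outgroup <- og_nt
  outgroup$in_protein_outgroup <- outgroup$protein_id %in% og_protein$protein_id

  # per-genome copy number over target members (identical copies counted)
  copy_number <- NULL
  if (nrow(targets) > 0 && !is.null(targets$member_genome_ids)) {
    members <- tibble::tibble(
      genome_id = unlist(targets$member_genome_ids),
      protein_id = rep(targets$protein_id,
                       lengths(targets$member_genome_ids)))
    copy_number <- members |>
      dplyr::group_by(.data$genome_id) |>
      dplyr::summarise(n_copies = dplyr::n(),
                       n_unique = dplyr::n_distinct(.data$protein_id),
                       multi_copy_distinct = dplyr::n_distinct(.data$protein_id) > 1,
                       .groups = "drop")
  }
  tx <- if (!is.null(taxonomy)) unname(taxonomy[targets$protein_id])
        else rep(NA_character_, nrow(targets))
  tcols <- targets[, intersect(c("protein_id", "protein", "gene_nt", "score",
                                 "coverage", "n_members"), names(targets))]
  tcols$taxonomy <- tx
  if (cluster_targets && nrow(tcols) > 1 && !is.null(model)) {
    al <- align_to_model(model, stats::setNames(tcols$protein, tcols$protein_id))
    aligned <- stats::setNames(apply(al$aligned, 1, paste, collapse = ""),
                               rownames(al$aligned))
    codal <- backtranslate_alignment(
      aligned, stats::setNames(trim_to_alignment(tcols, al), tcols$protein_id))
    cl <- cluster_sequences(codal, cutoff = 0.90)
    tcols$cluster90 <- sprintf("C%03d", unname(cl[tcols$protein_id]))
  } else {
    tcols$cluster90 <- if (nrow(tcols) > 0) sprintf("C%03d", seq_len(nrow(tcols)))
                       else character(0)
  }
  structure(list(
    gene_name = gene_name, targets = tcols,
    outgroup = outgroup[, c("protein_id", "protein", "gene_nt",
                            "in_protein_outgroup")],
    cutoff_used = cutoff, copy_number = copy_number, candidates = cand,
    params = list(phylo_filter = phylo_filter, phylo_quantile = phylo_quantile,
                  outgroup_protein_n = outgroup_protein_n,
                  outgroup_nt_n = outgroup_nt_n)
  ), class = "gene_database")
}

# restrict each target's gene_nt to the codons of residues that landed in
# the model alignment span (drops unaligned flanks so back-translation
# lengths agree with the aligned protein)
trim_to_alignment <- function(tcols, al) {
  vapply(seq_len(nrow(tcols)), function(i) {
    id <- tcols$protein_id[i]
    cols <- al$col_of_res[[id]]
    res_idx <- which(cols > 0)
    # keep residues from first to last aligned (inserts inside are dropped
    # from the aligned string as well, so use only aligned residues)
    nt <- tcols$gene_nt[i]
    codons <- substring(nt, 3 * (res_idx - 1) + 1, 3 * res_idx)
    paste(codons, collapse = "")
  }, character(1))
}

#' @export
print.gene_database <- function(x, ...) {
  cat("<gene_database> ", x$gene_name, ": ", nrow(x$targets), " target(s), ",
      nrow(x$outgroup), " outgroup reference(s), cutoff ",
      signif(x$cutoff_used, 6), " bits\n", sep = "")
  invisible(x)
}

#' Run the full multi-parametric database build
#'
#' Orchestrates the screen end to end: build + refine the gene and partner
#' profile models, screen all genomes, dereplicate, apply the coverage
#' filter, evaluate signature residues, phylogenetic distance to the top
#' sequence and synteny, set the score cutoff, and assemble the database.
#'
#' @param genomes list of `genome_record` objects.
#' @param seed_alignment aligned seed proteins of the target gene.
#' @param partner_seed_alignment aligned seed proteins of the partner gene
#'   (activator/reductase); `NULL` skips the synteny criterion.
#' @param signature_rules tibble of [signature_rule()] rows.
#' @param top_n proteins kept from the initial screen.
#' @param min_coverage minimum model coverage (default 0.8).
#' @param cutoff `"auto"` or a numeric manual cutoff.
#' @param max_separation synteny window in genes (default 10).
#' @param partner_fraction partner cutoff as a fraction of the top partner
#'   score.
#' @param refine_cycles profile refinement cycles (default 3).
#' @param gene_name database label.
#' @param ... forwarded to [assemble_database()].
#' @return list with `db` (`gene_database`), `candidates` (the evaluated
#'   candidate table behind the screening figure), `model`,
#'   `partner_model`.
#' @export
build_gene_database <- function(genomes, seed_alignment,
                                partner_seed_alignment = NULL,
                                signature_rules = NULL,
                                top_n = 3000, min_coverage = 0.8,
                                cutoff = "auto", max_separation = 10,
                                partner_fraction = 0.5, refine_cycles = 3,
                                gene_name = "gene", ...) {
  model <- build_refined_profile(seed_alignment, cycles = refine_cycles)
  partner_model <- NULL
  partner_cut <- NULL
  if (!is.null(partner_seed_alignment)) {
    partner_model <- build_refined_profile(partner_seed_alignment,
                                           cycles = refine_cycles)
    partner_cut <- partner_cutoff_from_top(genomes, partner_model,
                                           partner_fraction)
  }
  hits <- screen_genomes(genomes, model, top_n)
  uniq <- dereplicate(hits)
  al <- align_to_model(model, stats::setNames(uniq$protein, uniq$protein_id))
  uniq$coverage <- al$records$coverage[match(uniq$protein_id,
                                             al$records$sequence_id)]
  dropped <- uniq[uniq$coverage < min_coverage, ]
  uniq <- uniq[uniq$coverage >= min_coverage, ]
  if (nrow(uniq) < 2) stop("fewer than 2 candidates survive the coverage filter")
  al <- align_to_model(model, stats::setNames(uniq$protein, uniq$protein_id))
  sigs <- check_signatures(al, signature_rules)
  uniq$residues_ok <- sigs$residues_ok[match(uniq$protein_id, sigs$sequence_id)]
  dist_top <- phylo_distance_to_top(al)
  uniq$phylo_dist_to_top <- unname(dist_top[uniq$protein_id])

  genome_by_id <- stats::setNames(genomes, vapply(genomes, `[[`, character(1),
                                                  "genome_id"))
  if (!is.null(partner_model)) {
    syn <- lapply(seq_len(nrow(uniq)), function(i) {
      g <- genome_by_id[[uniq$genome_id[i]]]
      check_synteny(g, uniq[i, ], partner_model, partner_cut, max_separation)
    })
    uniq$partner_found <- vapply(syn, `[[`, logical(1), "partner_found")
    uniq$locus_separation <- vapply(syn, `[[`, integer(1), "locus_separation")
    uniq$same_contig <- vapply(syn, `[[`, logical(1), "same_contig")
  } else {
    uniq$partner_found <- NA
    uniq$locus_separation <- NA_integer_
    uniq$same_contig <- NA
  }
  cut_bits <- if (identical(cutoff, "auto")) detect_cutoff(sort(uniq$score, decreasing = TRUE))
              else detect_cutoff(uniq$score, mode = "manual", value = cutoff)
  db <- assemble_database(uniq, cut_bits, gene_name = gene_name,
                          model = model, ...)
  db$params$min_coverage <- min_coverage
  db$params$max_separation <- max_separation
  db$params$partner_fraction <- partner_fraction
  db$params$partner_cutoff <- partner_cut
  db$params$top_n <- top_n
  db$params$n_dropped_coverage <- nrow(dropped)
  list(db = db, candidates = db$candidates, model = model,
       partner_model = partner_model)
}

#' Plot the candidate score curve of a database build
#'
#' Unique proteins along the horizontal axis sorted by descending profile
#' score, with the chosen cutoff, synteny and phylogenetic distance
#' overlaid -- the standard diagnostic view of the multi-parametric screen.
#'
#' @param candidates candidate tibble (from `build_gene_database()$candidates`).
#' @param cutoff bit-score cutoff to draw.
#' @return a ggplot object.
#' @export
plot_candidates <- function(candidates, cutoff = NULL) {
  d <- dplyr::arrange(candidates, dplyr::desc(.data$score))
  d$rank <- seq_len(nrow(d))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 1) +
    ggplot2::labs(x = "unique protein (score rank)", y = "profile score (bits)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(d$partner_found) && !all(is.na(d$partner_found)))
    p <- p + ggplot2::geom_point(
      data = d[which(d$partner_found), ],
      ggplot2::aes(y = min(d$score, na.rm = TRUE)),
      shape = 18, colour = "grey40", size = 1.5)
  if (!is.null(cutoff))
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  p
}
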