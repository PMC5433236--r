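# Amplicon profiling: merge + quality filter, frameshift correction against
# a reference panel (targets + below-cutoff outgroup), target
# discrimination, codon-aware alignment, complete-linkage clustering,
# rarefaction, diversity summaries and best-match identity.

#' Merge paired-end reads and quality-filter
#'
#' Pairs are merged at the best ungapped overlap (minimum `min_overlap`,
#' mismatch fraction at most `max_mismatch_frac`); in the overlap the base
#' with the higher Phred quality is called. Merged reads whose mean quality
#' falls below `min_q` are discarded.
#'
#' @param r1,r2 read tibbles from [read_reads()] (or FASTQ paths).
#' @param min_q minimum mean Phred quality of the merged read (default 25).
#' @param min_overlap minimum overlap length (default 20).
#' @param max_mismatch_frac maximum mismatch fraction in the overlap.
#' @return list with `reads` (merged tibble) and `tally`.
#' @export
merge_and_filter <- function(r1, r2, min_q = 25, min_overlap = 20,
                             max_mismatch_frac = 0.1) {
  if (is.character(r1)) r1 <- read_reads(r1)
  if (is.character(r2)) r2 <- read_reads(r2)
  strip <- function(id) sub("[/ ].*$", "", sub("/[12]$", "", id))
  id1 <- strip(r1$read_id); id2 <- strip(r2$read_id)
  if (!setequal(id1, id2) || anyDuplicated(id1) || anyDuplicated(id2)) {
    off <- c(setdiff(id1, id2), setdiff(id2, id1), id1[duplicated(id1)])
    stop("unpaired or duplicated read id: ", off[1])
  }
  r2 <- r2[match(id1, id2), ]
  n <- nrow(r1)
  out_seq <- character(n); out_qual <- vector("list", n)
  merged <- logical(n); no_overlap <- 0L; low_q <- 0L
  for (i in seq_len(n)) {
    s1 <- strsplit(toupper(r1$seq[i]), "")[[1]]
    q1 <- r1$qual[[i]] %||% rep(40L, length(s1))
    s2rc <- strsplit(revcomp(r2$seq[i]), "")[[1]]
    q2 <- rev(r2$qual[[i]] %||% rep(40L, length(s2rc)))
    L1 <- length(s1); L2 <- length(s2rc)
    best <- NULL; best_score <- -Inf
    omax <- min(L1, L2)
    for (o in if (omax >= min_overlap) seq(omax, min_overlap) else integer(0)) {
      a <- s1[(L1 - o + 1):L1]; b <- s2rc[1:o]
      mm <- sum(a != b)
      if (mm > max_mismatch_frac * o) next
      score <- (o - mm) - mm
      if (score > best_score) { best_score <- score; best <- o }
    }
    if (is.null(best)) { no_overlap <- no_overlap + 1L; next }
    o <- best
    ov_idx1 <- (L1 - o + 1):L1
    ov_call <- ifelse(q1[ov_idx1] >= q2[1:o], s1[ov_idx1], s2rc[1:o])
    ov_q <- pmax(q1[ov_idx1], q2[1:o])
    seq_m <- c(s1[seq_len(L1 - o)], ov_call, s2rc[seq(o + 1, length.out = L2 - o)])
    qual_m <- c(q1[seq_len(L1 - o)], ov_q, q2[seq(o + 1, length.out = L2 - o)])
    if (mean(qual_m) < min_q) { low_q <- low_q + 1L; next }
    merged[i] <- TRUE
    out_seq[i] <- paste(seq_m, collapse = "")
    out_qual[[i]] <- qual_m
  }
  reads <- tibble::tibble(read_id = id1[merged], seq = out_seq[merged],
                          qual = out_qual[merged])
  list(reads = reads,
       tally = c(input_pairs = n, merged = sum(merged),
                 no_overlap = no_overlap, low_quality = low_q))
}

# ---- frameshift correction ------------------------------------------------

.framebot_params <- function(gap_open = 11, gap_ext = 1, frameshift = 12) {
  list(gap_open = gap_open, gap_ext = gap_ext, frameshift = frameshift)
}

#' Frameshift-corrected translated alignment of reads against references
#'
#' Each nucleotide read is aligned locally against every reference protein
#' with a dynamic program whose states are codon match/substitution
#' (BLOSUM62), protein-level affine gaps, and frameshift transitions
#' consuming 2 or 4 nucleotides at a fixed penalty. The best-scoring
#' reference wins (ties: higher protein identity, then lexicographic
#' reference id). The corrected nucleotide sequence restores the reading
#' frame: a 4-nt event keeps the triple scoring best against the reference
#' residue, a 2-nt event is repaired to a codon encoding the aligned
#' reference residue.
#'
#' @param reads tibble with `read_id`, `seq` and optionally `sample_id`.
#' @param refs reference panel tibble with `ref_id`, `protein`,
#'   `is_target` (targets plus the below-cutoff outgroup).
#' @param gap_open,gap_ext protein-level affine gap penalties (positive).
#' @param frameshift penalty per frameshift event (positive).
#' @param code genetic code id.
#' @return tibble of corrected amplicons: `read_id`, `sample_id`,
#'   `corrected_nt`, `corrected_protein`, `closest_ref_id`,
#'   `protein_identity`, `frameshift_count`, `has_stop`, `is_target`,
#'   `score`, `failed`.
#' @export
frameshift_correct <- function(reads, refs, gap_open = 11, gap_ext = 1,
                               frameshift = 12, code = "11") {
  stopifnot(all(c("ref_id", "protein") %in% names(refs)))
  if (is.null(refs$is_target)) refs$is_target <- TRUE
  refs <- dplyr::arrange(refs, .data$ref_id)
  sub <- blosum62_ext()
  c64 <- code64_table(code)
  refs_int <- lapply(refs$protein, aa_seq_to_int)
  sample_id <- if ("sample_id" %in% names(reads)) reads$sample_id
               else rep("sample1", nrow(reads))

  useq <- unique(reads$seq)
  res_by_seq <- vector("list", length(useq))
  for (k in seq_along(useq)) {
    nt <- nt_seq_to_int(useq[k])
    if (length(nt) < 3) { res_by_seq[[k]] <- list(failed = TRUE); next }
    als <- lapply(refs_int, function(ri)
      cpp_framebot(nt, ri, sub, c64, AA_X, gap_open, gap_ext, -frameshift))
    scores <- vapply(als, `[[`, numeric(1), "score")
    if (!any(is.finite(scores))) { res_by_seq[[k]] <- list(failed = TRUE); next }
    # ties on score resolved by higher protein identity, then the
    # lexicographically smallest ref id (refs are sorted by id)
    tie <- which(scores == max(scores))
    fixes <- lapply(tie, function(r)
      rebuild_corrected(useq[k], als[[r]], refs$protein[r], code))
    j <- which.max(vapply(fixes, `[[`, numeric(1), "identity"))
    res_by_seq[[k]] <- c(fixes[[j]],
                         list(score = scores[tie[j]], ref_idx = tie[j],
                              failed = FALSE))
  }
  idx <- match(reads$seq, useq)
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    b <- res_by_seq[[idx[i]]]
    if (isTRUE(b$failed))
      return(tibble::tibble(
        read_id = reads$read_id[i], sample_id = sample_id[i],
        corrected_nt = NA_character_, corrected_protein = NA_character_,
        closest_ref_id = NA_character_, protein_identity = NA_real_,
        frameshift_count = NA_integer_, has_stop = NA, is_target = FALSE,
        score = NA_real_, failed = TRUE))
    tibble::tibble(
      read_id = reads$read_id[i], sample_id = sample_id[i],
      corrected_nt = b$corrected_nt, corrected_protein = b$corrected_protein,
      closest_ref_id = refs$ref_id[b$ref_idx],
      protein_identity = b$identity, frameshift_count = b$frameshift_count,
      has_stop = b$has_stop, is_target = refs$is_target[b$ref_idx],
      score = b$score, failed = FALSE)
  })
  dplyr::bind_rows(rows)
}

# reconstruct the corrected nucleotide sequence from a framebot traceback
rebuild_corrected <- function(seq, al, ref_protein, code = "11") {
  ref_res <- strsplit(ref_protein, "")[[1]]
  sub <- blosum62_ext()
  ops <- al$op; op_i <- al$op_i; op_j <- al$op_j
  pieces <- character(length(ops))
  # codon-like ops keeping read bases: 1 (codon) and 4 (insertion)
  keep3 <- ops == 1L | ops == 4L
  pieces[keep3] <- substring(seq, op_i[keep3] - 2L, op_i[keep3])
  # 2-nt frameshift: repaired to a codon encoding the reference residue
  fs2 <- which(ops == 2L)
  if (length(fs2) > 0) {
    cods <- canonical_codons(code)[ref_res[op_j[fs2]]]
    cods[is.na(cods)] <- "NNN"
    pieces[fs2] <- cods
  }
  # 4-nt frameshift: keep the read triple scoring better vs the reference
  fs4 <- which(ops == 3L)
  if (length(fs4) > 0) {
    c1 <- substring(seq, op_i[fs4] - 3L, op_i[fs4] - 1L)
    c2 <- substring(seq, op_i[fs4] - 2L, op_i[fs4])
    a1 <- aa_to_int(fast_translate_codons(paste(c1, collapse = ""), code))
    a2 <- aa_to_int(fast_translate_codons(paste(c2, collapse = ""), code))
    rj <- aa_to_int(ref_res[op_j[fs4]])
    take1 <- sub[cbind(a1 + 1L, rj + 1L)] >= sub[cbind(a2 + 1L, rj + 1L)]
    pieces[fs4] <- ifelse(take1, c1, c2)
  }
  nt <- paste(pieces, collapse = "")
  prot_res <- if (nchar(nt) >= 3) fast_translate_codons(nt, code) else character(0)
  # identity over aligned columns: emitted residues vs reference residues,
  # with insertions and deletions counting as differences
  emitting <- ops != 5L
  ncols <- length(ops)
  nmatch <- if (any(emitting))
    sum(prot_res[cumsum(emitting)[emitting]] == ref_res[op_j[emitting]] &
          ops[emitting] != 4L)
  else 0L
  nfs <- sum(ops == 2L | ops == 3L)
  prot <- paste(prot_res, collapse = "")
  list(corrected_nt = nt, corrected_protein = prot,
       identity = if (ncols > 0) nmatch / ncols else 0,
       frameshift_count = nfs,
       has_stop = grepl("*", prot, fixed = TRUE))
}

#' Split corrected amplicons into target and rejected sets
#'
#' Retains reads whose closest reference is a target and whose corrected
#' frame carries no stop codon; everything else is tallied per sample.
#'
#' @param corrected tibble from [frameshift_correct()].
#' @return list with `retained` (tibble) and `tally` (per-sample tibble
#'   with `retained`, `non_target`, `stop_codon`, `failed_alignment`,
#'   `pass_rate`).
#' @export
discriminate_targets <- function(corrected) {
  keep <- !corrected$failed & corrected$is_target & !corrected$has_stop
  keep[is.na(keep)] <- FALSE
  tally <- corrected |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      input = dplyr::n(),
      retained = sum(!.data$failed & .data$is_target & !.data$has_stop,
                     na.rm = TRUE),
      non_target = sum(!.data$failed & !.data$is_target, na.rm = TRUE),
      stop_codon = sum(!.data$failed & .data$is_target & .data$has_stop,
                       na.rm = TRUE),
      failed_alignment = sum(.data$failed),
      .groups = "drop") |>
    dplyr::mutate(pass_rate = .data$retained / .data$input)
  list(retained = corrected[keep, , drop = FALSE], tally = tally)
}

# ---- codon alignment and clustering ---------------------------------------

#' Codon alignment of corrected amplicons via the profile model
#'
#' Aligns the corrected proteins to the model and back-translates the
#' match-column alignment with the corrected nucleotide sequences
#' (restricted to the aligned residues), yielding equal-length nucleotide
#' rows ready for identity computation and clustering.
#'
#' @param proteins,nts named character vectors (same names), in frame.
#' @param model `profile_model`.
#' @param code genetic code id.
#' @return named character vector: codon alignment rows of length
#'   `3 * consensus_length`.
#' @export
make_codon_alignment <- function(proteins, nts, model, code = "11") {
  al <- align_to_model(model, proteins)
  M <- model$consensus_length
  ids <- rownames(al$aligned)
  out <- vapply(ids, function(id) {
    cols <- al$col_of_res[[id]]
    nt <- nts[[id]]
    res_idx <- which(cols > 0)
    # columns outside the aligned span are missing ("..."), internal
    # deletions are gaps ("---")
    pieces <- rep("...", M)
    if (length(res_idx) > 0) {
      span <- range(cols[res_idx])
      pieces[span[1]:span[2]] <- "---"
      pieces[cols[res_idx]] <- substring(nt, 3 * (res_idx - 1) + 1, 3 * res_idx)
    }
    paste(pieces, collapse = "")
  }, character(1))
  stats::setNames(out, ids)
}

# core complete-linkage clustering of aligned nucleotide rows; returns an
# integer cluster id per sequence (deterministic; distance = 1 - identity
# with gap-gap columns ignored and residue-vs-gap counted as difference)
cluster_sequences <- function(codon_alignment, cutoff) {
  ids <- names(codon_alignment)
  n <- length(codon_alignment)
  if (n == 1) return(stats::setNames(1L, ids))
  Achar <- do.call(rbind, strsplit(toupper(codon_alignment), ""))
  codes <- matrix(match(Achar, c("A", "C", "G", "T", "-", ".", "N"),
                        nomatch = 8L), nrow = n)
  idm <- cpp_pairwise_identity(codes, gapcode = 5L, misscode = 6L)
  D <- stats::as.dist(1 - idm)
  hc <- stats::hclust(D, method = "complete")
  cl <- stats::cutree(hc, h = (1 - cutoff) + 1e-9)
  stats::setNames(as.integer(cl), ids)
}

#' Complete-linkage clustering of a codon alignment into a cluster table
#'
#' Complete linkage guarantees every within-cluster pair meets the identity
#' cutoff. Reference rows (ids in `reference_ids`) participate in
#' clustering and label the clusters they fall into, but contribute no
#' counts.
#'
#' @param codon_alignment named character vector from
#'   [make_codon_alignment()] (amplicons and, optionally, trimmed
#'   references).
#' @param cutoff nucleotide identity cutoff (e.g. 0.90).
#' @param counts tibble with `seq_id`, `sample_id`, `count` giving how many
#'   reads each aligned sequence represents per sample; defaults to one
#'   count in a single sample per non-reference row.
#' @param reference_ids character vector of reference row ids.
#' @return a `cluster_table`: list with `counts` (sample x cluster integer
#'   matrix), `clusters` (tibble: `cluster_id`, `representative_id`,
#'   `representative_nt`, `n_sequences`, `total_count`,
#'   `contains_reference`), `cutoff`.
#' @export
cluster_complete_linkage <- function(codon_alignment, cutoff, counts = NULL,
                                     reference_ids = character(0)) {
  ids <- names(codon_alignment)
  if (is.null(counts)) {
    amp <- setdiff(ids, reference_ids)
    counts <- tibble::tibble(seq_id = amp, sample_id = "sample1",
                             count = 1L)
  }
  cl <- cluster_sequences(codon_alignment, cutoff)
  counts$cluster <- cl[counts$seq_id]
  samples <- sort(unique(counts$sample_id))
  nclust <- max(cl)
  cm <- matrix(0L, length(samples), nclust,
               dimnames = list(samples, sprintf("cl%04d", seq_len(nclust))))
  agg <- counts |>
    dplyr::group_by(.data$sample_id, .data$cluster) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  cm[cbind(match(agg$sample_id, samples), agg$cluster)] <- as.integer(agg$count)

  totals <- counts |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  info <- lapply(seq_len(nclust), function(k) {
    mem <- names(cl)[cl == k]
    amp_mem <- setdiff(mem, reference_ids)
    tc <- totals$count[match(amp_mem, totals$seq_id)]
    tc[is.na(tc)] <- 0L
    rep_id <- if (length(amp_mem) > 0) amp_mem[order(-tc, amp_mem)][1]
              else sort(mem)[1]
    refs_in <- intersect(mem, reference_ids)
    tibble::tibble(cluster_id = sprintf("cl%04d", k),
                   representative_id = rep_id,
                   representative_nt = gsub("[-.]", "",
                                            codon_alignment[[rep_id]]),
                   n_sequences = length(amp_mem),
                   total_count = sum(tc),
                   contains_reference = if (length(refs_in) > 0)
                     paste(sort(refs_in), collapse = ",") else NA_character_)
  })
  structure(list(counts = cm, clusters = dplyr::bind_rows(info),
                 cutoff = cutoff, assignments = cl),
            class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  cat("<cluster_table> ", nrow(x$counts), " sample(s) x ", ncol(x$counts),
      " cluster(s) at ", x$cutoff * 100, "% identity\n", sep = "")
  invisible(x)
}

#' Drop clusters below a minimum total count
#' @param ct a `cluster_table`.
#' @param min_count minimum summed count to retain a cluster (default 5).
#' @export
filter_min_count <- function(ct, min_count = 5) {
  keep <- colSums(ct$counts) >= min_count
  ct$counts <- ct$counts[, keep, drop = FALSE]
  ct$clusters <- ct$clusters[ct$clusters$cluster_id %in% colnames(ct$counts), ]
  ct
}

#' Rarefy a cluster table to even depth
#'
#' Per sample, `depth` reads are drawn without replacement under the given
#' seed, so a fixed seed reproduces the table bit-identically.
#'
#' @param ct a `cluster_table` (or plain counts matrix).
#' @param depth target depth; must not exceed the smallest sample total.
#' @param seed integer RNG seed.
#' @return object of the same type with all row sums equal to `depth`.
#' @export
rarefy_even <- function(ct, depth, seed) {
  m <- if (inherits(ct, "cluster_table")) ct$counts else ct
  if (depth > min(rowSums(m)))
    stop("depth exceeds the smallest sample total (", min(rowSums(m)), ")")
  out <- withCallingHandlers(
    withr::with_seed(seed, vegan::rrarefy(m, depth)),
    warning = function(w) {
      # vegan's "observed counts" heuristic misfires on filtered tables
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  mode(out) <- "integer"
  if (inherits(ct, "cluster_table")) { ct$counts <- out; ct } else out
}

#' Diversity summary across clustering cutoffs
#'
#' For each cutoff: total clusters, clusters-per-sample mean and sd, and
#' prevalence-category binning (present in <10%, 10-50%, 50-90%, >90% of
#' samples) with each category's share of clusters and of sequences.
#'
#' @param tables named list of `cluster_table`s (names = cutoffs).
#' @return list with `summary` (per-cutoff tibble) and `prevalence`
#'   (per-cutoff-by-category tibble).
#' @export
diversity_profile <- function(tables) {
  summ <- list(); prev <- list()
  for (nm in names(tables)) {
    m <- tables[[nm]]$counts
    pres <- m > 0
    per_sample <- rowSums(pres)
    p <- colMeans(pres)
    cat_lab <- cut(p, breaks = c(-Inf, 0.10, 0.50, 0.90, Inf),
                   labels = c("<10%", "10-50%", "50-90%", ">90%"))
    seq_share <- tapply(colSums(m), cat_lab, sum, default = 0) / sum(m)
    cl_share <- tapply(rep(1, ncol(m)), cat_lab, sum, default = 0) / ncol(m)
    summ[[nm]] <- tibble::tibble(
      cutoff = as.numeric(nm), n_clusters = ncol(m),
      clusters_per_sample_mean = mean(per_sample),
      clusters_per_sample_sd = if (nrow(m) > 1) stats::sd(per_sample) else 0)
    prev[[nm]] <- tibble::tibble(
      cutoff = as.numeric(nm), category = names(seq_share),
      share_of_clusters = as.numeric(cl_share),
      share_of_sequences = as.numeric(seq_share))
  }
  list(summary = dplyr::bind_rows(summ), prevalence = dplyr::bind_rows(prev))
}

#' Best-match nucleotide identity of amplicons to target references
#'
#' Per read, the maximum nucleotide identity to any target reference over
#' a local pairwise alignment; summarized as mean and sd.
#'
#' @param corrected tibble from [frameshift_correct()] (retained set).
#' @param database a `gene_database` or character vector of reference
#'   nucleotide sequences.
#' @return list with `per_read` tibble (`read_id`, `best_ref`, `identity`)
#'   and `summary` (mean, sd).
#' @export
best_match_identity <- function(corrected, database) {
  refs <- if (inherits(database, "gene_database"))
    stats::setNames(database$targets$gene_nt, database$targets$protein_id)
  else stats::setNames(as.character(database),
                       names(database) %||% sprintf("ref%03d", seq_along(database)))
  useq <- unique(corrected$corrected_nt)
  refset <- Biostrings::DNAStringSet(refs)
  best_id <- numeric(length(useq)); best_ref <- character(length(useq))
  # blastn-like scoring so scattered mismatches stay inside the local
  # alignment instead of being clipped or gapped around
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  for (k in seq_along(useq)) {
    pa <- Biostrings::pairwiseAlignment(refset,
                                        Biostrings::DNAString(useq[k]),
                                        type = "local",
                                        substitutionMatrix = sm,
                                        gapOpening = 4, gapExtension = 2)
    pid <- Biostrings::pid(pa, type = "PID1") / 100
    j <- which.max(pid)
    best_id[k] <- pid[j]; best_ref[k] <- names(refs)[j]
  }
  idx <- match(corrected$corrected_nt, useq)
  per_read <- tibble::tibble(read_id = corrected$read_id,
                             best_ref = best_ref[idx],
                             identity = best_id[idx])
  list(per_read = per_read,
       summary = tibble::tibble(mean_identity = mean(per_read$identity),
                                sd_identity = stats::sd(per_read$identity)))
}

#' Run the amplicon profiling workflow
#'
#' Frameshift correction against the database panel (targets + outgroup),
#' target discrimination, codon alignment, complete-linkage clustering at
#' the requested cutoffs, minimum-count filtering and rarefaction.
#'
#' @param reads merged read tibble (`read_id`, `sample_id`, `seq`).
#' @param db a `gene_database`.
#' @param model the gene's `profile_model`.
#' @param cutoffs identity cutoffs (default `c(0.99, 0.98, 0.95, 0.90)`).
#' @param min_count minimum cluster count (default 5).
#' @param rarefy_depth depth for rarefaction; `NULL` = smallest sample
#'   total after filtering.
#' @param seed RNG seed for rarefaction.
#' @param include_references add trimmed target references to the
#'   clustering so clusters inherit reference labels.
#' @param flag_failure_rate per-sample failure fraction above which the
#'   sample is flagged for quality review (default 0.5).
#' @return list with `tables` (cluster tables per cutoff, filtered +
#'   rarefied), `corrected`, `tally`, `flagged_samples`.
#' @export
profile_amplicons <- function(reads, db, model,
                              cutoffs = c(0.99, 0.98, 0.95, 0.90),
                              min_count = 5, rarefy_depth = NULL, seed = 42,
                              include_references = TRUE,
                              flag_failure_rate = 0.5) {
  panel <- dplyr::bind_rows(
    tibble::tibble(ref_id = db$targets$protein_id,
                   protein = db$targets$protein, is_target = TRUE),
    tibble::tibble(ref_id = db$outgroup$protein_id,
                   protein = db$outgroup$protein, is_target = FALSE))
  corrected <- frameshift_correct(reads, panel)
  disc <- discriminate_targets(corrected)
  flagged <- disc$tally$sample_id[1 - disc$tally$pass_rate > flag_failure_rate]
  ret <- disc$retained
  if (nrow(ret) == 0) stop("no reads survived target discrimination")

  useq <- ret |>
    dplyr::group_by(.data$corrected_protein, .data$corrected_nt) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
  useq$seq_id <- sprintf("amp%05d", seq_len(nrow(useq)))
  key <- paste(ret$corrected_protein, ret$corrected_nt)
  ret$seq_id <- useq$seq_id[match(key, paste(useq$corrected_protein,
                                             useq$corrected_nt))]
  counts <- ret |>
    dplyr::group_by(.data$seq_id, .data$sample_id) |>
    dplyr::summarise(count = dplyr::n(), .groups = "drop")

  prot <- stats::setNames(useq$corrected_protein, useq$seq_id)
  nts <- stats::setNames(useq$corrected_nt, useq$seq_id)
  ref_ids <- character(0)
  if (include_references) {
    # full-length references join the alignment; pairwise identities are
    # computed over shared aligned columns, which restricts each
    # read-vs-reference comparison to the amplicon region automatically
    rid <- paste0("ref_", db$targets$protein_id)
    prot <- c(prot, stats::setNames(db$targets$protein, rid))
    nts <- c(nts, stats::setNames(db$targets$gene_nt, rid))
    ref_ids <- rid
  }
  codal <- make_codon_alignment(prot, nts, model)
  tables <- list()
  for (co in cutoffs) {
    ct <- cluster_complete_linkage(codal, co, counts = counts,
                                   reference_ids = ref_ids)
    ct <- filter_min_count(ct, min_count)
    tables[[format(co)]] <- ct
  }
  if (is.null(rarefy_depth))
    rarefy_depth <- min(vapply(tables, function(t) min(rowSums(t$counts)),
                               numeric(1)))
  tables <- lapply(tables, rarefy_even, depth = rarefy_depth, seed = seed)
  list(tables = tables, corrected = corrected, tally = disc$tally,
       flagged_samples = flagged, rarefy_depth = rarefy_depth)
}
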