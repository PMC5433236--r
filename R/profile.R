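# Position-specific profile models of protein families: build from a seed
# alignment, iterative refinement, local scoring/alignment in bits, and
# codon-aware back-translation of protein alignments.
#
# The engine is self-contained: match columns are alignment columns with a
# gap fraction at or below `match_threshold` (default 0.5), emissions are
# Henikoff position-weighted counts with +0.5 pseudocounts expressed as
# log2-odds against the BLOSUM62 background, and alignment is local Viterbi
# over match/insert/delete states with affine penalties in bits.

.default_penalties <- c(insert_open = 3, insert_ext = 1,
                        delete_open = 3, delete_ext = 1)

#' Build a profile model from a seed protein alignment
#'
#' @param seed_alignment named character vector (or `AAStringSet`) of
#'   aligned, equal-length protein sequences; `-` and `.` are gaps.
#' @param match_threshold maximum gap fraction for a column to become a
#'   match column.
#' @param pseudocount added to every weighted residue count.
#' @param penalties named numeric: `insert_open`, `insert_ext`,
#'   `delete_open`, `delete_ext` (bits).
#' @return a `profile_model` with `emissions` (match-columns x 20 log2-odds
#'   matrix), `consensus`, `consensus_length`, `seed_ids`, `refine_cycles`.
#' @export
build_profile <- function(seed_alignment, match_threshold = 0.5,
                          pseudocount = 0.5,
                          penalties = .default_penalties) {
  if (methods::is(seed_alignment, "AAStringSet"))
    seed_alignment <- stats::setNames(as.character(seed_alignment),
                                      names(seed_alignment))
  if (length(seed_alignment) < 2)
    stop("a profile model needs at least 2 aligned seed sequences")
  w <- unique(nchar(seed_alignment))
  if (length(w) != 1)
    stop("seed sequences are not aligned: unequal lengths ",
         paste(w, collapse = ", "))
  ids <- names(seed_alignment) %||% sprintf("seed%02d", seq_along(seed_alignment))
  A <- do.call(rbind, strsplit(toupper(seed_alignment), ""))
  A[A == "."] <- "-"
  rownames(A) <- ids

  gap_frac <- colMeans(A == "-")
  match_cols <- which(gap_frac <= match_threshold & gap_frac < 1)
  if (length(match_cols) == 0) stop("no match columns under the gap threshold")

  wts <- henikoff_weights(A)
  M <- length(match_cols)
  emis <- matrix(0, M, 20)
  consensus <- character(M)
  for (m in seq_len(M)) {
    col <- A[, match_cols[m]]
    keep <- col != "-"
    cnt <- rep(0, 20)
    if (any(keep)) {
      codes <- aa_to_int(col[keep]) + 1L
      valid <- codes <= 20L
      cnt <- vapply(1:20, function(k) sum(wts[keep][valid & codes == k]), numeric(1))
    }
    p <- (cnt + pseudocount) / (sum(cnt) + 20 * pseudocount)
    emis[m, ] <- log2(p / aa_background)
    consensus[m] <- AA20[which.max(cnt + pseudocount * aa_background)]
  }
  structure(list(
    emissions = emis, consensus = consensus, consensus_length = M,
    penalties = penalties, match_threshold = match_threshold,
    pseudocount = pseudocount, seed_ids = ids, refine_cycles = 0L
  ), class = "profile_model")
}

# Henikoff position-based sequence weights, normalized to sum to the number
# of sequences.
henikoff_weights <- function(A) {
  n <- nrow(A)
  w <- numeric(n)
  for (j in seq_len(ncol(A))) {
    col <- A[, j]
    keep <- col != "-"
    if (!any(keep)) next
    tab <- table(col[keep])
    r <- length(tab)
    w[keep] <- w[keep] + 1 / (r * as.numeric(tab[col[keep]]))
  }
  if (sum(w) == 0) return(rep(1, n))
  w * n / sum(w)
}

#' @export
print.profile_model <- function(x, ...) {
  cat("<profile_model> ", x$consensus_length, " match columns, ",
      length(x$seed_ids), " seeds, ", x$refine_cycles, " refine cycle(s)\n",
      sep = "")
  invisible(x)
}

#' Score protein sequences against a profile model
#'
#' Optimal local model-to-sequence alignment score in bits. Empty sequences
#' score `-Inf`.
#'
#' @param model a `profile_model`.
#' @param proteins character vector of protein sequences (`X` allowed,
#'   scored at background).
#' @return numeric vector of bit scores.
#' @export
score_sequence <- function(model, proteins) {
  stopifnot(inherits(model, "profile_model"))
  if (length(proteins) == 0) return(numeric(0))
  seqs <- lapply(proteins, aa_seq_to_int)
  p <- model$penalties
  cpp_profile_scores(model$emissions, seqs,
                     p[["insert_open"]], p[["insert_ext"]],
                     p[["delete_open"]], p[["delete_ext"]])
}

#' Align protein sequences to a profile model
#'
#' @param model a `profile_model`.
#' @param proteins named character vector of protein sequences.
#' @return a `model_alignment`: list with `records` (tibble: `sequence_id`,
#'   `score`, `coverage`, model span) and `aligned` (character matrix, one
#'   row per sequence, one column per model match column; `-` marks columns
#'   deleted or outside the aligned span).
#' @export
align_to_model <- function(model, proteins) {
  stopifnot(inherits(model, "profile_model"))
  ids <- names(proteins) %||% sprintf("seq%04d", seq_along(proteins))
  M <- model$consensus_length
  p <- model$penalties
  aligned <- matrix("-", length(proteins), M, dimnames = list(ids, NULL))
  col_of_res <- vector("list", length(proteins))
  recs <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    res <- strsplit(toupper(proteins[[i]]), "")[[1]]
    al <- cpp_profile_align(model$emissions, aa_to_int(res),
                            p[["insert_open"]], p[["insert_ext"]],
                            p[["delete_open"]], p[["delete_ext"]],
                            traceback = TRUE)
    cov <- if (is.finite(al$score)) (al$jend - al$jstart + 1) / M else 0
    hit <- al$col_of_res > 0
    if (any(hit)) aligned[i, al$col_of_res[hit]] <- res[hit]
    col_of_res[[i]] <- al$col_of_res
    recs[[i]] <- tibble::tibble(sequence_id = ids[i], score = al$score,
                                coverage = cov, model_start = al$jstart,
                                model_end = al$jend)
  }
  structure(list(records = dplyr::bind_rows(recs), aligned = aligned,
                 col_of_res = stats::setNames(col_of_res, ids),
                 consensus_length = M),
            class = "model_alignment")
}

#' @export
print.model_alignment <- function(x, ...) {
  cat("<model_alignment> ", nrow(x$aligned), " sequence(s) over ",
      x$consensus_length, " model columns\n", sep = "")
  invisible(x)
}

#' Iteratively refine a profile model
#'
#' Each cycle realigns the (ungapped) seeds to the current model and
#' rebuilds the model from the resulting match-column alignment; seeds
#' whose score falls below `score_floor` are dropped with a warning.
#'
#' @param model starting `profile_model`.
#' @param seeds named character vector of ungapped seed proteins.
#' @param cycles number of realign/rebuild cycles (>= 1).
#' @param score_floor minimum bit score for a seed to be kept.
#' @return refined `profile_model`; the final seed alignment is attached as
#'   attribute `"final_alignment"`.
#' @export
refine_profile <- function(model, seeds, cycles = 3, score_floor = 0) {
  stopifnot(cycles >= 1)
  if (is.null(names(seeds))) names(seeds) <- sprintf("seed%02d", seq_along(seeds))
  aligned <- NULL
  for (cy in seq_len(cycles)) {
    al <- align_to_model(model, seeds)
    keep <- al$records$score >= score_floor
    if (!all(keep)) {
      warning("dropping ", sum(!keep), " seed(s) below the score floor: ",
              paste(al$records$sequence_id[!keep], collapse = ", "))
      seeds <- seeds[keep]
      if (length(seeds) < 2) stop("fewer than 2 seeds survived realignment")
      al <- align_to_model(model, seeds)
    }
    aligned <- apply(al$aligned, 1, paste, collapse = "")
    model <- build_profile(aligned, match_threshold = model$match_threshold,
                           pseudocount = model$pseudocount,
                           penalties = model$penalties)
    model$refine_cycles <- cy
  }
  attr(model, "final_alignment") <- aligned
  model
}

#' Build and refine a profile model from ungapped or pre-aligned seeds
#'
#' Convenience wrapper: builds from the seed alignment, then runs
#' [refine_profile()] on the ungapped seeds.
#' @inheritParams build_profile
#' @param cycles refinement cycles (default 3).
#' @export
build_refined_profile <- function(seed_alignment, cycles = 3, ...) {
  model <- build_profile(seed_alignment, ...)
  seeds <- gsub("[-.]", "", seed_alignment)
  refine_profile(model, seeds, cycles = cycles)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Every protein gap expands to a 3-nt gap; ungapped columns stay intact
#' codons, so removing gaps recovers the input nucleotide sequence.
#'
#' @param protein_alignment named character vector of aligned proteins.
#' @param nt_sequences named character vector of in-frame nucleotide
#'   sequences; each must translate (frame 0) to its ungapped protein.
#' @param code genetic code id.
#' @return named character vector: the codon alignment.
#' @export
backtranslate_alignment <- function(protein_alignment, nt_sequences, code = "11") {
  ids <- names(protein_alignment)
  if (is.null(ids) || !all(ids %in% names(nt_sequences)))
    stop("every aligned protein needs a matching named nucleotide sequence")
  out <- vapply(ids, function(id) {
    prot <- protein_alignment[[id]]
    nt <- nt_sequences[[id]]
    res <- strsplit(prot, "")[[1]]
    ngaps <- sum(res %in% c("-", "."))
    if (nchar(nt) != 3 * (length(res) - ngaps))
      stop("nucleotide length of '", id, "' (", nchar(nt),
           ") does not match 3x its ungapped protein length")
    core <- gsub("[-.]", "", prot)
    tr <- sub("\\*$", "", translate_nt(nt, code))
    if (toupper(core) != toupper(sub("\\*$", "", tr)) && toupper(core) != toupper(tr))
      stop("'", id, "' does not translate to its aligned protein")
    codons <- substring(nt, seq(1, nchar(nt), by = 3), seq(3, nchar(nt), by = 3))
    pieces <- character(length(res))
    pieces[res %in% c("-", ".")] <- "---"
    pieces[!(res %in% c("-", "."))] <- codons
    paste(pieces, collapse = "")
  }, character(1))
  stats::setNames(out, ids)
}

# ---- serialization --------------------------------------------------------

#' Serialize a profile model to a versioned JSON file
#' @param model a `profile_model`.
#' @param path output path.
#' @export
write_profile <- function(model, path) {
  obj <- list(format = "quatscreen-profile", version = 1L,
              consensus = paste(model$consensus, collapse = ""),
              match_threshold = model$match_threshold,
              pseudocount = model$pseudocount,
              penalties = as.list(model$penalties),
              seed_ids = model$seed_ids, refine_cycles = model$refine_cycles,
              emissions = apply(model$emissions, 1, function(r) unname(r),
                                simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a profile model serialized by [write_profile()]
#' @param path JSON path.
#' @export
read_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "quatscreen-profile"))
    stop("not a quatscreen profile file: ", path)
  emis <- if (is.matrix(obj$emissions)) obj$emissions
          else do.call(rbind, obj$emissions)
  structure(list(
    emissions = emis, consensus = strsplit(obj$consensus, "")[[1]],
    consensus_length = nrow(emis),
    penalties = unlist(obj$penalties), match_threshold = obj$match_threshold,
    pseudocount = obj$pseudocount, seed_ids = obj$seed_ids,
    refine_cycles = as.integer(obj$refine_cycles)
  ), class = "profile_model")
}
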