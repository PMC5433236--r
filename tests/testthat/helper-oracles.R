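# Independent oracles used by the unit and acceptance tests. These
# re-derive expected results by direct computation (memoized recursion,
# naive agglomeration, closed forms) and never call the code paths they
# check.

# ---- frameshift-aware DP oracle -------------------------------------------
# Memoized recursive evaluation of the translated-alignment recurrence:
# states M (reference residue consumed by a 3-nt codon, or a 2-/4-nt
# frameshift chunk), I (3-nt insertion, reference unmoved), D (reference
# residue deleted). Local alignment; tie preference fixed as
# codon > fs2 > fs4 and M > I > D > restart; best end cell is the first
# (smallest nt index, then smallest ref index) maximal M cell.
oracle_framebot <- function(read_nt, ref_protein, gap_open = 11, gap_ext = 1,
                            frameshift = 12) {
  sub <- quatscreen:::blosum62_ext()
  c64 <- quatscreen:::code64_table("11")
  nt <- quatscreen:::nt_seq_to_int(read_nt)
  ref <- quatscreen:::aa_seq_to_int(ref_protein)
  L <- length(nt); P <- length(ref)
  NEG <- -1e18
  aa_of <- function(i) { # aa code of codon ending at i
    n <- nt[(i - 2):i]
    if (any(n > 3)) 20L else c64[16L * n[1] + 4L * n[2] + n[3] + 1L]
  }
  M <- array(NA_real_, c(L + 1, P + 1)); I <- M; D <- M
  get_state <- function(st, i, j) {
    if (j < 0 || i < 0) return(NEG)
    ii <- i + 1; jj <- j + 1
    if (st == "M") {
      if (!is.na(M[ii, jj])) return(M[ii, jj])
      if (j == 0) { M[ii, jj] <<- NEG; return(NEG) }
      v <- NEG
      if (i >= 3) {
        pre <- pre_of(i - 3, j - 1)
        v <- max(v, pre + sub[aa_of(i) + 1L, ref[j] + 1L])
      }
      if (i >= 2) v <- max(v, pre_of(i - 2, j - 1) - frameshift)
      if (i >= 4) v <- max(v, pre_of(i - 4, j - 1) - frameshift)
      M[ii, jj] <<- v
      v
    } else if (st == "I") {
      if (!is.na(I[ii, jj])) return(I[ii, jj])
      v <- if (i >= 3) max(get_state("M", i - 3, j) - gap_open,
                           get_state("I", i - 3, j) - gap_ext)
           else NEG
      I[ii, jj] <<- v
      v
    } else {
      if (!is.na(D[ii, jj])) return(D[ii, jj])
      v <- if (j >= 1) max(get_state("M", i, j - 1) - gap_open,
                           get_state("D", i, j - 1) - gap_ext)
           else NEG
      D[ii, jj] <<- v
      v
    }
  }
  pre_of <- function(i, j) {
    max(0, get_state("M", i, j), get_state("I", i, j), get_state("D", i, j))
  }
  best <- -Inf; bi <- 0L; bj <- 0L
  for (i in 0:L) for (j in seq_len(P)) {
    v <- get_state("M", i, j)
    if (v > best) { best <- v; bi <- i; bj <- j }
  }
  if (bj == 0 || best <= NEG / 2)
    return(list(score = -Inf, ops = integer(0)))

  # traceback with the fixed preference order: ways codon > fs2 > fs4;
  # predecessors M > I > D > restart (restart only when 0 strictly beats
  # all three states)
  ops <- integer(0); op_i <- integer(0); op_j <- integer(0)
  i <- bi; j <- bj; st <- "M"
  repeat {
    if (st == "M") {
      v <- get_state("M", i, j)
      way <- 0L; kk <- 0L
      for (cand in 1:3) {
        k <- c(3L, 2L, 4L)[cand]
        if (i < k) next
        inc <- if (cand == 1L) sub[aa_of(i) + 1L, ref[j] + 1L] else -frameshift
        if (pre_of(i - k, j - 1) + inc == v) { way <- cand; kk <- k; break }
      }
      stopifnot(way > 0L)
      ops <- c(ops, way); op_i <- c(op_i, i); op_j <- c(op_j, j)
      i <- i - kk; j <- j - 1
      pm <- get_state("M", i, j); pin <- get_state("I", i, j)
      pd <- get_state("D", i, j)
      top <- max(pm, pin, pd)
      if (0 > top) break                 # local restart
      st <- if (pm == top) "M" else if (pin == top) "I" else "D"
      if (j == 0 && st == "M") break
    } else if (st == "I") {
      v <- get_state("I", i, j)
      ops <- c(ops, 4L); op_i <- c(op_i, i); op_j <- c(op_j, j)
      st <- if (get_state("M", i - 3, j) - gap_open >=
                get_state("I", i - 3, j) - gap_ext) "M" else "I"
      i <- i - 3
      if (j == 0 && st == "M") break
    } else {
      v <- get_state("D", i, j)
      ops <- c(ops, 5L); op_i <- c(op_i, i); op_j <- c(op_j, j)
      st <- if (get_state("M", i, j - 1) - gap_open >=
                get_state("D", i, j - 1) - gap_ext) "M" else "D"
      j <- j - 1
      if (j == 0 && st == "M") break
    }
  }
  list(score = best, ops = as.integer(rev(ops)),
       op_i = as.integer(rev(op_i)), op_j = as.integer(rev(op_j)))
}

# ---- naive complete-linkage oracle ----------------------------------------
# Exhaustive agglomeration over an identity matrix: repeatedly merge the
# cluster pair with the smallest complete-linkage distance (ties by the
# smallest minimum member index) while that distance stays within the
# cutoff. Returns an integer partition.
oracle_complete_linkage <- function(idm, cutoff) {
  n <- nrow(idm)
  D <- 1 - idm
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- NULL; best_d <- Inf
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      d <- max(D[clusters[[a]], clusters[[b]]])
      if (d < best_d - 1e-12) { best_d <- d; best <- c(a, b) }
    }
    if (best_d > (1 - cutoff) + 1e-9) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  part <- integer(n)
  for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
  part
}

# partitions equal up to label renaming
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(tapply(seq_along(a), a, function(ix) length(unique(b[ix])) == 1)) &&
    length(unique(a)) == length(unique(b))
}

# ---- small fixture builders -----------------------------------------------

# a tiny gene database object built directly from sequences (no screen)
make_mini_db <- function(target_prots, target_nts, outgroup_prots = NULL,
                         outgroup_nts = NULL, gene_name = "gene") {
  og <- if (is.null(outgroup_prots))
    tibble::tibble(protein_id = character(), protein = character(),
                   gene_nt = character())
  else tibble::tibble(protein_id = names(outgroup_prots),
                      protein = unname(outgroup_prots),
                      gene_nt = unname(outgroup_nts))
  structure(list(
    gene_name = gene_name,
    targets = tibble::tibble(protein_id = names(target_prots),
                             protein = unname(target_prots),
                             gene_nt = unname(target_nts),
                             cluster90 = NA_character_,
                             taxonomy = NA_character_),
    outgroup = og, cutoff_used = 0, copy_number = NULL, candidates = NULL,
    params = list()), class = "gene_database")
}

# four diverged amplicon reference populations from one family
make_amplicon_refs <- function(fam, n = 4, divergence = 0.15, seed = 99) {
  withr::with_seed(seed, {
    prots <- vapply(seq_len(n), function(i)
      quatscreen:::mutate_protein(fam$ancestor, divergence), character(1))
    nts <- vapply(prots, quatscreen:::backtranslate_protein, character(1))
  })
  names(prots) <- names(nts) <- sprintf("ref%02d", seq_len(n))
  list(prots = prots, nts = nts)
}
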