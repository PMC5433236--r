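# Degenerate-primer arithmetic, in-silico PCR and database coverage.
# IUPAC symbols carry their base sets; inosine (I) pairs with any base and
# contributes a factor of 1 to degeneracy (wobble convention).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  I = c("A", "C", "G", "T")
)

.base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L)

iupac_mask <- function(chars) {
  vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (is.null(set)) 0L else sum(.base_bit[set])
  }, integer(1), USE.NAMES = FALSE)
}

.complement_char <- c(A = "T", C = "G", G = "C", T = "A", U = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N", I = "I")

iupac_revcomp <- function(seq) {
  chars <- rev(strsplit(toupper(seq), "")[[1]])
  out <- .complement_char[chars]
  if (anyNA(out)) stop("invalid IUPAC character in primer: ",
                       paste(unique(chars[is.na(out)]), collapse = ", "))
  paste(out, collapse = "")
}

#' Define a primer
#'
#' @param name primer name.
#' @param iupac_sequence 5'->3' sequence over the IUPAC alphabet including
#'   inosine (`I`).
#' @param orientation `"forward"` or `"reverse"`.
#' @return a `primer` object.
#' @export
primer <- function(name, iupac_sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  s <- toupper(iupac_sequence)
  if (!nzchar(s)) stop("primer sequence is empty")
  chars <- strsplit(s, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0)
    stop("invalid IUPAC character(s) in primer '", name, "': ",
         paste(bad, collapse = ", "))
  structure(list(name = name, iupac_sequence = s, orientation = orientation),
            class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat("<primer> ", x$name, " (", x$orientation, "): ", x$iupac_sequence,
      "  [degeneracy ", degeneracy(x), "]\n", sep = "")
  invisible(x)
}

#' Degeneracy of a primer
#'
#' Product over positions of the IUPAC set cardinality, with inosine
#' contributing a factor of 1 (it pairs universally, so it adds no
#' combinatorial variants to the synthesis).
#'
#' @param primer a `primer` object or an IUPAC string.
#' @return integer number of concrete oligonucleotide variants (>= 1).
#' @export
degeneracy <- function(primer) {
  s <- if (inherits(primer, "primer")) primer$iupac_sequence else toupper(primer)
  chars <- strsplit(s, "")[[1]]
  if (length(chars) == 0) stop("primer sequence is empty")
  card <- vapply(chars, function(ch) {
    if (ch == "I") return(1L)
    set <- IUPAC_SETS[[ch]]
    if (is.null(set)) stop("invalid IUPAC character: ", ch)
    length(set)
  }, integer(1))
  prod(card)
}

#' Find primer binding sites on a template
#'
#' Forward primers are matched on the given strand; reverse primers are
#' matched as their reverse complement (i.e. the site occupied on the plus
#' strand). A site matches when its mismatch count is at most
#' `max_mismatch`; a primer IUPAC symbol matches any base in its set,
#' inosine matches any base, and an ambiguity code in the template matches
#' when the two base sets intersect.
#'
#' @param template_nt template sequence (plain or IUPAC).
#' @param primer a `primer`.
#' @param max_mismatch allowed mismatches (default 0).
#' @return tibble with `start`, `end` (1-based, inclusive) and `mismatches`.
#' @export
find_sites <- function(template_nt, primer, max_mismatch = 0) {
  stopifnot(inherits(primer, "primer"))
  pat <- if (primer$orientation == "reverse") iupac_revcomp(primer$iupac_sequence)
         else primer$iupac_sequence
  scan_pattern(template_nt, pat, max_mismatch)
}

scan_pattern <- function(template_nt, pattern, max_mismatch) {
  tchars <- strsplit(toupper(template_nt), "")[[1]]
  tm <- iupac_mask(tchars)
  pm <- iupac_mask(strsplit(pattern, "")[[1]])
  mm <- cpp_primer_scan(tm, pm)
  hit <- which(mm <= max_mismatch)
  tibble::tibble(start = hit, end = hit + length(pm) - 1L,
                 mismatches = mm[hit])
}

#' In-silico PCR
#'
#' Emits the inter-primer sequence for every valid pairing of a forward
#' site upstream of a reverse site (both template orientations are
#' scanned). Product length excludes both primers. Products longer than
#' `max_len` are dropped to avoid spurious genome-spanning pairings.
#'
#' @param template_nt template sequence.
#' @param fwd,rev forward and reverse `primer` objects.
#' @param max_mismatch allowed mismatches per primer (default 1).
#' @param max_len maximum product length (default 5000).
#' @return tibble with `start`, `end` (product coordinates on the plus
#'   strand, excluding primers), `strand`, `length` and `product`, sorted
#'   by position.
#' @export
in_silico_pcr <- function(template_nt, fwd, rev, max_mismatch = 1,
                          max_len = 5000) {
  template_nt <- toupper(template_nt)
  pair_up <- function(fsites, rsites, strand) {
    out <- list()
    for (i in seq_len(nrow(fsites))) {
      ok <- rsites$start > fsites$end[i]
      for (j in which(ok)) {
        s <- fsites$end[i] + 1L
        e <- rsites$start[j] - 1L
        len <- e - s + 1L
        if (len < 0L || len > max_len) next
        prod <- substr(template_nt, s, e)
        if (strand == "-") prod <- revcomp(prod)
        out[[length(out) + 1L]] <- tibble::tibble(
          start = s, end = e, strand = strand, length = len, product = prod)
      }
    }
    dplyr::bind_rows(out)
  }
  f_plus <- scan_pattern(template_nt, fwd$iupac_sequence, max_mismatch)
  r_minus <- scan_pattern(template_nt, iupac_revcomp(rev$iupac_sequence),
                          max_mismatch)
  res <- pair_up(f_plus, r_minus, "+")
  # amplicon on the minus strand: reverse primer binds plus strand upstream
  # of the reverse-complemented forward site
  r_plus <- scan_pattern(template_nt, rev$iupac_sequence, max_mismatch)
  f_minus <- scan_pattern(template_nt, iupac_revcomp(fwd$iupac_sequence),
                          max_mismatch)
  res2 <- pair_up(r_plus, f_minus, "-")
  out <- dplyr::bind_rows(res, res2)
  if (nrow(out) == 0)
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), length = integer(),
                          product = character()))
  dplyr::arrange(dplyr::distinct(out), .data$start, .data$end)
}

#' Primer coverage of a reference database
#'
#' Fraction of unique target nucleotide references yielding at least one
#' in-silico PCR product.
#'
#' @param database a `gene_database` (its unique target `gene_nt` entries
#'   are used) or a character vector of reference sequences.
#' @param fwd,rev `primer` objects.
#' @param max_mismatch allowed mismatches per primer (default 1).
#' @param max_len maximum product length.
#' @return fraction in `[0, 1]`.
#' @export
primer_coverage <- function(database, fwd, rev, max_mismatch = 1,
                            max_len = 5000) {
  refs <- if (inherits(database, "gene_database")) database$targets$gene_nt
          else as.character(database)
  refs <- unique(refs)
  if (length(refs) == 0) stop("empty reference database")
  hit <- vapply(refs, function(r)
    nrow(in_silico_pcr(r, fwd, rev, max_mismatch, max_len)) > 0, logical(1))
  mean(hit)
}

#' Trim primers off amplicon reads
#'
#' The forward site must begin within `slack` bases of the 5' end and the
#' reverse site must end within `slack` bases of the 3' end; reads missing
#' either site are discarded and tallied. Trimming is idempotent (a
#' trimmed read no longer carries sites and would simply be discarded, so
#' re-trimming the retained set returns it unchanged when sites are
#' removed, and trimmed output never retains primer bases).
#'
#' @param reads tibble with `read_id`, `seq` (and optional other columns).
#' @param fwd,rev `primer` objects.
#' @param max_mismatch allowed mismatches per primer.
#' @param slack positional tolerance at either end (default 3).
#' @return list with `reads` (trimmed tibble) and `tally` (named counts:
#'   `input`, `trimmed`, `no_forward`, `no_reverse`).
#' @export
trim_primers <- function(reads, fwd, rev, max_mismatch = 1, slack = 3) {
  n <- nrow(reads)
  keep <- logical(n)
  trimmed <- character(n)
  no_f <- 0L; no_r <- 0L
  for (i in seq_len(n)) {
    s <- toupper(reads$seq[i])
    fs <- scan_pattern(s, fwd$iupac_sequence, max_mismatch)
    fs <- fs[fs$start <= slack + 1L, ]
    if (nrow(fs) == 0) { no_f <- no_f + 1L; next }
    rs <- scan_pattern(s, iupac_revcomp(rev$iupac_sequence), max_mismatch)
    rs <- rs[rs$end >= nchar(s) - slack, ]
    rs <- rs[rs$start > fs$end[1], ]
    if (nrow(rs) == 0) { no_r <- no_r + 1L; next }
    keep[i] <- TRUE
    trimmed[i] <- substr(s, fs$end[1] + 1L, rs$start[nrow(rs)] - 1L)
  }
  out <- reads[keep, , drop = FALSE]
  out$seq <- trimmed[keep]
  if ("qual" %in% names(out)) out$qual <- vector("list", nrow(out))
  list(reads = out,
       tally = c(input = n, trimmed = sum(keep), no_forward = no_f,
                 no_reverse = no_r))
}

#' Read primers from a TSV file
#'
#' Expected columns: `name`, `sequence`, `orientation` (and optionally
#' `gene`).
#' @param path TSV path.
#' @return named list of `primer` objects.
#' @export
read_primers <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "sequence", "orientation")
  if (!all(need %in% names(d)))
    stop("primer TSV needs columns: ", paste(need, collapse = ", "))
  ps <- lapply(seq_len(nrow(d)), function(i)
    primer(d$name[i], d$sequence[i], d$orientation[i]))
  stats::setNames(ps, d$name)
}

#' The package's shipped qPCR/sequencing assay primers
#'
#' Degenerate primer pairs targeting the choline TMA-lyase gene (cutC) and
#' the carnitine oxygenase gene (cntA), plus the V1-2 16S rRNA gene pair
#' used for total-community normalization, as used by the gene-targeted
#' assays this package implements.
#'
#' @return named list of `primer` objects (`cutC_F`, `cutC_R`, `cntA_F`,
#'   `cntA_R`, `16S_F`, `16S_R`).
#' @export
tma_primers <- function() {
  read_primers(system.file("extdata", "primers.tsv", package = "quatscreen",
                           mustWork = TRUE))
}
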