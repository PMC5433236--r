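# Shared alphabets, background frequencies and genetic-code helpers.

# 20-letter amino-acid alphabet used throughout; integer codes 0..19 feed
# the compiled kernels. 20 = X/unknown, 21 = * (stop).
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_X <- 20L
AA_STOP <- 21L

# Robinson & Robinson background amino-acid frequencies (the BLOSUM62
# background), reordered to AA20.
.bg_named <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216
)
aa_background <- unname(.bg_named[AA20])

aa_to_int <- function(x) {
  # character vector of single residues -> codes 0..19, 20 = X/other, 21 = *
  m <- match(x, AA20) - 1L
  m[is.na(m)] <- AA_X
  m[x == "*"] <- AA_STOP
  m
}

aa_seq_to_int <- function(seq) aa_to_int(strsplit(toupper(seq), "")[[1]])

NT4 <- c("A", "C", "G", "T")

nt_seq_to_int <- function(seq) {
  m <- match(strsplit(toupper(seq), "")[[1]], NT4) - 1L
  m[is.na(m)] <- 4L
  m
}

#' @noRd
genetic_code_table <- function(code = "11") {
  Biostrings::getGeneticCode(code)
}

# codon index (16*n1 + 4*n2 + n3, A=0 C=1 G=2 T=3) -> aa integer code
code64_table <- function(code = "11") {
  gc <- genetic_code_table(code)
  idx <- expand.grid(n3 = NT4, n2 = NT4, n1 = NT4, stringsAsFactors = FALSE)
  codons <- paste0(idx$n1, idx$n2, idx$n3)
  # expand.grid varies n3 fastest; reorder to index order n1 major
  ord <- order(match(idx$n1, NT4), match(idx$n2, NT4), match(idx$n3, NT4))
  aa_to_int(unname(gc[codons[ord]]))
}

#' Translate nucleotide sequences
#'
#' Thin wrapper over [Biostrings::translate()] using the bacterial genetic
#' code (table 11) by default; fuzzy codons (containing N) become `X`.
#'
#' @param nt character vector of nucleotide sequences.
#' @param code genetic code id passed to [Biostrings::getGeneticCode()].
#' @return character vector of protein sequences (`*` marks stops).
#' @export
translate_nt <- function(nt, code = "11") {
  if (length(nt) == 0) return(character(0))
  n <- nchar(nt)
  if (any(n %% 3L != 0L))
    stop("nucleotide length not a multiple of 3 for sequence(s): ",
         paste(which(n %% 3L != 0L), collapse = ", "))
  out <- character(length(nt))
  ok <- n > 0
  if (any(ok)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(nt[ok]),
                                genetic.code = genetic_code_table(code),
                                if.fuzzy.codon = "solve", no.init.codon = TRUE)
    out[ok] <- as.character(aa)
  }
  out
}

# fast codon-table translation used in inner loops (no Biostrings call);
# any codon containing a non-ACGT base becomes X
fast_translate_codons <- local({
  cache <- NULL
  function(nt, code = "11") {
    if (is.null(cache)) cache <<- c(AA20, "X", "*")[code64_table(code) + 1L]
    ints <- nt_seq_to_int(nt)
    n <- length(ints) %/% 3L
    if (n == 0) return(character(0))
    i1 <- ints[seq(1, by = 3, length.out = n)]
    i2 <- ints[seq(2, by = 3, length.out = n)]
    i3 <- ints[seq(3, by = 3, length.out = n)]
    aa <- rep("X", n)
    ok <- i1 < 4L & i2 < 4L & i3 < 4L
    aa[ok] <- cache[16L * i1[ok] + 4L * i2[ok] + i3[ok] + 1L]
    aa
  }
})

fast_translate <- function(nt, code = "11") {
  paste(fast_translate_codons(nt, code), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# BLOSUM62 extended to X (code 20) and * (code 21); 22x22 numeric matrix in
# AA20 order. Pulled from Biostrings' shipped matrix.
blosum62_ext <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    B <- e$BLOSUM62
    letters22 <- c(AA20, "X", "*")
    M <- B[letters22, letters22]
    dimnames(M) <- NULL
    cache <<- M
    M
  }
})

# first codon in the genetic code encoding each amino acid (used to repair
# 2-nt frameshift codons to a codon for the aligned reference residue)
canonical_codons <- local({
  cache <- NULL
  function(code = "11") {
    if (!is.null(cache)) return(cache)
    gc <- genetic_code_table(code)
    out <- vapply(AA20, function(a) names(gc)[gc == a][1], character(1))
    cache <<- out
    out
  }
})
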