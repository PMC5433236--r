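# Readers/writers for on-disk artifacts: genomes (FASTA + feature table),
# candidate tables, BLAST tabular hits, reads, reference databases and
# serialized profile models. Coordinates are 1-based inclusive on disk (GFF
# convention); locus indices are 0-based positions in coordinate order.

#' Read an annotated genome
#'
#' Loads contigs from a FASTA file and coding features from either the
#' package's TSV dialect (columns `genome_id`, `contig_id`, `start`, `end`,
#' `strand`, `locus_tag`, `protein`) or GFF3. Features are assigned a
#' 0-based `locus_index` per contig by sorted start coordinate, and the
#' nucleotide gene sequence is extracted from the contig (reverse
#' complemented for `-` strand features).
#'
#' @param fasta_path path to the contig FASTA.
#' @param features_path path to the feature table (TSV dialect or GFF3).
#' @param genome_id identifier; defaults to the value in the feature table
#'   or the FASTA basename.
#' @param format `"auto"` (by extension), `"tsv"` or `"gff3"`.
#' @param code genetic code used when translations must be derived.
#' @return a `genome_record`: list with `genome_id`, `contigs`
#'   ([Biostrings::DNAStringSet]) and `features` (tibble).
#' @export
read_genome <- function(fasta_path, features_path, genome_id = NULL,
                        format = c("auto", "tsv", "gff3"), code = "11") {
  format <- match.arg(format)
  contigs <- Biostrings::readDNAStringSet(fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", features_path, ignore.case = TRUE)) "gff3" else "tsv"
  feats <- if (format == "gff3") read_features_gff3(features_path)
           else read_features_tsv(features_path)
  if (is.null(genome_id)) {
    genome_id <- if (nrow(feats) > 0 && !all(is.na(feats$genome_id)))
      feats$genome_id[1]
    else sub("\\.(fa|fna|fasta)(\\.gz)?$", "", basename(fasta_path))
  }
  genome_record(genome_id, contigs, feats, code = code)
}

#' Construct a genome record from in-memory pieces
#'
#' @param genome_id identifier.
#' @param contigs named character vector or [Biostrings::DNAStringSet].
#' @param features tibble with at least `contig_id`, `start`, `end`,
#'   `strand`; `locus_tag` and `protein` filled in if absent.
#' @param code genetic code for derived translations.
#' @export
genome_record <- function(genome_id, contigs, features, code = "11") {
  if (!methods::is(contigs, "DNAStringSet"))
    contigs <- Biostrings::DNAStringSet(contigs)
  features <- tibble::as_tibble(features)
  if (nrow(features) > 0) {
    bad <- !features$contig_id %in% names(contigs)
    if (any(bad)) {
      f <- features[which(bad)[1], ]
      stop("feature ", f$locus_tag %||% which(bad)[1],
           " references contig '", f$contig_id,
           "' absent from the assembly FASTA")
    }
    if (any(features$start > features$end))
      stop("feature with start > end at row ", which(features$start > features$end)[1])
    features$genome_id <- genome_id
    if (is.null(features$locus_tag))
      features$locus_tag <- sprintf("%s_%05d", genome_id, seq_len(nrow(features)))
    features <- features |>
      dplyr::group_by(.data$contig_id) |>
      dplyr::arrange(.data$start, .by_group = TRUE) |>
      dplyr::mutate(locus_index = seq_len(dplyr::n()) - 1L) |>
      dplyr::ungroup()
    nt <- substr(rep(as.character(contigs[features$contig_id]), 1L),
                 features$start, features$end)
    nt <- ifelse(features$strand == "-", revcomp(nt), nt)
    features$gene_nt <- nt
    if (is.null(features$protein) || anyNA(features$protein)) {
      need <- if (is.null(features$protein)) rep(TRUE, nrow(features)) else is.na(features$protein)
      prot <- features$protein %||% rep(NA_character_, nrow(features))
      len_ok <- nchar(nt[need]) %% 3 == 0
      prot[need][len_ok] <- sub("\\*$", "", translate_nt(nt[need][len_ok], code))
      features$protein <- prot
    }
  } else {
    features <- tibble::tibble(genome_id = character(), contig_id = character(),
                               start = integer(), end = integer(),
                               strand = character(), locus_tag = character(),
                               locus_index = integer(), protein = character(),
                               gene_nt = character())
  }
  structure(list(genome_id = genome_id, contigs = contigs, features = features),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$genome_id, ": ", length(x$contigs), " contig(s), ",
      nrow(x$features), " feature(s)\n", sep = "")
  invisible(x)
}

read_features_tsv <- function(path) {
  cols <- c("genome_id", "contig_id", "start", "end", "strand", "locus_tag", "protein")
  if (file.size(path) == 0)
    return(tibble::as_tibble(stats::setNames(
      list(character(), character(), integer(), integer(), character(),
           character(), character()), cols)))
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(setdiff(cols, "protein"), names(d))
  if (length(missing) > 0)
    stop("feature TSV lacks column(s): ", paste(missing, collapse = ", "))
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  if (is.null(d$protein)) d$protein <- NA_character_
  tibble::as_tibble(d[, cols])
}

read_features_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  g <- rtracklayer::import(path, format = "gff3")
  g <- g[g$type == "CDS"]
  lt <- g$locus_tag %||% g$ID %||% sprintf("cds_%05d", seq_along(g))
  prot <- if (!is.null(g$translation)) as.character(g$translation) else NA_character_
  tibble::tibble(
    genome_id = NA_character_,
    contig_id = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g), end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    locus_tag = as.character(lt),
    protein = prot
  )
}

#' Write/read feature tables in the package TSV dialect
#' @param features feature tibble (as in a `genome_record`).
#' @param path output path.
#' @export
write_features_tsv <- function(features, path) {
  cols <- c("genome_id", "contig_id", "start", "end", "strand", "locus_tag", "protein")
  write.table(as.data.frame(features)[, cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- candidate tables -----------------------------------------------------

.cand_num_cols <- c("score", "coverage", "phylo_dist_to_top")

#' Write a candidate table to TSV
#'
#' Floats are written at fixed precision (4 decimals) so the file
#' round-trips identically and is locale-independent.
#' @param table candidate tibble.
#' @param path output path.
#' @export
write_candidate_table <- function(table, path) {
  d <- as.data.frame(table)
  d <- d[, !vapply(d, is.list, logical(1)), drop = FALSE]
  for (cl in intersect(.cand_num_cols, names(d)))
    d[[cl]] <- sprintf("%.4f", d[[cl]])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate table written by [write_candidate_table()]
#' @param path TSV path.
#' @return tibble with numeric score columns restored.
#' @export
read_candidate_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  for (cl in intersect(.cand_num_cols, names(d))) {
    v <- suppressWarnings(as.numeric(d[[cl]]))
    bad <- which(is.na(v) & !(d[[cl]] %in% c("NA", "")))
    if (length(bad) > 0)
      stop("malformed numeric field '", cl, "' at line ", bad[1] + 1L,
           " of ", path)
    d[[cl]] <- v
  }
  for (cl in intersect(c("residues_ok", "partner_found", "same_contig"), names(d)))
    d[[cl]] <- as.logical(d[[cl]])
  for (cl in intersect(c("n_members", "locus_separation"), names(d)))
    d[[cl]] <- as.integer(d[[cl]])
  tibble::as_tibble(d)
}

#' Read search hits in BLAST tabular (outfmt 6) layout
#'
#' Columns: qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore. Identity is rescaled to a 0-1 fraction.
#' @param path tabular file (no header).
#' @return tibble of hits; zero rows for an empty file.
#' @export
read_hit_table <- function(path) {
  cols <- c("read_id", "ref_id", "identity", "aligned_length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  empty <- tibble::as_tibble(stats::setNames(list(
    character(), character(), numeric(), integer(), integer(), integer(),
    integer(), integer(), integer(), integer(), numeric(), numeric()), cols))
  if (!file.exists(path) || file.size(path) == 0) return(empty)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12))
    stop("malformed hit row (fewer than 12 fields) at line ", which(nf < 12)[1])
  m <- do.call(rbind, lapply(parts, `[`, 1:12))
  num <- function(k, what) {
    v <- suppressWarnings(as.numeric(m[, k]))
    if (anyNA(v)) stop("non-numeric ", what, " at line ", which(is.na(v))[1])
    v
  }
  tibble::tibble(
    read_id = m[, 1], ref_id = m[, 2],
    identity = num(3, "identity") / 100,
    aligned_length = as.integer(num(4, "alignment length")),
    mismatch = as.integer(num(5, "mismatch count")),
    gapopen = as.integer(num(6, "gap-open count")),
    qstart = as.integer(num(7, "qstart")), qend = as.integer(num(8, "qend")),
    sstart = as.integer(num(9, "sstart")), send = as.integer(num(10, "send")),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore")
  )
}

# ---- reads ----------------------------------------------------------------

#' Read sequencing reads from FASTA or FASTQ
#' @param path file path; format detected from the first record.
#' @return tibble with `read_id`, `seq` and `qual` (integer list column of
#'   Phred scores; `NULL` entries for FASTA input).
#' @export
read_reads <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0)
    return(tibble::tibble(read_id = character(), seq = character(),
                          qual = list()))
  if (startsWith(first, "@")) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    q <- as(Biostrings::PhredQuality(S4Vectors::mcols(x)$qualities), "IntegerList")
    tibble::tibble(read_id = sub("\\s.*$", "", names(x)),
                   seq = unname(as.character(x)), qual = as.list(q))
  } else {
    x <- Biostrings::readDNAStringSet(path)
    tibble::tibble(read_id = sub("\\s.*$", "", names(x)),
                   seq = unname(as.character(x)),
                   qual = vector("list", length(x)))
  }
}

#' Write reads to FASTA or FASTQ
#' @param reads tibble with `read_id`, `seq` and optionally `qual`.
#' @param path output path; FASTQ written when qualities are present and
#'   the path ends in `.fastq`/`.fq`.
#' @export
write_reads <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  fastq <- grepl("\\.(fastq|fq)$", path) && "qual" %in% names(reads) &&
    length(reads$qual) > 0 && !is.null(reads$qual[[1]])
  if (fastq) {
    quals <- Biostrings::PhredQuality(
      vapply(reads$qual, function(q) as.character(Biostrings::PhredQuality(q)),
             character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  } else {
    Biostrings::writeXStringSet(x, path)
  }
  invisible(path)
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param type `"dna"` or `"aa"`.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::DNAStringSet(seqs)
       else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @param type `"dna"` or `"aa"`.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

# ---- gene database --------------------------------------------------------

#' Write a gene database directory
#'
#' Emits `targets.faa`/`targets.fna`, `outgroup.faa`/`outgroup.fna`,
#' `candidates.tsv` and `db.json` (cutoff, parameters, cluster labels,
#' copy numbers) under `dir`.
#' @param db a `gene_database` from [assemble_database()].
#' @param dir output directory (created).
#' @export
write_gene_database <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(stats::setNames(db$targets$protein, db$targets$protein_id),
              file.path(dir, "targets.faa"), "aa")
  write_fasta(stats::setNames(db$targets$gene_nt, db$targets$protein_id),
              file.path(dir, "targets.fna"), "dna")
  write_fasta(stats::setNames(db$outgroup$protein, db$outgroup$protein_id),
              file.path(dir, "outgroup.faa"), "aa")
  write_fasta(stats::setNames(db$outgroup$gene_nt, db$outgroup$protein_id),
              file.path(dir, "outgroup.fna"), "dna")
  if (!is.null(db$candidates))
    write_candidate_table(db$candidates, file.path(dir, "candidates.tsv"))
  meta <- list(
    gene_name = db$gene_name, cutoff_used = db$cutoff_used,
    params = db$params,
    cluster90 = as.list(stats::setNames(db$targets$cluster90 %||%
                                          rep(NA, nrow(db$targets)),
                                        db$targets$protein_id)),
    taxonomy = as.list(stats::setNames(db$targets$taxonomy %||%
                                         rep(NA, nrow(db$targets)),
                                       db$targets$protein_id)),
    copy_number = if (!is.null(db$copy_number))
      as.list(stats::setNames(db$copy_number$n_copies, db$copy_number$genome_id))
  )
  jsonlite::write_json(meta, file.path(dir, "db.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(dir)
}

#' Read a gene database directory written by [write_gene_database()]
#' @param dir database directory.
#' @return a `gene_database` object.
#' @export
read_gene_database <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "db.json"))
  tfaa <- read_fasta(file.path(dir, "targets.faa"), "aa")
  tfna <- read_fasta(file.path(dir, "targets.fna"), "dna")
  ofaa <- read_fasta(file.path(dir, "outgroup.faa"), "aa")
  ofna <- read_fasta(file.path(dir, "outgroup.fna"), "dna")
  unwrap <- function(x, ids) {
    if (is.null(x)) return(rep(NA_character_, length(ids)))
    v <- unlist(lapply(ids, function(i) {
      val <- x[[i]]
      if (is.null(val)) NA_character_ else as.character(val)
    }))
    v
  }
  targets <- tibble::tibble(
    protein_id = names(tfaa), protein = unname(tfaa),
    gene_nt = unname(tfna[names(tfaa)]),
    cluster90 = unwrap(meta$cluster90, names(tfaa)),
    taxonomy = unwrap(meta$taxonomy, names(tfaa))
  )
  outgroup <- tibble::tibble(protein_id = names(ofaa), protein = unname(ofaa),
                             gene_nt = unname(ofna[names(ofaa)]))
  cand_path <- file.path(dir, "candidates.tsv")
  structure(list(
    gene_name = meta$gene_name, targets = targets, outgroup = outgroup,
    cutoff_used = meta$cutoff_used,
    params = meta$params,
    copy_number = if (!is.null(meta$copy_number))
      tibble::tibble(genome_id = names(meta$copy_number),
                     n_copies = as.integer(unlist(meta$copy_number))),
    candidates = if (file.exists(cand_path)) read_candidate_table(cand_path)
  ), class = "gene_database")
}
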