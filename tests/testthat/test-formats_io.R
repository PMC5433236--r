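test_that("read_genome assigns locus indices by sorted start and extracts genes", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "g.fna")
  tsv <- file.path(td, "g.tsv")
  contig <- paste(rep("ACGT", 400), collapse = "")
  writeLines(c(">ctg1", contig), fa)
  feats <- tibble::tibble(
    genome_id = "g", contig_id = "ctg1",
    start = c(900L, 10L, 500L), end = c(929L, 39L, 529L),
    strand = c("+", "+", "-"),
    locus_tag = c("c", "a", "b"), protein = NA_character_)
  write_features_tsv(feats, tsv)
  g <- read_genome(fa, tsv)
  f <- g$features
  expect_equal(f$locus_tag[order(f$locus_index)], c("a", "c", "b")[c(1, 3, 2)])
  expect_equal(f$locus_index[match(c("a", "b", "c"), f$locus_tag)], c(0L, 1L, 2L))
  # minus-strand gene is reverse complemented
  minus <- f[f$locus_tag == "b", ]
  expect_equal(minus$gene_nt,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(contig, 500, 529)))))
})

test_that("a feature on a missing contig is a hard error naming the feature", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "g.fna"); tsv <- file.path(td, "g.tsv")
  writeLines(c(">ctg1", "ACGTACGTACGT"), fa)
  write_features_tsv(tibble::tibble(
    genome_id = "g", contig_id = "ctgX", start = 1L, end = 6L,
    strand = "+", locus_tag = "bad1", protein = NA_character_), tsv)
  expect_error(read_genome(fa, tsv), "bad1")
  expect_error(read_genome(fa, tsv), "ctgX")
})

test_that("an empty features file yields a valid zero-feature genome", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "g.fna"); tsv <- file.path(td, "g.tsv")
  writeLines(c(">ctg1", "ACGT"), fa)
  file.create(tsv)
  g <- read_genome(fa, tsv)
  expect_s3_class(g$features, "tbl_df")
  expect_equal(nrow(g$features), 0)
})

test_that("candidate tables round-trip through TSV", {
  td <- withr::local_tempdir()
  tbl <- tibble::tibble(
    protein_id = c("U0001", "U0002"), protein = c("MKL", "MNP"),
    score = c(123.4567, 89.1), coverage = c(1, 0.85),
    phylo_dist_to_top = c(0, 0.42), residues_ok = c(TRUE, FALSE),
    partner_found = c(TRUE, FALSE), n_members = c(3L, 1L),
    status = c("target", "below_cutoff"))
  p <- file.path(td, "cand.tsv")
  write_candidate_table(tbl, p)
  back <- read_candidate_table(p)
  expect_equal(back$score, round(tbl$score, 4))
  expect_equal(back$residues_ok, tbl$residues_ok)
  expect_equal(back$status, tbl$status)
  expect_equal(back$n_members, tbl$n_members)
})

test_that("hit tables parse outfmt-6 rows and reject malformed lines", {
  td <- withr::local_tempdir()
  p <- file.path(td, "hits.tsv")
  writeLines(c("r1\tref1\t98.5\t100\t1\t0\t1\t100\t5\t104\t1e-40\t180.2",
               "r2\tref2\t71.0\t70\t20\t1\t1\t70\t1\t70\t1e-5\t60.1"), p)
  h <- read_hit_table(p)
  expect_equal(nrow(h), 2)
  expect_equal(h$identity, c(0.985, 0.71))
  expect_equal(h$aligned_length, c(100L, 70L))

  file.create(file.path(td, "empty.tsv"))
  expect_equal(nrow(read_hit_table(file.path(td, "empty.tsv"))), 0)

  writeLines(c("r1\tref1\t98.5\t100\t1\t0\t1\t100\t5\t104\t1e-40\t180.2",
               "r2\tref2\tnot_a_number\t70\t20\t1\t1\t70\t1\t70\t1e-5\t60.1"),
             p)
  expect_error(read_hit_table(p), "line 2")
})

test_that("reads round-trip through FASTQ with qualities", {
  td <- withr::local_tempdir()
  reads <- tibble::tibble(read_id = c("r1", "r2"),
                          seq = c("ACGTACGT", "TTTTGGGG"),
                          qual = list(rep(37L, 8), c(2L, rep(40L, 7))))
  p <- file.path(td, "reads.fastq")
  write_reads(reads, p)
  back <- read_reads(p)
  expect_equal(back$read_id, reads$read_id)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$qual, reads$qual)
})

test_that("gene databases round-trip through a database directory", {
  td <- withr::local_tempdir()
  db <- make_mini_db(
    c(A = "MKLV", B = "MNPQ"),
    c(A = "ATGAAACTGGTT", B = "ATGAATCCGCAG"),
    c(X = "MWWW"), c(X = "ATGTGGTGGTGG"))
  db$cutoff_used <- 123.5
  db$targets$cluster90 <- c("C001", "C002")
  write_gene_database(db, file.path(td, "db"))
  back <- read_gene_database(file.path(td, "db"))
  expect_equal(back$targets$protein, db$targets$protein)
  expect_equal(back$targets$gene_nt, db$targets$gene_nt)
  expect_equal(back$outgroup$protein_id, db$outgroup$protein_id)
  expect_equal(back$cutoff_used, 123.5)
  expect_equal(back$targets$cluster90, c("C001", "C002"))
})

test_that("profile models round-trip through JSON", {
  fam <- sim_gene_family(length = 40, seed = 3)
  m <- build_profile(fam$seeds)
  td <- withr::local_tempdir()
  p <- file.path(td, "model.json")
  write_profile(m, p)
  back <- read_profile(p)
  expect_equal(back$consensus_length, m$consensus_length)
  expect_equal(back$emissions, m$emissions, tolerance = 1e-12)
  expect_equal(score_sequence(back, fam$ancestor),
               score_sequence(m, fam$ancestor))
})
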