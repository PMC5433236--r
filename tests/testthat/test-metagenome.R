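test_that("read QC keeps reads with enough high-quality bases", {
  reads <- tibble::tibble(
    read_id = c("allq40", "frac40", "frac60", "fasta"),
    seq = rep(strrep("ACGT", 25), 4),
    qual = list(rep(40L, 100),
                c(rep(35L, 40), rep(10L, 60)),   # 40% >= Q30
                c(rep(35L, 60), rep(10L, 40)),   # 60% >= Q30
                NULL))
  out <- qc_reads(reads, min_q = 30, min_frac = 0.5)
  expect_setequal(out$read_id, c("allq40", "frac60", "fasta"))
})

test_that("pathway abundance follows the median-over-rplB arithmetic", {
  h <- function(n) tibble::tibble(read_id = sprintf("r%d", seq_len(n)),
                                  ref_id = "x", is_target = TRUE)
  lens <- c(gene1 = 1000, gene2 = 500, rplB = 1000)
  ab <- pathway_abundance(h(100), h(50), h(200), lens)
  # a = (0.1, 0.1), rplB = 0.2 -> 50%
  expect_equal(ab$percent_of_community, 50)
  expect_true(ab$detected)
  # doubling all counts leaves the percentage unchanged
  ab2 <- pathway_abundance(h(200), h(100), h(400), lens)
  expect_equal(ab2$percent_of_community, 50)
  # the both-genes rule: one absent gene -> not detected, reported as 0
  ab0 <- pathway_abundance(h(100), h(0), h(200), lens)
  expect_false(ab0$detected)
  expect_equal(ab0$percent_of_community, 0)
})

test_that("top-hit selection and the 70 bp / 70% filters behave on edge cases", {
  hits <- tibble::tibble(
    read_id = c("a", "a", "b", "c", "d"),
    ref_id = c("t1", "t2", "t1", "t1", "og1"),
    identity = c(0.99, 0.95, 0.95, 0.69, 0.99),
    aligned_length = c(100L, 100L, 69L, 100L, 100L),
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
    sstart = 1L, send = 100L,
    evalue = c(1e-50, 1e-40, 1e-30, 1e-30, 1e-30),
    bitscore = c(200, 180, 120, 120, 150))
  refset <- tibble::tibble(ref_id = c("t1", "t2", "og1"),
                           nt = strrep("A", 3),
                           is_target = c(TRUE, TRUE, FALSE))
  top <- search_reads(NULL, refset, hits = hits)
  # read a: best e-value wins; read b: too short; read c: identity below 70%
  expect_setequal(top$read_id, c("a", "d"))
  expect_equal(top$ref_id[top$read_id == "a"], "t1")
  # the outgroup hit is retained in the table but flagged non-target
  expect_false(top$is_target[top$read_id == "d"])
  expect_error(search_reads(NULL, refset[0, ], hits = hits), "empty")
})

test_that("ties on e-value break by bitscore then reference id", {
  hits <- tibble::tibble(
    read_id = "a", ref_id = c("zz", "bb", "aa"),
    identity = 0.99, aligned_length = 100L, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
    evalue = c(1e-30, 1e-30, 1e-30), bitscore = c(200, 150, 150))
  refset <- tibble::tibble(ref_id = c("aa", "bb", "zz"), nt = "AAA",
                           is_target = TRUE)
  expect_equal(search_reads(NULL, refset, hits = hits)$ref_id, "zz")
  hits$bitscore <- 150
  expect_equal(search_reads(NULL, refset, hits = hits)$ref_id, "aa")
})

test_that("an exact 100-bp read is found by the search engine", {
  withr::with_seed(19, ref <- quatscreen:::random_dna(600))
  refset <- tibble::tibble(ref_id = "t1", nt = ref, is_target = TRUE)
  reads <- tibble::tibble(read_id = c("exact", "short"),
                          seq = c(substr(ref, 101, 200), substr(ref, 301, 360)))
  top <- search_reads(reads, refset)
  expect_equal(top$read_id, "exact")   # the 60-bp read fails the length filter
  expect_equal(top$identity, 1.0)
  expect_equal(top$aligned_length, 100L)
})

test_that("taxon profiles are median-across-genes and sum to the pathway total", {
  h1 <- tibble::tibble(read_id = sprintf("r%d", 1:10),
                       ref_id = c(rep("A1", 7), rep("B1", 3)))
  h2 <- tibble::tibble(read_id = sprintf("q%d", 1:10),
                       ref_id = c(rep("A2", 6), rep("B2", 4)))
  taxa <- taxon_profile(h1, h2,
                        ref_taxa = c(A1 = "taxA", A2 = "taxA",
                                     B1 = "taxB", B2 = "taxB"),
                        ref_lengths = c(gene1 = 100, gene2 = 100))
  expect_equal(taxa$taxon, c("taxA", "taxB"))
  expect_equal(taxa$abundance, c(stats::median(c(7, 6)) / 100,
                                 stats::median(c(3, 4)) / 100))
  expect_equal(sum(taxa$rel_abundance), 1)
  # a single source cluster gives a single 100% taxon
  one <- taxon_profile(h1[1:7, ], h2[1:6, ],
                       ref_taxa = c(A1 = "taxA", A2 = "taxA"),
                       ref_lengths = c(gene1 = 100, gene2 = 100))
  expect_equal(one$rel_abundance, 1)
})

test_that("the rplB builder emits one reference per genome and flags absences", {
  sim <- sim_genomes(n_genomes = 4, n_targets = 1, n_traps = 0, n_decoys = 2,
                     genes_per_genome = 8, separations = c(2), seed = 71)
  rmodel <- build_refined_profile(sim$rplB_family$seeds)
  rb <- rplB_reference_builder(sim$genomes, rmodel, cutoff = 50)
  expect_equal(nrow(rb$refs), 4)
  expect_equal(rb$median_length, stats::median(nchar(rb$refs$nt)))
  # a genome without rplB is listed with a warning
  g0 <- sim$genomes[[1]]
  g0$features <- g0$features[g0$features$label != "rplB", ]
  g0$genome_id <- "G_norplB"
  expect_warning(rb2 <- rplB_reference_builder(list(g0), rmodel, cutoff = 50),
                 "G_norplB")
  expect_equal(nrow(rb2$refs), 0)
})
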