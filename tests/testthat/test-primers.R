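test_that("degeneracy multiplies IUPAC set sizes with inosine as one", {
  expect_equal(degeneracy("ACGT"), 1)
  expect_equal(degeneracy("NN"), 16)
  expect_equal(degeneracy("RYI"), 4)
  expect_equal(degeneracy(primer("p", "TTYGCIGGITAYCARCCNTT", "forward")), 32)
  expect_error(degeneracy("ACQT"), "invalid IUPAC")
  expect_error(degeneracy(""), "empty")
  # always >= 1
  withr::with_seed(2, {
    for (i in 1:20) {
      s <- paste(sample(names(quatscreen:::IUPAC_SETS), 12, TRUE), collapse = "")
      expect_gte(degeneracy(s), 1)
    }
  })
})

test_that("site finding honours IUPAC sets, inosine and the mismatch budget", {
  fwd <- primer("f", "ACGRACGT", "forward")
  tmpl <- paste0("TTTTT", "ACGAACGT", "TTTTT")
  expect_equal(find_sites(tmpl, fwd, 0)$start, 6L)
  expect_equal(find_sites(tmpl, fwd, 0)$mismatches, 0L)    # R matches A
  tmpl_g <- paste0("TTTTT", "ACGGACGT", "TTTTT")
  expect_equal(find_sites(tmpl_g, fwd, 0)$mismatches, 0L)  # R matches G

  # two mismatches are not found at budget 1
  tmpl2 <- paste0("TTTTT", "TCGAACGA", "TTTTT")
  expect_equal(nrow(find_sites(tmpl2, fwd, 1)), 0)
  expect_equal(nrow(find_sites(tmpl2, fwd, 2)), 1)

  # inosine matches anything
  ino <- primer("i", "AIIT", "forward")
  expect_equal(nrow(find_sites("CCACGTCC", ino, 0)), 1)

  # a reverse primer is searched as its reverse complement
  rev <- primer("r", "ACGT", "reverse")  # palindromic revcomp = ACGT
  expect_equal(find_sites("GGACGTGG", rev, 0)$start, 3L)
  rev2 <- primer("r2", "AAGG", "reverse")   # revcomp = CCTT
  expect_equal(find_sites("TTCCTTTT", rev2, 0)$start, 3L)
})

test_that("in-silico PCR emits the inter-primer slice with correct length", {
  fwd <- primer("f", "ACGTACGTAC", "forward")
  rev <- primer("r", "TTGCAGGCAT", "reverse")
  spacer <- strrep("AG", 200)  # 400 nt
  tmpl <- paste0("CCC", "ACGTACGTAC", spacer,
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString("TTGCAGGCAT"))), "CCC")
  prod <- in_silico_pcr(tmpl, fwd, rev, max_mismatch = 0)
  expect_equal(nrow(prod), 1)
  expect_equal(prod$length, 400L)
  expect_equal(prod$product, spacer)
  # product equals the template slice at its coordinates
  expect_equal(substr(tmpl, prod$start, prod$end), prod$product)

  # missing reverse site: no product
  tmpl2 <- paste0("CCC", "ACGTACGTAC", spacer, "CCC")
  expect_equal(nrow(in_silico_pcr(tmpl2, fwd, rev, 0)), 0)

  # a product on the minus strand is found and reported 5'->3'
  tmpl3 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tmpl)))
  prod3 <- in_silico_pcr(tmpl3, fwd, rev, max_mismatch = 0)
  expect_equal(prod3$length, 400L)
  expect_equal(prod3$strand, "-")
  expect_equal(prod3$product, spacer)

  # over-long products are suppressed
  expect_equal(nrow(in_silico_pcr(tmpl, fwd, rev, 0, max_len = 100)), 0)
})

test_that("database coverage counts references with at least one product", {
  fwd <- primer("f", "ACGTACGTAC", "forward")
  rev <- primer("r", "TTGCAGGCAT", "reverse")
  site_r <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TTGCAGGCAT")))
  withr::with_seed(7, {
    good <- replicate(6, paste0("ACGTACGTAC", quatscreen:::random_dna(150),
                                site_r))
    # two mismatches planted in the forward site
    bad <- replicate(6, paste0("ACTTACGAAC", quatscreen:::random_dna(150),
                               site_r))
  })
  expect_equal(primer_coverage(good, fwd, rev, max_mismatch = 1), 1.0)
  # brute-force count: none of the damaged refs can amplify at 1 mismatch
  expect_equal(primer_coverage(c(good, bad), fwd, rev, max_mismatch = 1), 0.5)
  # coverage is monotone in the mismatch budget
  expect_gte(primer_coverage(c(good, bad), fwd, rev, max_mismatch = 2),
             primer_coverage(c(good, bad), fwd, rev, max_mismatch = 1))
  expect_error(primer_coverage(character(0), fwd, rev), "empty")
})

test_that("primer trimming keeps the insert and tallies failures; idempotent", {
  fwd <- primer("f", "ACGTACGTAC", "forward")
  rev <- primer("r", "TTGCAGGCAT", "reverse")
  site_r <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TTGCAGGCAT")))
  withr::with_seed(8, insert <- quatscreen:::random_dna(120))
  reads <- tibble::tibble(
    read_id = c("ok", "noprimer"),
    seq = c(paste0("ACGTACGTAC", insert, site_r), quatscreen:::random_dna(140)))
  tr <- trim_primers(reads, fwd, rev, max_mismatch = 1)
  expect_equal(tr$reads$seq[tr$reads$read_id == "ok"], insert)
  expect_equal(unname(tr$tally["trimmed"]), 1L)
  expect_equal(unname(tr$tally["no_forward"]), 1L)
  # idempotence: trimming the trimmed set discards everything (sites gone)
  tr2 <- trim_primers(tr$reads, fwd, rev, max_mismatch = 1)
  expect_equal(unname(tr2$tally["trimmed"]), 0L)
})

test_that("the shipped assay primer set loads and validates", {
  ps <- tma_primers()
  expect_named(ps, c("cutC_F", "cutC_R", "cntA_F", "cntA_R", "16S_F", "16S_R"),
               ignore.order = TRUE)
  expect_s3_class(ps$cutC_F, "primer")
  expect_equal(ps$cutC_R$orientation, "reverse")
})
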