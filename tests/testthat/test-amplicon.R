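fam_amp <- sim_gene_family(length = 90, seed = 21)
model_amp <- build_refined_profile(fam_amp$seeds)
refs_amp <- make_amplicon_refs(fam_amp)

test_that("paired reads merge at the best overlap with quality-aware calls", {
  withr::with_seed(31, {
    insert <- quatscreen:::random_dna(130)
  })
  # R1 = first 80, R2 = revcomp of last 80 -> 30 nt overlap
  r1 <- tibble::tibble(read_id = "p1", seq = substr(insert, 1, 80),
                       qual = list(rep(38L, 80)))
  r2 <- tibble::tibble(read_id = "p1",
                       seq = as.character(Biostrings::reverseComplement(
                         Biostrings::DNAString(substr(insert, 51, 130)))),
                       qual = list(rep(38L, 80)))
  m <- merge_and_filter(r1, r2)
  expect_equal(m$reads$seq, insert)
  expect_equal(nchar(m$reads$seq), 80 + 80 - 30)

  # disagreement in the overlap resolved toward the higher-quality base
  r1b <- r1
  s <- strsplit(r1b$seq, "")[[1]]; s[60] <- setdiff(c("A","C","G","T"), s[60])[1]
  r1b$seq <- paste(s, collapse = "")
  r1b$qual <- list(c(rep(38L, 59), 2L, rep(38L, 20)))
  m2 <- merge_and_filter(r1b, r2)
  expect_equal(m2$reads$seq, insert)

  # no sufficient overlap: discarded and tallied
  r2far <- tibble::tibble(read_id = "p1",
                          seq = quatscreen:::random_dna(60),
                          qual = list(rep(38L, 60)))
  m3 <- merge_and_filter(r1, r2far)
  expect_equal(nrow(m3$reads), 0)
  expect_equal(unname(m3$tally["no_overlap"]), 1L)

  # low mean quality merged read is dropped
  r1q <- r1; r1q$qual <- list(rep(10L, 80))
  r2q <- r2; r2q$qual <- list(rep(10L, 80))
  m4 <- merge_and_filter(r1q, r2q, min_q = 25)
  expect_equal(unname(m4$tally["low_quality"]), 1L)

  # unpaired ids are a hard error naming the first offender
  expect_error(merge_and_filter(r1, dplyr::mutate(r2, read_id = "zz")), "p1|zz")
})

test_that("frameshift correction restores frame and flags stops", {
  refs <- tibble::tibble(ref_id = names(refs_amp$prots),
                         protein = unname(refs_amp$prots), is_target = TRUE)
  nt <- refs_amp$nts[["ref01"]]
  frag <- substr(nt, 1, 60)  # 20-codon fragment
  res <- frameshift_correct(tibble::tibble(read_id = "r", seq = frag), refs)
  expect_equal(res$protein_identity, 1.0)
  expect_equal(res$frameshift_count, 0L)
  expect_equal(res$closest_ref_id, "ref01")
  expect_equal(res$corrected_protein, substr(refs_amp$prots[["ref01"]], 1, 20))

  # deleting one base mid-codon: corrected protein equals the fragment
  broken <- paste0(substr(frag, 1, 30), substr(frag, 32, 60))
  res2 <- frameshift_correct(tibble::tibble(read_id = "r", seq = broken), refs)
  expect_equal(res2$corrected_protein, substr(refs_amp$prots[["ref01"]], 1, 20))
  expect_equal(res2$frameshift_count, 1L)

  # an extra base mid-codon: also one frameshift, frame restored
  ins <- paste0(substr(frag, 1, 31), "A", substr(frag, 32, 60))
  res3 <- frameshift_correct(tibble::tibble(read_id = "r", seq = ins), refs)
  expect_equal(res3$frameshift_count, 1L)
  expect_equal(res3$corrected_protein, substr(refs_amp$prots[["ref01"]], 1, 20))

  # reads shorter than one codon are rejected
  tiny <- frameshift_correct(tibble::tibble(read_id = "r", seq = "AC"), refs)
  expect_true(tiny$failed)
})

test_that("outgroup-derived reads are recognised as non-target", {
  withr::with_seed(55, {
    og_prot <- quatscreen:::mutate_protein(fam_amp$ancestor, 0.45)
    og_nt <- quatscreen:::backtranslate_protein(og_prot)
  })
  panel <- dplyr::bind_rows(
    tibble::tibble(ref_id = names(refs_amp$prots),
                   protein = unname(refs_amp$prots), is_target = TRUE),
    tibble::tibble(ref_id = "og1", protein = og_prot, is_target = FALSE))
  res <- frameshift_correct(tibble::tibble(read_id = "r", seq = og_nt), panel)
  # brute-force nearest reference: the outgroup protein itself
  expect_equal(res$closest_ref_id, "og1")
  expect_false(res$is_target)

  # discrimination tallies it as non-target
  disc <- discriminate_targets(res)
  expect_equal(nrow(disc$retained), 0)
  expect_equal(disc$tally$non_target, 1L)
})

test_that("a mid-frame stop codon leads to rejection", {
  refs <- tibble::tibble(ref_id = names(refs_amp$prots),
                         protein = unname(refs_amp$prots), is_target = TRUE)
  nt <- substr(refs_amp$nts[["ref02"]], 1, 60)
  stopnt <- paste0(substr(nt, 1, 30), "TAA", substr(nt, 34, 60))
  res <- frameshift_correct(tibble::tibble(read_id = "r", seq = stopnt), refs)
  expect_true(res$has_stop)
  disc <- discriminate_targets(res)
  expect_equal(disc$tally$stop_codon, 1L)
  expect_equal(disc$tally$pass_rate, 0)
})

test_that("complete-linkage clustering matches brute-force linkage on a triad", {
  # A and B at ~95% nt identity, C at ~50% to both, cutoff 0.90 -> {A,B},{C}
  mutate_nt <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), round(rate * length(ch)))
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  withr::with_seed(61, {
    base <- quatscreen:::random_dna(180)
    nts <- c(A = base, B = mutate_nt(base, 0.05), C = mutate_nt(base, 0.5))
  })
  codal <- nts
  cl <- quatscreen:::cluster_sequences(codal, 0.90)
  expect_equal(cl[["A"]], cl[["B"]])
  expect_true(cl[["C"]] != cl[["A"]])

  # identical sequences collapse to one cluster; cutoff 1.0 splits distinct
  same <- stats::setNames(rep(nts[1], 3), c("x", "y", "z"))
  expect_equal(length(unique(quatscreen:::cluster_sequences(same, 0.9))), 1)
  expect_equal(length(unique(quatscreen:::cluster_sequences(codal, 1.0))), 3)
})

test_that("cluster tables carry counts, representatives and reference labels", {
  al <- c(a1 = "ATGAAACTG", a2 = "ATGAAACTG", b1 = "TTTCCCGGG",
          REF = "ATGAAACTG")
  counts <- tibble::tibble(seq_id = c("a1", "a2", "b1"),
                           sample_id = c("s1", "s2", "s1"),
                           count = c(7L, 4L, 9L))
  ct <- cluster_complete_linkage(al, 0.9, counts, reference_ids = "REF")
  expect_equal(dim(ct$counts), c(2, 2))
  expect_equal(sum(ct$counts), 20)
  lab <- ct$clusters$contains_reference[!is.na(ct$clusters$contains_reference)]
  expect_equal(lab, "REF")
  # representative is the most abundant member, not the reference
  rep_cl <- ct$clusters[!is.na(ct$clusters$contains_reference), ]
  expect_equal(rep_cl$representative_id, "a1")
  # min-count filter drops sparse clusters
  ct5 <- filter_min_count(ct, min_count = 10)
  expect_equal(ncol(ct5$counts), 1)
})

test_that("rarefaction hits the exact depth, reproducibly, unbiasedly", {
  m <- matrix(c(40L, 30L, 20L, 10L,
                10L, 20L, 30L, 40L), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), sprintf("cl%d", 1:4)))
  r1 <- rarefy_even(m, depth = 50, seed = 7)
  expect_true(all(rowSums(r1) == 50))
  expect_identical(r1, rarefy_even(m, depth = 50, seed = 7))
  # depth equal to the sample total leaves counts unchanged
  expect_equal(rarefy_even(m, depth = 100, seed = 7), m, ignore_attr = TRUE)
  expect_error(rarefy_even(m, depth = 101, seed = 7), "depth exceeds")
  # hypergeometric expectation: mean count ~ depth * p over many draws
  tot <- matrix(0, 2, 4)
  for (s in 1:300) tot <- tot + rarefy_even(m, 50, seed = s)
  expect_equal(tot[1, 1] / 300, 20, tolerance = 0.05 * 20 * 3)  # +-3 SE-ish
  expect_equal(tot[2, 4] / 300, 20, tolerance = 0.05 * 20 * 3)
})

test_that("diversity profile bins prevalence and conserves sequence shares", {
  m1 <- matrix(c(5L, 0L, 9L,
                 6L, 0L, 8L,
                 7L, 5L, 0L,
                 8L, 6L, 0L), nrow = 4, byrow = TRUE,
               dimnames = list(sprintf("s%d", 1:4), sprintf("cl%d", 1:3)))
  ct <- structure(list(counts = m1, cutoff = 0.95), class = "cluster_table")
  dp <- diversity_profile(list("0.95" = ct))
  expect_equal(dp$summary$n_clusters, 3)
  expect_equal(sum(dp$prevalence$share_of_sequences), 1)
  expect_equal(sum(dp$prevalence$share_of_clusters), 1)
  # single sample: every observed cluster sits in the >90% prevalence bin
  m2 <- matrix(c(5L, 3L, 9L), nrow = 1,
               dimnames = list("s1", sprintf("cl%d", 1:3)))
  ct1 <- structure(list(counts = m2, cutoff = 0.95), class = "cluster_table")
  dp1 <- diversity_profile(list("0.95" = ct1))
  pv <- dp1$prevalence
  expect_equal(pv$share_of_clusters[pv$category == ">90%"], 1)
})

test_that("cluster count never increases when the cutoff loosens", {
  withr::with_seed(77, {
    for (rep in 1:5) {
      base <- quatscreen:::sample_protein(50)
      seqs <- vapply(1:12, function(i)
        quatscreen:::backtranslate_protein(
          quatscreen:::mutate_protein(base, stats::runif(1, 0, 0.3))),
        character(1))
      names(seqs) <- sprintf("s%02d", 1:12)
      n_prev <- Inf
      for (co in c(0.99, 0.95, 0.90, 0.80)) {
        n <- length(unique(quatscreen:::cluster_sequences(seqs, co)))
        expect_lte(n, n_prev)
        n_prev <- n
      }
    }
  })
})

test_that("best-match identity is exact on copies and tracks planted mutations", {
  db <- make_mini_db(refs_amp$prots, refs_amp$nts)
  copies <- tibble::tibble(read_id = sprintf("c%d", 1:4),
                           corrected_nt = unname(refs_amp$nts))
  bm <- best_match_identity(copies, db)
  expect_equal(bm$summary$mean_identity, 1.0)
  expect_equal(bm$summary$sd_identity, 0)
  expect_true(all(bm$per_read$identity >= 0 & bm$per_read$identity <= 1))

  # ~90% planted identity recovered within a point
  withr::with_seed(83, {
    mut <- vapply(refs_amp$nts, function(s) {
      ch <- strsplit(s, "")[[1]]
      pos <- sample(length(ch), round(0.1 * length(ch)))
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      paste(ch, collapse = "")
    }, character(1))
  })
  bm2 <- best_match_identity(
    tibble::tibble(read_id = names(mut), corrected_nt = unname(mut)), db)
  expect_equal(bm2$summary$mean_identity, 0.90, tolerance = 0.015)
})
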