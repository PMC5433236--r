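sim_small <- sim_genomes(n_genomes = 10, n_targets = 2, n_traps = 1,
                         n_decoys = 10, genes_per_genome = 15, seed = 41)
model_small <- build_refined_profile(sim_small$target_family$seeds)
partner_small <- build_refined_profile(sim_small$partner_family$seeds)

test_that("screen_genomes ranks planted genes above decoys, deterministically", {
  hits <- screen_genomes(sim_small$genomes, model_small, top_n = 13)
  planted <- sim_small$truth$protein[sim_small$truth$role %in% c("target", "trap")]
  decoys <- sim_small$truth$protein[sim_small$truth$role == "decoy"]
  ranks_planted <- match(planted, hits$protein)
  ranks_decoys <- match(decoys, hits$protein)
  expect_true(all(!is.na(ranks_planted)))
  expect_true(max(ranks_planted) < min(ranks_decoys, na.rm = TRUE))

  expect_equal(nrow(screen_genomes(sim_small$genomes, model_small, 0)), 0)
  # duplicated genome input changes nothing
  dup <- c(sim_small$genomes, sim_small$genomes[1])
  expect_equal(screen_genomes(dup, model_small, 13), hits)
})

test_that("dereplication groups exact duplicates and keeps all members", {
  h <- tibble::tibble(
    genome_id = c("g2", "g1", "g3", "g1"), contig_id = "c",
    locus_tag = c("t2", "t1", "t3", "t4"), locus_index = c(0L, 0L, 0L, 1L),
    strand = "+", protein = c("MKL", "MKL", "MKL", "MKV"),
    gene_nt = c("ATGAAACTG", "ATGAAATTA", "ATGAAACTT", "ATGAAAGTT"),
    score = c(10, 10, 10, 8))
  u <- dereplicate(h)
  expect_equal(nrow(u), 2)
  grp <- u[u$protein == "MKL", ]
  expect_equal(grp$n_members, 3L)
  expect_equal(sort(grp$member_genome_ids[[1]]), c("g1", "g2", "g3"))
  expect_equal(grp$genome_id, "g1")  # lexicographically smallest genome
  expect_lte(nrow(u), nrow(h))
})

test_that("signature checks read the residue at the model column", {
  fam <- sim_small$target_family
  col <- signature_model_column(model_small, fam)
  seqs <- c(good = fam$ancestor,
            bad = local({
              r <- strsplit(fam$ancestor, "")[[1]]
              r[fam$signature_col] <- "D"
              paste(r, collapse = "")
            }))
  al <- align_to_model(model_small, seqs)
  ok <- check_signatures(al, signature_rule(col, "E", "bridging E"))
  expect_true(ok$residues_ok[ok$sequence_id == "good"])
  expect_false(ok$residues_ok[ok$sequence_id == "bad"])

  # a deletion spanning the signature column fails the rule
  del <- paste0(substr(fam$ancestor, 1, fam$signature_col - 3),
                substr(fam$ancestor, fam$signature_col + 3, nchar(fam$ancestor)))
  al2 <- align_to_model(model_small, c(del = del))
  ok2 <- check_signatures(al2, signature_rule(col, "E"))
  expect_false(ok2$residues_ok)

  # allowed set excluding the residue fails
  okx <- check_signatures(al, signature_rule(col, "D"))
  expect_false(okx$residues_ok[okx$sequence_id == "good"])
})

test_that("neighbor-joining distances reproduce an additive matrix exactly", {
  # additive (tree-realizable) distances for 4 taxa: ((A:1,B:2):1.5,(C:3,D:1))
  Dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  path <- function(a, b) a + b
  Dm["A", "B"] <- Dm["B", "A"] <- 3
  Dm["A", "C"] <- Dm["C", "A"] <- 1 + 1.5 + 3
  Dm["A", "D"] <- Dm["D", "A"] <- 1 + 1.5 + 1
  Dm["B", "C"] <- Dm["C", "B"] <- 2 + 1.5 + 3
  Dm["B", "D"] <- Dm["D", "B"] <- 2 + 1.5 + 1
  Dm["C", "D"] <- Dm["D", "C"] <- 4
  tree <- ape::nj(stats::as.dist(Dm))
  cd <- ape::cophenetic.phylo(tree)
  expect_equal(cd[rownames(Dm), colnames(Dm)], Dm, tolerance = 1e-9)
})

test_that("phylo distance to top: zero for duplicates, symmetric pipeline", {
  u <- c(top = sim_small$target_family$ancestor,
         dup = sim_small$target_family$ancestor,
         far = sim_small$truth$protein[sim_small$truth$role == "decoy"][1])
  al <- align_to_model(model_small, u)
  d <- phylo_distance_to_top(al, top_id = "top")
  expect_equal(unname(d["top"]), 0)
  expect_equal(unname(d["dup"]), 0, tolerance = 1e-9)
  expect_gt(unname(d["far"]), 0.2)
  expect_true(all(d >= -1e-9))
})

test_that("synteny respects the 10-gene window and contig boundaries", {
  g <- sim_small$genomes[[which(sim_small$roles == "target")[1]]]
  hit <- g$features[g$features$label == "target", ]
  partner_cut <- partner_cutoff_from_top(sim_small$genomes, partner_small, 0.5)
  syn <- check_synteny(g, hit, partner_small, partner_cut, max_separation = 10)
  expect_true(syn$partner_found)
  expect_lte(syn$locus_separation, 10)

  trap_g <- sim_small$genomes[[which(sim_small$roles == "trap")[1]]]
  trap_hit <- trap_g$features[trap_g$features$label == "target", ]
  syn11 <- check_synteny(trap_g, trap_hit, partner_small, partner_cut, 10)
  expect_false(syn11$partner_found)
  expect_equal(syn11$locus_separation, 11L)
  expect_true(syn11$same_contig)
  # raising the window to the separation flips the call (monotonicity)
  expect_true(check_synteny(trap_g, trap_hit, partner_small, partner_cut,
                            11)$partner_found)

  # partner on a different contig is never syntenous
  g2 <- g
  f <- g2$features
  pidx <- which(f$label == "partner")
  ctg2 <- substr(as.character(g2$contigs[[1]]), f$start[pidx], f$end[pidx])
  g2$contigs <- Biostrings::DNAStringSet(
    c(ctg1 = as.character(g2$contigs[[1]]), ctg2 = ctg2))
  f$contig_id[pidx] <- "ctg2"
  f$start[pidx] <- 1L; f$end[pidx] <- nchar(ctg2); f$locus_index[pidx] <- 0L
  g2$features <- f
  syn2 <- check_synteny(g2, f[f$label == "target", ], partner_small,
                        partner_cut, 10)
  expect_false(syn2$partner_found)
  expect_false(syn2$same_contig)
})

test_that("auto cutoff sits at the largest relative drop, framed by its scores", {
  # brute force over consecutive gaps confirms the framing pair (903, 500)
  s <- c(1000, 990, 985, 910, 903, 500, 480)
  rel <- (s[-length(s)] - s[-1]) / s[-length(s)]
  expect_equal(which.max(rel[-1]) + 1L, 5L)
  expect_equal(detect_cutoff(s), (903 + 500) / 2)
  expect_equal(detect_cutoff(c(10, 1)), 5.5)
  expect_equal(detect_cutoff(c(10, 1), mode = "manual", value = 906.4), 906.4)
  expect_error(detect_cutoff(rep(5, 4)), "no drop")
  expect_error(detect_cutoff(c(1, 5, 3)), "descending")
})

test_that("database assembly separates targets and outgroup and counts copies", {
  cand <- tibble::tibble(
    protein_id = sprintf("U%04d", 1:6),
    protein = c("AAA", "BBB", "CCC", "DDD", "EEE", "EEE"),
    gene_nt = c("GCAGCAGCA", "GCCGCCGCC", "TGTTGTTGT", "GATGATGAT",
                "GAAGAAGAA", "GAAGAGGAA"),
    score = c(100, 95, 90, 40, 30, 20),
    coverage = 1, residues_ok = TRUE, phylo_dist_to_top = 0.1,
    partner_found = TRUE, n_members = c(2L, 1L, 1L, 1L, 1L, 1L),
    member_genome_ids = list(c("g1", "g1"), "g2", "g3", "g1", "g2", "g3"))
  expect_warning(
    db <- assemble_database(cand, cutoff = 50, outgroup_protein_n = 300,
                            outgroup_nt_n = 500, cluster_targets = FALSE),
    "fewer below-cutoff")
  expect_equal(sort(db$targets$protein_id), c("U0001", "U0002", "U0003"))
  expect_length(intersect(db$targets$protein_id, db$outgroup$protein_id), 0)
  # genome g1 holds two identical copies of U0001: copy number 2, 1 unique
  cn <- db$copy_number[db$copy_number$genome_id == "g1", ]
  expect_equal(cn$n_copies, 2L)
  expect_equal(cn$n_unique, 1L)
  expect_false(cn$multi_copy_distinct)
  # raising the cutoff never adds targets
  db2 <- suppressWarnings(assemble_database(cand, cutoff = 92,
                                            cluster_targets = FALSE))
  expect_true(all(db2$targets$protein_id %in% db$targets$protein_id))
})
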