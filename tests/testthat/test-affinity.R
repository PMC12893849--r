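test_that("reconstruct_protein applies substitutions and checks the build", {
  set.seed(42)
  ref <- random_protein(20)
  ref_aa10 <- substr(ref, 10, 10)
  one <- reconstruct_protein(ref, data.frame(
    protein_position = 10L, ref_aa = ref_aa10, alt_aa = "V"), "TX1")
  expect_equal(substr(one, 10, 10), "V")
  expect_equal(substring(one, c(1, 11), c(9, 20)),
               substring(ref, c(1, 11), c(9, 20)))
  ## focal het plus a homozygous co-variant: both applied
  two <- reconstruct_protein(ref, data.frame(
    protein_position = c(10L, 3L),
    ref_aa = c(ref_aa10, substr(ref, 3, 3)), alt_aa = c("V", "R")), "TX1")
  ## independent string-edit oracle
  exp <- strsplit(ref, "")[[1]]; exp[10] <- "V"; exp[3] <- "R"
  expect_equal(two, paste(exp, collapse = ""))
  ## annotation/FASTA disagreement is a hard error naming the transcript
  wrong <- setdiff(c("A", "L"), ref_aa10)[1]
  expect_error(reconstruct_protein(ref, data.frame(
    protein_position = 10L, ref_aa = wrong, alt_aa = "V"), "TXZ"),
    "TXZ.*mismatch")
  expect_error(reconstruct_protein(ref, data.frame(
    protein_position = 99L, ref_aa = "A", alt_aa = "V"), "TXZ"), "outside")
})

test_that("window_peptides enumerates exactly the covering windows", {
  set.seed(7)
  p20 <- random_protein(20)
  expect_equal(nrow(window_peptides(p20, 10, 9)), 9L)       # interior
  w1 <- window_peptides(p20, 1, 9)
  expect_equal(nrow(w1), 1L)                                # N-terminus
  expect_equal(w1$sequence, substr(p20, 1, 9))
  expect_equal(w1$offset_in_peptide, 1L)
  expect_equal(nrow(window_peptides(random_protein(8), 4, 9)), 0L)  # L < k
  ## every window covers the focal residue with the right offset
  w <- window_peptides(p20, 12, 8)
  expect_true(all(substr(w$sequence, w$offset_in_peptide,
                         w$offset_in_peptide) == substr(p20, 12, 12)))
})

test_that("differential peptides equal the brute-force k-mer difference", {
  set.seed(11)
  for (rep in 1:10) {
    L <- sample(15:40, 1); p <- sample(seq_len(L), 1); k <- sample(8:11, 1)
    ref <- random_protein(L)
    ref_aa <- substr(ref, p, p)
    alt <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], ref_aa), 1)
    donor <- reconstruct_protein(ref, data.frame(
      protein_position = p, ref_aa = ref_aa, alt_aa = alt))
    ## donor het alt/ref vs recipient hom ref, SOT source = donor alt allele
    w <- window_peptides(donor, p, k)
    got <- sort(differential_peptides(w, all_kmers(ref, k))$sequence)
    want <- sort(setdiff(all_kmers(donor, k, covering = p),
                         all_kmers(ref, k)))
    expect_equal(got, want)
    ## donor hom alt vs recipient het (alt present in target) -> empty
    got2 <- differential_peptides(w, c(all_kmers(ref, k),
                                       all_kmers(donor, k)))
    expect_equal(nrow(got2), 0L)
  }
})

test_that("the mock predictor is deterministic, total and order-stable", {
  peps <- c("SIINFEKLM", "GILGFVFTL", "LLFGYPVYV")
  hla <- c("HLA-A*02:01", "HLA-B*07:02")
  a <- predict_affinity(peps, hla)
  b <- predict_affinity(peps, hla)
  expect_identical(a, b)
  expect_equal(nrow(a), 6L)                       # cartesian contract
  expect_equal(a$peptide, rep(peps, each = 2))    # order-stable
  expect_true(all(a$percent_rank >= 0 & a$percent_rank <= 100))
  ## empty input
  expect_equal(nrow(predict_affinity(character(), hla)), 0L)
  ## class I length bounds
  expect_error(predict_affinity("SHORT", hla), "8-14")
})

test_that("cleavage filtering keys on the C-terminal residue", {
  prot <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 2), collapse = "")
  w <- window_peptides(prot, 10, 9, transcript_id = "TX1")
  all_on <- structure(list(transcript_id = "TX1",
                           scores = rep(1, nchar(prot))),
                      class = "cleavage_profile")
  all_off <- structure(list(transcript_id = "TX1",
                            scores = rep(0, nchar(prot))),
                       class = "cleavage_profile")
  expect_equal(nrow(cleavage_filter(w, all_on)), nrow(w))
  expect_equal(nrow(cleavage_filter(w, all_off)), 0L)
  ## score above threshold only at protein position 12: only the window
  ## whose C-terminus sits at 12 survives
  spot <- all_off
  spot$scores[12] <- 0.9
  kept <- cleavage_filter(w, spot)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$protein_position - kept$offset_in_peptide + kept$length,
               12L)
  ## mock profile is deterministic and in [0, 1]
  pr1 <- mock_cleavage_profile(prot, "TX1")
  pr2 <- mock_cleavage_profile(prot, "TX1")
  expect_identical(pr1$scores, pr2$scores)
  expect_length(pr1$scores, nchar(prot))
  expect_true(all(pr1$scores >= 0 & pr1$scores <= 1))
})

test_that("af-AMS counting rules and threshold boundary are exact", {
  ranks <- c(0.1, 1.9, 2.0, 2.1, 5, 10, 50, 80, 99, 100)
  rec <- data.table::data.table(
    peptide = sprintf("PEPTIDE%02d", 1:10), hla_allele = "HLA-A*02:01",
    affinity_nm = exp(log(50000) * ranks / 100), percent_rank = ranks)
  ## boundary inclusive: 0.1, 1.9 and 2.0 are binders
  r <- compute_af_ams(rec, rank_threshold = 2.0)
  expect_equal(r$af_ams, 3L)
  expect_equal(sum(r$table$binder), 3L)
  ## no binders
  expect_equal(compute_af_ams(rec, rank_threshold = 0.01)$af_ams, 0L)
  ## one peptide binding two alleles: peptides=1, pairs=2
  rec2 <- data.table::data.table(
    peptide = "AAAAAAAAA", hla_allele = c("HLA-A*02:01", "HLA-B*07:02"),
    affinity_nm = c(10, 20), percent_rank = c(0.5, 1.0))
  expect_equal(compute_af_ams(rec2, rank_threshold = 2)$af_ams, 1L)
  expect_equal(compute_af_ams(rec2, rank_threshold = 2,
                              count = "pairs")$af_ams, 2L)
  ## exactly one criterion may be active
  expect_error(compute_af_ams(rec, rank_threshold = 2, nm_threshold = 500),
               "exactly one")
  expect_error(compute_af_ams(rec, rank_threshold = NULL), "required")
  ## nM criterion
  expect_equal(compute_af_ams(rec2, rank_threshold = NULL,
                              nm_threshold = 15)$af_ams, 1L)
})

test_that("af-AMS is monotone in threshold and in the allele panel", {
  set.seed(5)
  peps <- replicate(30, random_protein(9))
  hla4 <- c("HLA-A*02:01", "HLA-B*07:02", "HLA-C*07:01", "HLA-A*01:01")
  rec4 <- predict_affinity(peps, hla4)
  rec2 <- predict_affinity(peps, hla4[1:2])
  prev <- -1L
  for (thr in c(0.5, 2, 10, 50, 100)) {
    cur <- compute_af_ams(rec4, rank_threshold = thr)$af_ams
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_gte(compute_af_ams(rec4, rank_threshold = 10)$af_ams,
             compute_af_ams(rec2, rank_threshold = 10)$af_ams)
})

test_that("run_affinity composes the stages and drops odd residues", {
  ## one SOT mismatch row on a known protein
  ref <- paste(rep("ACDEFGHIKL", 3), collapse = "")
  proteome <- c(TX1 = ref)
  tab <- data.table::data.table(
    chrom = "chrS", pos = 500L, rsid = "rs1", transcript_id = "TX1",
    gene_id = "G1", protein_position = 15L, ref_aa = substr(ref, 15, 15),
    source_aas = paste(sort(c(substr(ref, 15, 15), "W")), collapse = "/"),
    target_aas = substr(ref, 15, 15), mismatch_aas = "W",
    direction = "SOT", contribution = 1L)
  res <- run_affinity(tab, proteome, hla_alleles = "HLA-A*02:01",
                      lengths = 9L)
  ## donor het W vs recipient hom ref: all 9 W-containing windows survive
  expect_equal(length(res$peptides), 9L)
  expect_true(all(grepl("W", res$peptides)))
  expect_equal(nrow(res$table), 9L)
  ## unknown transcript is a hard error
  tab2 <- data.table::copy(tab)[, transcript_id := "TXMISSING"]
  expect_error(run_affinity(tab2, proteome, "HLA-A*02:01"), "TXMISSING")
  ## non-standard residues in the protein are dropped with a warning
  ## (selenocysteine placed inside the window range around position 15)
  proteome_u <- c(TX1 = paste0(substr(ref, 1, 11), "U", substr(ref, 13, 30)))
  expect_warning(
    res_u <- run_affinity(tab, proteome_u, "HLA-A*02:01", lengths = 9L,
                          rank_threshold = 100),
    "non-standard")
  expect_true(all(!grepl("U", res_u$peptides)))
})

test_that("identical genotypes produce no differential peptides", {
  ref <- random_protein(30)
  tab <- data.table::data.table(
    chrom = "chrS", pos = 1L, rsid = "rs1", transcript_id = "TX1",
    gene_id = "G1", protein_position = 10L, ref_aa = substr(ref, 10, 10),
    source_aas = "V", target_aas = "V", mismatch_aas = character(0),
    direction = "SOT", contribution = integer(0))[0]
  res <- run_affinity(tab, c(TX1 = ref), "HLA-A*02:01")
  expect_equal(res$af_ams, 0L)
  expect_length(res$peptides, 0L)
})
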