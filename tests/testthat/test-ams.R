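cfg0 <- filter_config(min_gnomad_af = 0)

ams_of <- function(x, direction, missing, ...) {
  compute_ams(x, donor_sample = "DONOR", recipient_sample = "RECIPIENT",
              direction = direction, missing = missing, filters = cfg0, ...)
}

test_that("aa_set maps genotype alleles onto amino acids", {
  expect_setequal(aa_set(c(0L, 1L), "A", c(`1` = "V")), c("A", "V"))
  expect_equal(aa_set(c(1L, 1L), "A", c(`1` = "V")), "V")
  expect_setequal(aa_set(c(1L, 2L), "G", c(`1` = "R", `2` = "W")),
                  c("R", "W"))
  ## an allele with no annotated consequence falls back to the reference
  expect_setequal(aa_set(c(1L, 2L), "G", c(`1` = "R")), c("R", "G"))
  expect_error(aa_set(c(NA_integer_, 1L), "A", c(`1` = "V")))
})

test_that("directional_mismatch is a set difference", {
  expect_equal(directional_mismatch(c("A", "V"), "A"), "V")
  expect_equal(directional_mismatch("A", "A"), character())
  ## the reference amino acid can itself be the mismatch (HCT logic)
  expect_equal(directional_mismatch("R", c("G", "R")), character())
  expect_equal(directional_mismatch(c("G", "R"), "R"), "G")
})

test_that("the three-site toy gives the frozen scores in all four modes", {
  x <- fixture_to_variants(toy_pair_fixture())
  expect_equal(ams_of(x, "SOT", "stringent")$ams, 1L)
  expect_equal(ams_of(x, "HCT", "stringent")$ams, 1L)
  expect_equal(ams_of(x, "SOT", "impute")$ams, 1L)
  expect_equal(ams_of(x, "HCT", "impute")$ams, 2L)
  ## table provenance for the SOT mismatch
  tab <- ams_of(x, "SOT", "stringent")$table
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$mismatch_aas, "V")
  expect_equal(tab$source_aas, "A/V")
  expect_equal(tab$rsid, "rs1")
  ## HCT impute picks up both {G} and {P}
  tab2 <- ams_of(x, "HCT", "impute")$table
  expect_setequal(tab2$mismatch_aas, c("G", "P"))
  ## stringent masks exactly the ./. site
  expect_equal(ams_of(x, "SOT", "stringent")$masked_sites, 1L)
})

test_that("a GT=1/2 site mismatches with both alternate amino acids", {
  fx <- list(samples = c("DONOR", "RECIPIENT"), sites = list(
    list(chrom = "chrS", pos = 10L, id = "rs1", ref = "A", alts = c("T", "G"),
         filt = "PASS",
         gt = list(DONOR = c(1L, 2L), RECIPIENT = c(0L, 0L)),
         cons = list(
           list(transcript_id = "TX1", gene_id = "G1", allele = 1L,
                protein_position = 5L, amino_acids = "G/R", gnomad_af = 0.2,
                canonical = TRUE),
           list(transcript_id = "TX1", gene_id = "G1", allele = 2L,
                protein_position = 5L, amino_acids = "G/W", gnomad_af = 0.2,
                canonical = TRUE)))))
  r <- ams_of(fixture_to_variants(fx), "SOT", "stringent")
  expect_equal(r$ams, 2L)
  expect_equal(r$table$mismatch_aas, "R/W")
  expect_equal(oracle_ams(fx, direction = "SOT", missing = "stringent"), 2L)
})

test_that("self-comparison scores zero in every mode", {
  for (seed in 1:5) {
    fx <- random_fixture(n_sites = 25L, seed = seed)
    ## recipient := donor
    for (i in seq_along(fx$sites))
      fx$sites[[i]]$gt$RECIPIENT <- fx$sites[[i]]$gt$DONOR
    x <- fixture_to_variants(fx)
    for (d in c("SOT", "HCT")) for (m in c("stringent", "impute"))
      expect_equal(ams_of(x, d, m)$ams, 0L)
  }
})

test_that("direction duality: SOT(X,Y) equals HCT(Y,X) with identical tables", {
  for (seed in 1:8) {
    fx <- random_fixture(n_sites = 30L, seed = 100 + seed)
    x <- fixture_to_variants(fx)
    for (m in c("stringent", "impute")) {
      a <- compute_ams(x, donor_sample = "DONOR", recipient_sample = "RECIPIENT",
                       direction = "SOT", missing = m, filters = cfg0)
      b <- compute_ams(x, donor_sample = "RECIPIENT", recipient_sample = "DONOR",
                       direction = "HCT", missing = m, filters = cfg0)
      expect_identical(a$ams, b$ams)
      ta <- data.table::copy(a$table)[, direction := NULL]
      tb <- data.table::copy(b$table)[, direction := NULL]
      expect_equal(ta, tb)
    }
  }
})

test_that("stringent never exceeds impute", {
  for (seed in 1:8) {
    fx <- random_fixture(n_sites = 30L, seed = 200 + seed, p_missing = 0.3)
    x <- fixture_to_variants(fx)
    for (d in c("SOT", "HCT"))
      expect_lte(ams_of(x, d, "stringent")$ams, ams_of(x, d, "impute")$ams)
  }
})

test_that("lowering the AF threshold never decreases the score", {
  for (seed in 1:5) {
    fx <- random_fixture(n_sites = 40L, seed = 300 + seed)
    x <- fixture_to_variants(fx)
    a0 <- compute_ams(x, donor_sample = "DONOR", recipient_sample = "RECIPIENT",
                      filters = filter_config(min_gnomad_af = 0))$ams
    a1 <- compute_ams(x, donor_sample = "DONOR", recipient_sample = "RECIPIENT",
                      filters = filter_config(min_gnomad_af = 0.01))$ams
    a5 <- compute_ams(x, donor_sample = "DONOR", recipient_sample = "RECIPIENT",
                      filters = filter_config(min_gnomad_af = 0.05))$ams
    expect_gte(a0, a1)
    expect_gte(a1, a5)
  }
})

test_that("restriction operators follow their conventions", {
  fx <- toy_pair_fixture()
  x <- fixture_to_variants(fx)
  bed <- data.table::data.table(chrom = "chrS", start = c(99L), end = c(200L))
  ## 0-based half-open: pos 100 and 200 inside, pos 300 outside
  xr <- restrict(x, bed = bed)
  expect_equal(sort(xr$variants$pos), c(100L, 200L))
  ## a site at pos == start is excluded (start is 0-based)
  bed2 <- data.table::data.table(chrom = "chrS", start = 100L, end = 200L)
  expect_false(100L %in% restrict(x, bed = bed2)$variants$pos)
  ## rsID restriction; empty list removes everything
  expect_equal(restrict(x, rsids = c("rs1", "rs3"))$variants$id,
               c("rs1", "rs3"))
  expect_equal(nrow(restrict(x, rsids = character())$variants), 0L)
  ## transcript restriction drops consequences, keeps sites with some left
  fx2 <- random_fixture(n_sites = 1L, seed = 9)
  ## build a two-transcript site explicitly
  fx2$sites[[1]]$cons <- list(
    list(transcript_id = "TXA", gene_id = "G", allele = 1L,
         protein_position = 5L, amino_acids = "A/V", gnomad_af = 0.2,
         canonical = TRUE),
    list(transcript_id = "TXB", gene_id = "G", allele = 1L,
         protein_position = 9L, amino_acids = "A/W", gnomad_af = 0.2,
         canonical = FALSE))
  x2 <- fixture_to_variants(fx2)
  xt <- restrict(x2, transcripts = "TXB")
  expect_equal(nrow(xt$variants), 1L)
  expect_equal(xt$consequences$transcript_id, "TXB")
  expect_equal(nrow(restrict(x2, transcripts = "TXZ")$variants), 0L)
})

test_that("BED restriction is additive over disjoint regions", {
  fx <- random_fixture(n_sites = 40L, seed = 77)
  x <- fixture_to_variants(fx)       # positions 100, 200, ..., 4000
  bedA <- data.table::data.table(chrom = "chrS", start = 0L, end = 2000L)
  bedB <- data.table::data.table(chrom = "chrS", start = 2000L, end = 4000L)
  bedAB <- rbind(bedA, bedB)
  for (m in c("stringent", "impute")) {
    aA <- ams_of(x, "SOT", m, bed = bedA)$ams
    aB <- ams_of(x, "SOT", m, bed = bedB)$ams
    aAB <- ams_of(x, "SOT", m, bed = bedAB)$ams
    expect_identical(aA + aB, aAB)
    expect_lte(aAB, ams_of(x, "SOT", m)$ams)
  }
})

test_that("sites present in only one input follow the missing-data mode", {
  fx <- toy_pair_fixture()
  donor_only <- list(samples = "DONOR",
                     sites = lapply(fx$sites[1:2], function(s) {
                       s$gt <- s$gt["DONOR"]; s
                     }))
  rec_only <- list(samples = "RECIPIENT",
                   sites = lapply(fx$sites[2:3], function(s) {
                     s$gt <- s$gt["RECIPIENT"]; s
                   }))
  d <- fixture_to_variants(donor_only)
  r <- fixture_to_variants(rec_only)
  ## shared: site2 only.  stringent: sites 1 and 3 masked -> SOT 0, HCT 1
  s_sot <- compute_ams(d, r, direction = "SOT", missing = "stringent",
                       filters = cfg0)
  expect_equal(s_sot$ams, 0L)
  expect_equal(s_sot$masked_sites, 2L)
  expect_equal(compute_ams(d, r, direction = "HCT", missing = "stringent",
                           filters = cfg0)$ams, 1L)
  ## impute: site1 recipient imputed 0/0 -> V counts in SOT;
  ## site3 donor imputed -> P counts in HCT
  expect_equal(compute_ams(d, r, direction = "SOT", missing = "impute",
                           filters = cfg0)$ams, 1L)
  expect_equal(compute_ams(d, r, direction = "HCT", missing = "impute",
                           filters = cfg0)$ams, 2L)
})

test_that("contig mismatch between inputs is a hard error", {
  fx <- toy_pair_fixture()
  d <- fixture_to_variants(list(samples = "DONOR",
                                sites = lapply(fx$sites, function(s) {
                                  s$gt <- s$gt["DONOR"]; s
                                })))
  r_fx <- lapply(fx$sites, function(s) {
    s$chrom <- "chr7"; s$gt <- s$gt["RECIPIENT"]; s
  })
  r <- fixture_to_variants(list(samples = "RECIPIENT", sites = r_fx))
  expect_error(compute_ams(d, r, filters = cfg0), "contig")
})

test_that("counting rules behave as documented", {
  ## two transcripts, both canonical, same mismatch
  fx <- list(samples = c("DONOR", "RECIPIENT"), sites = list(
    list(chrom = "chrS", pos = 50L, id = "rs1", ref = "A", alts = "T",
         filt = "PASS",
         gt = list(DONOR = c(1L, 1L), RECIPIENT = c(0L, 0L)),
         cons = list(
           list(transcript_id = "TXA", gene_id = "G", allele = 1L,
                protein_position = 5L, amino_acids = "A/V", gnomad_af = 0.2,
                canonical = TRUE),
           list(transcript_id = "TXB", gene_id = "G", allele = 1L,
                protein_position = 8L, amino_acids = "A/V", gnomad_af = 0.2,
                canonical = FALSE)))))
  x <- fixture_to_variants(fx)
  ## canonical: only TXA counts
  expect_equal(ams_of(x, "SOT", "stringent")$ams, 1L)
  ## per-transcript: both isoforms count
  expect_equal(ams_of(x, "SOT", "stringent", counting = "per_transcript")$ams, 2L)
  ## binary site: capped at 1
  expect_equal(ams_of(x, "SOT", "stringent", counting = "binary_site")$ams, 1L)
  ## oracle agrees on all three rules
  for (cn in c("canonical", "per_transcript", "binary_site"))
    expect_equal(ams_of(x, "SOT", "stringent", counting = cn)$ams,
                 oracle_ams(fx, direction = "SOT", missing = "stringent",
                            counting = cn))
})

test_that("stop-gain substitutions are excluded unless requested", {
  fx <- list(samples = c("DONOR", "RECIPIENT"), sites = list(
    list(chrom = "chrS", pos = 50L, id = "rs1", ref = "C", alts = "T",
         filt = "PASS",
         gt = list(DONOR = c(1L, 1L), RECIPIENT = c(0L, 0L)),
         cons = list(list(transcript_id = "TXA", gene_id = "G", allele = 1L,
                          protein_position = 5L, amino_acids = "Q/*",
                          gnomad_af = 0.2, canonical = TRUE)))))
  x <- fixture_to_variants(fx)
  expect_equal(ams_of(x, "SOT", "stringent")$ams, 0L)
  expect_equal(ams_of(x, "SOT", "stringent", include_stop_gained = TRUE)$ams, 1L)
})

test_that("the dosage lookup table matches first-principles set logic", {
  ## SOT: rows donor dosage 0..2, cols recipient dosage 0..2
  expect_identical(oracle_contrib_table("SOT"),
                   matrix(c(0L, 1L, 1L,   # donor {R}, {R,A}, {A} vs rec {R}
                            0L, 0L, 0L,   # vs rec {R,A}
                            1L, 1L, 0L),  # vs rec {A}
                          nrow = 3))
  expect_identical(oracle_contrib_table("HCT"),
                   t(oracle_contrib_table("SOT")))
})
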