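## Synthetic data with the statistical structure the method assumes: a toy
## proteome, biallelic exonic missense sites with population allele
## frequencies, Mendelian transmission within a family (with recombination),
## genotyping error and missingness, and VEP-style annotated VCF output so
## the whole pipeline can be exercised end to end without any real data.

#' Simulation configuration
#'
#' Defaults encode the validation scenario: 20,000 biallelic missense sites
#' on one chromosome (labelled `chrS`), ALT frequencies from Beta(0.5, 0.5)
#' truncated to \[0.01, 0.5\], 15 siblings, Poisson(1.5) crossovers per
#' transmitted haplotype, per-genotype error rate 5e-4, no missingness.
#'
#' @param n_sites number of simulated missense sites.
#' @param beta_a,beta_b Beta parameters of the allele-frequency distribution.
#' @param af_min,af_max truncation interval of the common-variant AFs.
#' @param rare_fraction fraction of sites drawn instead from
#'   `rare_af_range` (below the default 1% AF gate); 0 by default.
#' @param rare_af_range AF interval for the rare-site fraction.
#' @param n_children number of siblings.
#' @param recomb_rate expected crossovers per transmitted haplotype.
#' @param error_rate per-(individual, site) probability of flipping the
#'   observed genotype to a uniformly random *different* genotype among
#'   \{hom-ref, het, hom-alt\}.
#' @param missing_rate per-(individual, site) probability of masking the
#'   observed genotype.
#' @param seed mandatory integer seed (no hidden global state).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_sites = 20000L, beta_a = 0.5, beta_b = 0.5,
                       af_min = 0.01, af_max = 0.5,
                       rare_fraction = 0, rare_af_range = c(0.001, 0.01),
                       n_children = 15L, recomb_rate = 1.5,
                       error_rate = 5e-4, missing_rate = 0, seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(n_sites >= 1, n_children >= 1,
            error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            rare_fraction >= 0, rare_fraction <= 1,
            af_min <= af_max)
  structure(list(n_sites = as.integer(n_sites), beta_a = beta_a,
                 beta_b = beta_b, af_min = af_min, af_max = af_max,
                 rare_fraction = rare_fraction, rare_af_range = rare_af_range,
                 n_children = as.integer(n_children),
                 recomb_rate = recomb_rate, error_rate = error_rate,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

rbeta_trunc <- function(n, a, b, lo, hi) {
  qbeta(runif(n, pbeta(lo, a, b), pbeta(hi, a, b)), a, b)
}

#' Generate a deterministic toy proteome
#'
#' Random amino-acid sequences over the 20-letter alphabet, reproducible per
#' seed.
#'
#' @param n_transcripts number of proteins.
#' @param length_range inclusive protein-length range; keep the minimum at
#'   or above the longest requested peptide length.
#' @param seed integer seed.
#' @param prefix transcript-ID prefix.
#' @return named character vector of protein sequences
#'   (`<prefix>00001`, ...).
#' @export
make_toy_proteome <- function(n_transcripts, length_range = c(60L, 120L),
                              seed, prefix = "TXS") {
  if (missing(seed)) stop("make_toy_proteome: seed is mandatory")
  set.seed(seed)
  lens <- sample(length_range[1]:length_range[2], n_transcripts, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(STANDARD_AA, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- sprintf("%s%05d", prefix, seq_len(n_transcripts))
  seqs
}

#' Write a proteome to FASTA
#' @param proteome named character vector of protein sequences.
#' @param path output FASTA path.
#' @export
write_proteome_fasta <- function(proteome, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), path)
  invisible(path)
}

## one meiosis: recombine a 2 x n_sites parental haplotype matrix
meiosis <- function(H, pos, chrom_len, recomb_rate) {
  n <- ncol(H)
  nx <- rpois(1L, recomb_rate)
  start <- sample(1:2, 1L)
  if (nx == 0L) return(H[start, ])
  bp <- sort(runif(nx, 0, chrom_len))
  seg <- findInterval(pos, bp)
  idx <- ((start - 1L + seg) %% 2L) + 1L
  H[cbind(idx, seq_len(n))]
}

#' Simulate a nuclear family of genotypes at missense sites
#'
#' Parents' haplotypes are drawn per site from the truncated AF
#' distribution; each child receives one recombined haplotype from each
#' parent.  Observed genotypes are the true ones perturbed by the error
#' model (uniform flip to a different genotype) and by missingness masks.
#' Ground-truth scores for every ordered sibling pair are computed on the
#' TRUE genotypes by the independent oracle ([oracle_family_ams()]), never
#' by the production scoring path.
#'
#' @param cfg a [sim_config()].
#' @param compute_truth compute `truth_ams` (default `TRUE`).
#' @return a `family_sim`: list with `sites` (metadata incl. transcript,
#'   protein position, ref/alt amino acids, gnomAD AF), `proteome`,
#'   `individuals` (`P1`, `P2`, `S01`...), `true` and `observed` dosage
#'   matrices (sites x individuals), haplotype matrices for the Mendelian
#'   audit trail, and `truth_ams` (ordered sibling pairs, SOT direction;
#'   the HCT truth follows by direction duality).
#' @export
simulate_family <- function(cfg, compute_truth = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_sites
  spacing <- 150L
  pos <- seq_len(n) * spacing
  chrom_len <- (n + 10L) * spacing

  ## toy proteome large enough to host every site at a distinct residue
  n_tx <- max(1L, ceiling(n / 40))
  lens <- sample(60:120, n_tx, replace = TRUE)
  prot <- vapply(lens, function(L)
    paste(sample(STANDARD_AA, L, replace = TRUE), collapse = ""), character(1))
  names(prot) <- sprintf("TXS%05d", seq_len(n_tx))
  pool <- data.table(transcript_id = rep(names(prot), times = lens),
                     protein_position = unlist(lapply(lens, seq_len)))
  stopifnot(nrow(pool) >= n)
  slots <- pool[sort(sample(nrow(pool), n))]
  ref_aa <- substring(prot[slots$transcript_id],
                      slots$protein_position, slots$protein_position)
  alt_aa <- vapply(ref_aa, function(a) sample(setdiff(STANDARD_AA, a), 1L),
                   character(1), USE.NAMES = FALSE)

  af <- rbeta_trunc(n, cfg$beta_a, cfg$beta_b, cfg$af_min, cfg$af_max)
  if (cfg$rare_fraction > 0) {
    rare <- runif(n) < cfg$rare_fraction
    af[rare] <- runif(sum(rare), cfg$rare_af_range[1], cfg$rare_af_range[2])
  }
  bases <- c("A", "C", "G", "T")
  refb <- sample(bases, n, replace = TRUE)
  altb <- vapply(refb, function(b) sample(setdiff(bases, b), 1L),
                 character(1), USE.NAMES = FALSE)

  sites <- data.table(site_id = seq_len(n), chrom = "chrS", pos = pos,
                      id = sprintf("rs%07d", seq_len(n) + 1000000L),
                      ref = refb, alt = altb,
                      transcript_id = slots$transcript_id,
                      gene_id = sub("^TXS", "GENE", slots$transcript_id),
                      protein_position = slots$protein_position,
                      ref_aa = ref_aa, alt_aa = alt_aa, gnomad_af = af)

  draw_parent <- function() rbind(runif(n) < af, runif(n) < af) + 0L
  father <- draw_parent(); mother <- draw_parent()
  kids <- sprintf("S%02d", seq_len(cfg$n_children))
  pat <- mat <- matrix(0L, nrow = cfg$n_children, ncol = n,
                       dimnames = list(kids, NULL))
  for (k in seq_len(cfg$n_children)) {
    pat[k, ] <- meiosis(father, pos, chrom_len, cfg$recomb_rate)
    mat[k, ] <- meiosis(mother, pos, chrom_len, cfg$recomb_rate)
  }
  individuals <- c("P1", "P2", kids)
  true <- cbind(P1 = colSums(father), P2 = colSums(mother), t(pat + mat))
  colnames(true) <- individuals

  observed <- true
  n_cells <- length(observed)
  flip <- runif(n_cells) < cfg$error_rate
  if (any(flip)) {
    shift <- sample(1:2, sum(flip), replace = TRUE)
    observed[flip] <- (observed[flip] + shift) %% 3L
  }
  if (cfg$missing_rate > 0)
    observed[runif(n_cells) < cfg$missing_rate] <- NA_integer_

  truth <- NULL
  if (compute_truth) {
    pairs <- CJ(donor = kids, recipient = kids)[donor != recipient]
    truth <- pairs[, .(donor, recipient, direction = "SOT",
                       ams = mapply(function(d, r)
                         oracle_family_ams(true[, d], true[, r], "SOT"),
                         donor, recipient))]
  }
  structure(list(config = cfg, sites = sites, proteome = prot,
                 individuals = individuals, children = kids,
                 true = true, observed = observed,
                 paternal_hap = pat, maternal_hap = mat,
                 father_hap = father, mother_hap = mother,
                 truth_ams = truth),
            class = "family_sim")
}

#' @export
print.family_sim <- function(x, ...) {
  cat(sprintf("family_sim: %d sites, %d children, error %g, missing %g (seed %d)\n",
              nrow(x$sites), length(x$children), x$config$error_rate,
              x$config$missing_rate, x$config$seed))
  invisible(x)
}

#' Expose simulated individuals as a joint variant object
#'
#' Builds the same in-memory model [read_vep_vcf()] produces, with quality
#' fields that satisfy the default filters (DP 60, GQ 99, balanced het AD),
#' so the production scoring path runs on simulated genotypes exactly as it
#' would on parsed VCFs.
#'
#' @param sim a `family_sim`.
#' @param individuals which individuals to include (default: all).
#' @param genotypes `"observed"` (with injected error/missingness) or
#'   `"true"`.
#' @return an [allo_variants()] object.
#' @export
family_to_variants <- function(sim, individuals = sim$individuals,
                               genotypes = c("observed", "true")) {
  genotypes <- match.arg(genotypes)
  G <- sim[[genotypes]][, individuals, drop = FALSE]
  s <- sim$sites
  n <- nrow(s)
  variants <- data.table(site_id = s$site_id, chrom = s$chrom, pos = s$pos,
                         id = s$id, ref = s$ref,
                         alts = as.list(s$alt), filt = "PASS")
  g <- as.vector(G)
  calls <- data.table(
    site_id = rep(s$site_id, times = length(individuals)),
    sample = rep(individuals, each = n),
    a1 = fifelse(is.na(g), NA_integer_, fifelse(g == 2L, 1L, 0L)),
    a2 = fifelse(is.na(g), NA_integer_, fifelse(g >= 1L, 1L, 0L)),
    phased = FALSE, dp = 60L, gq = 99L,
    ab = fifelse(!is.na(g) & g == 1L, 0.5, NA_real_),
    filt = "PASS")
  cons <- data.table(site_id = s$site_id, allele_index = 1L,
                     transcript_id = s$transcript_id, gene_id = s$gene_id,
                     consequence = "missense_variant",
                     protein_position = s$protein_position,
                     amino_acids = paste0(s$ref_aa, "/", s$alt_aa),
                     gnomad_af = s$gnomad_af,
                     existing_variation = s$id, canonical = TRUE)
  allo_variants(variants, calls, cons, samples = individuals)
}

#' Write simulated individuals as VEP-annotated VCF(s)
#'
#' Emits single-sample VCFs (or one joint multi-sample VCF) with GT/AD/DP/GQ
#' genotype fields satisfying the default filters and a header-declared CSQ
#' INFO field carrying transcript, protein position, amino acids and gnomAD
#' AF; round-trips through [read_vep_vcf()].
#'
#' @param sim a `family_sim`.
#' @param individuals individuals to write.
#' @param out_dir output directory (created if needed).
#' @param joint write one joint VCF (`joint.vcf`) instead of one file per
#'   individual (`<name>.vcf`).
#' @param genotypes `"observed"` or `"true"`.
#' @return character vector of written paths.
#' @export
write_pair_vcfs <- function(sim, individuals = sim$children[1:2], out_dir,
                            joint = FALSE, genotypes = c("observed", "true")) {
  genotypes <- match.arg(genotypes)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  G <- sim[[genotypes]][, individuals, drop = FALSE]
  s <- sim$sites
  csq_fields <- c("Allele", "Consequence", "IMPACT", "SYMBOL", "Gene",
                  "Feature", "Protein_position", "Amino_acids",
                  "Existing_variation", "CANONICAL", "gnomADe_AF")
  hdr <- function(samples) c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chrS,length=%d>", max(s$pos) + 1000L),
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations from Ensembl VEP. Format: ",
           paste(csq_fields, collapse = "|"), "\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  csq <- sprintf("CSQ=%s|missense_variant|MODERATE|%s|%s|%s|%d|%s/%s|%s|YES|%s",
                 s$alt, s$gene_id, s$gene_id, s$transcript_id,
                 s$protein_position, s$ref_aa, s$alt_aa, s$id,
                 formatC(s$gnomad_af, format = "g", digits = 6))
  gt_str <- function(g) {
    fifelse(is.na(g), "./.:.:.:.",
            fifelse(g == 0L, "0/0:60,0:60:99",
                    fifelse(g == 1L, "0/1:30,30:60:99", "1/1:0,60:60:99")))
  }
  body_for <- function(samples) {
    cols <- vapply(samples, function(smp) gt_str(G[, smp]),
                   character(nrow(s)))
    if (is.null(dim(cols))) cols <- matrix(cols, nrow = nrow(s))
    gt <- apply(cols, 1, paste, collapse = "\t")
    paste(s$chrom, s$pos, s$id, s$ref, s$alt, "100", "PASS", csq,
          "GT:AD:DP:GQ", gt, sep = "\t")
  }
  if (joint) {
    path <- file.path(out_dir, "joint.vcf")
    writeLines(c(hdr(individuals), body_for(individuals)), path)
    return(invisible(path))
  }
  paths <- vapply(individuals, function(smp) {
    path <- file.path(out_dir, paste0(smp, ".vcf"))
    writeLines(c(hdr(smp), body_for(smp)), path)
    path
  }, character(1))
  invisible(paths)
}

## ---------------------------------------------------------------------------
## Random small fixtures for oracle-equivalence and property testing

#' Generate a random small fixture (plain-list form)
#'
#' Exercises the comparison logic broadly: multi-allelic sites, several
#' transcripts, alleles without an annotated consequence, missing genotypes,
#' absent AF annotations, non-canonical transcripts.  All quality fields
#' pass the default filters (the fixture targets comparison semantics, not
#' QC).  Deterministic per seed.
#'
#' @param n_sites number of sites.
#' @param seed integer seed.
#' @param samples two sample names.
#' @param p_multi probability of a second ALT allele.
#' @param p_missing probability of a missing genotype per sample.
#' @param p_nocons probability that an ALT lacks a consequence.
#' @param p_af_absent probability that a consequence has no gnomAD AF.
#' @return a fixture list (see [oracle_ams()]).
#' @export
random_fixture <- function(n_sites = 20L, seed = 1L,
                           samples = c("DONOR", "RECIPIENT"),
                           p_multi = 0.25, p_missing = 0.1,
                           p_nocons = 0.15, p_af_absent = 0.2) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  mk_gt <- function(n_alt) {
    if (runif(1) < p_missing) return(c(NA_integer_, NA_integer_))
    sort(sample(0:n_alt, 2L, replace = TRUE))
  }
  sites <- lapply(seq_len(n_sites), function(i) {
    n_alt <- 1L + (runif(1) < p_multi)
    ref <- sample(bases, 1L)
    alts <- sample(setdiff(bases, ref), n_alt)
    n_tx <- 1L + (runif(1) < 0.3)
    cons <- list()
    for (t in seq_len(n_tx)) {
      tx <- sprintf("TX%04d_%d", i, t)
      ppos <- sample(5:50, 1L)
      ref_aa <- sample(STANDARD_AA, 1L)
      canonical <- (t == 1L) || (runif(1) < 0.3)
      for (a in seq_len(n_alt)) {
        if (runif(1) < p_nocons) next
        alt_aa <- sample(setdiff(STANDARD_AA, ref_aa), 1L)
        cons[[length(cons) + 1L]] <- list(
          transcript_id = tx, gene_id = sprintf("G%04d", i), allele = a,
          protein_position = ppos,
          amino_acids = paste0(ref_aa, "/", alt_aa),
          gnomad_af = if (runif(1) < p_af_absent) NA_real_
                      else round(runif(1, 0.001, 0.5), 4),
          canonical = canonical)
      }
    }
    gt <- lapply(samples, function(sm) mk_gt(n_alt))
    names(gt) <- samples
    list(chrom = "chrS", pos = i * 100L, id = sprintf("rs%06d", i),
         ref = ref, alts = alts, filt = "PASS", gt = gt, cons = cons)
  })
  list(samples = samples, sites = sites)
}

#' Convert a plain-list fixture to the internal variant model
#'
#' Quality fields are filled so the default filters pass (DP 60, GQ 99,
#' balanced het AB).
#'
#' @param fixture a fixture list (see [random_fixture()]).
#' @return an [allo_variants()] object.
#' @export
fixture_to_variants <- function(fixture) {
  ns <- length(fixture$sites)
  variants <- rbindlist(lapply(seq_len(ns), function(i) {
    st <- fixture$sites[[i]]
    data.table(site_id = i, chrom = st$chrom, pos = st$pos,
               id = st$id %||% NA_character_, ref = st$ref,
               alts = list(st$alts), filt = st$filt %||% "PASS")
  }))
  calls <- rbindlist(lapply(seq_len(ns), function(i) {
    st <- fixture$sites[[i]]
    rbindlist(lapply(fixture$samples, function(sm) {
      g <- st$gt[[sm]]
      if (is.null(g)) g <- c(NA_integer_, NA_integer_)
      data.table(site_id = i, sample = sm,
                 a1 = g[1], a2 = g[2], phased = FALSE, dp = 60L, gq = 99L,
                 ab = if (!anyNA(g) && g[1] != g[2]) 0.5 else NA_real_,
                 filt = st$filt %||% "PASS")
    }))
  }))
  cons <- rbindlist(lapply(seq_len(ns), function(i) {
    st <- fixture$sites[[i]]
    if (!length(st$cons)) return(NULL)
    rbindlist(lapply(st$cons, function(co) {
      data.table(site_id = i, allele_index = as.integer(co$allele),
                 transcript_id = co$transcript_id,
                 gene_id = co$gene_id %||% NA_character_,
                 consequence = "missense_variant",
                 protein_position = as.integer(co$protein_position),
                 amino_acids = co$amino_acids,
                 gnomad_af = co$gnomad_af %||% NA_real_,
                 existing_variation = st$id %||% NA_character_,
                 canonical = isTRUE(co$canonical))
    }))
  }))
  if (is.null(cons) || !nrow(cons))
    cons <- data.table(site_id = integer(), allele_index = integer(),
                       transcript_id = character(), gene_id = character(),
                       consequence = character(), protein_position = integer(),
                       amino_acids = character(), gnomad_af = numeric(),
                       existing_variation = character(), canonical = logical())
  allo_variants(variants, calls, cons, samples = fixture$samples)
}

#' Sibling-pair error-injection experiment
#'
#' The package's accuracy validation: simulate a family under `cfg`, score
#' every unordered sibling pair twice through the production path
#' ([compute_ams()], SOT direction, stringent mode, AF gate open) - once on
#' the true genotypes and once on the error-injected observed genotypes -
#' and summarise the agreement.
#'
#' @param seed integer seed for the simulation.
#' @param cfg a [sim_config()]; defaults to the validation scenario
#'   (20,000 sites, 15 siblings, error rate 5e-4).
#' @return list with `true` and `observed` score vectors (one entry per
#'   sibling pair), `pearson_r`, `pct_within_2` (percentage of pairs whose
#'   relative difference is below 2%) and `n_pairs`.
#' @export
sibling_error_experiment <- function(seed, cfg = sim_config(seed = seed)) {
  sim <- simulate_family(cfg, compute_truth = FALSE)
  xt <- family_to_variants(sim, genotypes = "true")
  xo <- family_to_variants(sim, genotypes = "observed")
  f0 <- filter_config(min_gnomad_af = 0)
  prs <- utils::combn(sim$children, 2)
  score <- function(x, d, r)
    compute_ams(x, donor_sample = d, recipient_sample = r,
                direction = "SOT", missing = "stringent", filters = f0)$ams
  true <- apply(prs, 2, function(p) score(xt, p[1], p[2]))
  obs <- apply(prs, 2, function(p) score(xo, p[1], p[2]))
  list(true = true, observed = obs,
       pearson_r = stats::cor(true, obs),
       pct_within_2 = 100 * mean(abs(obs - true) / true < 0.02),
       n_pairs = ncol(prs))
}
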