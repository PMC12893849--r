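## Independent brute-force scoring oracle.
##
## This module deliberately shares no code with the production scoring path
## (R/ams.R): it works on plain-list fixtures with naive nested loops and
## base-R set operations, so that agreement between the two is evidence of
## correctness rather than of shared bugs.

#' Brute-force directional mismatch score on a plain-list fixture
#'
#' Naive reference evaluator: loops over sites, materialises each sample's
#' amino-acid set per annotated (transcript, protein position) and takes set
#' differences.  Used as the ground-truth oracle in tests; intended for
#' small fixtures (every site visited with nested loops).
#'
#' Fixture format: `list(samples = <names>, sites = <list>)`, each site a
#' list with `chrom`, `pos`, `id`, `ref`, `alts`, `gt` (named list of
#' length-2 integer vectors, `NA` for missing) and `cons` (list of lists
#' with `transcript_id`, `allele` (1-based ALT number), `protein_position`,
#' `amino_acids` `"A/V"`, `gnomad_af`, `canonical`).
#'
#' @param fixture fixture list (see [random_fixture()]).
#' @param donor,recipient sample names inside the fixture genotypes.
#' @param direction `"SOT"` or `"HCT"`.
#' @param missing `"stringent"` or `"impute"`.
#' @param min_af,drop_af_absent gnomAD AF gate, as in [filter_config()].
#' @param counting `"canonical"`, `"per_transcript"` or `"binary_site"`.
#' @return integer score.
#' @export
oracle_ams <- function(fixture, donor = "DONOR", recipient = "RECIPIENT",
                       direction = "SOT", missing = "stringent",
                       min_af = 0, drop_af_absent = FALSE,
                       counting = "canonical") {
  total <- 0L
  for (site in fixture$sites) {
    ## --- AF gate (site level) ---
    afs <- unlist(lapply(site$cons, function(co) co$gnomad_af))
    afs <- afs[!is.na(afs)]
    if (length(afs) == 0) {
      if (drop_af_absent) next
    } else if (max(afs) < min_af) next

    gd <- site$gt[[donor]]; gr <- site$gt[[recipient]]
    if (is.null(gd)) gd <- c(NA_integer_, NA_integer_)
    if (is.null(gr)) gr <- c(NA_integer_, NA_integer_)
    if (anyNA(gd) || anyNA(gr)) {
      if (missing == "stringent") next
      if (anyNA(gd)) gd <- c(0L, 0L)
      if (anyNA(gr)) gr <- c(0L, 0L)
    }

    ## --- usable consequences: well-formed single-residue substitutions ---
    usable <- Filter(function(co) {
      !is.null(co$amino_acids) && !is.na(co$amino_acids) &&
        grepl("^[A-Z]/[A-Z]$", co$amino_acids) &&
        !is.null(co$protein_position) && !is.na(co$protein_position)
    }, site$cons)
    if (!length(usable)) next

    ## --- counting scope ---
    txs <- unique(vapply(usable, function(co) co$transcript_id, ""))
    if (counting == "canonical") {
      can <- unique(vapply(Filter(function(co) isTRUE(co$canonical), usable),
                           function(co) co$transcript_id, ""))
      txs <- if (length(can)) can else min(txs)
    }

    site_contrib <- 0L
    for (tx in txs) {
      tx_cons <- Filter(function(co) co$transcript_id == tx, usable)
      pps <- unique(vapply(tx_cons, function(co) co$protein_position, 0))
      for (pp in pps) {
        grp <- Filter(function(co) co$protein_position == pp, tx_cons)
        ref_aa <- substr(grp[[1]]$amino_acids, 1, 1)
        aa_of <- function(a) {
          if (a == 0L) return(ref_aa)
          for (co in grp) if (co$allele == a)
            return(substr(co$amino_acids, 3, 3))
          ref_aa                      # allele with no annotated consequence
        }
        S <- unique(c(aa_of(gd[1]), aa_of(gd[2])))
        T_ <- unique(c(aa_of(gr[1]), aa_of(gr[2])))
        if (direction == "HCT") { tmp <- S; S <- T_; T_ <- tmp }
        site_contrib <- site_contrib + length(setdiff(S, T_))
      }
    }
    total <- total + if (counting == "binary_site") as.integer(site_contrib > 0L)
                     else site_contrib
  }
  total
}

#' Genotype-dosage contribution table derived from the naive oracle
#'
#' For a biallelic missense site with distinct reference/alternate amino
#' acids, the per-site mismatch contribution depends only on the two
#' samples' alt-allele dosages.  This enumerates all nine dosage pairs
#' through the naive set-difference logic and returns the 3x3 lookup
#' (rows: donor dosage 0..2, columns: recipient dosage 0..2).
#'
#' @param direction `"SOT"` or `"HCT"`.
#' @return integer 3x3 matrix.
#' @export
oracle_contrib_table <- function(direction = "SOT") {
  sets <- list(c("R"), c("R", "A"), c("A"))   # dosage 0 / 1 / 2
  M <- matrix(0L, 3, 3)
  for (gd in 0:2) for (gr in 0:2) {
    S <- if (direction == "SOT") sets[[gd + 1]] else sets[[gr + 1]]
    T_ <- if (direction == "SOT") sets[[gr + 1]] else sets[[gd + 1]]
    M[gd + 1, gr + 1] <- length(setdiff(S, T_))
  }
  M
}

#' Oracle score for a pair of biallelic dosage vectors
#'
#' Fast, allocation-free application of [oracle_contrib_table()]; the truth
#' engine for the family simulator (all sites biallelic missense with
#' distinct amino acids).
#'
#' @param g_donor,g_recipient integer vectors of alt-allele dosages (0, 1,
#'   2; `NA` = missing).
#' @param direction `"SOT"` or `"HCT"`.
#' @param missing `"stringent"` (sites with any `NA` contribute 0) or
#'   `"impute"` (`NA` treated as dosage 0).
#' @return integer score.
#' @export
oracle_family_ams <- function(g_donor, g_recipient, direction = "SOT",
                              missing = "stringent") {
  stopifnot(length(g_donor) == length(g_recipient))
  M <- oracle_contrib_table(direction)
  gd <- g_donor; gr <- g_recipient
  na <- is.na(gd) | is.na(gr)
  if (missing == "stringent") {
    gd <- gd[!na]; gr <- gr[!na]
  } else {
    gd[is.na(gd)] <- 0L; gr[is.na(gr)] <- 0L
  }
  if (!length(gd)) return(0L)
  sum(M[cbind(gd + 1L, gr + 1L)])
}
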