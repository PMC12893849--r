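## Directional amino-acid comparison and the Allogenomics Mismatch Score.
##
## Direction semantics: the SOT direction counts amino acids present in the
## donor but absent in the recipient (host-versus-graft relevance); the HCT
## direction counts those present in the recipient but absent in the donor
## (graft-versus-host relevance).  The comparison is a set difference of the
## amino acids encoded by each sample's two alleles at every annotated
## (transcript, protein position).

#' Amino acids encoded by one genotype at one annotated protein position
#'
#' Allele index 0 contributes the reference amino acid (left-hand side of the
#' `"A/V"` pair); allele index i contributes the alternate amino acid of the
#' consequence annotated for ALT i.  An allele with no matching consequence
#' at a site that has consequences for other alleles is treated as the
#' reference amino acid.  Homozygous genotypes yield a singleton set.
#'
#' @param alleles integer vector of length 2 (GT allele indices); must not be
#'   missing.
#' @param ref_aa reference amino acid (single letter).
#' @param alt_aa named character vector mapping allele index (as character,
#'   e.g. `"1"`, `"2"`) to the alternate amino acid.
#' @return character vector (a set) of amino acids.
#' @export
aa_set <- function(alleles, ref_aa, alt_aa = character()) {
  stopifnot(length(alleles) == 2, !anyNA(alleles))
  aa <- vapply(alleles, function(a) {
    if (a == 0L) return(ref_aa)
    hit <- alt_aa[as.character(a)]
    if (is.na(hit)) ref_aa else unname(hit)
  }, character(1))
  unique(aa)
}

#' Directional mismatch between two amino-acid sets
#'
#' @param source,target character vectors (amino-acid sets) for the
#'   direction's source and target sample.
#' @return `setdiff(source, target)` - the amino acids the source carries
#'   that the target lacks.
#' @export
directional_mismatch <- function(source, target) setdiff(source, target)

## ---------------------------------------------------------------------------

#' Restrict a variant set to regions, rsIDs and/or transcripts
#'
#' A site survives iff (no BED given OR it falls in an interval) AND (no rsID
#' list given OR its ID is listed).  The transcript restriction removes
#' consequences for unlisted transcripts and keeps the site only if some
#' consequence remains.
#'
#' @param x an `allo_variants` object.
#' @param bed `NULL`, a path to a BED file, or a data.frame with columns
#'   `chrom`, `start`, `end` (0-based half-open, as in BED).
#' @param rsids `NULL`, a path to a one-ID-per-line file, or a character
#'   vector of rsIDs.
#' @param transcripts `NULL`, a path, or a character vector of transcript IDs.
#' @return the restricted `allo_variants`.
#' @export
restrict <- function(x, bed = NULL, rsids = NULL, transcripts = NULL) {
  stopifnot(inherits(x, "allo_variants"))
  if (is.null(bed) && is.null(rsids) && is.null(transcripts)) return(x)
  keep <- x$variants$site_id
  if (!is.null(bed)) {
    b <- if (is.character(bed)) read_bed(bed) else as.data.table(bed)
    v <- x$variants
    hit <- vapply(seq_len(nrow(v)), function(i) {
      any(b$chrom == v$chrom[i] & b$start < v$pos[i] & v$pos[i] <= b$end)
    }, logical(1))
    keep <- intersect(keep, v$site_id[hit])
  }
  if (!is.null(rsids)) {
    ids <- if (length(rsids) == 1 && file.exists(rsids)) read_id_list(rsids) else rsids
    keep <- intersect(keep, x$variants[id %in% ids, site_id])
  }
  x <- subset_sites(x, keep)
  if (!is.null(transcripts)) {
    txs <- if (length(transcripts) == 1 && file.exists(transcripts))
      read_id_list(transcripts) else transcripts
    cons <- x$consequences[transcript_id %in% txs]
    keep <- intersect(x$variants$site_id, unique(cons$site_id))
    x <- allo_variants(x$variants[site_id %in% keep],
                       x$calls[site_id %in% keep], cons[site_id %in% keep],
                       samples = x$samples, csq_fields = x$csq_fields)
  }
  x
}

## ---------------------------------------------------------------------------
## compute_ams internals

## Scope the consequence table to rows that can contribute to the score:
## amino-acid-level substitutions only, under the configured counting rule.
scope_consequences <- function(cons, counting, include_stop_gained) {
  cm <- cons[!is.na(amino_acids) & !is.na(protein_position) &
               !is.na(allele_index)]
  ## require a well-formed single-residue substitution; '*' (stop gained)
  ## only through the escape hatch
  pat <- if (include_stop_gained) "^[A-Z*]/[A-Z*]$" else "^[A-Z]/[A-Z]$"
  cm <- cm[grepl(pat, amino_acids)]
  if (!nrow(cm)) return(cm)
  if (counting == "canonical") {
    ## one transcript per site: the canonical one(s), else the
    ## lexicographically smallest (deterministic fallback)
    cm[, has_can := any(canonical), by = site_id]
    cm[, min_tx := min(transcript_id), by = site_id]
    cm <- cm[(has_can & canonical == TRUE) | (!has_can & transcript_id == min_tx)]
    cm[, c("has_can", "min_tx") := NULL]
  }
  cm
}

## Pair-invariant preparation: AF gate, consequence scoping and the
## (group x allele index) -> amino-acid lookup matrix.  Column a+1 of
## `aa_mat` holds the amino acid contributed by genotype allele a at each
## (site, transcript, protein position) group; alleles without an annotated
## consequence fall back to the reference amino acid.  Cached on the object
## (keyed by the parameters it depends on) so scoring many pairs of a joint
## multi-sample input does the heavy lifting once.
ams_prep <- function(x, filters, counting, include_stop_gained) {
  key <- paste(filters$min_gnomad_af, filters$drop_af_absent, counting,
               include_stop_gained, sep = "|")
  cached <- if (is.environment(x$cache)) x$cache[[key]] else NULL
  if (!is.null(cached)) return(cached)

  ag <- af_gate(x, filters)
  setkey(ag, site_id)
  av <- x$variants$site_id
  u <- ag[list(av), keep]
  af_tally <- ag[keep == FALSE, .(sample = "site", reason, n = 1L)][
    , .(n = sum(n)), by = .(sample, reason)]

  cons <- scope_consequences(x$consequences, counting, include_stop_gained)
  prep <- list(universe = u, af_tally = af_tally, n_groups = 0L)
  if (nrow(cons)) {
    cons[, ref_aa := substr(amino_acids, 1L, 1L)]
    groups <- unique(cons[, .(site_id, transcript_id, protein_position, ref_aa)],
                     by = c("site_id", "transcript_id", "protein_position"))
    groups[, grp := .I]
    cons_alt <- unique(cons[, .(site_id, transcript_id, protein_position,
                                allele_index,
                                alt_aa = substr(amino_acids, 3L, 3L))],
                       by = c("site_id", "transcript_id", "protein_position",
                              "allele_index"))
    cons_alt[groups, on = c("site_id", "transcript_id", "protein_position"),
             grp := i.grp]
    max_a <- max(lengths(x$variants$alts), cons_alt$allele_index, 1L)
    aa_mat <- matrix(rep(groups$ref_aa, max_a + 1L),
                     nrow = nrow(groups), ncol = max_a + 1L)
    ok <- !is.na(cons_alt$allele_index)
    aa_mat[cbind(cons_alt$grp[ok], cons_alt$allele_index[ok] + 1L)] <-
      cons_alt$alt_aa[ok]
    gmap <- unique(cons[, .(site_id, transcript_id, gene_id)],
                   by = c("site_id", "transcript_id"))
    prep <- list(universe = u, af_tally = af_tally,
                 groups = groups, aa_mat = aa_mat,
                 gsite = match(groups$site_id, av), gmap = gmap,
                 n_groups = nrow(groups))
  }
  if (is.environment(x$cache)) x$cache[[key]] <- prep
  prep
}

## One sample's genotype vectors aligned to x$variants row order, with
## quality-rejected calls masked to missing.
sample_genotypes <- function(x, smp, filters) {
  cc <- quality_decision(x$calls[list(smp), on = "sample"], filters)
  idx <- match(x$variants$site_id, cc$site_id)
  list(a1 = fifelse(cc$keep[idx], cc$a1[idx], NA_integer_),
       a2 = fifelse(cc$keep[idx], cc$a2[idx], NA_integer_),
       tally = cc[keep == FALSE, .(n = .N), by = reason][, sample := smp])
}

#' Compute the directional Allogenomics Mismatch Score (AMS)
#'
#' Filters both samples, joins their sites on (chrom, pos, ref), compares
#' amino-acid sets per annotated (transcript, protein position) in the chosen
#' direction, and returns the integer AMS together with its per-mismatch
#' table and filter tallies.
#'
#' @param donor an `allo_variants` object.  If `recipient` is `NULL`, `donor`
#'   must be a joint multi-sample object and both sample names must be given.
#' @param recipient optional second `allo_variants` (single-sample inputs).
#' @param donor_sample,recipient_sample sample names.
#' @param direction `"SOT"` (mismatches present in the donor, absent in the
#'   recipient) or `"HCT"` (the reverse).
#' @param missing `"stringent"` (sites with any missing genotype in either
#'   sample contribute 0 and are tallied as masked) or `"impute"` (missing
#'   genotypes are treated as homozygous reference).
#' @param filters a [filter_config()].
#' @param bed,rsids,transcripts optional restrictions, see [restrict()].
#' @param counting `"canonical"` (default; one transcript per site - the
#'   canonical one, or the lexicographically smallest when none is flagged),
#'   `"per_transcript"` (count every annotated transcript), or
#'   `"binary_site"` (a site contributes at most 1).
#' @param include_stop_gained include stop-gain substitutions (`"Q/*"`)
#'   in the score; off by default (peptide reconstruction is undefined for
#'   truncations).
#' @return an object of class `ams_result`: list with `ams` (integer),
#'   `table` (one row per directional mismatch), `masked_sites`,
#'   `rejected_by_filter` (data.table sample/reason/n) and `config`.
#' @export
compute_ams <- function(donor, recipient = NULL,
                        donor_sample = NULL, recipient_sample = NULL,
                        direction = c("SOT", "HCT"),
                        missing = c("stringent", "impute"),
                        filters = filter_config(),
                        bed = NULL, rsids = NULL, transcripts = NULL,
                        counting = c("canonical", "per_transcript", "binary_site"),
                        include_stop_gained = FALSE) {
  direction <- match.arg(toupper(direction[1]), c("SOT", "HCT"))
  missing <- match.arg(tolower(missing[1]), c("stringent", "impute"))
  counting <- match.arg(counting)

  if (is.null(recipient)) {
    x <- donor
    if (is.null(donor_sample) || is.null(recipient_sample))
      stop("joint input: donor_sample and recipient_sample are required")
  } else {
    if (is.null(donor_sample)) donor_sample <- donor$samples[1]
    if (is.null(recipient_sample)) recipient_sample <- recipient$samples[1]
    if (identical(donor_sample, recipient_sample)) {
      ## same name in both files (e.g. self-comparison): disambiguate
      new <- paste0(recipient_sample, ".recipient")
      recipient <- allo_variants(recipient$variants,
                                 copy(recipient$calls)[sample == recipient_sample,
                                                       sample := new],
                                 recipient$consequences,
                                 samples = replace(recipient$samples,
                                                   recipient$samples == recipient_sample,
                                                   new),
                                 csq_fields = recipient$csq_fields)
      recipient_sample <- new
    }
    x <- merge_pair(donor, recipient, donor_sample, recipient_sample)
  }
  for (s in c(donor_sample, recipient_sample))
    if (!s %in% x$samples)
      stop("sample '", s, "' not found; available: ",
           paste(x$samples, collapse = ", "))
  x <- dedupe_sites(x)
  x <- restrict(x, bed = bed, rsids = rsids, transcripts = transcripts)

  prep <- ams_prep(x, filters, counting, include_stop_gained)
  d <- sample_genotypes(x, donor_sample, filters)
  r <- sample_genotypes(x, recipient_sample, filters)
  rejected <- rbind(prep$af_tally,
                    d$tally[, .(sample, reason, n)],
                    r$tally[, .(sample, reason, n)], fill = TRUE)
  rejected <- rejected[, .(n = sum(n)), by = .(sample, reason)]

  ## missing-genotype handling over the AF-surviving universe
  u <- prep$universe
  miss <- is.na(d$a1) | is.na(r$a1)
  masked <- 0L
  if (missing == "stringent") {
    masked <- sum(u & miss, na.rm = TRUE)
    active <- u & !miss
  } else {
    active <- u
    d$a1[is.na(d$a1)] <- 0L; d$a2[is.na(d$a2)] <- 0L
    r$a1[is.na(r$a1)] <- 0L; r$a2[is.na(r$a2)] <- 0L
  }
  active[is.na(active)] <- FALSE

  empty_tab <- data.table(chrom = character(), pos = integer(),
                          rsid = character(), transcript_id = character(),
                          gene_id = character(), protein_position = integer(),
                          ref_aa = character(), source_aas = character(),
                          target_aas = character(), mismatch_aas = character(),
                          direction = character(), contribution = integer())
  cfg <- list(direction = direction, missing = missing, filters = filters,
              counting = counting, include_stop_gained = include_stop_gained,
              donor_sample = donor_sample, recipient_sample = recipient_sample)
  if (!prep$n_groups) {
    return(structure(list(ams = 0L, table = empty_tab, masked_sites = masked,
                          rejected_by_filter = rejected, config = cfg),
                     class = "ams_result"))
  }

  ## per-group amino acids by direct matrix lookup (no joins)
  gi <- which(active[prep$gsite])             # active group rows
  gs <- prep$gsite[gi]                        # their site index
  aa_of <- function(a) prep$aa_mat[cbind(gi, a[gs] + 1L)]
  if (direction == "SOT") {
    s1 <- aa_of(d$a1); s2 <- aa_of(d$a2); t1 <- aa_of(r$a1); t2 <- aa_of(r$a2)
  } else {
    s1 <- aa_of(r$a1); s2 <- aa_of(r$a2); t1 <- aa_of(d$a1); t2 <- aa_of(d$a2)
  }
  m1 <- s1 != t1 & s1 != t2                      # s1 missing from target set
  m2 <- s2 != s1 & s2 != t1 & s2 != t2           # s2 distinct and missing
  contrib <- as.integer(m1) + as.integer(m2)

  hit <- which(contrib > 0L)
  if (length(hit)) {
    tab <- prep$groups[gi[hit],
                       .(site_id, transcript_id, protein_position, ref_aa)]
    collapse_set <- function(a, b)
      fifelse(a == b, a, paste(pmin(a, b), pmax(a, b), sep = "/"))
    tab[, `:=`(source_aas = collapse_set(s1[hit], s2[hit]),
               target_aas = collapse_set(t1[hit], t2[hit]),
               mismatch_aas = fifelse(m1[hit] & m2[hit],
                                      collapse_set(s1[hit], s2[hit]),
                                      fifelse(m1[hit], s1[hit], s2[hit])),
               contribution = contrib[hit])]
    meta <- x$variants[, .(site_id, chrom, pos, rsid = id)]
    tab <- prep$gmap[tab, on = c("site_id", "transcript_id")]
    tab <- meta[tab, on = "site_id"]
    tab[, direction := cfg$direction]
    tab <- tab[, .(chrom, pos, rsid, transcript_id, gene_id, protein_position,
                   ref_aa, source_aas, target_aas, mismatch_aas, direction,
                   contribution, site_id)]
  } else {
    tab <- copy(empty_tab)[, site_id := integer()]
  }

  if (counting == "binary_site" && nrow(tab)) {
    ## one row per site; mismatch amino acids unioned across transcripts
    tab <- tab[, {
      aas <- sort(unique(unlist(strsplit(mismatch_aas, "/", fixed = TRUE))))
      c(.SD[1L, .(chrom, pos, rsid, transcript_id, gene_id, protein_position,
                  ref_aa, source_aas, target_aas)],
        list(mismatch_aas = paste(aas, collapse = "/"),
             direction = direction[1L], contribution = 1L))
    }, by = site_id][, names(empty_tab), with = FALSE]
  } else {
    tab[, site_id := NULL]
  }
  setorder(tab, chrom, pos, transcript_id)
  setkey(tab, NULL)
  structure(list(ams = sum(tab$contribution), table = tab,
                 masked_sites = masked, rejected_by_filter = rejected,
                 config = cfg),
            class = "ams_result")
}

#' @export
print.ams_result <- function(x, ...) {
  cat(sprintf("AMS (%s, %s, counting=%s): %d\n", x$config$direction,
              x$config$missing, x$config$counting, x$ams))
  cat(sprintf("  mismatch rows: %d; masked sites: %d; filter rejections: %d\n",
              nrow(x$table), x$masked_sites,
              sum(x$rejected_by_filter$n %||% 0L)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a
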