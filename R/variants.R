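#' In-memory variant model
#'
#' An `allo_variants` object holds the parsed content of one (possibly
#' multi-sample) VEP-annotated VCF: one row per site in `$variants`, one row
#' per (site, sample) genotype call in `$calls`, and one row per VEP
#' consequence in `$consequences`.  Multi-allelic sites are kept as single
#' records; per-ALT consequences are attached through `allele_index` (the GT
#' allele number: 1 = first ALT, 0 = REF which never carries a consequence).
#'
#' @param variants data.table with columns `site_id`, `chrom`, `pos`, `id`
#'   (rsID or `NA`), `ref`, `alts` (list column of character vectors),
#'   `filt` (FILTER string).
#' @param calls data.table with columns `site_id`, `sample`, `a1`, `a2`
#'   (integer allele indices, `NA` = missing), `phased`, `dp`, `gq`, `ab`
#'   (alt-allele depth fraction for heterozygous calls, else `NA`), `filt`.
#' @param consequences data.table with columns `site_id`, `allele_index`,
#'   `transcript_id`, `gene_id`, `consequence` (`&`-joined SO terms),
#'   `protein_position`, `amino_acids` (`"A/V"` style or `NA`), `gnomad_af`,
#'   `existing_variation`, `canonical`.
#' @param samples character vector of sample names present in `calls`.
#' @param csq_fields character vector of CSQ subfield names (provenance).
#' @return an object of class `allo_variants`.
#' @export
allo_variants <- function(variants, calls, consequences,
                          samples = unique(calls$sample),
                          csq_fields = character()) {
  variants <- as.data.table(variants)
  calls <- as.data.table(calls)
  consequences <- as.data.table(consequences)
  stopifnot(
    all(c("site_id", "chrom", "pos", "id", "ref", "alts", "filt") %in%
          names(variants)),
    all(c("site_id", "sample", "a1", "a2") %in% names(calls)),
    all(c("site_id", "allele_index", "transcript_id", "protein_position",
          "amino_acids", "gnomad_af") %in% names(consequences))
  )
  for (col in c("phased")) if (!col %in% names(calls)) calls[, (col) := FALSE]
  for (col in c("dp", "gq")) if (!col %in% names(calls)) calls[, (col) := NA_integer_]
  if (!"ab" %in% names(calls)) calls[, ab := NA_real_]
  if (!"filt" %in% names(calls)) calls[, filt := "PASS"]
  if (!"gene_id" %in% names(consequences)) consequences[, gene_id := NA_character_]
  if (!"consequence" %in% names(consequences)) consequences[, consequence := NA_character_]
  if (!"existing_variation" %in% names(consequences)) consequences[, existing_variation := NA_character_]
  if (!"canonical" %in% names(consequences)) consequences[, canonical := TRUE]
  if (nrow(variants)) {
    bad <- consequences[!is.na(allele_index)][
      variants, on = "site_id", nomatch = NULL][
        allele_index > lengths(alts) | allele_index < 1L]
    if (nrow(bad))
      stop("consequence allele_index out of range for site(s) ",
           paste(head(unique(bad$site_id), 5), collapse = ", "))
    if (any(variants$pos < 1L)) stop("variant pos must be >= 1")
    if (any(!nzchar(variants$ref)) ||
        any(vapply(variants$alts, function(a) any(!nzchar(a)), logical(1))))
      stop("REF and ALT alleles must be non-empty")
  }
  structure(list(variants = variants, calls = calls,
                 consequences = consequences, samples = samples,
                 csq_fields = csq_fields,
                 cache = new.env(parent = emptyenv())),
            class = "allo_variants")
}

#' @export
print.allo_variants <- function(x, ...) {
  cat(sprintf("allo_variants: %d site(s), %d sample(s) [%s], %d consequence row(s)\n",
              nrow(x$variants), length(x$samples),
              paste(head(x$samples, 6), collapse = ", "),
              nrow(x$consequences)))
  invisible(x)
}

#' Number of sites
#' @param x an `allo_variants` object
#' @export
n_sites <- function(x) nrow(x$variants)

## Drop duplicated (chrom, pos, ref) sites, keeping the first; warn.
dedupe_sites <- function(x) {
  v <- x$variants
  dup <- duplicated(v, by = c("chrom", "pos", "ref"))
  if (!any(dup)) return(x)
  warning(sum(dup), " duplicate (chrom, pos, ref) site(s); keeping first")
  keep_ids <- v$site_id[!dup]
  subset_sites(x, keep_ids)
}

subset_sites <- function(x, site_ids) {
  allo_variants(x$variants[site_id %in% site_ids],
                x$calls[site_id %in% site_ids],
                x$consequences[site_id %in% site_ids],
                samples = x$samples, csq_fields = x$csq_fields)
}

#' Merge a donor and a recipient single-sample object into one joint object
#'
#' Sites are joined on (chrom, pos, ref); ALT lists may differ between the two
#' inputs and are unioned, with the recipient's allele indices (calls and
#' consequences) remapped onto the union.  A site present in only one input
#' becomes a missing-genotype site for the other sample, to be resolved by the
#' missing-data mode downstream.
#'
#' @param donor,recipient `allo_variants` objects.
#' @param donor_sample,recipient_sample sample names to take from each input
#'   (default: the single sample of each).
#' @return a joint `allo_variants` with samples `c(donor_sample, recipient_sample)`.
#' @export
merge_pair <- function(donor, recipient,
                       donor_sample = donor$samples[1],
                       recipient_sample = recipient$samples[1]) {
  stopifnot(inherits(donor, "allo_variants"), inherits(recipient, "allo_variants"))
  if (!donor_sample %in% donor$samples)
    stop("donor sample '", donor_sample, "' not found; available: ",
         paste(donor$samples, collapse = ", "))
  if (!recipient_sample %in% recipient$samples)
    stop("recipient sample '", recipient_sample, "' not found; available: ",
         paste(recipient$samples, collapse = ", "))
  if (identical(donor_sample, recipient_sample))
    stop("donor and recipient sample names must differ in a joint object")
  cd <- unique(donor$variants$chrom); cr <- unique(recipient$variants$chrom)
  if (length(cd) && length(cr) && !length(intersect(cd, cr)))
    stop("contig names do not overlap between donor (", paste(head(cd, 3), collapse = ","),
         ") and recipient (", paste(head(cr, 3), collapse = ","),
         "): inputs look like different reference builds")
  donor <- dedupe_sites(donor); recipient <- dedupe_sites(recipient)

  vd <- copy(donor$variants)[, .(chrom, pos, ref, id_d = id, alts_d = alts,
                                 filt_d = filt, sid_d = site_id)]
  vr <- copy(recipient$variants)[, .(chrom, pos, ref, id_r = id, alts_r = alts,
                                     filt_r = filt, sid_r = site_id)]
  m <- merge(vd, vr, by = c("chrom", "pos", "ref"), all = TRUE)
  setorder(m, chrom, pos, ref)
  m[, site_id := seq_len(.N)]

  ## union ALTs (donor order first, then novel recipient ALTs)
  m[, alts := mapply(function(a, b) {
    if (is.null(a)) b else if (is.null(b)) a else c(a, setdiff(b, a))
  }, alts_d, alts_r, SIMPLIFY = FALSE)]
  ## recipient allele remap: old recipient index -> index in union
  remap_r <- mapply(function(b, u) if (is.null(b)) integer() else match(b, u),
                    m$alts_r, m$alts, SIMPLIFY = FALSE)

  map_d <- m[!is.na(sid_d), .(old = sid_d, new = site_id)]
  map_r <- m[!is.na(sid_r), .(old = sid_r, new = site_id)]

  remap_calls <- function(calls, map, remap = NULL) {
    cc <- calls[map, on = c(site_id = "old")]
    cc[, site_id := new][, new := NULL]
    if (!is.null(remap)) {
      idx <- match(cc$site_id, m$site_id)
      remap1 <- function(a, r) if (is.na(a) || a == 0L) a else r[a]
      cc[, a1 := as.integer(mapply(remap1, a1, remap[idx]))]
      cc[, a2 := as.integer(mapply(remap1, a2, remap[idx]))]
    }
    cc
  }
  cd2 <- remap_calls(donor$calls[sample == donor_sample], map_d)
  cr2 <- remap_calls(recipient$calls[sample == recipient_sample], map_r, remap_r)
  cr2[, sample := recipient_sample]

  ## pad missing-genotype rows for sites absent from one input
  pad <- function(smp, have, filt_col) {
    miss <- setdiff(m$site_id, have)
    if (!length(miss)) return(NULL)
    data.table(site_id = miss, sample = smp, a1 = NA_integer_, a2 = NA_integer_,
               phased = FALSE, dp = NA_integer_, gq = NA_integer_,
               ab = NA_real_, filt = "PASS")
  }
  calls <- rbind(cd2, cr2,
                 pad(donor_sample, cd2$site_id),
                 pad(recipient_sample, cr2$site_id),
                 fill = TRUE)

  remap_cons <- function(cons, map, remap = NULL) {
    cc <- cons[map, on = c(site_id = "old"), nomatch = NULL]
    cc[, site_id := new][, new := NULL]
    if (!is.null(remap) && nrow(cc)) {
      idx <- match(cc$site_id, m$site_id)
      cc[, allele_index := mapply(function(a, r) if (is.na(a)) NA_integer_ else r[a],
                                  allele_index, remap[idx])]
    }
    cc
  }
  cons <- rbind(remap_cons(donor$consequences, map_d),
                remap_cons(recipient$consequences, map_r, remap_r),
                fill = TRUE)
  cons <- unique(cons, by = c("site_id", "transcript_id", "allele_index",
                              "protein_position"))

  variants <- m[, .(site_id, chrom, pos,
                    id = fifelse(is.na(id_d), id_r, id_d),
                    ref, alts, filt = fifelse(is.na(filt_d), filt_r, filt_d))]
  allo_variants(variants, calls, cons,
                samples = c(donor_sample, recipient_sample),
                csq_fields = donor$csq_fields)
}
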