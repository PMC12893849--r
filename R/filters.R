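#' Quality-filter configuration
#'
#' Thresholds for the per-sample data-cleaning step applied before the two
#' samples are compared.  The gnomAD allele-frequency gate defaults to 1%
#' (the tool's documented default); the remaining thresholds are
#' repository-chosen defaults typical of germline short-variant QC and are
#' all user-configurable.
#'
#' @param require_pass reject sites whose FILTER is neither `PASS` nor `.`.
#' @param min_depth minimum read depth (DP), reads.
#' @param min_gq minimum genotype quality (GQ), Phred.
#' @param het_ab_range closed interval of acceptable alt-allele depth
#'   fraction for heterozygous calls.
#' @param min_gnomad_af minimum gnomAD exome allele frequency; sites whose
#'   consequences all fall below it are excluded. Set to 0 to keep rare
#'   variants.
#' @param drop_af_absent if `TRUE`, also exclude sites with no gnomAD AF
#'   annotation at all (absence is distinct from a frequency of 0).
#' @return a `filter_config` list.
#' @export
filter_config <- function(require_pass = TRUE, min_depth = 10L, min_gq = 20L,
                          het_ab_range = c(0.2, 0.8), min_gnomad_af = 0.01,
                          drop_af_absent = FALSE) {
  stopifnot(min_gnomad_af >= 0, min_gnomad_af <= 1,
            length(het_ab_range) == 2, het_ab_range[1] <= het_ab_range[2])
  structure(list(require_pass = require_pass, min_depth = as.integer(min_depth),
                 min_gq = as.integer(min_gq), het_ab_range = as.numeric(het_ab_range),
                 min_gnomad_af = as.numeric(min_gnomad_af),
                 drop_af_absent = isTRUE(drop_af_absent)),
            class = "filter_config")
}

## Vectorised per-(sample, site) quality decision on a calls table.
## Returns the calls table with `keep` and `reason` columns; the first
## failing check (in the order non_pass, low_depth, low_gq,
## allelic_imbalance) is reported.  A missing quality field with the
## corresponding check enabled counts as a failure of that check.
quality_decision <- function(calls, cfg) {
  cc <- copy(calls)
  cc[, `:=`(keep = TRUE, reason = NA_character_)]
  is_called <- !is.na(cc$a1)
  if (cfg$require_pass) {
    bad <- is_called & !(cc$filt %in% c("PASS", ".") | is.na(cc$filt))
    cc[bad, `:=`(keep = FALSE, reason = "non_pass")]
  }
  bad <- is_called & cc$keep & (is.na(cc$dp) | cc$dp < cfg$min_depth)
  cc[bad, `:=`(keep = FALSE, reason = "low_depth")]
  bad <- is_called & cc$keep & (is.na(cc$gq) | cc$gq < cfg$min_gq)
  cc[bad, `:=`(keep = FALSE, reason = "low_gq")]
  het <- is_called & cc$keep & cc$a1 != cc$a2
  bad <- het & (is.na(cc$ab) | cc$ab < cfg$het_ab_range[1] |
                  cc$ab > cfg$het_ab_range[2])
  cc[bad, `:=`(keep = FALSE, reason = "allelic_imbalance")]
  cc
}

#' Apply the per-sample quality filters to one sample of a variant set
#'
#' @param x an `allo_variants` object.
#' @param sample sample name.
#' @param cfg a [filter_config()].
#' @return data.table with `site_id`, `keep` and `reason`
#'   (`NA` when kept; one of `af_below_min`, `af_absent`, `non_pass`,
#'   `low_depth`, `low_gq`, `allelic_imbalance` when rejected).  The AF gate
#'   is sample-independent but reported here so the decision is total per
#'   (sample, site).  Missing genotypes are kept here (they are handled by
#'   the missing-data mode, not the filters).
#' @export
apply_filters <- function(x, sample = x$samples[1], cfg = filter_config()) {
  stopifnot(inherits(x, "allo_variants"))
  if (!sample %in% x$samples)
    stop("sample '", sample, "' not found; available: ",
         paste(x$samples, collapse = ", "))
  smp <- sample
  cc <- quality_decision(x$calls[list(smp), on = "sample"], cfg)
  ag <- af_gate(x, cfg)
  cc[ag, on = "site_id", `:=`(af_keep = i.keep, af_reason = i.reason)]
  cc[af_keep == FALSE, `:=`(keep = FALSE, reason = af_reason)]
  cc[, .(site_id, keep, reason)]
}

## Site-level gnomAD AF gate: a site is kept iff its maximum consequence AF
## reaches min_gnomad_af, or it has no AF annotation and drop_af_absent is
## FALSE.  Returns data.table(site_id, keep, reason).
af_gate <- function(x, cfg) {
  v <- x$variants[, .(site_id)]
  afs <- x$consequences[, .(af = if (all(is.na(gnomad_af))) NA_real_
                            else max(gnomad_af, na.rm = TRUE)),
                        by = site_id]
  v <- afs[v, on = "site_id"]
  v[, `:=`(keep = TRUE, reason = NA_character_)]
  v[!is.na(af) & af < cfg$min_gnomad_af,
    `:=`(keep = FALSE, reason = "af_below_min")]
  if (cfg$drop_af_absent)
    v[is.na(af), `:=`(keep = FALSE, reason = "af_absent")]
  v
}
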