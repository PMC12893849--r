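## File-format frontier: everything that touches VCF, FASTA, BED, TSV
## dialects lives here.  VCF parsing is delegated to VariantAnnotation;
## this module owns the CSQ subfield handling (always header-driven) and
## the mapping onto the internal `allo_variants` model.

#' Read a VEP-annotated VCF into the internal variant model
#'
#' The CSQ (or `csq_key`) INFO header line declares the pipe-delimited
#' subfield order, which is always taken from the header and never assumed.
#' Multi-allelic sites are retained as single records; each consequence is
#' attached to its ALT via the `ALLELE_NUM` subfield when present, otherwise
#' by matching the `Allele` subfield against the ALT alleles.
#'
#' @param path VCF 4.x file, plain or bgzipped.
#' @param samples optional character vector restricting to these samples; an
#'   absent sample is a hard error listing the available ones.
#' @param csq_key INFO key carrying the consequence annotation.
#' @param af_field CSQ subfield holding the gnomAD exome allele frequency;
#'   an empty value is recorded as `NA` (absence is distinct from 0).
#' @return an [allo_variants()] object, sites in file order.
#' @export
read_vep_vcf <- function(path, samples = NULL, csq_key = "CSQ",
                         af_field = "gnomADe_AF") {
  hdr <- VariantAnnotation::scanVcfHeader(path)
  avail <- VariantAnnotation::samples(hdr)
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, avail)
    if (length(missing_s))
      stop("sample(s) not in VCF header: ", paste(missing_s, collapse = ", "),
           "; available: ", paste(avail, collapse = ", "))
  }
  inf <- VariantAnnotation::info(hdr)
  if (!csq_key %in% rownames(inf))
    stop("no '", csq_key, "' INFO header line in ", path,
         ": input must be annotated with VEP-style consequences")
  desc <- inf[csq_key, "Description"]
  fields <- strsplit(sub('.*Format:\\s*', "", sub('"+$', "", desc)),
                     "|", fixed = TRUE)[[1]]

  param <- if (is.null(samples)) VariantAnnotation::ScanVcfParam()
           else VariantAnnotation::ScanVcfParam(samples = samples)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown", param = param)
  rr <- SummarizedExperiment::rowRanges(vcf)
  nv <- length(rr)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alts <- lapply(VariantAnnotation::alt(vcf), as.character)
  filt <- VariantAnnotation::filt(vcf)
  ## readVcf auto-names ID-less records "chrom:pos_ref/alt"
  ids <- names(rr)
  auto <- paste0(chrom, ":", pos, "_", ref, "/",
                 vapply(alts, paste, character(1), collapse = ","))
  ids[is.na(ids) | ids == "." | ids == auto] <- NA_character_

  variants <- data.table(site_id = seq_len(nv), chrom = chrom, pos = pos,
                         id = ids, ref = ref, alts = alts, filt = filt)

  ## ---- genotype calls -------------------------------------------------------
  g <- VariantAnnotation::geno(vcf)
  smp <- colnames(g$GT) %||% avail
  gt <- as.vector(g$GT)                      # column-major: all sites, sample 1, ...
  bad <- !grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$", gt)
  if (any(bad))
    stop("malformed genotype string '", gt[which(bad)[1]], "' at record ",
         ((which(bad)[1] - 1L) %% nv) + 1L)
  a <- tstrsplit(gt, "[/|]")
  a1 <- suppressWarnings(as.integer(a[[1]]))
  a2 <- if (length(a) > 1L) suppressWarnings(as.integer(a[[2]])) else a1
  half <- xor(is.na(a1), is.na(a2))          # half-calls treated as missing
  a1[half] <- NA_integer_; a2[half] <- NA_integer_
  phased <- grepl("|", gt, fixed = TRUE)

  num_mat <- function(key) {
    if (!key %in% names(g)) return(rep(NA_integer_, nv * length(smp)))
    as.vector(suppressWarnings(apply(g[[key]], 2, as.integer)))
  }
  dp <- num_mat("DP"); gq <- num_mat("GQ")
  ad <- if ("AD" %in% names(g)) {
    x <- g$AD
    if (length(dim(x)) == 3L) {
      lapply(seq_len(nv * length(smp)), function(i) {
        s <- ((i - 1L) %/% nv) + 1L; v <- ((i - 1L) %% nv) + 1L
        as.integer(x[v, s, ])
      })
    } else lapply(as.vector(x), function(e) suppressWarnings(as.integer(e)))
  } else vector("list", nv * length(smp))

  calls <- data.table(site_id = rep(seq_len(nv), times = length(smp)),
                      sample = rep(smp, each = nv),
                      a1 = a1, a2 = a2, phased = phased, dp = dp, gq = gq,
                      filt = rep(filt, times = length(smp)))
  ## allelic balance of het calls: depth fraction of the higher allele index
  calls[, ab := {
    het <- !is.na(a1) & a1 != a2
    abv <- rep(NA_real_, .N)
    ii <- which(het)
    abv[ii] <- vapply(ii, function(i) {
      v <- ad[[i]]
      hi <- max(a1[i], a2[i]) + 1L
      if (is.null(v) || anyNA(v) || length(v) < hi || sum(v) == 0) return(NA_real_)
      v[hi] / sum(v)
    }, numeric(1))
    abv
  }]

  ## ---- consequences ---------------------------------------------------------
  csq <- VariantAnnotation::info(vcf)[[csq_key]]
  cons <- parse_csq(csq, fields, variants, af_field)
  allo_variants(variants, calls, cons, samples = smp, csq_fields = fields)
}

## csq: CharacterList (one vector of pipe-strings per site)
parse_csq <- function(csq, fields, variants, af_field) {
  empty <- data.table(site_id = integer(), allele_index = integer(),
                      transcript_id = character(), gene_id = character(),
                      consequence = character(), protein_position = integer(),
                      amino_acids = character(), gnomad_af = numeric(),
                      existing_variation = character(), canonical = logical())
  lens <- lengths(csq)
  if (!sum(lens)) return(empty)
  entries <- unlist(csq, use.names = FALSE)
  site_of <- rep(seq_along(lens), times = lens)
  parts <- tstrsplit(entries, "|", fixed = TRUE)
  length(parts) <- length(fields)                # pad truncated entries
  parts <- lapply(parts, function(p) {
    if (is.null(p)) rep(NA_character_, length(entries))
    else fifelse(is.na(p) | p == "", NA_character_, p)
  })
  names(parts) <- fields
  fld <- function(nm) parts[[nm]] %||% rep(NA_character_, length(entries))

  allele_index <- if ("ALLELE_NUM" %in% fields) {
    suppressWarnings(as.integer(fld("ALLELE_NUM")))
  } else {
    av <- fld("Allele")
    mapply(function(s, a) {
      i <- match(a, variants$alts[[s]])
      if (is.na(i)) NA_integer_ else i
    }, site_of, av)
  }
  if (anyNA(allele_index) && any(!is.na(fld("Amino_acids")[is.na(allele_index)])))
    warning("dropped ", sum(is.na(allele_index)),
            " consequence(s) whose Allele could not be matched to an ALT")

  pp <- fld("Protein_position")
  pp_int <- suppressWarnings(as.integer(sub("[-/].*$", "", pp)))
  data.table(
    site_id = site_of,
    allele_index = allele_index,
    transcript_id = fld("Feature"),
    gene_id = fifelse(is.na(fld("Gene")), fld("SYMBOL"), fld("Gene")),
    consequence = fld("Consequence"),
    protein_position = pp_int,
    amino_acids = fld("Amino_acids"),
    gnomad_af = suppressWarnings(as.numeric(fld(af_field))),
    existing_variation = fld("Existing_variation"),
    canonical = !is.na(fld("CANONICAL")) & fld("CANONICAL") == "YES"
  )[!is.na(allele_index)]
}

## ---------------------------------------------------------------------------

#' Write a pipeline table as deterministic TSV
#'
#' UTF-8, tab-separated, one header line; rows sorted by whichever of
#' (chrom, pos, transcript_id, peptide) are present so reruns are
#' byte-identical.  Round-trips losslessly through [read_allo_tsv()].
#'
#' @param rows data.frame / data.table (may have zero rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allo_tsv <- function(rows, path) {
  dt <- as.data.table(rows)
  keys <- intersect(c("chrom", "pos", "transcript_id", "peptide"), names(dt))
  if (length(keys) && nrow(dt)) setorderv(dt, keys)
  ok <- tryCatch({ fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA"); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' @rdname write_allo_tsv
#' @export
read_allo_tsv <- function(path) {
  fread(path, sep = "\t", na.strings = "NA", header = TRUE)
}

#' Read a BED file (0-based half-open intervals)
#'
#' Only the first three columns are used; `track`/`browser`/comment lines are
#' skipped.  A malformed line is a hard error naming its line number.
#'
#' @param path BED path.
#' @return data.table with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (length(f) < 3L || is.na(s) || is.na(e) || s < 0L || e < s)
      stop("malformed BED line ", i, " in ", path, ": '", lines[i], "'")
    j <- j + 1L
    out[[j]] <- data.table(chrom = f[1], start = s, end = e)
  }
  if (!j) return(data.table(chrom = character(), start = integer(),
                            end = integer()))
  rbindlist(out[seq_len(j)])
}

## One identifier per line; blank lines and '#' comments ignored.
read_id_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a protein FASTA keyed by transcript ID
#'
#' @param path FASTA of amino-acid sequences; record names are truncated at
#'   the first whitespace (Ensembl-peptide style).
#' @return named character vector of protein sequences.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}
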