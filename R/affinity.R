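## Peptide reconstruction around directional mismatches and HLA class I
## scoring through a pluggable predictor interface.  The packaged
## predictors are thin adapters: external NetMHCpan-4.1 / MixMHCpred /
## NetChop binaries are driven through their native file formats, and a
## deterministic mock predictor makes the whole pipeline runnable (and
## testable) without licensed software.

STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Reconstruct a protein sequence from the reference and substitutions
#'
#' Applies single-residue substitutions to the reference protein.  The
#' reference amino acid stated by each substitution must match the FASTA
#' residue at that position; a disagreement indicates an annotation/FASTA
#' build mismatch and is a hard error.
#'
#' @param reference reference protein sequence (string).
#' @param substitutions data.frame with columns `protein_position`,
#'   `ref_aa`, `alt_aa`; typically the focal mismatch plus any homozygous
#'   co-variants on the same transcript.
#' @param transcript_id used in error messages only.
#' @return the edited protein sequence (string).
#' @export
reconstruct_protein <- function(reference, substitutions,
                                transcript_id = "<unknown>") {
  s <- as.data.table(substitutions)
  if (!nrow(s)) return(reference)
  stopifnot(all(c("protein_position", "ref_aa", "alt_aa") %in% names(s)))
  L <- nchar(reference)
  for (i in seq_len(nrow(s))) {
    p <- s$protein_position[i]
    if (is.na(p) || p < 1L || p > L)
      stop("transcript ", transcript_id, ": protein position ", p,
           " outside protein of length ", L)
    have <- substr(reference, p, p)
    if (have != s$ref_aa[i])
      stop("transcript ", transcript_id, " position ", p,
           ": FASTA residue '", have, "' disagrees with annotated reference '",
           s$ref_aa[i], "' (annotation/FASTA build mismatch)")
  }
  out <- strsplit(reference, "")[[1]]
  out[s$protein_position] <- s$alt_aa
  paste(out, collapse = "")
}

#' Enumerate the sliding-window peptides covering one protein position
#'
#' Returns every length-`k` substring of `protein` covering position `p`:
#' `min(p, L - k + 1) - max(1, p - k + 1) + 1` peptides when `L >= k`,
#' none otherwise (windows are truncated at the protein termini, never
#' padded).
#'
#' @param protein protein sequence (string).
#' @param p 1-based position of the mismatched residue.
#' @param k peptide length.
#' @param transcript_id,source_aa,origin provenance carried into the records.
#' @return data.table with `sequence`, `length`, `transcript_id`,
#'   `protein_position`, `offset_in_peptide` (1-based position of the
#'   mismatched residue inside the peptide), `source_aa`, `origin`.
#' @export
window_peptides <- function(protein, p, k, transcript_id = NA_character_,
                            source_aa = substr(protein, p, p),
                            origin = NA_character_) {
  L <- nchar(protein)
  stopifnot(p >= 1, p <= L, k >= 1)
  empty <- data.table(sequence = character(), length = integer(),
                      transcript_id = character(), protein_position = integer(),
                      offset_in_peptide = integer(), source_aa = character(),
                      origin = character())
  if (L < k) return(empty)
  starts <- seq.int(max(1L, p - k + 1L), min(p, L - k + 1L))
  data.table(sequence = substring(protein, starts, starts + k - 1L),
             length = as.integer(k), transcript_id = transcript_id,
             protein_position = as.integer(p),
             offset_in_peptide = as.integer(p - starts + 1L),
             source_aa = source_aa, origin = origin)
}

#' Source-only peptides: remove any peptide also encoded by the target
#'
#' Exact string matching against the target sample's peptide set, which must
#' be built over the same (transcript, window range, length) coverage and
#' include peptides from all target alleles (including reference).
#'
#' @param source_peptides data.table from [window_peptides()].
#' @param target_kmers character vector of target peptide sequences.
#' @return the surviving rows of `source_peptides`.
#' @export
differential_peptides <- function(source_peptides, target_kmers) {
  source_peptides[!sequence %in% target_kmers]
}

## All k-mers of `protein` whose window covers position p (helper for
## building target sets; start range matches window_peptides).
covering_kmers <- function(protein, p, k) {
  L <- nchar(protein)
  if (L < k) return(character())
  starts <- seq.int(max(1L, p - k + 1L), min(p, L - k + 1L))
  substring(protein, starts, starts + k - 1L)
}

## ---------------------------------------------------------------------------
## Predictor adapters

#' Built-in deterministic mock HLA class I predictor
#'
#' Maps each (peptide, allele) pair to a reproducible pseudo-uniform
#' percent rank in \[0, 100\] via a string hash; the nM affinity is derived
#' monotonically on the conventional 1-50,000 nM scale.  Identical inputs
#' always give identical outputs, across sessions and platforms.
#'
#' @return a predictor object usable with [predict_affinity()].
#' @export
mock_predictor <- function() {
  structure(list(id = "mock"), class = c("mock_predictor", "allo_predictor"))
}

#' External NetMHCpan-4.1 adapter
#' @param path path to the `netMHCpan` executable.
#' @export
netmhcpan_predictor <- function(path = Sys.which("netMHCpan")) {
  structure(list(id = "netmhcpan-4.1", path = path),
            class = c("netmhcpan_predictor", "allo_predictor"))
}

#' External MixMHCpred adapter
#' @param path path to the `MixMHCpred` executable.
#' @export
mixmhcpred_predictor <- function(path = Sys.which("MixMHCpred")) {
  structure(list(id = "mixmhcpred", path = path),
            class = c("mixmhcpred_predictor", "allo_predictor"))
}

## deterministic hash of strings onto [0, 1)
det_hash01 <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (cc in utf8ToInt(s)) h <- (h * 131 + cc) %% 2147483647
    h / 2147483647
  }, numeric(1), USE.NAMES = FALSE)
}

#' Predict HLA class I affinity for peptides
#'
#' One record per (peptide, allele), order-stable: peptides in input order
#' crossed with alleles in input order.  A predictor that fails to return a
#' requested peptide is a hard error (no silent drops).
#'
#' @param peptides character vector of peptide sequences (8-14 residues for
#'   class I by convention; enforced).
#' @param hla_alleles character vector, e.g. `"HLA-A*02:01"`.
#' @param predictor a predictor object ([mock_predictor()],
#'   [netmhcpan_predictor()], [mixmhcpred_predictor()]).
#' @return data.table with `peptide`, `hla_allele`, `affinity_nm`,
#'   `percent_rank`.
#' @export
predict_affinity <- function(peptides, hla_alleles,
                             predictor = mock_predictor()) {
  stopifnot(inherits(predictor, "allo_predictor"))
  peptides <- as.character(peptides)
  if (length(peptides) && any(nchar(peptides) < 8L | nchar(peptides) > 14L))
    stop("class I peptides must be 8-14 residues long")
  if (!length(peptides) || !length(hla_alleles))
    return(data.table(peptide = character(), hla_allele = character(),
                      affinity_nm = numeric(), percent_rank = numeric()))
  out <- predictor_scores(predictor, peptides, hla_alleles)
  want <- CJ(peptide = unique(peptides), hla_allele = hla_alleles,
             sorted = FALSE)
  miss <- want[!out, on = c("peptide", "hla_allele")]
  if (nrow(miss))
    stop("predictor '", predictor$id, "' returned no score for ",
         nrow(miss), " (peptide, allele) pair(s), e.g. ",
         miss$peptide[1], " / ", miss$hla_allele[1])
  ## order-stable: input peptide order x input allele order
  grid <- data.table(peptide = rep(unique(peptides), each = length(hla_alleles)),
                     hla_allele = rep(hla_alleles, times = length(unique(peptides))))
  out[grid, on = c("peptide", "hla_allele")]
}

predictor_scores <- function(predictor, peptides, hla_alleles)
  UseMethod("predictor_scores")

#' @export
predictor_scores.mock_predictor <- function(predictor, peptides, hla_alleles) {
  grid <- data.table(peptide = rep(unique(peptides), each = length(hla_alleles)),
                     hla_allele = rep(hla_alleles, times = length(unique(peptides))))
  grid[, percent_rank := det_hash01(paste(peptide, hla_allele)) * 100]
  grid[, affinity_nm := exp(log(50000) * percent_rank / 100)]
  grid[]
}

#' @export
predictor_scores.netmhcpan_predictor <- function(predictor, peptides, hla_alleles) {
  if (!nzchar(predictor$path) || !file.exists(predictor$path))
    stop("netMHCpan executable not found; pass netmhcpan_predictor(path=...) ",
         "or use mock_predictor()")
  pepfile <- tempfile(fileext = ".pep"); on.exit(unlink(pepfile))
  writeLines(unique(peptides), pepfile)
  xls <- tempfile(fileext = ".xls"); on.exit(unlink(xls), add = TRUE)
  ## native peptide-list input; alleles comma-separated without '*'
  alle <- paste(gsub("*", "", hla_alleles, fixed = TRUE), collapse = ",")
  system2(predictor$path, c("-p", pepfile, "-a", alle, "-BA",
                            "-xls", "-xlsfile", xls), stdout = TRUE)
  if (!file.exists(xls)) stop("netMHCpan produced no output file")
  parse_netmhcpan_xls(xls, hla_alleles)
}

## The -xls output: line 1 = allele names over column blocks, line 2 =
## per-block column headers (incl. nM and Rank), then one row per peptide.
parse_netmhcpan_xls <- function(path, hla_alleles) {
  l1 <- strsplit(readLines(path, n = 2)[1], "\t")[[1]]
  tab <- fread(path, skip = 1, sep = "\t")
  if (!"Peptide" %in% names(tab))
    stop("unexpected netMHCpan output: no 'Peptide' column")
  blocks <- which(nzchar(l1))
  out <- vector("list", length(blocks))
  rk <- grep("^Rank", names(tab)); nm <- grep("^nM", names(tab))
  if (length(rk) < length(blocks))
    stop("unexpected netMHCpan output: missing Rank column(s)")
  for (i in seq_along(blocks)) {
    out[[i]] <- data.table(
      peptide = tab$Peptide,
      hla_allele = hla_alleles[i],
      affinity_nm = if (length(nm) >= i) as.numeric(tab[[nm[i]]]) else NA_real_,
      percent_rank = as.numeric(tab[[rk[i]]]))
  }
  rbindlist(out)
}

#' @export
predictor_scores.mixmhcpred_predictor <- function(predictor, peptides, hla_alleles) {
  if (!nzchar(predictor$path) || !file.exists(predictor$path))
    stop("MixMHCpred executable not found; pass mixmhcpred_predictor(path=...) ",
         "or use mock_predictor()")
  pepfile <- tempfile(fileext = ".pep"); on.exit(unlink(pepfile))
  writeLines(unique(peptides), pepfile)
  outfile <- tempfile(fileext = ".tsv"); on.exit(unlink(outfile), add = TRUE)
  alle <- paste(gsub("HLA-|\\*|:", "", hla_alleles), collapse = ",")
  system2(predictor$path, c("-i", pepfile, "-o", outfile, "-a", alle),
          stdout = TRUE)
  if (!file.exists(outfile)) stop("MixMHCpred produced no output file")
  tab <- fread(outfile, skip = "Peptide")
  if (!"Peptide" %in% names(tab))
    stop("unexpected MixMHCpred output: no 'Peptide' column")
  out <- vector("list", length(hla_alleles))
  for (i in seq_along(hla_alleles)) {
    col <- grep(paste0("^%Rank_"), names(tab), value = TRUE)[i]
    if (is.na(col)) stop("unexpected MixMHCpred output: missing %Rank column")
    out[[i]] <- data.table(peptide = tab$Peptide, hla_allele = hla_alleles[i],
                           affinity_nm = NA_real_,
                           percent_rank = as.numeric(tab[[col]]))
  }
  rbindlist(out)
}

## ---------------------------------------------------------------------------
## Proteasomal cleavage

#' Deterministic mock per-residue cleavage profile
#'
#' Stand-in for a NetChop run: a reproducible pseudo-uniform score in
#' \[0, 1\] per residue of the reconstructed protein.
#'
#' @param protein reconstructed protein sequence.
#' @param transcript_id provenance.
#' @return a `cleavage_profile`: list with `transcript_id` and `scores`
#'   (length `nchar(protein)`).
#' @export
mock_cleavage_profile <- function(protein, transcript_id = NA_character_) {
  L <- nchar(protein)
  scores <- det_hash01(paste(transcript_id, seq_len(L),
                             substring(protein, seq_len(L), seq_len(L))))
  structure(list(transcript_id = transcript_id, scores = scores),
            class = "cleavage_profile")
}

#' Per-residue cleavage profile from an external NetChop executable
#' @param protein reconstructed protein sequence.
#' @param transcript_id provenance.
#' @param path path to the `netchop` executable.
#' @export
netchop_cleavage_profile <- function(protein, transcript_id = NA_character_,
                                     path = Sys.which("netchop")) {
  if (!nzchar(path) || !file.exists(path))
    stop("netchop executable not found; pass path=... or use ",
         "mock_cleavage_profile()")
  fa <- tempfile(fileext = ".fsa"); on.exit(unlink(fa))
  writeLines(c(paste0(">", transcript_id), protein), fa)
  out <- system2(path, fa, stdout = TRUE)
  ## native output: pos / AA / C / score / ident columns after a dashed header
  rows <- grep("^\\s*[0-9]+\\s+[A-Z]\\s", out, value = TRUE)
  if (length(rows) != nchar(protein))
    stop("unexpected netchop output: got ", length(rows), " residue rows for a ",
         nchar(protein), "-residue protein")
  scores <- as.numeric(vapply(strsplit(trimws(rows), "\\s+"), `[`, "", 4L))
  structure(list(transcript_id = transcript_id, scores = scores),
            class = "cleavage_profile")
}

#' Filter peptides by predicted proteasomal cleavage at their C-terminus
#'
#' A peptide is retained iff the cleavage score at the protein position of
#' its C-terminal residue reaches `threshold` (the proteasome must cut
#' exactly there to liberate that terminus; 0.5 is the conventional cutoff).
#'
#' @param peptides data.table from [window_peptides()].
#' @param profile a `cleavage_profile` covering the peptides' protein.
#' @param threshold minimum score, default 0.5.
#' @return the surviving rows.
#' @export
cleavage_filter <- function(peptides, profile, threshold = 0.5) {
  stopifnot(inherits(profile, "cleavage_profile"))
  if (!nrow(peptides)) return(peptides)
  cterm <- peptides$protein_position - peptides$offset_in_peptide +
    peptides$length
  if (any(cterm > length(profile$scores)))
    stop("cleavage profile shorter than the peptides' protein")
  peptides[profile$scores[cterm] >= threshold]
}

## ---------------------------------------------------------------------------

#' Count affinity-filtered mismatch peptides (af-AMS)
#'
#' Marks each record as a binder under exactly one criterion (percent rank
#' or nM, boundary inclusive) and counts: by default the number of distinct
#' peptide sequences binding at least one supplied HLA allele;
#' `count = "pairs"` counts (peptide, allele) binder pairs instead.
#'
#' @param records data.table from [predict_affinity()] (optionally carrying
#'   peptide provenance columns, which are preserved).
#' @param rank_threshold percent-rank cutoff (default 2.0, the conventional
#'   weak-binder limit).  Set to `NULL` to use `nm_threshold`.
#' @param nm_threshold nM affinity cutoff, mutually exclusive with
#'   `rank_threshold`.
#' @param count `"peptides"` or `"pairs"`.
#' @return an `af_ams_result`: list with `af_ams`, `table` (records with a
#'   `binder` column), `thresholds`, `count_rule`.
#' @export
compute_af_ams <- function(records, rank_threshold = 2.0, nm_threshold = NULL,
                           count = c("peptides", "pairs")) {
  count <- match.arg(count)
  if (!is.null(rank_threshold) && !is.null(nm_threshold))
    stop("exactly one of rank_threshold / nm_threshold may be set")
  if (is.null(rank_threshold) && is.null(nm_threshold))
    stop("one of rank_threshold / nm_threshold is required")
  tab <- as.data.table(records)
  if (nrow(tab)) {
    tab[, binder := if (!is.null(rank_threshold)) percent_rank <= rank_threshold
        else affinity_nm <= nm_threshold]
  } else tab[, binder := logical()]
  af <- if (count == "peptides") uniqueN(tab[binder == TRUE, peptide])
        else nrow(tab[binder == TRUE])
  structure(list(af_ams = as.integer(af), table = tab[],
                 thresholds = list(rank = rank_threshold, nm = nm_threshold),
                 count_rule = count),
            class = "af_ams_result")
}

#' @export
print.af_ams_result <- function(x, ...) {
  thr <- if (!is.null(x$thresholds$rank))
    paste0("%rank <= ", x$thresholds$rank) else paste0("nM <= ", x$thresholds$nm)
  cat(sprintf("af-AMS (%s, counting %s): %d over %d scored record(s)\n",
              thr, x$count_rule, x$af_ams, nrow(x$table)))
  invisible(x)
}

## ---------------------------------------------------------------------------

#' Run the full affinity stage on an AMS table
#'
#' For every mismatch row and every requested length: reconstruct the
#' source-sample protein (reference background with the focal substitution;
#' see the methods vignette for the haplotype policy), enumerate the
#' sliding-window peptides covering the mismatch, remove every peptide also
#' encoded by the target sample's alleles over the same windows, optionally
#' apply the cleavage filter on the reconstructed protein, score the
#' survivors against the HLA alleles and count the af-AMS.  Peptides
#' containing non-standard residues are dropped with a warning.
#'
#' @param ams_table data.table as produced by [compute_ams()] (columns
#'   `transcript_id`, `protein_position`, `ref_aa`, `source_aas`,
#'   `target_aas`, `mismatch_aas`, plus provenance).
#' @param proteome named character vector of reference proteins keyed by
#'   transcript ID (see [read_proteome()]).
#' @param hla_alleles character vector of HLA class I alleles.
#' @param lengths integer vector of peptide lengths (default 9).
#' @param predictor a predictor object; default [mock_predictor()].
#' @param cleavage `NULL` (off), `"mock"`, or a function
#'   `(protein, transcript_id) -> cleavage_profile`.
#' @param cleavage_threshold see [cleavage_filter()].
#' @param rank_threshold,nm_threshold,count see [compute_af_ams()].
#' @return an `af_ams_result` whose `table` carries full peptide provenance;
#'   also `$peptides`, the plain peptide list ready for any external
#'   prediction tool.
#' @export
run_affinity <- function(ams_table, proteome, hla_alleles, lengths = 9L,
                         predictor = mock_predictor(), cleavage = NULL,
                         cleavage_threshold = 0.5, rank_threshold = 2.0,
                         nm_threshold = NULL, count = c("peptides", "pairs")) {
  tab <- as.data.table(ams_table)
  cleave_fun <- if (is.null(cleavage)) NULL
    else if (is.function(cleavage)) cleavage
    else if (identical(cleavage, "mock")) function(pr, tx) mock_cleavage_profile(pr, tx)
    else stop("cleavage must be NULL, \"mock\" or a function")
  peps <- vector("list", nrow(tab) * length(lengths))
  ii <- 0L
  for (r in seq_len(nrow(tab))) {
    tx <- tab$transcript_id[r]
    if (!tx %in% names(proteome))
      stop("transcript '", tx, "' absent from the protein FASTA")
    refp <- proteome[[tx]]
    p <- tab$protein_position[r]
    ref_aa <- tab$ref_aa[r]
    mis <- strsplit(tab$mismatch_aas[r], "/", fixed = TRUE)[[1]]
    targ <- strsplit(tab$target_aas[r], "/", fixed = TRUE)[[1]]
    for (k in lengths) {
      target_set <- unlist(lapply(targ, function(aa) {
        covering_kmers(reconstruct_protein(refp,
          data.table(protein_position = p, ref_aa = ref_aa, alt_aa = aa), tx),
          p, k)
      }))
      for (aa in mis) {
        src <- reconstruct_protein(refp,
          data.table(protein_position = p, ref_aa = ref_aa, alt_aa = aa), tx)
        w <- window_peptides(src, p, k, transcript_id = tx, source_aa = aa,
                             origin = tab$direction[r] %||% NA_character_)
        w <- differential_peptides(w, target_set)
        if (!is.null(cleave_fun) && nrow(w))
          w <- cleavage_filter(w, cleave_fun(src, tx), cleavage_threshold)
        if (nrow(w)) {
          w[, `:=`(chrom = tab$chrom[r] %||% NA_character_,
                   pos = tab$pos[r] %||% NA_integer_,
                   rsid = tab$rsid[r] %||% NA_character_,
                   gene_id = tab$gene_id[r] %||% NA_character_)]
          ii <- ii + 1L
          peps[[ii]] <- w
        }
      }
    }
  }
  peps <- if (ii) rbindlist(peps[seq_len(ii)]) else
    data.table(sequence = character(), length = integer(),
               transcript_id = character(), protein_position = integer(),
               offset_in_peptide = integer(), source_aa = character(),
               origin = character(), chrom = character(), pos = integer(),
               rsid = character(), gene_id = character())
  ns <- !grepl(paste0("^[", paste(STANDARD_AA, collapse = ""), "]+$"),
               peps$sequence)
  if (any(ns)) {
    warning("dropped ", sum(ns), " peptide(s) containing non-standard residues")
    peps <- peps[!ns]
  }
  scored <- predict_affinity(unique(peps$sequence), hla_alleles, predictor)
  full <- scored[peps, on = c(peptide = "sequence"), allow.cartesian = TRUE]
  res <- compute_af_ams(full, rank_threshold = rank_threshold,
                        nm_threshold = nm_threshold, count = count)
  res$peptides <- sort(unique(peps$sequence))
  res$predictor_id <- predictor$id
  res$hla_alleles <- hla_alleles
  res
}
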