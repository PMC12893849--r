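## Shared in-code fixtures.  Everything is generated at test time; no data
## files.

## The canonical three-site toy pair:
##   site1  donor 0/1 A/V, recipient 0/0   -> SOT mismatch {V}
##   site2  donor 1/1 G/R, recipient 0/1   -> HCT mismatch {G}
##   site3  donor ./.,     recipient 0/1 L/P (missing-mode behaviour)
toy_pair_fixture <- function() {
  list(samples = c("DONOR", "RECIPIENT"), sites = list(
    list(chrom = "chrS", pos = 100L, id = "rs1", ref = "A", alts = "T",
         filt = "PASS",
         gt = list(DONOR = c(0L, 1L), RECIPIENT = c(0L, 0L)),
         cons = list(list(transcript_id = "TX1", gene_id = "G1", allele = 1L,
                          protein_position = 10L, amino_acids = "A/V",
                          gnomad_af = 0.2, canonical = TRUE))),
    list(chrom = "chrS", pos = 200L, id = "rs2", ref = "G", alts = "C",
         filt = "PASS",
         gt = list(DONOR = c(1L, 1L), RECIPIENT = c(0L, 1L)),
         cons = list(list(transcript_id = "TX2", gene_id = "G2", allele = 1L,
                          protein_position = 7L, amino_acids = "G/R",
                          gnomad_af = 0.3, canonical = TRUE))),
    list(chrom = "chrS", pos = 300L, id = "rs3", ref = "T", alts = "G",
         filt = "PASS",
         gt = list(DONOR = c(NA_integer_, NA_integer_),
                   RECIPIENT = c(0L, 1L)),
         cons = list(list(transcript_id = "TX3", gene_id = "G3", allele = 1L,
                          protein_position = 4L, amino_acids = "L/P",
                          gnomad_af = 0.1, canonical = TRUE)))))
}

## Write a small VEP-annotated VCF from explicit body lines.
## body rows: list(chrom, pos, id, ref, alt (comma string), filt, csq
## (full CSQ= value), gt strings per sample)
write_mini_vcf <- function(path, samples, rows,
                           csq_fields = c("Allele", "Consequence", "Gene",
                                          "Feature", "Protein_position",
                                          "Amino_acids", "Existing_variation",
                                          "CANONICAL", "gnomADe_AF")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##contig=<ID=chrS,length=100000>",
    "##FILTER=<ID=PASS,Description=\"ok\">",
    "##FILTER=<ID=q10,Description=\"low qual\">",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations from Ensembl VEP. Format: ",
           paste(csq_fields, collapse = "|"), "\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(rows, function(r)
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, "100", r$filt %||% "PASS",
            paste0("CSQ=", r$csq), "GT:AD:DP:GQ", r$gt), collapse = "\t"),
    character(1))
  writeLines(c(hdr, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Independent k-mer enumeration (brute-force oracle for peptide tests):
## all k-mers of a protein, optionally restricted to windows covering pos p.
all_kmers <- function(s, k, covering = NULL) {
  L <- nchar(s)
  if (L < k) return(character())
  starts <- seq_len(L - k + 1L)
  if (!is.null(covering))
    starts <- starts[starts <= covering & starts + k - 1L >= covering]
  substring(s, starts, starts + k - 1L)
}

random_protein <- function(L) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L, replace = TRUE),
        collapse = "")
}
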