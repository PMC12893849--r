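---
title: "Allogenomic mismatch scoring: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allogenomic mismatch scoring: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alloscore)
```

## The model

Minor histocompatibility antigens (mHAgs) are HLA-presented peptides that
differ in amino-acid sequence between a transplant donor and recipient
because of non-synonymous polymorphisms.  `alloscore` approximates the
mHAg load of a donor/recipient pair from their annotated variant calls in
two stages.

**Stage 1 — counting.**  Both samples' VCFs must carry amino-acid-level
consequences in a VEP-style `CSQ` INFO field.  After quality cleaning, the
two call sets are joined on (chromosome, position, reference allele).  At
every annotated (transcript, protein position), each sample's genotype
encodes a *set* of amino acids: allele 0 contributes the reference residue,
ALT allele *i* the alternate residue of the consequence annotated for that
ALT; an allele without an annotated consequence falls back to the reference
residue; homozygotes give singletons.  The comparison is directional:

* **SOT**: mismatches are `AA(donor) \ AA(recipient)` — donor-only amino
  acids, the host-versus-graft-relevant set after solid-organ
  transplantation;
* **HCT**: `AA(recipient) \ AA(donor)` — the graft-versus-host-relevant
  set after allogeneic haematopoietic cell transplantation.

The AMS is the sum of `|source \ target|` over all counted groups, and the
AMS table records one row per non-empty mismatch set.  Note the reference
residue itself can be the mismatch (e.g. donor `G/R` heterozygote versus
recipient homozygous `R`): direction duality —
`AMS_SOT(X, Y) = AMS_HCT(Y, X)` with identical tables — holds by
construction and is property-tested.

**Stage 2 — affinity.**  For every mismatch row the source sample's
protein is reconstructed from a user-supplied protein FASTA keyed by
transcript ID, every length-*k* sliding window covering the mismatched
residue is enumerated (`min(p, L−k+1) − max(1, p−k+1) + 1` windows for a
length-*L* protein, truncated at the termini, none when `L < k`), windows
also encoded by any target allele over the same coverage are removed by
exact string matching, and the survivors are scored per HLA class I allele
through the predictor interface.  The af-AMS counts distinct binder
peptides (optionally (peptide, allele) pairs).

## Assumptions

* Annotation is consumed, not produced: consequences are trusted as given
  and parsing is strictly header-driven (the `CSQ` subfield order is taken
  from the VCF header, never assumed).
* Only single-residue substitutions (missense and in-frame substitutions
  with a well-formed `X/Y` amino-acid pair) contribute.  Stop gains can be
  included via `include_stop_gained`, but frameshifts and other indels are
  out of scope: peptide reconstruction is ill-defined for truncations, and
  SNV-focused counting captures the large majority of exonic variation.
* Both inputs must come from the same reference/annotation build; a
  disjoint contig-name set is treated as evidence of a build mismatch and
  is a hard error, as is a disagreement between the FASTA residue and a
  consequence's stated reference amino acid.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_gnomad_af` | 0.01 | allele frequency | the tool's documented default gate; set to 0 to include rare variants, which carry a material share of the score |
| `drop_af_absent` | FALSE | — | absence from gnomAD is distinct from rarity; informative variants can be absent entirely, so they are kept by default |
| `min_depth` | 10 | reads | conventional germline QC floor |
| `min_gq` | 20 | Phred | conventional genotype-quality floor |
| `het_ab_range` | [0.2, 0.8] | depth fraction | allelic balance sanity check, heterozygous calls only |
| `missing` | `stringent` | — | masks any site with a missing genotype in either sample; `impute` treats missing as homozygous reference |
| `counting` | `canonical` | — | one transcript per site (see below) |
| peptide `lengths` | 9 | residues | canonical class I length; 8–14 supported |
| `rank_threshold` | 2.0 | %rank | the conventional weak-binder limit; boundary inclusive |
| `cleavage_threshold` | 0.5 | score | conventional cleavage-predictor cutoff |

The depth/GQ/allelic-balance defaults are this repository's choices (the
published filter appendix is not reproduced in the available text); the 1%
AF default is the method's stated default.  All are user-configurable and
echoed into the run manifest.

## Design decisions

**Counting rule.**  The method's definition — "number of directional
amino-acid mismatches" — leaves open whether isoforms multiply-count a
locus.  The default counts per (site, canonical transcript): if any
consequence at a site is flagged canonical, only canonical transcripts
count; otherwise the lexicographically smallest transcript ID is used as a
deterministic fallback.  `per_transcript` (count every annotated isoform)
and `binary_site` (a site contributes at most 1) are exposed because the
choice is genuinely open; canonical-only avoids inflating the score by
transcript multiplicity.

**Missing data and filters.**  A genotype rejected by a per-sample quality
filter is treated exactly like a missing genotype and then resolved by the
missing-data mode, mirroring the treatment of sites absent from one of two
single-sample files.  Consequently `impute` mode turns QC-failures into
homozygous reference calls — deliberate, and the reason `stringent` is the
default.  The AF gate is sample-independent (it is a property of the site's
population frequency, not of a call) and removes the site outright; its
rejections are tallied separately.  `masked_sites` counts sites that
survived the AF gate but were masked by `stringent`.

**Haplotype policy in peptide reconstruction.**  Phasing of nearby
heterozygous variants within one window is generally unknown.
`reconstruct_protein()` applies an arbitrary substitution set (the focal
variant plus homozygous co-variants, per its contract), but the pipeline
driver `run_affinity()` reconstructs each peptide on a reference background
with the focal substitution only: the AMS table it consumes carries
mismatch rows, not the full genotype background, and fabricating phased
haplotypes silently would overstate certainty.  The practical consequence
is that co-occurring variants closer than one window length may yield
peptides that are not exactly the sample's true haplotypic peptides.

**Binder boundary.**  Inclusive (`percent_rank <= 2.0` by default), with
`nm_threshold` as a mutually exclusive alternative; the two criteria are
never mixed within one run.

**Cleavage rule.**  A peptide is retained when the predicted cleavage score
at the protein position of its C-terminal residue reaches the threshold:
the proteasome must cut exactly there to liberate that terminus.  The
N-terminus is not gated (aminopeptidase trimming makes it uninformative).

**Predictor adapters.**  External NetMHCpan-4.1 / MixMHCpred / NetChop
binaries are driven through their native file formats with validated
column names; their scoring networks are not re-implemented.  The built-in
mock predictor hashes (peptide, allele) onto a pseudo-uniform percent rank
in [0, 100], which makes the full pipeline deterministic, portable and
testable without licensed software — mock scores are *not* biologically
meaningful.

**Non-standard residues.**  Peptides containing residues outside the
20-letter alphabet (e.g. selenocysteine `U`, ambiguity `X`) are dropped
with a warning; class I predictors do not score them.

## The synthetic-data generator

`simulate_family()` emulates the statistical structure the method assumes:
biallelic exonic missense sites with population allele frequencies
(Beta(0.5, 0.5) truncated to [0.01, 0.5] — a U-shaped folded-SFS-like
shape over the gated range), Mendelian transmission from two founders to
`n_children` siblings with Poisson(1.5) crossovers per transmitted
haplotype on a single chromosome (labelled `chrS`; uniform site spacing,
uniform crossover placement), per-genotype error (uniform flip to a
different genotype among hom-ref/het/hom-alt) and per-genotype
missingness, plus a toy proteome kept consistent with the annotated
amino-acid changes so reconstruction never fails on synthetic data.  The
generator's defaults are the accuracy-validation scenario: 20,000 sites,
15 siblings, error rate 5×10⁻⁴, no missingness.

What it does *not* emulate: linkage disequilibrium between sites, a
genetic map, indels/multi-allelic sites (the family simulator is
biallelic; the small random fixtures used for oracle-equivalence testing
do cover multi-allelic sites and missing annotations), read-level error
processes, or batch effects between capture platforms.  A green simulation
test therefore establishes that the *counting machinery* is exact and
robust to genotype-level noise — not that any particular cohort's score
distribution is reproduced.

Ground truth is supplied by a deliberately independent oracle
(`oracle_ams()`, naive nested loops over plain-list fixtures;
`oracle_family_ams()`, a 3×3 dosage-contribution table derived at run time
by enumerating the nine genotype pairs through the same naive set logic).
The oracle shares no code with the production scoring path.

## Numerical and degenerate-input choices

* Ties/ordering: all tables are sorted by (chrom, pos, transcript_id,
  peptide-where-present), making reruns byte-identical.
* Duplicate (chrom, pos, ref) records: first kept, warning raised.
* Half-calls (`./1`) are treated as fully missing.
* A site present in only one single-sample input is a missing genotype in
  the other sample.
* ALT lists may differ between the two inputs; they are unioned with
  per-sample allele-index remapping.
* Window enumeration at the termini truncates rather than pads; proteins
  shorter than the window yield no peptides.
* Sub-seeds derived from a user seed are kept below 2^31.

## Known limitations

* Class II prediction is out of scope; the exported peptide list can be
  fed to any external class II tool.
* The af-AMS depends entirely on the chosen affinity predictor; its
  accuracy is not validated here (only its plumbing and determinism are).
* Cohort-level statistics beyond per-pair scores, HLA typing, expression
  -based transcript list curation and any web interface are out of scope.
* The per-transcript counting mode can multiply-count a single locus
  across isoforms; that is its documented purpose, not a bug.
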