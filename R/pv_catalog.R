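## Catalog of modern-human pathogenic variants (PVs) in DNA damage repair
## (DDR) genes, with clinical-class / review-star filtering and pathway
## assignment. Coordinates are 1-based, fully closed, VCF-style; conversion
## to the 0-based MAF reckoning happens only at the alignment boundary.

CLIN_CLASSES <- c("pathogenic", "likely_pathogenic", "uncertain",
                  "likely_benign", "benign", "conflicting")

PATHWAY_LABELS <- c("FA", "HR", "MMR", "NER", "NHEJ", "DDR_response",
                    "BER", "DR")

new_pv_catalog <- function(variants, geneset = NULL, trail = character()) {
  structure(list(variants = variants, geneset = geneset, trail = trail),
            class = "pv_catalog")
}

#' @export
print.pv_catalog <- function(x, ...) {
  cat(sprintf("<pv_catalog> %d variants (%d SNVs) in %d genes\n",
              nrow(x$variants), sum(x$variants$is_snv),
              length(unique(x$variants$gene))))
  for (step in x$trail) cat("  - ", step, "\n", sep = "")
  invisible(x)
}

#' Number of variants in a catalog
#' @param x a `pv_catalog`.
#' @return integer count.
#' @export
n_variants <- function(x) nrow(x$variants)

validate_variant_rows <- function(df) {
  problems <- character()
  bad_pos <- which(!is.finite(df$pos) | df$pos < 1)
  if (length(bad_pos) > 0) {
    problems <- c(problems, sprintf("row %d: pos must be >= 1", bad_pos))
  }
  bad_class <- which(!(df$clin_class %in% CLIN_CLASSES))
  if (length(bad_class) > 0) {
    problems <- c(problems, sprintf("row %d: unknown clin_class '%s'",
                                    bad_class, df$clin_class[bad_class]))
  }
  single <- nchar(df$ref) == 1L & nchar(df$alt) == 1L
  bad_allele <- which(single & !(is_acgt(df$ref) & is_acgt(df$alt)))
  if (length(bad_allele) > 0) {
    problems <- c(problems,
                  sprintf("row %d: non-ACGT SNV allele %s>%s",
                          bad_allele, df$ref[bad_allele], df$alt[bad_allele]))
  }
  same <- which(single & df$ref == df$alt)
  if (length(same) > 0) {
    problems <- c(problems, sprintf("row %d: ref equals alt (%s)",
                                    same, df$ref[same]))
  }
  keys <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  dup <- unique(keys[duplicated(keys)])
  if (length(dup) > 0) {
    problems <- c(problems,
                  sprintf("duplicate variant key: %s", dup))
  }
  problems
}

#' Load a pathogenic-variant catalog
#'
#' Reads a variant table from TSV (canonical schema) or a minimal VCF v4.x
#' subset (`CHROM`, `POS`, `REF`, `ALT` plus INFO keys `CLNSIG`,
#' `CLNREVSTAT`, `GENEINFO`; multi-allelic records are split into biallelic
#' variants). Rows are validated against the catalog invariants: 1-based
#' positions, single-base SNV alleles in ACGT with `ref != alt`, a closed
#' clinical-class vocabulary, and unique `(chrom, pos, ref, alt)` keys.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return a `pv_catalog`: list with `variants` (data frame), `geneset`,
#'   and an append-only provenance `trail`.
#' @export
load_variant_table <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  df <- switch(format,
               tsv = read_variant_tsv(path),
               vcf = read_variant_vcf(path))
  df$is_snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    is_acgt(df$ref) & is_acgt(df$alt) & df$ref != df$alt
  problems <- validate_variant_rows(df)
  if (length(problems) > 0) {
    stop(paste0("invalid variant table '", path, "':\n  ",
                paste(problems, collapse = "\n  ")), call. = FALSE)
  }
  rownames(df) <- NULL
  new_pv_catalog(df, trail = sprintf("loaded %d variants from %s (%s)",
                                     nrow(df), path, format))
}

read_variant_tsv <- function(path) {
  req <- c("chrom", "pos", "ref", "alt", "gene", "clin_class", "review_stars")
  df <- read_tsv_strict(path, required = req, what = "variant TSV")
  df$pos <- as.integer(df$pos)
  df$review_stars <- as.integer(df$review_stars)
  for (opt in c("hgvs_c", "hgvs_p", "rsid")) {
    if (is.null(df[[opt]])) df[[opt]] <- rep(NA_character_, nrow(df))
  }
  df[c(req, "hgvs_c", "hgvs_p", "rsid")]
}

## ClinVar CLNSIG / CLNREVSTAT vocabularies -> internal enumerations
clnsig_to_class <- function(x) {
  x <- tolower(gsub("[ /]", "_", x))
  out <- rep(NA_character_, length(x))
  out[grepl("conflicting", x)] <- "conflicting"
  out[is.na(out) & grepl("likely_pathogenic", x)] <- "likely_pathogenic"
  out[is.na(out) & grepl("pathogenic", x)] <- "pathogenic"
  out[is.na(out) & grepl("uncertain", x)] <- "uncertain"
  out[is.na(out) & grepl("likely_benign", x)] <- "likely_benign"
  out[is.na(out) & grepl("benign", x)] <- "benign"
  out
}

clnrevstat_to_stars <- function(x) {
  x <- tolower(x)
  stars <- integer(length(x))
  stars[grepl("single_submitter", x)] <- 1L
  stars[grepl("multiple_submitters", x) & !grepl("conflicting", x)] <- 2L
  stars[grepl("expert_panel", x)] <- 3L
  stars[grepl("practice_guideline", x)] <- 4L
  stars
}

read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  info_field <- function(key) {
    vcfR::extract.info(vcf, element = key)
  }
  gene_raw <- info_field("GENEINFO")
  gene <- sub(":.*$", "", gene_raw)          # GENEINFO is SYMBOL:ID[|...]
  clin <- clnsig_to_class(info_field("CLNSIG"))
  stars <- clnrevstat_to_stars(info_field("CLNREVSTAT"))
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
               ref = fix$REF[i], alt = alts, gene = gene[i],
               clin_class = clin[i], review_stars = stars[i],
               hgvs_c = NA_character_, hgvs_p = NA_character_,
               rsid = if (!is.na(fix$ID[i]) && fix$ID[i] != ".")
                 fix$ID[i] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Filter a catalog by clinical class and review status
#'
#' Retains variants whose clinical class is in `keep_classes`, whose review
#' stars are at least `min_stars`, and (optionally) which are not of
#' conflicting classification. The published filter reads "over three
#' stars" against a 0-4 star scale; we interpret it as "three or more" and
#' surface that reading in the provenance trail. Likely-pathogenic is kept
#' with pathogenic by default, matching the use of "pathogenic and likely
#' pathogenic variants" as one class.
#'
#' @param catalog a `pv_catalog`.
#' @param keep_classes character subset of the class enumeration.
#' @param min_stars minimum review stars (default 3, i.e. "three or more").
#' @param exclude_conflicting drop conflicting classifications (default TRUE).
#' @return a new filtered `pv_catalog`; the input is unmodified.
#' @export
filter_clinical <- function(catalog,
                            keep_classes = c("pathogenic", "likely_pathogenic"),
                            min_stars = 3L,
                            exclude_conflicting = TRUE) {
  stopifnot(inherits(catalog, "pv_catalog"))
  if (length(keep_classes) == 0 || !all(keep_classes %in% CLIN_CLASSES)) {
    stop("keep_classes must be a non-empty subset of: ",
         paste(CLIN_CLASSES, collapse = ", "), call. = FALSE)
  }
  v <- catalog$variants
  keep <- v$clin_class %in% keep_classes & v$review_stars >= min_stars
  if (exclude_conflicting) keep <- keep & v$clin_class != "conflicting"
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    warning("filter_clinical retained no variants", call. = FALSE)
  }
  step <- sprintf(
    "filter_clinical(classes={%s}, min_stars=%d ['three or more' reading], exclude_conflicting=%s): %d -> %d (%d removed)",
    paste(keep_classes, collapse = ","), min_stars, exclude_conflicting,
    nrow(v), nrow(out), nrow(v) - nrow(out))
  new_pv_catalog(out, catalog$geneset, c(catalog$trail, step))
}

#' Restrict a catalog to single-nucleotide variants
#'
#' @param catalog a `pv_catalog`.
#' @return a new `pv_catalog` containing only SNVs.
#' @export
select_snvs <- function(catalog) {
  stopifnot(inherits(catalog, "pv_catalog"))
  v <- catalog$variants
  out <- v[v$is_snv, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("select_snvs retained no variants", call. = FALSE)
  step <- sprintf("select_snvs: %d -> %d (%d removed)",
                  nrow(v), nrow(out), nrow(v) - nrow(out))
  new_pv_catalog(out, catalog$geneset, c(catalog$trail, step))
}

#' Load a DDR gene-to-pathway panel
#'
#' The panel is a TSV with columns `gene` and `pathways` (comma-separated
#' labels from the closed set FA, HR, MMR, NER, NHEJ, DDR_response, BER,
#' DR). A gene may belong to several pathways; totals downstream are
#' nonredundant. The packaged default covers the genes appearing in the
#' published summary tables and is user-replaceable.
#'
#' @param path panel TSV; `NULL` for the packaged default.
#' @return a `ddr_gene_set`: data frame with `gene` and list-column
#'   `pathways`.
#' @export
load_gene_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fixtures", "ddr_gene_pathways.tsv",
                        package = "paleopv", mustWork = TRUE)
  }
  df <- read_tsv_strict(path, required = c("gene", "pathways"),
                        what = "gene panel")
  pw <- strsplit(df$pathways, ",", fixed = TRUE)
  pw <- lapply(pw, trimws)
  bad <- !vapply(pw, function(p) all(p %in% PATHWAY_LABELS), logical(1))
  if (any(bad)) {
    stop("gene panel has pathway labels outside the closed set for gene(s): ",
         paste(df$gene[bad], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$gene)) {
    stop("gene panel lists a gene twice", call. = FALSE)
  }
  out <- data.frame(gene = df$gene, stringsAsFactors = FALSE)
  out$pathways <- pw
  structure(out, class = c("ddr_gene_set", "data.frame"))
}

#' Tag catalog variants with their gene's DDR pathways
#'
#' Off-panel genes are flagged, not rejected (panel definitions of the DDR
#' gene universe differ between sources).
#'
#' @param catalog a `pv_catalog`.
#' @param geneset a `ddr_gene_set` from [load_gene_panel()].
#' @return the catalog with per-variant `pathways` list-column and
#'   `off_panel` flag, and the geneset attached.
#' @export
assign_pathways <- function(catalog, geneset) {
  stopifnot(inherits(catalog, "pv_catalog"), inherits(geneset, "ddr_gene_set"))
  v <- catalog$variants
  idx <- match(v$gene, geneset$gene)
  pl <- geneset$pathways[idx]
  pl[is.na(idx)] <- list(character())
  v$pathways <- pl
  v$off_panel <- is.na(idx)
  step <- sprintf("assign_pathways: %d on-panel, %d off-panel",
                  sum(!v$off_panel), sum(v$off_panel))
  new_pv_catalog(v, geneset, c(catalog$trail, step))
}
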