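## Synthetic-data generators: every input the pipeline consumes can be
## produced here with known ground truth (species alignments with planted
## convergent alleles, ancient reads with exponentially decaying terminal
## deamination, codon pairs at chosen omega), plus the loader for the
## packaged summary-table fixtures. Every generator is a pure function of
## (parameters, seed): identical seeds give identical bytes.

#' Simulate a species alignment and emit it as MAF
#'
#' Evolves sequences down a phylogeny under an HKY substitution process
#' (via [phangorn::simSeq()]) and emits a single MAF block with the human
#' leaf as reference row. Multi-block fragmentation is available for index
#' testing.
#'
#' @param tree an [ape::phylo] tree or newick string; must contain
#'   `human_label` as a leaf; branch lengths in substitutions/site.
#' @param length alignment length in bases.
#' @param kappa transition/transversion rate ratio (default 2).
#' @param base_freqs base frequencies in A,C,G,T order.
#' @param seed RNG seed.
#' @param human_label leaf treated as the reference assembly (default
#'   `"hg19"`).
#' @param chrom,start human coordinates assigned to the region (start is
#'   0-based, MAF convention).
#' @param n_blocks split the region into this many consecutive MAF blocks
#'   (default 1).
#' @return list with `sequences` (named character vector), `blocks` (MAF
#'   block list), `tree`.
#' @export
simulate_species_alignment <- function(tree, length, kappa = 2,
                                       base_freqs = rep(0.25, 4),
                                       seed = NULL, human_label = "hg19",
                                       chrom = "chr1", start = 0,
                                       n_blocks = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), length >= 1)
  if (!human_label %in% tree$tip.label) {
    stop("tree has no leaf named '", human_label, "'", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ## HKY: transitions (A<->G, C<->T) scaled by kappa in the 6-rate vector
  ## ordered (AC, AG, AT, CG, CT, GT)
  Q <- c(1, kappa, 1, 1, kappa, 1)
  sim <- phangorn::simSeq(tree, l = length, Q = Q, bf = base_freqs,
                          type = "DNA")
  mat <- toupper(as.character(sim))
  seqs <- apply(mat, 1, paste, collapse = "")
  seqs <- seqs[c(human_label, setdiff(names(seqs), human_label))]
  blocks <- make_maf_blocks(seqs, human_label, chrom, start, n_blocks)
  list(sequences = seqs, blocks = blocks, tree = tree)
}

make_maf_blocks <- function(seqs, human_label, chrom, start, n_blocks) {
  len <- nchar(seqs[[1]])
  cuts <- floor(seq(0, len, length.out = n_blocks + 1))
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    lo <- cuts[b] + 1
    hi <- cuts[b + 1]
    texts <- vapply(seqs, substr, character(1), lo, hi)
    size <- hi - lo + 1
    rows <- data.frame(
      species = names(seqs),
      src_chrom = ifelse(names(seqs) == human_label, chrom, "scaf1"),
      start = ifelse(names(seqs) == human_label, start + lo - 1, lo - 1),
      size = size, strand = "+", src_size = len, text = unname(texts),
      stringsAsFactors = FALSE)
    blocks[[b]] <- list(score = 1000 - b, offset = NA_integer_, rows = rows)
  }
  blocks
}

#' Plant SNVs (with optional convergent alleles) into a simulated alignment
#'
#' Chooses `n` distinct human positions, assigns each an alternate allele
#' by the substitution-class spectrum, and for every (variant, species)
#' pair in `convergent_plan` overwrites that species' aligned base with
#' the alternate allele — emulating the same coding variant arising
#' independently in a distant lineage. The human sequence keeps the
#' reference allele (the variants are the modern catalog, not the
#' reference genome).
#'
#' @param sim output of [simulate_species_alignment()].
#' @param n number of SNVs to plant.
#' @param spectrum named probabilities over substitution classes
#'   (`"C>T"`, `"G>A"`, `"A>G"`, ...); classes are conditioned on the
#'   human base at each candidate position.
#' @param convergent_plan data frame with columns `variant` (index
#'   1..n) and `species`; may be empty.
#' @param seed RNG seed.
#' @param gene gene symbol stamped on the planted variants.
#' @param human_label,chrom as in the simulation.
#' @return list with `catalog` (a `pv_catalog`), `blocks` (MAF blocks
#'   with convergent alleles applied), `sequences`, and `truth` (planted
#'   positions, alleles and per-species sharing plan).
#' @export
plant_variants <- function(sim, n, spectrum = c("C>T" = 0.25, "G>A" = 0.25,
                                                "A>G" = 0.25, "T>C" = 0.25),
                           convergent_plan = NULL, seed = NULL,
                           gene = "GENE1", human_label = "hg19",
                           chrom = "chr1") {
  if (!is.null(seed)) set.seed(seed)
  seqs <- sim$sequences
  human <- strsplit(seqs[[human_label]], "")[[1]]
  start0 <- sim$blocks[[1]]$rows$start[1]
  refs_of <- vapply(strsplit(names(spectrum), ">"), `[`, character(1), 1)
  alts_of <- vapply(strsplit(names(spectrum), ">"), `[`, character(1), 2)
  candidates <- which(human %in% refs_of)
  if (n > length(candidates)) {
    stop("not enough usable positions for ", n, " variants", call. = FALSE)
  }
  if (n == 0) {
    pos_idx <- integer(0)
  } else {
    pos_idx <- sort(sample(candidates, n))
  }
  alt <- character(n)
  for (i in seq_len(n)) {
    cls <- which(refs_of == human[pos_idx[i]])
    w <- spectrum[cls]
    alt[i] <- alts_of[cls][sample.int(length(cls), 1, prob = w)]
  }
  catalog_df <- data.frame(
    chrom = rep(chrom, n), pos = start0 + pos_idx, ref = human[pos_idx],
    alt = alt, gene = rep(gene, n), clin_class = rep("pathogenic", n),
    review_stars = rep(4L, n), hgvs_c = rep(NA_character_, n),
    hgvs_p = rep(NA_character_, n), rsid = rep(NA_character_, n),
    is_snv = rep(TRUE, n), stringsAsFactors = FALSE)
  ## apply the convergent plan to the species sequences
  if (!is.null(convergent_plan) && nrow(convergent_plan) > 0) {
    unknown <- setdiff(convergent_plan$species, names(seqs))
    if (length(unknown) > 0) {
      stop("convergent plan references unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (r in seq_len(nrow(convergent_plan))) {
      vi <- convergent_plan$variant[r]
      sp <- convergent_plan$species[r]
      s <- strsplit(seqs[[sp]], "")[[1]]
      s[pos_idx[vi]] <- alt[vi]
      seqs[[sp]] <- paste(s, collapse = "")
    }
  }
  n_blocks <- length(sim$blocks)
  blocks <- make_maf_blocks(seqs, human_label, chrom, start0, n_blocks)
  truth <- list(pos = start0 + pos_idx, ref = human[pos_idx], alt = alt,
                plan = convergent_plan, seed = seed)
  list(catalog = new_pv_catalog(catalog_df,
                                trail = sprintf("planted %d synthetic SNVs", n)),
       blocks = blocks, sequences = seqs, truth = truth)
}

#' Simulate ancient reads over a region as a pileup table
#'
#' Reads of fixed length are placed uniformly to a target mean coverage.
#' Carrier sites emit the alternate allele on each overlapping read with
#' probability 0.5 (heterozygote model; `homozygous = TRUE` makes it 1).
#' Post-mortem deamination is applied post-hoc: C->T at 5' offset `i`
#' with probability `d0 * exp(-lam * i)` and the mirrored G->A at the 3'
#' end; uniform sequencing error is added last. Rows carry the true
#' `dist5`/`dist3`.
#'
#' @param human_seq reference sequence of the region (character string).
#' @param genotypes data frame with `pos` (1-based within `chrom`
#'   coordinates), `alt`; the variant sites this sample carries. May be
#'   empty.
#' @param coverage target mean coverage.
#' @param read_len read length (>= 2).
#' @param d0,lam terminal deamination rate and per-base decay.
#' @param seq_error per-base sequencing error rate.
#' @param seed RNG seed.
#' @param sample_id sample identifier.
#' @param chrom chromosome label.
#' @param start0 0-based offset of the region on `chrom`.
#' @param sites optional data frame (`chrom`, `pos`) restricting emitted
#'   rows (pileups for a whole region can be large).
#' @param homozygous emit the alternate on every overlapping read.
#' @return pileup data frame in the canonical schema.
#' @export
simulate_ancient_reads <- function(human_seq, genotypes = NULL,
                                   coverage = 5, read_len = 60,
                                   d0 = 0, lam = 0.3, seq_error = 0,
                                   seed = NULL, sample_id = "S1",
                                   chrom = "chr1", start0 = 0,
                                   sites = NULL, homozygous = FALSE) {
  stopifnot(coverage > 0, read_len >= 2,
            d0 >= 0, d0 <= 1, lam >= 0, seq_error >= 0, seq_error < 1)
  if (!is.null(seed)) set.seed(seed)
  refchars <- strsplit(toupper(human_seq), "")[[1]]
  L <- length(refchars)
  if (read_len > L) stop("read_len longer than the region", call. = FALSE)
  n_reads <- max(1L, round(coverage * L / read_len))
  starts <- sample.int(L - read_len + 1, n_reads, replace = TRUE)
  alt_at <- NULL
  if (!is.null(genotypes) && nrow(genotypes) > 0) {
    alt_at <- stats::setNames(genotypes$alt, genotypes$pos)
  }
  keep_key <- if (!is.null(sites)) paste(sites$chrom, sites$pos) else NULL
  rows <- vector("list", n_reads)
  for (r in seq_len(n_reads)) {
    offs <- 0:(read_len - 1)
    pos1 <- start0 + starts[r] + offs          # 1-based chrom coords
    bases <- refchars[starts[r] + offs]
    ## heterozygous carrier: alt on ~half the overlapping reads
    if (!is.null(alt_at)) {
      hit <- which(as.character(pos1) %in% names(alt_at))
      for (h in hit) {
        p_alt <- if (homozygous) 1 else 0.5
        if (stats::runif(1) < p_alt) {
          bases[h] <- alt_at[[as.character(pos1[h])]]
        }
      }
    }
    ## post-mortem deamination, then sequencing error
    dist5 <- offs
    dist3 <- read_len - 1 - offs
    c_idx <- which(bases == "C")
    flip <- c_idx[stats::runif(length(c_idx)) < d0 * exp(-lam * dist5[c_idx])]
    bases[flip] <- "T"
    g_idx <- which(bases == "G")
    flip <- g_idx[stats::runif(length(g_idx)) < d0 * exp(-lam * dist3[g_idx])]
    bases[flip] <- "A"
    if (seq_error > 0) {
      err <- which(stats::runif(read_len) < seq_error)
      for (e in err) {
        bases[e] <- sample(setdiff(DNA_BASES, bases[e]), 1)
      }
    }
    keep <- if (is.null(keep_key)) seq_along(pos1) else
      which(paste(chrom, pos1) %in% keep_key)
    if (length(keep) == 0) next
    rows[[r]] <- data.frame(
      sample_id = sample_id, chrom = chrom, pos = pos1[keep],
      ref = refchars[starts[r] + offs][keep], base = bases[keep],
      baseq = 30L, dist5 = dist5[keep], dist3 = dist3[keep],
      strand = "+", read_id = sprintf("%s_r%04d", sample_id, r),
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(stats::setNames(
      data.frame(matrix(ncol = length(PILEUP_COLUMNS), nrow = 0)),
      PILEUP_COLUMNS))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## pinned checksums for the packaged fixture tables (integrity check)
FIXTURE_NAMES <- c("table2_primate_sharing", "table3_pathways",
                   "table4_gene_counts", "table5_chek2",
                   "table6_founders", "results_counts")

#' Load a packaged summary-table fixture
#'
#' The published per-gene, per-pathway, recurrence and founder summary
#' tables ship as plain-text TSVs (transcribed as printed, including known
#' internal discrepancies, which a NOTES column documents). Checksums are
#' pinned; a mismatch is an integrity error.
#'
#' @param name one of `table2_primate_sharing`, `table3_pathways`,
#'   `table4_gene_counts`, `table5_chek2`, `table6_founders`,
#'   `results_counts`.
#' @return validated data frame.
#' @export
load_published_fixtures <- function(name) {
  name <- match.arg(name, FIXTURE_NAMES)
  path <- system.file("extdata", "fixtures", paste0(name, ".tsv"),
                      package = "paleopv", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  expected <- fixture_checksums()[[name]]
  if (!identical(md5, expected)) {
    stop(sprintf("fixture %s failed its integrity check (md5 %s != %s)",
                 name, md5, expected), call. = FALSE)
  }
  df <- read_tsv_strict(path, what = paste("fixture", name))
  validate_fixture(name, df)
  df
}

validate_fixture <- function(name, df) {
  need <- switch(name,
    table2_primate_sharing = c("species", "mya", "gene", "hgvs_c", "hgvs_p"),
    table3_pathways = c("pathway", "n_genes", "ancient_genes_with_pvs",
                        "ancient_pvs", "modern_genes_with_pvs", "modern_pvs"),
    table4_gene_counts = c("gene", "pvs"),
    table5_chek2 = c("time_bp", "hgvs_c", "hgvs_p", "rsid", "position",
                     "variation_type", "locations", "n_carriers"),
    table6_founders = c("gene", "hgvs_c", "hgvs_p", "pmid", "population",
                        "age_bp_text", "age_bp_lo", "age_bp_hi"),
    results_counts = c("key", "value"))
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("fixture %s is missing column(s): %s", name,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (name == "table5_chek2" && any(is.na(df$n_carriers))) {
    stop("table5_chek2 must have a carrier count on every row", call. = FALSE)
  }
  if (name == "table6_founders") {
    ok <- (!is.na(df$age_bp_lo) & df$age_bp_lo > 0) |
      (!is.na(df$age_bp_hi) & df$age_bp_hi > 0)
    if (!all(ok)) stop("table6_founders ages must be positive", call. = FALSE)
  }
  invisible(df)
}

#' Fetch one value from the results_counts fixture
#'
#' @param key count name (e.g. `"snv_pvs"`).
#' @param counts optionally a preloaded results_counts data frame.
#' @return numeric value.
#' @export
results_count <- function(key, counts = NULL) {
  if (is.null(counts)) counts <- load_published_fixtures("results_counts")
  idx <- match(key, counts$key)
  if (is.na(idx)) stop("unknown results count: ", key, call. = FALSE)
  as.numeric(counts$value[idx])
}
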