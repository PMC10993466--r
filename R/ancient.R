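## Detection of catalog PVs in ancient-sample pileups with deamination-aware
## filtering. Post-mortem cytosine deamination is read as C->T near the 5'
## read end and, for double-stranded libraries, G->A near the 3' end; its
## per-position rate decays roughly exponentially into the read. Presence is
## a detection call (>= min_clean_alt damage-clean alternate reads), not a
## diploid genotype.

SAMPLE_GROUPS <- c("ancient_human", "neanderthal", "denisovan")

PILEUP_COLUMNS <- c("sample_id", "chrom", "pos", "ref", "base", "baseq",
                    "dist5", "dist3", "strand", "read_id")

#' Read the canonical pileup TSV
#'
#' One row per (read, site) observation: `sample_id`, `chrom`, `pos`
#' (1-based), `ref`, `base`, `baseq` (Phred), `dist5`/`dist3` (0-based
#' distances from the 5'/3' read ends), `strand`, `read_id`.
#'
#' @param path pileup TSV.
#' @return data frame of observations.
#' @export
read_pileup <- function(path) {
  df <- read_tsv_strict(path, required = PILEUP_COLUMNS, what = "pileup TSV")
  df$pos <- as.integer(df$pos)
  df$baseq <- as.integer(df$baseq)
  df$dist5 <- as.integer(df$dist5)
  df$dist3 <- as.integer(df$dist3)
  if (any(df$baseq < 0, na.rm = TRUE)) {
    stop("pileup has negative base qualities", call. = FALSE)
  }
  df
}

#' Read ancient-sample metadata
#'
#' TSV with `sample_id`, `date_bp` (years before present; may be empty for
#' undated samples), `location`, `group` (ancient_human, neanderthal or
#' denisovan).
#'
#' @param path metadata TSV.
#' @return data frame.
#' @export
read_sample_metadata <- function(path) {
  df <- read_tsv_strict(path, required = c("sample_id", "date_bp",
                                           "location", "group"),
                        what = "sample metadata")
  df$date_bp <- as.numeric(df$date_bp)
  if (any(!is.na(df$date_bp) & df$date_bp <= 0)) {
    stop("date_bp must be positive when present", call. = FALSE)
  }
  if (!all(df$group %in% SAMPLE_GROUPS)) {
    stop("sample group must be one of: ",
         paste(SAMPLE_GROUPS, collapse = ", "), call. = FALSE)
  }
  df
}

#' Is a read observation deamination-suspect?
#'
#' An observation supports a suspect call iff it is consistent with
#' post-mortem deamination at a read end: a C->T variant observed as T
#' within `k` bases of the 5' end, or a G->A variant observed as A within
#' `k` bases of the 3' end. All other substitution classes are never
#' suspect. Vectorised over observations.
#'
#' @param obs data frame of observations (needs `base`, `dist5`, `dist3`).
#' @param ref,alt single reference/alternate bases.
#' @param k filter window in bases from the relevant read end (`k = 0`
#'   disables the filter, e.g. for UDG-treated libraries).
#' @return logical vector.
#' @export
damage_suspect <- function(obs, ref, alt, k) {
  stopifnot(nchar(ref) == 1, nchar(alt) == 1, k >= 0)
  if (ref == "C" && alt == "T") {
    obs$base == "T" & obs$dist5 < k
  } else if (ref == "G" && alt == "A") {
    obs$base == "A" & obs$dist3 < k
  } else {
    rep(FALSE, nrow(obs))
  }
}

#' Call presence of one variant at one pileup site
#'
#' Observations below `min_baseq` are discarded (default 1, the maximally
#' permissive published setting); `alt_clean` is the alternate support
#' left after removing damage-suspect reads; the call is `present` iff
#' `alt_clean >= min_clean_alt`, `no_data` iff the filtered depth is zero,
#' else `absent`. `damage_only` flags sites whose alternate support was
#' entirely damage-suspect; `low_depth` flags filtered depth < 2.
#'
#' @param site list with `sample_id`, `chrom`, `pos`, `ref`, `obs` (data
#'   frame of observations).
#' @param variant one-row catalog slice (`chrom`, `pos`, `ref`, `alt`).
#' @param min_baseq minimum Phred base quality (default 1).
#' @param k damage-filter window (default 3).
#' @param min_clean_alt minimum damage-clean alternate reads (default 1).
#' @return one-row data frame (a carrier call).
#' @export
call_variant_presence <- function(site, variant, min_baseq = 1L, k = 3L,
                                  min_clean_alt = 1L) {
  if (site$chrom != variant$chrom || site$pos != variant$pos) {
    stop("pileup site and variant coordinates disagree", call. = FALSE)
  }
  obs <- site$obs
  obs <- obs[obs$baseq >= min_baseq, , drop = FALSE]
  depth <- nrow(obs)
  is_alt <- obs$base == variant$alt
  alt_total <- sum(is_alt)
  suspect <- damage_suspect(obs, variant$ref, variant$alt, k)
  alt_clean <- sum(is_alt & !suspect)
  status <- if (depth == 0) "no_data"
            else if (alt_clean >= min_clean_alt) "present"
            else "absent"
  data.frame(sample_id = site$sample_id,
             variant = variant_key(variant$chrom, variant$pos,
                                   variant$ref, variant$alt),
             chrom = variant$chrom, pos = variant$pos,
             ref = variant$ref, alt = variant$alt,
             gene = if (!is.null(variant$gene)) variant$gene else NA_character_,
             depth = depth, alt_total = alt_total, alt_clean = alt_clean,
             status = status,
             low_depth = depth < 2,
             damage_only = alt_total >= 1 && alt_clean == 0,
             stringsAsFactors = FALSE)
}

#' Scan a cohort of ancient samples for catalog PVs
#'
#' Produces one carrier call per (sample, catalog SNV) with pileup data,
#' joined with the sample's date, location and group.
#'
#' @param catalog SNV `pv_catalog`.
#' @param pileup data frame from [read_pileup()] (all samples together).
#' @param samples metadata data frame from [read_sample_metadata()].
#' @param min_baseq,k,min_clean_alt see [call_variant_presence()].
#' @return a `carrier_table` data frame with a `summary` attribute
#'   (distinct PVs present, carrier samples, genes hit).
#' @export
scan_samples <- function(catalog, pileup, samples, min_baseq = 1L, k = 3L,
                         min_clean_alt = 1L) {
  stopifnot(inherits(catalog, "pv_catalog"))
  orphan <- setdiff(unique(pileup$sample_id), samples$sample_id)
  if (length(orphan) > 0) {
    stop("pileup sample id(s) missing from metadata: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  v <- catalog$variants[catalog$variants$is_snv, , drop = FALSE]
  site_key <- paste(pileup$sample_id, pileup$chrom, pileup$pos)
  groups <- split(seq_len(nrow(pileup)), site_key)
  calls <- vector("list", 0L)
  for (i in seq_len(nrow(v))) {
    vi <- v[i, , drop = FALSE]
    for (sid in samples$sample_id) {
      key <- paste(sid, vi$chrom, vi$pos)
      idx <- groups[[key]]
      if (is.null(idx)) next
      site <- list(sample_id = sid, chrom = vi$chrom, pos = vi$pos,
                   ref = vi$ref, obs = pileup[idx, , drop = FALSE])
      calls[[length(calls) + 1]] <-
        call_variant_presence(site, vi, min_baseq, k, min_clean_alt)
    }
  }
  out <- if (length(calls) == 0) {
    empty <- call_variant_presence(
      list(sample_id = "x", chrom = "c", pos = 1L, ref = "A",
           obs = data.frame(base = character(), baseq = integer(),
                            dist5 = integer(), dist3 = integer())),
      list(chrom = "c", pos = 1L, ref = "A", alt = "C", gene = NA))
    empty[0, ]
  } else {
    do.call(rbind, calls)
  }
  meta_idx <- match(out$sample_id, samples$sample_id)
  out$date_bp <- samples$date_bp[meta_idx]
  out$location <- samples$location[meta_idx]
  out$group <- samples$group[meta_idx]
  out <- out[order(out$variant, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  present <- out[out$status == "present", , drop = FALSE]
  attr(out, "summary") <- list(
    n_pvs_present = length(unique(present$variant)),
    n_carriers = length(unique(present$sample_id)),
    n_genes_hit = length(unique(present$gene[!is.na(present$gene)])))
  class(out) <- c("carrier_table", "data.frame")
  out
}

#' Estimate a deamination damage profile
#'
#' Computes the C->T mismatch frequency at each 5' distance in
#' `[0, max_pos)` over reference-C observations and fits the exponential
#' decay `rate(i) = d0 * exp(-lam * i)` by least squares on log
#' frequencies (zero-count positions are skipped). This is the internal
#' stand-in for an external damage-pattern check: it summarises how
#' damaged a library is and supplies defaults for the filter window.
#'
#' @param pileup observation data frame (needs `ref`, `base`, `dist5`).
#' @param max_pos number of 5' positions to profile (default 20).
#' @return a `damage_model`: list with `d0`, `lam`, `freq` (per-position
#'   raw frequencies), `n_obs`.
#' @export
estimate_damage_profile <- function(pileup, max_pos = 20L) {
  cobs <- pileup[pileup$ref == "C" & pileup$dist5 < max_pos, , drop = FALSE]
  if (nrow(cobs) == 0) {
    stop("no reference-C observations; cannot estimate damage", call. = FALSE)
  }
  if (nrow(cobs) < 1000) {
    warning(sprintf("only %d reference-C observations; damage estimate will be noisy",
                    nrow(cobs)), call. = FALSE)
  }
  posv <- 0:(max_pos - 1)
  n_at <- vapply(posv, function(i) sum(cobs$dist5 == i), numeric(1))
  t_at <- vapply(posv, function(i) sum(cobs$dist5 == i & cobs$base == "T"),
                 numeric(1))
  freq <- ifelse(n_at > 0, t_at / n_at, NA_real_)
  usable <- which(!is.na(freq) & freq > 0)
  if (length(usable) < 2) {
    stop("fewer than two positions with observed C->T mismatches; cannot fit d0 and lam",
         call. = FALSE)
  }
  ## weight by mismatch count: Var(log f-hat) is ~ 1/(number of mismatches),
  ## so unweighted log-LS would let noisy distal positions bias the fit
  fit <- stats::lm(log(freq[usable]) ~ posv[usable], weights = t_at[usable])
  d0 <- unname(exp(stats::coef(fit)[1]))
  lam <- unname(-stats::coef(fit)[2])
  structure(list(d0 = min(max(d0, 0), 1), lam = max(lam, 0),
                 freq = stats::setNames(freq, posv), n_obs = nrow(cobs)),
            class = "damage_model")
}

#' @export
print.damage_model <- function(x, ...) {
  cat(sprintf("<damage_model> d0=%.3f lam=%.3f (from %d ref-C observations)\n",
              x$d0, x$lam, x$n_obs))
  invisible(x)
}

#' Convert a text SAM file to the canonical pileup TSV schema
#'
#' Minimal single-end SAM reader for the package's observation model:
#' walks each aligned read's CIGAR (`M`, `=`, `X`, `I`, `D`, `S`, `H`,
#' `N`) and emits one observation row per aligned base, restricted to
#' `sites` when given. Distances from the read ends are in original read
#' orientation: for reverse-strand alignments `dist5` counts from the
#' right end of the aligned sequence.
#'
#' @param sam_path SAM file (text, with or without header).
#' @param sample_id sample identifier for the emitted rows.
#' @param reference named character vector chrom -> reference sequence,
#'   used to fill the `ref` column.
#' @param sites optional data frame (`chrom`, `pos`) restricting output.
#' @return pileup data frame in the canonical schema.
#' @export
sam_to_pileup <- function(sam_path, sample_id, reference, sites = NULL) {
  lines <- readLines(sam_path, warn = FALSE)
  lines <- lines[!grepl("^@", lines) & nzchar(lines)]
  keep_key <- if (!is.null(sites)) paste(sites$chrom, sites$pos) else NULL
  rows <- list()
  for (line in lines) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0) next                 # unmapped
    chrom <- f[3]; rpos <- as.integer(f[4]); cigar <- f[6]
    seq <- f[10]; qual <- f[11]
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    qpos <- 1L
    read_len <- nchar(seq)
    reverse <- bitwAnd(flag, 16L) > 0
    for (op in ops) {
      n <- as.integer(sub("[MIDNSHP=X]$", "", op))
      code <- sub("^[0-9]+", "", op)
      if (code %in% c("M", "=", "X")) {
        for (j in seq_len(n)) {
          p <- rpos + j - 1L
          key <- paste(chrom, p)
          if (is.null(keep_key) || key %in% keep_key) {
            q0 <- qpos + j - 1L
            d5 <- if (reverse) read_len - q0 else q0 - 1L
            rows[[length(rows) + 1]] <- data.frame(
              sample_id = sample_id, chrom = chrom, pos = p,
              ref = toupper(substr(reference[[chrom]], p, p)),
              base = toupper(substr(seq, q0, q0)),
              baseq = utf8ToInt(substr(qual, q0, q0)) - 33L,
              dist5 = d5, dist3 = read_len - 1L - d5,
              strand = if (reverse) "-" else "+", read_id = f[1],
              stringsAsFactors = FALSE)
          }
        }
        rpos <- rpos + n; qpos <- qpos + n
      } else if (code %in% c("I", "S")) {
        qpos <- qpos + n
      } else if (code %in% c("D", "N")) {
        rpos <- rpos + n
      }                                             # H, P consume nothing
    }
  }
  if (length(rows) == 0) {
    return(stats::setNames(
      data.frame(matrix(ncol = length(PILEUP_COLUMNS), nrow = 0)),
      PILEUP_COLUMNS))
  }
  do.call(rbind, rows)
}
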