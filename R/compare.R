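## Summaries and statistics comparing PV content between cohorts: per-gene
## abundance ratios, modern-vs-ancient Pearson correlation, clade/group
## Kruskal-Wallis comparison, carrier-timing bins, recurrence, pathway and
## founder-variant summaries. All printed percentages use half-away-from-zero
## rounding; summaries are order-invariant (canonical sort before return).

#' Per-gene PV abundance profile
#'
#' The abundance of a gene is its PV count over the total PV count across
#' all genes (the normalisation used to compare cohorts of different
#' size).
#'
#' @param pv_table data frame with a `gene` column, either one row per PV
#'   or with a `count`/`pvs` column of per-gene counts.
#' @param by grouping column (default `"gene"`).
#' @return an `abundance_profile` data frame (`gene`, `n`, `ratio`) with
#'   attribute `total`.
#' @export
abundance_profile <- function(pv_table, by = "gene") {
  stopifnot(by %in% names(pv_table))
  if (nrow(pv_table) == 0) stop("empty PV table", call. = FALSE)
  count_col <- intersect(c("count", "pvs", "n"), names(pv_table))
  if (length(count_col) > 0) {
    counts <- tapply(as.numeric(pv_table[[count_col[1]]]), pv_table[[by]], sum)
  } else {
    counts <- table(pv_table[[by]])
  }
  total <- sum(counts)
  if (total <= 0) stop("abundance profile needs a positive PV total",
                       call. = FALSE)
  out <- data.frame(gene = names(counts), n = as.numeric(counts),
                    stringsAsFactors = FALSE)
  out$ratio <- out$n / total
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, total = total,
            class = c("abundance_profile", "data.frame"))
}

#' Pearson comparison of two abundance profiles
#'
#' Profiles are aligned by gene symbol (union of genes; a gene absent from
#' one cohort enters with ratio 0), then the Pearson correlation of the
#' ratio vectors is tested two-tailed (t statistic, `n - 2` degrees of
#' freedom).
#'
#' @param profile_a,profile_b `abundance_profile` objects.
#' @return list with `pearson_r`, `p_two_tailed`, `n_genes`, `method`,
#'   `degenerate` (TRUE when a ratio vector has zero variance).
#' @export
compare_abundance <- function(profile_a, profile_b) {
  genes <- sort(union(profile_a$gene, profile_b$gene))
  if (length(genes) < 3) {
    stop("need at least 3 genes in the union to test a correlation",
         call. = FALSE)
  }
  ra <- profile_a$ratio[match(genes, profile_a$gene)]
  rb <- profile_b$ratio[match(genes, profile_b$gene)]
  ra[is.na(ra)] <- 0
  rb[is.na(rb)] <- 0
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    return(list(pearson_r = NA_real_, p_two_tailed = NA_real_,
                n_genes = length(genes),
                method = "pearson (two-tailed t)", degenerate = TRUE))
  }
  ct <- stats::cor.test(ra, rb, method = "pearson",
                        alternative = "two.sided")
  list(pearson_r = unname(ct$estimate), p_two_tailed = ct$p.value,
       n_genes = length(genes), method = "pearson (two-tailed t)",
       degenerate = FALSE)
}

#' Kruskal-Wallis comparison of grouped values
#'
#' Rank-based one-way comparison with tie correction (e.g. per-clade
#' shared-PV counts).
#'
#' @param values_by_group named list of numeric vectors, one per group.
#' @return list with `H`, `df`, `p`, `n_groups`.
#' @export
group_compare <- function(values_by_group) {
  if (!is.list(values_by_group) || length(values_by_group) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(lengths(values_by_group) < 1)) {
    stop("every group needs at least one observation", call. = FALSE)
  }
  kt <- stats::kruskal.test(values_by_group)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n_groups = length(values_by_group))
}

#' Carrier timing summary
#'
#' Bins dated carriers into (0, 5000], (5000, 10000] and (10000, Inf)
#' years BP — "within 5000", "between 5000 and 10,000" and "before
#' 10,000" — and reports per-PV earliest (largest BP) and latest carrier
#' dates. Undated carriers are counted separately.
#'
#' @param carrier_table data frame of present calls with `variant` and
#'   `date_bp` columns (one row per carrier).
#' @param breaks bin boundaries in years BP (default `c(0, 5000, 10000, Inf)`).
#' @return list with `bin_counts`, `bin_percent` (1 d.p.), `n_dated`,
#'   `n_undated`, `per_pv` (data frame with earliest/latest dates).
#' @export
timing_summary <- function(carrier_table, breaks = c(0, 5000, 10000, Inf)) {
  dated <- carrier_table[!is.na(carrier_table$date_bp), , drop = FALSE]
  labs <- paste0("(", breaks[-length(breaks)], ",", breaks[-1], "]")
  bins <- cut(dated$date_bp, breaks = breaks, labels = labs, right = TRUE)
  counts <- as.integer(table(bins))
  names(counts) <- labs
  per_pv <- if (nrow(dated) > 0) {
    earliest <- tapply(dated$date_bp, dated$variant, max)
    latest <- tapply(dated$date_bp, dated$variant, min)
    data.frame(variant = names(earliest),
               earliest_bp = as.numeric(earliest),
               latest_bp = as.numeric(latest),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(variant = character(), earliest_bp = numeric(),
               latest_bp = numeric(), stringsAsFactors = FALSE)
  }
  per_pv <- per_pv[order(per_pv$variant), , drop = FALSE]
  rownames(per_pv) <- NULL
  list(bin_counts = counts,
       bin_percent = stats::setNames(pct(counts, nrow(dated), 1), labs),
       n_dated = nrow(dated),
       n_undated = sum(is.na(carrier_table$date_bp)),
       per_pv = per_pv)
}

#' Recurrent-PV summary
#'
#' A PV is recurrent when observed in at least `min_carriers` distinct
#' samples (default 2).
#'
#' @param carrier_table data frame of present calls with `variant`,
#'   `sample_id` (or a per-variant `n_carriers` count column), optionally
#'   `gene` and `date_bp`.
#' @param min_carriers recurrence threshold (default 2).
#' @return list with `per_pv` (carriers, first/last dates), `recurrent`
#'   subset, counts and the recurrent fraction (1 d.p. percent).
#' @export
recurrence_summary <- function(carrier_table, min_carriers = 2L) {
  ct <- carrier_table
  if (!is.null(ct$n_carriers)) {
    per <- data.frame(variant = ct$variant,
                      n_carriers = as.integer(ct$n_carriers),
                      gene = if (!is.null(ct$gene)) ct$gene else NA_character_,
                      earliest_bp = if (!is.null(ct$date_bp)) ct$date_bp else NA_real_,
                      latest_bp = if (!is.null(ct$date_bp)) ct$date_bp else NA_real_,
                      stringsAsFactors = FALSE)
  } else {
    n <- tapply(ct$sample_id, ct$variant,
                function(s) length(unique(s)))
    per <- data.frame(variant = names(n), n_carriers = as.integer(n),
                      stringsAsFactors = FALSE)
    if (!is.null(ct$gene)) {
      per$gene <- ct$gene[match(per$variant, ct$variant)]
    } else per$gene <- NA_character_
    if (!is.null(ct$date_bp)) {
      per$earliest_bp <- as.numeric(tapply(ct$date_bp, ct$variant,
                                           function(x) suppressWarnings(max(x, na.rm = TRUE))))
      per$latest_bp <- as.numeric(tapply(ct$date_bp, ct$variant,
                                         function(x) suppressWarnings(min(x, na.rm = TRUE))))
      per$earliest_bp[!is.finite(per$earliest_bp)] <- NA_real_
      per$latest_bp[!is.finite(per$latest_bp)] <- NA_real_
    }
  }
  per <- per[order(per$variant), , drop = FALSE]
  rownames(per) <- NULL
  rec <- per[per$n_carriers >= min_carriers, , drop = FALSE]
  list(per_pv = per,
       recurrent = rec,
       n_pvs = nrow(per),
       n_carriers = sum(per$n_carriers),
       n_recurrent_pvs = nrow(rec),
       n_recurrent_genes = length(unique(rec$gene[!is.na(rec$gene)])),
       recurrent_percent = pct(nrow(rec), nrow(per), 1))
}

#' Per-pathway PV summary with nonredundant totals
#'
#' Genes and PVs are counted once per pathway they belong to; the totals
#' row deduplicates genes and PVs across pathways ("nonredundant"
#' counting).
#'
#' @param pv_table data frame with `gene` and either one row per PV or a
#'   count column (`count`/`pvs`/`n`).
#' @param geneset a `ddr_gene_set`.
#' @return list with `per_pathway` data frame (`pathway`,
#'   `n_panel_genes`, `n_genes_with_pvs`, `gene_percent`, `n_pvs`) and
#'   nonredundant `total_genes_with_pvs` / `total_pvs`.
#' @export
pathway_summary <- function(pv_table, geneset) {
  stopifnot(inherits(geneset, "ddr_gene_set"))
  count_col <- intersect(c("count", "pvs", "n"), names(pv_table))
  per_gene <- if (length(count_col) > 0) {
    tapply(as.numeric(pv_table[[count_col[1]]]), pv_table$gene, sum)
  } else {
    table(pv_table$gene)
  }
  per_gene <- stats::setNames(as.numeric(per_gene), names(per_gene))
  rows <- lapply(PATHWAY_LABELS, function(pw) {
    panel <- geneset$gene[vapply(geneset$pathways, function(p) pw %in% p,
                                 logical(1))]
    with_pv <- intersect(panel, names(per_gene)[per_gene > 0])
    data.frame(pathway = pw, n_panel_genes = length(panel),
               n_genes_with_pvs = length(with_pv),
               gene_percent = pct(length(with_pv), length(panel), 0),
               n_pvs = sum(per_gene[with_pv]),
               stringsAsFactors = FALSE)
  })
  per_pathway <- do.call(rbind, rows)
  on_panel <- intersect(names(per_gene)[per_gene > 0], geneset$gene)
  list(per_pathway = per_pathway,
       total_genes_with_pvs = length(on_panel),
       total_pvs = sum(per_gene[on_panel]))
}

#' Founder-PV summary
#'
#' Per-gene founder counts and fractions, and the overall age span. Arisen
#' ages may be points or ranges; the span is taken over the older bound
#' (`age_bp_hi`) of each record.
#'
#' @param founder_table data frame with `gene` and `age_bp_lo`/`age_bp_hi`
#'   (point ages have `lo == hi`; open bounds are `NA`).
#' @return list with `per_gene` (`gene`, `n`, `percent` at 1 d.p.),
#'   `n_founders`, `oldest_bp`, `youngest_bp`.
#' @export
founder_summary <- function(founder_table) {
  stopifnot(all(c("gene", "age_bp_lo", "age_bp_hi") %in%
                  names(founder_table)))
  lo <- founder_table$age_bp_lo
  hi <- founder_table$age_bp_hi
  if (any(!is.na(lo) & lo <= 0) || any(!is.na(hi) & hi <= 0)) {
    stop("founder ages must be positive", call. = FALSE)
  }
  if (any(!is.na(lo) & !is.na(hi) & lo > hi)) {
    stop("founder age range has lower bound above upper bound",
         call. = FALSE)
  }
  n <- sort(table(founder_table$gene), decreasing = TRUE)
  per_gene <- data.frame(gene = names(n), n = as.integer(n),
                         percent = pct(as.integer(n), nrow(founder_table), 1),
                         stringsAsFactors = FALSE, row.names = NULL)
  list(per_gene = per_gene,
       n_founders = nrow(founder_table),
       n_genes = length(n),
       oldest_bp = suppressWarnings(max(hi, na.rm = TRUE)),
       youngest_bp = suppressWarnings(min(hi, na.rm = TRUE)))
}
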