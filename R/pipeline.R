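## Pipeline orchestration and export. The output bundle is a directory of
## canonical TSV tables plus a machine-readable JSON summary and the
## serialized configuration — a single-file database export is deliberately
## replaced by this self-contained TSV bundle.

#' Headline summary arithmetic from the packaged fixture tables
#'
#' Recomputes, from the packaged tables and printed counts, every headline
#' quantity of the analysis: per-gene totals, sharing and detection
#' percentages, recurrence, timing-bin percentages, founder fractions.
#' All percentages are exact rational arithmetic under half-away-from-zero
#' rounding; the sharing percentage is reported to two decimals, the rest
#' to one.
#'
#' @return named list of computed quantities.
#' @export
headline_summary <- function() {
  counts <- load_published_fixtures("results_counts")
  rc <- function(k) results_count(k, counts)
  tab2 <- load_published_fixtures("table2_primate_sharing")
  tab4 <- load_published_fixtures("table4_gene_counts")
  tab5 <- load_published_fixtures("table5_chek2")
  tab6 <- load_published_fixtures("table6_founders")

  prof <- abundance_profile(tab4)
  founders <- founder_summary(tab6)
  rec5 <- recurrence_summary(data.frame(variant = tab5$hgvs_c,
                                        n_carriers = tab5$n_carriers,
                                        gene = "CHEK2",
                                        stringsAsFactors = FALSE))
  ## carrier-timing table reconstructed from the printed bin counts
  timing <- timing_summary(data.frame(
    variant = "pv", date_bp = c(rep(2500, rc("carriers_within_5000")),
                                rep(7500, rc("carriers_5000_10000")),
                                rep(20000, rc("carriers_before_10000")))))
  list(
    snv_pvs = rc("snv_pvs"),
    percent_snvs_shared = pct(rc("shared_pvs"), rc("snv_pvs"), 2),
    percent_species_sharing = pct(rc("sharing_species"), rc("total_species"), 1),
    primate_shared_entries = nrow(tab2),
    ancient_pv_total = sum(tab4$pvs),
    ancient_gene_total = nrow(tab4),
    percent_genes_with_ancient_pvs = pct(nrow(tab4), rc("snv_genes"), 1),
    mlh1_abundance_percent = round_half_away(
      100 * prof$ratio[prof$gene == "MLH1"], 1),
    percent_recurrent = pct(rc("recurrent_pvs"), rc("ancient_pvs"), 1),
    percent_recurrent_genes = pct(rc("recurrent_genes"),
                                  rc("ancient_genes"), 1),
    chek2_pvs = rec5$n_pvs,
    chek2_carriers = rec5$n_carriers,
    timing_bin_percent = timing$bin_percent,
    founder_total = founders$n_founders,
    brca1_founder_percent =
      founders$per_gene$percent[founders$per_gene$gene == "BRCA1"],
    founder_oldest_bp = founders$oldest_bp,
    founder_youngest_bp = founders$youngest_bp)
}

default_config <- function() {
  list(min_stars = 3L, keep_classes = c("pathogenic", "likely_pathogenic"),
       exclude_conflicting = TRUE, k = 3L, min_baseq = 1L,
       min_clean_alt = 1L, bin_edges = c(0, 5000, 10000, Inf),
       n_boot = 1000L, seed = 1L, reference_assembly = "hg19")
}

validate_config <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  errs <- character()
  if (cfg$min_stars < 0 || cfg$min_stars > 4) {
    errs <- c(errs, "min_stars must be in 0..4")
  }
  if (cfg$k < 0) errs <- c(errs, "k must be >= 0")
  if (cfg$min_baseq < 0) errs <- c(errs, "min_baseq must be >= 0")
  if (cfg$min_clean_alt < 1) errs <- c(errs, "min_clean_alt must be >= 1")
  if (length(errs) > 0) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes catalog loading/filtering, alignment sharing, ancient-sample
#' scanning, cohort comparison and (optionally) dN/dS classification, as
#' configured, and writes a TSV/JSON output bundle. Paths absent from the
#' config simply skip their stage; with no paths at all the run is
#' fixtures-only and reproduces the headline summary arithmetic.
#'
#' @param config named list: paths (`catalog`, `catalog_format`, `maf`,
#'   `species_map`, `pileups`, `metadata`, `dnds_pairs`), parameters
#'   (`min_stars`, `keep_classes`, `k`, `min_baseq`, `min_clean_alt`,
#'   `bin_edges`, `n_boot`, `seed`), and `out` (output directory).
#' @return the summary list, invisibly; the bundle is written under
#'   `config$out` when given.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  out_dir <- cfg$out
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      write_tsv(df, file.path(out_dir, paste0(name, ".tsv")))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  summary <- list(config = cfg[setdiff(names(cfg), "out")])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  catalog <- NULL
  if (!is.null(cfg$catalog)) {
    catalog <- stage("catalog", {
      cat0 <- load_variant_table(cfg$catalog,
                                 format = if (is.null(cfg$catalog_format))
                                   "tsv" else cfg$catalog_format)
      cat0 <- filter_clinical(cat0, cfg$keep_classes, cfg$min_stars,
                              cfg$exclude_conflicting)
      select_snvs(cat0)
    })
    panel <- stage("catalog", load_gene_panel(cfg$gene_panel))
    catalog <- assign_pathways(catalog, panel)
    emit(catalog$variants[, setdiff(names(catalog$variants), "pathways")],
         "catalog")
    summary$catalog <- list(n_snvs = n_variants(catalog),
                            trail = catalog$trail)
  }

  if (!is.null(cfg$maf) && !is.null(catalog)) {
    sharing <- stage("sharing", {
      idx <- index_maf(cfg$maf, cfg$reference_assembly)
      clades <- if (!is.null(cfg$species_map))
        load_species_map(cfg$species_map) else NULL
      species <- if (!is.null(clades)) names(clades) else
        setdiff(unique(unlist(lapply(idx$blocks,
                                     function(b) b$rows$species))),
                cfg$reference_assembly)
      m <- build_sharing_matrix(catalog, idx, species, clades)
      list(matrix = m, summary = sharing_summary(m))
    })
    emit(data.frame(variant = rownames(sharing$matrix),
                    as.data.frame(unclass(sharing$matrix)),
                    check.names = FALSE), "sharing_matrix")
    emit(sharing$summary$per_species, "sharing_per_species")
    summary$sharing <- sharing$summary[c("n_variants", "n_shared_variants",
                                         "percent_shared",
                                         "n_species_sharing")]
    if (!is.null(sharing$summary$clade_values) &&
        length(sharing$summary$clade_values) >= 2) {
      summary$sharing$clade_test <-
        group_compare(sharing$summary$clade_values)
    }
  }

  if (!is.null(cfg$pileups) && !is.null(catalog)) {
    carriers <- stage("ancient", {
      pile <- read_pileup(cfg$pileups)
      meta <- read_sample_metadata(cfg$metadata)
      scan_samples(catalog, pile, meta, cfg$min_baseq, cfg$k,
                   cfg$min_clean_alt)
    })
    emit(as.data.frame(carriers), "carriers")
    present <- carriers[carriers$status == "present", , drop = FALSE]
    summary$ancient <- attr(carriers, "summary")
    summary$ancient$timing <- timing_summary(present, cfg$bin_edges)[
      c("bin_counts", "bin_percent", "n_dated", "n_undated")]
    rec <- recurrence_summary(present)
    emit(rec$per_pv, "recurrence")
    summary$ancient$recurrence <- rec[c("n_pvs", "n_carriers",
                                        "n_recurrent_pvs",
                                        "recurrent_percent")]
  }

  if (!is.null(cfg$dnds_pairs)) {
    dn <- stage("dnds", {
      files <- sort(list.files(cfg$dnds_pairs, pattern = "\\.(fa|fasta)$",
                               full.names = TRUE))
      rows <- lapply(files, function(f) {
        pair <- read_codon_pair(f)
        res <- dnds(pair)
        cls <- classify_selection(res, n_boot = cfg$n_boot,
                                  seed = cfg$seed)
        data.frame(pair = basename(f), N = res$N, S = res$S, Nd = res$Nd,
                   Sd = res$Sd, dN = res$dN, dS = res$dS,
                   omega = res$omega, ci_lower = cls$ci[["lower"]],
                   ci_upper = cls$ci[["upper"]],
                   classification = cls$classification,
                   method = res$method, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    emit(dn, "dnds")
    summary$dnds <- list(n_pairs = nrow(dn),
                         classifications = table(dn$classification))
  }

  summary$headline <- stage("fixtures", headline_summary())

  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(summary)
}
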