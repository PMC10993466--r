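# Shared helpers: tiny catalogs, pileups and independent oracles used
# across the unit tests. All fixtures are built in code.

write_catalog_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_catalog_df <- function(n = 3, clin_class = "pathogenic", stars = 4L,
                            snv = TRUE) {
  refs <- rep(c("A", "C", "G", "T"), length.out = n)
  alts <- rep(c("G", "T", "A", "C"), length.out = n)
  if (!snv) alts <- paste0(alts, "A")
  data.frame(chrom = rep("chr1", n),
             pos = seq(101, by = 10, length.out = n),
             ref = refs, alt = alts, gene = rep("GENE1", n),
             clin_class = rep_len(clin_class, n),
             review_stars = rep_len(stars, n),
             stringsAsFactors = FALSE)
}

catalog_from_df <- function(df) {
  load_variant_table(write_catalog_tsv(df), format = "tsv")
}

# independent brute-force reference-row walk: scan every character of the
# reference text of every block and record (position -> per-species base)
brute_maf_columns <- function(blocks, reference = "hg19") {
  out <- list()
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    r <- b$rows
    if (r$species[1] != reference) next
    texts <- strsplit(r$text, "")
    pos0 <- r$start[1]
    for (col in seq_along(texts[[1]])) {
      ch <- texts[[1]][col]
      if (ch == "-") next
      key <- paste(r$src_chrom[1], pos0 + 1)
      entries <- character(nrow(r) - 1)
      names(entries) <- r$species[-1]
      for (i in seq_len(nrow(r))[-1]) {
        c2 <- toupper(texts[[i]][col])
        entries[r$species[i]] <- if (c2 == "-") "gap" else c2
      }
      rec <- list(ref_base = toupper(ch), entries = entries,
                  score = b$score, block = bi)
      if (is.null(out[[key]]) || (!is.na(rec$score) &&
                                  rec$score > out[[key]]$score)) {
        out[[key]] <- rec
      }
      pos0 <- pos0 + 1
    }
  }
  out
}

# exhaustive pathway oracle for codon differences: enumerate every ordering
# of the differing positions recursively, classify each step by amino-acid
# change, drop orderings through stops (all orderings if none survive)
oracle_codon_diffs <- function(c1, c2, code = Biostrings::GENETIC_CODE) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  dp <- which(a != b)
  if (length(dp) == 0) return(c(nd = 0, sd = 0))
  paths <- list()
  walk <- function(cur, remaining, nd, sd, hit_stop) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- list(nd = nd, sd = sd,
                                          hit_stop = hit_stop)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- b[p]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      walk(nxt, setdiff(remaining, p),
           nd + (aa1 != aa2), sd + (aa1 == aa2),
           hit_stop || aa2 == "*")
    }
  }
  walk(a, dp, 0, 0, FALSE)
  ok <- Filter(function(p) !p$hit_stop, paths)
  if (length(ok) == 0) ok <- paths
  c(nd = mean(vapply(ok, `[[`, numeric(1), "nd")),
    sd = mean(vapply(ok, `[[`, numeric(1), "sd")))
}

sense_codon_list <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}
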