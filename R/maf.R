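## UCSC MAF (Multiple Alignment Format) reading/writing, position indexing,
## and per-species allele-sharing calls at human SNV positions.
##
## MAF conventions honored: "##maf version=1" header; 'a' lines open a block
## (score=...), 's' lines carry (src, start, size, strand, srcSize, text)
## where start is 0-based on the +-strand reckoning of the source (for '-'
## rows, relative to the reverse complement); i/e/q lines are ignored.
## The first 's' row of each block must be the configured reference
## (human) assembly. Soft-masked lowercase bases are uppercased before
## allele comparison.

SHARING_STATUSES <- c("shared", "not_shared", "unaligned", "ref_mismatch")

CLADE_LABELS <- c("Primate", "Euarchontoglires", "Laurasiatheria",
                  "Afrotheria", "Mammalia", "Aves", "Sarcopterygii", "Fish")

maf_src_species <- function(src) sub("\\..*$", "", src)
maf_src_chrom <- function(src) sub("^[^.]*\\.", "", src)

#' Read a MAF file
#'
#' @param path MAF file.
#' @return list of blocks; each block has `score`, `offset` (line number of
#'   its `a` line) and `rows`, a data frame with columns `species`,
#'   `src_chrom`, `start`, `size`, `strand`, `src_size`, `text`.
#' @export
read_maf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || length(cur$rows) == 0) return(NULL)
    rows <- do.call(rbind, cur$rows)
    lens <- nchar(rows$text)
    if (length(unique(lens)) != 1) {
      stop(sprintf("ragged MAF block at line %d: row texts of unequal length",
                   cur$offset), call. = FALSE)
    }
    ungapped <- nchar(gsub("-", "", rows$text, fixed = TRUE))
    if (any(ungapped != rows$size)) {
      stop(sprintf("MAF block at line %d: ungapped text length != size field",
                   cur$offset), call. = FALSE)
    }
    list(score = cur$score, offset = cur$offset, rows = rows)
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("^#", line) || !nzchar(trimws(line))) next
    type <- substr(line, 1, 1)
    if (type == "a") {
      b <- flush(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1]] <- b
      score <- NA_real_
      m <- regmatches(line, regexec("score=([-0-9.eE+]+)", line))[[1]]
      if (length(m) == 2) score <- as.numeric(m[2])
      cur <- list(score = score, offset = i, rows = list())
    } else if (type == "s") {
      if (is.null(cur)) stop("MAF 's' line outside any block at line ", i,
                             call. = FALSE)
      f <- strsplit(trimws(line), "[ \t]+")[[1]]
      if (length(f) != 7) stop("malformed MAF 's' line at line ", i,
                               call. = FALSE)
      cur$rows[[length(cur$rows) + 1]] <- data.frame(
        species = maf_src_species(f[2]), src_chrom = maf_src_chrom(f[2]),
        start = as.numeric(f[3]), size = as.numeric(f[4]), strand = f[5],
        src_size = as.numeric(f[6]), text = f[7], stringsAsFactors = FALSE)
    }
    ## i/e/q lines carry alignment metadata we do not use
  }
  b <- flush(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1]] <- b
  blocks
}

#' Write MAF blocks to a file
#'
#' @param blocks list of blocks as produced by [read_maf()] or the
#'   simulator.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines(sprintf("a score=%.6f", if (is.na(b$score)) 0 else b$score),
               con)
    r <- b$rows
    src <- paste(r$species, r$src_chrom, sep = ".")
    writeLines(sprintf("s %s %d %d %s %d %s", src, as.integer(r$start),
                       as.integer(r$size), r$strand, as.integer(r$src_size),
                       r$text), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Index a MAF by human reference interval
#'
#' Builds an interval lookup from human (chrom, 0-based half-open interval)
#' to alignment blocks. Blocks whose first row is not the reference
#' assembly are skipped with a warning. Overlapping blocks are all
#' retained, with scores, so queries can resolve conflicts.
#'
#' @param maf either a path or a block list from [read_maf()].
#' @param reference_assembly assembly label of the human reference rows
#'   (e.g. `"hg19"`).
#' @return a `maf_index`.
#' @export
index_maf <- function(maf, reference_assembly = "hg19") {
  blocks <- if (is.character(maf)) read_maf(maf) else maf
  keep <- logical(length(blocks))
  meta <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    r <- blocks[[i]]$rows
    if (r$species[1] != reference_assembly) {
      warning(sprintf("block at line %d has no leading %s reference row; skipped",
                      blocks[[i]]$offset, reference_assembly), call. = FALSE)
      next
    }
    if (r$strand[1] != "+") {
      warning(sprintf("block at line %d: reference row on '-' strand; skipped",
                      blocks[[i]]$offset), call. = FALSE)
      next
    }
    keep[i] <- TRUE
    meta[[i]] <- data.frame(block = i, chrom = r$src_chrom[1],
                            start = r$start[1], end = r$start[1] + r$size[1],
                            score = blocks[[i]]$score,
                            offset = blocks[[i]]$offset,
                            stringsAsFactors = FALSE)
  }
  structure(list(blocks = blocks,
                 intervals = do.call(rbind, meta[keep]),
                 reference_assembly = reference_assembly),
            class = "maf_index")
}

#' @export
print.maf_index <- function(x, ...) {
  cat(sprintf("<maf_index> %d indexed blocks (reference %s)\n",
              if (is.null(x$intervals)) 0L else nrow(x$intervals),
              x$reference_assembly))
  invisible(x)
}

#' Extract the alignment column at a human position
#'
#' Locates the block covering the 1-based human position (highest score
#' wins when blocks overlap; ties break to the lowest file offset), walks
#' the reference row text counting non-gap characters to find the column,
#' and reads every species' character there: a base (uppercased), `"gap"`
#' for `-`, or `"absent"` for species not in the block.
#'
#' @param index a `maf_index`.
#' @param chrom human chromosome.
#' @param pos1 1-based human position.
#' @return list with `chrom`, `pos`, `ref_base`, `entries` (named character
#'   vector per species) and `block`, or `NULL` if the position is not
#'   covered.
#' @export
column_at <- function(index, chrom, pos1) {
  stopifnot(inherits(index, "maf_index"), pos1 >= 1)
  iv <- index$intervals
  if (is.null(iv)) return(NULL)
  pos0 <- pos1 - 1
  hit <- iv[iv$chrom == chrom & iv$start <= pos0 & pos0 < iv$end, ,
            drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  hit <- hit[order(-hit$score, hit$offset), , drop = FALSE]
  b <- index$blocks[[hit$block[1]]]
  r <- b$rows
  ref_text <- strsplit(r$text[1], "")[[1]]
  ## walk the gapped reference text to the (pos0 - start + 1)-th base
  target <- pos0 - r$start[1] + 1
  bases_seen <- cumsum(ref_text != "-")
  col <- match(target, bases_seen)
  if (is.na(col)) return(NULL)   # unreachable given the interval test
  entries <- character(nrow(r) - 1)
  names(entries) <- r$species[-1]
  for (i in seq_len(nrow(r))[-1]) {
    ch <- toupper(substr(r$text[i], col, col))
    entries[r$species[i]] <- if (ch == "-") "gap" else ch
  }
  ## duplicate species rows: keep the first occurrence
  entries <- entries[!duplicated(names(entries))]
  list(chrom = chrom, pos = pos1, ref_base = toupper(ref_text[col]),
       entries = entries, block = hit$block[1])
}

#' Call per-species allele sharing for one SNV
#'
#' A species shares the human variant when its aligned base equals the
#' human ALTERNATE allele at the orthologous column. A non-gap base other
#' than the alternate is `not_shared`; a gap or a species missing from the
#' block is `unaligned`. When the aligned human base disagrees with the
#' catalog reference allele the whole variant is `ref_mismatch` and is
#' excluded from summaries.
#'
#' @param variant one-row slice of a catalog `variants` data frame (needs
#'   `ref`, `alt`, `is_snv`).
#' @param column output of [column_at()].
#' @param species_list species to report (default: species in the column).
#' @return named character vector of statuses per species, with attribute
#'   `ref_mismatch`.
#' @export
call_sharing <- function(variant, column, species_list = NULL) {
  if (!isTRUE(variant$is_snv)) {
    stop("call_sharing is defined for SNVs only", call. = FALSE)
  }
  if (is.null(species_list)) species_list <- names(column$entries)
  out <- rep("unaligned", length(species_list))
  names(out) <- species_list
  if (column$ref_base != toupper(variant$ref)) {
    out[] <- "ref_mismatch"
    attr(out, "ref_mismatch") <- TRUE
    return(out)
  }
  ent <- column$entries[species_list]
  names(ent) <- species_list
  aligned <- !is.na(ent) & ent %in% DNA_BASES
  out[aligned & ent == toupper(variant$alt)] <- "shared"
  out[aligned & ent != toupper(variant$alt)] <- "not_shared"
  attr(out, "ref_mismatch") <- FALSE
  out
}

#' Build the variant-by-species sharing matrix
#'
#' @param catalog SNV-only `pv_catalog`.
#' @param index a `maf_index`.
#' @param species_list character vector of species (column order).
#' @param clades optional named vector species -> clade (one of the eight
#'   vertebrate clades).
#' @return a `sharing_matrix`: character matrix (variants x species) with
#'   attributes `variants` (the catalog rows kept), `ref_mismatch`
#'   (excluded variant keys) and `clades`.
#' @export
build_sharing_matrix <- function(catalog, index, species_list,
                                 clades = NULL) {
  stopifnot(inherits(catalog, "pv_catalog"))
  v <- catalog$variants
  if (nrow(v) > 0 && !all(v$is_snv)) {
    stop("build_sharing_matrix requires an SNV-only catalog; run select_snvs()",
         call. = FALSE)
  }
  if (!is.null(clades) && !all(clades %in% CLADE_LABELS)) {
    stop("clade labels must be from the closed 8-clade set", call. = FALSE)
  }
  keys <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  m <- matrix("unaligned", nrow = nrow(v), ncol = length(species_list),
              dimnames = list(keys, species_list))
  mismatch <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    col <- column_at(index, v$chrom[i], v$pos[i])
    if (is.null(col)) next
    st <- call_sharing(v[i, , drop = FALSE], col, species_list)
    if (isTRUE(attr(st, "ref_mismatch"))) {
      mismatch[i] <- TRUE
    } else {
      m[i, ] <- st
    }
  }
  if (any(mismatch)) {
    message(sprintf("excluding %d variant(s) with reference mismatch: %s",
                    sum(mismatch),
                    paste(keys[mismatch], collapse = ", ")))
  }
  structure(m[!mismatch, , drop = FALSE],
            variants = v[!mismatch, , drop = FALSE],
            ref_mismatch = keys[mismatch],
            clades = clades,
            class = c("sharing_matrix", "matrix"))
}

#' Summarise a sharing matrix
#'
#' Percent shared is over the full catalog (unaligned species count
#' against sharing), to two decimals; per-species and per-clade shared
#' counts feed the clade comparison statistics.
#'
#' @param matrix a `sharing_matrix`.
#' @param clades optional named vector species -> clade, overriding the
#'   one attached to the matrix.
#' @return list with `n_variants`, `n_shared_variants`, `percent_shared`,
#'   `per_species` (data frame), `n_species_sharing`, and `per_clade`
#'   (data frame, when clades are known).
#' @export
sharing_summary <- function(matrix, clades = NULL) {
  stopifnot(inherits(matrix, "sharing_matrix"))
  if (is.null(clades)) clades <- attr(matrix, "clades")
  n_var <- nrow(matrix)
  shared_any <- if (n_var == 0) logical(0) else
    apply(matrix == "shared", 1, any)
  per_species <- data.frame(
    species = colnames(matrix),
    n_shared = if (n_var == 0) 0L else colSums(matrix == "shared"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(clades)) {
    per_species$clade <- unname(clades[per_species$species])
  }
  out <- list(
    n_variants = n_var,
    n_shared_variants = sum(shared_any),
    percent_shared = pct(sum(shared_any), n_var, digits = 2),
    per_species = per_species,
    n_species_sharing = sum(per_species$n_shared >= 1))
  if (!is.null(clades)) {
    agg <- stats::aggregate(n_shared ~ clade, data = per_species, FUN = sum)
    n_sp <- stats::aggregate(species ~ clade, data = per_species, FUN = length)
    per_clade <- merge(agg, n_sp, by = "clade")
    names(per_clade) <- c("clade", "n_shared", "n_species")
    out$per_clade <- per_clade
    out$clade_values <- split(per_species$n_shared, per_species$clade)
  }
  out
}

#' Load a species-to-clade map
#'
#' TSV with columns `species`, `assembly`, `clade` (clade from the closed
#' eight-clade vertebrate set).
#'
#' @param path TSV path.
#' @return named character vector assembly -> clade, with attribute
#'   `table` carrying the full data frame.
#' @export
load_species_map <- function(path) {
  df <- read_tsv_strict(path, required = c("species", "assembly", "clade"),
                        what = "species map")
  if (!all(df$clade %in% CLADE_LABELS)) {
    stop("species map has clade labels outside the closed 8-clade set",
         call. = FALSE)
  }
  structure(stats::setNames(df$clade, df$assembly), table = df)
}
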