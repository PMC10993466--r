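toy_maf <- function() {
  # hg19 row "AC-GT" starting at 0-based 100: bases at 100..103
  c("##maf version=1",
    "a score=50.0",
    "s hg19.chr1 100 4 + 1000 AC-GT",
    "s panTro.scaf1 0 5 + 500 ACTGT",
    "s galGal.scaf9 7 4 - 800 A-TGT",
    "",
    "a score=10.0",
    "s hg19.chr1 200 3 + 1000 GGA",
    "s panTro.scaf2 10 3 + 500 GCA")
}

write_toy_maf <- function(lines = toy_maf()) {
  f <- tempfile(fileext = ".maf")
  writeLines(lines, f)
  f
}

test_that("a toy MAF parses into indexed blocks and survives a round trip", {
  f <- write_toy_maf()
  blocks <- read_maf(f)
  expect_length(blocks, 2)
  expect_equal(blocks[[1]]$score, 50)
  expect_equal(blocks[[1]]$rows$size, c(4, 5, 4))
  idx <- index_maf(blocks)
  expect_equal(nrow(idx$intervals), 2)
  f2 <- tempfile(fileext = ".maf")
  write_maf(blocks, f2)
  b2 <- read_maf(f2)
  expect_equal(b2[[1]]$rows$text, blocks[[1]]$rows$text)
  expect_equal(b2[[2]]$rows$start, blocks[[2]]$rows$start)
})

test_that("ragged blocks and missing reference rows are rejected or skipped", {
  bad <- toy_maf()
  bad[4] <- "s panTro.scaf1 0 4 + 500 ACTG"   # shorter text
  expect_error(read_maf(write_toy_maf(bad)), "ragged|unequal")
  noref <- c("##maf version=1", "a score=1",
             "s panTro.scaf1 0 2 + 10 AC")
  expect_warning(idx <- index_maf(write_toy_maf(noref)), "reference row")
  expect_null(idx$intervals)
})

test_that("column_at walks reference gaps correctly (hand-checked arithmetic)", {
  idx <- index_maf(write_toy_maf())
  # pos1 = 104 is 0-based 103, the 4th reference base, text column 5 ('T')
  col <- column_at(idx, "chr1", 104)
  expect_equal(col$ref_base, "T")
  expect_equal(unname(col$entries["panTro"]), "T")
  expect_equal(unname(col$entries["galGal"]), "T")
  # pos1 = 102 -> 0-based 101 -> 2nd base, text column 2 ('C'); galGal gap
  col2 <- column_at(idx, "chr1", 102)
  expect_equal(col2$ref_base, "C")
  expect_equal(unname(col2$entries["galGal"]), "gap")
  # outside every block
  expect_null(column_at(idx, "chr1", 50))
  expect_null(column_at(idx, "chr2", 101))
})

test_that("sharing calls match alt-allele semantics with closed statuses", {
  idx <- index_maf(write_toy_maf())
  v <- data.frame(chrom = "chr1", pos = 102L, ref = "C", alt = "T",
                  is_snv = TRUE, stringsAsFactors = FALSE)
  col <- column_at(idx, "chr1", 102)
  st <- call_sharing(v, col, c("panTro", "galGal", "mm10"))
  expect_equal(unname(st["panTro"]), "not_shared")  # base C == ref, not alt
  expect_equal(unname(st["galGal"]), "unaligned")   # gap
  expect_equal(unname(st["mm10"]), "unaligned")     # absent species
  # alt match
  v2 <- v; v2$pos <- 104L; v2$ref <- "T"; v2$alt <- "G"
  st2 <- call_sharing(v2, column_at(idx, "chr1", 104), "panTro")
  expect_equal(unname(st2["panTro"]), "not_shared")
  # ref mismatch poisons the variant
  v3 <- v; v3$ref <- "A"
  st3 <- call_sharing(v3, col, "panTro")
  expect_true(attr(st3, "ref_mismatch"))
  expect_equal(unname(st3["panTro"]), "ref_mismatch")
  # non-SNV is a contract error
  v4 <- v; v4$is_snv <- FALSE
  expect_error(call_sharing(v4, col), "SNV")
})

test_that("column_at equals a brute-force per-character walk on simulated MAFs", {
  for (seed in 1:3) {
    tree <- "((hg19:0.08,panTro:0.08):0.1,(galGal:0.3,danRer:0.4):0.15);"
    sim <- simulate_species_alignment(tree, 400, seed = seed,
                                      start = 5000, n_blocks = 7)
    f <- tempfile(fileext = ".maf")
    write_maf(sim$blocks, f)
    idx <- index_maf(f)
    oracle <- brute_maf_columns(read_maf(f))
    for (pos1 in c(5001, 5100, 5203, 5399, 5400)) {
      col <- column_at(idx, "chr1", pos1)
      key <- paste("chr1", pos1)
      if (is.null(oracle[[key]])) {
        expect_null(col)
      } else {
        expect_equal(col$ref_base, oracle[[key]]$ref_base)
        expect_equal(col$entries[names(oracle[[key]]$entries)],
                     oracle[[key]]$entries)
      }
    }
  }
})

test_that("overlapping blocks resolve by score then file offset", {
  lines <- c("##maf version=1",
             "a score=5",
             "s hg19.chr1 100 3 + 1000 AAA",
             "s sp1.s1 0 3 + 10 CCC",
             "",
             "a score=9",
             "s hg19.chr1 101 3 + 1000 TTT",
             "s sp1.s1 0 3 + 10 GGG",
             "",
             "a score=9",
             "s hg19.chr1 101 3 + 1000 TTT",
             "s sp1.s1 3 3 + 10 AAA")
  idx <- index_maf(write_toy_maf(lines))
  col <- column_at(idx, "chr1", 102)   # overlap of all three
  expect_equal(col$ref_base, "T")                   # higher score wins
  expect_equal(unname(col$entries["sp1"]), "G")     # earlier block wins tie
})

test_that("sharing matrix equals a brute-force nested-loop oracle with planted truth", {
  tree <- paste0("(hg19:0,(", paste(sprintf("sp%02d:0", 1:10),
                                    collapse = ","), "):0);")
  sim <- simulate_species_alignment(tree, 3000, seed = 21, start = 0)
  plan <- data.frame(variant = c(1, 1, 5, 12, 40),
                     species = c("sp01", "sp07", "sp03", "sp10", "sp01"),
                     stringsAsFactors = FALSE)
  pl <- plant_variants(sim, 40, convergent_plan = plan, seed = 22)
  species <- sprintf("sp%02d", 1:10)
  idx <- index_maf(pl$blocks)
  m <- build_sharing_matrix(pl$catalog, idx, species)
  # zero-branch tree: sharing is exactly the planted plan
  expect_equal(sum(m == "shared"), nrow(plan))
  for (r in seq_len(nrow(plan))) {
    expect_equal(unname(m[plan$variant[r], plan$species[r]]), "shared")
  }
  # independent O(nm) re-scan over sequences
  v <- pl$catalog$variants
  for (i in seq_len(nrow(v))) {
    for (sp in species) {
      base <- substr(pl$sequences[[sp]], v$pos[i], v$pos[i])
      want <- if (base == v$alt[i]) "shared" else "not_shared"
      expect_equal(unname(m[i, sp]), want)
    }
  }
  # partition property: statuses sum to the species count per variant
  expect_true(all(rowSums(m == "shared") + rowSums(m == "not_shared") +
                    rowSums(m == "unaligned") == length(species)))
  # monotonicity: adding a species leaves existing statuses unchanged
  m2 <- build_sharing_matrix(pl$catalog, idx, c(species, "spXX"))
  expect_equal(m2[, species], m[, species])
  expect_true(all(m2[, "spXX"] == "unaligned"))
})

test_that("sharing summary computes percentages and clade rollups", {
  tree <- "(hg19:0,(sp1:0,sp2:0,sp3:0):0);"
  sim <- simulate_species_alignment(tree, 500, seed = 5)
  plan <- data.frame(variant = c(1, 2, 2), species = c("sp1", "sp1", "sp2"))
  pl <- plant_variants(sim, 8, convergent_plan = plan, seed = 6)
  idx <- index_maf(pl$blocks)
  clades <- c(sp1 = "Primate", sp2 = "Aves", sp3 = "Fish")
  m <- build_sharing_matrix(pl$catalog, idx, names(clades), clades)
  s <- sharing_summary(m)
  expect_equal(s$n_variants, 8)
  expect_equal(s$n_shared_variants, 2)
  expect_equal(s$percent_shared, 25)
  expect_equal(s$n_species_sharing, 2)
  expect_equal(sum(s$per_clade$n_shared), 3)
  # empty matrix degenerates gracefully
  empty <- build_sharing_matrix(
    catalog_from_df(make_catalog_df(0)[0, ]), idx, names(clades), clades)
  expect_equal(sharing_summary(empty)$n_shared_variants, 0)
})

test_that("strand field on species rows does not affect sharing calls", {
  # MAF texts are always reference-oriented; flipping a species' strand
  # bookkeeping (as for a reverse-complemented source genome) must not
  # change any call
  f <- write_toy_maf()
  blocks <- read_maf(f)
  flipped <- blocks
  flipped[[1]]$rows$strand[3] <- "+"
  v <- data.frame(chrom = "chr1", pos = 104L, ref = "T", alt = "C",
                  is_snv = TRUE, stringsAsFactors = FALSE)
  s1 <- call_sharing(v, column_at(index_maf(blocks), "chr1", 104))
  s2 <- call_sharing(v, column_at(index_maf(flipped), "chr1", 104))
  expect_identical(s1, s2)
})
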