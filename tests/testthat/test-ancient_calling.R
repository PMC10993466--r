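region_seq <- function(len = 2000, seed = 100) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

meta_for <- function(ids, date_bp = 3000) {
  data.frame(sample_id = ids, date_bp = date_bp, location = "X",
             group = "ancient_human", stringsAsFactors = FALSE)
}

test_that("damage suspicion covers exactly the terminal deamination classes", {
  obs <- data.frame(base = c("T", "T", "A", "A", "G"),
                    dist5 = c(0, 5, 9, 9, 0), dist3 = c(9, 4, 0, 5, 9))
  expect_equal(damage_suspect(obs, "C", "T", k = 3),
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(damage_suspect(obs, "G", "A", k = 3),
               c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # non-deamination class never suspect at any position
  expect_false(any(damage_suspect(obs, "A", "G", k = 10)))
  expect_false(any(damage_suspect(obs, "C", "T", k = 0)))
})

test_that("suspect fraction at 5' termini matches the simulated rate", {
  seqc <- region_seq(3000)
  pile <- simulate_ancient_reads(seqc, NULL, coverage = 40, read_len = 60,
                                 d0 = 0.3, lam = 0.5, seed = 31)
  term <- pile[pile$ref == "C" & pile$dist5 == 0, ]
  phat <- mean(term$base == "T")
  se <- sqrt(0.3 * 0.7 / nrow(term))
  expect_gt(nrow(term), 500)
  expect_lt(abs(phat - 0.3), 4 * se)
})

test_that("presence calls follow the clean-alt rule with damage flags", {
  site <- function(bases, d5, ref = "C") {
    list(sample_id = "S1", chrom = "chr1", pos = 10L, ref = ref,
         obs = data.frame(base = bases, baseq = rep(30L, length(bases)),
                          dist5 = d5, dist3 = 59L - d5,
                          stringsAsFactors = FALSE))
  }
  v <- data.frame(chrom = "chr1", pos = 10L, ref = "C", alt = "T",
                  gene = "G1", stringsAsFactors = FALSE)
  # empty site
  empty <- site(character(0), integer(0))
  expect_equal(call_variant_presence(empty, v)$status, "no_data")
  # all alt support within the damage window: absent + damage_only
  allend <- call_variant_presence(site(c("T", "T", "T"), c(0, 1, 2)), v, k = 3)
  expect_equal(allend$status, "absent")
  expect_true(allend$damage_only)
  expect_equal(allend$alt_total, 3)
  expect_equal(allend$alt_clean, 0)
  # one clean alt read is enough
  one <- call_variant_presence(site(c("T", "C"), c(30, 0)), v, k = 3)
  expect_equal(one$status, "present")
  # damage rule inapplicable to A>G even at the terminus, min_baseq = 1
  v2 <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "G",
                   gene = "G1", stringsAsFactors = FALSE)
  s2 <- site("G", 0L, ref = "A")
  s2$obs$baseq <- 1L
  expect_equal(call_variant_presence(s2, v2)$status, "present")
  # base quality below threshold drops the observation
  s3 <- site("T", 30L)
  s3$obs$baseq <- 0L
  expect_equal(call_variant_presence(s3, v, min_baseq = 1)$status, "no_data")
  # coordinate mismatch is a contract error
  v4 <- v; v4$pos <- 11L
  expect_error(call_variant_presence(site("T", 30L), v4), "coordinates")
})

test_that("cohort scan recovers planted carrier truth exactly without damage", {
  seqc <- region_seq(4000)
  sim <- list(sequences = c(hg19 = seqc),
              blocks = list(list(score = 1, offset = NA, rows = data.frame(
                species = "hg19", src_chrom = "chr1", start = 0,
                size = 4000, strand = "+", src_size = 4000, text = seqc,
                stringsAsFactors = FALSE))))
  pl <- plant_variants(sim, 50, seed = 41)
  v <- pl$catalog$variants
  sites <- data.frame(chrom = "chr1", pos = v$pos)
  set.seed(42)
  truth <- list()
  piles <- list()
  for (s in 1:20) {
    sid <- sprintf("S%02d", s)
    carried <- sort(sample(50, sample(0:5, 1)))
    truth[[sid]] <- carried
    gt <- data.frame(pos = v$pos[carried], alt = v$alt[carried])
    piles[[sid]] <- simulate_ancient_reads(
      seqc, gt, coverage = 30, read_len = 60, d0 = 0, seq_error = 0,
      seed = 1000 + s, sample_id = sid, sites = sites, homozygous = TRUE)
  }
  pile <- do.call(rbind, piles)
  ct <- scan_samples(pl$catalog, pile, meta_for(names(truth)), k = 3)
  for (sid in names(truth)) {
    calls <- ct[ct$sample_id == sid & ct$status == "present", ]
    expect_setequal(calls$variant,
                    with(v[truth[[sid]], , drop = FALSE],
                         paste(chrom, pos, ref, alt, sep = ":")))
  }
  # metadata joined
  expect_true(all(ct$date_bp == 3000))
  # orphan sample id errors
  expect_error(scan_samples(pl$catalog, pile, meta_for("SOMEONE_ELSE")),
               "missing from metadata")
})

test_that("zero-coverage cohorts yield only no_data", {
  cat0 <- catalog_from_df(make_catalog_df(3))
  pile <- data.frame(sample_id = "S1", chrom = "chr1",
                     pos = cat0$variants$pos, ref = cat0$variants$ref,
                     base = "A", baseq = 0L, dist5 = 10L, dist3 = 39L,
                     strand = "+", read_id = "r1",
                     stringsAsFactors = FALSE)
  ct <- scan_samples(cat0, pile, meta_for("S1"), min_baseq = 20)
  expect_true(all(ct$status == "no_data"))
  expect_equal(attr(ct, "summary")$n_pvs_present, 0)
})

test_that("damage filter is inert outside the C>T / G>A classes", {
  seqc <- region_seq(3000, seed = 55)
  sim <- list(sequences = c(hg19 = seqc),
              blocks = list(list(score = 1, offset = NA, rows = data.frame(
                species = "hg19", src_chrom = "chr1", start = 0,
                size = 3000, strand = "+", src_size = 3000, text = seqc,
                stringsAsFactors = FALSE))))
  pl <- plant_variants(sim, 30, spectrum = c("A>G" = 0.5, "T>C" = 0.5),
                       seed = 56)
  v <- pl$catalog$variants
  gt <- data.frame(pos = v$pos[1:10], alt = v$alt[1:10])
  pile <- simulate_ancient_reads(seqc, gt, coverage = 15, read_len = 60,
                                 d0 = 0.3, lam = 0.5, seed = 57,
                                 sample_id = "S1",
                                 sites = data.frame(chrom = "chr1",
                                                    pos = v$pos))
  meta <- meta_for("S1")
  ct0 <- scan_samples(pl$catalog, pile, meta, k = 0)
  ct10 <- scan_samples(pl$catalog, pile, meta, k = 10)
  expect_identical(ct0$status, ct10$status)
  expect_identical(ct0$alt_clean, ct10$alt_clean)
})

test_that("sensitivity is non-decreasing in coverage", {
  seqc <- region_seq(3000, seed = 60)
  sim <- list(sequences = c(hg19 = seqc),
              blocks = list(list(score = 1, offset = NA, rows = data.frame(
                species = "hg19", src_chrom = "chr1", start = 0,
                size = 3000, strand = "+", src_size = 3000, text = seqc,
                stringsAsFactors = FALSE))))
  pl <- plant_variants(sim, 40, seed = 61)
  v <- pl$catalog$variants
  gt <- data.frame(pos = v$pos, alt = v$alt)   # carrier of everything
  sens <- vapply(c(1, 2, 5, 10), function(cov) {
    hits <- 0
    for (s in 1:4) {
      pile <- simulate_ancient_reads(
        seqc, gt, coverage = cov, read_len = 60, d0 = 0.2, lam = 0.4,
        seed = 7000 + 17 * s + round(100 * cov), sample_id = "S1",
        sites = data.frame(chrom = "chr1", pos = v$pos))
      ct <- scan_samples(pl$catalog, pile, meta_for("S1"))
      hits <- hits + sum(ct$status == "present")
    }
    hits / (4 * nrow(v))
  }, numeric(1))
  expect_true(all(diff(sens) >= -0.02))   # monotone up to binomial jitter
  expect_gt(sens[4], sens[1])
})

test_that("damage profile recovery and degenerate inputs behave as specified", {
  seqc <- region_seq(4000, seed = 70)
  pile <- simulate_ancient_reads(seqc, NULL, coverage = 120, read_len = 60,
                                 d0 = 0.3, lam = 0.5, seed = 71)
  dm <- estimate_damage_profile(pile)
  expect_lt(abs(dm$d0 - 0.3), 0.05)
  expect_lt(abs(dm$lam - 0.5), 0.15)
  # null library: fitted d0 bounded by sequencing error + 3 sigma
  err <- 0.002
  pile0 <- simulate_ancient_reads(seqc, NULL, coverage = 60, read_len = 60,
                                  d0 = 0, seq_error = err, seed = 72)
  n_c <- sum(pile0$ref == "C" & pile0$dist5 == 0)
  dm0 <- estimate_damage_profile(pile0)
  expect_lt(dm0$d0, err / 3 + 3 * sqrt(err * (1 - err) / n_c))
  # single-position data cannot fit two parameters
  single <- pile[pile$dist5 == 0, ]
  expect_error(suppressWarnings(estimate_damage_profile(single, max_pos = 1)),
               "fewer than two positions")
  # no reference-C observations at all
  noc <- pile[pile$ref == "A", ]
  expect_error(estimate_damage_profile(noc), "no reference-C")
})

test_that("SAM reader reproduces a hand-built pileup with CIGAR clips", {
  ref <- c(chr1 = "ACGTACGTACGTACGTACGT")
  sam <- c("@HD\tVN:1.6",
           paste("r1", 0, "chr1", 3, 60, "2S4M1D3M", "*", 0, 0,
                 "TTGTACCGT", "IIIIIIIII", sep = "\t"),
           paste("r2", 16, "chr1", 5, 60, "4M", "*", 0, 0,
                 "ACGT", "IIII", sep = "\t"))
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  p <- sam_to_pileup(f, "S1", ref)
  r1 <- p[p$read_id == "r1", ]
  # r1: soft-clip consumes query; 4M aligns query 3..6 to ref 3..6
  expect_equal(r1$pos[1:4], 3:6)
  expect_equal(r1$base[1:4], c("G", "T", "A", "C"))
  expect_equal(r1$ref[1:4], c("G", "T", "A", "C"))
  expect_equal(r1$dist5[1:4], 2:5)
  # deletion advances the reference: next M block at ref 8..10
  expect_equal(r1$pos[5:7], 8:10)
  # reverse-strand read counts dist5 from the right end
  r2 <- p[p$read_id == "r2", ]
  expect_equal(r2$strand, rep("-", 4))
  expect_equal(r2$dist5, 3:0)
  expect_equal(r2$dist3, 0:3)
  # Phred decoding
  expect_true(all(p$baseq == 40))
})
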