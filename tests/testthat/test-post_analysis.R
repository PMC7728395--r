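# Post-analysis accounting: flanks, coverage, correlations, the
# long-range screen.

test_that("introgression is called from shared flanks", {
  set.seed(23)
  up <- random_dna(3500)
  down <- random_dna(3500)
  shared <- classify_introgression(
    list(upstream = up, downstream = down),
    list(upstream = up, downstream = random_dna(3500)))
  expect_equal(shared$verdict, "putative_introgression")

  different <- classify_introgression(
    list(upstream = up, downstream = down),
    list(upstream = random_dna(3500), downstream = random_dna(3500)))
  expect_equal(different$verdict, "HTT")

  missing <- classify_introgression(
    list(upstream = NA_character_, downstream = NA_character_),
    list(upstream = up, downstream = down))
  expect_equal(missing$verdict, "indeterminate")
})

test_that("raising flank identity never flips introgression back to HTT", {
  set.seed(24)
  a <- random_dna(3200)
  verdicts <- vapply(c(0.5, 0.25, 0.1, 0), function(rate) {
    b <- paste(vapply(strsplit(a, "")[[1]], function(ch) {
      if (runif(1) < rate) sample(c("A", "C", "G", "T"), 1) else ch
    }, character(1)), collapse = "")
    classify_introgression(
      list(upstream = a, downstream = NA_character_),
      list(upstream = b, downstream = NA_character_))$verdict
  }, character(1))
  # once shared at some identity, higher identity stays shared
  first_shared <- match("putative_introgression", verdicts)
  if (!is.na(first_shared)) {
    expect_true(all(verdicts[first_shared:length(verdicts)] ==
                      "putative_introgression"))
  }
  expect_equal(verdicts[length(verdicts)], "putative_introgression")
})

test_that("flank extraction clips at contig edges", {
  genome <- c(ctg = random_dna(12000))
  fl <- extract_flanks(genome, "ctg", 5000, 6000, flank = 4000,
                       min_flank = 3000)
  expect_equal(nchar(fl$upstream), 4000)
  expect_equal(nchar(fl$downstream), 4000)
  # too close to the edge: 800 nt available < 3000 minimum
  fl2 <- extract_flanks(genome, "ctg", 800, 1000, flank = 4000)
  expect_true(is.na(fl2$upstream))
})

test_that("genome fraction uses union semantics", {
  iv <- data.frame(species = "sp1", contig = "c1",
                   start = c(0, 50), end = c(100, 150))
  rep <- genome_htt_fraction(iv, c(sp1 = 1000))
  expect_equal(rep$htt_bp, 150)
  expect_equal(rep$fraction, 0.15)

  # duplicates counted once; empty species get zero
  iv2 <- rbind(iv, iv[1, ])
  rep2 <- genome_htt_fraction(iv2, c(sp1 = 1000, sp2 = 500))
  expect_equal(rep2$htt_bp[rep2$species == "sp1"], 150)
  expect_equal(rep2$fraction[rep2$species == "sp2"], 0)

  expect_error(genome_htt_fraction(
    data.frame(species = "sp1", contig = "c1", start = 0, end = 2000),
    c(sp1 = 1000), contig_sizes = c(c1 = 1500)), "out of contig")
})

test_that("coverage union matches the boolean-array oracle", {
  set.seed(25)
  for (i in 1:20) {
    n <- sample(1:15, 1)
    starts <- sample.int(5000, n) - 1
    ends <- starts + sample.int(800, n)
    iv <- data.frame(species = "s", contig = "c", start = starts,
                     end = ends)
    rep <- genome_htt_fraction(iv, c(s = 10000))
    expect_equal(rep$htt_bp, oracle_union_bp(starts, ends, 10000))
  }
})

test_that("rank correlation handles monotone and tied data", {
  x <- 1:8
  expect_equal(correlate_fraction_size(x, 2 * x + 3)$rho, 1)
  expect_equal(correlate_fraction_size(x, -x)$rho, -1)

  set.seed(26)
  for (i in 1:10) {
    a <- sample(c(1:6, 3, 3), 8)        # ties included
    b <- rnorm(8)
    got <- correlate_fraction_size(a, b)
    ra <- rank(a); rb <- rank(b)
    pearson_on_ranks <- sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
    expect_equal(got$rho, pearson_on_ranks, tolerance = 1e-12)
  }
  expect_error(correlate_fraction_size(rep(1, 8), rnorm(8)), "constant")
  expect_error(correlate_fraction_size(1:3, 1:3), "at least 4")
})

test_that("point-biserial equals Pearson with 0/1 coding", {
  got <- geo_correlation(c(1, 1, 0, 0), c(2, 2, 0, 0))
  expect_equal(got$r_pb, 1)
  expect_equal(got$p, 0)

  flat <- geo_correlation(c(1, 1, 0, 0), c(3, 1, 1, 3))
  expect_equal(flat$r_pb, 0)

  set.seed(27)
  for (i in 1:15) {
    ov <- c(1, 0, rbinom(10, 1, 0.5))
    ct <- rpois(12, 3)
    if (var(ct) == 0) next
    got <- geo_correlation(ov, ct)
    expect_equal(got$r_pb, cor(ov, ct), tolerance = 1e-12)
    expect_equal(got$p, cor.test(ov, ct)$p.value, tolerance = 1e-9)
  }
  expect_error(geo_correlation(c(1, 1, 1), c(1, 2, 3)), "both")
  expect_error(geo_correlation(c(1, 0, 1), c(2, 2, 2)), "constant")
})

screen_hits <- function(fam, asm, n_copies, cov = 0.9, pid = 0.9,
                        flen = 1000) {
  # one HSP per copy, each on its own contig, covering cov of the family
  do.call(rbind, lapply(seq_len(n_copies), function(i) {
    data.frame(query_id = fam, subject_id = paste0(asm, "_ctg", i),
               percent_identity = pid, aln_length = round(cov * flen),
               q_start = 0, q_end = round(cov * flen),
               s_start = 0, s_end = round(cov * flen),
               strand = "+", evalue = 0, bit_score = 500,
               search_kind = "nucleotide", assembly = asm,
               stringsAsFactors = FALSE)
  }))
}

test_that("long-range screen applies coverage, identity and copy rules", {
  fl <- c(fam = 1000)
  amap <- data.frame(assembly = c("asm1", "asm2", "asm3", "asm4"),
                     species = c("sp1", "sp2", "sp2", "sp2"))

  # coverage 0.85, identity 0.9, 6 copies: candidate
  r1 <- long_range_screen(screen_hits("fam", "asm1", 6, cov = 0.85),
                          amap, fl)
  expect_true(r1$candidate[r1$species == "sp1"])
  expect_equal(r1$basis[r1$species == "sp1"], "copy_number")

  # 5 copies in a single assembly: rejected (strictly more than five)
  r2 <- long_range_screen(screen_hits("fam", "asm1", 5, cov = 0.85),
                          amap, fl)
  expect_false(r2$candidate[r2$species == "sp1"])

  # coverage exactly 0.80 fails the strict coverage rule
  r3 <- long_range_screen(screen_hits("fam", "asm1", 6, cov = 0.80),
                          amap, fl)
  expect_false(r3$candidate[r3$species == "sp1"])

  # 2 copies but qualifying matches in 2 of 3 assemblies of the species
  hits <- rbind(screen_hits("fam", "asm2", 2), screen_hits("fam", "asm3", 2))
  r4 <- long_range_screen(hits, amap, fl)
  expect_true(r4$candidate[r4$species == "sp2"])
  expect_equal(r4$basis[r4$species == "sp2"], "assembly_majority")

  # 1 of 3 assemblies is not a majority
  r5 <- long_range_screen(screen_hits("fam", "asm2", 2), amap, fl)
  expect_false(r5$candidate[r5$species == "sp2"])
})
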