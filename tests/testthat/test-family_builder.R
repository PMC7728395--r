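# Family construction: clustering, consensus, ORFs, candidate filters,
# alignment trimming.

test_that("greedy clustering follows identity and coverage thresholds", {
  set.seed(3)
  base <- random_dna(200)
  # identical pair: one cluster
  cl <- cluster_sequences(c(x = base, y = base))
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$members, c("x", "y"))

  # ~70% identity: separate singletons
  far <- mutate_at(base, sample.int(200, 60))
  cl2 <- cluster_sequences(c(x = base, y = far))
  expect_length(cl2, 2)

  # A~B 85%, A~C 85%, B~C ~82%: all join A's cluster under greedy order
  b <- mutate_at(base, 1:15)
  c_ <- mutate_at(base, 186:200)
  cl3 <- cluster_sequences(c(A = base, B = b, C = c_))
  expect_length(cl3, 1)
  expect_equal(cl3[[1]]$representative, "A")

  # short sequence failing coverage of the shorter stays separate
  frag <- substr(base, 1, 100)
  cl4 <- cluster_sequences(c(long = base, frag = frag),
                           min_coverage = 0.8)
  expect_length(cl4, 1)   # full coverage of the shorter: joins
  cl5 <- cluster_sequences(c(long = base,
                             frag = substr(far, 1, 100)))
  expect_length(cl5, 2)
})

test_that("clustering is deterministic under permutation", {
  set.seed(9)
  recs <- stats::setNames(
    replicate(6, random_dna(sample(120:180, 1))),
    paste0("s", 1:6))
  ref <- cluster_sequences(recs)
  canon <- function(cl) {
    sorted <- lapply(cl, function(x) sort(x$members))
    sorted[order(vapply(sorted, `[[`, "", 1))]
  }
  for (i in 1:5) {
    perm <- sample(seq_along(recs))
    expect_identical(canon(cluster_sequences(recs[perm])), canon(ref))
  }
})

test_that("consensus takes the per-column plurality with A<C<G<T ties", {
  expect_identical(build_consensus(c(a = "ACGTACGT")), "ACGTACGT")
  # three members differing at one column: majority base wins
  expect_identical(
    build_consensus(c(a = "AAAAAAA", b = "AAAAAAA", c = "AAGAAAA")),
    "AAAAAAA")
  # two members disagreeing at a column: A beats G by fixed order
  expect_identical(build_consensus(c(a = "TTATT", b = "TTGTT")), "TTATT")
})

test_that("longest ORF agrees with the exhaustive six-frame oracle", {
  # hand case: the plus strand reads ATG AAA CCC | TAA (3 aa), but the
  # reverse strand TTA GGG TTT CAT runs stop-free for 4 codons and wins
  orf <- find_longest_orf("ATGAAACCCTAA")
  expect_equal(orf$aa_length, oracle_longest_orf_aa("ATGAAACCCTAA"))
  expect_equal(orf$aa_length, 4)
  expect_equal(orf$strand, "-")

  # stop-bounded cassette blocked in the other five frames: exact length
  expect_equal(find_longest_orf(orf_cassette(40))$aa_length, 40)
  expect_equal(oracle_longest_orf_aa(orf_cassette(40)), 40)

  expect_equal(find_longest_orf("")$aa_length, 0)
  expect_equal(find_longest_orf("AC")$aa_length, 0)

  set.seed(21)
  for (i in 1:25) {
    s <- random_dna(300)
    expect_equal(find_longest_orf(s)$aa_length, oracle_longest_orf_aa(s),
                 info = s)
  }
  # an all-stop plus frame still yields an ORF from another frame/strand
  s <- strrep("TAA", 30)
  expect_gt(find_longest_orf(s)$aa_length, 0)
  expect_equal(find_longest_orf(s)$aa_length, oracle_longest_orf_aa(s))
})

test_that("ORF coordinates are frame-consistent on the oriented sequence", {
  set.seed(4)
  for (i in 1:10) {
    s <- random_dna(250)
    orf <- find_longest_orf(s)
    expect_equal((orf$end - orf$start) %% 3, 0)
    expect_equal(orf$aa_length, (orf$end - orf$start) / 3)
    oriented <- if (orf$strand == "+") toupper(s) else revcomp(toupper(s))
    expect_identical(substring(oriented, orf$start + 1, orf$end),
                     orf$sequence)
  }
})

make_family <- function(id, species, lens, te_class = "ClassI",
                        orf_codons = 350) {
  # members are clean ORFs of orf_codons sense codons, padded to length
  seqs <- vapply(lens, function(L) {
    body <- paste(random_codon(orf_codons), collapse = "")
    substr(paste0(body, random_dna(max(0, L - nchar(body)))), 1, L)
  }, character(1))
  list(family_id = id, te_class = te_class,
       members = data.frame(species = species, sequence = seqs,
                            stringsAsFactors = FALSE))
}

test_that("candidate filters apply the three rules in order", {
  set.seed(5)
  one_sp <- make_family("f1", c("A", "A"), c(1200, 1200))
  short <- make_family("f2", c("A", "B"), c(1200, 599))
  good <- make_family("f3", c("A", "B"), c(1200, 1200))
  res <- filter_htt_candidates(list(one_sp, short, good))
  expect_equal(vapply(res$kept, `[[`, "", "family_id"), "f3")
  expect_match(res$rejected$reason[res$rejected$family_id == "f1"],
               "species")
  expect_match(res$rejected$reason[res$rejected$family_id == "f2"],
               "shorter")
})

test_that("ORF thresholds are strict and class-specific", {
  # ClassI: a longest ORF of exactly 300 aa fails, 301 passes
  fam_300 <- list(family_id = "f300", te_class = "ClassI",
                  members = data.frame(
                    species = c("A", "B"),
                    sequence = rep(orf_cassette(300), 2)))
  fam_301 <- list(family_id = "f301", te_class = "ClassI",
                  members = data.frame(
                    species = c("A", "B"),
                    sequence = rep(orf_cassette(301), 2)))
  res <- filter_htt_candidates(list(fam_300, fam_301))
  expect_equal(vapply(res$kept, `[[`, "", "family_id"), "f301")
  # a 201-aa ORF passes for ClassII (threshold 200) only
  fam_ii <- list(family_id = "fii", te_class = "ClassII",
                 members = data.frame(species = c("A", "B"),
                                      sequence = rep(orf_cassette(201), 2)))
  res2 <- filter_htt_candidates(list(fam_ii))
  expect_length(res2$kept, 1)
  fam_i_short <- list(family_id = "fi", te_class = "ClassI",
                      members = fam_ii$members)
  expect_length(filter_htt_candidates(list(fam_i_short))$kept, 0)
  # unknown class errors without an override
  fam_uk <- list(family_id = "fuk", te_class = "unknown",
                 members = fam_ii$members)
  expect_error(filter_htt_candidates(list(fam_uk)), "unknown")
  res3 <- filter_htt_candidates(list(fam_uk),
                                orf_min_aa = c(unknown = 200))
  expect_length(res3$kept, 1)
})

test_that("kept families pass all filters on independent re-check", {
  set.seed(8)
  fams <- list(
    make_family("a", c("A", "B"), c(700, 650)),
    make_family("b", c("A", "A"), c(700, 700)),
    make_family("c", c("A", "B", "C"), c(1500, 900, 620))
  )
  res <- filter_htt_candidates(fams, min_len = 600)
  for (fam in res$kept) {
    expect_gte(length(unique(fam$members$species)), 2)
    expect_true(all(nchar(fam$members$sequence) >= 600))
    expect_gt(max(vapply(fam$members$sequence,
                         function(s) find_longest_orf(s)$aa_length,
                         integer(1))), 300)
  }
})

test_that("reference trimming removes flanks and enforces frame", {
  aln <- c(ref = "---ATGAAA---", other = "CCCATGAAACCC")
  tr <- trim_to_reference(aln, "ref")
  expect_identical(unname(tr["ref"]), "ATGAAA")
  expect_identical(unname(tr["other"]), "ATGAAA")

  # gapless reference: only the trailing frame trim applies
  aln2 <- c(ref = "ATGAAACCCT", other = "ATGAAACCCT")
  tr2 <- trim_to_reference(aln2, "ref")
  expect_equal(nchar(tr2[["ref"]]), 9)

  expect_error(trim_to_reference(aln, "missing"), "absent")
})
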