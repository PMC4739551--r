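test_that("SAM parsing maps fields, converts POS, and skips unmapped reads", {
  f <- sam_file(c(
    sam_line("r1", 0, "chrT", 5, 60, "4M", "ACGT", "IIII"),
    sam_line("r2", 4, "*", 0, 0, "*", "ACGT", "IIII"),
    sam_line("r3", 0, "chrT", 10, 60, "2M1I1M", "ACGT", "IIII")
  ))
  p <- parse_sam(f)
  expect_equal(p$skipped_unmapped, 1)
  expect_equal(nrow(p$reads), 2)
  expect_equal(p$reads$pos0[1], 4)      # 1-based SAM POS - 1
  expect_equal(p$reads$mapq[1], 60)
  expect_equal(p$reads$cigar[2], "2M1I1M")  # query-consuming ops sum to 4
})

test_that("SAM parsing rejects malformed CIGARs and length mismatches", {
  f <- sam_file(sam_line("r1", 0, "chrT", 5, 60, "4Q", "ACGT", "IIII"))
  expect_error(parse_sam(f), "malformed CIGAR")
  f <- sam_file(sam_line("r1", 0, "chrT", 5, 60, "5M", "ACGT", "IIII"))
  expect_error(parse_sam(f), "query length")
  f <- sam_file(sam_line("r1", 0, "chrT", 5, 60, "4M", "ACGT", "III"))
  expect_error(parse_sam(f), "qual/seq length")
})

test_that("duplicate marking keeps the best quality sum, qname tie-break", {
  f <- sam_file(c(
    sam_line("a", 0, "chrT", 100, 60, "4M", "ACGT", qstr(rep(30, 4))),
    sam_line("b", 0, "chrT", 100, 60, "4M", "ACGT", qstr(c(30, 30, 30, 20)))
  ))
  r <- mark_duplicates(parse_sam(f)$reads)
  expect_equal(bitwAnd(r$flag, 1024L) != 0, c(FALSE, TRUE))

  # opposite strands never group
  f <- sam_file(c(
    sam_line("a", 0, "chrT", 100, 60, "4M", "ACGT", qstr(rep(30, 4))),
    sam_line("b", 16, "chrT", 97, 60, "4M", "ACGT", qstr(rep(30, 4)))
  ))
  r <- mark_duplicates(parse_sam(f)$reads)
  expect_true(all(bitwAnd(r$flag, 1024L) == 0))

  # equal-quality three-read group: lexicographically smallest qname kept
  f <- sam_file(c(
    sam_line("b", 0, "chrT", 100, 60, "3M", "ACG", qstr(rep(30, 3))),
    sam_line("a", 0, "chrT", 100, 60, "3M", "ACG", qstr(rep(30, 3))),
    sam_line("c", 0, "chrT", 100, 60, "3M", "ACG", qstr(c(30, 30, 20)))
  ))
  r <- mark_duplicates(parse_sam(f)$reads)
  kept <- r$qname[bitwAnd(r$flag, 1024L) == 0]
  expect_equal(kept, "a")

  # clipped 5' ends group with unclipped ones
  f <- sam_file(c(
    sam_line("a", 0, "chrT", 100, 60, "4M", "ACGT", qstr(rep(30, 4))),
    sam_line("b", 0, "chrT", 102, 60, "2S2M", "ACGT", qstr(rep(20, 4)))
  ))
  r <- mark_duplicates(parse_sam(f)$reads)
  expect_equal(r$qname[bitwAnd(r$flag, 1024L) != 0], "b")
})

test_that("duplicate marking is idempotent", {
  set.seed(7)
  lines <- vapply(1:30, function(i) {
    sam_line(sprintf("r%02d", i), sample(c(0, 16), 1), "chrT",
             sample(100:105, 1), 60, "5M",
             paste(sample(c("A", "C", "G", "T"), 5, TRUE), collapse = ""),
             qstr(sample(20:40, 5, TRUE)))
  }, character(1))
  r1 <- mark_duplicates(parse_sam(sam_file(lines))$reads)
  r2 <- mark_duplicates(r1)
  expect_identical(r1, r2)
  expect_true(any(bitwAnd(r1$flag, 1024L) != 0))
})

test_that("pileup deposits bases per the CIGAR walk", {
  f <- sam_file(sam_line("r1", 0, "chrT", 11, 60, "4M", "ACGT",
                         qstr(rep(40, 4))))
  pu <- build_pileup(parse_sam(f)$reads, "chrT", 0, 30)
  for (i in 0:3) {
    col <- pileup_column(pu, 10 + i)
    expect_equal(col$total_raw, 1)
    expect_equal(unname(col$raw_counts[c("A", "C", "G", "T")[i + 1]]), 1)
  }

  # deletion: reference-consuming, no base deposited in the gap
  f <- sam_file(sam_line("r1", 0, "chrT", 1, 60, "2M1D2M", "ACGT",
                         qstr(rep(40, 4))))
  pu <- build_pileup(parse_sam(f)$reads, "chrT", 0, 10)
  expect_equal(pileup_column(pu, 0)$total_raw, 1)
  expect_equal(pileup_column(pu, 1)$total_raw, 1)
  expect_equal(pileup_column(pu, 2)$total_raw, 0)
  expect_equal(pileup_column(pu, 3)$total_raw, 1)
  expect_equal(pileup_column(pu, 4)$total_raw, 1)
  expect_equal(unname(pileup_column(pu, 3)$raw_counts["G"]), 1)

  # insertions consume query only; soft clips deposit nowhere
  f <- sam_file(sam_line("r1", 0, "chrT", 1, 60, "1S2M2I1M", "AACGGT",
                         qstr(rep(40, 6))))
  pu <- build_pileup(parse_sam(f)$reads, "chrT", 0, 10)
  expect_equal(sum(pu$raw), 3)
  expect_equal(unname(pileup_column(pu, 2)$raw_counts["T"]), 1)
})

test_that("base-quality filtering separates raw from filtered counts", {
  f <- sam_file(sam_line("r1", 0, "chrT", 5, 60, "1M", "A", qstr(5)))
  pu <- build_pileup(parse_sam(f)$reads, "chrT", 0, 10, min_base_qual = 20)
  col <- pileup_column(pu, 4)
  expect_equal(unname(col$raw_counts["A"]), 1)
  expect_equal(unname(col$filtered_counts["A"]), 0)
})

test_that("read filter policy drops low mapq, improper pairs, duplicates", {
  # distinct start positions so only dupA/dupB form a duplicate group;
  # all reads cover 0-based column 14
  lines <- c(
    sam_line("lowq", 0, "chrT", 8, 5, "10M", strrep("A", 10),
             qstr(rep(40, 10))),
    sam_line("pair_bad", 1, "chrT", 9, 60, "10M", strrep("A", 10),
             qstr(rep(40, 10))),
    sam_line("pair_ok", 3, "chrT", 10, 60, "10M", strrep("A", 10),
             qstr(rep(40, 10))),
    sam_line("dupA", 0, "chrT", 11, 60, "10M", strrep("A", 10),
             qstr(rep(40, 10))),
    sam_line("dupB", 0, "chrT", 11, 60, "10M", strrep("A", 10),
             qstr(rep(30, 10)))
  )
  reads <- mark_duplicates(parse_sam(sam_file(lines))$reads)
  pu <- build_pileup(reads, "chrT", 13, 16,
                     policy = read_filter_policy(min_mapq = 20,
                                                 require_proper_pair = TRUE,
                                                 drop_duplicates = TRUE))
  # surviving: pair_ok and dupA only
  expect_equal(pileup_column(pu, 14)$total_raw, 2)
})

test_that("pileup equals the read-expansion oracle on random CIGAR mixes", {
  set.seed(2024)
  for (rep in 1:12) {
    reads <- random_sam_reads(sample(20:200, 1))
    mbq <- sample(c(0, 13, 20, 30), 1)
    pu <- build_pileup(reads, "chrT", 0, 150,
                       policy = read_filter_policy(min_mapq = 0,
                                                   require_proper_pair = FALSE,
                                                   drop_duplicates = FALSE),
                       min_base_qual = mbq)
    orc <- oracle_pileup(reads, "chrT", 0, 150, mbq)
    expect_equal(unname(pu$raw), unname(orc$raw))
    expect_equal(unname(pu$filtered), unname(orc$filtered))
    expect_true(all(pu$filtered <= pu$raw))
  }
})

test_that("raising min_base_qual never increases filtered counts", {
  set.seed(99)
  reads <- random_sam_reads(100)
  policy <- read_filter_policy(0, FALSE, FALSE)
  prev <- build_pileup(reads, "chrT", 0, 150, policy, min_base_qual = 0)
  for (bq in c(10, 20, 30, 41)) {
    cur <- build_pileup(reads, "chrT", 0, 150, policy, min_base_qual = bq)
    expect_true(all(cur$filtered <= prev$filtered))
    prev <- cur
  }
})
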