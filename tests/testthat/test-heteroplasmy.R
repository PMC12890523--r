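test_that("pileup construction counts quality-passing calls per strand", {
  g <- genome(substr(strrep("ACGT", 300), 1, 800), name = "chrM",
              circular = TRUE)
  one <- frag_table(0L, 92L, strand = "+",
                    seq = substr(g$sequence, 1, 93),
                    qual = strrep("F", 93))
  pu <- build_pileup(one, g)
  expect_equal(nrow(pu), 93L)
  expect_true(all(pu$coverage == 1L))
  expect_true(all(pu$position == 0:92))
  # all calls are reference, on the plus strand
  refcol <- vapply(seq_len(93), function(i)
    pu[[paste0(pu$ref[i], "_plus")]][i], integer(1))
  expect_true(all(refcol == 1L))

  # a call below the base-quality threshold is excluded
  lowq <- one
  lowq$qual <- paste0(rawToChar(as.raw(33 + 10)), strrep("F", 92))
  pu2 <- build_pileup(lowq, g, min_baseq = 20)
  expect_false(0L %in% pu2$position)
  expect_equal(nrow(pu2), 92L)

  # two fragments on opposite strands at the same site
  two <- frag_table(c(0L, 0L), c(92L, 92L), strand = c("+", "-"),
                    seq = substr(g$sequence, 1, 93), qual = strrep("F", 93))
  pu3 <- build_pileup(two, g)
  expect_true(all(pu3$coverage == 2L))
  plus_tot <- rowSums(pu3[paste0(c("A", "C", "G", "T"), "_plus")])
  minus_tot <- rowSums(pu3[paste0(c("A", "C", "G", "T"), "_minus")])
  expect_true(all(plus_tot == 1L & minus_tot == 1L))

  # N calls are ignored; other letters are an error
  withn <- one
  substr(withn$seq, 5, 5) <- "N"
  expect_equal(nrow(build_pileup(withn, g)), 92L)
  bad <- one
  substr(bad$seq, 5, 5) <- "X"
  expect_error(build_pileup(bad, g), "alphabet")
})

test_that("pileup wraps circular coordinates and round-trips TSV", {
  g <- genome(substr(strrep("ACGT", 300), 1, 100), name = "chrM",
              circular = TRUE)
  wrap <- frag_table(95L, 104L, seq = paste0(substr(g$sequence, 96, 100),
                                             substr(g$sequence, 1, 5)),
                     qual = strrep("F", 10))
  pu <- build_pileup(wrap, g)
  expect_setequal(pu$position, c(95:99, 0:4))
  tsv <- tempfile(fileext = ".tsv")
  write_pileup_tsv(pu, tsv)
  expect_equal(read_pileup_tsv(tsv)$coverage, pu$coverage)
})

test_that("Fisher strand test matches the enumeration oracle", {
  expect_equal(strand_equality_test(5, 495, 5, 495), 1)
  cases <- list(c(10, 490, 0, 500), c(3, 197, 9, 191), c(25, 475, 25, 475),
                c(0, 100, 5, 95), c(7, 3, 2, 8))
  for (cs in cases)
    expect_equal(strand_equality_test(cs[1], cs[2], cs[3], cs[4]),
                 oracle_fisher_2x2(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-10, info = paste(cs, collapse = ","))
  expect_error(strand_equality_test(0, 0, 5, 5), "at least one")
})

test_that("the four heteroplasmy criteria gate candidates in order", {
  site <- function(ap, am, rp, rm, ref = "A", alt = "G") {
    cn <- c(paste0(ref, c("_plus", "_minus")), paste0(alt, c("_plus", "_minus")))
    pileup_site(100L, ref, setNames(c(rp, rm, ap, am), cn))
  }
  # canonical pass: coverage 1000, alt 50 split 25/25 over 500-strand depths
  ok <- call_heteroplasmy(site(25, 25, 475, 475))
  expect_true(ok$pass)
  expect_equal(ok$site$maf, 0.05)
  expect_equal(ok$site$maf_plus, 0.05)
  expect_equal(ok$site$strand_p, 1)
  expect_equal(ok$site$alt, "G")

  # coverage must be strictly greater than 400
  at400 <- call_heteroplasmy(site(10, 10, 190, 190))
  expect_false(at400$pass)
  expect_equal(at400$reason, "coverage")
  just401 <- call_heteroplasmy(site(10, 10, 190, 191))
  expect_true(just401$pass)
  # ... and the boundary moves with the threshold
  expect_true(call_heteroplasmy(site(10, 10, 190, 190),
                                min_coverage = 399L)$pass)

  # overall MAF >= 1%
  low <- call_heteroplasmy(site(2, 2, 498, 498))
  expect_false(low$pass)
  expect_equal(low$reason, "MAF")
  expect_true(call_heteroplasmy(site(5, 5, 495, 495))$pass)  # exactly 1%
  expect_false(call_heteroplasmy(site(5, 5, 495, 495),
                                 min_maf = 0.0101)$pass)

  # per-strand MAF >= 0.6% on both strands
  skew <- call_heteroplasmy(site(9, 1, 491, 499))
  expect_false(skew$pass)
  expect_equal(skew$reason, "per-strand MAF")
  # relaxing the strand floor moves the candidate past that gate
  relaxed <- call_heteroplasmy(site(9, 1, 491, 499), min_strand_maf = 0.002)
  expect_false(identical(relaxed$reason, "per-strand MAF"))

  # strand balance: heavily unbalanced alt counts fail the Fisher gate
  bias <- call_heteroplasmy(site(30, 4, 470, 496))
  expect_false(bias$pass)
  expect_equal(bias$reason, "strand balance")
  expect_true(call_heteroplasmy(site(30, 4, 470, 496), alpha = 1e-6)$pass)
})

test_that("call_all recovers planted SNPs and reports none elsewhere", {
  g <- make_genomes(1200, 2000, seed = 21)
  positions <- c(150L, 600L, 900L)
  plans <- lapply(positions, function(p) {
    ref <- substr(g$mt$sequence, p + 1, p + 1)
    heteroplasmy_plan("kidney", p, ref,
                      setdiff(c("A", "C", "G", "T"), ref)[1], 0.05)
  })
  fr <- make_cfdna_fragments(g$mt, n_fragments = 10000, mt_fraction = 1,
                             plans = plans, error_rate = 0.001, seed = 22)
  pu <- build_pileup(fr, g$mt)
  calls <- call_all(pu, "kidney")
  expect_setequal(calls$position, positions)
  expect_true(all(abs(calls$maf - 0.05) < 0.02))
  expect_identical(attr(calls, "tissue"), "kidney")

  # determinism: identical pileups give identical call sets
  calls2 <- call_all(pu, "kidney")
  expect_identical(as.data.frame(calls), as.data.frame(calls2))

  # VCF round trip preserves the calls
  vcf <- tempfile(fileext = ".vcf")
  write_snp_vcf(calls, vcf)
  back <- read_snp_vcf(vcf, "kidney")
  expect_equal(back$position, calls$position)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$maf, calls$maf, tolerance = 1e-5)

  expect_equal(nrow(call_all(empty_pileup_for_test())), 0L)
})
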