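test_that("fragmentize windows a genome one centre per position", {
  # linear genome of exactly one window
  lin <- genome(substr(strrep("ACGT", 30), 1, 101), circular = FALSE)
  f1 <- fragmentize(lin, 101)
  expect_equal(nrow(f1), 1L)
  expect_equal(f1$center, 50L)

  # circular genome of length 200: 200 windows, wrapping across the origin
  circ <- make_genomes(200, 200, seed = 1)$mt
  f <- fragmentize(circ, 101)
  expect_equal(nrow(f), 200L)
  expect_equal(f$center, 0:199)
  ext <- paste0(circ$sequence, circ$sequence)
  wrap <- f$sequence[f$center == 0L]
  expect_identical(wrap, substr(ext, 200 - 50 + 1L, 200 + 51L))
  # consecutive windows overlap by window - 1 bases
  expect_identical(substr(f$sequence[1L], 2L, 101L),
                   substr(f$sequence[2L], 1L, 100L))

  expect_error(fragmentize(circ, 100), "odd")
  expect_error(fragmentize(genome("ACGTACGT"), 101), "shorter")
})

test_that("min_hamming finds planted windows on either strand", {
  g <- make_genomes(1200, 4000, seed = 3)
  win <- fragmentize(g$mt, 101)$sequence[500]

  nuc_fwd <- paste0(substr(g$nuclear$sequence, 1, 2000), win,
                    substr(g$nuclear$sequence, 2001, 3899))
  expect_equal(min_hamming(win, nuc_fwd), 0L)
  nuc_rc <- paste0(substr(g$nuclear$sequence, 1, 2000), oracle_revcomp(win),
                   substr(g$nuclear$sequence, 2001, 3899))
  expect_equal(min_hamming(win, nuc_rc), 0L)

  g3 <- make_genomes(1200, 4000, numts = list(numt_plan(1500, 500, 3)),
                     seed = 3)
  w3 <- fragmentize(g3$mt, 101)$sequence[501]
  expect_equal(min_hamming(w3, g3$nuclear),
               oracle_min_hamming(w3, g3$nuclear$sequence))
  expect_error(min_hamming(win, "ACGT"), "shorter")
})

test_that("profile equals the exhaustive brute-force oracle everywhere", {
  W <- 31L
  for (seed in c(2, 9)) {
    g <- make_genomes(120, 600,
                      numts = list(numt_plan(100, 30, 2),
                                   numt_plan(400, 80, 0, revcomp = TRUE)),
                      window = W, seed = seed)
    prof <- numt_profile(g$mt, g$nuclear, W)
    expect_equal(prof$d_min,
                 oracle_profile(g$mt$sequence, g$nuclear$sequence, W),
                 info = sprintf("seed %d", seed))
    # planted centres carry their planted distances
    expect_equal(prof$d_min[prof$position == 30], 2L)
    expect_equal(prof$d_min[prof$position == 80], 0L)
  }
})

test_that("profile respects strand symmetry, rotation and monotonicity", {
  W <- 21L
  g <- make_genomes(100, 400, numts = list(numt_plan(150, 40, 1)),
                    window = W, seed = 4)
  prof <- numt_profile(g$mt, g$nuclear, W)

  # reverse-complementing the nuclear genome leaves the profile unchanged
  rc <- genome(oracle_revcomp(g$nuclear$sequence), name = "rc")
  expect_equal(numt_profile(g$mt, rc, W)$d_min, prof$d_min)

  # rotating the circular origin permutes the values with the positions
  k <- 37L
  rot <- genome(paste0(substr(g$mt$sequence, k + 1L, 100L),
                       substr(g$mt$sequence, 1L, k)), circular = TRUE)
  prot <- numt_profile(rot, g$nuclear, W)
  expect_equal(prot$d_min, prof$d_min[((0:99 + k) %% 100) + 1L])

  # appending nuclear sequence can never increase any d_min
  longer <- genome(paste0(g$nuclear$sequence, random_dna_for_test(300)))
  expect_true(all(numt_profile(g$mt, longer, W)$d_min <= prof$d_min))

  # nuclear genome made of all windows: profile identically zero
  allwin <- genome(paste(fragmentize(g$mt, W)$sequence, collapse = ""))
  expect_true(all(numt_profile(g$mt, allwin, W)$d_min == 0L))

  # any comparison involving N is a mismatch, even N vs N: windows carrying
  # the N never reach 0 against a text built from themselves
  gn <- genome(paste0("N", substr(g$mt$sequence, 2L, 100L)), circular = TRUE)
  fn <- fragmentize(gn, W)
  alln <- genome(paste(fn$sequence, collapse = ""))
  pn <- numt_profile(gn, alln, W)
  has_n <- grepl("N", fn$sequence, fixed = TRUE)
  expect_true(all(pn$d_min[has_n] >= 1L))
  expect_true(all(pn$d_min[!has_n] == 0L))
})

test_that("target-region selection reports maximal qualifying runs", {
  mkprof <- function(d) {
    structure(data.frame(position = seq_along(d) - 1L, d_min = as.integer(d)),
              class = c("hamming_profile", "data.frame"), window = 101L,
              nuclear_name = "x")
  }
  expect_equal(nrow(select_target_regions(mkprof(rep(0, 10)), 1, 1)), 0L)

  allhigh <- select_target_regions(mkprof(rep(101, 10)), 50, 1)
  expect_equal(nrow(allhigh), 1L)
  expect_equal(c(allhigh$start, allhigh$end), c(0L, 10L))

  r <- select_target_regions(mkprof(c(0, 5, 5, 5, 0)), 5, 3)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end, r$min_profile_value), c(1L, 4L, 5L))
  # the same run is dropped when min_length exceeds it
  expect_equal(nrow(select_target_regions(mkprof(c(0, 5, 5, 5, 0)), 5, 4)), 0L)

  r2 <- select_target_regions(mkprof(c(9, 9, 0, 7, 9, 9, 0, 9)), 7, 2)
  expect_equal(r2$start, c(0L, 3L))
  expect_equal(r2$end, c(2L, 6L))
  expect_equal(r2$min_profile_value, c(9L, 7L))
})

test_that("profile and regions serialise to TSV and BED", {
  g <- make_genomes(150, 500, seed = 6, window = 21L)
  prof <- numt_profile(g$mt, g$nuclear, 21L)
  tsv <- tempfile(fileext = ".tsv")
  write_profile_tsv(prof, tsv)
  back <- read.table(tsv, header = TRUE)
  expect_equal(back$d_min, prof$d_min)

  reg <- select_target_regions(prof, min_distance = 2, min_length = 5)
  bed <- tempfile(fileext = ".bed")
  write_regions_bed(reg, bed)
  if (nrow(reg)) {
    bb <- read.table(bed)
    expect_equal(bb$V2, reg$start)
    expect_equal(bb$V3, reg$end)
  }
})
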