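# Synthetic genome pair generator: a circular mitochondrial genome plus a
# linear nuclear genome carrying planted NUMT copies at controlled Hamming
# distances. Ground truth for the NUMT scan.

#' Plan a planted NUMT insertion
#'
#' Describes one copy of a mitochondrial window to be planted into the
#' synthetic nuclear genome: where it lands, which mt window it copies,
#' how many substitutions it carries and whether it is reverse-complemented.
#'
#' @param insert_position 0-based nuclear coordinate of the first planted base.
#' @param mt_window_center 0-based mt coordinate of the window's central base.
#' @param n_mismatches number of substitutions planted into the copy.
#' @param revcomp plant the reverse complement?
#' @return an object of class `"numt_plan"`.
#' @export
numt_plan <- function(insert_position, mt_window_center, n_mismatches = 0L,
                      revcomp = FALSE) {
  stopifnot(insert_position >= 0, mt_window_center >= 0, n_mismatches >= 0)
  structure(list(insert_position = as.integer(insert_position),
                 mt_window_center = as.integer(mt_window_center),
                 n_mismatches = as.integer(n_mismatches),
                 revcomp = isTRUE(revcomp)),
            class = "numt_plan")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# substitute exactly n bases of `s` at positions sampled without replacement,
# each to a uniformly chosen *different* base: exact Hamming distance n
plant_mismatches <- function(s, n) {
  if (n == 0L) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (n > length(ch)) stop("n_mismatches exceeds window length")
  idx <- sample.int(length(ch), n)
  for (i in idx) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Generate a synthetic mitochondrial / nuclear genome pair
#'
#' Background bases are i.i.d. uniform over A/C/G/T. Each [numt_plan()] plants
#' a copy of the mt window centred at `mt_window_center` (window length
#' `window`) into the nuclear genome at `insert_position`, reverse-complemented
#' if requested, with exactly `n_mismatches` substitutions.
#'
#' @param mt_length length of the circular mitochondrial genome (bp).
#' @param nuc_length length of the linear nuclear genome (bp).
#' @param numts list of [numt_plan()] objects (may be empty).
#' @param window window length copied per plan (odd, default 101).
#' @param seed integer seed; the generator is bit-reproducible under it.
#' @param mt_name,nuc_name contig names.
#' @return list with elements `mt` (circular [genome()]) and `nuclear`
#'   (linear [genome()]), plus attribute `"numts"` echoing the plans.
#' @export
#' @examples
#' g <- make_genomes(2000, 5000,
#'                   numts = list(numt_plan(1000, 300, n_mismatches = 3)),
#'                   seed = 1)
#' g$mt; g$nuclear
make_genomes <- function(mt_length, nuc_length, numts = list(), window = 101L,
                         seed = 1L, mt_name = "chrM", nuc_name = "nuc1") {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window length must be odd")
  if (mt_length < window) stop("mt_length must be at least the window length")
  if (inherits(numts, "numt_plan")) numts <- list(numts)
  half <- (window - 1L) %/% 2L

  set.seed(as.integer(seed))
  mt_seq <- random_dna(mt_length)
  nuc_seq <- random_dna(nuc_length)

  if (length(numts)) {
    ins <- vapply(numts, `[[`, 0L, "insert_position")
    if (any(ins + window > nuc_length))
      stop("a planted window does not fit within the nuclear genome")
    o <- order(ins)
    if (any(diff(ins[o]) < window))
      stop("planted NUMT inserts overlap")
    for (p in numts) {
      win <- circ_substr(mt_seq, p$mt_window_center - half, window)
      if (p$revcomp) win <- revcomp(win)
      win <- plant_mismatches(win, p$n_mismatches)
      substr(nuc_seq, p$insert_position + 1L,
             p$insert_position + window) <- win
    }
  }

  out <- list(mt = genome(mt_seq, name = mt_name, circular = TRUE),
              nuclear = genome(nuc_seq, name = nuc_name, circular = FALSE))
  attr(out, "numts") <- numts
  attr(out, "window") <- window
  out
}
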