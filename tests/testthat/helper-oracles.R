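# Independent brute-force oracles used to validate the production code.
# These deliberately avoid the package's own scan/adjustment routines.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# mismatch count with the N-always-mismatches rule
oracle_mismatches <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(ca != cb | ca == "N" | cb == "N")
}

# exhaustive scan of one window (both strands) over every nuclear offset
oracle_min_hamming <- function(window, nuclear) {
  W <- nchar(window)
  offs <- 0:(nchar(nuclear) - W)
  subs <- substring(nuclear, offs + 1L, offs + W)
  best <- function(w) min(vapply(subs, oracle_mismatches, 0, a = w,
                                 USE.NAMES = FALSE))
  min(best(window), best(oracle_revcomp(window)))
}

# full profile by looping the single-window oracle over every centre
oracle_profile <- function(mt_seq, nuclear, window) {
  L <- nchar(mt_seq)
  half <- (window - 1L) %/% 2L
  ext <- paste0(mt_seq, substr(mt_seq, 1L, window - 1L))
  vapply(0:(L - 1L), function(center) {
    s <- (center - half) %% L
    oracle_min_hamming(substr(ext, s + 1L, s + window), nuclear)
  }, 0)
}

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (r in seq_len(m))
    q[o[r]] <- min(1, min(m * p[o][r:m] / (r:m)))
  q
}

# two-sided Fisher exact p for a 2x2 table by enumerating hypergeometric
# tables with the observed margins
oracle_fisher_2x2 <- function(a, b, c, d) {
  m1 <- a + c          # alt margin
  n1 <- a + b          # plus-strand margin
  N <- a + b + c + d
  support <- max(0, m1 + n1 - N):min(m1, n1)
  probs <- stats::dhyper(support, n1, N - n1, m1)
  obs <- stats::dhyper(a, n1, N - n1, m1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# CDF of the rounded, range-rejected truncated normal mixture that the
# fragment-size generator samples from
oracle_size_cdf <- function(model) {
  lo <- model$min_len - 0.5
  hi <- model$max_len + 0.5
  mass <- function(x) {
    sum(model$weights * (stats::pnorm(x, model$means, model$sds) -
                           stats::pnorm(lo, model$means, model$sds)))
  }
  total <- mass(hi)
  function(x) vapply(pmin(x + 0.5, hi), mass, 0) / total
}

empty_pileup_for_test <- function() {
  build_pileup(frag_table(integer(0), integer(0), seq = character(0),
                          qual = character(0)),
               genome("ACGTACGT", circular = TRUE))
}

random_dna_for_test <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small hand-built fragment record table for fragmentomics tests
frag_table <- function(first, last, rname = "chrM", strand = "+",
                       mapq = 60L, primary = TRUE, seq = NA, qual = NA) {
  n <- length(first)
  structure(data.frame(
    qname = sprintf("t%03d", seq_len(n)), rname = rep_len(rname, n),
    first_aligned = first, last_aligned = last, length = last - first + 1L,
    strand = rep_len(strand, n), mapq = rep_len(mapq, n),
    primary = rep_len(primary, n),
    seq = rep_len(seq, n), qual = rep_len(qual, n),
    stringsAsFactors = FALSE),
    class = c("cfdna_fragments", "data.frame"))
}

# quick tissue SNP set from position/alt vectors
snp_set <- function(tissue, position = integer(0), alt = character(0)) {
  n <- length(position)
  tissue_snp_set(if (n) data.frame(
    position = as.integer(position), ref = rep("A", n), alt = alt,
    maf = rep(0.05, n), maf_plus = rep(0.05, n), maf_minus = rep(0.05, n),
    strand_p = rep(1, n), coverage = rep(1000L, n),
    stringsAsFactors = FALSE) else NULL, tissue)
}
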