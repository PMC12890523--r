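# Synthetic paired-end cfDNA fragments: a truncated-normal mixture of
# fragment sizes, uniform placement on the circular mt genome (with wrap
# across the origin), planted heteroplasmies at specified allele fractions,
# uniform sequencing error, and a minimal SAM-dialect serialisation.

#' Fragment-size mixture model
#'
#' Sizes are drawn from a mixture of normal components truncated to
#' `[min_len, max_len]`. The defaults emulate the bimodal cfDNA size
#' distribution seen in plasma sequencing: a sub-nucleosomal mode near
#' 95 bp and a mononucleosomal mode near 167 bp, with roughly 15% of
#' fragments below 100 bp and 40% below 150 bp.
#'
#' @param means,sds,weights component means (bp), SDs (bp) and mixture
#'   weights (non-negative, summing to 1).
#' @param min_len,max_len truncation bounds in bp.
#' @return an object of class `"fragment_size_model"`.
#' @export
fragment_size_model <- function(means = c(95, 167), sds = c(15, 25),
                                weights = c(0.25, 0.75),
                                min_len = 30L, max_len = 500L) {
  stopifnot(length(means) == length(sds), length(means) == length(weights),
            all(weights >= 0), min_len >= 1L, max_len >= min_len)
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  structure(list(means = means, sds = sds, weights = weights,
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "fragment_size_model")
}

# draw n sizes from the truncated mixture (rejection sampling; clamp the
# rare stragglers after 50 rounds)
sample_fragment_sizes <- function(model, n) {
  draw <- function(m) {
    comp <- sample.int(length(model$means), m, replace = TRUE,
                       prob = model$weights)
    round(rnorm(m, model$means[comp], model$sds[comp]))
  }
  out <- draw(n)
  for (i in 1:50) {
    bad <- out < model$min_len | out > model$max_len
    if (!any(bad)) break
    out[bad] <- draw(sum(bad))
  }
  as.integer(pmin(pmax(out, model$min_len), model$max_len))
}

#' Plan a planted heteroplasmy
#'
#' Ground truth for a tissue-specific mtDNA SNP: at `position`, fragments
#' carry `alt_base` instead of the reference with probability
#' `allele_fraction` (before sequencing error).
#'
#' @param tissue tissue label the plan belongs to (e.g. `"kidney"`).
#' @param position 0-based mt coordinate.
#' @param ref_base,alt_base reference and alternate bases (must differ).
#' @param allele_fraction proportion in [0, 1].
#' @return an object of class `"heteroplasmy_plan"`.
#' @export
heteroplasmy_plan <- function(tissue, position, ref_base, alt_base,
                              allele_fraction) {
  stopifnot(ref_base %in% DNA_BASES, alt_base %in% DNA_BASES,
            allele_fraction >= 0, allele_fraction <= 1)
  if (identical(ref_base, alt_base)) stop("alt_base must differ from ref_base")
  structure(list(tissue = tissue, position = as.integer(position),
                 ref_base = ref_base, alt_base = alt_base,
                 allele_fraction = allele_fraction),
            class = "heteroplasmy_plan")
}

#' Simulate aligned paired-end cfDNA fragments
#'
#' Mitochondrial fragments are placed uniformly on the circular mt genome
#' (wrapping across the origin), with sizes from `size_model`; planted
#' heteroplasmies emit their alternate base with the planned allele fraction
#' before a uniform per-base sequencing error is applied; strands are
#' assigned independently with probability 1/2. The remaining fragments are
#' nuclear, with primary alignments on the nuclear contig. Base calls are
#' stored on the forward reference strand (alignment orientation) with
#' constant base quality Q37.
#'
#' @param mt circular mitochondrial [genome()].
#' @param nuclear linear nuclear [genome()]; may be `NULL` if
#'   `mt_fraction = 1`.
#' @param size_model a [fragment_size_model()].
#' @param n_fragments total number of fragments (> 0).
#' @param mt_fraction expected proportion of fragments that are
#'   mitochondrial.
#' @param plans list of [heteroplasmy_plan()] objects to plant.
#' @param error_rate per-base substitution error probability (< 0.25).
#' @param seed integer seed.
#' @param mapq mapping quality assigned to every record.
#' @return a data frame of class `"cfdna_fragments"` with one row per
#'   fragment: `qname`, `rname`, `first_aligned`, `last_aligned` (0-based,
#'   inclusive; `last_aligned` may exceed the mt length - 1 for
#'   origin-spanning fragments, interpreted mod L), `length`, `strand`,
#'   `mapq`, `primary`, `seq`, `qual`.
#' @export
make_cfdna_fragments <- function(mt, nuclear = NULL,
                                 size_model = fragment_size_model(),
                                 n_fragments, mt_fraction = 1,
                                 plans = list(), error_rate = 0,
                                 seed = 1L, mapq = 60L) {
  stopifnot(inherits(mt, "genome"), mt_fraction >= 0, mt_fraction <= 1,
            error_rate >= 0, error_rate < 0.25)
  if (n_fragments <= 0) stop("n_fragments must be positive")
  if (inherits(plans, "heteroplasmy_plan")) plans <- list(plans)
  if (mt_fraction < 1 && is.null(nuclear))
    stop("a nuclear genome is required when mt_fraction < 1")

  set.seed(as.integer(seed))
  L <- nchar(mt$sequence)
  n_mt <- rbinom(1L, n_fragments, mt_fraction)
  n_nuc <- n_fragments - n_mt

  len_mt <- sample_fragment_sizes(size_model, n_mt)
  if (any(len_mt > L)) stop("fragment size exceeds the mt genome length")
  start_mt <- sample.int(L, n_mt, replace = TRUE) - 1L
  ext <- paste0(mt$sequence, substr(mt$sequence, 1L, size_model$max_len))
  seq_mt <- substring(ext, start_mt + 1L, start_mt + len_mt)

  for (p in plans) {
    ref_here <- substr(mt$sequence, p$position + 1L, p$position + 1L)
    if (!identical(ref_here, p$ref_base))
      stop(sprintf("plan ref_base %s does not match the genome (%s) at %d",
                   p$ref_base, ref_here, p$position))
    off <- (p$position - start_mt) %% L
    cov <- which(off < len_mt)
    if (!length(cov)) next
    hit <- cov[rbinom(length(cov), 1L, p$allele_fraction) == 1L]
    if (length(hit))
      substr(seq_mt[hit], off[hit] + 1L, off[hit] + 1L) <- p$alt_base
  }

  if (n_nuc > 0L) {
    Ln <- nchar(nuclear$sequence)
    len_nuc <- sample_fragment_sizes(size_model, n_nuc)
    if (any(len_nuc > Ln)) stop("fragment size exceeds the nuclear genome length")
    start_nuc <- as.integer(floor(runif(n_nuc) * (Ln - len_nuc + 1L)))
    seq_nuc <- substring(nuclear$sequence, start_nuc + 1L, start_nuc + len_nuc)
  } else {
    len_nuc <- integer(0); start_nuc <- integer(0); seq_nuc <- character(0)
  }

  seqs <- c(seq_mt, seq_nuc)
  lens <- c(len_mt, len_nuc)
  if (error_rate > 0) {
    nerr <- rbinom(length(lens), lens, error_rate)
    for (i in which(nerr > 0L)) {
      pos <- sample.int(lens[i], nerr[i])
      for (j in pos) {
        old <- substr(seqs[i], j, j)
        substr(seqs[i], j, j) <- sample(setdiff(DNA_BASES, old), 1L)
      }
    }
  }

  out <- data.frame(
    qname = sprintf("frag%07d", seq_len(n_fragments)),
    rname = c(rep(mt$name, n_mt),
              rep(if (n_nuc > 0L) nuclear$name else character(0), n_nuc)),
    first_aligned = c(start_mt, start_nuc),
    last_aligned = c(start_mt, start_nuc) + lens - 1L,
    length = lens,
    strand = sample(c("+", "-"), n_fragments, replace = TRUE),
    mapq = as.integer(mapq),
    primary = TRUE,
    seq = seqs,
    qual = strrep(rawToChar(as.raw(33L + 37L)), lens),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("cfdna_fragments", "data.frame"),
            mt_name = mt$name, mt_length = L,
            nuc_name = if (!is.null(nuclear)) nuclear$name,
            nuc_length = if (!is.null(nuclear)) nchar(nuclear$sequence))
}

#' Write fragments as a minimal SAM dialect
#'
#' Each fragment is serialised as two abutting proper-pair mates (first half
#' / second half), CIGAR all-match, so that pairing the mates back together
#' recovers the full fragment span and base calls without double counting.
#' Both mates carry the reverse flag (0x10) when the fragment strand is
#' `-`. Origin-spanning fragments keep their unwrapped coordinates.
#'
#' @param frags a [make_cfdna_fragments()] result.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(frags, path) {
  stopifnot(inherits(frags, "cfdna_fragments"), all(frags$length >= 2L))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", attr(frags, "mt_name"),
                   attr(frags, "mt_length")))
  if (!is.null(attr(frags, "nuc_name")))
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", attr(frags, "nuc_name"),
                          attr(frags, "nuc_length")))
  len1 <- (frags$length + 1L) %/% 2L
  len2 <- frags$length - len1
  rev_bit <- ifelse(frags$strand == "-", 16L, 0L)
  pos1 <- frags$first_aligned + 1L          # SAM is 1-based
  pos2 <- frags$first_aligned + len1 + 1L
  r1 <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s",
                frags$qname, 1L + 2L + 64L + rev_bit, frags$rname, pos1,
                frags$mapq, len1, pos2, frags$length,
                substr(frags$seq, 1L, len1), substr(frags$qual, 1L, len1))
  r2 <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s",
                frags$qname, 1L + 2L + 128L + rev_bit, frags$rname, pos2,
                frags$mapq, len2, pos1, -frags$length,
                substr(frags$seq, len1 + 1L, frags$length),
                substr(frags$qual, len1 + 1L, frags$length))
  writeLines(c(hdr, as.vector(rbind(r1, r2))), path)
  invisible(path)
}

#' Write fragments as TSV
#'
#' Tabular equivalent of the SAM dialect: one row per fragment with the
#' columns of [make_cfdna_fragments()].
#'
#' @param frags a [make_cfdna_fragments()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments_tsv <- function(frags, path) {
  write.table(as.data.frame(frags), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
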