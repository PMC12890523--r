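# NUMT-aware scan of the mitochondrial genome: per-position minimum Hamming
# distance of every fixed-length mt window (and its reverse complement)
# against the whole nuclear genome, ungapped, and selection of NUMT-safe
# ddPCR target regions from the resulting profile.

#' Cut a genome into overlapping fixed-length windows
#'
#' Each window is identified by its central nucleotide. A circular genome of
#' length L yields exactly L windows, one per position, wrapping across the
#' origin; a linear genome of length L yields L - window + 1. Consecutive
#' windows overlap by window - 1 bases.
#'
#' @param genome a [genome()] object.
#' @param window odd window length in bp (default 101).
#' @return data frame with columns `center` (0-based) and `sequence`.
#' @export
#' @examples
#' g <- genome(strrep("ACGT", 50), circular = TRUE)
#' nrow(fragmentize(g))  # 200 windows for a 200-bp circular genome
fragmentize <- function(genome, window = 101L) {
  stopifnot(inherits(genome, "genome"))
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window length must be odd")
  L <- nchar(genome$sequence)
  half <- (window - 1L) %/% 2L
  if (genome$circular) {
    centers <- 0:(L - 1L)
    ext <- paste0(genome$sequence, substr(genome$sequence, 1L, window - 1L))
    starts <- (centers - half) %% L
    seqs <- substring(ext, starts + 1L, starts + window)
  } else {
    if (L < window) stop("linear genome shorter than the window length")
    centers <- half:(L - half - 1L)
    starts <- centers - half
    seqs <- substring(genome$sequence, starts + 1L, starts + window)
  }
  data.frame(center = as.integer(centers), sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Minimum Hamming distance of a window against a nuclear genome
#'
#' Scans every ungapped offset of the nuclear sequence with the window and
#' with its reverse complement, and returns the smallest mismatch count.
#' Any comparison involving an N counts as a mismatch.
#'
#' @param window DNA string (one window), or a single row of [fragmentize()]
#'   output.
#' @param nuclear nuclear sequence: a [genome()] object or a DNA string.
#' @return non-negative integer mismatch count.
#' @export
min_hamming <- function(window, nuclear) {
  if (is.data.frame(window)) window <- window$sequence
  stopifnot(is.character(window), length(window) == 1L)
  if (inherits(nuclear, "genome")) nuclear <- nuclear$sequence
  if (nchar(nuclear) < nchar(window))
    stop("nuclear sequence shorter than the window")
  min(min_hamming_one_strand(window, nuclear),
      min_hamming_one_strand(revcomp(window), nuclear))
}

#' Per-position minimum-Hamming-distance profile (NUMT scan)
#'
#' Computes, for every window of the mitochondrial genome, the minimum
#' Hamming distance between the window (or its reverse complement) and the
#' best ungapped match anywhere in the nuclear genome. Positions with low
#' values are candidate NUMTs; high values mark mtDNA-specific sequence
#' suitable for ddPCR targets.
#'
#' The scan is exact (an exhaustive ungapped comparison at every offset and
#' both strands), implemented as a sliding mismatch sum along every diagonal
#' of the comparison grid, O(mt length x nuclear length).
#'
#' @param mt mitochondrial [genome()] (typically circular).
#' @param nuclear nuclear [genome()] or DNA string.
#' @param window odd window length in bp (default 101).
#' @return object of class `"hamming_profile"`: a data frame with columns
#'   `position` (0-based window centre) and `d_min`, with attributes
#'   `window` and `nuclear_name`.
#' @export
numt_profile <- function(mt, nuclear, window = 101L) {
  stopifnot(inherits(mt, "genome"))
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window length must be odd")
  nuc_name <- if (inherits(nuclear, "genome")) nuclear$name else "nuclear"
  nuc_seq <- if (inherits(nuclear, "genome")) nuclear$sequence else nuclear
  L <- nchar(mt$sequence)
  half <- (window - 1L) %/% 2L
  if (mt$circular) {
    pattern_ext <- paste0(mt$sequence, substr(mt$sequence, 1L, window - 1L))
    n_windows <- L
  } else {
    if (L < window) stop("linear genome shorter than the window length")
    pattern_ext <- mt$sequence
    n_windows <- L - window + 1L
  }
  best <- hamming_profile_cpp(pattern_ext, nuc_seq, revcomp(nuc_seq),
                              window, n_windows)
  if (mt$circular) {
    # window with 0-based start s has centre (s + half) mod L
    position <- (seq_len(n_windows) - 1L + half) %% L
    o <- order(position)
    out <- data.frame(position = position[o], d_min = best[o])
  } else {
    out <- data.frame(position = half:(L - half - 1L), d_min = best)
  }
  structure(out, class = c("hamming_profile", "data.frame"),
            window = window, nuclear_name = nuc_name)
}

#' @export
print.hamming_profile <- function(x, ...) {
  cat(sprintf("<hamming_profile> %d positions, window %d, vs %s\n",
              nrow(x), attr(x, "window"), attr(x, "nuclear_name")))
  cat(sprintf("  d_min: min %d, median %s, max %d; %d position(s) at 0\n",
              min(x$d_min), format(stats::median(x$d_min)), max(x$d_min),
              sum(x$d_min == 0L)))
  invisible(x)
}

#' @export
plot.hamming_profile <- function(x, ...) {
  plot(x$position, x$d_min, type = "l", xlab = "mt position (bp)",
       ylab = "minimum Hamming distance", ...)
}

#' Select NUMT-safe target regions from a Hamming profile
#'
#' Reports the maximal runs of consecutive positions whose minimum Hamming
#' distance is at least `min_distance`, keeping runs of at least
#' `min_length` bp. These runs are unlikely to exist as NUMTs and are the
#' preferred ddPCR target regions.
#'
#' @param profile a [numt_profile()] result.
#' @param min_distance smallest acceptable d_min (>= 1).
#' @param min_length smallest reportable run length in bp.
#' @return data frame with 0-based half-open `start`, `end`, plus `length`
#'   and `min_profile_value`, sorted by start.
#' @export
select_target_regions <- function(profile, min_distance, min_length = 1L) {
  stopifnot(min_distance >= 1L, min_length >= 1L)
  ok <- profile$d_min >= min_distance
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  out <- data.frame(
    start = profile$position[starts[keep]],
    end = profile$position[ends[keep]] + 1L,
    length = r$lengths[keep],
    min_profile_value = vapply(which(keep), function(i)
      min(profile$d_min[starts[i]:ends[i]]), integer(1))
  )
  out[order(out$start), , drop = FALSE]
}

#' Write a Hamming profile as TSV
#'
#' Two columns: `position` (0-based) and `d_min`.
#'
#' @param profile a [numt_profile()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(as.data.frame(profile)[, c("position", "d_min")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write target regions as BED
#'
#' @param regions a [select_target_regions()] result.
#' @param path output path.
#' @param chrom contig name for the BED records.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path, chrom = "chrM") {
  bed <- data.frame(chrom = chrom, start = regions$start, end = regions$end,
                    name = sprintf("target_%d", seq_len(nrow(regions))),
                    score = regions$min_profile_value)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
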