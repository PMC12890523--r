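# cfDNA fragmentomics: read paired-end alignment records, partition by
# mitochondrial vs nuclear primary alignment, compute per-fragment lengths
# and empirical size distributions.

#' Read paired-end alignment records
#'
#' Accepts either the package's minimal SAM dialect (header lines starting
#' with `@`; QNAME FLAG RNAME POS MAPQ CIGAR RNEXT PNEXT TLEN SEQ QUAL,
#' CIGAR all-match) or the TSV written by [write_fragments_tsv()]. Mates are
#' paired by query name; the fragment span runs from the smaller first
#' aligned base to the larger last aligned base of the two mates. Records
#' below `min_mapq` (the pair's minimum) are excluded; unpaired reads are
#' dropped with a message reporting their count.
#'
#' @param path input path.
#' @param min_mapq minimum mapping quality retained (default 30).
#' @return a data frame of class `"cfdna_fragments"`, one row per fragment.
#' @export
read_alignments <- function(path, min_mapq = 30L) {
  first <- readLines(path, n = 1L)
  if (!length(first)) return(empty_fragments())
  frags <- if (startsWith(first, "@")) read_sam_pairs(path)
           else read_fragments_tsv(path)
  keep <- frags$mapq >= min_mapq
  frags[keep, , drop = FALSE]
}

read_sam_pairs <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  if (!length(body))
    return(empty_fragments())
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop(sprintf("malformed alignment record at line %d (%d fields)",
                 body[which(nf < 11L)[1L]], min(nf)))
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  rname <- vapply(fields, `[[`, "", 3L)
  pos <- as.integer(vapply(fields, `[[`, "", 4L))
  mapq <- as.integer(vapply(fields, `[[`, "", 5L))
  seq <- vapply(fields, `[[`, "", 10L)
  qual <- vapply(fields, `[[`, "", 11L)
  if (anyNA(flag) || anyNA(pos) || anyNA(mapq))
    stop(sprintf("malformed alignment record at line %d",
                 body[which(is.na(flag) | is.na(pos) | is.na(mapq))[1L]]))
  end <- pos + nchar(seq) - 1L

  cnt <- table(qname)
  paired <- names(cnt)[cnt == 2L]
  n_drop <- sum(cnt[cnt != 2L])
  if (n_drop > 0L)
    message(sprintf("dropped %d unpaired read(s)", n_drop))
  ok <- qname %in% paired
  if (!any(ok)) return(empty_fragments())
  o <- order(qname[ok], pos[ok])
  idx <- which(ok)[o]
  i1 <- idx[seq(1L, length(idx), by = 2L)]   # leftmost mate
  i2 <- idx[seq(2L, length(idx), by = 2L)]
  if (any(rname[i1] != rname[i2]))
    stop("mates of a pair align to different contigs")
  contiguous <- end[i1] + 1L == pos[i2]
  out <- data.frame(
    qname = qname[i1],
    rname = rname[i1],
    first_aligned = pos[i1] - 1L,
    last_aligned = pmax(end[i1], end[i2]) - 1L,
    length = pmax(end[i1], end[i2]) - pos[i1] + 1L,
    strand = ifelse(bitwAnd(flag[i1], 16L) > 0L, "-", "+"),
    mapq = pmin(mapq[i1], mapq[i2]),
    primary = bitwAnd(flag[i1], 256L) == 0L,
    seq = ifelse(contiguous, paste0(seq[i1], seq[i2]), NA_character_),
    qual = ifelse(contiguous, paste0(qual[i1], qual[i2]), NA_character_),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("cfdna_fragments", "data.frame"))
}

read_fragments_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, colClasses = NA)
  need <- c("qname", "rname", "first_aligned", "last_aligned", "strand",
            "mapq", "primary")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fragment TSV is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$length)) df$length <- df$last_aligned - df$first_aligned + 1L
  structure(df, class = c("cfdna_fragments", "data.frame"))
}

empty_fragments <- function() {
  structure(data.frame(qname = character(0), rname = character(0),
                       first_aligned = integer(0), last_aligned = integer(0),
                       length = integer(0), strand = character(0),
                       mapq = integer(0), primary = logical(0),
                       seq = character(0), qual = character(0),
                       stringsAsFactors = FALSE),
            class = c("cfdna_fragments", "data.frame"))
}

#' Keep fragments whose primary alignment is mitochondrial
#'
#' Fragments with primary alignments on the nuclear genome are removed so
#' that NUMT-derived reads do not contaminate the mitochondrial analyses; a
#' fragment whose primary alignment is mitochondrial is kept even if it has
#' secondary nuclear alignments.
#'
#' @param records a `cfdna_fragments` data frame.
#' @param mt_name mitochondrial contig name.
#' @param known_contigs contigs allowed in `rname`; anything else is an
#'   error. Defaults to all contigs present plus `mt_name`... set it to
#'   validate against a genome's contig list.
#' @return the mitochondrial-primary subset.
#' @export
filter_mt <- function(records, mt_name = "chrM", known_contigs = NULL) {
  if (!is.null(known_contigs)) {
    bad <- setdiff(unique(records$rname), union(known_contigs, mt_name))
    if (length(bad))
      stop("unknown contig(s) in alignment records: ",
           paste(bad, collapse = ", "))
  }
  records[records$primary & records$rname == mt_name, , drop = FALSE]
}

#' Fragment length from aligned end points
#'
#' The length of a paired-end fragment is the distance (+1) between the
#' first and the last aligned base of the pair.
#'
#' @param record a `cfdna_fragments` data frame (any number of rows).
#' @return integer vector of lengths in bp.
#' @export
#' @examples
#' fragment_length(data.frame(first_aligned = 1000, last_aligned = 1092))  # 93
fragment_length <- function(record) {
  as.integer(record$last_aligned - record$first_aligned + 1L)
}

#' Empirical fragment-size distribution
#'
#' @param lengths integer vector of fragment lengths (non-empty), or a
#'   `cfdna_fragments` data frame.
#' @param binwidth histogram bin width in bp.
#' @return object of class `"size_distribution"`: list with `lengths`,
#'   `breaks`, `counts` and the empirical CDF function `cdf`.
#' @export
size_distribution <- function(lengths, binwidth = 10L) {
  if (is.data.frame(lengths)) lengths <- fragment_length(lengths)
  if (!length(lengths)) stop("no fragment lengths supplied")
  stopifnot(all(lengths >= 1L))
  breaks <- seq(0L, (max(lengths) %/% binwidth + 1L) * binwidth, by = binwidth)
  h <- hist(lengths, breaks = breaks, plot = FALSE)
  structure(list(lengths = lengths, breaks = breaks, counts = h$counts,
                 cdf = stats::ecdf(lengths)),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  q <- stats::quantile(x$lengths, c(0.25, 0.5, 0.75))
  cat(sprintf("<size_distribution> n=%d fragments, median %d bp (IQR %d-%d)\n",
              length(x$lengths), as.integer(q[2]), as.integer(q[1]),
              as.integer(q[3])))
  cat(sprintf("  %.1f%% below 100 bp, %.1f%% below 150 bp\n",
              100 * fraction_below(x, 100), 100 * fraction_below(x, 150)))
  invisible(x)
}

#' @export
plot.size_distribution <- function(x, ...) {
  hist(x$lengths, breaks = x$breaks, xlab = "fragment length (bp)",
       main = "cfDNA fragment sizes", ...)
}

#' Fraction of fragments strictly below a length
#'
#' @param dist a [size_distribution()].
#' @param t length threshold in bp (strict `<`).
#' @return proportion in [0, 1].
#' @export
fraction_below <- function(dist, t) {
  mean(dist$lengths < t)
}

#' Fraction of fragments in a closed length interval
#'
#' @param dist a [size_distribution()].
#' @param lo,hi interval bounds in bp, both included.
#' @return proportion in [0, 1].
#' @export
fraction_in <- function(dist, lo, hi) {
  mean(dist$lengths >= lo & dist$lengths <= hi)
}

#' Mitochondrial yield
#'
#' Proportion of fragments whose primary alignment is mitochondrial,
#' relative to all primary fragments.
#'
#' @param records a `cfdna_fragments` data frame (non-empty).
#' @param mt_name mitochondrial contig name.
#' @return proportion in [0, 1].
#' @export
mt_yield <- function(records, mt_name = "chrM") {
  if (!nrow(records)) stop("no alignment records supplied")
  sum(records$primary & records$rname == mt_name) / sum(records$primary)
}

#' Write a size distribution (histogram + CDF) as CSV
#'
#' @param dist a [size_distribution()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_size_distribution_csv <- function(dist, path) {
  mids <- (head(dist$breaks, -1L) + dist$breaks[-1L]) / 2
  df <- data.frame(bin_start = head(dist$breaks, -1L),
                   bin_end = dist$breaks[-1L], bin_mid = mids,
                   count = dist$counts,
                   cdf_at_bin_end = dist$cdf(dist$breaks[-1L]))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
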