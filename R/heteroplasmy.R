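# Stranded pileups and heteroplasmy calling. A site passes when sequencing
# coverage exceeds 400, the top non-reference allele reaches 1% overall and
# 0.6% on each strand, and its counts are not significantly unbalanced
# between strands (two-sided Fisher's exact test).

STRANDS <- c("plus", "minus")
PILEUP_COUNT_COLS <- as.vector(outer(DNA_BASES, STRANDS, paste, sep = "_"))

#' Build a stranded pileup from mitochondrial fragments
#'
#' Expands per-fragment base calls into per-position, per-strand allele
#' counts over the circular mitochondrial genome. Calls below the base
#' quality threshold and fragments below the mapping quality threshold are
#' excluded; N calls are ignored. Positions with no passing calls are
#' omitted.
#'
#' @param records mitochondrial-primary `cfdna_fragments` (after
#'   [filter_mt()]) with `seq` and `qual` columns.
#' @param mt mitochondrial [genome()] providing reference bases.
#' @param min_mapq minimum fragment mapping quality (default 30).
#' @param min_baseq minimum base quality, Phred scale (default 20).
#' @return data frame of class `"stranded_pileup"`: `position` (0-based),
#'   `ref`, the eight `A_plus` ... `T_minus` counts and `coverage`.
#' @export
build_pileup <- function(records, mt, min_mapq = 30L, min_baseq = 20L) {
  stopifnot(inherits(mt, "genome"))
  records <- records[records$mapq >= min_mapq & !is.na(records$seq), ,
                     drop = FALSE]
  L <- nchar(mt$sequence)
  if (!nrow(records)) return(empty_pileup())

  lens <- nchar(records$seq)
  pos <- (rep(records$first_aligned, lens) + (sequence(lens) - 1L)) %% L
  base <- strsplit(paste(records$seq, collapse = ""), "", fixed = TRUE)[[1]]
  baseq <- as.integer(charToRaw(paste(records$qual, collapse = ""))) - 33L
  strand <- rep(records$strand, lens)

  bad <- !(base %in% c(DNA_BASES, "N"))
  if (any(bad))
    stop("base call outside the A/C/G/T/N alphabet: ", base[which(bad)[1L]])
  keep <- baseq >= min_baseq & base != "N"
  pos <- pos[keep]; base <- base[keep]; strand <- strand[keep]
  if (!length(pos)) return(empty_pileup())

  base_i <- match(base, DNA_BASES) - 1L          # 0..3
  strand_i <- ifelse(strand == "-", 1L, 0L)      # plus = 0, minus = 1
  idx <- pos * 8L + strand_i * 4L + base_i
  counts <- tabulate(idx + 1L, nbins = L * 8L)
  m <- matrix(counts, ncol = 8L, byrow = TRUE)   # rows = positions
  # columns: plus A C G T, minus A C G T
  colnames(m) <- as.vector(t(outer(STRANDS, DNA_BASES, paste, sep = "_")))
  covered <- which(rowSums(m) > 0L)
  out <- data.frame(position = covered - 1L,
                    ref = substring(mt$sequence, covered, covered))
  for (b in DNA_BASES) {
    out[[paste0(b, "_plus")]] <- m[covered, paste0("plus_", b)]
    out[[paste0(b, "_minus")]] <- m[covered, paste0("minus_", b)]
  }
  out$coverage <- as.integer(rowSums(m[covered, , drop = FALSE]))
  structure(out, class = c("stranded_pileup", "data.frame"))
}

empty_pileup <- function() {
  out <- data.frame(position = integer(0), ref = character(0))
  for (cc in PILEUP_COUNT_COLS) out[[cc]] <- integer(0)
  out$coverage <- integer(0)
  structure(out, class = c("stranded_pileup", "data.frame"))
}

#' Construct a single stranded pileup site
#'
#' Convenience constructor for one site from explicit per-strand counts.
#'
#' @param position 0-based mt coordinate.
#' @param ref reference base.
#' @param counts named integer vector with entries `A_plus`, `C_plus`,
#'   `G_plus`, `T_plus`, `A_minus`, `C_minus`, `G_minus`, `T_minus`
#'   (missing entries default to 0).
#' @return a one-row `"stranded_pileup"` data frame.
#' @export
pileup_site <- function(position, ref, counts) {
  stopifnot(ref %in% DNA_BASES, all(counts >= 0))
  full <- setNames(integer(8L), PILEUP_COUNT_COLS)
  bad <- setdiff(names(counts), PILEUP_COUNT_COLS)
  if (length(bad)) stop("unknown count name(s): ", paste(bad, collapse = ", "))
  full[names(counts)] <- as.integer(counts)
  out <- data.frame(position = as.integer(position), ref = ref)
  for (cc in PILEUP_COUNT_COLS) out[[cc]] <- full[[cc]]
  out$coverage <- sum(full)
  structure(out, class = c("stranded_pileup", "data.frame"))
}

#' Fisher test of allele balance between strands
#'
#' Two-sided Fisher's exact test on the 2x2 table of alternate and
#' reference counts by strand. Used to reject heteroplasmy candidates whose
#' alternate allele is significantly strand-biased (a sequencing-artefact
#' signature).
#'
#' @param alt_plus,ref_plus,alt_minus,ref_minus non-negative counts; each
#'   strand must have at least one observation.
#' @return two-sided p-value.
#' @export
strand_equality_test <- function(alt_plus, ref_plus, alt_minus, ref_minus) {
  stopifnot(alt_plus >= 0, ref_plus >= 0, alt_minus >= 0, ref_minus >= 0)
  if (alt_plus + ref_plus == 0L || alt_minus + ref_minus == 0L)
    stop("each strand needs at least one observation")
  tab <- matrix(c(alt_plus, ref_plus, alt_minus, ref_minus), nrow = 2L)
  fisher.test(tab)$p.value
}

#' Evaluate the heteroplasmy criteria at one pileup site
#'
#' The evaluated alternate is the most abundant non-reference base. The
#' site passes when all four criteria hold, in this order:
#' coverage strictly greater than `min_coverage`; alternate allele fraction
#' at least `min_maf`; per-strand alternate fraction at least
#' `min_strand_maf` on both strands; Fisher strand-balance p-value at least
#' `alpha`.
#'
#' @param site one row of a `"stranded_pileup"`.
#' @param min_coverage coverage must exceed this (default 400, strict).
#' @param min_maf minimum overall alternate fraction (default 0.01).
#' @param min_strand_maf minimum per-strand alternate fraction
#'   (default 0.006).
#' @param alpha strand-test significance level; candidates with p < alpha
#'   are rejected (default 0.05).
#' @return list with `pass` (logical), `reason` (first failed criterion, or
#'   `NA` on pass) and, on pass, `site`: a one-row data frame with
#'   `position`, `ref`, `alt`, `maf`, `maf_plus`, `maf_minus`, `strand_p`,
#'   `coverage`.
#' @export
call_heteroplasmy <- function(site, min_coverage = 400L, min_maf = 0.01,
                              min_strand_maf = 0.006, alpha = 0.05) {
  reject <- function(reason) list(pass = FALSE, reason = reason, site = NULL)
  cov <- site$coverage
  if (cov <= min_coverage) return(reject("coverage"))
  plus <- as.numeric(site[paste0(DNA_BASES, "_plus")])
  minus <- as.numeric(site[paste0(DNA_BASES, "_minus")])
  both <- plus + minus
  ref_i <- match(site$ref, DNA_BASES)
  alt_candidates <- setdiff(seq_along(DNA_BASES), ref_i)
  alt_i <- alt_candidates[which.max(both[alt_candidates])]
  maf <- both[alt_i] / cov
  if (maf < min_maf) return(reject("MAF"))
  cov_plus <- sum(plus); cov_minus <- sum(minus)
  maf_plus <- if (cov_plus > 0) plus[alt_i] / cov_plus else 0
  maf_minus <- if (cov_minus > 0) minus[alt_i] / cov_minus else 0
  if (maf_plus < min_strand_maf || maf_minus < min_strand_maf)
    return(reject("per-strand MAF"))
  p <- strand_equality_test(plus[alt_i], plus[ref_i],
                            minus[alt_i], minus[ref_i])
  if (p < alpha) return(reject("strand balance"))
  list(pass = TRUE, reason = NA_character_,
       site = data.frame(position = site$position, ref = site$ref,
                         alt = DNA_BASES[alt_i], maf = maf,
                         maf_plus = maf_plus, maf_minus = maf_minus,
                         strand_p = p, coverage = cov,
                         stringsAsFactors = FALSE))
}

#' Call heteroplasmy across a pileup
#'
#' Applies [call_heteroplasmy()] to every site and collects the passing
#' SNPs into a tissue-labelled call set sorted by position.
#'
#' @param pileup a `"stranded_pileup"` data frame.
#' @param tissue label attached to the call set (e.g. `"plasma"`).
#' @inheritParams call_heteroplasmy
#' @return a [tissue_snp_set()].
#' @export
call_all <- function(pileup, tissue = "plasma", min_coverage = 400L,
                     min_maf = 0.01, min_strand_maf = 0.006, alpha = 0.05) {
  candidates <- which(pileup$coverage > min_coverage)
  calls <- list()
  for (i in candidates) {
    r <- call_heteroplasmy(pileup[i, , drop = FALSE], min_coverage, min_maf,
                           min_strand_maf, alpha)
    if (r$pass) calls[[length(calls) + 1L]] <- r$site
  }
  sites <- if (length(calls)) do.call(rbind, calls) else NULL
  tissue_snp_set(sites, tissue)
}

#' Construct a tissue SNP call set
#'
#' @param sites data frame with columns `position`, `ref`, `alt`, `maf`,
#'   `maf_plus`, `maf_minus`, `strand_p`, `coverage`, or `NULL` for an
#'   empty set.
#' @param tissue tissue label.
#' @return data frame of class `"tissue_snp_set"` sorted by position, with
#'   attribute `tissue`; duplicate (position, alt) pairs are an error.
#' @export
tissue_snp_set <- function(sites, tissue) {
  if (is.null(sites))
    sites <- data.frame(position = integer(0), ref = character(0),
                        alt = character(0), maf = numeric(0),
                        maf_plus = numeric(0), maf_minus = numeric(0),
                        strand_p = numeric(0), coverage = integer(0),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(sites[c("position", "alt")]))
    stop("duplicate (position, alt) entries in a tissue SNP set")
  sites <- sites[order(sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  structure(sites, class = c("tissue_snp_set", "data.frame"), tissue = tissue)
}

#' @export
print.tissue_snp_set <- function(x, ...) {
  cat(sprintf("<tissue_snp_set> %s: %d heteroplasmy site(s)\n",
              attr(x, "tissue"), nrow(x)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L), digits = 4)
  invisible(x)
}

#' Write a call set as minimal VCF
#'
#' CHROM/POS (1-based)/ID/REF/ALT/QUAL/FILTER/INFO records with INFO keys
#' MAF, MAF_PLUS, MAF_MINUS, STRAND_P and DP.
#'
#' @param snps a [tissue_snp_set()].
#' @param path output path.
#' @param chrom contig name.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path, chrom = "chrM") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=cfmtdna; tissue=%s", attr(snps, "tissue")),
           "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
           "##INFO=<ID=MAF_PLUS,Number=1,Type=Float,Description=\"Plus-strand alternate fraction\">",
           "##INFO=<ID=MAF_MINUS,Number=1,Type=Float,Description=\"Minus-strand alternate fraction\">",
           "##INFO=<ID=STRAND_P,Number=1,Type=Float,Description=\"Fisher strand-balance p-value\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Coverage\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tMAF=%.6g;MAF_PLUS=%.6g;MAF_MINUS=%.6g;STRAND_P=%.6g;DP=%d",
                 chrom, snps$position + 1L, snps$ref, snps$alt, snps$maf,
                 snps$maf_plus, snps$maf_minus, snps$strand_p, snps$coverage)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a call set from the minimal VCF
#'
#' @param path VCF path.
#' @param tissue tissue label to attach.
#' @return a [tissue_snp_set()].
#' @export
read_snp_vcf <- function(path, tissue = "plasma") {
  lines <- readLines(path)
  rec <- lines[!startsWith(lines, "#")]
  if (!length(rec)) return(tissue_snp_set(NULL, tissue))
  f <- strsplit(rec, "\t", fixed = TRUE)
  info <- vapply(f, `[[`, "", 8L)
  get <- function(key) {
    as.numeric(sub(sprintf(".*%s=([^;]+).*", key), "\\1", info))
  }
  tissue_snp_set(data.frame(
    position = as.integer(vapply(f, `[[`, "", 2L)) - 1L,
    ref = vapply(f, `[[`, "", 4L), alt = vapply(f, `[[`, "", 5L),
    maf = get("MAF"), maf_plus = get("MAF_PLUS"),
    maf_minus = get("MAF_MINUS"), strand_p = get("STRAND_P"),
    coverage = as.integer(get("DP")), stringsAsFactors = FALSE), tissue)
}

#' Write / read a stranded pileup as TSV
#'
#' @param pileup a `"stranded_pileup"` data frame.
#' @param path TSV path.
#' @return `path` (writer) or a `"stranded_pileup"` (reader).
#' @export
write_pileup_tsv <- function(pileup, path) {
  write.table(as.data.frame(pileup), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  structure(df, class = c("stranded_pileup", "data.frame"))
}
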