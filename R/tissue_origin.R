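# Tissue-of-origin inference: match each plasma heteroplasmy site against
# per-tissue call sets from the same animal on the (position, alternate
# allele) key, and classify as unique, multiple or unmatched.

#' Classify one plasma SNP against tissue call sets
#'
#' A tissue matches when it carries a SNP with the identical position and
#' alternate allele; allele fractions are not compared. The category is
#' `unmatched` (no tissue), `unique` (exactly one) or `multiple` (two or
#' more).
#'
#' @param position 0-based mt coordinate of the plasma SNP.
#' @param alt alternate base of the plasma SNP.
#' @param tissue_sets list of [tissue_snp_set()] objects (excluding plasma
#'   itself); tissue labels must be unique.
#' @return list with `position`, `alt`, `category` and `matched_tissues`.
#' @export
match_site <- function(position, alt, tissue_sets) {
  labels <- vapply(tissue_sets, attr, "", "tissue")
  if (anyDuplicated(labels)) stop("duplicate tissue labels")
  hit <- vapply(tissue_sets, function(ts)
    any(ts$position == position & ts$alt == alt), logical(1))
  matched <- labels[hit]
  category <- if (length(matched) == 0L) "unmatched"
              else if (length(matched) == 1L) "unique" else "multiple"
  list(position = as.integer(position), alt = alt, category = category,
       matched_tissues = matched)
}

#' Per-tissue SNP counts
#'
#' @param tissue_sets list of [tissue_snp_set()] objects.
#' @return named integer vector of call-set sizes (zero-site tissues are
#'   retained with count 0).
#' @export
tissue_snp_counts <- function(tissue_sets) {
  setNames(vapply(tissue_sets, nrow, integer(1)),
           vapply(tissue_sets, attr, "", "tissue"))
}

#' Tissue-of-origin report for one animal
#'
#' Classifies every plasma heteroplasmy site against the animal's tissue
#' call sets and summarises the partition into unique / multiple /
#' unmatched, which always sums to the plasma call-set size.
#'
#' @param animal_id animal identifier.
#' @param plasma plasma [tissue_snp_set()].
#' @param tissue_sets list of per-tissue [tissue_snp_set()] objects.
#' @return object of class `"origin_report"`: list with `animal_id`,
#'   `classifications` (data frame: position, alt, category,
#'   matched_tissues comma-separated), `tissue_counts`, and `summary`
#'   (named counts unique/multiple/unmatched).
#' @export
origin_report <- function(animal_id, plasma, tissue_sets) {
  cls <- lapply(seq_len(nrow(plasma)), function(i)
    match_site(plasma$position[i], plasma$alt[i], tissue_sets))
  classifications <- data.frame(
    position = vapply(cls, `[[`, 0L, "position"),
    alt = vapply(cls, `[[`, "", "alt"),
    category = vapply(cls, `[[`, "", "category"),
    matched_tissues = vapply(cls, function(x)
      paste(x$matched_tissues, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  summary <- setNames(
    vapply(c("unique", "multiple", "unmatched"),
           function(k) sum(classifications$category == k), integer(1)),
    c("unique", "multiple", "unmatched"))
  structure(list(animal_id = animal_id, classifications = classifications,
                 tissue_counts = tissue_snp_counts(tissue_sets),
                 summary = summary),
            class = "origin_report")
}

#' @export
print.origin_report <- function(x, ...) {
  cat(sprintf("<origin_report> animal %s: %d plasma site(s) — %d unique, %d multiple, %d unmatched\n",
              x$animal_id, sum(x$summary), x$summary["unique"],
              x$summary["multiple"], x$summary["unmatched"]))
  if (length(x$tissue_counts))
    cat("  tissue SNP counts:",
        paste(sprintf("%s=%d", names(x$tissue_counts), x$tissue_counts),
              collapse = ", "), "\n")
  invisible(x)
}

#' Write an origin report as CSV or JSON
#'
#' @param report an [origin_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_origin_csv <- function(report, path) {
  df <- cbind(animal_id = report$animal_id, report$classifications)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_origin_csv
#' @export
write_origin_json <- function(report, path) {
  jsonlite::write_json(
    list(animal_id = report$animal_id,
         summary = as.list(report$summary),
         tissue_counts = as.list(report$tissue_counts),
         classifications = report$classifications),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
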