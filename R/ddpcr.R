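# Droplet digital PCR quantification: positive-droplet fraction -> Poisson
# occupancy lambda = -ln(1 - p) copies per droplet -> copies/uL of the
# original plasma sample after volume and dilution scaling.

#' Quantify target concentration from droplet counts
#'
#' With positive fraction `p = positives / total`, the mean number of
#' target copies per droplet under Poisson loading is
#' `lambda = -ln(1 - p)`; the sample concentration is
#' `(lambda / droplet_volume) * dilution` copies/uL. With
#' `poisson = FALSE` the raw fraction `p` replaces `lambda` (no occupancy
#' correction), which agrees with the Poisson estimate to <1% for
#' p <= 0.02.
#'
#' @param assay a [droplet_assay()], or positives when `total` is given.
#' @param total total droplets (when `assay` is a count).
#' @param droplet_volume droplet volume in uL; defaults to the assay's
#'   value or 0.00085.
#' @param dilution dilution factor back to the plasma sample; defaults to
#'   the assay's value or 20.
#' @param poisson apply the Poisson occupancy correction (default TRUE).
#' @return concentration in copies/uL of the original sample.
#' @export
#' @examples
#' # p = 1 - exp(-1) gives exactly one copy per droplet:
#' ddpcr_quantify(droplet_assay(round(2e4 * (1 - exp(-1))), 2e4))
ddpcr_quantify <- function(assay, total = NULL, droplet_volume = NULL,
                           dilution = NULL, poisson = TRUE) {
  if (!inherits(assay, "droplet_assay")) {
    assay <- droplet_assay(assay, total,
                           droplet_volume = droplet_volume %||% 0.00085,
                           dilution = dilution %||% 20)
  }
  vol <- droplet_volume %||% assay$droplet_volume
  dil <- dilution %||% assay$dilution
  if (assay$total == 0L) stop("total droplet count must be positive")
  if (assay$positives == assay$total)
    stop("assay is saturated (all droplets positive); cannot quantify")
  p <- assay$positives / assay$total
  lambda <- if (poisson) -log1p(-p) else p
  (lambda / vol) * dil
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantify a CSV of droplet assays
#'
#' Input columns: `sample`, `positives`, `total` (optional
#' `droplet_volume`, `dilution`). Output columns: `sample`,
#' `copies_per_ul`.
#'
#' @param path input CSV.
#' @param out optional output CSV path.
#' @inheritParams ddpcr_quantify
#' @return data frame of concentrations (invisibly written to `out` if
#'   given).
#' @export
ddpcr_quantify_csv <- function(path, out = NULL, droplet_volume = 0.00085,
                               dilution = 20, poisson = TRUE) {
  df <- utils::read.csv(path)
  vol <- if ("droplet_volume" %in% names(df)) df$droplet_volume else droplet_volume
  dil <- if ("dilution" %in% names(df)) df$dilution else dilution
  vol <- rep_len(vol, nrow(df)); dil <- rep_len(dil, nrow(df))
  conc <- vapply(seq_len(nrow(df)), function(i)
    ddpcr_quantify(droplet_assay(df$positives[i], df$total[i], vol[i], dil[i]),
                   poisson = poisson), numeric(1))
  res <- data.frame(sample = df$sample, copies_per_ul = conc)
  if (!is.null(out)) write.csv(res, out, row.names = FALSE)
  res
}
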