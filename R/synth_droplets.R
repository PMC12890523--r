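# Simulated droplet digital PCR assay: droplets are loaded with Poisson
# occupancy, so a droplet is positive with probability 1 - exp(-conc * vol).

#' Simulate a droplet digital PCR assay
#'
#' Each droplet is positive independently with probability
#' `1 - exp(-true_conc * droplet_volume)` (Poisson occupancy of target
#' copies across droplets).
#'
#' @param true_conc target concentration in the reaction, copies/uL.
#' @param n_droplets number of droplets generated (~20,000 on the usual
#'   instrument).
#' @param droplet_volume droplet volume in uL (nominal 0.00085).
#' @param seed integer seed.
#' @return an object of class `"droplet_assay"` with fields `positives`,
#'   `total`, `droplet_volume`.
#' @export
#' @examples
#' a <- make_droplet_assay(1000, n_droplets = 20000, seed = 1)
#' a$positives / a$total
make_droplet_assay <- function(true_conc, n_droplets = 20000L,
                               droplet_volume = 0.00085, seed = 1L) {
  if (true_conc < 0) stop("true_conc must be non-negative")
  if (n_droplets < 1) stop("n_droplets must be at least 1")
  if (droplet_volume <= 0) stop("droplet_volume must be positive")
  set.seed(as.integer(seed))
  p <- 1 - exp(-true_conc * droplet_volume)
  droplet_assay(positives = rbinom(1L, n_droplets, p), total = n_droplets,
                droplet_volume = droplet_volume)
}

#' Construct a droplet assay record
#'
#' @param positives number of PCR-positive droplets.
#' @param total total accepted droplets (>= 1).
#' @param droplet_volume droplet volume in uL.
#' @param dilution dilution factor from plasma sample to reaction (the
#'   assay's default is 20).
#' @return an object of class `"droplet_assay"`.
#' @export
droplet_assay <- function(positives, total, droplet_volume = 0.00085,
                          dilution = 20) {
  stopifnot(total >= 1, positives >= 0, positives <= total,
            droplet_volume > 0, dilution > 0)
  structure(list(positives = as.integer(positives), total = as.integer(total),
                 droplet_volume = droplet_volume, dilution = dilution),
            class = "droplet_assay")
}

#' @export
print.droplet_assay <- function(x, ...) {
  cat(sprintf("<droplet_assay> %d / %d positive (%.3f), droplet %.5g uL, dilution x%g\n",
              x$positives, x$total, x$positives / x$total,
              x$droplet_volume, x$dilution))
  invisible(x)
}
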