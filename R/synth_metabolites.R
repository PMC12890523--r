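# Synthetic two-group targeted-metabolomics matrix: lognormal intensities,
# a planted log2 fold-change in the first n_affected metabolites of group 2,
# and missing-at-random entries.

#' Simulate a two-group metabolite intensity matrix
#'
#' Intensities are lognormal: per-metabolite baseline log2 abundances are
#' drawn uniformly on [10, 20], per-sample log2 noise has SD `noise_sd`, and
#' the first `n_affected` metabolites are shifted by `effect_log2fc` log2
#' units in group 2. Entries are then set missing independently with
#' probability `missing_rate`. The default panel size of 483 matches a
#' typical targeted LC-MS panel.
#'
#' @param n_per_group samples per group (>= 2).
#' @param n_metabolites panel size.
#' @param n_affected number of metabolites carrying the planted effect
#'   (default 20% of the panel, the order of change seen in septic tissue).
#' @param effect_log2fc planted shift in log2 units (group 2 minus group 1).
#' @param missing_rate per-entry missingness probability in [0, 1).
#' @param noise_sd per-entry log2 noise SD.
#' @param seed integer seed.
#' @return object of class `"metabolite_matrix"`: list with `intensities`
#'   (samples x metabolites, NAs for missing), `group` (factor with levels
#'   `"group1"`, `"group2"`) and `affected` (names of shifted metabolites).
#' @export
make_metabolite_matrix <- function(n_per_group = 5L, n_metabolites = 483L,
                                   n_affected = round(0.2 * n_metabolites),
                                   effect_log2fc = 1, missing_rate = 0.05,
                                   noise_sd = 0.5, seed = 1L) {
  if (n_per_group < 2) stop("each group needs at least 2 samples")
  stopifnot(n_affected <= n_metabolites, missing_rate >= 0, missing_rate < 1,
            noise_sd >= 0)
  set.seed(as.integer(seed))
  n <- 2L * n_per_group
  met <- sprintf("met%03d", seq_len(n_metabolites))
  group <- factor(rep(c("group1", "group2"), each = n_per_group))
  base_log2 <- runif(n_metabolites, 10, 20)
  logx <- matrix(rnorm(n * n_metabolites, sd = noise_sd), n, n_metabolites)
  logx <- sweep(logx, 2L, base_log2, `+`)
  if (n_affected > 0L)
    logx[group == "group2", seq_len(n_affected)] <-
      logx[group == "group2", seq_len(n_affected), drop = FALSE] + effect_log2fc
  x <- 2^logx
  dimnames(x) <- list(sprintf("s%02d", seq_len(n)), met)
  if (missing_rate > 0)
    x[matrix(runif(length(x)) < missing_rate, n, n_metabolites)] <- NA_real_
  metabolite_matrix(x, group, affected = met[seq_len(n_affected)])
}

#' Construct a metabolite matrix object
#'
#' @param intensities numeric samples x metabolites matrix (NAs allowed).
#' @param group two-level factor of length `nrow(intensities)`.
#' @param affected optional character vector of ground-truth affected
#'   metabolites (synthetic data only).
#' @return an object of class `"metabolite_matrix"`.
#' @export
metabolite_matrix <- function(intensities, group, affected = NULL) {
  stopifnot(is.matrix(intensities), !is.null(colnames(intensities)))
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  if (length(group) != nrow(intensities))
    stop("group length must equal the number of samples")
  if (any(table(group) < 2L)) stop("each group needs at least 2 samples")
  if (anyDuplicated(colnames(intensities)))
    stop("metabolite names must be unique")
  structure(list(intensities = intensities, group = group,
                 affected = affected),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("<metabolite_matrix> %d samples x %d metabolites (%s); %.1f%% missing\n",
              nrow(x$intensities), ncol(x$intensities),
              paste(sprintf("%s n=%d", levels(x$group), table(x$group)),
                    collapse = ", "),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Write / read a metabolite matrix as CSV
#'
#' Layout: first column `sample`, second `group`, remaining columns the
#' metabolites.
#'
#' @param x a [metabolite_matrix()].
#' @param path CSV path.
#' @return `path` (writer) or a `metabolite_matrix` (reader).
#' @export
write_metabolite_csv <- function(x, path) {
  df <- data.frame(sample = rownames(x$intensities), group = x$group,
                   x$intensities, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metabolite_csv
#' @export
read_metabolite_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$sample
  metabolite_matrix(m, factor(df$group))
}
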