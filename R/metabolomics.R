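# Metabolomics preprocessing and univariate/pathway statistics: KNN
# imputation of missing intensities, log2 + autoscaling, volcano filtering
# (Welch t on log2 data, BH-adjusted, raw-scale fold change) and the
# pathway fractional-impact score built from VIP values.

#' KNN imputation of missing metabolite intensities
#'
#' Feature-wise imputation: for each missing entry, the k metabolites
#' nearest to the target metabolite (mean squared Euclidean distance over
#' mutually observed samples) that are observed in that sample are
#' averaged. Complete entries are untouched. A metabolite observed in no
#' sample is an error; a missing entry with no observed neighbour falls
#' back to the metabolite's mean.
#'
#' @param x a [metabolite_matrix()] or a numeric samples x metabolites
#'   matrix with NAs.
#' @param k number of neighbours (default 10).
#' @return the completed object, same type as the input.
#' @export
impute_knn <- function(x, k = 10L) {
  if (inherits(x, "metabolite_matrix")) {
    x$intensities <- impute_knn(x$intensities, k = k)
    return(x)
  }
  stopifnot(is.matrix(x), k >= 1L)
  if (!anyNA(x)) return(x)
  all_missing <- colSums(!is.na(x)) == 0L
  if (any(all_missing))
    stop("metabolite(s) with no observed value: ",
         paste(colnames(x)[all_missing], collapse = ", "))

  O <- !is.na(x)
  X0 <- x; X0[!O] <- 0
  mode(O) <- "numeric"
  # mean squared difference over co-observed samples, feature x feature
  A <- crossprod(X0^2, O)                      # sum_i x_ij^2 over co-observed
  n_both <- crossprod(O)
  d2 <- (A + t(A) - 2 * crossprod(X0)) / n_both
  d2[n_both == 0] <- Inf
  diag(d2) <- Inf

  out <- x
  col_mean <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(!O) > 0L)) {
    nb <- order(d2[, j])                       # nearest metabolites first
    for (i in which(!O[, j])) {
      usable <- nb[O[i, nb] == 1][seq_len(k)]
      usable <- usable[!is.na(usable)]
      out[i, j] <- if (length(usable)) mean(x[i, usable]) else col_mean[j]
    }
  }
  out
}

#' Log2 transform and autoscale
#'
#' Applies log2 to strictly positive intensities, then centres each
#' metabolite to mean 0 and scales it to unit standard deviation (sample
#' SD, n - 1 denominator).
#'
#' @param x a completed [metabolite_matrix()] or numeric matrix
#'   (strictly positive).
#' @return numeric matrix on the modelling scale, with attributes
#'   `"center"` and `"scale"` (per-metabolite log2 mean and SD).
#' @export
log2_autoscale <- function(x) {
  if (inherits(x, "metabolite_matrix")) x <- x$intensities
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("matrix contains missing values; impute first")
  if (any(x <= 0)) stop("all intensities must be strictly positive")
  lg <- log2(x)
  ctr <- colMeans(lg)
  sc <- apply(lg, 2L, sd)
  if (any(sc == 0))
    stop("zero-variance metabolite(s): ",
         paste(colnames(x)[sc == 0], collapse = ", "))
  out <- sweep(sweep(lg, 2L, ctr), 2L, sc, `/`)
  attr(out, "center") <- ctr
  attr(out, "scale") <- sc
  out
}

#' Volcano analysis: fold change and FDR-adjusted Welch t-tests
#'
#' Fold change is the raw-scale ratio of group means (second factor level
#' over first); the gate is direction-agnostic, `max(FC, 1/FC) >=
#' fc_threshold` (inclusive). P-values come from Welch's two-sample t-test
#' on log2 intensities and are Benjamini-Hochberg adjusted; the q gate is
#' strict (`q < q_threshold`). A metabolite is significant when it passes
#' both gates.
#'
#' @param x a completed [metabolite_matrix()], or a raw-scale matrix when
#'   `group` is given.
#' @param group two-level factor (ignored when `x` is a
#'   `metabolite_matrix`).
#' @param fc_threshold fold-change gate (default 1.2, inclusive).
#' @param q_threshold FDR gate (default 0.05, strict).
#' @return data frame of class `"volcano_result"`: `metabolite`, `fc`
#'   (signed ratio group2/group1), `log2fc`, `p`, `q`, `significant`.
#' @export
volcano <- function(x, group = NULL, fc_threshold = 1.2, q_threshold = 0.05) {
  if (inherits(x, "metabolite_matrix")) {
    group <- x$group
    x <- x$intensities
  }
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  if (any(table(group) < 2L)) stop("each group needs at least 2 samples")
  if (anyNA(x)) stop("matrix contains missing values; impute first")
  g1 <- group == levels(group)[1L]
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  fc <- m2 / m1
  lg <- log2(x)
  p <- vapply(seq_len(ncol(x)), function(j)
    t.test(lg[!g1, j], lg[g1, j])$p.value, numeric(1))
  q <- p.adjust(p, method = "BH")
  significant <- pmax(fc, 1 / fc) >= fc_threshold & q < q_threshold
  structure(data.frame(metabolite = colnames(x), fc = fc, log2fc = log2(fc),
                       p = p, q = q, significant = significant,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("volcano_result", "data.frame"),
            fc_threshold = fc_threshold, q_threshold = q_threshold,
            levels = levels(group))
}

#' @export
print.volcano_result <- function(x, ...) {
  cat(sprintf("<volcano_result> %d metabolites, %d significant (|FC| >= %g and q < %g; %s vs %s)\n",
              nrow(x), sum(x$significant), attr(x, "fc_threshold"),
              attr(x, "q_threshold"), attr(x, "levels")[2L],
              attr(x, "levels")[1L]))
  invisible(x)
}

#' Pathway fractional-impact scores
#'
#' For each pathway, the impact is the sum of VIP scores of its significant
#' member metabolites divided by the sum of VIP scores of all its members,
#' so `I` lies in [0, 1]: 0 when no member is significant, 1 when all are.
#' The per-tissue total metabolomic impact is the sum of `I` over pathways.
#'
#' @param pathway_map data frame with columns `pathway` and `metabolite`.
#' @param vip named VIP vector (from [vip_scores()]) covering every mapped
#'   metabolite.
#' @param significant character vector of significant metabolite names
#'   (e.g. from [volcano()], or the VIP > 1.5 set).
#' @return data frame of class `"pathway_impact"`: `pathway`, `n_members`,
#'   `n_significant`, `impact`; attribute `"total"` holds the summed
#'   fractional impact.
#' @export
pathway_impact <- function(pathway_map, vip, significant) {
  stopifnot(all(c("pathway", "metabolite") %in% names(pathway_map)))
  missing_met <- setdiff(pathway_map$metabolite, names(vip))
  if (length(missing_met))
    stop("pathway member(s) absent from the VIP vector: ",
         paste(missing_met, collapse = ", "))
  by_pw <- split(pathway_map$metabolite, pathway_map$pathway)
  rows <- lapply(names(by_pw), function(pw) {
    members <- unique(by_pw[[pw]])
    denom <- sum(vip[members])
    if (denom == 0)
      stop(sprintf("pathway '%s' has zero total VIP", pw))
    sig <- intersect(members, significant)
    data.frame(pathway = pw, n_members = length(members),
               n_significant = length(sig),
               impact = sum(vip[sig]) / denom, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("pathway_impact", "data.frame"),
            total = sum(out$impact))
}

#' @export
print.pathway_impact <- function(x, ...) {
  cat(sprintf("<pathway_impact> %d pathway(s), total fractional impact %.3f\n",
              nrow(x), attr(x, "total")))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Read a pathway membership map from TSV
#'
#' Two columns: `pathway` and `metabolite`.
#'
#' @param path TSV path.
#' @return data frame suitable for [pathway_impact()].
#' @export
read_pathway_map <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
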