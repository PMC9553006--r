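# PCA over the morphometrics table --------------------------------------

#' Standardized PCA of a morphometrics table
#'
#' Principal component analysis of the descriptor columns: variables are
#' centered and (by default) scaled to unit variance, i.e. the
#' eigendecomposition of the correlation matrix. Because the 14 descriptors
#' carry incommensurate units (um, um^2, degrees, dimensionless ratios),
#' standardization is the default. Constant columns cannot be scaled and
#' are dropped with a warning. Loading signs are fixed by making the
#' largest-magnitude loading of each PC positive.
#'
#' @param table A data.frame from [build_table()], or any data.frame whose
#'   descriptor columns are given by `columns`.
#' @param standardize Scale variables to unit variance (default TRUE).
#' @param columns Descriptor column names (default [descriptor_names()]
#'   intersected with the table).
#' @return A `shape_pca` object:
#'   \describe{
#'     \item{loadings}{variables x K matrix of unit-norm eigenvectors.}
#'     \item{scores}{cells x K matrix of PC scores.}
#'     \item{variance_fraction}{per-PC fraction of total variance.}
#'     \item{contributions}{variables x K percent contributions,
#'       `100 * loading^2`; each column sums to 100.}
#'     \item{sdev, center, scale}{as in [stats::prcomp()].}
#'   }
#' @export
run_pca <- function(table, standardize = TRUE, columns = NULL) {
  if (is.null(columns))
    columns <- intersect(descriptor_names(), names(table))
  stop_if_not(length(columns) >= 2L, "need at least 2 descriptor columns")
  X <- as.matrix(table[, columns, drop = FALSE])
  stop_if_not(is.numeric(X) && all(is.finite(X)),
              "descriptor columns must be finite numeric")
  stop_if_not(nrow(X) >= 2L, "need at least 2 rows")
  if (standardize) {
    const <- apply(X, 2, stats::sd) == 0
    if (any(const)) {
      warning("dropping constant column(s): ",
              paste(columns[const], collapse = ", "))
      X <- X[, !const, drop = FALSE]
      stop_if_not(ncol(X) >= 2L, "fewer than 2 non-constant columns")
    }
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = standardize)
  # sign convention: largest |loading| per PC is positive
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  rotation <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  contrib <- 100 * rotation^2
  structure(list(
    loadings = rotation, scores = scores,
    variance_fraction = varfrac, contributions = contrib,
    sdev = pc$sdev, center = pc$center, scale = pc$scale,
    standardized = standardize
  ), class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- min(4L, length(x$variance_fraction))
  cat(sprintf("<shape_pca> %d cells x %d descriptors (%s)\n",
              nrow(x$scores), nrow(x$loadings),
              if (x$standardized) "standardized" else "unscaled"))
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_len(k),
                    100 * x$variance_fraction[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
predict.shape_pca <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, rownames(object$loadings), drop = FALSE])
  X <- sweep(X, 2, object$center)
  if (!isFALSE(object$scale[1])) X <- sweep(X, 2, object$scale, `/`)
  X %*% object$loadings
}

#' Per-descriptor two-group comparison
#'
#' Two-sided two-sample Student's t-tests (pooled variance) of each shape
#' descriptor between exactly two groups, with a significance flag at
#' `alpha`.
#'
#' @param table A data.frame from [build_table()].
#' @param group_label Name of the grouping column (e.g. `"genotype"`).
#' @param columns Descriptor columns (default: the standard 14 present).
#' @param alpha Significance level (default 0.05).
#' @return A data.frame with one row per descriptor: group means, SDs, n,
#'   `p`, and `significant`.
#' @export
compare_descriptors <- function(table, group_label = "genotype",
                                columns = NULL, alpha = 0.05) {
  stop_if_not(group_label %in% names(table),
              sprintf("column '%s' not found", group_label))
  if (is.null(columns))
    columns <- intersect(descriptor_names(), names(table))
  g <- as.character(table[[group_label]])
  lev <- sort(unique(g))
  stop_if_not(length(lev) == 2L, "`group_label` must define exactly 2 groups")
  stop_if_not(min(table(g)) >= 2L, "each group needs n >= 2")
  rows <- lapply(columns, function(cl) {
    x <- table[[cl]][g == lev[1]]
    y <- table[[cl]][g == lev[2]]
    p <- if (stats::sd(c(x, y)) == 0) 1 else
      stats::t.test(x, y, var.equal = TRUE)$p.value
    data.frame(descriptor = cl,
               group1 = lev[1], mean1 = mean(x), sd1 = stats::sd(x),
               n1 = length(x),
               group2 = lev[2], mean2 = mean(y), sd2 = stats::sd(y),
               n2 = length(y),
               p = p, significant = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
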