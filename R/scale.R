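#' Per-variable scaling model
#'
#' Stores the column means and standard deviations used by [autoscale()] so
#' that codebooks and factor profiles can be mapped back to concentration
#' units with [inverse_autoscale()].
#'
#' @param means,sds numeric vectors of equal length; `sds` strictly positive.
#' @return An object of class `aq_scaling`.
#' @export
aq_scaling <- function(means, sds) {
  if (length(means) != length(sds)) stop("means and sds lengths differ")
  if (any(!is.finite(means)) || any(!is.finite(sds)))
    stop("non-finite scaling parameters")
  if (any(sds <= 0)) stop("standard deviations must be strictly positive")
  structure(list(means = means, sds = sds), class = "aq_scaling")
}

#' @export
print.aq_scaling <- function(x, ...) {
  cat("<aq_scaling>\n")
  print(data.frame(variable = names(x$means), mean = unname(x$means),
                   sd = unname(x$sds)), row.names = FALSE)
  invisible(x)
}

#' Autoscale (z-score) a concentration matrix by variable
#'
#' Each column is centred on its mean and divided by its sample standard
#' deviation (denominator n - 1), the standard pretreatment before SOM
#' training so that no pollutant dominates the Euclidean metric.
#'
#' @param X numeric matrix without missing values.
#' @return A list with `X` (the scaled matrix, columns mean 0 / sd 1) and
#'   `scaling` (an [aq_scaling] model for the inverse transform).
#' @export
autoscale <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing values; impute before autoscaling")
  means <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  bad <- sds <= .Machine$double.eps
  if (any(bad))
    stop("constant variable(s) cannot be autoscaled: ",
         paste(if (is.null(colnames(X))) which(bad) else colnames(X)[bad],
               collapse = ", "))
  names(means) <- names(sds) <- colnames(X)
  Xs <- sweep(sweep(X, 2L, means), 2L, sds, "/")
  list(X = Xs, scaling = aq_scaling(means, sds))
}

#' Map an autoscaled matrix back to concentration units
#'
#' @param Xs autoscaled matrix (e.g. a trained codebook).
#' @param scaling the [aq_scaling] model produced by [autoscale()].
#' @return Matrix on the original concentration scale,
#'   `x = xs * sd + mean` per column.
#' @export
inverse_autoscale <- function(Xs, scaling) {
  Xs <- as.matrix(Xs)
  if (ncol(Xs) != length(scaling$means))
    stop("column count (", ncol(Xs), ") does not match scaling model (",
         length(scaling$means), ")")
  sweep(sweep(Xs, 2L, scaling$sds, "*"), 2L, scaling$means, "+")
}

#' Write / read a scaling model as plain text
#'
#' Key-value text with one line per variable: `variable mean sd`.
#' @param scaling an [aq_scaling].
#' @param path file path.
#' @return `path` (write) or an [aq_scaling] (read).
#' @export
write_scaling <- function(scaling, path) {
  df <- data.frame(variable = names(scaling$means),
                   mean = unname(scaling$means), sd = unname(scaling$sds))
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scaling
#' @export
read_scaling <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  aq_scaling(stats::setNames(df$mean, df$variable),
             stats::setNames(df$sd, df$variable))
}
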