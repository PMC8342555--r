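#' Pairwise population statistic matrix
#'
#' Symmetric matrix of a named among-population statistic (F_ST, R_ST, G_ST,
#' phi_ST, waterway distance in km, ...) with an optional matching matrix of
#' permutation p-values.  The diagonal is `NA` (undefined).
#'
#' @param values symmetric numeric matrix with row/column names.
#' @param statistic name of the statistic.
#' @param pvalues optional p-value matrix of the same shape.
#' @return An object of class `pairwise_stat`.
#' @export
pairwise_stat_matrix <- function(values, statistic, pvalues = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (is.null(rownames(values))) stop("matrix needs population labels")
  off <- values[row(values) != col(values)]
  if (any(!is.finite(off))) stop("off-diagonal entries must be finite")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("matrix must be symmetric")
  diag(values) <- NA_real_
  if (!is.null(pvalues)) {
    pvalues <- as.matrix(pvalues)
    if (!all(dim(pvalues) == dim(values))) stop("p-value matrix shape mismatch")
    diag(pvalues) <- NA_real_
  }
  structure(list(labels = rownames(values), values = values,
                 pvalues = pvalues, statistic = statistic),
            class = "pairwise_stat")
}

#' @export
print.pairwise_stat <- function(x, ...) {
  cat("pairwise", x$statistic, "among", length(x$labels), "populations\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Extract the pairwise values for a subset of populations
#' @param m a [pairwise_stat_matrix()].
#' @param pops population labels (default: all).
#' @return Named numeric vector, one entry per unordered pair.
#' @export
pair_values <- function(m, pops = m$labels) {
  stopifnot(all(pops %in% m$labels))
  prs <- combn(pops, 2)
  v <- m$values[cbind(prs[1, ], prs[2, ])]
  names(v) <- paste(prs[1, ], prs[2, ], sep = "-")
  v
}

#' Write one or two pairwise matrices as CSV
#'
#' With both `upper` and `lower` supplied, emits the classic combined layout
#' with one statistic above and another below the diagonal (e.g. F_ST above,
#' R_ST below).
#'
#' @param upper a [pairwise_stat_matrix()].
#' @param path output path.
#' @param lower optional second matrix with identical labels.
#' @return `path`, invisibly.
#' @export
write_pairwise_csv <- function(upper, path, lower = NULL) {
  v <- upper$values
  if (!is.null(lower)) {
    stopifnot(identical(upper$labels, lower$labels))
    v[lower.tri(v)] <- lower$values[lower.tri(v)]
  }
  df <- data.frame(pop = rownames(v), v, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a (possibly combined upper/lower) pairwise CSV
#'
#' @param path file path (first column population labels).
#' @param statistic_upper name for the above-diagonal statistic.
#' @param statistic_lower optional name for the below-diagonal statistic; when
#'   given, two matrices are returned (each symmetrised from its triangle).
#' @return A `pairwise_stat` or a list `list(upper =, lower =)`.
#' @export
read_pairwise_csv <- function(path, statistic_upper = "stat",
                              statistic_lower = NULL) {
  df <- read.csv(path, check.names = FALSE)
  labs <- as.character(df[[1]])
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- labs
  if (!identical(colnames(v), labs)) stop("row/column labels differ")
  mirror <- function(m) {
    m[is.na(m)] <- t(m)[is.na(m)]
    diag(m) <- NA_real_
    m
  }
  sym_from <- function(use_upper) {
    m <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
    tri <- if (use_upper) upper.tri(m) else lower.tri(m)
    m[tri] <- v[tri]
    mirror(m)
  }
  if (is.null(statistic_lower))
    return(pairwise_stat_matrix(mirror(v), statistic_upper))
  list(upper = pairwise_stat_matrix(sym_from(TRUE), statistic_upper),
       lower = pairwise_stat_matrix(sym_from(FALSE), statistic_lower))
}
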