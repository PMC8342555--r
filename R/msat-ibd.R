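#' Isolation-by-distance (Mantel) test
#'
#' Regresses pairwise genetic divergence on pairwise waterway distance and
#' assesses the Mantel correlation by permuting population labels of the
#' distance matrix.  Untransformed values are used by default (genetic
#' distance against km); log options are available but off.
#'
#' @param genetic a [pairwise_stat_matrix()] of genetic divergence.
#' @param distance_km a [pairwise_stat_matrix()] of distances (same labels).
#' @param permutations Mantel permutation count.
#' @param seed optional seed.
#' @param log_genetic,log_distance optional log transforms.
#' @return list with `slope`, `intercept`, `r` (Pearson correlation of the
#'   pairwise vectors), and one-tailed `p` for positive association
#'   (minimum attainable `1 / (permutations + 1)`).
#' @export
ibd_test <- function(genetic, distance_km, permutations = 9999, seed = NULL,
                     log_genetic = FALSE, log_distance = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(identical(genetic$labels, distance_km$labels))
  G <- genetic$values
  D <- distance_km$values
  if (log_genetic) G <- log(G)
  if (log_distance) D <- log(D)
  lt <- lower.tri(G)
  g <- G[lt]; d <- D[lt]
  r_obs <- stats::cor(d, g)
  fit <- stats::lm.fit(cbind(1, d), g)
  ge <- 0L
  n <- nrow(G)
  for (b in seq_len(permutations)) {
    ix <- sample.int(n)
    if (stats::cor(D[ix, ix][lt], g) >= r_obs) ge <- ge + 1L
  }
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r = r_obs, p = (ge + 1) / (permutations + 1))
}

#' Principal coordinates from a pairwise differentiation matrix
#'
#' Classical metric scaling (Gower): double-centre -D^2/2, eigendecompose,
#' order coordinates by eigenvalue.  Visualises among-population genetic
#' differentiation from pairwise F_ST-type matrices.
#'
#' @param matrix a [pairwise_stat_matrix()] (treated as distances).
#' @return list with `coordinates` (populations x axes, positive-eigenvalue
#'   axes only), `eigenvalues` and `fractions` (share of the positive
#'   eigenvalue total).
#' @export
pcoa_from_fst <- function(matrix) {
  D <- matrix$values
  diag(D) <- 0
  fit <- cmdscale(stats::as.dist(D), k = nrow(D) - 1, eig = TRUE)
  ev <- fit$eig
  pos <- ev > 1e-10
  frac <- ifelse(pos, ev / sum(ev[pos]), 0)
  coords <- fit$points
  rownames(coords) <- matrix$labels
  list(coordinates = coords[, seq_len(min(sum(pos), ncol(coords))), drop = FALSE],
       eigenvalues = ev, fractions = frac)
}
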