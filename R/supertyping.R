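# Physicochemical supertype classification of MHC alleles.

#' Five-dimensional amino-acid z-scale descriptors
#'
#' The extended 20 x 5 z-scale table (z1 hydrophobicity, z2 steric bulk,
#' z3 polarity, z4/z5 electronic effects) derived from principal-components
#' analysis of a large physicochemical property panel; the standard choice
#' for embedding peptide-binding residues in a metric space.
#'
#' @return data.frame with rownames A..Y and columns z1..z5.
#' @export
z_scales <- function() {
  z <- read.csv(system.file("extdata", "zscales_sandberg.csv",
                            package = "consgen"))
  rownames(z) <- z$aa
  z[, -1]
}

#' Translate the PBR codons of catalog alleles
#' @param catalog an [allele_catalog()] (or named nucleotide vector).
#' @param pbr_positions PBR codon numbers.
#' @param offset codon number of the first codon of the sequences.
#' @return Character matrix alleles x PBR positions of amino acids; errors on
#'   in-frame stop codons.
#' @export
pbr_amino_acids <- function(catalog, pbr_positions = default_pbr_positions(),
                            offset = 9L) {
  seqs <- if (inherits(catalog, "allele_catalog")) catalog$alleles else catalog
  aln <- codon_alignment(seqs, offset = offset, pbr_mask = pbr_positions)
  cm <- .codon_matrix(seqs)
  aa <- matrix(.codon_env$aa[cm], nrow(cm), ncol(cm), dimnames = dimnames(cm))
  idx <- match(sort(pbr_positions), aln$codon_numbers)
  out <- aa[, idx, drop = FALSE]
  colnames(out) <- sort(pbr_positions)
  rownames(out) <- names(seqs)
  out
}

#' Build the z-descriptor matrix over PBR positions
#'
#' One row per allele; columns are the concatenation of z1..z5 for each PBR
#' residue in position order, so alleles synonymous at every PBR codon get
#' identical rows.
#'
#' @inheritParams pbr_amino_acids
#' @param z_table descriptor table (defaults to [z_scales()]).
#' @return Numeric matrix alleles x (5 * n_PBR), class `descriptor_matrix`.
#' @export
build_descriptor_matrix <- function(catalog,
                                    pbr_positions = default_pbr_positions(),
                                    z_table = z_scales(), offset = 9L) {
  aa <- pbr_amino_acids(catalog, pbr_positions, offset)
  unknown <- setdiff(unique(as.vector(aa)), rownames(z_table))
  if (length(unknown)) stop("amino acids missing from z table: ",
                            paste(unknown, collapse = ", "))
  blocks <- lapply(seq_len(ncol(aa)), function(j) {
    m <- as.matrix(z_table[aa[, j], , drop = FALSE])
    colnames(m) <- paste0("p", colnames(aa)[j], "_", colnames(z_table))
    m
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- rownames(aa)
  class(out) <- c("descriptor_matrix", class(out))
  out
}

# ---- cluster-validity indices --------------------------------------------

.index_ch <- function(mat, cl) {
  X <- mat
  n <- nrow(X); k <- length(unique(cl))
  gm <- colMeans(X)
  W <- 0; B <- 0
  for (g in unique(cl)) {
    Xi <- X[cl == g, , drop = FALSE]
    cm <- colMeans(Xi)
    W <- W + sum(sweep(Xi, 2, cm)^2)
    B <- B + nrow(Xi) * sum((cm - gm)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

.index_silhouette <- function(mat, cl) {
  mean(cluster::silhouette(cl, dist(mat))[, 3])
}

.index_db <- function(mat, cl) {
  X <- mat
  gs <- sort(unique(cl)); k <- length(gs)
  cent <- t(vapply(gs, function(g) colMeans(X[cl == g, , drop = FALSE]),
                   numeric(ncol(X))))
  sbar <- vapply(gs, function(g) {
    Xi <- X[cl == g, , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xi, 2, colMeans(Xi))^2)))
  }, 0)
  db <- 0
  for (i in seq_len(k)) {
    ratios <- vapply(setdiff(seq_len(k), i), function(j)
      (sbar[i] + sbar[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2)), 0)
    db <- db + max(ratios)
  }
  db / k
}

.index_dunn <- function(mat, cl) {
  D <- as.matrix(dist(mat))
  gs <- sort(unique(cl))
  inter <- Inf; intra <- 0
  for (i in seq_along(gs)) {
    wi <- which(cl == gs[i])
    if (length(wi) > 1) intra <- max(intra, max(D[wi, wi]))
    for (j in seq_along(gs)) if (j > i) {
      wj <- which(cl == gs[j])
      inter <- min(inter, min(D[wi, wj]))
    }
  }
  if (intra == 0) Inf else inter / intra
}

# gap statistic (uniform reference over the data's column ranges);
# vote by the Tibshirani one-standard-error rule
.gap_curve <- function(X, ks, B = 25, nstart = 50) {
  wk <- function(Y, k) {
    if (k == 1) sum(sweep(Y, 2, colMeans(Y))^2)
    else kmeans(Y, k, nstart = nstart, iter.max = 50)$tot.withinss
  }
  lw_obs <- vapply(ks, function(k) log(wk(X, k)), 0)
  rng <- apply(X, 2, range)
  lw_ref <- matrix(0, B, length(ks))
  for (b in seq_len(B)) {
    Y <- apply(rng, 2, function(r) runif(nrow(X), r[1], r[2]))
    lw_ref[b, ] <- vapply(ks, function(k) log(wk(Y, k)), 0)
  }
  gap <- colMeans(lw_ref) - lw_obs
  se <- apply(lw_ref, 2, sd) * sqrt(1 + 1 / B)
  list(gap = gap, se = se)
}

#' Choose the number of supertypes by majority rule
#'
#' For each candidate K, partitions the descriptor matrix by k-means (50
#' restarts); five cluster-validity indices (Calinski-Harabasz, mean
#' silhouette width, Davies-Bouldin, Dunn, gap statistic) each vote for
#' their optimal K and the majority wins, ties resolved toward the smaller
#' K (parsimony).
#'
#' @param matrix descriptor matrix (alleles x descriptors).
#' @param k_range candidate K values (default 2..8, truncated to n - 1).
#' @param seed integer seed (k-means restarts and gap references).
#' @param gap_B reference-set count for the gap statistic.
#' @return list with `K`, `votes` (index -> chosen K), and
#'   `clusterings` (k-means labels per candidate K).
#' @export
choose_k <- function(matrix, k_range = 2:8, seed = 1, gap_B = 25) {
  set.seed(seed)
  X <- unclass(matrix)
  n_distinct <- nrow(unique(X))
  if (n_distinct < 2) stop("all descriptor rows identical: K undefined")
  k_range <- k_range[k_range < nrow(X) & k_range <= n_distinct]
  if (!length(k_range)) stop("no feasible K in range")
  cls <- lapply(k_range, function(k) kmeans(X, k, nstart = 50, iter.max = 50)$cluster)
  names(cls) <- k_range
  votes <- c(
    calinski_harabasz = k_range[which.max(vapply(cls, .index_ch, 0, mat = X))],
    silhouette = k_range[which.max(vapply(cls, .index_silhouette, 0, mat = X))],
    davies_bouldin = k_range[which.min(vapply(cls, .index_db, 0, mat = X))],
    dunn = k_range[which.max(vapply(cls, .index_dunn, 0, mat = X))])
  g <- .gap_curve(X, k_range, B = gap_B)
  pick <- NA_integer_
  for (j in seq_along(k_range)[-length(k_range)]) {
    if (g$gap[j] >= g$gap[j + 1] - g$se[j + 1]) { pick <- k_range[j]; break }
  }
  if (is.na(pick)) pick <- k_range[which.max(g$gap)]
  votes <- c(votes, gap = pick)
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(K = min(winners), votes = votes, clusterings = cls)
}

#' Assign alleles to supertypes by DAPC
#'
#' Discriminant analysis of principal components: columns are centred and
#' scaled (constant columns dropped), principal components covering at least
#' 90% of variance are retained (capped at n - K), k-means provides the
#' initial groups and linear discriminant analysis on the retained PCs gives
#' the final assignment.
#'
#' @param matrix descriptor matrix.
#' @param K number of supertypes.
#' @param seed integer seed.
#' @param retain_var PC variance fraction to retain.
#' @return list of class `supertype_assignment`: `assignment` (named integer
#'   vector allele -> supertype 1..K), `K`, `coordinates` (discriminant or PC
#'   coordinates).
#' @export
dapc_assign <- function(matrix, K, seed = 1, retain_var = 0.9) {
  set.seed(seed)
  X <- unclass(matrix)
  n <- nrow(X)
  if (K == 1) {
    return(structure(list(assignment = setNames(rep(1L, n), rownames(X)),
                          K = 1L, coordinates = NULL),
                     class = "supertype_assignment"))
  }
  if (K > n) stop("K exceeds the number of alleles")
  keep <- apply(X, 2, sd) > 0
  pc <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  npc <- which(cum >= retain_var)[1]
  npc <- max(1L, min(npc, n - K, sum(pc$sdev > 1e-8)))
  scores <- pc$x[, seq_len(npc), drop = FALSE]
  grp <- kmeans(scores, K, nstart = 50, iter.max = 50)$cluster
  # identical rows share identical scores, hence identical assignments
  lab <- tryCatch({
    fit <- MASS::lda(scores, grouping = factor(grp), tol = 1e-8)
    as.integer(stats::predict(fit, scores)$class)
  }, error = function(e) as.integer(grp))
  coords <- tryCatch(stats::predict(MASS::lda(scores, grouping = factor(grp),
                                              tol = 1e-8), scores)$x,
                     error = function(e) scores)
  structure(list(assignment = setNames(lab, rownames(X)), K = as.integer(K),
                 coordinates = coords),
            class = "supertype_assignment")
}

#' Per-population supertype frequencies
#'
#' Collapses the catalog's per-population allele frequencies by supertype.
#'
#' @param assignment a `supertype_assignment` from [dapc_assign()].
#' @param catalog an [allele_catalog()].
#' @return Matrix populations x supertypes; rows sum to 1.
#' @export
supertype_frequencies <- function(assignment, catalog) {
  f <- catalog$frequencies
  st <- assignment$assignment[colnames(f)]
  if (any(is.na(st))) stop("assignment does not cover all catalog alleles")
  out <- t(rowsum(t(f), group = st))
  colnames(out) <- paste0("ST", colnames(out))
  out
}

#' Run the full supertyping pipeline on an allele FASTA
#'
#' Convenience wrapper: read alleles, build the z-descriptor matrix over the
#' default PBR mask, select K by majority rule and assign supertypes.
#'
#' @param fasta_path path to a nucleotide allele FASTA (in-frame, first codon
#'   = `offset`).
#' @param pbr_positions PBR codon numbers.
#' @param offset first codon number.
#' @param k_range,seed passed to [choose_k()]/[dapc_assign()].
#' @return list with `K`, `votes`, `assignment`, `matrix`.
#' @export
supertype_pipeline <- function(fasta_path,
                               pbr_positions = default_pbr_positions(),
                               offset = 9L, k_range = 2:8, seed = 1) {
  seqs <- read_fasta(fasta_path)
  M <- build_descriptor_matrix(seqs, pbr_positions, offset = offset)
  ck <- choose_k(M, k_range = k_range, seed = seed)
  asg <- dapc_assign(M, ck$K, seed = seed)
  list(K = ck$K, votes = ck$votes, assignment = asg, matrix = M)
}
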