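# Positive-selection statistics on codon alignments.

#' In-frame codon alignment with a PBR mask
#'
#' @param sequences named character vector of equal-length nucleotide
#'   sequences (length divisible by 3, no internal stop codons).
#' @param offset codon number of the first column (1-based inclusive
#'   numbering; beta-1 domain amplicons conventionally start at codon 9).
#' @param pbr_mask codon numbers flagged as peptide-binding residues (must
#'   fall inside the codon range).
#' @return An object of class `codon_alignment` with fields `sequences`,
#'   `codon_numbers` and `pbr_mask`.
#' @export
codon_alignment <- function(sequences, offset = 9L, pbr_mask = integer(0)) {
  .codon_setup()
  lens <- unique(nchar(sequences))
  if (length(lens) != 1) stop("sequences must be aligned (equal length)")
  if (lens %% 3 != 0) stop("alignment length not divisible by 3")
  n_codons <- lens / 3
  cm <- .codon_matrix(sequences)
  if (any(.codon_env$aa[cm] == "*"))
    stop("internal stop codon in alignment")
  codon_numbers <- seq_len(n_codons) + as.integer(offset) - 1L
  if (length(pbr_mask) && !all(pbr_mask %in% codon_numbers))
    stop("pbr_mask positions outside codon range")
  structure(list(sequences = sequences, codon_numbers = codon_numbers,
                 pbr_mask = sort(as.integer(pbr_mask))),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d sequences x %d codons (numbered %d-%d), %d PBR\n",
              length(x$sequences), length(x$codon_numbers),
              min(x$codon_numbers), max(x$codon_numbers), length(x$pbr_mask)))
  invisible(x)
}

.codon_matrix <- function(sequences) {
  n_codons <- nchar(sequences[1]) %/% 3
  m <- vapply(sequences, function(s)
    substring(s, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons)),
    character(n_codons))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(sequences)))
  t(m)
}

#' Default peptide-binding-residue codon positions for the DAB beta-1 domain
#' @return Integer vector of PBR codon numbers (mature-protein numbering).
#' @export
default_pbr_positions <- function() {
  as.integer(read.csv(system.file("extdata", "pbr_positions.csv",
                                  package = "consgen"))$codon)
}

#' Jukes-Cantor distance correction
#' @param p proportion of differing sites (p-distance).
#' @return d = -(3/4) log(1 - 4p/3); errors when `4p/3 >= 1` (correction
#'   undefined).
#' @export
jukes_cantor <- function(p) {
  if (any(4 * p / 3 >= 1)) stop("Jukes-Cantor correction undefined: p >= 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

#' Split an alignment into PBR and non-PBR partitions
#' @param aln a [codon_alignment()].
#' @param pbr_positions codon numbers (defaults to the alignment's mask).
#' @return list with `pbr` and `non_pbr` codon alignments (empty partitions
#'   are returned as `NULL`).
#' @export
partition_alignment <- function(aln, pbr_positions = aln$pbr_mask) {
  if (!all(pbr_positions %in% aln$codon_numbers))
    stop("pbr positions outside codon range")
  take <- function(nums) {
    if (!length(nums)) return(NULL)
    idx <- match(nums, aln$codon_numbers)
    cm <- .codon_matrix(aln$sequences)
    seqs <- apply(cm[, idx, drop = FALSE], 1, paste, collapse = "")
    names(seqs) <- names(aln$sequences)
    out <- codon_alignment(seqs, offset = 1L)
    out$codon_numbers <- as.integer(nums)
    out
  }
  pbr_positions <- sort(pbr_positions)
  list(pbr = take(pbr_positions),
       non_pbr = take(setdiff(aln$codon_numbers, pbr_positions)))
}

# --- Nei-Gojobori machinery ------------------------------------------------

# synonymous site count of one codon: at each position, the fraction of
# non-stop single-nucleotide changes that are synonymous; nonsyn sites are
# the complement (3 - s)
.codon_syn_sites <- function(codon) {
  .codon_setup()
  nb <- .codon_env$neighbors[[codon]]
  pos <- rep(1:3, each = 3)
  s <- 0
  for (p in 1:3) {
    rows <- nb[pos == p & !nb$stop, , drop = FALSE]
    if (nrow(rows)) s <- s + sum(rows$syn) / nrow(rows)
  }
  s
}

# synonymous/nonsynonymous difference counts between two codons by
# equal-weight pathway enumeration; pathways through stop codons are dropped
# and weights renormalised (all-blocked pairs fall back to all pathways)
.codon_pair_diffs <- function(c1, c2) {
  .codon_setup()
  if (c1 == c2) return(c(sd = 0, nd = 0))
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  dpos <- which(ch1 != ch2)
  aa <- .codon_env$aa
  paths <- .permutations(dpos)
  acc <- matrix(0, 0, 2)
  acc_all <- matrix(0, 0, 2)
  for (r in seq_len(nrow(paths))) {
    cur <- ch1; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in paths[r, ]) {
      prev <- paste(cur, collapse = "")
      cur[p] <- ch2[p]
      nxt <- paste(cur, collapse = "")
      if (aa[[nxt]] == "*") blocked <- TRUE
      if (aa[[nxt]] == aa[[prev]]) sd <- sd + 1 else nd <- nd + 1
    }
    acc_all <- rbind(acc_all, c(sd, nd))
    if (!blocked) acc <- rbind(acc, c(sd, nd))
  }
  use <- if (nrow(acc)) acc else acc_all
  c(sd = mean(use[, 1]), nd = mean(use[, 2]))
}

# cached per-codon sites and per-codon-pair differences
.ng_cache <- new.env(parent = emptyenv())

.ng_sites <- function(codon) {
  v <- .ng_cache[[paste0("s_", codon)]]
  if (is.null(v)) {
    v <- .codon_syn_sites(codon)
    .ng_cache[[paste0("s_", codon)]] <- v
  }
  v
}

.ng_diffs <- function(c1, c2) {
  key <- if (c1 < c2) paste0(c1, c2) else paste0(c2, c1)
  v <- .ng_cache[[key]]
  if (is.null(v)) {
    v <- .codon_pair_diffs(c1, c2)
    .ng_cache[[key]] <- v
  }
  v
}

#' Nei-Gojobori dN/dS with Jukes-Cantor correction and codon bootstrap
#'
#' For every sequence pair, synonymous and nonsynonymous sites are averaged
#' over the two sequences and differences counted by equal-weight pathway
#' enumeration; the resulting proportions are Jukes-Cantor corrected and
#' averaged over all unique pairs.  Codon-resampling bootstrap provides
#' standard errors and a one-tailed Z test of dN > dS (positive selection).
#'
#' @param aln a [codon_alignment()] (>= 2 sequences).
#' @param partition `"all"`, `"PBR"` or `"nonPBR"`; the PBR mask of `aln`
#'   defines the split (partition must be non-empty).
#' @param bootstrap bootstrap replicate count (default 2000).
#' @param seed optional seed for the bootstrap.
#' @param correction `"jc"` (Jukes-Cantor, the default) or `"none"` (raw
#'   proportions; useful for tiny hand-checked alignments where p >= 3/4
#'   makes the correction undefined).
#' @return list of class `dnds_result`: `dN`, `dS`, `omega`, `SE_dN`,
#'   `SE_dS`, `Z`, `p` (one-tailed normal), `partition`, `n_codons`.
#' @export
nei_gojobori <- function(aln, partition = c("all", "PBR", "nonPBR"),
                         bootstrap = 2000, seed = NULL,
                         correction = c("jc", "none")) {
  partition <- match.arg(partition)
  correction <- match.arg(correction)
  corr <- if (correction == "jc") jukes_cantor else identity
  if (!is.null(seed)) set.seed(seed)
  .codon_setup()
  if (length(aln$sequences) < 2) stop("need at least 2 sequences")
  cm <- .codon_matrix(aln$sequences)
  idx <- switch(partition,
                all = seq_along(aln$codon_numbers),
                PBR = match(aln$pbr_mask, aln$codon_numbers),
                nonPBR = which(!aln$codon_numbers %in% aln$pbr_mask))
  if (!length(idx)) stop("empty partition: ", partition)
  cm <- cm[, idx, drop = FALSE]
  nseq <- nrow(cm); ncod <- ncol(cm)
  prs <- combn(nseq, 2)
  npair <- ncol(prs)
  Ssite <- Nsite <- Sdiff <- Ndiff <- matrix(0, npair, ncod)
  site_per_codon <- matrix(vapply(cm, .ng_sites, 0), nseq, ncod)
  for (k in seq_len(npair)) {
    i <- prs[1, k]; j <- prs[2, k]
    Ssite[k, ] <- (site_per_codon[i, ] + site_per_codon[j, ]) / 2
    Nsite[k, ] <- 3 - Ssite[k, ]
    for (c in seq_len(ncod)) {
      d <- .ng_diffs(cm[i, c], cm[j, c])
      Sdiff[k, c] <- d["sd"]; Ndiff[k, c] <- d["nd"]
    }
  }
  pair_d <- function(cols) {
    S <- rowSums(Ssite[, cols, drop = FALSE])
    N <- rowSums(Nsite[, cols, drop = FALSE])
    # a (resampled) codon set can lack synonymous sites entirely; with no
    # sites there are no observable differences, so the proportion is 0
    pS <- ifelse(S > 0, rowSums(Sdiff[, cols, drop = FALSE]) / S, 0)
    pN <- ifelse(N > 0, rowSums(Ndiff[, cols, drop = FALSE]) / N, 0)
    list(pS = pS, pN = pN)
  }
  obs <- pair_d(seq_len(ncod))
  if (correction == "jc" &&
      (any(4 * obs$pS / 3 >= 1) || any(4 * obs$pN / 3 >= 1))) {
    bad <- which(4 * obs$pS / 3 >= 1 | 4 * obs$pN / 3 >= 1)[1]
    stop(sprintf("Jukes-Cantor correction undefined for pair %s-%s",
                 rownames(cm)[prs[1, bad]], rownames(cm)[prs[2, bad]]))
  }
  dS <- mean(corr(obs$pS))
  dN <- mean(corr(obs$pN))
  bs_dN <- bs_dS <- rep(NA_real_, bootstrap)
  for (b in seq_len(bootstrap)) {
    cols <- sample.int(ncod, ncod, replace = TRUE)
    d <- pair_d(cols)
    if (correction == "jc" &&
        (any(4 * d$pS / 3 >= 1) || any(4 * d$pN / 3 >= 1))) next  # drop replicate
    bs_dS[b] <- mean(corr(d$pS))
    bs_dN[b] <- mean(corr(d$pN))
  }
  se_dN <- sd(bs_dN, na.rm = TRUE)
  se_dS <- sd(bs_dS, na.rm = TRUE)
  vv <- var(bs_dN, na.rm = TRUE) + var(bs_dS, na.rm = TRUE)
  Z <- if (vv > 0) (dN - dS) / sqrt(vv) else 0
  structure(list(dN = dN, dS = dS,
                 omega = if (dS > 0) dN / dS else NA_real_,
                 SE_dN = se_dN, SE_dS = se_dS, Z = Z,
                 p = 1 - pnorm(Z), partition = partition, n_codons = ncod,
                 n_pairs = npair),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("dN/dS (%s, %d codons): dN=%.4f (SE %.4f), dS=%.4f (SE %.4f), omega=%s, Z=%.2f, p=%.4g\n",
              x$partition, x$n_codons, x$dN, x$SE_dN, x$dS, x$SE_dS,
              ifelse(is.na(x$omega), "NA", sprintf("%.3f", x$omega)), x$Z, x$p))
  invisible(x)
}

#' Export a codon alignment in interleaved PHYLIP format
#'
#' Convenience export for external codon-model software (site-model
#' likelihood tests are not re-implemented here).
#'
#' @param aln a [codon_alignment()].
#' @param path output path.
#' @param width block width in bp.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(aln, path, width = 60) {
  seqs <- aln$sequences
  n <- length(seqs); len <- nchar(seqs[1])
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf(" %d %d", n, len), con)
  starts <- seq(1, len, width)
  for (bi in seq_along(starts)) {
    for (i in seq_len(n)) {
      chunk <- substr(seqs[i], starts[bi], min(starts[bi] + width - 1, len))
      nm <- if (bi == 1) sprintf("%-10s", substr(names(seqs)[i], 1, 10)) else
        strrep(" ", 10)
      writeLines(paste0(nm, chunk), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
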