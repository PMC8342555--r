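# Codon-level sequence simulation with per-site omega.

# cached codon machinery (built on first use)
.codon_env <- new.env(parent = emptyenv())

.codon_setup <- function() {
  if (!is.null(.codon_env$codons)) return(invisible())
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  aa <- unname(gc_tab)
  nonstop <- codons[aa != "*"]
  bases <- c("A", "C", "G", "T")
  is_ts <- function(x, y) paste0(sort(c(x, y)), collapse = "") %in% c("AG", "CT")
  nb <- list()
  for (cd in codons) {
    ch <- strsplit(cd, "")[[1]]
    rows <- list()
    for (p in 1:3) for (b in setdiff(bases, ch[p])) {
      ch2 <- ch; ch2[p] <- b
      cd2 <- paste(ch2, collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        to = cd2, ts = is_ts(ch[p], b),
        syn = gc_tab[[cd2]] == gc_tab[[cd]],
        stop = gc_tab[[cd2]] == "*")
    }
    nb[[cd]] <- do.call(rbind, rows)
  }
  # neutral normalisation: mean total leaving rate over non-stop codons with
  # kappa = 1, omega = 1, stop-bound changes forbidden
  .codon_env$codons <- codons
  .codon_env$aa <- setNames(aa, codons)
  .codon_env$nonstop <- nonstop
  .codon_env$neighbors <- nb
  invisible()
}

.codon_rates <- function(codon, omega, kappa) {
  nb <- .codon_env$neighbors[[codon]]
  r <- ifelse(nb$ts, kappa, 1) * ifelse(nb$syn, 1, omega)
  r[nb$stop] <- 0
  list(to = nb$to, rate = r)
}

#' Simulate an in-frame codon alignment under site-specific omega
#'
#' Evolves codons independently along a rooted tree under a
#' Goldman-Yang-style model: single-nucleotide exchanges at relative rate
#' `kappa` for transitions, multiplied by the site's `omega` when the change
#' is nonsynonymous; changes to stop codons are forbidden.  Branch lengths
#' are interpreted as expected substitutions per codon for a neutral
#' (`omega = 1`) site, so `omega` scales only the nonsynonymous flux.
#'
#' @param tree a rooted `ape::phylo` tree with branch lengths.
#' @param omega_map numeric vector of per-codon omega values (length
#'   `n_codons`); sites with `omega > 1` define the PBR mask of the result.
#' @param kappa transition/transversion rate ratio.
#' @param n_codons number of codons.
#' @param seed integer seed.
#' @param offset codon number of the first alignment column (mature-protein
#'   numbering; the beta-1 domain amplicons start at codon 9).
#' @return A [codon_alignment()] whose `pbr_mask` lists the codons simulated
#'   with `omega > 1`.
#' @export
simulate_codon_alignment <- function(tree, omega_map, kappa = 2,
                                     n_codons = length(omega_map), seed,
                                     offset = 9L) {
  .codon_setup()
  set.seed(seed)
  omega_map <- rep_len(omega_map, n_codons)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  edges <- tree$edge
  elen <- tree$edge.length
  # neutral scaling so one unit of branch length = one expected neutral
  # substitution per codon (averaged over non-stop codons)
  mean_rate <- mean(vapply(.codon_env$nonstop, function(cd) {
    sum(.codon_rates(cd, 1, kappa)$rate)
  }, 0))
  ord <- seq_len(nrow(edges))
  nnode <- max(edges)
  tipstates <- matrix("", ntip, n_codons)
  for (s in seq_len(n_codons)) {
    st <- character(nnode)
    st[root] <- sample(.codon_env$nonstop, 1L)
    for (e in ord) {
      parent <- edges[e, 1]; child <- edges[e, 2]
      cd <- st[parent]
      t_rem <- elen[e]
      repeat {
        rt <- .codon_rates(cd, omega_map[s], kappa)
        tot <- sum(rt$rate) / mean_rate
        if (tot <= 0) break
        w <- stats::rexp(1, tot)
        if (w > t_rem) break
        t_rem <- t_rem - w
        cd <- sample(rt$to, 1L, prob = rt$rate)
      }
      st[child] <- cd
    }
    tipstates[, s] <- st[seq_len(ntip)]
  }
  seqs <- apply(tipstates, 1, paste, collapse = "")
  names(seqs) <- tree$tip.label
  codon_alignment(seqs, offset = offset,
                  pbr_mask = (seq_len(n_codons) + offset - 1L)[omega_map > 1])
}
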