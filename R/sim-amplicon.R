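#' Amplicon sequencing simulation model
#'
#' Describes per-individual MHC amplicon read sets generated from known
#' allele pairs: sequencing depth, uniform per-base substitution error,
#' PCR chimeras (single crossover between the individual's two alleles) and
#' optional index hopping.
#'
#' @param catalog named character vector: the true allele sequences of one
#'   locus (equal length).
#' @param genotypes data.frame with columns `individual`, `pop`, `allele1`,
#'   `allele2` (allele names from `catalog`; homozygotes repeat the name,
#'   `NA` in both means failed amplification).
#' @param locus locus label (e.g. "DAB1").
#' @param depth mean read depth per amplicon; either a single number (fixed)
#'   or a function `f(n)` returning `n` depths.
#' @param error_rate per-base substitution error probability.
#' @param chimera_rate probability a read is a single-crossover chimera of
#'   the individual's two alleles (heterozygotes only).
#' @param hop_rate probability a read is reassigned to a random other
#'   individual (index hopping).
#' @return An object of class `amplicon_sim_model`.
#' @export
amplicon_sim_model <- function(catalog, genotypes, locus = "DAB1",
                               depth = 2000, error_rate = 0.003,
                               chimera_rate = 0.05, hop_rate = 0) {
  if (length(unique(nchar(catalog))) != 1)
    stop("catalog alleles must be equal length")
  for (r in c(error_rate, chimera_rate, hop_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0,1]")
  if (is.numeric(depth) && any(depth < 0)) stop("depth must be >= 0")
  need <- c("individual", "pop", "allele1", "allele2")
  if (!all(need %in% names(genotypes))) stop("genotypes needs columns ",
                                             paste(need, collapse = ", "))
  known <- c(genotypes$allele1, genotypes$allele2)
  if (!all(known %in% c(names(catalog), NA)))
    stop("genotypes reference alleles absent from the catalog")
  structure(list(catalog = catalog, genotypes = genotypes, locus = locus,
                 depth = depth, error_rate = error_rate,
                 chimera_rate = chimera_rate, hop_rate = hop_rate),
            class = "amplicon_sim_model")
}

#' Per-individual amplicon read set
#'
#' @param individual individual ID.
#' @param locus locus label.
#' @param variants data.frame with columns `seq`, `count` (unique trimmed
#'   sequences and read counts).
#' @param pop population ID.
#' @return An object of class `amplicon_read_set`.
#' @export
amplicon_read_set <- function(individual, locus, variants, pop = NA_character_) {
  stopifnot(all(variants$count >= 1))
  variants <- variants[order(-variants$count, variants$seq), , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(individual = individual, pop = pop, locus = locus,
                 variants = variants, total = sum(variants$count)),
            class = "amplicon_read_set")
}

#' @export
print.amplicon_read_set <- function(x, ...) {
  cat(sprintf("amplicon_read_set %s/%s: %d variants, %.0f reads\n",
              x$individual, x$locus, nrow(x$variants), x$total))
  invisible(x)
}

# number of errors per read, conditioned on >= 1, via inverse-CDF truncation
.n_errors <- function(nreads, len, rate) {
  p0 <- (1 - rate)^len
  qbinom(runif(nreads, p0, 1), len, rate)
}

# apply k random substitutions to a template string
.mutate_read <- function(template_chars, k) {
  pos <- sample.int(length(template_chars), k)
  for (p in pos) {
    template_chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                        template_chars[p]), 1L)
  }
  paste(template_chars, collapse = "")
}

# expand one template into error-free + errorful variant counts
.seq_with_errors <- function(template, m, rate, acc) {
  len <- nchar(template)
  nerr <- rbinom(1L, m, 1 - (1 - rate)^len)
  if (m - nerr > 0) acc[[template]] <- (acc[[template]] %||% 0L) + (m - nerr)
  if (nerr > 0) {
    tc <- strsplit(template, "")[[1]]
    ks <- .n_errors(nerr, len, rate)
    for (k in ks) {
      v <- .mutate_read(tc, k)
      acc[[v]] <- (acc[[v]] %||% 0L) + 1L
    }
  }
  acc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate per-individual amplicon read sets
#'
#' Reads are drawn from the individual's one or two alleles; heterozygote
#' reads become single-breakpoint chimeras with probability `chimera_rate`;
#' every read then receives independent per-base substitution errors.
#' Individuals with `NA` alleles (failed amplification) yield no read set,
#' so missing-data bookkeeping propagates downstream.
#'
#' @param model an [amplicon_sim_model()].
#' @param seed integer seed.
#' @return List of [amplicon_read_set()] objects (one per amplifying
#'   individual) with attribute `truth`, the true catalog.
#' @export
simulate_amplicon_reads <- function(model, seed) {
  set.seed(seed)
  g <- model$genotypes
  out <- list()
  for (i in seq_len(nrow(g))) {
    if (is.na(g$allele1[i]) && is.na(g$allele2[i])) next
    a1 <- model$catalog[[g$allele1[i]]]
    a2 <- model$catalog[[g$allele2[i]]]
    het <- g$allele1[i] != g$allele2[i]
    D <- as.integer(if (is.function(model$depth)) model$depth(1L) else model$depth)
    if (D == 0) next
    acc <- list()
    n_chim <- if (het) rbinom(1L, D, model$chimera_rate) else 0L
    n1 <- rbinom(1L, D - n_chim, 0.5)
    if (!het) n1 <- D - n_chim
    acc <- .seq_with_errors(a1, n1, model$error_rate, acc)
    if (D - n_chim - n1 > 0)
      acc <- .seq_with_errors(a2, D - n_chim - n1, model$error_rate, acc)
    if (n_chim > 0) {
      len <- nchar(a1)
      brk <- sample.int(len - 1L, n_chim, replace = TRUE)
      for (b in unique(brk)) {
        chim <- paste0(substr(a1, 1, b), substr(a2, b + 1, len))
        acc <- .seq_with_errors(chim, sum(brk == b), model$error_rate, acc)
      }
    }
    out[[g$individual[i]]] <- amplicon_read_set(
      g$individual[i], model$locus,
      data.frame(seq = names(acc), count = unlist(acc, use.names = FALSE)),
      pop = g$pop[i])
  }
  if (model$hop_rate > 0 && length(out) > 1) out <- .hop_indices(out, model$hop_rate)
  attr(out, "truth") <- model$catalog
  out
}

# crude index hopping: each read moves to a random other individual w.p. rate
.hop_indices <- function(readsets, rate) {
  nm <- names(readsets)
  moved <- list()
  for (j in seq_along(readsets)) {
    v <- readsets[[j]]$variants
    hop <- rbinom(nrow(v), v$count, rate)
    keep <- v$count - hop
    for (r in which(hop > 0)) {
      tgt <- sample(nm[-j], 1L)
      moved[[length(moved) + 1L]] <- list(tgt = tgt, seq = v$seq[r], n = hop[r])
    }
    v$count <- keep
    readsets[[j]]$variants <- v[v$count > 0, , drop = FALSE]
  }
  for (mv in moved) {
    v <- readsets[[mv$tgt]]$variants
    hit <- match(mv$seq, v$seq)
    if (is.na(hit)) v <- rbind(v, data.frame(seq = mv$seq, count = mv$n))
    else v$count[hit] <- v$count[hit] + mv$n
    readsets[[mv$tgt]]$variants <- v
  }
  for (j in seq_along(readsets))
    readsets[[j]] <- amplicon_read_set(readsets[[j]]$individual,
                                       readsets[[j]]$locus,
                                       readsets[[j]]$variants,
                                       readsets[[j]]$pop)
  readsets
}

#' Emit simulated read sets as an indexed, primer-tagged FASTQ
#'
#' Reconstructs merged MiSeq-style reads
#' `[index_f][primer_f][insert][revcomp(primer_r)][revcomp(index_r)]`
#' with uniform quality, for exercising the demultiplexing/trimming stage.
#'
#' @param readsets output of [simulate_amplicon_reads()].
#' @param index_table data.frame `individual`, `index_f`, `index_r` (8 bp).
#' @param primer_f,primer_r primer sequences (IUPAC allowed).
#' @param path output FASTQ path.
#' @param q uniform Phred quality for all bases.
#' @return `path`, invisibly.
#' @export
write_amplicon_fastq <- function(readsets, index_table, primer_f, primer_r,
                                 path, q = 37L) {
  # sequencers emit concrete bases: resolve primer degeneracies at random
  concretize <- function(s) {
    ch <- strsplit(s, "")[[1]]
    deg <- !ch %in% c("A", "C", "G", "T")
    ch[deg] <- vapply(ch[deg], function(b)
      sample(strsplit(.iupac_table[[b]], "")[[1]], 1L), "")
    paste(ch, collapse = "")
  }
  pf <- concretize(primer_f)
  prc <- concretize(revcomp(primer_r))
  rows <- list()
  for (rs in readsets) {
    ix <- index_table[index_table$individual == rs$individual, ]
    if (nrow(ix) != 1) stop("no unique index pair for ", rs$individual)
    for (r in seq_len(nrow(rs$variants))) {
      full <- paste0(ix$index_f, pf, rs$variants$seq[r],
                     prc, revcomp(ix$index_r))
      n <- rs$variants$count[r]
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_v%d_%d", rs$individual, r, seq_len(n)),
        seq = full, qual = strrep(phred_string(q), nchar(full)))
    }
  }
  write_fastq(do.call(rbind, rows), path)
}

#' Reverse complement (IUPAC-aware)
#' @param x character vector of sequences.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}
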