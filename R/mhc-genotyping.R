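# MHC amplicon genotyping: from reads to a validated allele catalog.

#' Quality-filter amplicon reads
#'
#' Drops reads whose mean Phred score is below `q_threshold`, that contain
#' ambiguous nucleotides (N), or whose length deviates from the expected
#' amplicon length by more than `len_tol` bp.  The Phred rule is interpreted
#' as mean read quality (a per-base Q30 rule would discard nearly all real
#' reads); set `quality_mode = "min"` for the stricter reading.
#'
#' @param reads data.frame with `id`, `seq`, `qual` (Sanger encoding).
#' @param expected_len expected insert/amplicon length in bp.
#' @param q_threshold Phred threshold (default 30).
#' @param len_tol allowed +/- length deviation in bp (default 5).
#' @param quality_mode `"mean"` or `"min"` read quality.
#' @return The surviving rows, with an `accounting` attribute
#'   (input/passed counts).
#' @export
quality_filter <- function(reads, expected_len, q_threshold = 30,
                           len_tol = 5, quality_mode = c("mean", "min")) {
  quality_mode <- match.arg(quality_mode)
  qstat <- vapply(reads$qual, function(q) {
    s <- phred_scores(q)
    if (quality_mode == "mean") mean(s) else min(s)
  }, 0, USE.NAMES = FALSE)
  keep <- qstat >= q_threshold &
    !grepl("N", reads$seq, fixed = TRUE) &
    abs(nchar(reads$seq) - expected_len) <= len_tol
  out <- reads[keep, , drop = FALSE]
  attr(out, "accounting") <- data.frame(stage = "quality_filter",
                                        input = nrow(reads), passed = nrow(out))
  out
}

# best gapless identity between two sequences allowing a small offset range
.gapless_identity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  shifts <- -abs(la - lb):abs(la - lb)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0
  for (s in shifts) {
    ia <- max(1, 1 + s); ib <- max(1, 1 - s)
    len <- min(la - ia + 1, lb - ib + 1)
    if (len <= 0) next
    ident <- sum(av[ia:(ia + len - 1)] == bv[ib:(ib + len - 1)]) / len
    if (ident > best) best <- ident
  }
  best
}

#' Assign reads to loci by mapping against draft references
#'
#' Each read is compared (gapless, small offsets allowed) against every draft
#' sequence and assigned to the locus of its best match when the identity
#' reaches `min_identity`; otherwise it is discarded.
#'
#' @param reads data.frame with `seq` (and any other columns, preserved).
#' @param draft_refs named character vector of draft sequences; names encode
#'   the locus as `"<locus>_<anything>"` or are used verbatim.
#' @param min_identity identity threshold (default 0.85).
#' @return `reads` with an added `locus` column, unmapped reads dropped;
#'   `accounting` attribute records counts.
#' @export
map_to_draft <- function(reads, draft_refs, min_identity = 0.85) {
  loci <- sub("_.*$", "", names(draft_refs))
  hit <- character(nrow(reads)); score <- numeric(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    ids <- vapply(draft_refs, .gapless_identity, 0, a = reads$seq[i])
    j <- which.max(ids)
    hit[i] <- loci[j]; score[i] <- ids[j]
  }
  keep <- score >= min_identity
  out <- reads[keep, , drop = FALSE]
  out$locus <- hit[keep]
  attr(out, "accounting") <- data.frame(stage = "map_to_draft",
                                        input = nrow(reads), passed = nrow(out))
  out
}

# IUPAC-aware mismatch count between equal-length sequences (b may contain
# degenerate codes)
.iupac_table <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                  S = "GC", W = "AT", K = "GT", M = "AC", B = "CGT",
                  D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

iupac_mismatches <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  if (length(av) != length(bv)) return(Inf)
  sum(!vapply(seq_along(av),
              function(i) grepl(av[i], .iupac_table[[bv[i]]], fixed = TRUE),
              TRUE))
}

#' Demultiplex indexed reads and trim adapters/primers
#'
#' Expects merged reads laid out as
#' `[index_f][primer_f][insert][revcomp(primer_r)][revcomp(index_r)]`.
#' Both 8-bp indices must match an index-table row exactly; each primer may
#' carry at most one mismatch, honouring IUPAC degeneracy in the primer.
#' Non-matching reads are dropped and counted.
#'
#' @param reads data.frame with `id`, `seq` (qualities optional).
#' @param index_table data.frame with `individual`, `index_f`, `index_r`
#'   (8 bp each) and optionally `pop`.
#' @param primer_f,primer_r locus primers (IUPAC codes allowed).
#' @param locus locus label for the resulting read sets.
#' @param max_primer_mismatch per-primer mismatch allowance (default 1).
#' @return Named list of [amplicon_read_set()] per individual; attribute
#'   `accounting` records input, index-matched and primer-matched counts.
#' @export
demultiplex_and_trim <- function(reads, index_table, primer_f, primer_r,
                                 locus = "DAB1", max_primer_mismatch = 1) {
  stopifnot(all(nchar(index_table$index_f) == 8),
            all(nchar(index_table$index_r) == 8))
  key <- paste(index_table$index_f, index_table$index_r)
  lp_f <- nchar(primer_f); lp_r <- nchar(primer_r)
  prc <- revcomp(primer_r)
  n_index <- 0L; n_primer <- 0L
  buckets <- list()
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    L <- nchar(s)
    if (L < 16 + lp_f + lp_r + 1) next
    ix_f <- substr(s, 1, 8)
    ix_r <- revcomp(substr(s, L - 7, L))
    hit <- match(paste(ix_f, ix_r), key)
    if (is.na(hit)) next
    n_index <- n_index + 1L
    pf <- substr(s, 9, 8 + lp_f)
    pr <- substr(s, L - 8 - lp_r + 1, L - 8)
    if (iupac_mismatches(pf, primer_f) > max_primer_mismatch) next
    if (iupac_mismatches(pr, prc) > max_primer_mismatch) next
    n_primer <- n_primer + 1L
    insert <- substr(s, 9 + lp_f, L - 8 - lp_r)
    ind <- index_table$individual[hit]
    if (is.null(buckets[[ind]])) buckets[[ind]] <- list()
    buckets[[ind]][[insert]] <- (buckets[[ind]][[insert]] %||% 0L) + 1L
  }
  pops <- if ("pop" %in% names(index_table))
    setNames(index_table$pop, index_table$individual) else NULL
  out <- lapply(names(buckets), function(ind) {
    amplicon_read_set(ind, locus,
                      data.frame(seq = names(buckets[[ind]]),
                                 count = unlist(buckets[[ind]], use.names = FALSE)),
                      pop = if (is.null(pops)) NA_character_ else pops[[ind]])
  })
  names(out) <- names(buckets)
  attr(out, "accounting") <- data.frame(stage = "demultiplex_and_trim",
                                        input = nrow(reads),
                                        index_matched = n_index,
                                        primer_matched = n_primer)
  out
}

#' Validated allele catalog
#'
#' @param locus locus label.
#' @param alleles named character vector of validated allele sequences.
#' @param genotypes data.frame `individual`, `pop`, `allele1`, `allele2`.
#' @return An object of class `allele_catalog` with per-population allele
#'   frequencies (single-allele individuals counted as homozygous).
#' @export
allele_catalog <- function(locus, alleles, genotypes) {
  stopifnot(all(na.omit(c(genotypes$allele1, genotypes$allele2)) %in% names(alleles)))
  freqs <- allele_frequencies(genotypes, names(alleles))
  structure(list(locus = locus, alleles = alleles, genotypes = genotypes,
                 frequencies = freqs),
            class = "allele_catalog")
}

#' @export
print.allele_catalog <- function(x, ...) {
  cat(sprintf("allele_catalog %s: %d alleles, %d genotyped individuals\n",
              x$locus, length(x$alleles), nrow(x$genotypes)))
  invisible(x)
}

#' Per-population allele frequencies from MHC genotypes
#' @param genotypes data.frame `individual`, `pop`, `allele1`, `allele2`.
#' @param allele_names catalog allele names (column order of the result).
#' @param single_allele count single-allele individuals as `"homozygote"`
#'   (two copies) or `"haploid"` (one copy).
#' @return Matrix populations x alleles of frequencies (rows sum to 1).
#' @export
allele_frequencies <- function(genotypes, allele_names,
                               single_allele = c("homozygote", "haploid")) {
  single_allele <- match.arg(single_allele)
  pops <- unique(genotypes$pop)
  F <- matrix(0, length(pops), length(allele_names),
              dimnames = list(pops, allele_names))
  for (i in seq_len(nrow(genotypes))) {
    a1 <- genotypes$allele1[i]; a2 <- genotypes$allele2[i]
    if (is.na(a1) && is.na(a2)) next
    if (is.na(a2)) a2 <- if (single_allele == "homozygote") a1 else NA
    F[genotypes$pop[i], a1] <- F[genotypes$pop[i], a1] + 1
    if (!is.na(a2)) F[genotypes$pop[i], a2] <- F[genotypes$pop[i], a2] + 1
  }
  sw <- rowSums(F)
  F[sw > 0, ] <- F[sw > 0, , drop = FALSE] / sw[sw > 0]
  F
}

#' Validate amplicon variants into an allele catalog
#'
#' Two-stage validation protocol applied per population and locus:
#' \enumerate{
#'   \item within each individual, a variant is retained when it is supported
#'     by more than `min_reads` reads \strong{or} exceeds a within-individual
#'     frequency of `min_freq` (set `rule = "and"` for a stricter sensitivity
#'     analysis);
#'   \item across the population, a retained variant becomes an allele when
#'     it appears in at least two individuals, or in exactly one individual
#'     that also carries another validated allele (the heterozygote
#'     exception).
#' }
#' Per-individual genotypes are the up-to-two highest-count validated
#' variants; individuals with more than two are flagged as putative
#' contamination/paralogy (top two kept, warning logged).
#'
#' @param readsets list of [amplicon_read_set()] objects for one locus (all
#'   populations; grouping uses each read set's `pop`).
#' @param min_reads read-count clause of rule 1 (strictly greater than).
#' @param min_freq within-individual frequency clause of rule 1 (strictly
#'   greater than).
#' @param rule `"or"` (as stated) or `"and"` combination of the two clauses.
#' @param prefix allele naming prefix, e.g. `"Rhps-DAB1"` giving
#'   `Rhps-DAB1*01`, `Rhps-DAB1*02`, ... ordered by total read support.
#' @return An [allele_catalog()]; attribute `depth` holds per-amplicon read
#'   totals.
#' @export
validate_alleles <- function(readsets, min_reads = 1000, min_freq = 0.1,
                             rule = c("or", "and"), prefix = NULL) {
  rule <- match.arg(rule)
  if (!length(readsets)) stop("no read sets supplied")
  locus <- readsets[[1]]$locus
  if (is.null(prefix)) prefix <- paste0("Rhps-", locus)
  pops <- vapply(readsets, function(r) r$pop, "")
  retained <- list()  # per individual: variants surviving rule 1
  for (rs in readsets) {
    v <- rs$variants
    fr <- v$count / rs$total
    keep <- if (rule == "or") v$count > min_reads | fr > min_freq
            else v$count > min_reads & fr > min_freq
    retained[[rs$individual]] <- v[keep, , drop = FALSE]
  }
  validated_seq <- character(0)
  genotype_rows <- list()
  for (p in unique(pops)) {
    ind_p <- names(readsets)[pops == p]
    varlist <- lapply(ind_p, function(i) retained[[i]]$seq)
    names(varlist) <- ind_p
    carriers <- table(unlist(varlist))
    shared <- names(carriers)[carriers >= 2]
    # heterozygote exception: a private variant is rescued when its carrier
    # also holds an independently shared allele
    private_ok <- character(0)
    for (i in ind_p) {
      priv <- setdiff(varlist[[i]], shared)
      if (length(priv) && length(intersect(varlist[[i]], shared)))
        private_ok <- c(private_ok, priv)
    }
    pop_alleles <- union(shared, private_ok)
    validated_seq <- union(validated_seq, pop_alleles)
    for (i in ind_p) {
      v <- retained[[i]]
      v <- v[v$seq %in% pop_alleles, , drop = FALSE]
      if (nrow(v) > 2) {
        consgen_log(sprintf(
          "%s: %d validated variants (putative contamination/paralog); keeping top 2",
          i, nrow(v)), level = "WARN")
        v <- v[order(-v$count), , drop = FALSE][1:2, , drop = FALSE]
      }
      a1 <- if (nrow(v) >= 1) v$seq[1] else NA_character_
      a2 <- if (nrow(v) >= 2) v$seq[2] else NA_character_
      genotype_rows[[length(genotype_rows) + 1L]] <-
        data.frame(individual = i, pop = p, allele1 = a1, allele2 = a2)
    }
  }
  if (!length(validated_seq)) stop("no variants survived validation")
  # name alleles by total read support across all individuals
  support <- vapply(validated_seq, function(s)
    sum(vapply(readsets, function(rs) {
      hit <- match(s, rs$variants$seq)
      if (is.na(hit)) 0 else as.numeric(rs$variants$count[hit])
    }, 0)), 0)
  ord <- order(-support, validated_seq)
  alleles <- setNames(validated_seq[ord],
                      sprintf("%s*%02d", prefix, seq_along(validated_seq)))
  seq2name <- setNames(names(alleles), alleles)
  geno <- do.call(rbind, genotype_rows)
  geno$allele1 <- unname(seq2name[geno$allele1])
  geno$allele2 <- unname(seq2name[geno$allele2])
  # homozygote bookkeeping: one validated variant = two copies of it
  cat <- allele_catalog(locus, alleles, geno)
  attr(cat, "depth") <- vapply(readsets, function(r) as.numeric(r$total), 0)
  cat
}

#' Mean +/- sd summary of per-amplicon read depth
#' @param readsets list of [amplicon_read_set()] (or a validated catalog's
#'   `depth` attribute).
#' @return list with `mean`, `sd`, `range` and a formatted `label` like
#'   `"8569 +/- 5495 (1040-22155)"`.
#' @export
amplicon_depth_summary <- function(readsets) {
  tot <- if (is.numeric(readsets)) readsets
         else vapply(readsets, function(r) as.numeric(r$total), 0)
  list(mean = mean(tot), sd = sd(tot), range = range(tot),
       label = sprintf("%.0f +/- %.0f (%d-%d)", mean(tot), sd(tot),
                       min(tot), max(tot)))
}

#' Assemble a read-accounting ledger across pipeline stages
#' @param ... stage outputs carrying `accounting` attributes.
#' @return data.frame concatenating the accounting rows.
#' @export
read_ledger <- function(...) {
  rows <- lapply(list(...), attr, "accounting")
  do.call(rbind, lapply(rows, function(r) {
    data.frame(stage = r$stage[1], detail = paste(names(r)[-1], unlist(r[1, -1]),
                                                  sep = "=", collapse = "; "))
  }))
}
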