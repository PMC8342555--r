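#' Run configuration with reproducibility guarantees
#'
#' A flat key-value store holding the seed and the iteration/threshold knobs
#' of every stochastic operation.  Fixing the config and the inputs makes all
#' pipeline outputs byte-identical across runs.
#'
#' @param seed integer RNG seed.
#' @param ... overrides of the defaults listed below.
#' @return A named list of class `run_config`.
#' @details Defaults (all Monte-Carlo counts must be >= 1):
#' `hwe_batches` 1000, `hwe_iters` 10000, `hwe_burnin` 10000 (exact-test
#' chain); `fst_permutations` 10000; `ibd_permutations` 9999;
#' `bottleneck_sims` 1000, `bottleneck_max_attempts` 50000; `dnds_bootstrap`
#' 2000; `phi_permutations` 1000; `structure_burnin` 1e5, `structure_iters`
#' 4e5, `structure_runs` 10; `quality_mode` "mean"; `q_threshold` 30;
#' `len_tol` 5; `min_identity` 0.85; `validate_min_reads` 1000,
#' `validate_min_freq` 0.1, `validate_rule` "or"; `single_allele`
#' "homozygote"; `hwe_alpha` 0.05 (per-locus HWE rejection, applied after
#' Bonferroni across loci).
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    hwe_batches = 1000L, hwe_iters = 10000L, hwe_burnin = 10000L,
    fst_permutations = 10000L,
    ibd_permutations = 9999L,
    bottleneck_sims = 1000L, bottleneck_max_attempts = 50000L,
    dnds_bootstrap = 2000L,
    phi_permutations = 1000L,
    structure_burnin = 100000L, structure_iters = 400000L, structure_runs = 10L,
    quality_mode = "mean", q_threshold = 30, len_tol = 5L,
    min_identity = 0.85,
    validate_min_reads = 1000L, validate_min_freq = 0.1, validate_rule = "or",
    single_allele = "homozygote",
    hwe_alpha = 0.05
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  mc <- c("hwe_batches", "hwe_iters", "hwe_burnin", "fst_permutations",
          "ibd_permutations", "bottleneck_sims", "bottleneck_max_attempts",
          "dnds_bootstrap", "phi_permutations", "structure_burnin",
          "structure_iters", "structure_runs")
  bad <- mc[vapply(cfg[mc], function(v) !is.numeric(v) || v < 1, TRUE)]
  if (length(bad)) stop("Monte-Carlo counts must be >= 1: ", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Read a flat key = value config file
#' @param path file path; lines `key = value`, `#` comments allowed.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  vals <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, "", 1)
  do.call(run_config, vals)
}

#' Write a run_config to a flat key = value file
#' @param cfg a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, function(v) format(v, scientific = FALSE), "")),
             path)
  invisible(path)
}

#' Newline-delimited level + timestamp logging
#'
#' @param msg message.
#' @param level one of "INFO", "WARN", "ERROR", "DEBUG".
#' @param file connection or path; defaults to `getOption("consgen.logfile")`
#'   and falls back to stderr.
#' @return The formatted line, invisibly.
#' @export
consgen_log <- function(msg, level = "INFO", file = getOption("consgen.logfile")) {
  line <- sprintf("%s %s %s", level,
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), msg)
  if (is.null(file)) message(line)
  else cat(line, "\n", sep = "", file = file, append = TRUE)
  invisible(line)
}
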