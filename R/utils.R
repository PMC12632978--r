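# Shared constants and small helpers.

STAT_PATHWAYS <- c("pSTAT1", "pSTAT3", "pSTAT4", "pSTAT5", "pSTAT6")
ORIGIN_LEVELS <- c("rosetta", "rfdiffusion", "redesigned_agonist", "prior_work")
FAMILY_LEVELS <- c("cytokine_common", "cytokine_private", "tnf_family",
                   "checkpoint", "growth_factor")
CHAIN_LEVELS <- c("common", "private", "non_cytokine")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Read a tab-separated table
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used for all
#' package tables: UTF-8, tab separation, no factor coercion, `NA` for
#' missing values.
#'
#' @param path file path.
#' @return a `data.frame`.
#' @keywords internal
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA", fileEncoding = "UTF-8")
}

#' @keywords internal
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

# lognormal with a given mean of 1 and coefficient of variation on the
# natural scale; cv = 0 degenerates to exactly 1
rlnorm_cv <- function(n, cv) {
  if (cv < 0) stopf("coefficient of variation must be >= 0, got %g", cv)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# derive a reproducible child seed from a base seed and a stage label,
# kept within 32-bit integer range
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}

path_to_extdata <- function(file) {
  p <- system.file("extdata", file, package = "novoscreen", mustWork = FALSE)
  if (!nzchar(p)) stopf("packaged file '%s' not found", file)
  p
}
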