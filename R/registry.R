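#' Binder registries
#'
#' A binder registry is the catalogue of receptor-binding domains available for
#' fusion-library construction, together with the receptors they target. Each
#' binder targets exactly one receptor subunit; receptors carry a family, a
#' chain class (`common` chains are shared across several natural cytokines,
#' `private` chains confer specificity, `non_cytokine` covers TNF-family,
#' checkpoint and growth-factor receptors) and a canonical pSTAT weight vector
#' used by the synthetic screen generator: private chains dictate the STAT
#' signature of a pairing, common chains act as assembly platforms.
#'
#' The packaged fixture (`default_registry()`) holds the 33-domain set used for
#' full-scale library enumeration: 9 newly designed binders (Rosetta,
#' RFdiffusion, or redesign of an existing agonist) plus 24 previously
#' developed ones. Affinities for the 9 new binders are synthetic placeholders
#' drawn from the plausible 1-200 nM design range (true per-binder values are
#' not tabulated anywhere reusable); prior-work binders carry `NA`.
#'
#' @name binder_registry
NULL

REGISTRY_COLUMNS <- c("binder_id", "target_receptor", "receptor_family",
                      "chain_class", "length_aa", "kd_nM", "origin",
                      "blocks_native_site")

#' Load a binder registry from a TSV file
#'
#' Reads and validates a registry table. The expected dialect is UTF-8,
#' tab-separated, with columns `binder_id, target_receptor, receptor_family,
#' chain_class, length_aa, kd_nM, origin, blocks_native_site` and `NA` for
#' unknown affinities. Canonical pSTAT weights per receptor are taken from a
#' receptor catalog (packaged default: textbook pathway assignments, zero
#' vectors for non-STAT receptors).
#'
#' @param path path to the registry TSV.
#' @param catalog_path path to a receptor catalog TSV (`receptor, family,
#'   chain_class, pSTAT1..pSTAT6`); defaults to the packaged catalog.
#' @return an object of class `binder_registry`: a list with data frames
#'   `binders` and `receptors`.
#' @examples
#' reg <- default_registry()
#' nrow(reg$binders)  # 33
#' count_by_origin(reg)
#' @export
load_registry <- function(path, catalog_path = path_to_extdata("receptor_catalog.tsv")) {
  if (!file.exists(path)) stopf("registry file '%s' does not exist", path)
  tab <- read_tsv(path)
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(tab))
  if (length(missing_cols) > 0)
    stopf("registry load error: missing column(s) %s in '%s'",
          paste(missing_cols, collapse = ", "), path)
  tab <- tab[, REGISTRY_COLUMNS, drop = FALSE]
  catalog <- read_catalog(catalog_path)

  if (nrow(tab) > 0) {
    dup <- tab$binder_id[duplicated(tab$binder_id)]
    if (length(dup) > 0)
      stopf("registry load error: duplicate binder id '%s' (row %d)",
            dup[1], which(tab$binder_id == dup[1])[2])
    for (i in seq_len(nrow(tab))) {
      row <- tab[i, ]
      if (is.na(row$binder_id) || !nzchar(row$binder_id))
        stopf("registry load error: empty binder_id at row %d", i)
      if (grepl("__", row$binder_id, fixed = TRUE))
        stopf("registry load error: binder_id '%s' (row %d) must not contain '__' (reserved construct-id separator)",
              row$binder_id, i)
      if (is.na(row$length_aa) || !is.finite(as.numeric(row$length_aa)) ||
          as.numeric(row$length_aa) <= 0 ||
          as.numeric(row$length_aa) != round(as.numeric(row$length_aa)))
        stopf("registry load error: length_aa must be a positive integer at row %d (binder '%s')",
              i, row$binder_id)
      if (!is.na(row$kd_nM) && !(is.finite(as.numeric(row$kd_nM)) && as.numeric(row$kd_nM) > 0))
        stopf("registry load error: kd_nM must be positive or NA at row %d (binder '%s')",
              i, row$binder_id)
      if (!row$origin %in% ORIGIN_LEVELS)
        stopf("registry load error: unknown origin '%s' at row %d (binder '%s')",
              row$origin, i, row$binder_id)
      if (!row$receptor_family %in% FAMILY_LEVELS)
        stopf("registry load error: unknown receptor_family '%s' at row %d (binder '%s')",
              row$receptor_family, i, row$binder_id)
      if (!row$chain_class %in% CHAIN_LEVELS)
        stopf("registry load error: unknown chain_class '%s' at row %d (binder '%s')",
              row$chain_class, i, row$binder_id)
      if (is.na(row$target_receptor) || !nzchar(row$target_receptor))
        stopf("registry load error: unresolvable target at row %d (binder '%s')",
              i, row$binder_id)
    }
    tab$length_aa <- as.integer(tab$length_aa)
    tab$kd_nM <- as.numeric(tab$kd_nM)
    tab$blocks_native_site <- as.logical(tab$blocks_native_site)
    if (anyNA(tab$blocks_native_site))
      stopf("registry load error: blocks_native_site must be TRUE/FALSE (row %d)",
            which(is.na(tab$blocks_native_site))[1])
    # a target resolves if the catalog knows it, or the registry row itself
    # defines it consistently with every other row naming the same receptor
    for (tr in unique(tab$target_receptor)) {
      rows <- tab[tab$target_receptor == tr, ]
      if (length(unique(rows$receptor_family)) > 1 ||
          length(unique(rows$chain_class)) > 1)
        stopf("registry load error: unresolvable target '%s': rows disagree on family/chain_class", tr)
      if (tr %in% catalog$receptor) {
        crow <- catalog[catalog$receptor == tr, ]
        if (crow$family != rows$receptor_family[1] || crow$chain_class != rows$chain_class[1])
          stopf("registry load error: target '%s' conflicts with receptor catalog (row %d)",
                tr, which(tab$target_receptor == tr)[1])
      }
    }
  } else {
    tab$length_aa <- integer(0)
    tab$kd_nM <- numeric(0)
    tab$blocks_native_site <- logical(0)
  }

  receptors <- build_receptor_table(tab, catalog)
  structure(list(binders = tab, receptors = receptors),
            class = "binder_registry")
}

read_catalog <- function(path) {
  cat_tab <- read_tsv(path)
  needed <- c("receptor", "family", "chain_class", STAT_PATHWAYS)
  missing_cols <- setdiff(needed, names(cat_tab))
  if (length(missing_cols) > 0)
    stopf("receptor catalog missing column(s): %s", paste(missing_cols, collapse = ", "))
  for (p in STAT_PATHWAYS) {
    w <- cat_tab[[p]]
    if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
      stopf("receptor catalog: %s weights must lie in [0,1]", p)
  }
  sums <- rowSums(cat_tab[, STAT_PATHWAYS])
  if (any(sums > 1 + 1e-9))
    stopf("receptor catalog: canonical pSTAT weights of '%s' sum to %.3f > 1",
          cat_tab$receptor[which.max(sums)], max(sums))
  if (anyDuplicated(cat_tab$receptor))
    stopf("receptor catalog: duplicate receptor '%s'",
          cat_tab$receptor[duplicated(cat_tab$receptor)][1])
  cat_tab
}

build_receptor_table <- function(binders, catalog) {
  targets <- unique(binders$target_receptor)
  known <- catalog[catalog$receptor %in% targets, , drop = FALSE]
  new_targets <- setdiff(targets, catalog$receptor)
  if (length(new_targets) > 0) {
    extra <- data.frame(receptor = new_targets, stringsAsFactors = FALSE)
    extra$family <- binders$receptor_family[match(new_targets, binders$target_receptor)]
    extra$chain_class <- binders$chain_class[match(new_targets, binders$target_receptor)]
    for (p in STAT_PATHWAYS) extra[[p]] <- 0
    known <- rbind(known, extra[, names(known)])
  }
  known <- known[order(known$receptor, method = "radix"), , drop = FALSE]
  rownames(known) <- NULL
  known
}

#' Write a registry back to its canonical TSV form
#'
#' The canonical form is sorted by `binder_id` with the dialect's column
#' order; `load_registry()` followed by `write_registry()` is idempotent at
#' the byte level.
#'
#' @param registry a `binder_registry`.
#' @param path output path.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "binder_registry"))
  tab <- registry$binders[, REGISTRY_COLUMNS, drop = FALSE]
  tab <- tab[order(tab$binder_id, method = "radix"), , drop = FALSE]
  write_tsv(tab, path)
}

#' The packaged 33-binder registry
#'
#' @return a `binder_registry` with 33 binders (9 newly designed, 24 prior),
#'   each targeting a distinct receptor.
#' @export
default_registry <- function() {
  load_registry(path_to_extdata("binder_registry.tsv"))
}

#' Count binders by design origin
#'
#' @param registry a `binder_registry`.
#' @return named integer vector over all origin levels (zeros included);
#'   entries always sum to the total binder count.
#' @export
count_by_origin <- function(registry) {
  stopifnot(inherits(registry, "binder_registry"))
  counts <- table(factor(registry$binders$origin, levels = ORIGIN_LEVELS))
  stats::setNames(as.integer(counts), ORIGIN_LEVELS)
}

#' Restrict a registry to a subset of binders
#'
#' @param registry a `binder_registry`.
#' @param binder_ids character vector of binder ids to keep.
#' @export
subset_registry <- function(registry, binder_ids) {
  stopifnot(inherits(registry, "binder_registry"))
  unknown <- setdiff(binder_ids, registry$binders$binder_id)
  if (length(unknown) > 0)
    stopf("unknown binder id(s): %s", paste(unknown, collapse = ", "))
  tab <- registry$binders[registry$binders$binder_id %in% binder_ids, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(binders = tab,
                 receptors = registry$receptors[
                   registry$receptors$receptor %in% tab$target_receptor, ,
                   drop = FALSE]),
            class = "binder_registry")
}

#' Attach amino-acid sequences to registry binders
#'
#' Reads a FASTA file whose headers are binder ids and stores the sequences in
#' the `sequence` column of the binder table, checking that each sequence
#' length matches the registered `length_aa`.
#'
#' @param registry a `binder_registry`.
#' @param fasta_path FASTA file of binder sequences. The packaged
#'   `binder_sequences_synthetic.fasta` holds random placeholder sequences of
#'   the registered lengths (real binder sequences are not redistributable).
#' @export
attach_sequences <- function(registry,
                             fasta_path = path_to_extdata("binder_sequences_synthetic.fasta")) {
  stopifnot(inherits(registry, "binder_registry"))
  seqs <- Biostrings::readAAStringSet(fasta_path)
  idx <- match(registry$binders$binder_id, names(seqs))
  if (anyNA(idx)) {
    miss <- registry$binders$binder_id[is.na(idx)]
    stopf("no sequence for binder(s): %s", paste(miss, collapse = ", "))
  }
  sq <- as.character(seqs[idx])
  bad <- which(nchar(sq) != registry$binders$length_aa)
  if (length(bad) > 0)
    stopf("sequence length of '%s' (%d aa) disagrees with registry length_aa (%d)",
          registry$binders$binder_id[bad[1]], nchar(sq[bad[1]]),
          registry$binders$length_aa[bad[1]])
  registry$binders$sequence <- unname(sq)
  registry
}

#' @export
print.binder_registry <- function(x, ...) {
  cat(sprintf("binder_registry: %d binders targeting %d receptors\n",
              nrow(x$binders), length(unique(x$binders$target_receptor))))
  cnt <- count_by_origin(x)
  cat("  by origin:",
      paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  invisible(x)
}
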