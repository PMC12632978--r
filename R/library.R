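#' Linker specification
#'
#' Flexible linkers are short amino-acid motifs (default `GGS`) repeated a
#' given number of times between the two fused binder domains. Rigid
#' constructs carry no repeat linker: the two domains are joined through a
#' designed rigid scaffold, which this package represents as metadata only
#' (no geometry is modelled).
#'
#' @param unit amino-acid motif, e.g. `"GGS"`.
#' @param repeats non-negative repeat count; ignored when `rigid = TRUE`.
#' @param rigid logical.
#' @return a `linker_spec` list.
#' @examples
#' linker_spec("GGS", 2)   # the "medium" 2xGGS linker used at library scale
#' @export
linker_spec <- function(unit = "GGS", repeats = 2L, rigid = FALSE) {
  if (!is.character(unit) || length(unit) != 1 || !grepl("^[A-Z]*$", unit))
    stopf("linker unit must be an amino-acid motif string")
  repeats <- as.integer(repeats)
  if (is.na(repeats) || repeats < 0) stopf("linker repeats must be >= 0")
  structure(list(unit = unit, repeats = repeats, rigid = isTRUE(rigid)),
            class = "linker_spec")
}

linker_label <- function(linker) {
  if (linker$rigid) "rigid" else sprintf("%dx%s", linker$repeats, linker$unit)
}

linker_sequence <- function(linker) {
  if (linker$rigid) "" else strrep(linker$unit, linker$repeats)
}

MANIFEST_COLUMNS <- c("construct_id", "n_term_binder", "c_term_binder",
                      "linker_unit", "linker_repeats", "rigid",
                      "receptor_a", "receptor_b")

#' Enumerate a fusion-construct library all-by-all
#'
#' Builds every two-domain fusion from the binders of a registry. With
#' `orientations = "ordered_all"` and a single linker the library contains
#' exactly `n^2` constructs for `n` binders: both orientations of each
#' heterotypic pair plus the `n` homotypic fusions (which have a single
#' orientation by symmetry). The 33-binder registry therefore yields the
#' 1,089-construct full library and a 24-binder subset the 576-construct
#' pilot. Ordering is deterministic (lexicographic by N-terminal binder,
#' C-terminal binder, then linker label).
#'
#' @param registry a `binder_registry`.
#' @param linkers a `linker_spec` or list of them; default a single 2xGGS.
#' @param orientations `"ordered_all"` (both orientations) or `"unordered"`
#'   (one construct per unordered binder pair, N-terminal binder the
#'   lexicographically smaller one).
#' @return a manifest `data.frame` with columns `construct_id, n_term_binder,
#'   c_term_binder, linker_unit, linker_repeats, rigid, receptor_a,
#'   receptor_b`. `receptor_a`/`receptor_b` are the (sorted) receptor pair
#'   derived from the binders' targets, never user-set.
#' @examples
#' lib <- enumerate_library(default_registry())
#' nrow(lib)                    # 1089
#' count_unique_pairings(lib)   # 561
#' @export
enumerate_library <- function(registry, linkers = linker_spec(),
                              orientations = c("ordered_all", "unordered")) {
  stopifnot(inherits(registry, "binder_registry"))
  orientations <- match.arg(orientations)
  if (nrow(registry$binders) == 0) stopf("cannot enumerate from an empty registry")
  if (inherits(linkers, "linker_spec")) linkers <- list(linkers)
  if (length(linkers) == 0) stopf("at least one linker spec is required")
  ids <- sort(registry$binders$binder_id, method = "radix")

  grid <- expand.grid(c_term = ids, n_term = ids,
                      stringsAsFactors = FALSE)[, c("n_term", "c_term")]
  if (orientations == "unordered")
    grid <- grid[match(grid$n_term, ids) <= match(grid$c_term, ids), ]

  out <- do.call(rbind, lapply(linkers, function(lk) {
    stopifnot(inherits(lk, "linker_spec"))
    data.frame(
      construct_id = paste(grid$n_term, linker_label(lk), grid$c_term, sep = "__"),
      n_term_binder = grid$n_term,
      c_term_binder = grid$c_term,
      linker_unit = lk$unit,
      linker_repeats = lk$repeats,
      rigid = lk$rigid,
      stringsAsFactors = FALSE)
  }))

  targets <- registry$binders$target_receptor
  names(targets) <- registry$binders$binder_id
  ra <- unname(targets[out$n_term_binder])
  rb <- unname(targets[out$c_term_binder])
  rec_sorted <- sort(unique(c(ra, rb)), method = "radix")
  swap <- match(ra, rec_sorted) > match(rb, rec_sorted)
  out$receptor_a <- ifelse(swap, rb, ra)
  out$receptor_b <- ifelse(swap, ra, rb)

  out <- out[order(out$n_term_binder, out$c_term_binder,
                   paste(out$linker_unit, out$linker_repeats, out$rigid),
                   method = "radix"), ]
  rownames(out) <- NULL
  if (anyDuplicated(out$construct_id))
    stopf("internal error: duplicate construct ids in enumeration")
  out
}

#' Count distinct unordered receptor pairings in a library
#'
#' Homotypic pairings count once; the two orientations of a heterotypic pair
#' are the same pairing. For a full ordered library over `n` binders with
#' distinct targets this is `n(n+1)/2` (561 for 33).
#'
#' @param constructs a manifest from [enumerate_library()].
#' @return integer count.
#' @export
count_unique_pairings <- function(constructs) {
  if (nrow(constructs) == 0) stopf("constructs must be non-empty")
  length(unique(paste(constructs$receptor_a, constructs$receptor_b, sep = "|")))
}

#' Assemble the amino-acid sequence of a fusion construct
#'
#' Grammar: N-terminal binder sequence, then `repeats` copies of the linker
#' unit, then the C-terminal binder sequence.
#'
#' @param construct one manifest row (or a list with the same fields).
#' @param registry a `binder_registry` whose binder table carries a
#'   `sequence` column (see [attach_sequences()]).
#' @return a single amino-acid string.
#' @export
assemble_sequence <- function(construct, registry) {
  stopifnot(inherits(registry, "binder_registry"))
  if (is.null(registry$binders$sequence))
    stopf("registry carries no sequences; call attach_sequences() first")
  b <- registry$binders
  get_seq <- function(id) {
    i <- match(id, b$binder_id)
    if (is.na(i)) stopf("unknown binder id '%s'", id)
    s <- b$sequence[i]
    if (is.na(s) || !nzchar(s)) stopf("missing sequence for binder '%s'", id)
    s
  }
  lk <- linker_spec(construct$linker_unit, construct$linker_repeats,
                    construct$rigid)
  paste0(get_seq(construct$n_term_binder), linker_sequence(lk),
         get_seq(construct$c_term_binder))
}

#' Write a library as FASTA plus manifest
#'
#' FASTA headers equal the construct ids; the manifest is the TSV form of the
#' enumeration table (one row per construct). Both files are deterministic
#' functions of the library, so re-running an enumeration reproduces them
#' byte-identically.
#'
#' @param constructs manifest `data.frame`.
#' @param registry registry with sequences attached.
#' @param fasta_path,manifest_path output paths.
#' @export
write_library <- function(constructs, registry, fasta_path, manifest_path) {
  seqs <- vapply(seq_len(nrow(constructs)), function(i)
    assemble_sequence(constructs[i, ], registry), character(1))
  aas <- Biostrings::AAStringSet(stats::setNames(seqs, constructs$construct_id))
  Biostrings::writeXStringSet(aas, fasta_path, width = 60L)
  write_tsv(constructs[, MANIFEST_COLUMNS, drop = FALSE], manifest_path)
  invisible(list(fasta = fasta_path, manifest = manifest_path))
}

#' Read a library manifest written by [write_library()] or [run_pipeline()]
#' @param path manifest TSV path.
#' @export
read_manifest <- function(path) {
  tab <- read_tsv(path)
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(tab))
  if (length(missing_cols) > 0)
    stopf("manifest missing column(s): %s", paste(missing_cols, collapse = ", "))
  tab
}
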