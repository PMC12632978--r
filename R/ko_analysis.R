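#' Receptor-knockout dependence test
#'
#' Tests whether a construct's signaling requires each of its two targeted
#' receptor subunits, mirroring the knockout validation logic: the construct
#' is assayed in a cell context where it signals (wild type), then re-assayed
#' with each targeted receptor knocked out; a receptor is required when the
#' signaling call is lost under its knockout, and the construct is
#' dual-dependent when both are. The wild-type experiment must yield a
#' positive call -- knockouts are only interpretable where the parental line
#' signals as expected -- otherwise the verdict is undefined and an error is
#' raised.
#'
#' The simulated experiment is a targeted validation rather than a
#' library-scale screen: each donor contributes three stimulated replicates
#' alongside the three unstimulated controls, a donor is positive when the
#' majority of its replicates pass the mean + k x SEM call on the construct's
#' measured pathways, and positivity must be reproducible in at least
#' `min_donors` donors.
#'
#' @param construct one manifest row.
#' @param truth ground truth covering the construct.
#' @param registry a `binder_registry`.
#' @param panel a `cell_panel` containing `cell_type`.
#' @param cell_type assay cell line (default `"U937_like"`, an engineered
#'   line expressing every receptor).
#' @param k SEM multiplier for the signaling call (default 6).
#' @param min_donors donor-reproducibility threshold (default 2).
#' @param n_donors number of donors simulated (default 3).
#' @param noise_cv well noise (default 0.15).
#' @param seed integer seed.
#' @return an object of class `dependence_verdict`: list with
#'   `construct_id`, `receptor_a`, `receptor_b`, `a_required`, `b_required`,
#'   `dual_dependent`.
#' @export
knockout_test <- function(construct, truth, registry, panel,
                          cell_type = "U937_like", k = 6, min_donors = 2,
                          n_donors = 3, noise_cv = 0.15, seed = 1) {
  stopifnot(inherits(panel, "cell_panel"))
  if (!cell_type %in% rownames(panel$density))
    stopf("cell type '%s' not in panel", cell_type)

  assay_call <- function(pnl, label, seed_label) {
    donors <- donor_profiles(n_donors, colnames(pnl$density),
                             noise_cv = noise_cv,
                             seed = derive_seed(seed, "ko-donors"))
    plan <- screen_plan(n_stim_reps = 3, include_single_binder = FALSE,
                        condition_label = label,
                        seed = derive_seed(seed, seed_label))
    one_cell <- pnl
    one_cell$density <- pnl$density[cell_type, , drop = FALSE]
    tab <- generate_screen(construct, truth, registry, one_cell, donors, plan)
    hits <- call_hits(tab, k = k, min_donors = min_donors)
    hits <- hits[hits$construct_id == construct$construct_id, , drop = FALSE]
    any(hits$reproducible)
  }

  wt_positive <- assay_call(panel, "stimulated", "ko-wt")
  if (!wt_positive)
    stopf(paste("wild-type condition for '%s' is not a signaling call;",
                "knockout dependence is undefined (knockouts require a",
                "signaling parental line)"), construct$construct_id)

  ra <- construct$receptor_a
  rb <- construct$receptor_b
  a_req <- !assay_call(apply_knockout(panel, cell_type, ra),
                       paste0("knockout:", ra), paste0("ko-", ra))
  b_req <- if (rb == ra) a_req else
    !assay_call(apply_knockout(panel, cell_type, rb),
                paste0("knockout:", rb), paste0("ko-", rb))

  structure(list(construct_id = construct$construct_id,
                 receptor_a = ra, receptor_b = rb,
                 a_required = a_req, b_required = b_req,
                 dual_dependent = a_req && b_req),
            class = "dependence_verdict")
}

#' @export
print.dependence_verdict <- function(x, ...) {
  cat(sprintf("%s: %s %s, %s %s -> %s\n", x$construct_id,
              x$receptor_a, if (x$a_required) "required" else "dispensable",
              x$receptor_b, if (x$b_required) "required" else "dispensable",
              if (x$dual_dependent) "dual-dependent" else "not dual-dependent"))
  invisible(x)
}

#' Batch knockout testing
#'
#' Applies [knockout_test()] to a set of constructs and summarizes how many
#' are dual-dependent. Per-construct errors (e.g. a wild type that does not
#' signal) propagate.
#'
#' @param constructs manifest rows.
#' @param ... passed to [knockout_test()].
#' @return `data.frame` with columns `construct_id, receptor_a, a_required,
#'   receptor_b, b_required, dual_dependent`, with attribute
#'   `n_dual_dependent`.
#' @export
batch_ko <- function(constructs, ...) {
  rows <- lapply(seq_len(nrow(constructs)), function(i) {
    v <- knockout_test(constructs[i, ], ...)
    data.frame(construct_id = v$construct_id,
               receptor_a = v$receptor_a, a_required = v$a_required,
               receptor_b = v$receptor_b, b_required = v$b_required,
               dual_dependent = v$dual_dependent, stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(construct_id = character(0), receptor_a = character(0),
               a_required = logical(0), receptor_b = character(0),
               b_required = logical(0), dual_dependent = logical(0))
  attr(out, "n_dual_dependent") <- sum(out$dual_dependent)
  out
}
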