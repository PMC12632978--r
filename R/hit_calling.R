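#' Per-stratum 0-1 normalization of screen intensities
#'
#' Signaling is normalized per donor, cell type and pathway on a 0-1 scale:
#' within each stratum, `score = (x - min) / (max - min)` over all
#' conditions including the unstimulated controls, so the stratum minimum
#' maps to 0 and the maximum to 1. Following standard flow-cytometry
#' practice, intensities are log-transformed before normalization (fold
#' changes, not absolute differences, are the meaningful signal in
#' fluorescence data, and multiplicative well noise is symmetric on the log
#' scale); set `transform = "identity"` to normalize raw intensities. The
#' downstream call statistic is invariant to any affine rescaling of the
#' (transformed) intensities within a stratum. Degenerate (constant) strata
#' get all-zero scores with a warning.
#'
#' @param table a screen table (long format, `mfi` column, all values > 0).
#' @param transform `"log"` (default) or `"identity"`.
#' @return the table with a `normalized_score` column.
#' @export
normalize_01 <- function(table, transform = c("log", "identity")) {
  stopifnot(all(c("donor_id", "cell_type", "pathway", "mfi") %in% names(table)))
  transform <- match.arg(transform)
  if (any(table$mfi <= 0)) stopf("intensities must be > 0")
  x <- if (transform == "log") log(table$mfi) else table$mfi
  key <- interaction(table$donor_id, table$cell_type, table$pathway, drop = TRUE)
  lo <- stats::ave(x, key, FUN = min)
  hi <- stats::ave(x, key, FUN = max)
  rng <- hi - lo
  if (any(rng == 0)) {
    warnf("%d stratum/strata with constant intensities; scores set to 0",
          length(unique(key[rng == 0])))
    rng[rng == 0] <- 1
  }
  table$normalized_score <- (x - lo) / rng
  table
}

#' Unstimulated-control summary statistics per stratum
#'
#' Mean and standard error of the mean of the normalized unstimulated-control
#' scores in each donor x cell type x pathway stratum (the screen uses three
#' control replicates). The SEM uses the sample standard deviation (`n - 1`
#' denominator) and is floored at a fraction of the normalized stratum range
#' (which is 1 by construction). The floor matters: with only three
#' replicates the sample SEM occasionally collapses by chance, and a
#' `mean + k x SEM` rule then calls every condition in the stratum a hit.
#' Flooring the SEM at 0.025 normalized units turns the rule into
#' "exceed the controls by at least `k x SEM`, and in any case by at least
#' `0.025 k` of the stratum range" -- a conventional minimal-effect
#' requirement that leaves real responses (which clear 0.3-0.5 normalized
#' units) untouched.
#'
#' @param table normalized screen table (see [normalize_01()]).
#' @param sem_floor lower bound on the SEM in normalized units
#'   (default `0.025`).
#' @return `data.frame` with `donor_id, cell_type, pathway, mean, sem, n`.
#' @export
control_stats <- function(table, sem_floor = 0.025) {
  stopifnot("normalized_score" %in% names(table))
  ctrl <- table[table$condition == "unstimulated_control", , drop = FALSE]
  if (nrow(ctrl) == 0) stopf("no unstimulated_control records in table")
  key <- paste(ctrl$donor_id, ctrl$cell_type, ctrl$pathway, sep = "\r")
  agg <- function(f) tapply(ctrl$normalized_score, key, f)
  m <- agg(mean); s <- agg(stats::sd); n <- agg(length)
  if (any(n < 2)) stopf("control SEM undefined: stratum with fewer than 2 controls")
  parts <- do.call(rbind, strsplit(names(m), "\r", fixed = TRUE))
  data.frame(donor_id = parts[, 1], cell_type = parts[, 2], pathway = parts[, 3],
             mean = as.numeric(m),
             sem = pmax(as.numeric(s) / sqrt(as.numeric(n)), sem_floor),
             n = as.integer(n), stringsAsFactors = FALSE)
}

#' The mean + k x SEM signaling call
#'
#' A condition is called signaling when its normalized score exceeds the
#' unstimulated-control mean by more than `k` standard errors (default
#' `k = 6`). With three Gaussian controls this rule has a closed-form
#' per-test false-positive rate: the statistic reduces to a t with 2 degrees
#' of freedom at threshold `k / 2`, i.e. `P(t_2 > 3) ~= 0.0477` at the
#' default.
#'
#' @param score normalized score(s) of the tested condition(s).
#' @param control control statistics: a row (or aligned rows) with `mean`,
#'   `sem` and `n` as returned by [control_stats()].
#' @param k SEM multiplier (default 6).
#' @return logical vector.
#' @export
call_signal <- function(score, control, k = 6) {
  if (any(control$n < 2)) stopf("SEM undefined for n < 2 controls")
  if (any(control$sem < 0)) stopf("sem must be >= 0")
  score > control$mean + k * control$sem
}

#' Adaptive SEM cutoff for weak-response strata
#'
#' In strata where the natural-cytokine positive controls respond only
#' weakly, the SEM cutoff is escalated to keep noise from being classified
#' as signal: `k` stays at `k_base` when the positive-control effect (best
#' positive-control score minus control mean) reaches `theta`, and is
#' `k_base * gamma` otherwise. The returned cutoff never decreases as the
#' positive-control effect shrinks.
#'
#' @param control one stratum's control statistics row.
#' @param positive_control_scores normalized scores of the stratum's natural
#'   cytokine (positive control) conditions; may be empty.
#' @param k_base base multiplier (default 6).
#' @param theta minimal positive-control effect in normalized units
#'   (default 0.2).
#' @param gamma escalation factor (default 1.5).
#' @return the cutoff `k` for that stratum.
#' @export
adaptive_cutoff <- function(control, positive_control_scores, k_base = 6,
                            theta = 0.2, gamma = 1.5) {
  if (gamma < 1) stopf("gamma must be >= 1")
  if (length(positive_control_scores) == 0) {
    warnf("no positive controls in stratum; using k_base")
    return(k_base)
  }
  effect <- max(positive_control_scores) - control$mean
  if (effect >= theta) k_base else k_base * gamma
}

#' Donor reproducibility gate
#'
#' A construct x pathway x cell type result is reproducible when it is called
#' signaling in at least `min_donors` of the screened donors (default 2 of
#' 3).
#'
#' @param calls logical vector of per-donor calls.
#' @param min_donors minimum number of positive donors (default 2).
#' @return single logical.
#' @export
reproducibility <- function(calls, min_donors = 2) {
  sum(calls) >= min_donors
}

#' Call hits across a screen table
#'
#' Runs the full hit-calling chain: 0-1 normalization per donor x cell type x
#' pathway stratum, control statistics from the unstimulated replicates, the
#' mean + k x SEM call per condition and donor, and the donor-reproducibility
#' gate. Single-binder control records are scored like constructs (they carry
#' condition `single_binder_control` and `SB__` ids) but are excluded from
#' activation-rate summaries.
#'
#' @param screen long-format screen table from [generate_screen()] or read
#'   from TSV.
#' @param k SEM multiplier (default 6). Ignored when `adaptive = TRUE` and
#'   positive controls are present.
#' @param min_donors donor-reproducibility threshold (default 2).
#' @param sem_floor see [control_stats()].
#' @param adaptive use [adaptive_cutoff()] per stratum, based on records with
#'   condition `positive_control` (default `FALSE`).
#' @param theta,gamma adaptive-cutoff parameters.
#' @param p_adjust optional multiple-testing mode: `"none"` (default,
#'   matching the plain 6xSEM + reproducibility gate) or `"BH"`, which
#'   additionally requires a Benjamini-Hochberg-adjusted one-sided t p-value
#'   below 0.05 per donor call.
#' @param transform analysis scale passed to [normalize_01()].
#' @return a hit table: one row per construct x cell type x pathway with
#'   `donor_calls` (comma-separated), `n_donors_positive`, `n_donors`,
#'   `reproducible`, `mean_score` and `condition`.
#' @export
call_hits <- function(screen, k = 6, min_donors = 2, sem_floor = 0.025,
                      adaptive = FALSE, theta = 0.2, gamma = 1.5,
                      p_adjust = c("none", "BH"),
                      transform = c("log", "identity")) {
  p_adjust <- match.arg(p_adjust)
  norm <- normalize_01(screen, transform = transform)
  ctrl <- control_stats(norm, sem_floor = sem_floor)

  test <- norm[!norm$condition %in% c("unstimulated_control", "positive_control"), ,
               drop = FALSE]
  si <- match(paste(test$donor_id, test$cell_type, test$pathway),
              paste(ctrl$donor_id, ctrl$cell_type, ctrl$pathway))
  if (anyNA(si)) stopf("stratum without controls encountered")

  k_use <- rep(k, nrow(ctrl))
  if (isTRUE(adaptive)) {
    pos <- norm[norm$condition == "positive_control", , drop = FALSE]
    pkey <- paste(pos$donor_id, pos$cell_type, pos$pathway)
    ckey <- paste(ctrl$donor_id, ctrl$cell_type, ctrl$pathway)
    for (j in seq_len(nrow(ctrl))) {
      k_use[j] <- adaptive_cutoff(ctrl[j, ], pos$normalized_score[pkey == ckey[j]],
                                  k_base = k, theta = theta, gamma = gamma)
    }
  }

  called <- call_signal(test$normalized_score, ctrl[si, ], k = k_use[si])
  if (p_adjust == "BH") {
    tstat <- (test$normalized_score - ctrl$mean[si]) /
      (ctrl$sem[si] * sqrt(ctrl$n[si] + 1))
    pval <- stats::pt(tstat, df = ctrl$n[si] - 1, lower.tail = FALSE)
    called <- called & stats::p.adjust(pval, method = "BH") < 0.05
  }

  # aggregate replicates within donor (majority rule), then across donors
  dkey <- paste(test$construct_id, test$cell_type, test$pathway, test$donor_id,
                sep = "\r")
  donor_pos <- tapply(called, dkey, function(z) mean(z) > 0.5)
  donor_score <- tapply(test$normalized_score, dkey, mean)
  dparts <- do.call(rbind, strsplit(names(donor_pos), "\r", fixed = TRUE))
  ddf <- data.frame(construct_id = dparts[, 1], cell_type = dparts[, 2],
                    pathway = dparts[, 3], donor_id = dparts[, 4],
                    call = as.logical(donor_pos),
                    score = as.numeric(donor_score), stringsAsFactors = FALSE)
  ddf <- ddf[order(ddf$construct_id, ddf$cell_type, ddf$pathway, ddf$donor_id,
              method = "radix"), ]

  gkey <- paste(ddf$construct_id, ddf$cell_type, ddf$pathway, sep = "\r")
  first <- !duplicated(gkey)
  n_pos <- tapply(ddf$call, gkey, sum)
  n_don <- tapply(ddf$call, gkey, length)
  calls_str <- tapply(ddf$call, gkey, function(z) paste(ifelse(z, "T", "F"),
                                                        collapse = ","))
  mscore <- tapply(ddf$score, gkey, mean)
  ord <- unique(gkey)
  cond <- test$condition[match(ord, paste(test$construct_id, test$cell_type,
                                          test$pathway, sep = "\r"))]
  parts <- do.call(rbind, strsplit(ord, "\r", fixed = TRUE))
  hits <- data.frame(construct_id = parts[, 1], cell_type = parts[, 2],
                     pathway = parts[, 3],
                     donor_calls = as.character(calls_str[ord]),
                     n_donors_positive = as.integer(n_pos[ord]),
                     n_donors = as.integer(n_don[ord]),
                     reproducible = as.integer(n_pos[ord]) >= min_donors,
                     mean_score = as.numeric(mscore[ord]),
                     condition = cond, stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  hits
}

#' Per-receptor activation rate
#'
#' Fraction of screened constructs involving each receptor that produced at
#' least one reproducible hit (any cell type or pathway). Single-binder
#' control rows never count. Receptors with no constructs are absent from
#' the result.
#'
#' @param hit_table result of [call_hits()].
#' @param manifest the library manifest (provides each construct's receptor
#'   pair).
#' @return named numeric vector of rates in `[0, 1]`.
#' @export
activation_rate_by_receptor <- function(hit_table, manifest) {
  ht <- hit_table[hit_table$condition != "single_binder_control" &
                    !startsWith(hit_table$construct_id, "SB__"), , drop = FALSE]
  hit_constructs <- unique(ht$construct_id[ht$reproducible])
  receptors <- sort(unique(c(manifest$receptor_a, manifest$receptor_b)),
                    method = "radix")
  rates <- vapply(receptors, function(r) {
    involved <- manifest$construct_id[manifest$receptor_a == r |
                                        manifest$receptor_b == r]
    if (length(involved) == 0) return(NA_real_)
    mean(involved %in% hit_constructs)
  }, numeric(1))
  rates[!is.na(rates)]
}
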