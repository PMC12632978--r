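#' Cell panels
#'
#' A cell panel maps each cell population to receptor surface densities
#' (copies/cell) and a baseline fluorescence level per pathway. The packaged
#' default emulates the six PBMC populations typically resolved in
#' phospho-flow (CD4 and CD8 T cells, NK, B, monocytes, DCs) with common
#' cytokine chains broadly expressed and private chains restricted to their
#' physiological lineages; a `U937_like` engineered line expressing every
#' registered receptor is included for targeted knockout experiments.
#' Densities are round-number literature-scale placeholders encoding the
#' specificity logic (who expresses what), not measured copy numbers.
#'
#' @param path panel TSV with columns `cell_type, receptor, density`
#'   (unlisted combinations are zero).
#' @param baseline_mfi positive baseline fluorescence used for every
#'   cell type and pathway (default 100).
#' @return a `cell_panel`: list with `density` (cell x receptor matrix) and
#'   `baseline_mfi`.
#' @export
load_cell_panel <- function(path, baseline_mfi = 100) {
  if (baseline_mfi <= 0) stopf("baseline_mfi must be > 0")
  tab <- read_tsv(path)
  needed <- c("cell_type", "receptor", "density")
  if (length(setdiff(needed, names(tab))) > 0)
    stopf("cell panel file must have columns %s", paste(needed, collapse = ", "))
  if (any(tab$density < 0)) stopf("receptor densities must be >= 0")
  cells <- unique(tab$cell_type)
  receptors <- sort(unique(tab$receptor), method = "radix")
  dens <- matrix(0, length(cells), length(receptors),
                 dimnames = list(cells, receptors))
  dens[cbind(tab$cell_type, tab$receptor)] <- tab$density
  structure(list(density = dens, baseline_mfi = baseline_mfi),
            class = "cell_panel")
}

#' @describeIn load_cell_panel the packaged PBMC panel; set
#'   `include_u937 = TRUE` to keep the engineered all-receptor line.
#' @param include_u937 keep the `U937_like` entry (default `FALSE`: the
#'   primary-cell screen does not include it).
#' @export
default_cell_panel <- function(include_u937 = FALSE, baseline_mfi = 100) {
  panel <- load_cell_panel(path_to_extdata("cell_panel.tsv"), baseline_mfi)
  if (!include_u937)
    panel$density <- panel$density[rownames(panel$density) != "U937_like", ,
                                   drop = FALSE]
  panel
}

#' Knock out one receptor in one cell type
#'
#' Returns the panel with the receptor's surface density set to zero in the
#' given cell type; a strict intervention on the generative model, so any
#' signal requiring that receptor vanishes. Idempotent.
#'
#' @param panel a `cell_panel`.
#' @param cell_type cell population name.
#' @param receptor receptor name; must be present in the panel's density map.
#' @export
apply_knockout <- function(panel, cell_type, receptor) {
  stopifnot(inherits(panel, "cell_panel"))
  if (!cell_type %in% rownames(panel$density))
    stopf("unknown cell type '%s'", cell_type)
  if (!receptor %in% colnames(panel$density))
    stopf("unknown receptor '%s'", receptor)
  panel$density[cell_type, receptor] <- 0
  panel
}

#' Donor profiles
#'
#' Human donors differ in receptor expression and assay noise; the generator
#' models this with per-donor, per-receptor lognormal multipliers on surface
#' density and a per-donor multiplicative noise CV applied at well level.
#'
#' @param n_donors number of donors (default 3, matching the reproducibility
#'   gate's denominator).
#' @param receptors receptor names the multipliers cover.
#' @param noise_cv well-level multiplicative noise CV (default 0.15).
#' @param density_sdlog sdlog of the donor density multipliers (default 0.3).
#' @param seed integer seed.
#' @return a `donor_profiles`: list with `donor_id`, `multipliers`
#'   (donor x receptor matrix), `noise_cv`.
#' @export
donor_profiles <- function(n_donors = 3, receptors, noise_cv = 0.15,
                           density_sdlog = 0.3, seed = 1) {
  if (n_donors < 1) stopf("need at least one donor")
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  set.seed(derive_seed(seed, "donors"))
  ids <- sprintf("donor%02d", seq_len(n_donors))
  mult <- matrix(stats::rlnorm(n_donors * length(receptors),
                               meanlog = -density_sdlog^2 / 2,
                               sdlog = density_sdlog),
                 n_donors, length(receptors),
                 dimnames = list(ids, receptors))
  structure(list(donor_id = ids, multipliers = mult, noise_cv = noise_cv),
            class = "donor_profiles")
}

#' Plant ground-truth mechanisms for a construct library
#'
#' Assigns each construct a mechanism (`ternary`, `clustering`, `inactive`),
#' an efficacy, and a pSTAT weight profile. Only constructs that could in
#' principle be detected are eligible for an active mechanism: their dominant
#' pSTAT output must lie on a measured pathway and the receptor pair must be
#' co-expressed in at least one panel cell type.
#' Eligible constructs are planted active at a per-receptor rate: the
#' governing rate of a construct is the maximum rate over its two receptors.
#' Defaults mirror the screening outcome the generator is meant to emulate:
#' gamma-common pairings are the most productive (42%), a set of other
#' productive receptors sits near 20%, and everything else is rare; active
#' constructs are ternary vs clustering in the 14:4 ratio seen in
#' dose-response triage. Counts are planted exactly (rounded), with seeded
#' sampling deciding which constructs get them.
#'
#' @param constructs manifest from [enumerate_library()].
#' @param registry a `binder_registry`.
#' @param panel a `cell_panel` (used for the co-expression gate).
#' @param pathways measured pathways (default the 4-plex screen panel
#'   `pSTAT1/3/5/6`).
#' @param p_active named per-receptor activation rates; must contain a
#'   `.default` entry.
#' @param clustering_fraction fraction of actives planted as clustering
#'   (default 4/18).
#' @param efficacy_meanlog,efficacy_sdlog lognormal efficacy parameters for
#'   active constructs (default median 3).
#' @param lambda pSTAT5 leak passed to [stat_profile()].
#' @param seed integer seed.
#' @return `data.frame` with columns `construct_id, mechanism, efficacy,
#'   cluster_receptor` and one weight column per pathway (`w_pSTAT1`, ...).
#' @export
make_ground_truth <- function(constructs, registry, panel,
                              pathways = c("pSTAT1", "pSTAT3", "pSTAT5", "pSTAT6"),
                              p_active = c(gcommon = 0.42,
                                           gp130 = 0.2, IL7Ra = 0.2, IL10Ra = 0.2,
                                           IL21Ra = 0.2, bcommon = 0.2, TrkA = 0.2,
                                           IFNAR1 = 0.2, .default = 0.02),
                              clustering_fraction = 4 / 18,
                              efficacy_meanlog = log(3), efficacy_sdlog = 0.5,
                              lambda = 0.15, seed = 1) {
  stopifnot(inherits(registry, "binder_registry"), inherits(panel, "cell_panel"))
  if (!".default" %in% names(p_active))
    stopf("p_active must contain a '.default' entry")
  set.seed(derive_seed(seed, "truth"))
  n <- nrow(constructs)

  prof <- t(vapply(seq_len(n), function(i)
    stat_profile(constructs[i, ], registry, lambda = lambda),
    numeric(length(STAT_PATHWAYS))))
  colnames(prof) <- STAT_PATHWAYS

  dens <- panel$density
  coexpr <- vapply(seq_len(n), function(i) {
    ra <- constructs$receptor_a[i]; rb <- constructs$receptor_b[i]
    if (!ra %in% colnames(dens) || !rb %in% colnames(dens)) return(FALSE)
    any(dens[, ra] > 0 & dens[, rb] > 0)
  }, logical(1))
  # detectable: the construct's principal output must be on a measured
  # pathway (a pairing read out only through the small pSTAT5 leak, e.g. a
  # pSTAT4-dominant pairing under a 4-plex panel, is not screenable)
  max_meas <- apply(prof[, pathways, drop = FALSE], 1, max)
  detectable <- max_meas > 0 &
    max_meas >= apply(prof, 1, max) - 1e-9
  eligible <- coexpr & detectable

  rate_of <- function(r) {
    v <- p_active[r]
    ifelse(is.na(v), p_active[[".default"]], v)
  }
  rate <- pmax(rate_of(constructs$receptor_a), rate_of(constructs$receptor_b))
  rate[!eligible] <- 0

  mechanism <- rep("inactive", n)
  for (r in sort(unique(rate[rate > 0]))) {
    grp <- which(rate == r)
    n_active <- round(r * length(grp))
    if (n_active > 0) {
      chosen <- grp[sample.int(length(grp), n_active)]
      n_clust <- round(clustering_fraction * n_active)
      clust <- if (n_clust > 0) chosen[sample.int(n_active, n_clust)] else integer(0)
      mechanism[chosen] <- "ternary"
      mechanism[clust] <- "clustering"
    }
  }

  efficacy <- numeric(n)
  active <- mechanism != "inactive"
  efficacy[active] <- stats::rlnorm(sum(active), efficacy_meanlog, efficacy_sdlog)

  # clustering engages only the self-associating domain's receptor; of the
  # two arms, the signaling-competent one (larger canonical pSTAT weight,
  # N-terminal on ties) is the one whose aggregation can produce a readout
  cluster_receptor <- rep(NA_character_, n)
  targets <- registry$binders$target_receptor
  names(targets) <- registry$binders$binder_id
  is_cl <- mechanism == "clustering"
  rec <- registry$receptors
  max_w <- apply(as.matrix(rec[, STAT_PATHWAYS]), 1, max)
  names(max_w) <- rec$receptor
  t_n <- unname(targets[constructs$n_term_binder[is_cl]])
  t_c <- unname(targets[constructs$c_term_binder[is_cl]])
  cluster_receptor[is_cl] <- ifelse(max_w[t_c] > max_w[t_n], t_c, t_n)
  for (i in which(is_cl)) {
    pseudo <- constructs[i, ]
    pseudo$receptor_a <- cluster_receptor[i]
    pseudo$receptor_b <- cluster_receptor[i]
    prof[i, ] <- stat_profile(pseudo, registry, lambda = lambda)
  }

  out <- data.frame(construct_id = constructs$construct_id,
                    mechanism = mechanism, efficacy = efficacy,
                    cluster_receptor = cluster_receptor,
                    stringsAsFactors = FALSE)
  for (p in STAT_PATHWAYS) out[[paste0("w_", p)]] <- prof[, p]
  out
}

#' Screen plan
#'
#' Bundles the acquisition settings of a simulated screen: single-point dose
#' (250 nM by default, the screening stimulation), three unstimulated control
#' replicates per donor x cell type x pathway stratum, the measured pathway
#' panel, and the seed.
#'
#' @param dose_nM stimulation dose (default 250).
#' @param n_control_reps unstimulated control replicates per stratum
#'   (default 3).
#' @param n_stim_reps stimulated replicates per construct (default 1, as in
#'   a library-scale screen; targeted validation uses 3).
#' @param pathways measured pSTAT panel.
#' @param include_single_binder emit one inactive record per registry binder
#'   (`SB__<binder_id>`, condition `single_binder_control`).
#' @param condition_label condition tag for stimulated records (the knockout
#'   machinery relabels these `knockout:<receptor>`).
#' @param avidity_alpha,k_half ternary model constants.
#' @param seed integer seed.
#' @export
screen_plan <- function(dose_nM = 250, n_control_reps = 3, n_stim_reps = 1,
                        pathways = c("pSTAT1", "pSTAT3", "pSTAT5", "pSTAT6"),
                        include_single_binder = TRUE,
                        condition_label = "stimulated",
                        avidity_alpha = 1, k_half = 50, seed = 1) {
  if (n_control_reps < 2) stopf("need >= 2 control replicates to form an SEM")
  stopifnot(all(pathways %in% STAT_PATHWAYS))
  structure(list(dose_nM = dose_nM, n_control_reps = n_control_reps,
                 n_stim_reps = n_stim_reps, pathways = pathways,
                 include_single_binder = include_single_binder,
                 condition_label = condition_label,
                 avidity_alpha = avidity_alpha, k_half = k_half, seed = seed),
            class = "screen_plan")
}

binder_kd <- function(registry, binder_ids, default_kd = 50) {
  kd <- registry$binders$kd_nM[match(binder_ids, registry$binders$binder_id)]
  kd[is.na(kd)] <- default_kd
  kd
}

mechanism_signal <- function(truth_row, dose, kd1, kd2, d1, d2,
                             engaged_first, plan) {
  switch(truth_row$mechanism,
    ternary = ternary_signal(dose, kd1, kd2, d1, d2,
                             avidity_alpha = plan$avidity_alpha,
                             emax = truth_row$efficacy, k_half = plan$k_half),
    clustering = clustering_signal(dose,
                                   if (engaged_first) kd1 else kd2,
                                   if (engaged_first) d1 else d2,
                                   slope = truth_row$efficacy),
    inactive = rep(0, length(dose)),
    stopf("unknown mechanism '%s'", truth_row$mechanism))
}

#' Generate a synthetic phospho-flow screen table
#'
#' Produces long-format well-level measurements with the structure the
#' hit-calling stage assumes: for every donor x cell type x pathway stratum,
#' `n_control_reps` unstimulated control wells at baseline, one stimulated
#' record per construct with
#' `mfi = baseline * (1 + signal * stat_weight) * noise`, and (optionally)
#' inactive single-binder control records. Signal comes from the construct's
#' planted mechanism evaluated at the plan dose with donor-scaled receptor
#' densities; noise is multiplicative lognormal at well level. Fully
#' reproducible for a given plan seed.
#'
#' @param constructs manifest rows to screen.
#' @param truth ground truth from [make_ground_truth()]; must cover every
#'   construct.
#' @param registry a `binder_registry` (affinity lookup and single-binder
#'   controls).
#' @param panel a `cell_panel`.
#' @param donors a `donor_profiles`.
#' @param plan a `screen_plan`.
#' @return `data.frame` with columns `construct_id, donor_id, cell_type,
#'   pathway, dose_nM, replicate, condition, mfi`.
#' @export
generate_screen <- function(constructs, truth, registry, panel, donors, plan) {
  stopifnot(inherits(registry, "binder_registry"),
            inherits(panel, "cell_panel"),
            inherits(donors, "donor_profiles"),
            inherits(plan, "screen_plan"))
  missing_truth <- setdiff(constructs$construct_id, truth$construct_id)
  if (length(missing_truth) > 0)
    stopf("ground truth missing construct(s): %s",
          paste(utils::head(missing_truth, 3), collapse = ", "))
  set.seed(derive_seed(plan$seed, "screen"))

  cells <- rownames(panel$density)
  base <- panel$baseline_mfi
  n_con <- nrow(constructs)

  ti <- match(constructs$construct_id, truth$construct_id)
  t1 <- registry$binders$target_receptor[match(constructs$n_term_binder,
                                               registry$binders$binder_id)]
  t2 <- registry$binders$target_receptor[match(constructs$c_term_binder,
                                               registry$binders$binder_id)]
  kd1 <- binder_kd(registry, constructs$n_term_binder)
  kd2 <- binder_kd(registry, constructs$c_term_binder)

  grid <- expand.grid(replicate = seq_len(plan$n_stim_reps),
                      ci = seq_len(n_con),
                      pathway = plan$pathways,
                      cell_type = cells,
                      donor_id = donors$donor_id,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  gi <- grid$ci
  d1 <- panel$density[cbind(grid$cell_type, t1[gi])] *
    donors$multipliers[cbind(grid$donor_id, t1[gi])]
  d2 <- panel$density[cbind(grid$cell_type, t2[gi])] *
    donors$multipliers[cbind(grid$donor_id, t2[gi])]

  mech <- truth$mechanism[ti][gi]
  eff <- truth$efficacy[ti][gi]
  sig <- numeric(nrow(grid))
  is_t <- mech == "ternary"
  if (any(is_t))
    sig[is_t] <- ternary_signal(plan$dose_nM, kd1[gi][is_t], kd2[gi][is_t],
                                d1[is_t], d2[is_t],
                                avidity_alpha = plan$avidity_alpha,
                                emax = eff[is_t], k_half = plan$k_half)
  is_c <- mech == "clustering"
  if (any(is_c)) {
    eng_first <- truth$cluster_receptor[ti][gi][is_c] == t1[gi][is_c]
    kd_c <- ifelse(eng_first, kd1[gi][is_c], kd2[gi][is_c])
    dn_c <- ifelse(eng_first, d1[is_c], d2[is_c])
    sig[is_c] <- clustering_signal(plan$dose_nM, kd_c, dn_c, slope = eff[is_c])
  }
  w <- as.matrix(truth[ti, paste0("w_", STAT_PATHWAYS)])[
    cbind(gi, match(grid$pathway, STAT_PATHWAYS))]

  stim <- data.frame(construct_id = constructs$construct_id[gi],
                     donor_id = grid$donor_id, cell_type = grid$cell_type,
                     pathway = grid$pathway, dose_nM = plan$dose_nM,
                     replicate = grid$replicate,
                     condition = plan$condition_label,
                     mfi = base * (1 + sig * w) *
                       rlnorm_cv(nrow(grid), donors$noise_cv),
                     stringsAsFactors = FALSE)

  cgrid <- expand.grid(replicate = seq_len(plan$n_control_reps),
                       pathway = plan$pathways, cell_type = cells,
                       donor_id = donors$donor_id,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ctrl <- data.frame(construct_id = "UNSTIM", donor_id = cgrid$donor_id,
                     cell_type = cgrid$cell_type, pathway = cgrid$pathway,
                     dose_nM = 0, replicate = cgrid$replicate,
                     condition = "unstimulated_control",
                     mfi = base * rlnorm_cv(nrow(cgrid), donors$noise_cv),
                     stringsAsFactors = FALSE)

  out <- rbind(ctrl, stim)

  if (isTRUE(plan$include_single_binder) && nrow(registry$binders) > 0) {
    sgrid <- expand.grid(binder = registry$binders$binder_id,
                         pathway = plan$pathways, cell_type = cells,
                         donor_id = donors$donor_id,
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    sb <- data.frame(construct_id = paste0("SB__", sgrid$binder),
                     donor_id = sgrid$donor_id, cell_type = sgrid$cell_type,
                     pathway = sgrid$pathway, dose_nM = plan$dose_nM,
                     replicate = 1L, condition = "single_binder_control",
                     mfi = base * rlnorm_cv(nrow(sgrid), donors$noise_cv),
                     stringsAsFactors = FALSE)
    out <- rbind(out, sb)
  }
  rownames(out) <- NULL
  out
}

#' Generate a noisy dose-response series for one construct
#'
#' Evaluates the construct's planted mechanism over a dose grid in a fixed
#' cellular context and adds multiplicative lognormal noise; responses are on
#' the fluorescence scale, `baseline * (1 + signal * w)`, with `w` the weight
#' of the construct's dominant measured pathway.
#'
#' @param construct one manifest row.
#' @param truth ground truth table covering the construct.
#' @param doses dose grid (nM); at least 4 values including 0.
#' @param registry a `binder_registry`.
#' @param density receptor density of each arm in the assay context
#'   (default 1000).
#' @param baseline_mfi baseline fluorescence (default 100).
#' @param noise_cv multiplicative well noise CV (default 0.15).
#' @param n_reps wells per dose; the reported response is their mean
#'   (default 3, the conventional triplicate).
#' @param seed integer seed.
#' @return `data.frame` with `construct_id, dose_nM, response, pathway,
#'   cell_type`.
#' @export
generate_dose_series <- function(construct, truth, doses, registry,
                                 density = 1000, baseline_mfi = 100,
                                 noise_cv = 0.15, n_reps = 3, seed = 1) {
  if (length(doses) < 4) stopf("need at least 4 doses")
  if (!any(doses == 0)) stopf("dose grid must include 0")
  if (is.unsorted(doses, strictly = TRUE)) stopf("doses must be strictly increasing")
  ti <- match(construct$construct_id, truth$construct_id)
  if (is.na(ti)) stopf("ground truth missing construct '%s'", construct$construct_id)
  trow <- truth[ti, ]
  set.seed(derive_seed(seed, paste0("dose:", construct$construct_id)))
  kd1 <- binder_kd(registry, construct$n_term_binder)
  kd2 <- binder_kd(registry, construct$c_term_binder)
  t1 <- registry$binders$target_receptor[match(construct$n_term_binder,
                                               registry$binders$binder_id)]
  plan <- screen_plan(seed = seed)
  sig <- mechanism_signal(trow, doses, kd1, kd2, density, density,
                          engaged_first = identical(trow$cluster_receptor, t1),
                          plan = plan)
  wts <- as.numeric(trow[paste0("w_", STAT_PATHWAYS)])
  pth <- STAT_PATHWAYS[which.max(wts)]
  w <- max(wts)
  wells <- matrix(rlnorm_cv(length(doses) * n_reps, noise_cv),
                  nrow = length(doses))
  data.frame(construct_id = construct$construct_id, dose_nM = doses,
             response = baseline_mfi * (1 + sig * w) * rowMeans(wells),
             pathway = pth, cell_type = "assay", stringsAsFactors = FALSE)
}
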