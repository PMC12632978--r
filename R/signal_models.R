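#' Equilibrium bridging signal of a dual-receptor agonist
#'
#' Closed-form approximation to the abundance of the ternary
#' receptor1--ligand--receptor2 complex that drives signaling in the
#' dual-receptor mechanism. The bridging term
#' \deqn{T = \alpha \, r_1 r_2 \, d / ((K_1 + d)(K_2 + d))}
#' is proportional to the product of the fraction of receptor 1 occupied and
#' the fraction of receptor 2 free to be recruited (and vice versa); it is
#' symmetric in the two receptor arms, zero when either receptor is absent,
#' and single-peaked in dose with its maximum at \eqn{d = \sqrt{K_1 K_2}} --
#' the classic high-dose hook, where excess ligand saturates each receptor
#' with separate molecules. Signal is a saturable readout of T:
#' \eqn{S = E_{max} \, T / (T + K_{half})}.
#'
#' This is an equilibrium approximation chosen for analytic transparency, not
#' a full mass-balance solve; within the screened dose range (well below the
#' hook for nanomolar binders at 250 nM) it produces the saturable,
#' dual-receptor-dependent dose responses the hit-calling and classification
#' stages assume.
#'
#' @param dose_nM ligand dose (nM), scalar or vector.
#' @param kd1_nM,kd2_nM dissociation constants of the two binder arms (nM).
#' @param r1_density,r2_density receptor surface densities (copies/cell).
#' @param avidity_alpha bridging efficiency scale (default 1).
#' @param emax maximal signal (arbitrary units; the generator uses the
#'   planted efficacy here).
#' @param k_half bridging-term abundance giving half-maximal signal
#'   (default 50, in T units at densities of order 1000).
#' @return signal values `>= 0`, same length as `dose_nM`.
#' @examples
#' ternary_signal(250, 10, 10, 1000, 1000, emax = 3)
#' ternary_signal(250, 10, 10, 1000, 0, emax = 3)  # knockout: 0
#' @export
ternary_signal <- function(dose_nM, kd1_nM, kd2_nM, r1_density, r2_density,
                           avidity_alpha = 1, emax = 1, k_half = 50) {
  if (any(dose_nM < 0) || any(r1_density < 0) || any(r2_density < 0) ||
      any(avidity_alpha < 0) || any(emax < 0))
    stopf("ternary_signal: negative inputs are not allowed")
  if (any(kd1_nM <= 0) || any(kd2_nM <= 0))
    stopf("ternary_signal: dissociation constants must be > 0")
  if (k_half <= 0) stopf("ternary_signal: k_half must be > 0")
  bridging <- avidity_alpha * r1_density * r2_density * dose_nM /
    ((kd1_nM + dose_nM) * (kd2_nM + dose_nM))
  emax * bridging / (bridging + k_half)
}

#' Non-saturating clustering signal of a self-associating binder
#'
#' Alternative signaling mechanism in which one self-associating binding
#' domain aggregates a single receptor. Modelled as receptor occupancy times
#' a slowly growing log term,
#' \eqn{S = s \cdot (r/1000) \cdot \frac{d}{d+K} \cdot \log(1 + d/K)},
#' which is strictly increasing in dose over any bounded range (no plateau)
#' and depends on one receptor only. The log-growth form is a stand-in for
#' aggregation statistics, not fit to data; only its qualitative
#' non-saturation is relied upon downstream.
#'
#' @param dose_nM dose (nM), scalar or vector.
#' @param kd_nM dissociation constant of the engaged arm (nM).
#' @param density surface density of the engaged receptor (copies/cell).
#' @param slope signal scale per log-unit (the generator's planted efficacy).
#' @return signal values `>= 0`.
#' @export
clustering_signal <- function(dose_nM, kd_nM, density, slope) {
  if (any(dose_nM < 0) || any(density < 0) || any(slope < 0))
    stopf("clustering_signal: negative inputs are not allowed")
  if (any(kd_nM <= 0)) stopf("clustering_signal: kd_nM must be > 0")
  occupancy <- dose_nM / (dose_nM + kd_nM)
  slope * (density / 1000) * occupancy * log1p(dose_nM / kd_nM)
}

#' Expected pSTAT signature of a receptor pairing
#'
#' Private receptor chains define the STAT signature of a pairing while
#' common chains act as assembly platforms: the profile is the sum of the
#' canonical pSTAT weight vectors of the pair's private cytokine receptor(s),
#' falling back to both receptors' weights when the pair contains no private
#' chain with a nonzero vector (e.g. common-common fusions, or
#' cytokine-growth-factor hybrids where the cytokine chain is a common one).
#' The result is scaled so its largest weight is 1, then, for flexible
#' (non-rigid) constructs, a pSTAT5 "leak" of weight `lambda` is added --
#' relaxed dimer geometries bias output toward STAT5, which is how e.g. IL-21
#' mimics pick up pSTAT5 alongside their canonical pSTAT3. Weights are
#' clipped to `[0, 1]`.
#'
#' @param construct one manifest row.
#' @param registry a `binder_registry`.
#' @param lambda pSTAT5 leak weight in `[0,1]` for flexible constructs
#'   (default 0.15).
#' @return named numeric vector over `pSTAT1, pSTAT3, pSTAT4, pSTAT5, pSTAT6`.
#' @export
stat_profile <- function(construct, registry, lambda = 0.15) {
  stopifnot(inherits(registry, "binder_registry"))
  if (lambda < 0 || lambda > 1) stopf("lambda must lie in [0,1]")
  rec <- registry$receptors
  pair <- c(construct$receptor_a, construct$receptor_b)
  idx <- match(pair, rec$receptor)
  if (anyNA(idx)) stopf("receptor(s) %s not registered",
                        paste(pair[is.na(idx)], collapse = ", "))
  rows <- rec[idx, , drop = FALSE]
  weights <- as.matrix(rows[, STAT_PATHWAYS, drop = FALSE])
  private <- rows$chain_class == "private" & rowSums(weights) > 0
  w <- if (any(private)) colSums(weights[private, , drop = FALSE])
       else colSums(weights)
  if (max(w) > 0) w <- w / max(w)
  if (!isTRUE(construct$rigid) && max(w) > 0)
    w["pSTAT5"] <- w["pSTAT5"] + lambda
  w <- pmin(pmax(w, 0), 1)
  stats::setNames(as.numeric(w), STAT_PATHWAYS)
}
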