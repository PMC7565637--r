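# Assembly-state calculators: oligomeric order from intact mass, fiber
# stoichiometry from gel densitometry under T=3, EM particle statistics.

#' Assign an oligomeric state from an intact mass
#'
#' Chooses the multimer order k in `1..k_max` whose theoretical mass
#' `k * monomer_mass` lies closest to the observed mass; ties are broken
#' toward the smaller k (parsimony).
#'
#' @param observed_mass observed (deconvolved neutral) complex mass, Da.
#' @param monomer_mass theoretical monomer mass, Da.
#' @param k_max largest multimer order considered.
#' @return List of class `oligomer_assignment`: `observed_mass`,
#'   `monomer_mass`, `k`, `theoretical_mass`, `delta` (observed minus
#'   theoretical, Da) and `percent_dev` (|delta| as percent of
#'   theoretical, 2 decimals).
#' @examples
#' assign_oligomer_state(184824.5, 36961.6)  # pentamer, 184808.0 Da
#' @export
assign_oligomer_state <- function(observed_mass, monomer_mass,
                                  k_max = 8L) {
  if (observed_mass <= 0 || monomer_mass <= 0)
    stop("masses must be > 0")
  if (k_max < 1) stop("k_max must be >= 1")
  if (observed_mass < monomer_mass / 2)
    stop("observed mass ", observed_mass, " is below half the monomer ",
         "mass; no valid oligomeric state")
  k <- seq_len(k_max)
  dev <- abs(observed_mass - k * monomer_mass)
  best <- k[which.min(dev)]  # which.min takes the first (smallest k) tie
  theo <- best * monomer_mass
  structure(list(observed_mass = observed_mass,
                 monomer_mass = monomer_mass, k = best,
                 theoretical_mass = theo,
                 delta = observed_mass - theo,
                 percent_dev = round(100 * abs(observed_mass - theo) /
                                       theo, 2)),
            class = "oligomer_assignment")
}

#' @export
print.oligomer_assignment <- function(x, ...) {
  cat(sprintf(
    "Oligomer assignment: k = %d (theoretical %.1f Da, observed %.1f Da, delta %+.1f Da, %.2f%%)\n",
    x$k, x$theoretical_mass, x$observed_mass, x$delta, x$percent_dev))
  invisible(x)
}

#' Deviation of a mass peak from a reference mass
#'
#' @param peak_mass peak mass, Da.
#' @param reference_mass reference (e.g. theoretical complex) mass, Da.
#' @return List: `delta` (peak minus reference, Da) and `percent`
#'   (|delta| as percent of the reference, reported to 2 decimals).
#' @examples
#' peak_deviation(217560.9 - 526.9, 217560.9)  # -526.9 Da, 0.24%
#' @export
peak_deviation <- function(peak_mass, reference_mass) {
  if (reference_mass <= 0) stop("reference_mass must be > 0")
  delta <- peak_mass - reference_mass
  list(delta = delta,
       percent = round(100 * abs(delta) / reference_mass, 2))
}

#' Estimate fibers per capsid from gel band densitometry
#'
#' Under T=3 icosahedral symmetry the capsid offers `total_subunits`
#' (180) quasi-equivalent positions shared between CP and the CP-delta
#' read-through fusion. Band intensity is assumed proportional to
#' protein mass, so intensities are divided by molecular weight to form
#' the molar ratio r = (I_cpdelta/MW_cpdelta) / (I_cp/MW_cp); CP-delta
#' copies per particle are `total_subunits * r / (1 + r)` and fibers per
#' capsid are copies divided by `fiber_order`.
#'
#' @param replicates data frame (or matrix) with columns `I_cp` and
#'   `I_cpdelta`, one row per replicate; intensities must be >= 0.
#' @param mw_cp,mw_cpdelta molecular weights, kDa.
#' @param total_subunits capsid positions (default 180, T=3).
#' @param fiber_order chains per fiber (default 5).
#' @return List of class `stoichiometry_estimate`: `fibers_per_capsid`
#'   (mean across replicates), `sd` (`NA` with one replicate),
#'   `per_replicate`, `saturated` (TRUE when a replicate had I_cp = 0
#'   with CP-delta signal, capping it at `total_subunits/fiber_order`)
#'   and the assumptions used.
#' @examples
#' est <- estimate_fiber_stoichiometry(
#'   data.frame(I_cp = 175 * 36, I_cpdelta = 5 * 72), 36, 72)
#' est$fibers_per_capsid  # exactly 1
#' @export
estimate_fiber_stoichiometry <- function(replicates, mw_cp, mw_cpdelta,
                                         total_subunits = 180,
                                         fiber_order = 5) {
  replicates <- as.data.frame(replicates)
  if (!all(c("I_cp", "I_cpdelta") %in% names(replicates)))
    stop("replicates needs columns I_cp and I_cpdelta")
  if (nrow(replicates) < 1) stop("need at least one replicate")
  if (any(replicates$I_cp < 0) || any(replicates$I_cpdelta < 0))
    stop("intensities must be >= 0")
  if (mw_cp <= 0 || mw_cpdelta <= 0) stop("molecular weights must be > 0")
  cap <- total_subunits / fiber_order
  saturated <- FALSE
  per <- mapply(function(icp, icpd) {
    if (icp == 0) {
      if (icpd > 0) {
        saturated <<- TRUE
        return(cap)
      }
      return(NA_real_)
    }
    r <- (icpd / mw_cpdelta) / (icp / mw_cp)
    total_subunits * r / (1 + r) / fiber_order
  }, replicates$I_cp, replicates$I_cpdelta)
  if (saturated)
    warning("replicate with I_cp = 0 and CP-delta signal: estimate ",
            "saturates at ", cap, " fibers per capsid")
  structure(list(
    fibers_per_capsid = mean(per, na.rm = TRUE),
    sd = if (sum(!is.na(per)) >= 2) stats::sd(per, na.rm = TRUE)
         else NA_real_,
    per_replicate = per,
    saturated = saturated,
    assumptions = list(total_subunits = total_subunits,
                       fiber_order = fiber_order,
                       mw_cp = mw_cp, mw_cpdelta = mw_cpdelta)),
    class = "stoichiometry_estimate")
}

#' @export
print.stoichiometry_estimate <- function(x, ...) {
  cat(sprintf("Fibers per capsid: %.2f +/- %s (n = %d replicates)\n",
              x$fibers_per_capsid,
              if (is.na(x$sd)) "NA" else sprintf("%.2f", x$sd),
              length(x$per_replicate)))
  invisible(x)
}

#' Electron-microscopy particle statistics
#'
#' @param n_total particles examined.
#' @param n_with_fiber particles bearing a visible fiber.
#' @param lengths optional fiber-length measurements (A).
#' @return List of class `particle_stats`: `n_total`, `n_with_fiber`,
#'   `fraction` (percent), `length_mean`, `length_sd` (sample SD; `NA`
#'   when too few lengths), `lengths`.
#' @examples
#' particle_stats(479, 93)$fraction  # 19.4
#' @export
particle_stats <- function(n_total, n_with_fiber, lengths = numeric(0)) {
  if (n_total <= 0) stop("n_total must be > 0")
  if (n_with_fiber < 0 || n_with_fiber > n_total)
    stop("n_with_fiber must lie in [0, n_total]")
  if (length(lengths) && any(!is.finite(lengths)))
    stop("lengths must be finite")
  structure(list(
    n_total = n_total, n_with_fiber = n_with_fiber,
    fraction = 100 * n_with_fiber / n_total,
    length_mean = if (length(lengths) >= 1) mean(lengths) else NA_real_,
    length_sd = if (length(lengths) >= 2) stats::sd(lengths)
                else NA_real_,
    lengths = lengths), class = "particle_stats")
}

#' @export
print.particle_stats <- function(x, ...) {
  cat(sprintf("Particles: %d/%d with fiber (%.1f%%)\n",
              x$n_with_fiber, x$n_total, x$fraction))
  if (!is.na(x$length_mean))
    cat(sprintf("Fiber length: %.0f +/- %s A (n = %d)\n", x$length_mean,
                if (is.na(x$length_sd)) "NA"
                else sprintf("%.0f", x$length_sd), length(x$lengths)))
  invisible(x)
}
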