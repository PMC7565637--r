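# Additive fiber-architecture length model and residue-economy comparison.

#' Fiber architecture components
#'
#' Bundles the component lengths of the additive fiber length model: the
#' N-terminal region covered by the crystal structure, a number of
#' additional beta-bracelet segments of fixed height, and the diameters
#' of the internal globular domain and the C-terminal globular head.
#'
#' @param l_crystal_region length of the crystallographically determined
#'   N-terminal region, in Angstrom.
#' @param n_extra_segments number of predicted beta-bracelet segments
#'   beyond the crystal region.
#' @param h_segment height of one beta-bracelet segment, in Angstrom.
#'   The default 15 equals the rise observed in the crystal fragment
#'   (five repeats over ~75 A).
#' @param d_internal diameter of the internal globular domain (A); set 0
#'   for fibers without a visible internal globule.
#' @param d_head diameter of the C-terminal globular head (A).
#'
#' @return Object of class `fiber_architecture`.
#' @examples
#' orsay <- fiber_architecture(145, 11, 15, 30, 50)
#' predict_length(orsay)  # 390
#' @export
fiber_architecture <- function(l_crystal_region, n_extra_segments,
                               h_segment = 15, d_internal = 0,
                               d_head = 0) {
  vals <- c(l_crystal_region = l_crystal_region,
            n_extra_segments = n_extra_segments,
            h_segment = h_segment, d_internal = d_internal,
            d_head = d_head)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all architecture components must be finite and >= 0")
  if (n_extra_segments != round(n_extra_segments))
    stop("n_extra_segments must be an integer count")
  structure(as.list(vals), class = "fiber_architecture")
}

#' Predict total fiber length from its architecture
#'
#' The additive model: total length = crystal region + (number of extra
#' segments x segment height) + internal globule diameter + head
#' diameter.
#'
#' @param arch a [fiber_architecture()] object.
#' @return Total length in Angstrom.
#' @export
predict_length <- function(arch) {
  stopifnot(inherits(arch, "fiber_architecture"))
  arch$l_crystal_region + arch$n_extra_segments * arch$h_segment +
    arch$d_internal + arch$d_head
}

#' Infer the beta-bracelet segment count from an observed fiber length
#'
#' Inverts the additive length model: subtracts the fixed components
#' from the observed length and divides by the segment height. The
#' real-valued count is reported alongside its nearest integer — the
#' model never silently rounds, since segment counts inferred from EM
#' lengths are estimates.
#'
#' @param observed_length measured fiber length (A).
#' @param arch a [fiber_architecture()] whose `n_extra_segments` is
#'   ignored; its fixed components and `h_segment` are used.
#' @return List with `n` (real), `n_round` (nearest integer) and
#'   `negative` (TRUE, with a warning, when the observed length is
#'   smaller than the fixed components).
#' @examples
#' arch <- fiber_architecture(145, 0, 15, 30, 50)
#' infer_segment_count(473, arch)  # n ~ 16.5, rounds to 17
#' @export
infer_segment_count <- function(observed_length, arch) {
  stopifnot(inherits(arch, "fiber_architecture"))
  if (arch$h_segment <= 0) stop("h_segment must be > 0")
  n <- (observed_length - arch$l_crystal_region - arch$d_internal -
          arch$d_head) / arch$h_segment
  if (n < 0)
    warning("observed length is smaller than the fixed components; ",
            "inferred segment count is negative")
  list(n = n, n_round = round(n), negative = n < 0)
}

#' Geometry of a fibrous beta-fold class
#'
#' @param fold fold name; `"beta_bracelet"`, `"beta_spiral"` and
#'   `"triple_beta_helix"` are registered with the per-chain residue
#'   costs of a 15-A unit (8, 17 and 31 residues on 5, 3 and 3 chains
#'   respectively); other folds require explicit geometry.
#' @param chains oligomer order.
#' @param residues_per_unit_per_chain residues one chain contributes per
#'   axial unit.
#' @param unit_height axial height of one unit (A).
#' @return Object of class `fold_class_geometry`.
#' @export
fold_geometry <- function(fold, chains = NULL,
                          residues_per_unit_per_chain = NULL,
                          unit_height = NULL) {
  registry <- list(
    beta_bracelet = list(chains = 5L, rpu = 8L, h = 15),
    beta_spiral = list(chains = 3L, rpu = 17L, h = 15),
    triple_beta_helix = list(chains = 3L, rpu = 31L, h = 15))
  if (fold %in% names(registry)) {
    g <- registry[[fold]]
    chains <- chains %||% g$chains
    residues_per_unit_per_chain <- residues_per_unit_per_chain %||% g$rpu
    unit_height <- unit_height %||% g$h
  }
  if (is.null(chains) || is.null(residues_per_unit_per_chain) ||
      is.null(unit_height))
    stop("unknown fold '", fold, "': supply chains, ",
         "residues_per_unit_per_chain and unit_height explicitly")
  if (residues_per_unit_per_chain < 1 || unit_height <= 0)
    stop("invalid fold geometry")
  structure(list(fold = fold, chains = chains,
                 residues_per_unit_per_chain = residues_per_unit_per_chain,
                 unit_height = unit_height),
            class = "fold_class_geometry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Residues required per chain to span a target height
#'
#' Residue economy of a fibrous fold: the number of residues one chain
#' must contribute to build a structure of the target height, in whole
#' axial units. For the three registered fold classes at 15 A this
#' returns 8 (pentameric beta-bracelet), 17 (trimeric beta-spiral) and
#' 31 (triple beta-helix): the beta-bracelet yields the longest fiber
#' per residue.
#'
#' @param fold a fold name (see [fold_geometry()]) or a
#'   `fold_class_geometry` object.
#' @param target_height height to span (A).
#' @return Residues per chain (integer).
#' @examples
#' residues_per_height("beta_bracelet", 15)  # 8
#' residues_per_height("beta_spiral", 15)    # 17
#' @export
residues_per_height <- function(fold, target_height) {
  g <- if (inherits(fold, "fold_class_geometry")) fold else fold_geometry(fold)
  if (target_height <= 0) stop("target_height must be > 0")
  ceiling(target_height / g$unit_height) * g$residues_per_unit_per_chain
}
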