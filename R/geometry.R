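# Quantitative geometry of pentameric fiber coordinates: C5 axis fitting,
# rise per repeat, strand tilt, radial/channel profiles, hydrogen-bond
# census and inward-facing residue detection.

#' Construct a pentamer coordinate model
#'
#' @param chains named list of exactly five data frames (one per chain,
#'   names are chain IDs), each with columns `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`. Every chain needs at least two residues with Calpha
#'   coordinates; N/C/O backbone atoms are optional.
#' @param source identifier of the originating file or generator.
#' @return Object of class `pentamer_model`.
#' @export
pentamer_model <- function(chains, source = "in-memory") {
  if (length(chains) != 5L)
    stop("a pentamer model needs exactly 5 chains, got ", length(chains))
  if (is.null(names(chains)) || anyDuplicated(names(chains)))
    stop("chains must be uniquely named by chain ID")
  for (id in names(chains)) {
    ch <- chains[[id]]
    need <- c("resno", "resid", "elety", "x", "y", "z")
    if (!all(need %in% names(ch)))
      stop("chain ", id, " is missing columns: ",
           paste(setdiff(need, names(ch)), collapse = ", "))
    ca <- ch[ch$elety == "CA", ]
    if (nrow(ca) < 2L)
      stop("chain ", id, " has fewer than 2 Calpha residues")
    if (!all(is.finite(as.matrix(ch[, c("x", "y", "z")]))))
      stop("chain ", id, " contains non-finite coordinates")
  }
  structure(list(chains = chains[order(names(chains))], source = source),
            class = "pentamer_model")
}

#' @export
print.pentamer_model <- function(x, ...) {
  n <- vapply(x$chains, function(ch) length(unique(ch$resno)), integer(1))
  cat("Pentamer model (", x$source, ")\n", sep = "")
  cat("  chains:", paste(sprintf("%s(%d res)", names(x$chains), n),
                         collapse = " "), "\n")
  invisible(x)
}

#' Read a pentameric fiber structure from a PDB file
#'
#' Parses the file with [bio3d::read.pdb()], keeps protein ATOM records
#' of the first model, drops waters and heteroatoms, and retains the five
#' largest chains ordered by chain ID. Gaps in the residue numbering of
#' each retained chain are recorded as missing residues.
#'
#' @param path path to a PDB-format file.
#' @return A `pentamer_model`; the per-chain missing-residue lists are
#'   available as `attr(model, "missing_residues")`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT")), ]
  if (nrow(at) == 0) stop("no protein ATOM records in ", path)
  by_chain <- split(at, at$chain)
  sizes <- vapply(by_chain, function(ch) length(unique(ch$resno)),
                  integer(1))
  if (length(by_chain) < 5L)
    stop("need >= 5 chains, found ", length(by_chain), " (",
         paste(sprintf("%s:%d", names(sizes), sizes), collapse = ", "), ")")
  keep <- names(sort(sizes, decreasing = TRUE))[1:5]
  chains <- lapply(by_chain[sort(keep)], function(ch)
    ch[, c("resno", "resid", "elety", "x", "y", "z")])
  missing <- lapply(chains, function(ch) {
    r <- sort(unique(ch$resno))
    setdiff(seq(min(r), max(r)), r)
  })
  m <- pentamer_model(chains, source = path)
  attr(m, "missing_residues") <- missing
  m
}

ca_coords <- function(chain) {
  ca <- chain[chain$elety == "CA", ]
  ca <- ca[!duplicated(ca$resno), ]
  list(resno = ca$resno, xyz = as.matrix(ca[, c("x", "y", "z")]))
}

# Kabsch superposition: rotation R and translation t with y ~ x %*% t(R) + t
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  h <- crossprod(sweep(x, 2, cx), sweep(y, 2, cy))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cy - as.vector(r %*% cx)
  fitted <- sweep(x %*% t(r), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - y)^2)))
  list(R = r, t = t, rmsd = rmsd)
}

rotation_axis_angle <- function(R) {
  ang <- acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("degenerate rotation (angle near 0 or 180 deg)")
  list(axis = v / nv, angle_deg = ang * 180 / pi)
}

# minimal-norm point on the screw axis: solve (I - R) p = t_perp
axis_point <- function(R, t, axis) {
  t_perp <- t - sum(t * axis) * axis
  A <- diag(3) - R
  s <- svd(A)
  pos <- s$d > max(s$d) * 1e-8
  dinv <- ifelse(pos, 1 / s$d, 0)
  as.vector(s$v %*% (dinv * crossprod(s$u, t_perp)))
}

#' Fit the cyclic symmetry axis of a pentamer
#'
#' Extracts the C5 axis from the rigid rotations superposing each chain
#' onto its cyclic neighbour, averaged over the five pairs. Superposition
#' uses matched residue numbers (Calpha only); the fitted rotation angle
#' of every pair must lie within `angle_tol` of 360/order degrees,
#' otherwise a symmetry error reports the fitted angles.
#'
#' @param model a `pentamer_model`.
#' @param order rotational order (5 for a pentamer).
#' @param angle_tol permitted deviation of each pairwise rotation angle
#'   from the ideal 360/order, in degrees.
#' @return List of class `axis_frame`: `point` (3-vector on the axis),
#'   `direction` (unit 3-vector), `order`, `angle_deg` (mean fitted
#'   rotation angle) and `mean_rotation_error` (mean Calpha RMSD of the
#'   pairwise superpositions, A).
#' @export
fit_cyclic_axis <- function(model, order = 5L, angle_tol = 5) {
  stopifnot(inherits(model, "pentamer_model"))
  ids <- names(model$chains)
  cas <- lapply(model$chains, ca_coords)
  axes <- matrix(0, 5, 3)
  pts <- matrix(0, 5, 3)
  angs <- numeric(5)
  errs <- numeric(5)
  for (i in seq_len(5)) {
    j <- i %% 5L + 1L
    shared <- intersect(cas[[i]]$resno, cas[[j]]$resno)
    if (length(shared) < 10L)
      stop("chains ", ids[i], " and ", ids[j], " share only ",
           length(shared), " Calpha positions (need >= 10)")
    xi <- cas[[i]]$xyz[match(shared, cas[[i]]$resno), , drop = FALSE]
    xj <- cas[[j]]$xyz[match(shared, cas[[j]]$resno), , drop = FALSE]
    k <- kabsch(xi, xj)
    aa <- rotation_axis_angle(k$R)
    axes[i, ] <- aa$axis
    angs[i] <- aa$angle_deg
    errs[i] <- k$rmsd
    pts[i, ] <- axis_point(k$R, k$t, aa$axis)
  }
  ideal <- 360 / order
  if (any(abs(angs - ideal) > angle_tol))
    stop(sprintf(
      "rotation angles deviate from %g deg by more than %g deg: %s",
      ideal, angle_tol, paste(sprintf("%.2f", angs), collapse = ", ")))
  # align axis signs with the first pair before averaging
  for (i in 2:5) if (sum(axes[i, ] * axes[1, ]) < 0) {
    axes[i, ] <- -axes[i, ]
  }
  direction <- colMeans(axes)
  direction <- direction / sqrt(sum(direction^2))
  point <- colMeans(pts)
  structure(list(point = point, direction = direction, order = order,
                 angle_deg = mean(angs),
                 mean_rotation_error = mean(errs)),
            class = "axis_frame")
}

axial_radial <- function(xyz, axis) {
  d <- sweep(xyz, 2, axis$point)
  z <- as.vector(d %*% axis$direction)
  perp <- d - outer(z, axis$direction)
  r <- sqrt(rowSums(perp^2))
  list(z = z, r = r)
}

#' Rise per beta-bracelet repeat along the fiber axis
#'
#' Projects the per-repeat Calpha centroid (pooled over all five chains)
#' onto the fitted axis and returns the mean consecutive spacing. The
#' repeats must be monotonically ordered along the axis.
#'
#' @param model a `pentamer_model`.
#' @param axis an `axis_frame` from [fit_cyclic_axis()].
#' @param repeat_starts first residue index of each repeat (>= 2 repeats).
#' @param repeat_length residues per repeat (default 8: 5-strand + 3-loop).
#' @return List: `rise_mean` (A), `rise_sd` (A; `NA` with fewer than
#'   three repeats), `span` (distance between first and last centroid),
#'   `covered_length` (`span` plus one mean rise, i.e. the length covered
#'   by n repeats including the terminal unit) and `centroid_z`.
#' @export
rise_per_repeat <- function(model, axis, repeat_starts,
                            repeat_length = 8L) {
  stopifnot(inherits(model, "pentamer_model"),
            inherits(axis, "axis_frame"))
  if (length(repeat_starts) < 2L) stop("need >= 2 repeats")
  zs <- vapply(repeat_starts, function(s) {
    res <- seq(s, s + repeat_length - 1L)
    xyz <- do.call(rbind, lapply(model$chains, function(ch) {
      ca <- ch[ch$elety == "CA" & ch$resno %in% res, c("x", "y", "z")]
      as.matrix(ca)
    }))
    if (nrow(xyz) == 0) stop("repeat at ", s, " has no Calpha atoms")
    axial_radial(matrix(colMeans(xyz), 1), axis)$z
  }, numeric(1))
  d <- diff(zs)
  if (!(all(d > 0) || all(d < 0)))
    stop("repeats are not monotonically ordered along the axis")
  rises <- abs(d)
  list(rise_mean = mean(rises),
       rise_sd = if (length(rises) >= 2) stats::sd(rises) else NA_real_,
       span = abs(zs[length(zs)] - zs[1]),
       covered_length = abs(zs[length(zs)] - zs[1]) + mean(rises),
       centroid_z = zs)
}

#' Tilt of beta-strands relative to the fiber axis
#'
#' For every chain and strand span, fits the principal line through the
#' strand Calpha atoms and measures the acute angle between that line and
#' the symmetry axis. Beta-bracelet strands run at ~45 degrees; beta-helix
#' strands at ~90.
#'
#' @param model a `pentamer_model`.
#' @param axis an `axis_frame`.
#' @param strand_spans list of length-2 integer vectors (inclusive
#'   residue ranges), each covering >= 3 Calpha positions. Spans with
#'   fewer than 3 distinct points are skipped with a warning.
#' @return List: `tilt_mean`, `tilt_sd` (degrees), `angles` (per
#'   chain-strand), `n_skipped`.
#' @export
strand_tilt <- function(model, axis, strand_spans) {
  stopifnot(inherits(model, "pentamer_model"),
            inherits(axis, "axis_frame"))
  if (!is.list(strand_spans)) strand_spans <- list(strand_spans)
  angles <- c()
  skipped <- 0L
  for (id in names(model$chains)) {
    ch <- model$chains[[id]]
    for (sp in strand_spans) {
      ca <- ch[ch$elety == "CA" & ch$resno >= sp[1] & ch$resno <= sp[2],
               c("x", "y", "z")]
      xyz <- unique(as.matrix(ca))
      if (nrow(xyz) < 3L) {
        skipped <- skipped + 1L
        next
      }
      v <- svd(scale(xyz, scale = FALSE))$v[, 1]
      cosang <- abs(sum(v * axis$direction))
      angles <- c(angles, acos(pmin(cosang, 1)) * 180 / pi)
    }
  }
  if (skipped > 0)
    warning(skipped, " strand span(s) skipped (fewer than 3 distinct points)")
  if (length(angles) == 0) stop("no usable strand spans")
  list(tilt_mean = mean(angles),
       tilt_sd = if (length(angles) >= 2) stats::sd(angles) else NA_real_,
       angles = angles, n_skipped = skipped)
}

#' Radial and channel profile along the fiber axis
#'
#' Bins the selected atoms by axial position and reports per-bin radius
#' statistics about the symmetry axis, plus a channel radius defined as
#' the minimum atom-centre radius minus a probe allowance (floored at
#' zero). Diameters are twice the reported radii; choosing
#' `atoms = "mainchain"` reproduces main-chain-measured diameters.
#'
#' @param model a `pentamer_model`.
#' @param axis an `axis_frame`.
#' @param bin_width axial bin width (A).
#' @param atoms `"calpha"`, `"mainchain"` (N, CA, C, O) or `"all"`.
#' @param probe probe allowance subtracted from the minimum radius for
#'   the channel estimate (A; default 1.4, a water radius).
#' @return Data frame of class `radial_profile` with columns `z_mid`,
#'   `n`, `mean_radius`, `min_radius`, `max_radius`, `channel_radius`;
#'   bins without atoms are absent. The probe, selector and bin width are
#'   attached as attributes.
#' @export
radial_profile <- function(model, axis, bin_width = 3,
                           atoms = c("calpha", "mainchain", "all"),
                           probe = 1.4) {
  stopifnot(inherits(model, "pentamer_model"),
            inherits(axis, "axis_frame"))
  atoms <- match.arg(atoms)
  sel <- switch(atoms,
                calpha = "CA",
                mainchain = c("N", "CA", "C", "O"),
                all = NULL)
  xyz <- do.call(rbind, lapply(model$chains, function(ch) {
    if (!is.null(sel)) ch <- ch[ch$elety %in% sel, ]
    as.matrix(ch[, c("x", "y", "z")])
  }))
  if (nrow(xyz) == 0) stop("no atoms match selector '", atoms, "'")
  ar <- axial_radial(xyz, axis)
  z0 <- floor(min(ar$z) / bin_width) * bin_width
  bin <- floor((ar$z - z0) / bin_width)
  agg <- lapply(split(ar$r, bin), function(r)
    c(n = length(r), mean_radius = mean(r), min_radius = min(r),
      max_radius = max(r)))
  b <- as.integer(names(agg))
  out <- data.frame(z_mid = z0 + (b + 0.5) * bin_width,
                    do.call(rbind, agg))
  out$channel_radius <- pmax(out$min_radius - probe, 0)
  out <- out[order(out$z_mid), ]
  rownames(out) <- NULL
  attr(out, "probe") <- probe
  attr(out, "atoms") <- atoms
  attr(out, "bin_width") <- bin_width
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Geometric census of main-chain hydrogen bonds
#'
#' Detects backbone N-H...O=C hydrogen bonds by a geometric criterion:
#' donor-acceptor N...O distance at most `cutoff_dist` and, when the
#' amide hydrogen position can be inferred from the backbone (previous
#' C and own CA present), an N-H...O angle of at least `cutoff_angle`.
#' Bonds are classified as interchain or intrachain. Proline (no amide
#' hydrogen) never donates; the covalently adjacent carbonyl (residue
#' i-1 of the donor) and the donor's own carbonyl are excluded.
#'
#' @param model a `pentamer_model` with backbone N and O atoms; a
#'   Calpha-only model raises a capability error.
#' @param cutoff_dist maximum N...O distance (A, default 3.5).
#' @param cutoff_angle minimum N-H...O angle (degrees, default 120).
#' @param strand_spans optional list of inclusive residue ranges; when
#'   given, per-chain-strand interchain bond counts and partner chains
#'   are reported.
#' @return List: `bonds` (data frame: donor_chain, donor_resno,
#'   acceptor_chain, acceptor_resno, distance, angle, interchain),
#'   `n_skipped_residues` (residues lacking backbone atoms) and, when
#'   `strand_spans` is given, `strand_counts`.
#' @export
mainchain_hbonds <- function(model, cutoff_dist = 3.5, cutoff_angle = 120,
                             strand_spans = NULL) {
  stopifnot(inherits(model, "pentamer_model"))
  get_atoms <- function(elety) do.call(rbind, lapply(
    names(model$chains), function(id) {
      ch <- model$chains[[id]]
      a <- ch[ch$elety == elety, c("resno", "resid", "x", "y", "z")]
      if (nrow(a) == 0) return(NULL)
      a$chain <- id
      a
    }))
  Ns <- get_atoms("N"); Os <- get_atoms("O")
  CAs <- get_atoms("CA"); Cs <- get_atoms("C")
  if (is.null(Ns) || is.null(Os))
    stop("Calpha-only model: H-bond census unavailable ",
         "(no backbone N/O atoms)")
  # residues missing either backbone atom are skipped from the census
  key <- function(df) if (is.null(df)) character(0) else paste(df$chain, df$resno)
  all_res <- unique(c(key(CAs), key(Ns), key(Os)))
  n_skipped <- sum(!(all_res %in% key(Ns)) | !(all_res %in% key(Os)))
  donors <- Ns[Ns$resid != "PRO", ]

  dxyz <- as.matrix(donors[, c("x", "y", "z")])
  axyz <- as.matrix(Os[, c("x", "y", "z")])
  bonds <- NULL
  ca_key <- key(CAs); c_key <- if (!is.null(Cs)) key(Cs) else character(0)
  for (i in seq_len(nrow(donors))) {
    d2 <- colSums((t(axyz) - dxyz[i, ])^2)
    hit <- which(d2 <= cutoff_dist^2)
    for (j in hit) {
      same_chain <- donors$chain[i] == Os$chain[j]
      dres <- donors$resno[i]; ares <- Os$resno[j]
      if (same_chain && (ares == dres || ares == dres - 1L)) next
      ang <- NA_real_
      # infer H from previous C and own CA when available
      ic <- match(paste(donors$chain[i], dres - 1L), c_key)
      ica <- match(paste(donors$chain[i], dres), ca_key)
      if (!is.na(ic) && !is.na(ica)) {
        np <- dxyz[i, ]
        u1 <- np - as.numeric(Cs[ic, c("x", "y", "z")])
        u2 <- np - as.numeric(CAs[ica, c("x", "y", "z")])
        u1 <- u1 / sqrt(sum(u1^2)); u2 <- u2 / sqrt(sum(u2^2))
        hdir <- u1 + u2
        nh <- sqrt(sum(hdir^2))
        if (nh > 1e-6) {
          h <- np + hdir / nh
          v1 <- np - h
          v2 <- as.numeric(Os[j, c("x", "y", "z")]) - h
          ang <- acos(pmin(pmax(sum(v1 * v2) /
            sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
          if (ang < cutoff_angle) next
        }
      }
      bonds <- rbind(bonds, data.frame(
        donor_chain = donors$chain[i], donor_resno = dres,
        acceptor_chain = Os$chain[j], acceptor_resno = ares,
        distance = sqrt(d2[j]), angle = ang,
        interchain = !same_chain))
    }
  }
  if (is.null(bonds))
    bonds <- data.frame(donor_chain = character(0),
                        donor_resno = integer(0),
                        acceptor_chain = character(0),
                        acceptor_resno = integer(0),
                        distance = numeric(0), angle = numeric(0),
                        interchain = logical(0))
  out <- list(bonds = bonds, n_skipped_residues = max(n_skipped, 0L))
  if (!is.null(strand_spans)) {
    counts <- NULL
    for (id in names(model$chains)) for (sp in strand_spans) {
      inv <- bonds$interchain &
        ((bonds$donor_chain == id & bonds$donor_resno >= sp[1] &
            bonds$donor_resno <= sp[2]) |
           (bonds$acceptor_chain == id & bonds$acceptor_resno >= sp[1] &
              bonds$acceptor_resno <= sp[2]))
      partners <- unique(c(
        bonds$acceptor_chain[inv & bonds$donor_chain == id],
        bonds$donor_chain[inv & bonds$acceptor_chain == id]))
      partners <- setdiff(partners, id)
      counts <- rbind(counts, data.frame(
        chain = id, strand_start = sp[1], strand_end = sp[2],
        n_interchain = sum(inv),
        partners = paste(sort(partners), collapse = ",")))
    }
    out$strand_counts <- counts
  }
  out
}

#' Label residues as facing the fiber interior or exterior
#'
#' A residue faces inward when the radial component of its Calpha->Cbeta
#' vector points toward the symmetry axis. For residues without a Cbeta a
#' pseudo-Cbeta is constructed from the backbone N, CA and C positions;
#' glycine (and residues lacking both Cbeta and a full backbone) are
#' labelled `"undetermined"`.
#'
#' @param model a `pentamer_model`.
#' @param axis an `axis_frame`.
#' @param threshold radial dot-product threshold: inward when the
#'   radial component of the unit CA->CB vector is below `-threshold`
#'   (default 0).
#' @param anchor_positions optional residue indices of strand anchor
#'   positions; when given, the fraction labelled inward is reported.
#' @return List: `labels` (data frame: chain, resno, resid, radial_dot,
#'   label in inward/outward/undetermined) and `anchor_inward_fraction`
#'   (`NA` unless `anchor_positions` supplied).
#' @export
inward_facing_residues <- function(model, axis, threshold = 0,
                                   anchor_positions = NULL) {
  stopifnot(inherits(model, "pentamer_model"),
            inherits(axis, "axis_frame"))
  rows <- NULL
  for (id in names(model$chains)) {
    ch <- model$chains[[id]]
    for (resno in sort(unique(ch$resno))) {
      res <- ch[ch$resno == resno, ]
      ca <- res[res$elety == "CA", c("x", "y", "z")]
      if (nrow(ca) == 0) next
      ca <- as.numeric(ca[1, ])
      cb <- res[res$elety == "CB", c("x", "y", "z")]
      cb <- if (nrow(cb) > 0) as.numeric(cb[1, ]) else {
        nb <- res[res$elety == "N", c("x", "y", "z")]
        cc <- res[res$elety == "C", c("x", "y", "z")]
        if (res$resid[1] != "GLY" && nrow(nb) > 0 && nrow(cc) > 0)
          pseudo_cbeta(as.numeric(nb[1, ]), ca, as.numeric(cc[1, ]))
        else NULL
      }
      if (is.null(cb)) {
        rows <- rbind(rows, data.frame(
          chain = id, resno = resno, resid = res$resid[1],
          radial_dot = NA_real_, label = "undetermined"))
        next
      }
      d <- ca - axis$point
      zc <- sum(d * axis$direction)
      radial <- d - zc * axis$direction
      nr <- sqrt(sum(radial^2))
      if (nr < 1e-6) {
        rows <- rbind(rows, data.frame(
          chain = id, resno = resno, resid = res$resid[1],
          radial_dot = NA_real_, label = "undetermined"))
        next
      }
      v <- cb - ca
      dot <- sum(v / sqrt(sum(v^2)) * radial / nr)
      rows <- rbind(rows, data.frame(
        chain = id, resno = resno, resid = res$resid[1],
        radial_dot = dot,
        label = if (dot < -threshold) "inward" else "outward"))
    }
  }
  frac <- NA_real_
  if (!is.null(anchor_positions)) {
    anc <- rows[rows$resno %in% anchor_positions &
                  rows$label != "undetermined", ]
    if (nrow(anc) > 0) frac <- mean(anc$label == "inward")
  }
  list(labels = rows, anchor_inward_fraction = frac)
}

# standard tetrahedral Cbeta reconstruction from backbone atoms
pseudo_cbeta <- function(n, ca, c) {
  b <- ca - n
  cdir <- c - ca
  a <- c(b[2] * cdir[3] - b[3] * cdir[2],
         b[3] * cdir[1] - b[1] * cdir[3],
         b[1] * cdir[2] - b[2] * cdir[1])
  ca - 0.58273431 * a + 0.56802827 * b - 0.54067466 * cdir
}
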