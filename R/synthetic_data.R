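# Seeded generators producing ground-truth-labelled fixtures for every
# analysis stage: planted-repeat sequences, idealized C5 fiber
# coordinates, intact-mass peak lists, gel densitometry replicates and
# EM fiber-length samples. Identical seed + parameters give identical
# output.

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
         G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
         M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
         S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

#' Generate a delta-like sequence with planted beta-bracelet repeats
#'
#' Emits, N to C: a coiled-coil stub of ideal heptads, `n_strict` tandem
#' strict-consensus periods, an internal non-matching spacer, `n_relaxed`
#' relaxed-consensus periods and a non-matching C-terminal tail. Spacer
#' and tail residues are drawn from an alphabet (G, P, N, Q) outside
#' every anchor and loop-flank class, so no window crossing or inside
#' them can satisfy the consensus; the strand x positions vary over
#' S/T/G and the loop positions over their permitted classes.
#'
#' With the default domain lengths and five strict plus eleven relaxed
#' repeats stretched over a 104-residue span, the planted domains sit at
#' the canonical boundaries of the Orsay delta protein: coiled coil
#' 1-62, first bracelet region 63-102, internal globule 103-145, second
#' bracelet region 146-249, C-terminal head 250-346.
#'
#' @param n_strict,n_relaxed number of planted strict / relaxed periods.
#' @param domain_lengths named numeric vector; recognised keys: `cc`
#'   (coiled-coil stub), `spacer` (internal non-matching region), `tail`
#'   (C-terminal non-matching region) and optional `relaxed_span`, a
#'   total span for the relaxed region. When `relaxed_span` exceeds
#'   `8 * n_relaxed` the surplus is distributed as non-matching linkers
#'   between relaxed segments (mirroring repeats "separated by loops of
#'   various lengths"), so each relaxed segment forms its own run.
#' @param seed integer seed; output is reproducible bit for bit.
#' @param id sequence identifier for FASTA output.
#' @param path optional file stem: writes `<path>.fasta` and a sidecar
#'   `<path>.truth.json`.
#' @return List: `sequence`, `id`, and `truth` (planted strict and
#'   relaxed repeat starts plus the domain ranges).
#' @examples
#' g <- gen_repeat_sequence(5, 0, c(cc = 62, tail = 0), seed = 1)
#' nchar(g$sequence)  # 102
#' @export
gen_repeat_sequence <- function(n_strict, n_relaxed,
                                domain_lengths = c(cc = 62, spacer = 43,
                                                   relaxed_span = 104,
                                                   tail = 97),
                                seed = 1L, id = "synthetic_delta",
                                path = NULL) {
  if (n_strict < 0 || n_relaxed < 0) stop("repeat counts must be >= 0")
  dl <- function(k, default = 0) {
    v <- unname(domain_lengths[k])
    if (is.na(v) || length(v) == 0) default else v
  }
  cc_len <- dl("cc"); spacer_len <- dl("spacer"); tail_len <- dl("tail")
  relaxed_span <- dl("relaxed_span", 8 * n_relaxed)
  if (n_relaxed > 0 && relaxed_span < 8 * n_relaxed)
    stop("relaxed_span must be >= 8 * n_relaxed")
  if (n_relaxed == 0) relaxed_span <- 0
  set.seed(seed)

  decoy <- function(n) if (n <= 0) character(0) else
    sample(c("G", "P", "N", "Q"), n, replace = TRUE)
  strict_unit <- function() c("V", sample(c("S", "T", "G"), 2, TRUE), "V",
                              sample(c("S", "T", "G"), 1),
                              sample(c("D", "E", "K", "R"), 1),
                              sample(c("E", "D", "N"), 1),
                              sample(c("D", "E", "K", "R"), 1))
  relaxed_unit <- function() c(sample(c("I", "M", "F"), 1),
                               sample(c("S", "T", "G"), 2, TRUE),
                               sample(c("I", "L", "M", "F"), 1),
                               sample(c("S", "T", "G"), 1),
                               sample(c("D", "E", "K", "R"), 1),
                               sample(c("Q", "S", "T", "N"), 1),
                               sample(c("D", "E", "K", "R"), 1))

  cc <- if (cc_len > 0)
    rep(c("L", "A", "A", "A", "Q", "A", "A"),
        length.out = cc_len) else character(0)

  res <- cc
  strict_starts <- integer(0)
  for (i in seq_len(n_strict)) {
    strict_starts <- c(strict_starts, length(res) + 1L)
    res <- c(res, strict_unit())
  }
  strict_end <- length(res)
  res <- c(res, decoy(spacer_len))

  relaxed_starts <- integer(0)
  if (n_relaxed > 0) {
    extra <- relaxed_span - 8 * n_relaxed
    gaps <- rep(0L, n_relaxed - 1L)
    if (n_relaxed > 1 && extra > 0) {
      add <- rep(extra %/% (n_relaxed - 1L), n_relaxed - 1L)
      rem <- extra %% (n_relaxed - 1L)
      if (rem > 0) add[seq_len(rem)] <- add[seq_len(rem)] + 1L
      gaps <- add
    } else if (n_relaxed == 1 && extra > 0) {
      stop("relaxed_span > 8 with a single relaxed repeat has no gap to fill")
    }
    for (i in seq_len(n_relaxed)) {
      relaxed_starts <- c(relaxed_starts, length(res) + 1L)
      res <- c(res, relaxed_unit())
      if (i < n_relaxed && gaps[i] > 0) res <- c(res, decoy(gaps[i]))
    }
  }
  relaxed_end <- length(res)
  res <- c(res, decoy(tail_len))

  truth <- list(
    strict_starts = strict_starts,
    relaxed_starts = relaxed_starts,
    coiled_coil = if (cc_len > 0) c(1L, cc_len) else NULL,
    bracelet_region_1 = if (n_strict > 0)
      c(strict_starts[1], strict_end) else NULL,
    internal_globular = if (n_strict > 0 && n_relaxed > 0 &&
                              spacer_len > 0)
      c(strict_end + 1L, strict_end + spacer_len) else NULL,
    bracelet_region_2 = if (n_relaxed > 0)
      c(relaxed_starts[1], relaxed_end) else NULL,
    c_terminal_globular = if (tail_len > 0)
      c(relaxed_end + 1L, length(res)) else NULL)

  out <- list(sequence = paste(res, collapse = ""), id = id,
              truth = truth)
  if (!is.null(path)) {
    write_fasta(stats::setNames(out$sequence, id),
                paste0(path, ".fasta"))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' Generate idealized five-fold-symmetric fiber coordinates
#'
#' Builds a pentamer of `n_repeats` beta-bracelet repeats about the z
#' axis: chains B-E are exact 72-degree rotations of chain A. Each
#' repeat contributes five strand Calpha placed on the cylinder of
#' radius `strand_radius` along a helical arc whose local direction
#' makes the requested `tilt` with the axis, followed by three loop
#' Calpha at `loop_radius`; successive repeats are translated by `rise`.
#' The Calpha spacing is deliberately compact (1.9 A) so the chord of
#' the on-cylinder arc preserves the nominal tilt. Optional isotropic
#' Gaussian noise perturbs every coordinate; an optional pseudo-backbone
#' (N, C, O at ideal bond lengths, non-physical placement) gives the
#' hydrogen-bond census atoms to count.
#'
#' @param n_repeats repeats per chain (>= 1).
#' @param rise axial translation per repeat (A).
#' @param tilt nominal strand tilt to the axis (degrees).
#' @param strand_radius,loop_radius cylinder radii of strand and loop
#'   Calpha (A); the main-chain strand diameter is `2 * strand_radius`.
#' @param noise_sd isotropic Gaussian coordinate noise (A).
#' @param seed integer seed.
#' @param ca_spacing Calpha-Calpha spacing along the strand arc (A).
#' @param with_backbone also place pseudo N, C, O atoms.
#' @param path optional file stem: writes `<path>.pdb` plus
#'   `<path>.truth.json`.
#' @return A `pentamer_model` with a `truth` attribute recording axis
#'   point/direction, rise, tilt, radii, the planted `repeat_starts`
#'   (period 8) and the per-repeat `strand_spans`.
#' @export
gen_pentamer_coords <- function(n_repeats, rise = 15, tilt = 45,
                                strand_radius = 6, loop_radius = 9.5,
                                noise_sd = 0, seed = 1L,
                                ca_spacing = 1.9, with_backbone = FALSE,
                                path = NULL) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (strand_radius <= 0 || loop_radius <= 0) stop("radii must be > 0")
  set.seed(seed)
  tr <- tilt * pi / 180
  dtheta <- ca_spacing * sin(tr) / strand_radius
  dz <- ca_spacing * cos(tr)
  unit_res <- c("V", "S", "T", "V", "S", "K", "E", "D")

  coords <- NULL
  for (j in seq_len(n_repeats) - 1L) {
    z0 <- j * rise
    th <- (0:4) * dtheta
    strand <- cbind(strand_radius * cos(th), strand_radius * sin(th),
                    z0 + (0:4) * dz)
    z_end <- z0 + 4 * dz
    lth <- 4 * dtheta + (1:3) * dtheta
    lz <- z_end + (1:3) / 4 * (rise - 4 * dz)
    loop <- cbind(loop_radius * cos(lth), loop_radius * sin(lth), lz)
    coords <- rbind(coords, strand, loop)
  }
  n_res <- nrow(coords)
  resid <- AA3[rep(unit_res, n_repeats)]

  rot_z <- function(deg) {
    a <- deg * pi / 180
    matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
           3, 3, byrow = TRUE)
  }
  chains <- list()
  for (k in 0:4) {
    xyz <- coords %*% t(rot_z(72 * k))
    ch <- data.frame(resno = seq_len(n_res), resid = unname(resid),
                     elety = "CA", x = xyz[, 1], y = xyz[, 2],
                     z = xyz[, 3])
    if (with_backbone) ch <- add_pseudo_backbone(ch)
    chains[[LETTERS[k + 1]]] <- ch
  }
  if (noise_sd > 0) {
    for (id in names(chains)) {
      n <- nrow(chains[[id]])
      chains[[id]]$x <- chains[[id]]$x + stats::rnorm(n, 0, noise_sd)
      chains[[id]]$y <- chains[[id]]$y + stats::rnorm(n, 0, noise_sd)
      chains[[id]]$z <- chains[[id]]$z + stats::rnorm(n, 0, noise_sd)
    }
  }
  model <- pentamer_model(chains, source = "gen_pentamer_coords")
  truth <- list(axis_point = c(0, 0, 0), axis_direction = c(0, 0, 1),
                rise = rise, tilt = tilt,
                strand_radius = strand_radius, loop_radius = loop_radius,
                n_repeats = n_repeats,
                repeat_starts = seq(1L, by = 8L,
                                    length.out = n_repeats),
                strand_spans = lapply(
                  seq(1L, by = 8L, length.out = n_repeats),
                  function(s) c(s, s + 4L)),
                noise_sd = noise_sd, seed = seed,
                pseudo_backbone = with_backbone)
  attr(model, "truth") <- truth
  if (!is.null(path)) {
    write_pentamer_pdb(model, paste0(path, ".pdb"))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  model
}

# Non-physical pseudo-backbone at ideal bond lengths (N-CA 1.46,
# CA-C 1.52, C-O 1.23 A) so the H-bond census has atoms to count.
add_pseudo_backbone <- function(ch) {
  ca <- as.matrix(ch[, c("x", "y", "z")])
  n <- nrow(ca)
  unit <- function(v) v / sqrt(sum(v^2))
  rows <- NULL
  for (i in seq_len(n)) {
    prev <- if (i > 1) unit(ca[i, ] - ca[i - 1, ]) else
      unit(ca[i, ] - ca[i + 1, ]) * -1
    nxt <- if (i < n) unit(ca[i + 1, ] - ca[i, ]) else
      unit(ca[i, ] - ca[i - 1, ])
    npos <- ca[i, ] - 1.46 * prev
    cpos <- ca[i, ] + 1.52 * nxt
    radial <- c(cpos[1], cpos[2], 0)
    radial <- if (sqrt(sum(radial^2)) > 1e-6) unit(radial) else c(1, 0, 0)
    opos <- cpos + 1.23 * radial
    rows <- rbind(rows,
                  data.frame(resno = ch$resno[i], resid = ch$resid[i],
                             elety = c("N", "C", "O"),
                             x = c(npos[1], cpos[1], opos[1]),
                             y = c(npos[2], cpos[2], opos[2]),
                             z = c(npos[3], cpos[3], opos[3])))
  }
  out <- rbind(ch, rows)
  out[order(out$resno, match(out$elety, c("N", "CA", "C", "O"))), ]
}

#' Generate intact-mass peaks for a k-mer assembly
#'
#' Main peak at `k * monomer_mass` (plus optional Gaussian noise) and one
#' minor peak per adduct offset.
#'
#' @param monomer_mass monomer mass (Da).
#' @param k oligomer order.
#' @param adduct_offsets numeric offsets (Da) of minor peaks relative to
#'   the theoretical main mass.
#' @param noise_sd Gaussian mass noise (Da).
#' @param seed integer seed.
#' @return List: `peaks` (data frame with `peak`, `mass`) and `truth`
#'   (`theoretical`, `k`, `monomer_mass`, `adduct_offsets`).
#' @export
gen_mass_peaks <- function(monomer_mass, k, adduct_offsets = numeric(0),
                           noise_sd = 0, seed = 1L) {
  if (monomer_mass <= 0 || k < 1) stop("invalid monomer mass or k")
  set.seed(seed)
  theo <- k * monomer_mass
  masses <- c(theo, theo + adduct_offsets)
  if (noise_sd > 0) masses <- masses + stats::rnorm(length(masses), 0,
                                                    noise_sd)
  labels <- c("main", if (length(adduct_offsets))
    paste0("minor", seq_along(adduct_offsets)))
  list(peaks = data.frame(peak = labels, mass = masses),
       truth = list(theoretical = theo, k = k,
                    monomer_mass = monomer_mass,
                    adduct_offsets = adduct_offsets))
}

#' Generate gel densitometry replicates around a true fiber count
#'
#' Inverts the stoichiometry model to produce noiseless CP and CP-delta
#' band intensities for the requested fibers-per-capsid value, then
#' applies multiplicative log-normal noise of the given coefficient of
#' variation (mean-preserving) to each band independently.
#'
#' @param true_fibers true pentameric fibers per capsid.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_replicates number of replicates.
#' @param mw_cp,mw_cpdelta molecular weights of CP and CP-delta (kDa).
#' @param seed integer seed.
#' @param total_subunits capsid subunit positions (180 for T=3).
#' @param fiber_order chains per fiber (5).
#' @param i_cp_base noiseless CP band intensity (arbitrary units).
#' @return List: `replicates` (data frame: replicate, I_cp, I_cpdelta)
#'   and `truth`.
#' @export
gen_gel_intensities <- function(true_fibers, noise_cv, n_replicates,
                                mw_cp = 36, mw_cpdelta = 72, seed = 1L,
                                total_subunits = 180, fiber_order = 5,
                                i_cp_base = 1000) {
  if (true_fibers < 0 || true_fibers > total_subunits / fiber_order)
    stop("true_fibers outside [0, total_subunits / fiber_order]")
  if (n_replicates < 1) stop("need >= 1 replicate")
  set.seed(seed)
  copies <- true_fibers * fiber_order
  r <- copies / (total_subunits - copies)  # molar CP-delta : CP ratio
  i_cpd <- r * (mw_cpdelta / mw_cp) * i_cp_base
  noise <- function(n) {
    if (noise_cv <= 0) return(rep(1, n))
    s <- sqrt(log(1 + noise_cv^2))
    stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
  }
  reps <- data.frame(replicate = seq_len(n_replicates),
                     I_cp = i_cp_base * noise(n_replicates),
                     I_cpdelta = i_cpd * noise(n_replicates))
  list(replicates = reps,
       truth = list(true_fibers = true_fibers, noise_cv = noise_cv,
                    mw_cp = mw_cp, mw_cpdelta = mw_cpdelta,
                    total_subunits = total_subunits,
                    fiber_order = fiber_order))
}

#' Generate EM fiber-length samples
#'
#' Gaussian lengths truncated at zero (negative draws are resampled).
#'
#' @param mean,sd distribution parameters (A).
#' @param n sample size (0 gives an empty vector).
#' @param seed integer seed.
#' @return Numeric vector of lengths.
#' @export
gen_em_lengths <- function(mean, sd, n, seed = 1L) {
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(numeric(0))
  set.seed(seed)
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}
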