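# Independent brute-force oracle for the repeat scanner, plus small
# hand-built coordinate models used across the geometry tests.

# Enumerate repeats by phase-wise lattice walking, scoring every window
# with match_repeat_window, then resolving overlaps by exhaustive
# longest-run-first selection. Independent of scan_repeats internals.
brute_scan_starts <- function(sequence, mode, classes = residue_classes(),
                              min_run = 1L) {
  res <- strsplit(toupper(sequence), "")[[1]]
  L <- length(res)
  full_ok <- function(i) {
    if (i + 7L > L) return(FALSE)
    w <- paste(res[i:(i + 7L)], collapse = "")
    match_repeat_window(w, mode, classes)$score == 1
  }
  strand_ok <- function(i) {
    pc <- pentafiber:::position_classes(classes, mode)
    res[i] %in% pc$p1 && res[i + 3L] %in% pc$p4
  }
  runs <- list()
  for (phase in 1:8) {
    lattice <- seq(phase, L, by = 8L)
    ok <- vapply(lattice, full_ok, logical(1))
    r <- rle(ok)
    stop_at <- cumsum(r$lengths)
    start_at <- c(1L, head(stop_at, -1) + 1L)
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      starts <- lattice[start_at[k]:stop_at[k]]
      nxt <- starts[length(starts)] + 8L
      trunc <- FALSE
      if (nxt + 4L - 1L <= L && nxt + 7L > L && strand_ok(nxt)) {
        starts <- c(starts, nxt)
        trunc <- TRUE
      }
      last <- starts[length(starts)]
      runs[[length(runs) + 1L]] <- list(
        starts = starts,
        span = c(starts[1L], if (trunc) last + 4L else last + 7L))
    }
  }
  runs <- Filter(function(r) length(r$starts) >= min_run, runs)
  chosen <- integer(0)
  occupied <- rep(FALSE, L)
  repeat {
    avail <- Filter(function(r)
      !any(occupied[seq(r$span[1], r$span[2])]), runs)
    if (length(avail) == 0) break
    lens <- vapply(avail, function(r) length(r$starts), integer(1))
    firsts <- vapply(avail, function(r) r$span[1], numeric(1))
    pick <- avail[[order(-lens, firsts)[1]]]
    occupied[seq(pick$span[1], pick$span[2])] <- TRUE
    chosen <- c(chosen, pick$starts)
  }
  sort(chosen)
}

# random test sequences enriched in consensus-relevant residues so that
# chance repeats actually occur
random_test_sequence <- function(n) {
  pool <- c("V", "V", "L", "E", "D", "K", "R", "N", "S", "T", "A", "G",
            "Q", "I", "F", "P")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# five chains related by exact 72-degree rotations of a template chain
rotated_pentamer <- function(template, source = "hand-built") {
  rot_z <- function(deg) {
    a <- deg * pi / 180
    matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
           3, 3, byrow = TRUE)
  }
  chains <- list()
  for (k in 0:4) {
    xyz <- as.matrix(template[, c("x", "y", "z")]) %*% t(rot_z(72 * k))
    ch <- template
    ch$x <- xyz[, 1]; ch$y <- xyz[, 2]; ch$z <- xyz[, 3]
    chains[[LETTERS[k + 1]]] <- ch
  }
  pentamer_model(chains, source = source)
}

# vertical line of n Calpha at a given radius (strand tilt 0)
vertical_chain <- function(n = 12, radius = 6, dz = 3) {
  data.frame(resno = seq_len(n), resid = "VAL", elety = "CA",
             x = radius, y = 0, z = (seq_len(n) - 1) * dz)
}

random_rigid_transform <- function() {
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = stats::rnorm(3, sd = 20))
}

apply_rigid <- function(model, tf) {
  chains <- lapply(model$chains, function(ch) {
    xyz <- as.matrix(ch[, c("x", "y", "z")]) %*% t(tf$R)
    ch$x <- xyz[, 1] + tf$t[1]
    ch$y <- xyz[, 2] + tf$t[2]
    ch$z <- xyz[, 3] + tf$t[3]
    ch
  })
  pentamer_model(chains, source = paste0(model$source, "+rigid"))
}

# axis frame built by construction (for models whose chains are too
# featureless for pairwise superposition, e.g. straight lines)
z_axis_frame <- function() {
  structure(list(point = c(0, 0, 0), direction = c(0, 0, 1),
                 order = 5, angle_deg = 72, mean_rotation_error = 0),
            class = "axis_frame")
}

# distance from a point to the line (p, d)
point_line_distance <- function(x, p, d) {
  v <- x - p
  sqrt(sum((v - sum(v * d) * d)^2))
}

# strand-radius estimate from a radial profile: innermost well-populated bin
profile_strand_radius <- function(pr, min_atoms = 10) {
  min(pr$mean_radius[pr$n >= min_atoms])
}
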