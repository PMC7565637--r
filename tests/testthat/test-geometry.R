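test_that("the C5 axis of ideal coordinates is recovered exactly", {
  m <- gen_pentamer_coords(4, seed = 1)
  ax <- fit_cyclic_axis(m)
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-6)
  ang <- acos(abs(ax$direction[3])) * 180 / pi
  expect_lt(ang, 0.1)
  expect_lt(ax$mean_rotation_error, 1e-8)
  expect_equal(ax$angle_deg, 72, tolerance = 1e-6)
})

test_that("axis fitting is equivariant under rigid-body transforms", {
  set.seed(47)
  m <- gen_pentamer_coords(4, noise_sd = 0.1, seed = 2)
  ax <- fit_cyclic_axis(m)
  for (i in 1:5) {
    tf <- random_rigid_transform()
    axt <- fit_cyclic_axis(apply_rigid(m, tf))
    want <- as.vector(tf$R %*% ax$direction)
    expect_equal(abs(sum(axt$direction * want)), 1, tolerance = 1e-6)
    # recovered point lies on the transformed axis line
    p_want <- as.vector(tf$R %*% ax$point + tf$t)
    expect_lt(point_line_distance(axt$point, p_want, want), 0.01)
  }
})

test_that("axis direction survives coordinate noise", {
  m <- gen_pentamer_coords(5, noise_sd = 0.2, seed = 3)
  ax <- fit_cyclic_axis(m)
  ang <- acos(abs(ax$direction[3])) * 180 / pi
  expect_lt(ang, 1)
  expect_gt(ax$mean_rotation_error, 0)
})

test_that("broken symmetry raises a symmetry error with the fitted angle", {
  m <- gen_pentamer_coords(4, seed = 4)
  # rotate one chain an extra 20 degrees: pair angles leave 72 +/- tol
  a <- 20 * pi / 180
  rot <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  xyz <- as.matrix(m$chains$C[, c("x", "y", "z")]) %*% t(rot)
  m$chains$C$x <- xyz[, 1]; m$chains$C$y <- xyz[, 2]
  m$chains$C$z <- xyz[, 3]
  expect_error(fit_cyclic_axis(m), "deviate")
})

test_that("rise per repeat matches the construction", {
  m <- gen_pentamer_coords(5, rise = 15, seed = 5)
  ax <- fit_cyclic_axis(m)
  tr <- attr(m, "truth")
  rp <- rise_per_repeat(m, ax, tr$repeat_starts)
  expect_equal(rp$rise_mean, 15, tolerance = 1e-6)
  expect_equal(rp$span, 60, tolerance = 1e-6)
  # five repeats cover span + one terminal unit height = 75 A
  expect_equal(rp$covered_length, 75, tolerance = 1e-6)

  # two repeats: a single spacing, no dispersion to report
  m2 <- gen_pentamer_coords(2, rise = 12, seed = 6)
  rp2 <- rise_per_repeat(m2, fit_cyclic_axis(m2),
                         attr(m2, "truth")$repeat_starts)
  expect_equal(rp2$rise_mean, 12, tolerance = 1e-6)
  expect_true(is.na(rp2$rise_sd))

  expect_error(rise_per_repeat(m, ax, tr$repeat_starts[1]), ">= 2")
  expect_error(rise_per_repeat(m, ax, c(1, 17, 9)), "monoton")
})

test_that("strand tilt reports the acute angle to the axis", {
  m <- gen_pentamer_coords(4, tilt = 45, seed = 7)
  ax <- fit_cyclic_axis(m)
  st <- strand_tilt(m, ax, attr(m, "truth")$strand_spans)
  expect_equal(st$tilt_mean, 45, tolerance = 3 / 45)

  # strands parallel to the axis: 0 degrees (straight-line chains are
  # rotationally featureless, so the known axis is supplied directly)
  mv <- rotated_pentamer(vertical_chain(12, radius = 6))
  expect_equal(strand_tilt(mv, z_axis_frame(), list(c(1, 12)))$tilt_mean,
               0, tolerance = 1e-6)

  # radial spokes perpendicular to the axis: 90 degrees
  spoke <- data.frame(resno = 1:12, resid = "VAL", elety = "CA",
                      x = 4 + (0:11) * 2, y = 0.5, z = 0)
  ms <- rotated_pentamer(spoke)
  expect_equal(strand_tilt(ms, z_axis_frame(), list(c(1, 12)))$tilt_mean,
               90, tolerance = 1e-6)

  # degenerate span: skipped with a warning
  expect_warning(
    st2 <- strand_tilt(m, ax, list(c(1, 5), c(200, 210))), "skipped")
  expect_equal(st2$n_skipped, 5)
})

test_that("radial profile reports cylinder radii and channel width", {
  mv <- rotated_pentamer(vertical_chain(12, radius = 6))
  ax <- z_axis_frame()
  pr <- radial_profile(mv, ax, bin_width = 3)
  expect_true(all(abs(pr$mean_radius - 6) < 1e-9))
  expect_true(all(pr$min_radius <= pr$mean_radius &
                    pr$mean_radius <= pr$max_radius))
  # channel = min radius minus the probe allowance
  expect_true(all(abs(pr$channel_radius - (6 - 1.4)) < 1e-9))

  # alternating strand/loop rings oscillate between the two radii
  ring <- function(r, z) data.frame(resno = NA, resid = "VAL",
                                    elety = "CA", x = r, y = 0, z = z)
  tmpl <- do.call(rbind, lapply(0:5, function(i)
    ring(if (i %% 2 == 0) 6 else 9.5, i * 4)))
  tmpl$resno <- seq_len(nrow(tmpl))
  mo <- rotated_pentamer(tmpl)
  pro <- radial_profile(mo, z_axis_frame(), bin_width = 4)
  expect_equal(pro$mean_radius, rep(c(6, 9.5), 3), tolerance = 1e-9)

  # two coincident atoms per chain: single bin with min = max
  pt <- data.frame(resno = 1:2, resid = "VAL", elety = "CA",
                   x = 5, y = 0, z = 0)
  prp <- radial_profile(rotated_pentamer(pt),
                        structure(list(point = c(0, 0, 0),
                                       direction = c(0, 0, 1),
                                       order = 5, angle_deg = 72,
                                       mean_rotation_error = 0),
                                  class = "axis_frame"),
                        bin_width = 3)
  expect_equal(nrow(prp), 1)
  expect_equal(prp$min_radius, prp$max_radius)
})

test_that("geometry measurements are invariant under rigid transforms", {
  set.seed(48)
  m <- gen_pentamer_coords(4, noise_sd = 0.1, seed = 8)
  tr <- attr(m, "truth")
  ax <- fit_cyclic_axis(m)
  rp <- rise_per_repeat(m, ax, tr$repeat_starts)
  st <- strand_tilt(m, ax, tr$strand_spans)
  pr <- radial_profile(m, ax, bin_width = 3)
  tf <- random_rigid_transform()
  mt <- apply_rigid(m, tf)
  axt <- fit_cyclic_axis(mt)
  expect_equal(rise_per_repeat(mt, axt, tr$repeat_starts)$rise_mean,
               rp$rise_mean, tolerance = 1e-6)
  expect_equal(strand_tilt(mt, axt, tr$strand_spans)$tilt_mean,
               st$tilt_mean, tolerance = 1e-6)
  # bin boundaries shift with the frame, so compare bin-independent
  # summaries: atom-weighted mean radius and the radial extremes
  prt <- radial_profile(mt, axt, bin_width = 3)
  expect_equal(sum(prt$mean_radius * prt$n) / sum(prt$n),
               sum(pr$mean_radius * pr$n) / sum(pr$n), tolerance = 1e-6)
  expect_equal(min(prt$min_radius), min(pr$min_radius), tolerance = 1e-4)
  expect_equal(max(prt$max_radius), max(pr$max_radius), tolerance = 1e-4)
})

test_that("hydrogen bonds follow the distance and angle cutoffs", {
  # donor N (chain A, residue 2) with its inferred amide H pointing at
  # the acceptor O (chain B, residue 1) placed at the requested distance
  mk <- function(no_dist) {
    a <- data.frame(
      resno = c(1, 1, 1, 1, 2, 2, 2, 2), resid = "VAL",
      elety = rep(c("N", "CA", "C", "O"), 2),
      x = c(0, 1.4, 2.4, 2.4, 4, 5.4, 6.4, 6.4),
      y = c(0, -0.5, -0.8, -2, 0, -0.8, 0, -2),
      z = 0)
    b <- a
    b$y <- b$y + 6
    b[b$resno == 1 & b$elety == "O", c("x", "y", "z")] <-
      c(4, no_dist, 0)
    filler <- function(x0) data.frame(resno = 1:2, resid = "GLY",
                                      elety = "CA", x = x0,
                                      y = -30, z = 0:1)
    pentamer_model(list(A = a, B = b, C = filler(10), D = filler(20),
                        E = filler(30)))
  }
  hb <- mainchain_hbonds(mk(2.9))
  expect_equal(nrow(hb$bonds), 1)
  expect_equal(hb$bonds$donor_chain, "A")
  expect_equal(hb$bonds$acceptor_chain, "B")
  expect_true(hb$bonds$interchain)
  expect_equal(hb$bonds$distance, 2.9, tolerance = 1e-6)

  expect_equal(nrow(mainchain_hbonds(mk(5.0))$bonds), 0)

  # Calpha-only model: capability error
  mca <- gen_pentamer_coords(2, seed = 9)
  expect_error(mainchain_hbonds(mca), "Calpha-only")
})

test_that("interchain bond bookkeeping reports partner chains", {
  m <- gen_pentamer_coords(3, with_backbone = TRUE, seed = 10)
  tr <- attr(m, "truth")
  hb <- mainchain_hbonds(m, strand_spans = tr$strand_spans)
  expect_true(is.data.frame(hb$strand_counts))
  expect_equal(nrow(hb$strand_counts), 5 * length(tr$strand_spans))
  expect_true(all(hb$strand_counts$n_interchain >= 0))
})

test_that("inward and outward side chains are classified radially", {
  with_cb <- function(cb_r) {
    tm <- vertical_chain(12, radius = 6)
    cb <- tm
    cb$elety <- "CB"
    cb$x <- cb_r
    rbind(tm, cb)
  }
  ax <- structure(list(point = c(0, 0, 0), direction = c(0, 0, 1),
                       order = 5, angle_deg = 72,
                       mean_rotation_error = 0), class = "axis_frame")
  m_in <- rotated_pentamer(with_cb(4.5))   # CB closer to the axis
  lab <- inward_facing_residues(m_in, ax, anchor_positions = c(1, 4))
  expect_true(all(lab$labels$label == "inward"))
  expect_equal(lab$anchor_inward_fraction, 1)

  m_out <- rotated_pentamer(with_cb(7.5))  # CB away from the axis
  lab2 <- inward_facing_residues(m_out, ax, anchor_positions = c(1, 4))
  expect_true(all(lab2$labels$label == "outward"))
  expect_equal(lab2$anchor_inward_fraction, 0)

  # glycine without CB is undetermined
  tm <- vertical_chain(12, radius = 6)
  tm$resid <- "GLY"
  lab3 <- inward_facing_residues(rotated_pentamer(tm), ax)
  expect_true(all(lab3$labels$label == "undetermined"))
})

test_that("PDB round trip preserves the model", {
  f <- tempfile(fileext = ".pdb")
  m <- gen_pentamer_coords(3, noise_sd = 0.2, seed = 11)
  write_pentamer_pdb(m, f)
  m2 <- read_structure(f)
  expect_equal(names(m2$chains), c("A", "B", "C", "D", "E"))
  expect_equal(
    vapply(m2$chains, function(ch) length(unique(ch$resno)), integer(1)),
    vapply(m$chains, function(ch) length(unique(ch$resno)), integer(1)))
  expect_equal(m2$chains$A$x, m$chains$A$x, tolerance = 1e-3)

  # a sixth short peptide chain is dropped in favour of the 5 largest
  txt <- readLines(f)
  extra <- sprintf(
    "ATOM  %5d  CA  GLY F%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    9001:9003, 1:3, c(50, 53, 56), 0, 0)
  writeLines(c(txt[txt != "END"], extra, "END"), f)
  m3 <- read_structure(f)
  expect_equal(names(m3$chains), c("A", "B", "C", "D", "E"))

  # fewer than five chains is an input error listing the census
  short <- txt[grepl("^ATOM", txt)]
  short <- short[substr(short, 22, 22) %in% c("A", "B")]
  writeLines(c(short, "END"), f)
  expect_error(read_structure(f), ">= 5 chains")
})
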