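# Period-8 beta-bracelet consensus scanning and domain segmentation.

split_residues <- function(sequence) {
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!(res %in% AA20))
  if (length(bad))
    stop("non-amino-acid character '", res[bad[1]],
         "' at position ", bad[1])
  res
}

#' Score one consensus window
#'
#' Scores an 8- or 9-residue window against the beta-bracelet consensus.
#' The constrained positions are the strand anchors P1 and P4, the loop
#' positions P6/P7/P8, and — when a ninth residue is supplied — the
#' trailing anchor P9, which in tandem repeats is the next repeat's P1.
#' The x positions (P2, P3, P5) are wildcards and never lower the score.
#'
#' @param window character scalar of 8 or 9 upper-case one-letter codes.
#' @param mode `"strict"` (literal V/L anchors) or `"relaxed"`
#'   (hydrophobic anchors, widened loop middle).
#' @param classes a [residue_classes()] object.
#'
#' @return A list with `score` (matched constrained positions / total
#'   constrained positions, in `[0, 1]`) and `flags`, a logical vector of
#'   the window length holding the per-position match outcome (`NA` at
#'   unconstrained positions).
#'
#' @examples
#' match_repeat_window("VSTVSKEDV", "strict")$score   # 1.0
#' match_repeat_window("ISTVSKEDV", "relaxed")$score  # 1.0
#' @export
match_repeat_window <- function(window, mode = c("strict", "relaxed"),
                                classes = residue_classes()) {
  mode <- match.arg(mode)
  res <- split_residues(window)
  n <- length(res)
  if (!(n %in% c(8L, 9L)))
    stop("window must have 8 or 9 residues, got ", n)
  pc <- position_classes(classes, mode)
  pos <- c(1L, 4L, 6L, 7L, 8L)
  cls <- pc[c("p1", "p4", "p6", "p7", "p8")]
  if (n == 9L) {
    pos <- c(pos, 9L)
    cls <- c(cls, pc["p9"])
  }
  flags <- rep(NA, n)
  ok <- mapply(function(p, set) res[p] %in% set, pos, cls)
  flags[pos] <- ok
  list(score = sum(ok) / length(ok), flags = flags)
}

# Does the full 8-residue window starting at i match in `mode`?
# The trailing anchor is not part of a repeat's own window: for internal
# repeats of a run it is enforced as the next repeat's P1, and the paper's
# repeat runs end against non-consensus sequence (the strict consensus
# "stops" at the domain boundary), so the residue after a run's last
# repeat is never constrained.
full_match_at <- function(res, i, pc) {
  res[i] %in% pc$p1 && res[i + 3L] %in% pc$p4 &&
    res[i + 5L] %in% pc$p6 && res[i + 6L] %in% pc$p7 &&
    res[i + 7L] %in% pc$p8
}

strand_match_at <- function(res, i, pc) {
  res[i] %in% pc$p1 && res[i + 3L] %in% pc$p4
}

strict_window_score <- function(res, i, classes) {
  pc <- position_classes(classes, "strict")
  L <- length(res)
  if (i + 7L <= L) {
    ok <- c(res[i] %in% pc$p1, res[i + 3L] %in% pc$p4,
            res[i + 5L] %in% pc$p6, res[i + 6L] %in% pc$p7,
            res[i + 7L] %in% pc$p8)
  } else {
    ok <- c(res[i] %in% pc$p1, res[i + 3L] %in% pc$p4)
  }
  sum(ok) / length(ok)
}

#' Scan a protein sequence for tandem beta-bracelet repeats
#'
#' Finds runs of period-8 repeats matching the strict or relaxed
#' consensus. Within a run, consecutive repeat starts differ by exactly 8
#' residues; every repeat must match all constrained positions of its
#' mode. A terminal repeat whose five-residue strand fits but whose loop
#' is truncated by the sequence end extends its run with `loop_start` and
#' `loop_end` absent (`NA`). Runs with fewer than `min_run` repeats are
#' discarded; when candidate runs on different lattices overlap, the
#' longest run wins, ties broken by the smaller start index.
#'
#' @param sequence protein sequence (character scalar, one-letter codes).
#' @param mode `"strict"` or `"relaxed"`.
#' @param classes a [residue_classes()] object.
#' @param min_run minimum number of repeats per reported run. The default
#'   2 suppresses isolated chance matches in de-novo scans; use 1 when
#'   annotating regions already known to contain repeats.
#'
#' @return A data frame of class `repeat_units` with one row per repeat:
#'   `start`, `end`, `strand_start`, `strand_end`, `loop_start`,
#'   `loop_end` (NA when the loop is truncated), `mode`, `score` (the
#'   strict-consensus score of the window, 1.0 for every strict-mode
#'   repeat) and `run` (run identifier).
#'
#' @examples
#' scan_repeats(strrep("VSTVSKED", 2), "strict", min_run = 1)
#' @export
scan_repeats <- function(sequence, mode = c("strict", "relaxed"),
                         classes = residue_classes(), min_run = 2L) {
  mode <- match.arg(mode)
  if (!nzchar(sequence))
    stop("sequence must be non-empty")
  res <- split_residues(sequence)
  L <- length(res)
  if (L < 8L)
    stop("sequence must have at least 8 residues, got ", L)
  if (min_run < 1L)
    stop("min_run must be >= 1")
  pc <- position_classes(classes, mode)

  full <- rep(FALSE, L)
  for (i in seq_len(L - 7L)) full[i] <- full_match_at(res, i, pc)

  # assemble maximal period-8 runs of full matches
  runs <- list()
  for (i in which(full)) {
    if (i > 8L && full[i - 8L]) next  # not a run head
    starts <- i
    j <- i + 8L
    while (j <= L - 7L && full[j]) {
      starts <- c(starts, j)
      j <- j + 8L
    }
    truncated <- FALSE
    # terminal strand whose loop is cut by the sequence end
    if (j + 4L - 1L <= L && j + 7L > L && strand_match_at(res, j, pc)) {
      starts <- c(starts, j)
      truncated <- TRUE
    }
    last <- starts[length(starts)]
    runs[[length(runs) + 1L]] <- list(
      starts = starts, truncated = truncated,
      span = c(starts[1L], if (truncated) last + 4L else last + 7L))
  }
  runs <- Filter(function(r) length(r$starts) >= min_run, runs)

  # longest run wins on overlap, ties to the leftmost
  ord <- order(-vapply(runs, function(r) length(r$starts), integer(1)),
               vapply(runs, function(r) r$span[1L], numeric(1)))
  runs <- runs[ord]
  chosen <- list()
  occupied <- rep(FALSE, L)
  for (r in runs) {
    idx <- seq(r$span[1L], r$span[2L])
    if (!any(occupied[idx])) {
      occupied[idx] <- TRUE
      chosen[[length(chosen) + 1L]] <- r
    }
  }
  if (length(chosen) == 0L) return(empty_repeat_units())
  chosen <- chosen[order(vapply(chosen, function(r) r$span[1L],
                                numeric(1)))]

  rows <- do.call(rbind, lapply(seq_along(chosen), function(k) {
    r <- chosen[[k]]
    n <- length(r$starts)
    data.frame(
      start = r$starts,
      end = ifelse(seq_len(n) == n & r$truncated,
                   r$starts + 4L, r$starts + 7L),
      strand_start = r$starts,
      strand_end = r$starts + 4L,
      loop_start = ifelse(seq_len(n) == n & r$truncated,
                          NA_integer_, r$starts + 5L),
      loop_end = ifelse(seq_len(n) == n & r$truncated,
                        NA_integer_, r$starts + 7L),
      mode = mode,
      score = vapply(r$starts, strict_window_score, numeric(1),
                     res = res, classes = classes),
      run = k)
  }))
  class(rows) <- c("repeat_units", "data.frame")
  rows
}

empty_repeat_units <- function() {
  rows <- data.frame(start = integer(0), end = integer(0),
                     strand_start = integer(0), strand_end = integer(0),
                     loop_start = integer(0), loop_end = integer(0),
                     mode = character(0), score = numeric(0),
                     run = integer(0))
  class(rows) <- c("repeat_units", "data.frame")
  rows
}

#' Assign a heptad coiled-coil register
#'
#' Chooses the heptad register phase, and at most one single-residue
#' insertion (stutter), that best explains a helical span: the objective
#' is the number of `a`/`d` positions occupied by hydrophobic residues.
#' A stutter pauses the register for one residue (labelled `"-"`), so a
#' kinked helix with one extra residue keeps its hydrophobic seam in
#' frame on both sides of the kink. The insertion is reported only when
#' it improves the a/d hydrophobic count by at least `margin`.
#'
#' @param sequence protein sequence (character scalar).
#' @param helix_span integer length-2 vector, 1-based inclusive residue
#'   range of the helix; must cover at least two heptads (14 residues).
#' @param scale named numeric hydropathy scale; defaults to
#'   Kyte–Doolittle. Residues with positive hydropathy other than
#'   alanine count as hydrophobic for the objective; the summed
#'   hydropathy at a/d breaks ties between phases.
#' @param margin minimum improvement in the a/d hydrophobic count for an
#'   insertion to be accepted (default 2).
#'
#' @return List of class `heptad_assignment`: `helix_span`, `register`
#'   (per-residue letters a–g, `"-"` at an insertion), and
#'   `insertion_positions` (1-based sequence indices, possibly empty),
#'   plus the achieved `ad_hydrophobic_count` and starting `phase`.
#' @export
assign_heptad <- function(sequence, helix_span,
                          scale = kyte_doolittle(), margin = 2L) {
  res <- split_residues(sequence)
  if (length(helix_span) != 2L || helix_span[1] < 1L ||
      helix_span[2] > length(res) || helix_span[1] > helix_span[2])
    stop("helix_span must be an increasing 1-based range within the sequence")
  span <- seq(helix_span[1], helix_span[2])
  if (length(span) < 14L)
    stop("helix span must cover at least two heptads (14 residues), got ",
         length(span))
  hres <- res[span]
  hydro <- names(scale)[scale > 0]
  hydro <- setdiff(hydro, "A")

  register_for <- function(phase, ins_local) {
    # ins_local: local index of the inserted residue, or 0 for none
    reg <- character(length(hres))
    idx <- phase
    for (i in seq_along(hres)) {
      if (i == ins_local) {
        reg[i] <- "-"
      } else {
        reg[i] <- letters[(idx %% 7L) + 1L]
        idx <- idx + 1L
      }
    }
    reg
  }
  objective <- function(reg) {
    ad <- reg %in% c("a", "d")
    c(count = sum(ad & hres %in% hydro),
      hyd = sum(scale[hres[ad]]))
  }

  best <- function(ins_candidates) {
    top <- NULL
    for (ins in ins_candidates) {
      for (phase in 0:6) {
        reg <- register_for(phase, ins)
        ob <- objective(reg)
        key <- unname(c(ob["count"], ob["hyd"], -phase, -ins))
        if (is.null(top) || lexi_gt(key, top$key)) {
          top <- list(reg = reg, phase = phase, ins = ins,
                      count = ob[["count"]], key = key)
        }
      }
    }
    top
  }
  no_ins <- best(0L)
  with_ins <- best(seq(2L, length(hres) - 1L))
  use_ins <- with_ins$count >= no_ins$count + margin
  pick <- if (use_ins) with_ins else no_ins
  structure(list(
    helix_span = helix_span,
    register = pick$reg,
    insertion_positions = if (use_ins) span[pick$ins] else integer(0),
    ad_hydrophobic_count = pick$count,
    phase = pick$phase), class = "heptad_assignment")
}

# lexicographic greater-than on numeric keys
lexi_gt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

#' Kyte–Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 amino acids.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
    E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
    M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
    Y = -1.3, V = 4.2)
}

#' Segment a delta-like sequence into fiber domains
#'
#' Combines a strict and a relaxed repeat scan of the same sequence into
#' the canonical five-domain organisation of the delta fiber protein:
#' an N-terminal coiled coil, a first (strict-consensus) bracelet region,
#' an internal globular domain, a second (relaxed-consensus) bracelet
#' region, and a C-terminal globular head. All coordinates are 1-based
#' inclusive; empty domains are `NULL`.
#'
#' @param sequence the protein sequence that both scans were run on.
#' @param strict_repeats,relaxed_repeats `repeat_units` data frames from
#'   [scan_repeats()] in the respective mode.
#'
#' @return List of class `domain_annotation` with elements
#'   `coiled_coil`, `bracelet_region_1`, `internal_globular`,
#'   `bracelet_region_2`, `c_terminal_globular` (each `c(start, end)` or
#'   `NULL`), `repeats` (the combined repeat table) and `no_repeats`
#'   (TRUE, with a warning, when neither scan found anything).
#' @export
segment_domains <- function(sequence, strict_repeats, relaxed_repeats) {
  L <- length(split_residues(sequence))
  rng <- function(a, b) if (!is.na(a) && !is.na(b) && a <= b) c(a, b) else NULL

  r1 <- NULL
  if (nrow(strict_repeats) > 0)
    r1 <- c(min(strict_repeats$start), max(strict_repeats$end))

  after <- relaxed_repeats
  if (!is.null(r1)) after <- after[after$start > r1[2], , drop = FALSE]
  r2 <- if (nrow(after) > 0) c(min(after$start), max(after$end)) else NULL

  no_repeats <- is.null(r1) && is.null(r2)
  if (no_repeats)
    warning("no repeats found; bracelet regions are empty")

  first_start <- min(c(r1[1], r2[1], Inf))
  last_end <- max(c(r1[2], r2[2], -Inf))
  cc <- if (is.finite(first_start) && first_start > 1)
    c(1L, first_start - 1L) else NULL
  tail_dom <- if (is.finite(last_end) && last_end < L)
    c(last_end + 1L, L) else NULL
  internal <- if (!is.null(r1) && !is.null(r2) && r2[1] > r1[2] + 1)
    c(r1[2] + 1L, r2[1] - 1L) else NULL

  reps <- rbind(strict_repeats, after)
  structure(list(
    coiled_coil = cc,
    bracelet_region_1 = r1,
    internal_globular = internal,
    bracelet_region_2 = r2,
    c_terminal_globular = tail_dom,
    repeats = reps,
    sequence_length = L,
    no_repeats = no_repeats), class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat("Delta fiber domain annotation (", x$sequence_length,
      " residues)\n", sep = "")
  show <- function(nm, r)
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(r)) "-" else paste(r[1], r[2], sep = "-")))
  show("coiled_coil", x$coiled_coil)
  show("bracelet_region_1", x$bracelet_region_1)
  show("internal_globular", x$internal_globular)
  show("bracelet_region_2", x$bracelet_region_2)
  show("c_terminal_globular", x$c_terminal_globular)
  cat("  repeats:", nrow(x$repeats), "\n")
  invisible(x)
}
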