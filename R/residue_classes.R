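#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Residue classes for beta-bracelet consensus matching
#'
#' Defines the residue sets used to score the period-8 beta-bracelet
#' consensus. One repeat is a five-residue strand followed by a
#' three-residue loop. Within the printed nine-position consensus
#' `(V/L) x x V x x x x V` the anchors sit at strand positions P1 and P4
#' and at P9, which is the next repeat's P1; the loop consensus is
#' `y (E/D/N) y` with y a charged residue at P6/P8.
#'
#' Strict mode enforces the valine/leucine anchors literally; relaxed
#' mode uses a generic hydrophobic anchor class (the "phi" positions of
#' the variable form of the consensus) and widens the permitted loop
#' middle. The x positions (P2, P3, P5) are unconstrained in both modes:
#' the stated tendencies ("often small, polar or charged") are
#' preferences, not rules, and enforcing them would reject genuine
#' repeats.
#'
#' @param strict_anchor_p1 residues accepted at P1 in strict mode.
#' @param strict_anchor_p4 residues accepted at P4 (and P9) in strict mode.
#' @param relaxed_anchor hydrophobic residues accepted at P1/P4/P9 in
#'   relaxed mode.
#' @param loop_flank charged residues accepted at loop positions P6 and P8.
#' @param loop_middle_strict residues accepted at P7 in strict mode.
#' @param loop_middle_relaxed residues accepted at P7 in relaxed mode.
#'
#' @return An object of class `residue_classes`.
#'
#' @details Invariants are checked on construction: the strict anchor
#'   sets must be subsets of `relaxed_anchor` and the strict loop middle
#'   a subset of the relaxed one, which guarantees that every strict
#'   match is also a relaxed match; all sets must be non-empty subsets of
#'   the 20-letter amino-acid alphabet.
#'
#' @examples
#' cls <- residue_classes()
#' cls$relaxed_anchor
#' @export
residue_classes <- function(strict_anchor_p1 = c("V", "L"),
                            strict_anchor_p4 = "V",
                            relaxed_anchor = c("A", "V", "L", "I", "M",
                                               "F", "W", "Y", "C"),
                            loop_flank = c("D", "E", "K", "R", "H"),
                            loop_middle_strict = c("E", "D", "N"),
                            loop_middle_relaxed = union(
                              loop_flank, c("N", "Q", "S", "T"))) {
  sets <- list(strict_anchor_p1 = strict_anchor_p1,
               strict_anchor_p4 = strict_anchor_p4,
               relaxed_anchor = relaxed_anchor,
               loop_flank = loop_flank,
               loop_middle_strict = loop_middle_strict,
               loop_middle_relaxed = loop_middle_relaxed)
  for (nm in names(sets)) {
    s <- toupper(sets[[nm]])
    if (length(s) == 0L)
      stop("residue class '", nm, "' must be non-empty")
    bad <- setdiff(s, AA20)
    if (length(bad))
      stop("residue class '", nm, "' contains non-amino-acid codes: ",
           paste(bad, collapse = ", "))
    sets[[nm]] <- s
  }
  if (!all(sets$strict_anchor_p1 %in% sets$relaxed_anchor) ||
      !all(sets$strict_anchor_p4 %in% sets$relaxed_anchor))
    stop("strict anchor classes must be subsets of relaxed_anchor ",
         "(otherwise strict matches are not a subset of relaxed matches)")
  if (!all(sets$loop_middle_strict %in% sets$loop_middle_relaxed))
    stop("loop_middle_strict must be a subset of loop_middle_relaxed")
  structure(sets, class = "residue_classes")
}

#' @export
print.residue_classes <- function(x, ...) {
  cat("Beta-bracelet residue classes\n")
  for (nm in names(x))
    cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = "")))
  invisible(x)
}

# Per-mode class lookup for the constrained window positions
# (P1, P4, P6, P7, P8, P9). Internal.
position_classes <- function(classes, mode) {
  if (mode == "strict") {
    list(p1 = classes$strict_anchor_p1,
         p4 = classes$strict_anchor_p4,
         p6 = classes$loop_flank,
         p7 = classes$loop_middle_strict,
         p8 = classes$loop_flank,
         p9 = classes$strict_anchor_p4)
  } else {
    list(p1 = classes$relaxed_anchor,
         p4 = classes$relaxed_anchor,
         p6 = classes$loop_flank,
         p7 = classes$loop_middle_relaxed,
         p8 = classes$loop_flank,
         p9 = classes$relaxed_anchor)
  }
}
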