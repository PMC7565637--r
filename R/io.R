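# File interfaces: FASTA in/out, annotation tables as TSV/JSON, PDB out.

#' Read a multi-record FASTA file
#'
#' @param path FASTA file. The first whitespace-delimited word of each
#'   header is used as the sequence ID.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("writing FASTA requires the Biostrings package")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Flatten repeats and domains into an annotation table
#'
#' @param annotation a `domain_annotation` from [segment_domains()] or a
#'   `repeat_units` table from [scan_repeats()].
#' @param seq_id sequence identifier for the first column.
#' @return Data frame with columns `seq_id`, `start`, `end`,
#'   `element_type`, `mode`, `score` (1-based inclusive coordinates).
#' @export
annotation_table <- function(annotation, seq_id = "seq") {
  rows <- NULL
  add <- function(start, end, type, mode = NA_character_,
                  score = NA_real_)
    rbind(rows, data.frame(seq_id = seq_id, start = start, end = end,
                           element_type = type, mode = mode,
                           score = score))
  if (inherits(annotation, "repeat_units")) {
    reps <- annotation
  } else if (inherits(annotation, "domain_annotation")) {
    for (nm in c("coiled_coil", "bracelet_region_1", "internal_globular",
                 "bracelet_region_2", "c_terminal_globular")) {
      r <- annotation[[nm]]
      if (!is.null(r)) rows <- add(r[1], r[2], nm)
    }
    reps <- annotation$repeats
  } else stop("unsupported annotation object")
  if (!is.null(reps) && nrow(reps) > 0)
    for (i in seq_len(nrow(reps)))
      rows <- add(reps$start[i], reps$end[i], "repeat", reps$mode[i],
                  reps$score[i])
  rows
}

#' Write an annotation table as TSV
#'
#' @inheritParams annotation_table
#' @param path output file.
#' @export
write_annotation_tsv <- function(annotation, path, seq_id = "seq") {
  utils::write.table(annotation_table(annotation, seq_id), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an annotation table as JSON
#'
#' @inheritParams annotation_table
#' @param path output file.
#' @export
write_annotation_json <- function(annotation, path, seq_id = "seq") {
  jsonlite::write_json(annotation_table(annotation, seq_id), path,
                       dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Write a pentamer model to a PDB file
#'
#' @param model a `pentamer_model`.
#' @param path output PDB file.
#' @export
write_pentamer_pdb <- function(model, path) {
  stopifnot(inherits(model, "pentamer_model"))
  at <- do.call(rbind, lapply(names(model$chains), function(id) {
    ch <- model$chains[[id]]
    ch$chain <- id
    ch
  }))
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   elety = at$elety)
  invisible(path)
}
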