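## Plain-text writers for the pipeline's standard artifacts.

#' Write an alignment as aligned FASTA
#' @param alignment an [msa].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(alignment, path) {
  seqs <- apply(alignment$seqs, 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- alignment$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write sequences as FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sequences_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a toy complex as a PDB file
#'
#' ATOM records with occupancy 1.00 and B-factor 0.00, suitable for
#' round-tripping through [read_structure()].
#'
#' @param structure a `complex_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(structure, path) {
  at <- structure$atoms
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno,
                   chain = at$chain, resid = at$resname, elety = at$atom,
                   elesy = at$element, o = rep(1, nrow(at)),
                   b = rep(0, nrow(at)))
  invisible(path)
}

#' Write a profile matrix as TSV (species rows, component columns)
#' @param matrix a `profile_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(matrix, path) {
  df <- data.frame(species = rownames(matrix), unclass(matrix),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a conservation track as TSV
#' @param track a `conservation_track`.
#' @param path output file.
#' @param mapping optional `reference_mapping`; adds a `ref_pos` column.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path, mapping = NULL) {
  df <- as.data.frame(track)
  if (!is.null(mapping))
    df$ref_pos <- mapping$ref_pos[match(df$column, mapping$column)]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a ground-truth sidecar as JSON
#' @param truth any of the generator truth objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  x$alignment <- NULL
  x$structure <- NULL
  x$matrix <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
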