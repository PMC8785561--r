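## Proline-rich motif screen. The five motifs are literal wildcard
## patterns ('x' = any amino acid); matching is exact and reports all
## overlapping occurrences.

#' The five proline-rich motif patterns
#'
#' PPRxxP, PPPPP, PxPPxR, PPLP and PPxY, where `x` matches any amino
#' acid. These short linear motifs mediate protein-protein interactions
#' and occur in the C-terminal tails of human-like homologs of
#' RRM-containing splicing factors.
#'
#' @return data frame with columns `name` and `pattern`.
#' @export
default_motifs <- function() {
  pats <- c("PPRxxP", "PPPPP", "PxPPxR", "PPLP", "PPxY")
  data.frame(name = pats, pattern = pats)
}

motif_regex <- function(pattern) {
  chartr("x", ".", pattern)
}

#' Scan a sequence region for motif occurrences
#'
#' Reports every (overlapping) occurrence of every motif whose full span
#' lies inside the region, sorted by (start, motif name).
#'
#' @param sequence amino-acid string.
#' @param region `c(start, end)`, 1-based inclusive (default: full
#'   sequence).
#' @param motifs data frame as from [default_motifs()].
#' @param id optional sequence id carried into the result.
#' @return data frame `id`, `motif`, `start`, `end`, `match`.
#' @export
scan_motifs <- function(sequence, region = NULL, motifs = default_motifs(),
                        id = NA_character_) {
  n <- nchar(sequence)
  if (is.null(region)) region <- c(1L, n)
  if (!(length(region) == 2L && region[1] >= 1 && region[1] <= region[2] &&
        region[2] <= n))
    stop("invalid region [", paste(region, collapse = ", "),
         "] for sequence of length ", n, call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(motifs))) {
    len <- nchar(motifs$pattern[i])
    rx <- paste0("(?=", motif_regex(motifs$pattern[i]), ")")
    starts <- gregexpr(rx, sequence, perl = TRUE)[[1L]]
    starts <- starts[starts > 0]
    starts <- starts[starts >= region[1] & starts + len - 1L <= region[2]]
    if (length(starts))
      out[[length(out) + 1L]] <- data.frame(
        id = id, motif = motifs$name[i], start = as.integer(starts),
        end = as.integer(starts + len - 1L),
        match = substring(sequence, starts, starts + len - 1L))
  }
  if (!length(out))
    return(data.frame(id = character(), motif = character(),
                      start = integer(), end = integer(),
                      match = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$motif), ]
  rownames(res) <- NULL
  res
}

#' Classify one homolog from its motif hits
#'
#' `human_like_motif` when at least one motif hit was found in the
#' searched region; `human_like_disorder` when there is no hit but an
#' external disorder annotation marks the region disordered;
#' `yeast_like` otherwise.
#'
#' @param hits data frame of hits for one sequence (as from
#'   [scan_motifs()]).
#' @param disorder logical disorder annotation (default FALSE; never
#'   computed, only consumed).
#' @return classification string.
#' @export
classify_homolog <- function(hits, disorder = FALSE) {
  if (nrow(hits) && length(unique(hits$id[!is.na(hits$id)])) > 1L)
    stop("hits belong to more than one sequence", call. = FALSE)
  if (nrow(hits) > 0) "human_like_motif"
  else if (isTRUE(disorder)) "human_like_disorder"
  else "yeast_like"
}

#' Scan and classify a batch of homolog sequences
#'
#' Scans each sequence's annotated region (typically the C-terminal tail
#' downstream of the last structured domain) for the proline-rich motifs
#' and classifies it. Sequences without a region row are reported as
#' `unscanned`, never silently skipped; a region outside the sequence
#' bounds is a per-record error that does not stop the run.
#'
#' @param sequences named character vector of amino-acid sequences, or a
#'   FASTA file path.
#' @param regions data frame `id`, `start`, `end` (1-based inclusive).
#' @param taxa optional data frame `id`, `taxon` (default: one group
#'   `all`).
#' @param disorder optional data frame `id`, `disordered` (logical).
#' @param motifs motif set (default [default_motifs()]).
#' @return list with `classifications` (data frame `id`, `taxon`,
#'   `class`, `n_hits`, `note`), `hits` (all hits), `proportions`
#'   (per-taxon class proportions) and `counts` (totals reconciling with
#'   the input count).
#' @export
batch_classify <- function(sequences, regions, taxa = NULL, disorder = NULL,
                           motifs = default_motifs()) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    set <- Biostrings::readAAStringSet(sequences)
    sequences <- stats::setNames(as.character(set),
                                 sub("\\s.*$", "", names(set)))
  }
  ids <- names(sequences)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  taxon <- if (is.null(taxa)) stats::setNames(rep("all", length(ids)), ids)
  else stats::setNames(as.character(taxa$taxon), taxa$id)
  dis <- if (is.null(disorder)) stats::setNames(logical(length(ids)), ids)
  else stats::setNames(as.logical(disorder$disordered), disorder$id)
  all_hits <- list()
  cls <- character(length(ids))
  nhits <- integer(length(ids))
  note <- character(length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    r <- regions[regions$id == id, , drop = FALSE]
    if (!nrow(r)) {
      cls[i] <- "unscanned"
      note[i] <- "no region annotation"
      next
    }
    h <- tryCatch(
      scan_motifs(sequences[[i]], region = c(r$start[1L], r$end[1L]),
                  motifs = motifs, id = id),
      error = function(e) e)
    if (inherits(h, "error")) {
      cls[i] <- "unscanned"
      note[i] <- conditionMessage(h)
      next
    }
    if (nrow(h)) all_hits[[length(all_hits) + 1L]] <- h
    nhits[i] <- nrow(h)
    d <- dis[id]
    cls[i] <- classify_homolog(h, disorder = !is.na(d) && isTRUE(unname(d)))
  }
  classifications <- data.frame(
    id = ids, taxon = unname(taxon[ids]), class = cls, n_hits = nhits,
    note = note)
  classifications$taxon[is.na(classifications$taxon)] <- "unknown"
  hits <- if (length(all_hits)) do.call(rbind, all_hits)
  else data.frame(id = character(), motif = character(), start = integer(),
                  end = integer(), match = character())
  lvls <- c("human_like_motif", "human_like_disorder", "yeast_like",
            "unscanned")
  tab <- table(factor(classifications$taxon),
               factor(classifications$class, levels = lvls))
  prop <- sweep(tab, 1L, rowSums(tab), "/")
  counts <- stats::setNames(as.integer(colSums(tab)), lvls)
  stopifnot(sum(counts) == length(ids))
  list(classifications = classifications, hits = hits,
       proportions = as.data.frame.matrix(prop), counts = counts)
}
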