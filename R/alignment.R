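#' Construct a multiple sequence alignment object
#'
#' The container for gapped homolog sequences of one complex component.
#' Sequences are stored as a character matrix (rows = records, columns =
#' alignment columns) over the 20 amino acids, the gap character `-` and
#' the unknown character `X`.
#'
#' @param seqs character vector of gapped sequences (equal length) or a
#'   character matrix with one row per record.
#' @param ids unique record identifiers.
#' @param taxon optional per-record taxon labels.
#' @return an object of class `msa`.
#' @export
msa <- function(seqs, ids = NULL, taxon = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
    if (is.null(ids)) ids <- rownames(m)
  } else {
    if (is.null(ids)) ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("seq%03d", seq_along(seqs))
    seqs <- toupper(seqs)
    seqs <- gsub(".", "-", seqs, fixed = TRUE)
    w <- nchar(seqs)
    if (length(unique(w)) != 1L)
      stop("ragged alignment: sequences have unequal lengths (",
           paste(unique(w), collapse = ", "), ")", call. = FALSE)
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  if (is.null(ids)) ids <- sprintf("seq%03d", seq_len(nrow(m)))
  if (nrow(m) < 2L) stop("an alignment needs >= 2 records", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(as.vector(m)), c(AMINO_ACIDS, GAP_CHAR, UNKNOWN_CHAR))
  if (length(bad))
    stop("characters outside the alignment alphabet: ",
         paste(bad, collapse = " "), call. = FALSE)
  all_unknown <- apply(m, 2L, function(col) all(col == UNKNOWN_CHAR))
  if (any(all_unknown))
    stop("column(s) entirely unknown ('X'): ",
         paste(which(all_unknown), collapse = ", "), call. = FALSE)
  rownames(m) <- ids
  structure(list(seqs = m, ids = as.character(ids), taxon = taxon),
            class = "msa")
}

#' Read an aligned FASTA file
#'
#' Lowercase letters are uppercased and `.` is treated as the gap
#' character. Ragged records, duplicate ids, an empty file and characters
#' outside the alphabet each raise a distinct error.
#'
#' @param path path to an aligned-FASTA file.
#' @return an [msa] object.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  msa(as.character(set), ids = ids)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("Multiple sequence alignment: %d records x %d columns\n",
              nrow(x$seqs), ncol(x$seqs)))
  invisible(x)
}

#' @export
dim.msa <- function(x) dim(x$seqs)

#' @rdname msa
#' @param x an `msa` object.
#' @param ... unused.
#' @export
as.matrix.msa <- function(x, ...) x$seqs

#' Position-based (Henikoff) sequence weights
#'
#' In each column every distinct residue type present receives mass
#' `1/(r*s)` where `r` is the number of distinct residue types in the
#' column and `s` the number of sequences carrying that type; gaps and
#' unknowns contribute no mass. Per-sequence sums are normalized to 1.
#'
#' @param alignment an [msa] object.
#' @return numeric weight vector (one per record, summing to 1).
#' @export
henikoff_weights <- function(alignment) {
  m <- alignment$seqs
  n <- nrow(m)
  raw <- numeric(n)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    keep <- col != GAP_CHAR & col != UNKNOWN_CHAR
    if (!any(keep)) next
    tab <- table(col[keep])
    r <- length(tab)
    raw[keep] <- raw[keep] + 1 / (r * as.numeric(tab[col[keep]]))
  }
  if (any(raw == 0))
    stop("record(s) with no residues (all gaps/unknowns): ",
         paste(alignment$ids[raw == 0], collapse = ", "), call. = FALSE)
  w <- raw / sum(raw)
  names(w) <- alignment$ids
  w
}

#' Weighted amino-acid distribution of one alignment column
#'
#' Weighted frequencies over the 20 amino acids at a column, excluding
#' gaps and unknown residues, plus an optional per-amino-acid pseudocount,
#' renormalized. The gap fraction is the weighted fraction of gap
#' characters ('X' is not a gap). An all-gap column yields the uniform
#' distribution and gap fraction 1.
#'
#' @param alignment an [msa] object.
#' @param column 1-based column index.
#' @param weights per-record weights (default equal); any positive vector
#'   is renormalized.
#' @param pseudocount added to each amino-acid mass before renormalizing.
#' @return list with `p` (named probabilities over [AMINO_ACIDS]) and
#'   `gap_fraction`.
#' @export
column_distribution <- function(alignment, column, weights = NULL,
                                pseudocount = 0) {
  m <- alignment$seqs
  if (!(column >= 1 && column <= ncol(m)))
    stop("column out of range: ", column, call. = FALSE)
  n <- nrow(m)
  if (is.null(weights)) weights <- rep(1 / n, n)
  stopifnot(length(weights) == n, all(weights > 0))
  weights <- weights / sum(weights)
  col <- m[, column]
  gap_fraction <- sum(weights[col == GAP_CHAR])
  counts <- stats::setNames(numeric(20L), AMINO_ACIDS)
  is_aa <- col %in% AMINO_ACIDS
  if (any(is_aa)) {
    agg <- tapply(weights[is_aa], col[is_aa], sum)
    counts[names(agg)] <- agg
  }
  counts <- counts + pseudocount
  tot <- sum(counts)
  p <- if (tot > 0) counts / tot else stats::setNames(rep(1 / 20, 20L), AMINO_ACIDS)
  list(p = p, gap_fraction = unname(gap_fraction))
}

#' BLOSUM62 background amino-acid distribution
#'
#' Marginal amino-acid frequencies derived from the BLOSUM62 substitution
#' table, embedded as constants and renormalized to sum exactly to 1.
#' This is the background (`q`) against which column distributions are
#' compared when scoring conservation.
#'
#' @return named probability vector over [AMINO_ACIDS].
#' @export
blosum62_background <- function() {
  q <- c(A = 0.078, C = 0.024, D = 0.052, E = 0.059, F = 0.044,
         G = 0.083, H = 0.025, I = 0.062, K = 0.056, L = 0.092,
         M = 0.024, N = 0.041, P = 0.043, Q = 0.034, R = 0.051,
         S = 0.059, T = 0.055, V = 0.072, W = 0.014, Y = 0.034)
  q <- q[AMINO_ACIDS]
  q / sum(q)
}

#' Jensen-Shannon divergence between two distributions
#'
#' `JSD = lambda * KL(p || r) + (1 - lambda) * KL(q || r)` with
#' `r = lambda * p + (1 - lambda) * q`, logarithms base 2 and the
#' convention `0 * log 0 = 0`. For `lambda = 0.5` the value lies in
#' \[0, 1\], reaching 1 only for distributions with disjoint support.
#'
#' @param p,q probability vectors on the same support (same length; if
#'   both are named the names must agree).
#' @param lambda mixture weight in (0, 1); default 0.5.
#' @return the divergence (non-negative scalar).
#' @export
js_divergence <- function(p, q, lambda = 0.5) {
  if (length(p) != length(q))
    stop("`p` and `q` must share a support (equal lengths)", call. = FALSE)
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q)))
    stop("`p` and `q` have mismatched supports (names differ)", call. = FALSE)
  if (any(p < 0) || any(q < 0) || abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("`p` and `q` must be probability distributions", call. = FALSE)
  if (!(lambda > 0 && lambda < 1))
    stop("`lambda` must be in (0, 1)", call. = FALSE)
  r <- lambda * p + (1 - lambda) * q
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / r[i]))
  }
  lambda * kl(p) + (1 - lambda) * kl(q)
}

#' Per-column Jensen-Shannon conservation track
#'
#' For each column the weighted amino-acid distribution is compared to the
#' BLOSUM62 background with the Jensen-Shannon divergence (base-2 logs, so
#' scores lie in \[0, 1\]). With `gap_penalty` the raw score is multiplied
#' by `1 - gap_fraction`. The reported (windowed) score averages the raw
#' score with the mean raw score of up to `window` columns on each side of
#' the focal column (focal column excluded, window truncated at the
#' alignment edges; an empty window falls back to the raw score):
#' `windowed = (1 - window_weight) * raw + window_weight * mean(neighbors)`.
#'
#' @param alignment an [msa] object.
#' @param lambda JSD mixture weight (default 0.5).
#' @param window number of columns on each side contributing to the
#'   windowed score (default 3).
#' @param window_weight weight of the window mean (default 0.5).
#' @param pseudocount per-amino-acid pseudocount (default 1e-7).
#' @param gap_penalty multiply raw scores by `1 - gap_fraction`
#'   (default TRUE).
#' @param use_weights use position-based sequence weights (default TRUE);
#'   otherwise equal weights.
#' @param background background distribution (default
#'   [blosum62_background()]).
#' @return a data frame of class `conservation_track` with columns
#'   `column`, `raw_jsd`, `windowed_jsd`, `gap_fraction`; the per-column
#'   amino-acid distributions are attached as attribute `distributions`
#'   (columns x 20 matrix) and the parameters as attribute `params`.
#' @export
jsd_track <- function(alignment, lambda = 0.5, window = 3L,
                      window_weight = 0.5, pseudocount = 1e-7,
                      gap_penalty = TRUE, use_weights = TRUE,
                      background = blosum62_background()) {
  stopifnot(inherits(alignment, "msa"))
  L <- ncol(alignment$seqs)
  w <- if (use_weights) henikoff_weights(alignment) else NULL
  raw <- numeric(L)
  gapf <- numeric(L)
  dists <- matrix(NA_real_, L, 20L, dimnames = list(NULL, AMINO_ACIDS))
  for (j in seq_len(L)) {
    cd <- column_distribution(alignment, j, weights = w,
                              pseudocount = pseudocount)
    d <- js_divergence(cd$p, background, lambda = lambda)
    d <- min(max(d, 0), 1)
    if (gap_penalty) d <- d * (1 - cd$gap_fraction)
    raw[j] <- d
    gapf[j] <- cd$gap_fraction
    dists[j, ] <- cd$p
  }
  windowed <- raw
  if (window > 0 && window_weight > 0) {
    for (j in seq_len(L)) {
      nb <- setdiff(max(1L, j - window):min(L, j + window), j)
      if (length(nb))
        windowed[j] <- (1 - window_weight) * raw[j] +
          window_weight * mean(raw[nb])
    }
  }
  out <- data.frame(column = seq_len(L), raw_jsd = raw,
                    windowed_jsd = windowed, gap_fraction = gapf)
  attr(out, "distributions") <- dists
  attr(out, "params") <- list(lambda = lambda, window = window,
                              window_weight = window_weight,
                              pseudocount = pseudocount,
                              gap_penalty = gap_penalty,
                              use_weights = use_weights)
  class(out) <- c("conservation_track", "data.frame")
  out
}

#' Pairwise sequence identity statistics
#'
#' Per pair of records, identity is `100 * identical columns / columns
#' where both records are non-gap`. Pairs with no co-aligned columns are
#' excluded from the mean and flagged.
#'
#' @param alignment an [msa] object.
#' @return list with `mean_percent` and a data frame `pairs`
#'   (`id_a`, `id_b`, `identity`, `n_coaligned`, `flagged`).
#' @export
pairwise_identity <- function(alignment) {
  m <- alignment$seqs
  n <- nrow(m)
  stopifnot(n >= 2)
  nongap <- m != GAP_CHAR
  res <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- nongap[i, ] & nongap[j, ]
      nco <- sum(both)
      ident <- if (nco > 0) 100 * sum(m[i, both] == m[j, both]) / nco else NA_real_
      k <- k + 1L
      res[[k]] <- data.frame(id_a = alignment$ids[i], id_b = alignment$ids[j],
                             identity = ident, n_coaligned = nco,
                             flagged = nco == 0L)
    }
  }
  pairs <- do.call(rbind, res)
  list(mean_percent = mean(pairs$identity[!pairs$flagged]), pairs = pairs)
}

#' Map reference-sequence positions to alignment columns
#'
#' Builds the bijection between the ungapped positions of one record and
#' the alignment columns where it has a residue, so that annotated sites
#' given in reference numbering (e.g. "Lys700") can be looked up in
#' conservation tracks.
#'
#' @param alignment an [msa] object.
#' @param reference_id id of the reference record.
#' @return data frame of class `reference_mapping` with columns `ref_pos`
#'   and `column`; the reference id is attached as attribute
#'   `reference_id`.
#' @export
map_reference <- function(alignment, reference_id) {
  i <- match(reference_id, alignment$ids)
  if (is.na(i)) stop("unknown reference id: ", reference_id, call. = FALSE)
  row <- alignment$seqs[i, ]
  cols <- which(row != GAP_CHAR)
  out <- data.frame(ref_pos = seq_along(cols), column = cols)
  attr(out, "reference_id") <- reference_id
  class(out) <- c("reference_mapping", "data.frame")
  out
}
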