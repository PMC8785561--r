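## Aggregation of conservation tracks, interface sets and site
## annotations into component-level and site-level summaries.

#' Per-component conservation summary
#'
#' Arithmetic mean of the windowed JSD over all columns (gap-penalized
#' zeros included), mean pairwise identity, and the percentage of the
#' sequence at any inter-component interface.
#'
#' @param track a `conservation_track`.
#' @param identity result of [pairwise_identity()].
#' @param pct_interface percentage from [percent_interface()].
#' @param component component label.
#' @param n_seqs number of aligned homologs.
#' @return one-row data frame: `component`, `mean_windowed_jsd`,
#'   `mean_identity`, `n_seqs`, `alignment_length`, `pct_interface`.
#' @export
protein_summary <- function(track, identity, pct_interface, component,
                            n_seqs) {
  if (!nrow(track)) stop("empty conservation track", call. = FALSE)
  data.frame(component = component,
             mean_windowed_jsd = mean(track$windowed_jsd),
             mean_identity = identity$mean_percent,
             n_seqs = n_seqs,
             alignment_length = nrow(track),
             pct_interface = pct_interface)
}

lookup_jsd <- function(ref_pos, track, mapping) {
  col <- mapping$column[match(ref_pos, mapping$ref_pos)]
  track$windowed_jsd[match(col, track$column)]
}

#' Interface conservation matrix
#'
#' For every ordered (owner, partner) interface the mean windowed JSD
#' over the owner-side interface residues, mapped to alignment columns
#' through the owner's reference mapping. Rows are owner components,
#' columns partners (protein or RNA). Residues without a mapping are
#' reported in `unmapped` and excluded from the mean; an empty cell is
#' NA, not 0.
#'
#' @param interfaces data frame with columns `owner`, `partner`,
#'   `ref_pos` (reference numbering; an `interface_table` whose `resno`
#'   is already in reference numbering is accepted).
#' @param tracks named list of `conservation_track`s by component.
#' @param mappings named list of `reference_mapping`s by component.
#' @return list with `mean_jsd` (matrix), `support` (interface sizes) and
#'   `unmapped` (data frame of residues with no mapped column).
#' @export
interface_conservation_matrix <- function(interfaces, tracks, mappings) {
  ifc <- as.data.frame(interfaces)
  if (!"ref_pos" %in% names(ifc)) ifc$ref_pos <- ifc$resno
  owners <- sort(unique(ifc$owner))
  partners <- sort(unique(ifc$partner))
  missing_tracks <- setdiff(owners, names(tracks))
  if (length(missing_tracks))
    stop("component(s) missing a conservation track: ",
         paste(missing_tracks, collapse = ", "), call. = FALSE)
  mj <- matrix(NA_real_, length(owners), length(partners),
               dimnames = list(owners, partners))
  support <- matrix(0L, length(owners), length(partners),
                    dimnames = list(owners, partners))
  unmapped <- list()
  for (ow in owners) {
    for (pa in partners) {
      rows <- ifc[ifc$owner == ow & ifc$partner == pa, , drop = FALSE]
      if (!nrow(rows)) next
      support[ow, pa] <- nrow(rows)
      jsd <- lookup_jsd(rows$ref_pos, tracks[[ow]], mappings[[ow]])
      miss <- is.na(jsd)
      if (any(miss))
        unmapped[[length(unmapped) + 1L]] <-
          data.frame(owner = ow, partner = pa, ref_pos = rows$ref_pos[miss])
      if (any(!miss)) mj[ow, pa] <- mean(jsd[!miss])
    }
  }
  list(mean_jsd = mj, support = support,
       unmapped = if (length(unmapped)) do.call(rbind, unmapped)
       else data.frame(owner = character(), partner = character(),
                       ref_pos = integer()))
}

#' Compare conservation of overlapping vs non-overlapping interface residues
#'
#' Tests whether residues at bifurcated (multi-partner) interface regions
#' are better conserved than single-partner interface residues, with a
#' two-sided Mann-Whitney U test on per-residue windowed JSD: exact null
#' for both group sizes <= 20 without ties, normal approximation with tie
#' correction otherwise.
#'
#' @param track the owner's `conservation_track`.
#' @param classes data frame from [classify_overlap()] with residue
#'   numbers in reference numbering (column `resno` or `ref_pos`).
#' @param mapping the owner's `reference_mapping`.
#' @return list: `mean_overlapping`, `mean_non_overlapping`, `p_value`
#'   (NA when either class is empty), `n_overlapping`,
#'   `n_non_overlapping`, `test`.
#' @export
overlap_compare <- function(track, classes, mapping) {
  cls <- as.data.frame(classes)
  if (!"ref_pos" %in% names(cls)) cls$ref_pos <- cls$resno
  jsd <- lookup_jsd(cls$ref_pos, track, mapping)
  ov <- jsd[cls$class == "overlapping" & !is.na(jsd)]
  nov <- jsd[cls$class == "non_overlapping" & !is.na(jsd)]
  p <- NA_real_
  if (length(ov) && length(nov)) {
    if (length(unique(c(ov, nov))) == 1L) {
      p <- 1  # all values tied: no evidence either way
    } else {
      exact <- length(ov) <= 20 && length(nov) <= 20 &&
        !any(duplicated(c(ov, nov)))
      p <- suppressWarnings(
        stats::wilcox.test(ov, nov, alternative = "two.sided",
                           exact = exact, correct = TRUE)$p.value)
    }
  }
  list(mean_overlapping = if (length(ov)) mean(ov) else NA_real_,
       mean_non_overlapping = if (length(nov)) mean(nov) else NA_real_,
       p_value = p, n_overlapping = length(ov),
       n_non_overlapping = length(nov), test = "two-sided Mann-Whitney U")
}

#' Critical residue pairs at an interface
#'
#' A contacting residue pair is critical (core candidate) when one
#' partner's JSD exceeds `high` (strict) and the other's is at least
#' `low`. Pairs are returned sorted by the smaller of the two scores,
#' descending.
#'
#' @param contact_pairs data frame of residue-level contact pairs for one
#'   component pair: `component_a`, `ref_pos_a`, `component_b`,
#'   `ref_pos_b` (reference numbering) and optionally `types`.
#' @param tracks,mappings named lists by component.
#' @param high strict threshold on the larger score (default 0.5).
#' @param low inclusive threshold on the smaller score (default 0.4).
#' @return data frame of qualifying pairs with `jsd_a`, `jsd_b`.
#' @export
critical_pairs <- function(contact_pairs, tracks, mappings,
                           high = 0.5, low = 0.4) {
  cp <- as.data.frame(contact_pairs)
  if (!nrow(cp)) {
    cp$jsd_a <- numeric(0)
    cp$jsd_b <- numeric(0)
    return(cp)
  }
  comps <- unique(c(cp$component_a, cp$component_b))
  jsd_for <- function(comp, pos)
    lookup_jsd(pos, tracks[[comp]], mappings[[comp]])
  cp$jsd_a <- NA_real_
  cp$jsd_b <- NA_real_
  for (comp in comps) {
    ia <- cp$component_a == comp
    ib <- cp$component_b == comp
    if (any(ia)) cp$jsd_a[ia] <- jsd_for(comp, cp$ref_pos_a[ia])
    if (any(ib)) cp$jsd_b[ib] <- jsd_for(comp, cp$ref_pos_b[ib])
  }
  hi <- pmax(cp$jsd_a, cp$jsd_b)
  lo <- pmin(cp$jsd_a, cp$jsd_b)
  keep <- !is.na(hi) & !is.na(lo) & hi > high & lo >= low
  out <- cp[keep, , drop = FALSE]
  out[order(-pmin(out$jsd_a, out$jsd_b)), , drop = FALSE]
}

#' Site-level conservation report
#'
#' Resolves annotated sites (reference numbering) to alignment columns,
#' reads off their windowed JSD, reports the per-taxon-group residue
#' composition at each mapped column (weighted frequencies over the group
#' members), and summarizes the fraction of mapped sites with JSD
#' strictly above the threshold. Unmapped sites are listed, never
#' silently dropped.
#'
#' @param sites data frame `ref_pos`, `label`.
#' @param track a `conservation_track`.
#' @param alignment the underlying [msa].
#' @param mapping the component's `reference_mapping`.
#' @param taxon_groups optional data frame `id`, `group` (default: one
#'   group `all`).
#' @param threshold conservation threshold (default 0.4, strict).
#' @param weights per-record weights (default: position-based weights of
#'   the alignment).
#' @return list: `sites` (per-site data frame with `ref_pos`, `label`,
#'   `column`, `windowed_jsd`), `composition` (long data frame `ref_pos`,
#'   `group`, `residue`, `freq`), `unmapped`, `fraction_above`,
#'   `threshold`.
#' @export
site_report <- function(sites, track, alignment, mapping,
                        taxon_groups = NULL, threshold = 0.4,
                        weights = NULL) {
  stopifnot(inherits(alignment, "msa"))
  if (is.null(weights)) weights <- henikoff_weights(alignment)
  groups <- if (is.null(taxon_groups))
    stats::setNames(rep("all", length(alignment$ids)), alignment$ids)
  else stats::setNames(as.character(taxon_groups$group), taxon_groups$id)
  col <- mapping$column[match(sites$ref_pos, mapping$ref_pos)]
  jsd <- track$windowed_jsd[match(col, track$column)]
  per_site <- data.frame(ref_pos = sites$ref_pos, label = sites$label,
                         column = col, windowed_jsd = jsd)
  unmapped <- per_site[is.na(per_site$column), , drop = FALSE]
  mapped <- per_site[!is.na(per_site$column), , drop = FALSE]
  comp <- list()
  m <- alignment$seqs
  for (i in seq_len(nrow(mapped))) {
    colchars <- m[, mapped$column[i]]
    for (g in unique(groups[alignment$ids])) {
      member <- groups[alignment$ids] == g
      w <- weights[member]
      ch <- colchars[member]
      keep <- ch %in% AMINO_ACIDS
      if (!any(keep)) next
      f <- tapply(w[keep], ch[keep], sum)
      f <- f / sum(f)
      comp[[length(comp) + 1L]] <- data.frame(
        ref_pos = mapped$ref_pos[i], group = g, residue = names(f),
        freq = as.numeric(f))
    }
  }
  fraction <- if (nrow(mapped)) mean(mapped$windowed_jsd > threshold)
  else NA_real_
  list(sites = per_site,
       composition = if (length(comp)) do.call(rbind, comp)
       else data.frame(ref_pos = integer(), group = character(),
                       residue = character(), freq = numeric()),
       unmapped = unmapped, fraction_above = fraction,
       threshold = threshold)
}
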