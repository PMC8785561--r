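## Phylogenetic profiling: species x component presence/absence matrices
## clustered with correlation distance and average linkage to expose
## putative subcomplexes.

#' Build a presence/absence profile matrix from a homolog table
#'
#' An entry is 1 iff at least one homolog is recorded for the
#' (species, component) pair (rows with a `present` or `hits` column are
#' thresholded at > 0). Missing pairs are 0. Species keep their order of
#' first appearance; duplicate rows are combined with logical OR.
#'
#' @param homolog_table data frame with columns `species`, `component`
#'   and optionally `present` (flag) or `hits` (count).
#' @param components component labels defining the column set (default:
#'   those observed, in order of first appearance).
#' @param species optional species ids defining the row set.
#' @return 0/1 integer matrix (species x components) of class
#'   `profile_matrix`.
#' @export
build_profile <- function(homolog_table, components = NULL, species = NULL) {
  stopifnot(is.data.frame(homolog_table),
            all(c("species", "component") %in% names(homolog_table)))
  tab <- homolog_table
  flag <- if ("present" %in% names(tab)) tab$present > 0
  else if ("hits" %in% names(tab)) tab$hits > 0
  else rep(TRUE, nrow(tab))
  tab <- tab[flag, , drop = FALSE]
  if (is.null(species)) species <- unique(homolog_table$species)
  if (is.null(components)) components <- unique(homolog_table$component)
  if (anyDuplicated(species) || anyDuplicated(components))
    stop("duplicate species or component labels", call. = FALSE)
  m <- matrix(0L, length(species), length(components),
              dimnames = list(species, components))
  keep <- tab$species %in% species & tab$component %in% components
  m[cbind(match(tab$species[keep], species),
          match(tab$component[keep], components))] <- 1L
  structure(m, class = c("profile_matrix", class(m)))
}

#' Correlation distance between two binary profiles
#'
#' `1 - Pearson correlation`, in \[0, 2\]. A constant vector has no
#' defined correlation and raises an error rather than returning NaN.
#'
#' @param u,v equal-length numeric (0/1) vectors, length >= 2.
#' @return distance in \[0, 2\].
#' @export
correlation_distance <- function(u, v) {
  if (length(u) != length(v) || length(u) < 2L)
    stop("`u` and `v` must have equal length >= 2", call. = FALSE)
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stop("correlation distance undefined for a constant profile; drop the ",
         "component or use a Jaccard fallback", call. = FALSE)
  1 - stats::cor(u, v)
}

#' Cluster component profiles (correlation distance, average linkage)
#'
#' UPGMA agglomeration over the pairwise correlation-distance matrix of
#' the component columns. Components are ordered lexicographically before
#' clustering so tie-breaking is deterministic. Flat clusters are cut by
#' requested count `k` or by height `h`.
#'
#' @param matrix a `profile_matrix` (or 0/1 matrix with dimnames).
#' @param k requested number of flat clusters (optional).
#' @param h cut height (optional; one of `k`/`h` must be given for flat
#'   clusters).
#' @return list of class `profile_clusters`: `hclust` (the linkage),
#'   `flat` (named cluster ids, if `k` or `h` given), `distances`
#'   (the correlation-distance matrix), `cophenetic`.
#' @export
cluster_profiles <- function(matrix, k = NULL, h = NULL) {
  m <- unclass(matrix)
  if (ncol(m) < 2L) stop(">= 2 component columns required", call. = FALSE)
  m <- m[, order(colnames(m)), drop = FALSE]
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant component column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "),
         "; correlation distance is undefined (drop them or use a Jaccard ",
         "fallback)", call. = FALSE)
  D <- 1 - stats::cor(m)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  flat <- NULL
  if (!is.null(k)) flat <- stats::cutree(hc, k = k)
  else if (!is.null(h)) flat <- stats::cutree(hc, h = h)
  structure(list(hclust = hc, flat = flat, distances = D,
                 cophenetic = as.matrix(stats::cophenetic(hc))),
            class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat(sprintf("Profile clustering of %d components (correlation distance, average linkage)\n",
              length(x$hclust$labels)))
  if (!is.null(x$flat)) {
    for (cl in sort(unique(x$flat)))
      cat(sprintf("  cluster %d: %s\n", cl,
                  paste(names(x$flat)[x$flat == cl], collapse = ", ")))
  }
  invisible(x)
}

#' Export display-ready heatmap data and a newick dendrogram
#'
#' Permutes the profile matrix columns to dendrogram leaf order and
#' serializes the component dendrogram as newick. Branch lengths are
#' derived from the merge heights so that the patristic (leaf-to-leaf)
#' distance in the tree equals the cophenetic distance of the linkage.
#'
#' @param matrix the clustered `profile_matrix`.
#' @param result a `profile_clusters` object computed from `matrix`.
#' @return list with `matrix` (columns permuted to leaf order),
#'   `leaf_order` (component labels) and `newick` (string).
#' @export
export_heatmap_data <- function(matrix, result) {
  hc <- result$hclust
  leaves <- hc$labels[hc$order]
  phy <- ape::as.phylo(hc)
  list(matrix = unclass(matrix)[, leaves, drop = FALSE],
       leaf_order = leaves,
       newick = ape::write.tree(phy))
}
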