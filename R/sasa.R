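## Shrake-Rupley solvent-accessible surface area over heavy atoms.
## Sphere points come from a deterministic golden-spiral lattice, so
## results are reproducible for a fixed n_points.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
DEFAULT_VDW <- 1.70

## Theoretical maximum residue SASA (Gly-X-Gly reference state), used to
## express residue SASA as a percentage (rSASA).
MAX_SASA_GXG <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
                  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
                  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
                  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA over heavy atoms with standard van der Waals
#' radii, summed per residue. Only atoms of the selected chains are
#' considered (both as surface and as occluders), so calling with a
#' single chain gives that chain's unbound SASA.
#'
#' @param structure a `complex_structure`.
#' @param chains chain ids to include (default: all).
#' @param probe_radius probe sphere radius in Angstrom (default 1.4).
#' @param n_points sphere sample points per atom (default 960).
#' @return data frame `chain`, `resno`, `ins`, `resname`, `sasa`
#'   (Angstrom^2).
#' @export
sasa <- function(structure, chains = NULL, probe_radius = 1.4,
                 n_points = 960L) {
  at <- structure$atoms
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (!nrow(at)) stop("empty chain selection", call. = FALSE)
  r <- VDW_RADII[at$element]
  r[is.na(r)] <- DEFAULT_VDW
  r <- unname(r) + probe_radius
  pts <- sphere_points(n_points)
  xyz <- cbind(at$x, at$y, at$z)
  n <- nrow(at)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
    if (!length(nb)) {
      acc <- n_points
    } else {
      p <- pts * r[i]
      p <- sweep(p, 2L, xyz[i, ], "+")
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dj <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
          (p[free, 3] - xyz[j, 3])^2
        free[free] <- dj >= r[j]^2
      }
      acc <- sum(free)
    }
    area[i] <- 4 * pi * r[i]^2 * acc / n_points
  }
  key <- paste(at$chain, at$resno, at$ins, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(chain = at$chain[first], resno = at$resno[first],
                    ins = at$ins[first], resname = at$resname[first],
                    sasa = as.numeric(tapply(area, key, sum)[key[first]]))
  rownames(out) <- NULL
  out
}

relative_sasa <- function(sasa_df) {
  ref <- MAX_SASA_GXG[sasa_df$resname]
  unknown <- is.na(ref)
  if (any(unknown)) {
    warning("unknown residue type(s), using mean reference SASA: ",
            paste(unique(sasa_df$resname[unknown]), collapse = ", "))
    ref[unknown] <- mean(MAX_SASA_GXG)
  }
  pmin(100, 100 * sasa_df$sasa / unname(ref))
}

#' Label relative-SASA values as interface core, rim or other
#'
#' A residue is `core` when it is surface-exposed in the unbound chain
#' (`rsasa_unbound > rim_max`) and becomes highly buried on complex
#' formation (`rsasa_bound <= core_max`); `rim` when
#' `core_max < rsasa_bound <= rim_max`; otherwise `other`.
#'
#' @param rsasa_unbound,rsasa_bound relative SASA percentages in
#'   \[0, 100\].
#' @param core_max core threshold on bound rSASA (default 7).
#' @param rim_max rim threshold on bound rSASA (default 10).
#' @return character vector of labels.
#' @export
classify_core_rim <- function(rsasa_unbound, rsasa_bound,
                              core_max = 7, rim_max = 10) {
  stopifnot(length(rsasa_unbound) == length(rsasa_bound))
  ifelse(rsasa_unbound > rim_max & rsasa_bound <= core_max, "core",
         ifelse(rsasa_bound > core_max & rsasa_bound <= rim_max, "rim",
                "other"))
}

#' Core/rim classification of an interface by relative SASA change
#'
#' Computes per-residue relative SASA for the owner component alone
#' (unbound) and within the two-component pair (bound), and labels the
#' owner's interface residues with [classify_core_rim()].
#'
#' @param structure a `complex_structure` containing both components.
#' @param pair character vector `c(owner, partner)` of component labels.
#' @param core_max,rim_max thresholds (percent bound rSASA; defaults 7
#'   and 10).
#' @param params contact criteria used to delimit the interface.
#' @param probe_radius,n_points passed to [sasa()].
#' @return data frame `chain`, `resno`, `ins`, `resname`,
#'   `rsasa_unbound`, `rsasa_bound`, `label` for the owner-side interface
#'   residues.
#' @export
core_rim <- function(structure, pair, core_max = 7, rim_max = 10,
                     params = contact_params(), probe_radius = 1.4,
                     n_points = 960L) {
  at <- structure$atoms
  owner_chains <- unique(at$chain[at$component == pair[1L]])
  partner_chains <- unique(at$chain[at$component == pair[2L]])
  if (!length(owner_chains) || !length(partner_chains))
    stop("pair components not found in structure", call. = FALSE)
  sub <- structure
  sub$atoms <- at[at$chain %in% c(owner_chains, partner_chains), ]
  contacts <- find_contacts(sub, params)
  iface <- interface_sets(contacts)
  iface <- iface[iface$owner == pair[1L] & iface$partner == pair[2L], ,
                 drop = FALSE]
  if (!nrow(iface))
    stop("pair has no interface residues: ", paste(pair, collapse = "/"),
         call. = FALSE)
  unbound <- sasa(sub, chains = owner_chains, probe_radius = probe_radius,
                  n_points = n_points)
  bound <- sasa(sub, probe_radius = probe_radius, n_points = n_points)
  unbound$rsasa <- relative_sasa(unbound)
  bound$rsasa <- relative_sasa(bound)
  ku <- paste(unbound$chain, unbound$resno, unbound$ins, sep = "\r")
  kb <- paste(bound$chain, bound$resno, bound$ins, sep = "\r")
  ki <- paste(iface$chain, iface$resno, iface$ins, sep = "\r")
  out <- data.frame(chain = iface$chain, resno = iface$resno,
                    ins = iface$ins, resname = iface$resname,
                    rsasa_unbound = unbound$rsasa[match(ki, ku)],
                    rsasa_bound = bound$rsasa[match(ki, kb)])
  out$label <- classify_core_rim(out$rsasa_unbound, out$rsasa_bound,
                                 core_max = core_max, rim_max = rim_max)
  out
}
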