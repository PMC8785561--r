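## Geometric interface detection in multi-chain complex structures.
## Criteria are hydrogen-free (cryo-EM models rarely carry hydrogens):
## distances between heavy atoms only, no angle terms.

#' Contact-detection distance criteria
#'
#' @param generic_cutoff any inter-chain heavy-atom pair within this
#'   distance is a generic contact (Angstrom, default 5.0).
#' @param hbond_cutoff donor/acceptor-class (N or O) atom pair cutoff
#'   (default 3.5).
#' @param ionic_cutoff charged-group pair cutoff, including protein
#'   charged group vs RNA phosphate (default 6.0).
#' @param hydrophobic_cutoff apolar side-chain carbon-carbon cutoff
#'   (default 5.0).
#' @return list of class `contact_params`.
#' @export
contact_params <- function(generic_cutoff = 5.0, hbond_cutoff = 3.5,
                           ionic_cutoff = 6.0, hydrophobic_cutoff = 5.0) {
  p <- list(generic_cutoff = generic_cutoff, hbond_cutoff = hbond_cutoff,
            ionic_cutoff = ionic_cutoff,
            hydrophobic_cutoff = hydrophobic_cutoff)
  if (any(unlist(p) <= 0)) stop("all cutoffs must be > 0", call. = FALSE)
  structure(p, class = "contact_params")
}

#' Construct a complex structure from an atom table
#'
#' @param id structure identifier.
#' @param atoms data frame with columns `chain`, `component`,
#'   `molecule_class`, `resno`, `ins`, `resname`, `atom`, `element`,
#'   `x`, `y`, `z` (coordinates in Angstrom).
#' @param chain_map optional chain-to-component map (derived from `atoms`
#'   when omitted).
#' @return object of class `complex_structure`.
#' @export
complex_structure <- function(id, atoms, chain_map = NULL) {
  if (is.null(chain_map))
    chain_map <- unique(atoms[, c("chain", "component", "molecule_class")])
  new_complex_structure(id, atoms, chain_map)
}

new_complex_structure <- function(id, atoms, chain_map) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "component", "molecule_class", "resno", "ins",
                  "resname", "atom", "element", "x", "y", "z") %in%
                  names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates", call. = FALSE)
  structure(list(id = id, atoms = atoms, chain_map = chain_map),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  ch <- unique(x$atoms[, c("chain", "component", "molecule_class")])
  cat(sprintf("Complex structure '%s': %d chains, %d atoms\n",
              x$id, nrow(ch), nrow(x$atoms)))
  for (i in seq_len(nrow(ch)))
    cat(sprintf("  chain %s -> %s (%s), %d residues\n", ch$chain[i],
                ch$component[i], ch$molecule_class[i],
                nrow(unique(x$atoms[x$atoms$chain == ch$chain[i],
                                    c("resno", "ins")]))))
  invisible(x)
}

#' Read a multi-chain structure with a chain-to-component map
#'
#' Parses a PDB (or mmCIF) file, drops waters and hydrogens, resolves
#' altlocs to the highest-occupancy copy (ties: first), and annotates each
#' mapped chain with its component label and molecule class. Chains
#' absent from `chain_map` are dropped with a warning; `chain_map` rows
#' naming chains not present in the file are an error.
#'
#' @param path PDB or mmCIF file.
#' @param chain_map data frame with columns `chain`, `component`,
#'   `molecule_class` (`"protein"` or `"RNA"`).
#' @param id structure identifier (default: file name without extension).
#' @return object of class `complex_structure`.
#' @export
read_structure <- function(path, chain_map,
                           id = sub("\\.[^.]+$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(is.data.frame(chain_map),
            all(c("chain", "component", "molecule_class") %in% names(chain_map)))
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path, rm.alt = FALSE)
  else bio3d::read.pdb(path, rm.alt = FALSE)
  at <- pdb$atom
  elem <- toupper(trimws(if ("elesy" %in% names(at)) at$elesy else ""))
  guess <- toupper(substr(gsub("[0-9']", "", trimws(at$elety)), 1L, 1L))
  elem[is.na(elem) | elem == ""] <- guess[is.na(elem) | elem == ""]
  at$element <- elem
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")) & at$element != "H", ]
  missing_chains <- setdiff(chain_map$chain, at$chain)
  if (length(missing_chains))
    stop("chain_map names chain(s) absent from the structure: ",
         paste(missing_chains, collapse = ", "), call. = FALSE)
  unmapped <- setdiff(unique(at$chain), chain_map$chain)
  if (length(unmapped))
    warning("unmapped chain(s) ignored: ", paste(unmapped, collapse = ", "))
  at <- at[at$chain %in% chain_map$chain, ]
  ## altloc resolution: highest occupancy per (chain, resno, ins, atom)
  at$insert[is.na(at$insert)] <- ""
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -occ, seq_len(nrow(at)))
  at <- at[ord, ][!duplicated(key[ord]), ]
  at <- at[order(match(at$chain, chain_map$chain), at$resno, at$insert,
                 at$elety), ]
  i <- match(at$chain, chain_map$chain)
  atoms <- data.frame(chain = at$chain,
                      component = chain_map$component[i],
                      molecule_class = chain_map$molecule_class[i],
                      resno = at$resno, ins = at$insert,
                      resname = trimws(at$resid), atom = trimws(at$elety),
                      element = at$element,
                      x = at$x, y = at$y, z = at$z)
  new_complex_structure(id, atoms, chain_map)
}

## Atom-class predicates used by the contact subtypes.
RNA_PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "O1P", "O2P", "OP3", "O3P")
POSITIVE_SC_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                          HIS = c("ND1", "NE2"))
NEGATIVE_SC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
APOLAR_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

atom_in_group <- function(resname, atom, groups) {
  idx <- match(resname, names(groups))
  !is.na(idx) & mapply(function(a, i) !is.na(i) && a %in% groups[[i]],
                       atom, idx)
}

charge_class <- function(atoms) {
  cls <- rep("none", nrow(atoms))
  cls[atom_in_group(atoms$resname, atoms$atom, POSITIVE_SC_ATOMS)] <- "pos"
  cls[atom_in_group(atoms$resname, atoms$atom, NEGATIVE_SC_ATOMS)] <- "neg"
  cls[atoms$molecule_class == "RNA" &
        atoms$atom %in% RNA_PHOSPHATE_ATOMS] <- "phos"
  cls
}

#' Detect inter-chain atomic contacts
#'
#' All inter-chain heavy-atom pairs within `generic_cutoff` are reported
#' as `generic` contacts. In addition, pairs qualifying under the typed
#' criteria are reported once per type: `hbond` (both atoms N or O,
#' within the hbond cutoff), `ionic` (oppositely charged protein
#' side-chain groups, or a protein charged group against an RNA
#' phosphate, within the ionic cutoff), `hydrophobic` (apolar side-chain
#' carbon pair within the hydrophobic cutoff). Records are ordered by
#' (chain A, residue A, atom A, chain B, residue B, atom B, type).
#'
#' @param structure a `complex_structure` with >= 2 mapped chains.
#' @param params a [contact_params()] object.
#' @return data frame of contact records (one row per qualifying atom
#'   pair and type) with the structure id in column `structure`.
#' @export
find_contacts <- function(structure, params = contact_params()) {
  at <- structure$atoms
  chains <- unique(at$chain)
  if (length(chains) < 2L) stop(">= 2 mapped chains required", call. = FALSE)
  maxcut <- max(params$generic_cutoff, params$hbond_cutoff,
                params$ionic_cutoff, params$hydrophobic_cutoff)
  cc <- charge_class(at)
  hb <- at$element %in% c("N", "O")
  apolar <- at$element == "C" & at$resname %in% APOLAR_RESIDUES &
    !(at$atom %in% BACKBONE_ATOMS)
  out <- list()
  for (a in seq_len(length(chains) - 1L)) {
    for (b in (a + 1L):length(chains)) {
      ia <- which(at$chain == chains[a])
      ib <- which(at$chain == chains[b])
      dx <- outer(at$x[ia], at$x[ib], "-")
      dy <- outer(at$y[ia], at$y[ib], "-")
      dz <- outer(at$z[ia], at$z[ib], "-")
      d <- sqrt(dx^2 + dy^2 + dz^2)
      hit <- which(d <= maxcut, arr.ind = TRUE)
      if (!nrow(hit)) next
      i <- ia[hit[, 1L]]
      j <- ib[hit[, 2L]]
      dist <- d[hit]
      types <- list(
        generic = dist <= params$generic_cutoff,
        hbond = hb[i] & hb[j] & dist <= params$hbond_cutoff,
        ionic = ((cc[i] == "pos" & cc[j] %in% c("neg", "phos")) |
                   (cc[i] == "neg" & cc[j] == "pos") |
                   (cc[i] == "phos" & cc[j] %in% c("pos", "neg")) |
                   (cc[i] == "neg" & cc[j] == "phos")) &
          dist <= params$ionic_cutoff,
        hydrophobic = apolar[i] & apolar[j] &
          dist <= params$hydrophobic_cutoff)
      for (ty in names(types)) {
        k <- which(types[[ty]])
        if (!length(k)) next
        out[[length(out) + 1L]] <- data.frame(
          chain_a = at$chain[i[k]], component_a = at$component[i[k]],
          resno_a = at$resno[i[k]], ins_a = at$ins[i[k]],
          resname_a = at$resname[i[k]], atom_a = at$atom[i[k]],
          chain_b = at$chain[j[k]], component_b = at$component[j[k]],
          resno_b = at$resno[j[k]], ins_b = at$ins[j[k]],
          resname_b = at$resname[j[k]], atom_b = at$atom[j[k]],
          distance = dist[k], type = ty, structure = structure$id)
      }
    }
  }
  if (!length(out))
    return(data.frame(chain_a = character(), component_a = character(),
                      resno_a = integer(), ins_a = character(),
                      resname_a = character(), atom_a = character(),
                      chain_b = character(), component_b = character(),
                      resno_b = integer(), ins_b = character(),
                      resname_b = character(), atom_b = character(),
                      distance = numeric(), type = character(),
                      structure = character()))
  res <- do.call(rbind, out)
  res[order(res$chain_a, res$resno_a, res$atom_a, res$chain_b, res$resno_b,
            res$atom_b, res$type), , drop = FALSE]
}

#' Build ordered per-component-pair interface sets
#'
#' An interface residue is any residue with at least one qualifying
#' inter-chain contact of any type. For every unordered component pair
#' with a contact, two ordered sets are produced (one per side); a
#' residue is listed once per (owner, partner) regardless of how many
#' contacts it makes.
#'
#' @param contacts contact records from [find_contacts()] (one or more
#'   structures).
#' @return data frame of class `interface_table` with one row per
#'   (owner, partner, residue): columns `owner`, `partner`, `chain`,
#'   `resno`, `ins`, `resname`, `types`, `structures`, `n_contacts`.
#' @export
interface_sets <- function(contacts) {
  empty <- data.frame(owner = character(), partner = character(),
                      chain = character(), resno = integer(),
                      ins = character(), resname = character(),
                      types = character(), structures = character(),
                      n_contacts = integer())
  if (!nrow(contacts)) return(structure(empty, class = c("interface_table",
                                                         "data.frame")))
  side <- function(owner_suffix, partner_suffix) {
    data.frame(owner = contacts[[paste0("component_", owner_suffix)]],
               partner = contacts[[paste0("component_", partner_suffix)]],
               chain = contacts[[paste0("chain_", owner_suffix)]],
               resno = contacts[[paste0("resno_", owner_suffix)]],
               ins = contacts[[paste0("ins_", owner_suffix)]],
               resname = contacts[[paste0("resname_", owner_suffix)]],
               type = contacts$type, structure = contacts$structure)
  }
  long <- rbind(side("a", "b"), side("b", "a"))
  key <- paste(long$owner, long$partner, long$chain, long$resno, long$ins,
               sep = "\r")
  agg <- lapply(split(seq_len(nrow(long)), key), function(idx) {
    first <- idx[1L]
    data.frame(owner = long$owner[first], partner = long$partner[first],
               chain = long$chain[first], resno = long$resno[first],
               ins = long$ins[first], resname = long$resname[first],
               types = paste(sort(unique(long$type[idx])), collapse = ","),
               structures = paste(sort(unique(long$structure[idx])),
                                  collapse = ","),
               n_contacts = length(idx))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out <- out[order(out$owner, out$partner, out$chain, out$resno, out$ins), ]
  structure(out, class = c("interface_table", "data.frame"))
}

#' Union per-structure interface sets in reference numbering
#'
#' Maps each structure's owner-side residues to reference coordinates and
#' takes the union, keeping per-residue provenance (every contributing
#' structure). Residues without a mapping row are returned in `unmapped`,
#' never silently dropped. All sets must describe the same ordered
#' (owner, partner) component pair.
#'
#' @param sets list of `interface_table` subsets (one ordered pair each,
#'   possibly from different structures).
#' @param mapping data frame with columns `structure`, `resno`, `ref_pos`
#'   (optionally `chain`); a structure residue mapping to two different
#'   reference positions is an error. `NULL` means structure numbering is
#'   already reference numbering.
#' @return list with `set` (data frame `owner`, `partner`, `ref_pos`,
#'   `structures`) and `unmapped` (rows that had no mapping).
#' @export
union_interfaces <- function(sets, mapping = NULL) {
  all <- do.call(rbind, lapply(sets, as.data.frame))
  pairs <- unique(all[, c("owner", "partner")])
  if (nrow(pairs) != 1L)
    stop("all sets must share one ordered (owner, partner) pair",
         call. = FALSE)
  if (is.null(mapping)) {
    all$ref_pos <- all$resno
    unmapped <- all[0, ]
  } else {
    stopifnot(all(c("structure", "resno", "ref_pos") %in% names(mapping)))
    dup <- unique(mapping[, c("structure", "resno")])
    if (nrow(dup) != nrow(unique(mapping[, c("structure", "resno", "ref_pos")])))
      stop("conflicting mappings: a structure residue maps to two reference positions",
           call. = FALSE)
    ## each interface row may list several contributing structures
    all$ref_pos <- NA_integer_
    for (r in seq_len(nrow(all))) {
      structs <- strsplit(all$structures[r], ",", fixed = TRUE)[[1L]]
      hits <- mapping$ref_pos[mapping$structure %in% structs &
                                mapping$resno == all$resno[r]]
      hits <- unique(hits)
      if (length(hits) > 1L)
        stop("conflicting mappings for residue ", all$resno[r], call. = FALSE)
      if (length(hits) == 1L) all$ref_pos[r] <- hits
    }
    unmapped <- all[is.na(all$ref_pos), ]
    all <- all[!is.na(all$ref_pos), ]
  }
  if (!nrow(all)) {
    set <- data.frame(owner = character(), partner = character(),
                      ref_pos = integer(), structures = character())
  } else {
    agg <- lapply(split(seq_len(nrow(all)), all$ref_pos), function(idx) {
      structs <- unlist(strsplit(all$structures[idx], ",", fixed = TRUE))
      data.frame(owner = all$owner[idx[1L]], partner = all$partner[idx[1L]],
                 ref_pos = all$ref_pos[idx[1L]],
                 structures = paste(sort(unique(structs)), collapse = ","))
    })
    set <- do.call(rbind, agg)
    set <- set[order(set$ref_pos), ]
    rownames(set) <- NULL
  }
  list(set = set, unmapped = unmapped)
}

#' Percentage of a component's residues at any interface
#'
#' `100 * |union over partners of owner-side interface residues| /
#' denominator`. A residue contacting several partners counts once.
#'
#' @param interfaces an `interface_table` (all sets, any owners).
#' @param component owner component label.
#' @param denominator residue count to normalize by (> 0); typically the
#'   number of residues resolved in the structure, or the full sequence
#'   length.
#' @return percentage.
#' @export
percent_interface <- function(interfaces, component, denominator) {
  if (!(is.numeric(denominator) && denominator > 0))
    stop("`denominator` must be > 0", call. = FALSE)
  own <- interfaces[interfaces$owner == component, , drop = FALSE]
  if (!nrow(own)) return(0)
  100 * nrow(unique(own[, c("chain", "resno", "ins")])) / denominator
}

#' Classify interface residues as overlapping or non-overlapping
#'
#' A residue is `overlapping` (bifurcated) when it appears in the owner's
#' interface sets for two or more distinct partners, `non_overlapping`
#' otherwise.
#'
#' @param interfaces an `interface_table`.
#' @param component owner component label.
#' @return data frame `chain`, `resno`, `ins`, `n_partners`, `class`.
#' @export
classify_overlap <- function(interfaces, component) {
  own <- interfaces[interfaces$owner == component, , drop = FALSE]
  if (!nrow(own)) stop("component has no interface residues: ", component,
                       call. = FALSE)
  key <- paste(own$chain, own$resno, own$ins, sep = "\r")
  np <- tapply(own$partner, key, function(p) length(unique(p)))
  first <- !duplicated(key)
  out <- data.frame(chain = own$chain[first], resno = own$resno[first],
                    ins = own$ins[first],
                    n_partners = as.integer(np[key[first]]))
  out$class <- ifelse(out$n_partners >= 2L, "overlapping", "non_overlapping")
  out[order(out$chain, out$resno, out$ins), ]
}
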