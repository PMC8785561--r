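## Seeded synthetic-data generators with known ground truth. Each takes
## one explicit integer seed and restores the caller's RNG state.

#' Simulate an alignment with planted conserved and variable columns
#'
#' Conserved columns are near point masses: one dominant residue occupies
#' `ceiling(0.95 * n_seqs)` records and the remaining 5% of records carry
#' residues drawn uniformly from the other 19 amino acids. Variable
#' columns are drawn i.i.d. from the BLOSUM62 background; per-cell gaps
#' at `gap_rate` are inserted in variable columns only.
#'
#' @param n_seqs,n_cols alignment dimensions.
#' @param n_conserved number of planted conserved columns
#'   (`<= n_cols`).
#' @param gap_rate per-cell gap probability in variable columns, in
#'   \[0, 1).
#' @param seed integer seed.
#' @return list of class `msa_truth`: `alignment` ([msa]),
#'   `conserved_columns`, `gap_columns` (columns that received at least
#'   one gap).
#' @export
simulate_msa <- function(n_seqs, n_cols, n_conserved, gap_rate = 0.05,
                         seed = 1L) {
  n_seqs <- assert_count(n_seqs, "n_seqs", min = 2L)
  n_cols <- assert_count(n_cols, "n_cols")
  n_conserved <- assert_count(n_conserved, "n_conserved", min = 0L)
  assert_fraction(gap_rate, "gap_rate", hi = 1, hi_open = TRUE)
  if (n_conserved > n_cols)
    stop("n_conserved must be <= n_cols", call. = FALSE)
  bg <- blosum62_background()
  with_seed(seed, {
    conserved <- sort(sample.int(n_cols, n_conserved))
    m <- matrix("", n_seqs, n_cols)
    n_dom <- min(n_seqs, ceiling(0.95 * n_seqs))
    for (j in seq_len(n_cols)) {
      if (j %in% conserved) {
        dom <- sample(AMINO_ACIDS, 1L)
        col <- rep(dom, n_seqs)
        minority <- sample.int(n_seqs, n_seqs - n_dom)
        if (length(minority))
          col[minority] <- sample(setdiff(AMINO_ACIDS, dom),
                                  length(minority), replace = TRUE)
        m[, j] <- col
      } else {
        repeat {
          col <- sample(AMINO_ACIDS, n_seqs, replace = TRUE, prob = bg)
          if (gap_rate > 0)
            col[stats::runif(n_seqs) < gap_rate] <- GAP_CHAR
          if (any(col != GAP_CHAR)) break  # never emit an all-gap column
        }
        m[, j] <- col
      }
    }
    gap_cols <- which(apply(m == GAP_CHAR, 2L, any))
    structure(list(alignment = msa(m, ids = sprintf("seq%03d",
                                                    seq_len(n_seqs))),
                   conserved_columns = conserved,
                   gap_columns = gap_cols),
              class = "msa_truth")
  })
}

#' Simulate a toy multi-chain complex with planted inter-chain contacts
#'
#' Chains are laid out far apart (residues 10 Angstrom apart within a
#' chain, chains separated by 120 Angstrom) so that by construction no
#' unplanned inter-chain heavy-atom pair lies within 6.5 Angstrom. For
#' each planted contact a residue of the higher-indexed chain is moved so
#' that its designated atom sits at a drawn distance in \[3.0, 4.9\]
#' Angstrom from a host residue of the lower-indexed chain; each residue
#' hosts at most one planted contact. Residues are single-atom
#' pseudo-residues by default (Calpha for proteins, phosphate for RNA);
#' `sidechains = TRUE` adds one side-chain atom per residue (cycling
#' Asp/Lys/Leu/Ser for proteins) so the typed contact classifiers can be
#' exercised.
#'
#' @param chain_spec data frame with columns `component`,
#'   `molecule_class` (`"protein"`/`"RNA"`) and `n_residues`;
#'   >= 2 chains.
#' @param n_contacts number of planted inter-chain contacts.
#' @param seed integer seed.
#' @param sidechains add one side-chain atom per residue (default FALSE).
#' @return list of class `complex_truth`: `structure`
#'   (`complex_structure`) and `contacts` (data frame `chain_a`,
#'   `resno_a`, `chain_b`, `resno_b`, `distance`).
#' @export
simulate_complex <- function(chain_spec, n_contacts, seed = 1L,
                             sidechains = FALSE) {
  stopifnot(is.data.frame(chain_spec),
            all(c("component", "molecule_class", "n_residues") %in%
                  names(chain_spec)))
  if (nrow(chain_spec) < 2L) stop(">= 2 chains required", call. = FALSE)
  n_contacts <- assert_count(n_contacts, "n_contacts", min = 0L)
  k <- nrow(chain_spec)
  chain_ids <- LETTERS[seq_len(k)]
  sc_names <- data.frame(resname = c("ASP", "LYS", "LEU", "SER"),
                         atom = c("OD1", "NZ", "CD1", "OG"),
                         element = c("O", "N", "C", "O"))
  with_seed(seed, {
    res <- list()
    for (c in seq_len(k)) {
      nres <- chain_spec$n_residues[c]
      is_rna <- chain_spec$molecule_class[c] == "RNA"
      for (i in seq_len(nres)) {
        pos <- c(10 * (i - 1), 120 * (c - 1), 0)
        if (is_rna) {
          rn <- "A"; an <- "P"; el <- "P"
        } else if (sidechains) {
          j <- ((i - 1) %% nrow(sc_names)) + 1L
          rn <- sc_names$resname[j]; an <- "CA"; el <- "C"
        } else {
          rn <- "GLY"; an <- "CA"; el <- "C"
        }
        res[[length(res) + 1L]] <- list(chain = c, resno = i, resname = rn,
                                        anchor = an, element = el,
                                        pos = pos)
      }
    }
    pool <- lapply(chain_spec$n_residues, seq_len)
    pairs <- utils::combn(k, 2L)
    planted <- list()
    for (ct in seq_len(n_contacts)) {
      pi <- sample.int(ncol(pairs), 1L)
      ca <- pairs[1L, pi]; cb <- pairs[2L, pi]
      if (!length(pool[[ca]]) || !length(pool[[cb]]))
        stop("geometric placement failure: chain residue pool exhausted ",
             "after ", ct - 1L, " contacts", call. = FALSE)
      ia <- pool[[ca]][sample.int(length(pool[[ca]]), 1L)]
      ib <- pool[[cb]][sample.int(length(pool[[cb]]), 1L)]
      pool[[ca]] <- setdiff(pool[[ca]], ia)
      pool[[cb]] <- setdiff(pool[[cb]], ib)
      d <- stats::runif(1L, 3.0, 4.9)
      host <- Find(function(r) r$chain == ca && r$resno == ia, res)
      for (r in seq_along(res)) {
        if (res[[r]]$chain == cb && res[[r]]$resno == ib) {
          res[[r]]$pos <- host$pos + c(0, 0, d)
          res[[r]]$moved <- TRUE
        }
      }
      planted[[length(planted) + 1L]] <- data.frame(
        chain_a = chain_ids[ca], resno_a = ia,
        chain_b = chain_ids[cb], resno_b = ib, distance = d)
    }
    rows <- list()
    for (r in res) {
      is_moved <- isTRUE(r$moved)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain_ids[r$chain],
        component = chain_spec$component[r$chain],
        molecule_class = chain_spec$molecule_class[r$chain],
        resno = r$resno, ins = "", resname = r$resname, atom = r$anchor,
        element = r$element, x = r$pos[1], y = r$pos[2], z = r$pos[3])
      if (sidechains && chain_spec$molecule_class[r$chain] != "RNA") {
        j <- ((r$resno - 1) %% nrow(sc_names)) + 1L
        ## side chain points away from the planted partner
        off <- if (is_moved) 1.3 else -1.3
        rows[[length(rows) + 1L]] <- data.frame(
          chain = chain_ids[r$chain],
          component = chain_spec$component[r$chain],
          molecule_class = chain_spec$molecule_class[r$chain],
          resno = r$resno, ins = "", resname = r$resname,
          atom = sc_names$atom[j], element = sc_names$element[j],
          x = r$pos[1], y = r$pos[2], z = r$pos[3] + off)
      }
    }
    atoms <- do.call(rbind, rows)
    structure_obj <- new_complex_structure(
      sprintf("toy_seed%d", as.integer(seed)), atoms,
      data.frame(chain = chain_ids, component = chain_spec$component,
                 molecule_class = chain_spec$molecule_class))
    contacts <- if (length(planted)) do.call(rbind, planted)
    else data.frame(chain_a = character(), resno_a = integer(),
                    chain_b = character(), resno_b = integer(),
                    distance = numeric())
    structure(list(structure = structure_obj, contacts = contacts),
              class = "complex_truth")
  })
}

#' Simulate presence/absence profiles with planted co-occurring modules
#'
#' Components in the same module share one Bernoulli presence draw per
#' species (at that module's presence rate); independent bit flips are
#' then applied at `noise_rate`.
#'
#' @param n_species number of species rows.
#' @param modules named list of character vectors partitioning the
#'   component labels into co-occurrence groups.
#' @param presence_rate per-module presence probability (recycled;
#'   default 0.7).
#' @param noise_rate independent bit-flip probability, `< 0.5`.
#' @param seed integer seed.
#' @return list of class `profile_truth`: `matrix` (`profile_matrix`),
#'   `modules`, `noise_rate`.
#' @export
simulate_profiles <- function(n_species, modules, presence_rate = 0.7,
                              noise_rate = 0.05, seed = 1L) {
  n_species <- assert_count(n_species, "n_species", min = 2L)
  stopifnot(is.list(modules), length(modules) >= 1L)
  if (any(lengths(modules) == 0L)) stop("empty module", call. = FALSE)
  comps <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(comps))
    stop("modules must partition the component set", call. = FALSE)
  assert_fraction(noise_rate, "noise_rate", hi = 0.5, hi_open = TRUE)
  presence_rate <- rep_len(presence_rate, length(modules))
  with_seed(seed, {
    m <- matrix(0L, n_species, length(comps),
                dimnames = list(sprintf("sp%03d", seq_len(n_species)),
                                comps))
    for (g in seq_along(modules)) {
      draw <- stats::rbinom(n_species, 1L, presence_rate[g])
      for (comp in modules[[g]]) m[, comp] <- draw
    }
    if (noise_rate > 0) {
      flip <- matrix(stats::runif(length(m)) < noise_rate, nrow(m))
      m[flip] <- 1L - m[flip]
    }
    structure(list(matrix = structure(m, class = c("profile_matrix",
                                                   "matrix", "array")),
                   modules = modules, noise_rate = noise_rate),
              class = "profile_truth")
  })
}

#' Simulate sequences with planted C-terminal motifs
#'
#' Background residues are drawn uniformly over the 20 amino acids; a
#' whole sequence is redrawn (rejection step) if the background contains
#' a spurious match to any motif in the default set. One motif instance
#' per sequence is then planted inside the annotated region (wildcard
#' positions filled at random), and the sequence is accepted only when a
#' full scan returns exactly the planted hits.
#'
#' @param n_seqs number of sequences.
#' @param motif_names motifs to plant, drawn from [default_motifs()]
#'   names (recycled across sequences; empty vector plants nothing).
#' @param seq_length sequence length (default 150).
#' @param region `c(start, end)` region emulating the annotated
#'   C-terminal tail (default: final third of the sequence).
#' @param seed integer seed.
#' @return list of class `motif_truth`: `sequences` (named character),
#'   `region`, `planted_hits` (data frame `id`, `motif`, `start`, `end`,
#'   `match`).
#' @export
simulate_motif_sequences <- function(n_seqs, motif_names = default_motifs()$name,
                                     seq_length = 150L, region = NULL,
                                     seed = 1L) {
  n_seqs <- assert_count(n_seqs, "n_seqs")
  seq_length <- assert_count(seq_length, "seq_length", min = 10L)
  motifs <- default_motifs()
  if (length(motif_names) && !all(motif_names %in% motifs$name))
    stop("unknown motif name(s): ",
         paste(setdiff(motif_names, motifs$name), collapse = ", "),
         call. = FALSE)
  if (is.null(region))
    region <- c(seq_length - ceiling(seq_length / 3) + 1L, seq_length)
  stopifnot(region[1] >= 1, region[2] <= seq_length, region[1] <= region[2])
  with_seed(seed, {
    seqs <- character(n_seqs)
    hits <- list()
    for (i in seq_len(n_seqs)) {
      plant <- if (length(motif_names))
        motif_names[((i - 1L) %% length(motif_names)) + 1L] else NULL
      ok <- FALSE
      for (attempt in seq_len(1000L)) {
        s <- paste(sample(AMINO_ACIDS, seq_length, replace = TRUE),
                   collapse = "")
        expected <- data.frame(id = character(), motif = character(),
                               start = integer(), end = integer(),
                               match = character())
        if (!is.null(plant)) {
          pat <- motifs$pattern[motifs$name == plant]
          len <- nchar(pat)
          if (region[2] - region[1] + 1L < len)
            stop("region too short for motif ", plant, call. = FALSE)
          start <- sample(region[1]:(region[2] - len + 1L), 1L)
          inst <- strsplit(pat, "")[[1L]]
          wild <- inst == "x"
          inst[wild] <- sample(AMINO_ACIDS, sum(wild), replace = TRUE)
          inst <- paste(inst, collapse = "")
          s <- paste0(substring(s, 1L, start - 1L), inst,
                      substring(s, start + len, seq_length))
          expected <- data.frame(id = sprintf("seq%03d", i), motif = plant,
                                 start = start, end = start + len - 1L,
                                 match = inst)
        }
        found <- scan_motifs(s, region = c(1L, seq_length), motifs = motifs,
                             id = sprintf("seq%03d", i))
        rownames(found) <- NULL
        if (identical(found[, c("motif", "start")],
                      expected[, c("motif", "start")])) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("failed to generate a clean sequence", call. = FALSE)
      seqs[i] <- s
      if (!is.null(plant)) hits[[length(hits) + 1L]] <- expected
    }
    names(seqs) <- sprintf("seq%03d", seq_len(n_seqs))
    planted <- if (length(hits)) do.call(rbind, hits)
    else data.frame(id = character(), motif = character(),
                    start = integer(), end = integer(), match = character())
    structure(list(sequences = seqs, region = region,
                   planted_hits = planted),
              class = "motif_truth")
  })
}
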