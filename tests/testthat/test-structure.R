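toy_spec <- function(n = 2, nres = 20) {
  data.frame(component = paste0("P", seq_len(n)),
             molecule_class = "protein", n_residues = nres)
}

# minimal hand-built structure: two chains, one residue each, at distance d
two_atom_structure <- function(d, resname = c("GLY", "GLY"),
                               atom = c("CA", "CA"),
                               element = c("C", "C"),
                               molclass = c("protein", "protein")) {
  atoms <- data.frame(chain = c("A", "B"), component = c("P1", "P2"),
                      molecule_class = molclass, resno = 1L, ins = "",
                      resname = resname, atom = atom, element = element,
                      x = c(0, d), y = 0, z = 0)
  complex_structure("two", atoms)
}

test_that("PDB round trip preserves chains, residues and contacts", {
  t <- simulate_complex(toy_spec(), 4, seed = 9)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(t$structure, f)
  s <- read_structure(f, t$structure$chain_map)
  expect_identical(sort(unique(s$atoms$chain)), c("A", "B"))
  expect_identical(nrow(unique(s$atoms[s$atoms$chain == "A",
                                       c("resno", "ins")])), 20L)
  expect_identical(contact_pair_keys(find_contacts(s)),
                   contact_pair_keys(find_contacts(t$structure)))
})

test_that("chain-map validation: absent chains error, unmapped chains warn", {
  t <- simulate_complex(toy_spec(), 0, seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(t$structure, f)
  bad <- rbind(t$structure$chain_map,
               data.frame(chain = "Z", component = "PZ",
                          molecule_class = "protein"))
  expect_error(read_structure(f, bad), "Z")
  partial <- t$structure$chain_map[1, , drop = FALSE]
  expect_warning(s <- read_structure(f, partial), "unmapped")
  expect_identical(unique(s$atoms$chain), "A")
})

test_that("altlocs resolve to the highest-occupancy copy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  GLY B   1       3.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  s <- read_structure(f, data.frame(chain = c("A", "B"),
                                    component = c("P1", "P2"),
                                    molecule_class = "protein"))
  a <- s$atoms[s$atoms$chain == "A", ]
  expect_identical(nrow(a), 1L)
  expect_equal(a$x, 1.0)  # the 0.60-occupancy copy
})

test_that("generic contact cutoff is sharp at 5.0 A", {
  expect_gte(nrow(find_contacts(two_atom_structure(4.9))), 1L)
  expect_identical(nrow(find_contacts(two_atom_structure(5.1))), 0L)
})

test_that("typed contacts fire on the right atom classes", {
  # oppositely charged side-chain atoms at 5.5 A: ionic only
  s <- two_atom_structure(5.5, resname = c("ASP", "LYS"),
                          atom = c("OD1", "NZ"), element = c("O", "N"))
  cc <- find_contacts(s)
  expect_identical(unique(cc$type), "ionic")
  # N/O pair at 3.0 A: hbond and generic
  s2 <- two_atom_structure(3.0, resname = c("SER", "SER"),
                           atom = c("OG", "OG"), element = c("O", "O"))
  expect_setequal(unique(find_contacts(s2)$type), c("generic", "hbond"))
  # apolar side-chain carbons at 4.5 A: hydrophobic and generic
  s3 <- two_atom_structure(4.5, resname = c("LEU", "LEU"),
                           atom = c("CD1", "CD1"), element = c("C", "C"))
  expect_setequal(unique(find_contacts(s3)$type), c("generic", "hydrophobic"))
  # protein charged group vs RNA phosphate at 5.5 A: ionic
  s4 <- two_atom_structure(5.5, resname = c("LYS", "A"),
                           atom = c("NZ", "OP1"), element = c("N", "O"),
                           molclass = c("protein", "RNA"))
  expect_true("ionic" %in% find_contacts(s4)$type)
})

test_that("contact detection equals the brute-force oracle on seeded toys", {
  for (seed in 1:10) {
    t <- simulate_complex(toy_spec(3, 15), 5, seed = seed)
    cc <- find_contacts(t$structure)
    expect_identical(contact_pair_keys(cc),
                     oracle_residue_pairs(t$structure, 5.0))
  }
})

test_that("the residue-pair relation is symmetric under chain order swap", {
  t <- simulate_complex(toy_spec(), 5, seed = 21)
  swapped <- t$structure
  swapped$atoms <- swapped$atoms[order(swapped$atoms$chain,
                                       decreasing = TRUE), ]
  expect_identical(contact_pair_keys(find_contacts(t$structure)),
                   contact_pair_keys(find_contacts(swapped)))
})

test_that("interface sets come in ordered pairs per touching component pair", {
  t <- simulate_complex(toy_spec(), 5, seed = 2)
  sets <- interface_sets(find_contacts(t$structure))
  expect_identical(nrow(unique(sets[, c("owner", "partner")])), 2L)
  expect_identical(nrow(interface_sets(find_contacts(t$structure)[0, ])), 0L)
  # 3 components pairwise touching -> 6 ordered sets
  atoms <- data.frame(chain = c("A", "B", "C"),
                      component = c("P1", "P2", "P3"),
                      molecule_class = "protein", resno = 1L, ins = "",
                      resname = "GLY", atom = "CA", element = "C",
                      x = c(0, 3, 1.5), y = c(0, 0, 2.6), z = 0)
  tri <- complex_structure("tri", atoms)
  sets3 <- interface_sets(find_contacts(tri))
  expect_identical(nrow(unique(sets3[, c("owner", "partner")])), 6L)
})

test_that("interface residues are listed once regardless of contact count", {
  t <- simulate_complex(toy_spec(), 5, seed = 2, sidechains = TRUE)
  sets <- interface_sets(find_contacts(t$structure))
  expect_false(any(duplicated(
    sets[, c("owner", "partner", "chain", "resno", "ins")])))
})

test_that("multi-structure union maps residues and keeps provenance", {
  set1 <- data.frame(owner = "P1", partner = "P2", chain = "A",
                     resno = c(10, 11, 12), ins = "", resname = "GLY",
                     types = "generic", structures = "s1", n_contacts = 1L)
  set2 <- set1
  set2$structures <- "s2"
  u <- union_interfaces(list(set1, set2))
  expect_identical(u$set$ref_pos, c(10, 11, 12))
  expect_identical(unique(u$set$structures), "s1,s2")

  set3 <- set1
  set3$resno <- c(20, 21, 22, 23)[1:3]
  set3$resno <- c(20, 21, 22)
  set4 <- set1
  set4$resno <- c(30, 31, 32, 33)[1:3]
  u2 <- union_interfaces(list(set3, set4))
  expect_identical(nrow(u2$set), 6L)

  # cross-species union through an explicit 5-residue mapping table:
  # yeast structure s1 numbers 101..105, human structure s2 numbers 201..205,
  # both onto reference positions 1..5
  mapping <- data.frame(structure = rep(c("s1", "s2"), each = 5),
                        resno = c(101:105, 201:205),
                        ref_pos = rep(1:5, 2))
  ys <- data.frame(owner = "P1", partner = "P2", chain = "A",
                   resno = c(101, 103), ins = "", resname = "GLY",
                   types = "generic", structures = "s1", n_contacts = 1L)
  hs <- data.frame(owner = "P1", partner = "P2", chain = "A",
                   resno = c(203, 205, 299), ins = "", resname = "GLY",
                   types = "generic", structures = "s2", n_contacts = 1L)
  u3 <- union_interfaces(list(ys, hs), mapping = mapping)
  expect_identical(u3$set$ref_pos, c(1L, 3L, 5L))
  expect_identical(u3$set$structures[u3$set$ref_pos == 3], "s1,s2")
  expect_identical(u3$unmapped$resno, 299)  # reported, not dropped

  bad_map <- rbind(mapping, data.frame(structure = "s1", resno = 101,
                                       ref_pos = 9))
  expect_error(union_interfaces(list(ys), mapping = bad_map), "conflict")
})

test_that("percent at interface uses set semantics and is monotone", {
  sets <- data.frame(owner = "P1", partner = c(rep("P2", 10)),
                     chain = "A", resno = 1:10, ins = "", resname = "GLY",
                     types = "generic", structures = "s", n_contacts = 1L)
  expect_equal(percent_interface(sets, "P1", 100), 10)
  # same residue contacting a second partner counts once
  sets2 <- rbind(sets, transform(sets[1, ], partner = "P3"))
  expect_equal(percent_interface(sets2, "P1", 100), 10)
  expect_equal(percent_interface(sets, "nope", 100), 0)
  expect_error(percent_interface(sets, "P1", 0), "denominator")
  # monotone as partners are added
  expect_gte(percent_interface(rbind(sets, transform(sets, partner = "P4",
                                                     resno = resno + 5)),
                               "P1", 100),
             percent_interface(sets, "P1", 100))
})

test_that("overlap classification requires two distinct partners", {
  sets <- data.frame(owner = "P1", partner = c("X", "Y", "X"),
                     chain = "A", resno = c(5, 5, 6), ins = "",
                     resname = "GLY", types = "generic", structures = "s",
                     n_contacts = 1L)
  cl <- classify_overlap(sets, "P1")
  expect_identical(cl$class[cl$resno == 5], "overlapping")
  expect_identical(cl$class[cl$resno == 6], "non_overlapping")
  one <- sets[sets$partner == "X", ]
  expect_true(all(classify_overlap(one, "P1")$class == "non_overlapping"))
})
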