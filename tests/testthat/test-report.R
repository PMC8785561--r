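test_that("protein summaries are plain arithmetic means", {
  tr <- fake_track(rep(0.5, 10))
  s <- protein_summary(tr, list(mean_percent = 40), 12.5, "P1", 8)
  expect_equal(s$mean_windowed_jsd, 0.5)
  tr2 <- fake_track(c(0, 1))
  expect_equal(protein_summary(tr2, list(mean_percent = 40), 0, "P1",
                               2)$mean_windowed_jsd, 0.5)
  expect_error(protein_summary(fake_track(numeric(0)),
                               list(mean_percent = 1), 0, "P", 2), "empty")
})

test_that("end-to-end summary means equal direct recomputation", {
  t <- simulate_msa(15, 40, 8, seed = 3)
  tr <- jsd_track(t$alignment)
  pi <- pairwise_identity(t$alignment)
  s <- protein_summary(tr, pi, 0, "P1", 15)
  expect_equal(s$mean_windowed_jsd, mean(tr$windowed_jsd),
               tolerance = 1e-9)
  expect_equal(s$mean_identity,
               mean(pi$pairs$identity[!pi$pairs$flagged]), tolerance = 1e-9)
})

test_that("interface conservation matrix averages mapped owner residues", {
  ifc <- data.frame(owner = "P1", partner = "P2", ref_pos = c(1, 2))
  tracks <- list(P1 = fake_track(c(0.4, 0.6)))
  mappings <- list(P1 = identity_mapping(2))
  m <- interface_conservation_matrix(ifc, tracks, mappings)
  expect_equal(m$mean_jsd["P1", "P2"], 0.5)
  expect_identical(m$support["P1", "P2"], 2L)
  # a pair with no residues stays NA, not 0
  ifc2 <- rbind(ifc, data.frame(owner = "P1", partner = "P3", ref_pos = 99))
  tracks2 <- list(P1 = fake_track(c(0.4, 0.6)))
  m2 <- interface_conservation_matrix(ifc2, tracks2,
                                      list(P1 = identity_mapping(2)))
  expect_true(is.na(m2$mean_jsd["P1", "P3"]))
  expect_identical(m2$unmapped$ref_pos, 99)
  expect_error(interface_conservation_matrix(
    data.frame(owner = "PX", partner = "P2", ref_pos = 1), tracks,
    mappings), "missing a conservation track")
})

test_that("a three-component fixture reproduces the hand-computed matrix", {
  # planted contacts: P1:1-P2:1, P1:2-P2:2, P1:3-P3:1, P2:3-P3:2,
  # P1:1-P3:3, P2:1-P3:3 (owner-side residues read off by hand)
  ifc <- data.frame(
    owner   = c("P1", "P1", "P2", "P2", "P1", "P3", "P2", "P3", "P1", "P3",
                "P2", "P3"),
    partner = c("P2", "P2", "P1", "P1", "P3", "P1", "P3", "P2", "P3", "P1",
                "P3", "P2"),
    ref_pos = c(1, 2, 1, 2, 3, 1, 3, 2, 1, 3, 1, 3))
  tracks <- list(P1 = fake_track(c(0.9, 0.5, 0.1)),
                 P2 = fake_track(c(0.2, 0.4, 0.6)),
                 P3 = fake_track(c(0.3, 0.7, 0.8)))
  mappings <- list(P1 = identity_mapping(3), P2 = identity_mapping(3),
                   P3 = identity_mapping(3))
  m <- interface_conservation_matrix(ifc, tracks, mappings)
  expect_equal(m$mean_jsd["P1", "P2"], mean(c(0.9, 0.5)))
  expect_equal(m$mean_jsd["P2", "P1"], mean(c(0.2, 0.4)))
  expect_equal(m$mean_jsd["P1", "P3"], mean(c(0.1, 0.9)))
  expect_equal(m$mean_jsd["P3", "P1"], mean(c(0.3, 0.8)))
  expect_equal(m$mean_jsd["P2", "P3"], mean(c(0.6, 0.2)))
  expect_equal(m$mean_jsd["P3", "P2"], mean(c(0.7, 0.8)))
})

test_that("overlap comparison: degenerate ties give p = 1", {
  cls <- data.frame(resno = 1:4,
                    class = c("overlapping", "overlapping",
                              "non_overlapping", "non_overlapping"))
  tr <- fake_track(rep(0.5, 4))
  res <- overlap_compare(tr, cls, identity_mapping(4))
  expect_equal(res$p_value, 1)
  expect_equal(res$mean_overlapping, res$mean_non_overlapping)
})

test_that("overlap comparison: extreme separation gives the exact U p-value", {
  cls <- data.frame(resno = 1:4,
                    class = c("overlapping", "overlapping",
                              "non_overlapping", "non_overlapping"))
  tr <- fake_track(c(0.9, 0.8, 0.1, 0.2))
  res <- overlap_compare(tr, cls, identity_mapping(4))
  expect_equal(res$mean_overlapping - res$mean_non_overlapping, 0.7)
  # most extreme of the choose(4,2) = 6 arrangements, two-sided
  expect_equal(res$p_value, 2 / 6, tolerance = 1e-12)
})

test_that("planted elevated conservation is detected in the right direction", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    n <- 30
    jsd <- pmin(1, pmax(0, c(rnorm(10, 0.7, 0.1), rnorm(20, 0.3, 0.1))))
    cls <- data.frame(resno = 1:n,
                      class = c(rep("overlapping", 10),
                                rep("non_overlapping", 20)))
    res <- overlap_compare(fake_track(jsd), cls, identity_mapping(n))
    if (res$mean_overlapping > res$mean_non_overlapping) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("critical pair rule is two-sided and order-invariant", {
  pairs <- data.frame(component_a = "P1", ref_pos_a = 1:3,
                      component_b = "P2", ref_pos_b = 1:3)
  tracks <- list(P1 = fake_track(c(0.55, 0.55, 0.45)),
                 P2 = fake_track(c(0.45, 0.39, 0.45)))
  mappings <- list(P1 = identity_mapping(3), P2 = identity_mapping(3))
  got <- critical_pairs(pairs, tracks, mappings)
  expect_identical(got$ref_pos_a, 1L)  # (0.55, 0.45) only
  swapped <- data.frame(component_a = "P2", ref_pos_a = 1:3,
                        component_b = "P1", ref_pos_b = 1:3)
  got2 <- critical_pairs(swapped, tracks, mappings)
  expect_identical(got2$ref_pos_a, 1L)
  expect_equal(sort(c(got$jsd_a, got$jsd_b)),
               sort(c(got2$jsd_a, got2$jsd_b)))
})

test_that("site reports resolve sites, compositions and the threshold fraction", {
  aln <- msa(c("KKAA", "KKAA", "KKCA", "RRCA", "RRCA", "RRCA"),
             ids = sprintf("s%d", 1:6))
  mp <- map_reference(aln, "s1")
  tr <- jsd_track(aln)
  sites <- data.frame(ref_pos = c(1, 2, 3, 99),
                      label = c("siteA", "siteB", "siteC", "ghost"))
  groups <- data.frame(id = sprintf("s%d", 1:6),
                       group = rep(c("metazoa", "fungi"), each = 3))
  rep <- site_report(sites, tr, aln, mp, taxon_groups = groups)
  expect_identical(rep$unmapped$ref_pos, 99)
  expect_identical(nrow(rep$sites), 4L)
  # disjoint residues at column 1: point masses on K and R per group
  c1 <- rep$composition[rep$composition$ref_pos == 1, ]
  expect_equal(c1$freq[c1$group == "metazoa" & c1$residue == "K"], 1)
  expect_equal(c1$freq[c1$group == "fungi" & c1$residue == "R"], 1)
})

test_that("the above-threshold fraction is strict and monotone in threshold", {
  tr <- fake_track(c(0.9, 0.5, 0.3, 0.41))
  sites <- data.frame(ref_pos = 1:4, label = letters[1:4])
  aln <- msa(c("AAAA", "AAAA"))
  mp <- identity_mapping(4)
  r <- site_report(sites, tr, aln, mp, threshold = 0.4)
  expect_equal(r$fraction_above, 0.75)
  # strictness: a site exactly at the threshold does not count
  r2 <- site_report(sites, tr, aln, mp, threshold = 0.41)
  expect_equal(r2$fraction_above, 0.5)
  fr <- vapply(c(0, 0.3, 0.41, 0.5, 0.9),
               function(th) site_report(sites, tr, aln, mp,
                                        threshold = th)$fraction_above,
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})
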