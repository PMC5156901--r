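# Ligand classification, site extraction, motif matching, census,
# coordination geometry.

test_that("ligand classification follows the donor table exactly", {
  expect_equal(classify_ligand("ASP", "OD1"), "carboxylate_O")
  expect_equal(classify_ligand("ASP", "OD2"), "carboxylate_O")
  expect_equal(classify_ligand("GLU", "OE1"), "carboxylate_O")
  expect_equal(classify_ligand("GLU", "OE2"), "carboxylate_O")
  expect_equal(classify_ligand("HIS", "ND1"), "imidazole_N")
  expect_equal(classify_ligand("HIS", "NE2"), "imidazole_N")
  expect_equal(classify_ligand("PRO", "O"), "backbone_carbonyl_O")
  expect_equal(classify_ligand("GLY", "O"), "backbone_carbonyl_O")
  expect_equal(classify_ligand("HOH", "O"), "water_O")
  expect_equal(classify_ligand("WAT", "O"), "water_O")
  expect_equal(classify_ligand("LYS", "NZ"), "other")
  expect_equal(classify_ligand("XYZ", "O"), "other")

  # property: atoms outside the table always classify as "other"
  set.seed(31)
  table_keys <- c("ASP OD1", "ASP OD2", "GLU OE1", "GLU OE2", "HIS ND1",
                  "HIS NE2", "HOH O", "WAT O")
  resnames <- c("ALA", "ARG", "LYS", "SER", "TYR", "TRP", "MET", "FOO")
  atomnames <- c("CB", "CG", "NZ", "OG", "OH", "SD", "NE1", "CD1", "OXT")
  for (i in 1:50) {
    rn <- sample(resnames, 1)
    an <- sample(atomnames, 1)
    if (paste(rn, an) %in% table_keys || an == "O") next
    expect_equal(classify_ligand(rn, an), "other",
                 label = paste(rn, an))
  }
})

test_that("site extraction respects the distance cutoff", {
  s <- manual_site_structure(list(
    list(name = "OD1", resname = "ASP", pos = c(2.9, 0, 0)),
    list(name = "OD2", resname = "ASP", pos = c(0, 3.1, 0))))
  sites <- extract_sites(s, "Cd", cutoff = 3.0)
  expect_length(sites, 1L)
  expect_equal(nrow(sites[[1]]$ligands), 1L)
  expect_equal(sites[[1]]$ligands$distance, 2.9)
  expect_equal(sites[[1]]$ligands$ligand_class, "carboxylate_O")

  # metal-free structure: no sites
  pep <- read_structure(write_tmp_lines(peptide_pdb_lines()))
  expect_length(extract_sites(pep, "Cd", 3.0), 0L)
})

test_that("the refined-site fixture classifies as carboxylate, imidazole, backbone O, water", {
  fix <- gen_metal_fixtures(list(list(
    metal = "Cd", ligands = c("ASP:OD1", "HIS:ND1", "PRO:O", "HOH:O"),
    distances = c(2.14, 2.21, 2.22, 2.26), geometry = "tetrahedral")),
    seed = 6)
  site <- extract_sites(fix$structures$site_1, "Cd", 3.0)[[1]]
  expect_setequal(site$ligands$ligand_class,
                  c("carboxylate_O", "imidazole_N", "backbone_carbonyl_O",
                    "water_O"))
  expect_true(match_motif(site, motif_ung_like()))
  expect_true(match_motif(site, motif_exact_site()))
  # ligands are sorted by distance and reported as constructed
  expect_equal(sort(site$ligands$distance), c(2.14, 2.21, 2.22, 2.26),
               tolerance = 1e-9)
  expect_false(is.unsorted(site$ligands$distance))
})

test_that("motif matching counts residues, not donor atoms", {
  ung <- motif_ung_like()
  two_his <- manual_site_structure(list(
    list(name = "OD1", resname = "ASP", pos = c(2.2, 0, 0), resid = 2),
    list(name = "ND1", resname = "HIS", element = "N",
         pos = c(0, 2.2, 0), resid = 3),
    list(name = "NE2", resname = "HIS", element = "N",
         pos = c(0, 0, 2.2), resid = 4)))
  expect_false(match_motif(extract_sites(two_his, "Cd", 3)[[1]], ung))

  # bidentate aspartate: both oxygens of one residue count once
  bidentate <- manual_site_structure(list(
    list(name = "OD1", resname = "ASP", pos = c(2.2, 0, 0), resid = 2),
    list(name = "OD2", resname = "ASP", pos = c(2.2, 1.0, 0), resid = 2),
    list(name = "ND1", resname = "HIS", element = "N",
         pos = c(0, 0, 2.2), resid = 3)))
  expect_true(match_motif(extract_sites(bidentate, "Cd", 3)[[1]], ung))

  # same two residues on DIFFERENT aspartates: two carboxyls, no match
  two_asp <- manual_site_structure(list(
    list(name = "OD1", resname = "ASP", pos = c(2.2, 0, 0), resid = 2),
    list(name = "OD2", resname = "ASP", pos = c(2.2, 1.0, 0), resid = 5),
    list(name = "ND1", resname = "HIS", element = "N",
         pos = c(0, 0, 2.2), resid = 3)))
  expect_false(match_motif(extract_sites(two_asp, "Cd", 3)[[1]], ung))

  # strict motif rejects non-table donors
  with_other <- manual_site_structure(list(
    list(name = "OD1", resname = "ASP", pos = c(2.2, 0, 0), resid = 2),
    list(name = "ND1", resname = "HIS", element = "N",
         pos = c(0, 2.2, 0), resid = 3),
    list(name = "O", resname = "PRO", pos = c(0, 0, 2.2), resid = 4),
    list(name = "NZ", resname = "LYS", element = "N",
         pos = c(-2.2, 0, 0), resid = 5)))
  site <- extract_sites(with_other, "Cd", 3)[[1]]
  expect_true(match_motif(site, ung))            # relaxed allows others
  expect_false(match_motif(site, motif_exact_site()))
})

test_that("census matches constructed ground truth and is order-invariant", {
  fix <- ung_like_fixture_set(seed = 17)
  res <- census(fix$structures, metals = "Cd", spec = motif_ung_like(),
                cutoff = 3.0)
  expect_equal(res$n_structures, 10L)
  expect_equal(res$n_sites, 10L)
  expect_equal(res$n_matches, sum(fix$truth$expected_match))
  expect_equal(res$n_matches, 3L)
  expect_equal(res$percent_matches, 30.0)

  # per-structure additivity
  per_structure <- vapply(fix$structures, function(s) {
    sum(vapply(extract_sites(s, "Cd", 3.0), match_motif, TRUE,
               spec = motif_ung_like()))
  }, 0)
  expect_equal(sum(per_structure), res$n_matches)

  # shuffling the structure list changes nothing
  set.seed(8)
  shuffled <- fix$structures[sample(seq_along(fix$structures))]
  res2 <- census(shuffled, metals = "Cd", spec = motif_ung_like(),
                 cutoff = 3.0)
  expect_equal(as.data.frame(res2), as.data.frame(res))

  # scanning for a metal that is absent: zero sites, percentage undefined
  res3 <- census(fix$structures, metals = "Zn", spec = motif_ung_like())
  expect_equal(res3$n_sites, 0L)
  expect_true(is.na(res3$percent_matches))
})

test_that("coordination geometry: tau4 and angle deviations", {
  verts <- tetrahedral_unit_vectors()
  tet <- manual_site_structure(lapply(1:4, function(i) {
    list(name = "O", resname = "HOH", pos = verts[i, ] * 2.2,
         resid = i + 1, hetero = TRUE)
  }))
  g <- coordination_geometry(extract_sites(tet, "Cd", 3)[[1]])
  expect_equal(g$coordination_number, 4L)
  expect_equal(g$tau4, 1.0, tolerance = 1e-9)
  expect_equal(g$mean_abs_dev_from_109_47, 0, tolerance = 1e-9)

  sq <- manual_site_structure(list(
    list(name = "O", resname = "HOH", pos = c(2.2, 0, 0), resid = 2),
    list(name = "O", resname = "HOH", pos = c(-2.2, 0, 0), resid = 3),
    list(name = "O", resname = "HOH", pos = c(0, 2.2, 0), resid = 4),
    list(name = "O", resname = "HOH", pos = c(0, -2.2, 0), resid = 5)))
  g2 <- coordination_geometry(extract_sites(sq, "Cd", 3)[[1]])
  expect_equal(g2$tau4, 0.0, tolerance = 1e-9)

  # constructed distances are reported exactly (sorted by distance)
  fix <- gen_metal_fixtures(list(list(
    metal = "Cd", ligands = c("ASP:OD1", "HIS:ND1", "PRO:O", "HOH:O"),
    distances = c(2.14, 2.21, 2.22, 2.26), geometry = "tetrahedral")),
    seed = 2)
  g3 <- coordination_geometry(extract_sites(fix$structures$site_1,
                                            "Cd", 3)[[1]])
  expect_equal(g3$distances, c(2.14, 2.21, 2.22, 2.26), tolerance = 1e-9)

  # tau4 is invariant to ligand relabeling (row order)
  site <- extract_sites(tet, "Cd", 3)[[1]]
  site$ligands <- site$ligands[c(3, 1, 4, 2), ]
  expect_equal(coordination_geometry(site)$tau4, g$tau4)

  # fewer than four ligands: no tau4; fewer than two: error
  tri <- manual_site_structure(lapply(1:3, function(i) {
    list(name = "O", resname = "HOH", pos = verts[i, ] * 2.2, resid = i + 1)
  }))
  expect_true(is.na(coordination_geometry(
    extract_sites(tri, "Cd", 3)[[1]])$tau4))
  mono <- manual_site_structure(list(
    list(name = "O", resname = "HOH", pos = c(2.2, 0, 0), resid = 2)))
  expect_error(coordination_geometry(extract_sites(mono, "Cd", 3)[[1]]),
               "at least 2")
})
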