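test_that("the mini-channel has the prescribed architecture", {
  mc <- shared_channel()
  res <- structure_residues(mc$open)
  p <- mc$info$params
  expect_equal(nrow(res), 4L * (3L * p$res_per_helix + p$p_len))
  ann <- mc$annotation
  expect_setequal(unique(ann$segment), c("k", "o", "p", "i"))
  expect_setequal(unique(ann$domain), 1:4)
  # every residue is covered by the annotation
  labs <- assign_labels(mc$open, ann)
  expect_equal(nrow(labs), nrow(res))
})

test_that("the two gating states share P1 exactly and differ elsewhere", {
  mc <- shared_channel()
  expect_equal(rmsd_subset(mc$open, mc$inactivated, "p1-ca"), 0)
  expect_gt(rmsd_subset(mc$open, mc$inactivated, "ca"), 0.5)
  expect_identical(mc$open$state, "open_pm")
  expect_identical(mc$inactivated$state, "inactivated_pm")
})

test_that("mini-channel construction is deterministic", {
  a <- make_mini_channel()
  b <- make_mini_channel()
  expect_identical(coords(a$open), coords(b$open))
  expect_identical(coords(a$inactivated), coords(b$inactivated))
  expect_identical(a$info$planted_pose, b$info$planted_pose)
})

test_that("sensing hosts span k, o and i segments of the pocket domains", {
  mc <- shared_channel()
  seg <- substr(mc$info$sensing, 1, 2)
  expect_true(any(seg == "2k"))
  expect_true(any(seg == "2o"))
  expect_true(any(seg == "3i"))
})

test_that("toy ligands carry the class-defining groups", {
  t2 <- make_toy_ligand("type2")
  expect_equal(nrow(t2$xb_donors), 2L)
  expect_identical(t2$atoms$element[t2$xb_donors[, 2L]], c("Br", "Br"))
  expect_true(all(c("CNC", "NN") %in% t2$atoms$name))
  expect_gte(length(t2$torsions), 3L)
  expect_equal(sum(t2$atoms$charge), 0, tolerance = 1e-9)
  t1 <- make_toy_ligand("type1")
  expect_identical(t1$atoms$element[t1$xb_donors[, 2L]], c("Cl", "Cl"))
  expect_false(any(c("CNC", "NN") %in% t1$atoms$name))
  expect_equal(sum(t1$atoms$charge), 0, tolerance = 1e-9)
  # bonded distances are chemically sane
  blen <- sqrt(rowSums((t2$xyz[t2$bonds[, 1L], ] -
                          t2$xyz[t2$bonds[, 2L], ])^2))
  expect_true(all(blen > 1.1 & blen < 2.0))
})

test_that("planted truth is a verified local minimum with stable contacts", {
  mc <- shared_channel()
  tr1 <- shared_truth()
  expect_s3_class(tr1, "planted_truth")
  # self-consistency: expected contacts equal the oracle contacts
  cc <- ligand_contacts(mc$open, tr1$pose, tr1$ligand, cutoff = 4)
  expect_identical(tr1$expected_contacts, cc$label)
  expect_true(all(tr1$sensing_contacts %in% cc$label))
  # inactivation loses at least one planted contact
  expect_gte(length(tr1$expected_lost), 1L)
  # different seeds: distinct conformers, same contact story
  tr2 <- make_docking_truth(mc, seed = 7)
  expect_false(identical(tr1$pose, tr2$pose))
  expect_true(length(intersect(tr1$sensing_contacts,
                               tr2$sensing_contacts)) >= 3L)
})

test_that("write_fixtures emits a complete regenerable set", {
  dir <- tempfile("fixtures")
  paths <- write_fixtures(dir)
  expect_true(all(file.exists(paths)))
  open <- read_structure(paths[["open"]],
                         annotation = read_annotation(paths[["annotation"]]))
  expect_identical(open$state, "open_pm")
  lig <- ligand_from_sdf(paths[["ligand"]])
  expect_equal(nrow(lig$atoms), 19L)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_true(length(truth$expected_contacts) >= 3L)
  unlink(dir, recursive = TRUE)
})
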