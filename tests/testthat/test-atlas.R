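test_that("the packaged atlas loads completely with linked combinations", {
  atlas <- load_kdr_atlas()
  expect_s3_class(atlas, "kdr_atlas")
  expect_gt(nrow(atlas$mutations), 100)
  # combination rows are split into linked records sharing a group
  m918 <- atlas$mutations[atlas$mutations$raw == "M918/2k11T" &
                            atlas$mutations$table == "table1", ]
  expect_true(any(m918$combination))
  grp <- m918$group[m918$combination][1L]
  partners <- atlas$mutations[atlas$mutations$group == grp, ]
  expect_equal(nrow(partners), 2L)
  expect_setequal(partners$site, c("PyR1", "PyR2"))
  expect_setequal(partners$universal, c("2k11", "2i16"))
  # records without a universal label survive with their region
  m827 <- atlas$mutations[atlas$mutations$native %in% 827, ]
  expect_true(all(is.na(m827$universal)))
  expect_true("IIS1-S2" %in% m827$region)
  # loading is deterministic and order-stable
  atlas2 <- load_kdr_atlas()
  expect_identical(atlas$mutations, atlas2$mutations)
})

test_that("malformed or empty atlas files are load errors", {
  f <- tempfile(fileext = ".tsv")
  writeLines("table\tgroup\traw\twt\tnative\tuniversal\tsub\tsite\tspecies", f)
  expect_error(load_kdr_atlas(f), "empty")
  writeLines(c("table\tgroup\traw\twt\tnative\tuniversal\tsub\tsite\tspecies",
               "tablex\t1\t\t\t\t\t\tPyR1\tspp"), f)
  expect_error(load_kdr_atlas(f), "malformed")
})

test_that("site classification reproduces every transcribed location", {
  atlas <- load_kdr_atlas()
  expect_identical(classify_site("2k11", atlas), "PyR1")
  expect_identical(classify_site("1k11", atlas), "PyR2")
  expect_identical(classify_site("3k10", atlas), "beyond")
  expect_identical(classify_site("M918/2k11", atlas), "PyR1")
  expect_identical(classify_site(universal_label("V", 1, "k", 11), atlas),
                   "PyR2")
  # zero mismatches across all table-1/2 records with universal labels
  rec <- atlas$mutations[!is.na(atlas$mutations$universal) &
                           atlas$mutations$site %in% c("PyR1", "PyR2"), ]
  got <- vapply(rec$universal, classify_site, "", membership = atlas)
  expect_identical(unname(got), rec$site)
  # the inner-helix IIS6 labels split between the two sites by depth,
  # so membership must be per-label data
  expect_identical(classify_site("2i16", atlas), "PyR2")
  expect_identical(classify_site("2i18", atlas), "PyR1")
  # beyond-site records never claim membership
  bey <- atlas$mutations[!is.na(atlas$mutations$universal) &
                           atlas$mutations$site == "beyond", ]
  expect_true(all(vapply(bey$universal, classify_site, "",
                         membership = atlas) == "beyond"))
})

test_that("conflicting membership entries are surfaced, not resolved", {
  bad <- rbind(kdr_mutation("X1/2k11A", "X", "A", 1, "2k11", site = "PyR1"),
               kdr_mutation("X2/2k11B", "X", "B", 2, "2k11", site = "PyR2"))
  expect_error(site_membership(bad), "conflicting")
})

test_that("mutation_report resolves labels against a structure", {
  mc <- shared_channel()
  tr <- shared_truth()
  muts <- do.call(rbind, c(
    lapply(tr$sensing_contacts, function(lab)
      kdr_mutation(paste0(lab, "A"), wt = "X", sub = "A", universal = lab,
                   site = "PyR1")),
    list(kdr_mutation("Q9999Z", wt = "Q", sub = "Z", native = 9999))))
  rep <- mutation_report(mc$open, muts,
                         poses = list(list(ligand = tr$ligand,
                                           xyz = tr$pose)))
  expect_equal(nrow(rep$resolved), length(tr$sensing_contacts))
  expect_true(all(rep$resolved$ligand_contact))
  expect_true(all(is.finite(rep$resolved$min_dist)))
  # the record without a resolvable label is listed separately
  expect_equal(nrow(rep$unresolved), 1L)
  expect_identical(rep$unresolved$raw, "Q9999Z")
  # without poses the contact fields are absent but sites are reported
  rep2 <- mutation_report(mc$open, muts)
  expect_false("ligand_contact" %in% names(rep2$resolved))
  expect_true(all(rep2$resolved$site_class == "PyR1"))
  # beyond-site mutations get an intersegment environment
  muts3 <- kdr_mutation("1o7A", wt = "S", sub = "A", universal = "1o7")
  rep3 <- mutation_report(mc$open, muts3)
  expect_true("1o7" %in% names(rep3$environment))
  expect_gt(nrow(rep3$environment[["1o7"]]), 0)
})
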