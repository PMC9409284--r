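test_that("PDB write/read round-trip preserves atoms, numbering and state", {
  mc <- shared_channel()
  f <- tempfile(fileext = ".pdb")
  write_structure(mc$open, f)
  back <- read_structure(f, annotation = mc$annotation)
  expect_equal(nrow(back$atoms), nrow(mc$open$atoms))
  expect_identical(back$atoms$resno, mc$open$atoms$resno)
  expect_identical(back$state, "open_pm")
  expect_lt(max(abs(coords(back) - coords(mc$open))), 1e-3 + 1e-9)
})

test_that("truncated and malformed PDB files raise parse errors", {
  mc <- shared_channel()
  f <- tempfile(fileext = ".pdb")
  write_structure(mc$open, f)
  lines <- readLines(f)
  atom_line <- grep("^ATOM", lines)[5L]
  trunc <- tempfile(fileext = ".pdb")
  writeLines(c(lines[seq_len(atom_line - 1L)],
               substr(lines[atom_line], 1, 40)), trunc)
  expect_error(read_structure(trunc), "line")
  bad <- tempfile(fileext = ".pdb")
  l2 <- lines
  substr(l2[atom_line], 31, 38) <- "   abc  "
  writeLines(l2, bad)
  expect_error(read_structure(bad), "malformed")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("mmCIF atom_site loops parse with auth numbering", {
  f <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_mini", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.auth_atom_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "ATOM 1 C CA ALA 101 1.000 2.000 3.000",
    "ATOM 2 C CB ALA 101 2.500 2.000 3.000",
    "HETATM 3 O O HOH 500 9.000 9.000 9.000",
    "#"), f)
  s <- read_structure(f, format = "mmcif")
  expect_equal(nrow(s$atoms), 3L)
  expect_identical(s$atoms$resno, c(101L, 101L, 500L))
  expect_identical(s$atoms$het, c(FALSE, FALSE, TRUE))
  expect_equal(s$atoms$x, c(1, 2.5, 9))
  bad <- tempfile(fileext = ".cif")
  writeLines(c("data_x", "loop_", "_atom_site.group_PDB",
               "_atom_site.Cartn_x", "ATOM 1.0 extra_token_here junk"), bad)
  expect_error(read_structure(bad, format = "mmcif"))
})

test_that("hetero records survive I/O without domain labels", {
  mc <- shared_channel()
  at <- mc$open$atoms
  het <- data.frame(eleno = max(at$eleno) + 1L, elety = "NA", resid = "ION",
                    resno = 9000L, x = 0, y = 0, z = 0, elesy = "Na",
                    het = TRUE, stringsAsFactors = FALSE)
  s <- channel_structure(rbind(at, het), state = "open_pm",
                         annotation = mc$annotation)
  f <- tempfile(fileext = ".pdb")
  write_structure(s, f)
  back <- read_structure(f, annotation = mc$annotation)
  expect_true(any(back$atoms$het))
  labs <- assign_labels(back, mc$annotation)
  expect_false(9000L %in% labs$resno)
})

test_that("ligand SDF round-trip preserves bonds, charges and topology", {
  for (kind in c("type1", "type2")) {
    lig <- make_toy_ligand(kind)
    f <- tempfile(fileext = ".sdf")
    ligand_to_sdf(lig, f)
    back <- ligand_from_sdf(f)
    expect_identical(back$bonds, lig$bonds)
    expect_identical(back$orders, lig$orders)
    expect_identical(back$atoms$formal, lig$atoms$formal)
    expect_equal(back$atoms$charge, lig$atoms$charge, tolerance = 1e-6)
    expect_identical(back$atoms$name, lig$atoms$name)
    expect_lt(max(abs(back$xyz - lig$xyz)), 1e-4)
    expect_identical(back$kind, kind)
  }
})
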