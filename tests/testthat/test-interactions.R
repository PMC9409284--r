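# a minimal single-residue receptor with one atom planted at a given spot
point_receptor <- function(..., state = "open_pm") {
  rows <- list(...)
  at <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(eleno = i, elety = r$elety, resid = r$resid,
               resno = r$resno, x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               elesy = r$elesy, het = FALSE, stringsAsFactors = FALSE)
  }))
  channel_structure(at, state = state)
}

test_that("hydrogen-bond detection follows the two-clause predicate", {
  expect_true(detect_hbond(c(0, 0, 0), c(2.9, 0, 0)))
  expect_false(detect_hbond(c(0, 0, 0), c(3.6, 0, 0)))
  # explicit hydrogen: 165 degrees passes, 100 degrees fails
  d <- c(0, 0, 0); a <- c(2.9, 0, 0)
  h_good <- c(1.0, 0.07, 0)    # nearly along D->A
  expect_true(detect_hbond(d, a, h_good))
  h_bad <- c(-0.17, 0.98, 0)   # D-H points away
  expect_false(detect_hbond(d, a, h_bad))
  expect_error(detect_hbond(d, d), "same atom")
  # grid of geometries vs the predicate evaluated directly
  cr <- interaction_criteria()
  ang3 <- function(p, q, r3) {  # independent angle formula, degrees
    v1 <- p - q; v2 <- r3 - q
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }
  for (r in seq(2.4, 4.0, 0.2)) for (th in seq(90, 180, 15)) {
    a2 <- c(r, 0, 0)
    h <- d + 1.0 * c(cos(pi - th * pi / 180), sin(pi - th * pi / 180), 0)
    got <- detect_hbond(d, a2, h)
    want <- r <= cr$hbond_dist && ang3(d, h, a2) >= cr$hbond_angle
    expect_identical(got, want)
  }
})

test_that("halogen-bond detection gates on distance and sigma-hole angle", {
  c0 <- c(-1.9, 0, 0); x <- c(0, 0, 0)
  # Br + S radii sum 3.65 (+0.2 pad)
  expect_true(detect_halogen_bond(c0, x, c(3.5, 0, 0), "Br", "S"))
  expect_false(detect_halogen_bond(c0, x, c(3.95, 0, 0), "Br", "S"))
  # same distance, angle 100 degrees: rejected
  a_bent <- 3.5 * c(cos(100 * pi / 180), sin(100 * pi / 180), 0)
  expect_false(detect_halogen_bond(c0, x, a_bent, "Br", "S"))
  expect_error(detect_halogen_bond(c0, x, c(3, 0, 0), "C", "S"), "halogen")
  cr <- interaction_criteria()
  for (r in seq(3.0, 4.2, 0.3)) for (ang in seq(120, 180, 10)) {
    a <- r * c(cos((180 - ang) * pi / 180), sin((180 - ang) * pi / 180), 0)
    got <- detect_halogen_bond(c0, x, a, "Br", "S")
    want <- r <= (1.85 + 1.80 + cr$xbond_pad) && ang >= cr$xbond_angle
    expect_identical(got, want)
  }
})

test_that("salt-bridge detection is symmetric and flags missing atoms", {
  o <- rbind(c(0, 0, 0), c(1.2, 1.2, 0))
  n <- rbind(c(2.8, 0, 0))
  expect_true(detect_salt_bridge(o, n))
  expect_true(detect_salt_bridge(n, o))  # chemically symmetric
  expect_false(detect_salt_bridge(rbind(c(0, 0, 0)), rbind(c(4.2, 0, 0))))
  expect_true(is.na(detect_salt_bridge(matrix(0, 0, 3), n)))
  # sweep against the min-distance rule
  for (r in seq(2.5, 5, 0.25)) {
    got <- detect_salt_bridge(rbind(c(0, 0, 0)), rbind(c(r, 0, 0)))
    expect_identical(got, r <= 4.0)
  }
})

test_that("ligand contacts are boundary-inclusive and match the oracle", {
  lig <- make_toy_ligand("type2")
  pose <- lig$xyz
  # probe atoms beyond the ligand's +x extreme: their closest ligand atom
  # is that extreme by construction, at exactly 3.9 and 4.1 A
  tipi <- which.max(pose[, 1])
  near <- point_receptor(list(elety = "CB", resid = "ALA", resno = 1L,
                              xyz = pose[tipi, ] + c(3.9, 0, 0), elesy = "C"),
                         list(elety = "CB", resid = "ALA", resno = 2L,
                              xyz = pose[tipi, ] + c(4.1, 0, 0), elesy = "C"))
  cc <- ligand_contacts(near, pose, lig, cutoff = 4)
  expect_identical(cc$resno, 1L)
  expect_equal(cc$min_dist, 3.9, tolerance = 1e-9)
  # random fixtures vs the all-pairs brute-force oracle
  mc <- shared_channel()
  for (s in 1:100) {
    set.seed(s)
    shift <- runif(3, -14, 14) * c(1, 1, 0.5)
    p2 <- sweep(pose, 2, -(mc$info$pocket_center + shift))
    cc2 <- ligand_contacts(mc$open, p2, lig, cutoff = 4)
    expect_setequal(as.character(cc2$resno), oracle_contacts(mc$open, p2, 4))
  }
})

test_that("contact ordering and class hierarchy are consistent", {
  mc <- shared_channel()
  tr <- shared_truth()
  cc <- ligand_contacts(mc$open, tr$pose, tr$ligand, cutoff = 4)
  labs <- assign_labels(mc$open, mc$annotation)
  m <- match(cc$resno, labs$resno)
  key <- order(labs$domain[m], match(labs$segment[m], c("k", "o", "p", "i")),
               labs$index[m])
  expect_identical(key, seq_len(nrow(cc)))
  # every specially classed contact also satisfies its detector's
  # distance gate
  cr <- interaction_criteria()
  expect_true(all(cc$min_dist[cc$class == "hbond"] <= 4))
  expect_true(all(cc$min_dist > 0))
  # empty ligand: empty contact table
  e <- ligand_contacts(mc$open, tr$pose[0, , drop = FALSE], tr$ligand)
  expect_equal(nrow(e), 0)
})

test_that("contact_diff partitions contacts into lost/gained/retained", {
  mc <- shared_channel()
  tr <- shared_truth()
  a <- interaction_report(mc$open, tr$pose, tr$ligand)
  # identical reports: all retained, nothing lost/gained, diff is empty
  d0 <- contact_diff(a, a)
  expect_equal(nrow(d0$lost), 0)
  expect_equal(nrow(d0$gained), 0)
  expect_equal(nrow(d0$retained), nrow(a$contacts))
  expect_equal(nrow(d0$weakened), 0)
  # drop one residue from b: it must appear in lost
  b <- a
  b$contacts <- b$contacts[-1, ]
  expect_identical(contact_diff(a, b)$lost$resno, a$contacts$resno[1])
  # mismatched ligand ids refuse to compare
  b2 <- a
  b2$ligand_id <- "other"
  expect_error(contact_diff(a, b2), "different ligands")
})

test_that("the planted gate shift loses or weakens the retreating contact", {
  mc <- shared_channel()
  tr <- shared_truth()
  rep_open <- interaction_report(mc$open, tr$pose, tr$ligand)
  rep_in <- interaction_report(mc$inactivated, tr$pose, tr$ligand)
  d <- contact_diff(rep_open, rep_in)
  moved <- unique(c(d$lost$label, d$weakened$label))
  expect_gt(length(moved), 0)
  expect_identical(sort(moved), sort(tr$expected_lost))
  # the retreating residues live on the shifted segments (inner-helix lower
  # halves or the linker helices)
  labs <- assign_labels(mc$open, mc$annotation)
  seg <- labs$segment[match(moved, labs$label)]
  expect_true(all(seg %in% c("i", "k")))
})

test_that("residue_environment reports intersegment neighbors with classes", {
  mc <- shared_channel_s4()
  # planted intersegment hydrogen-bond pair
  envh <- residue_environment(mc$open, mc$info$hbond_pair[1])
  row <- envh[envh$label == mc$info$hbond_pair[2], ]
  expect_equal(nrow(row), 1)
  expect_identical(row$class, "hbond")
  # planted salt bridge between the outer helix and the voltage sensor
  envs <- residue_environment(mc$open, mc$info$salt_bridge_pair[1])
  expect_true("salt_bridge" %in% envs$class)
  # cutoff 0 gives nothing; absent label errors
  expect_equal(nrow(residue_environment(mc$open, "1o7", cutoff = 0)), 0)
  expect_error(residue_environment(mc$open, "4p99"), "not present")
  # same-segment sequential neighbors are excluded
  env2 <- residue_environment(mc$open, "1i6", cutoff = 8)
  labs <- assign_labels(mc$open, mc$annotation)
  m <- match(env2$label, labs$label)
  same <- !is.na(m) & labs$segment[m] == "i" & labs$domain[m] == 1
  expect_true(all(abs(labs$index[m][same] - 6L) > 2L))
})

test_that("interaction reports round-trip to TSV and JSON", {
  mc <- shared_channel()
  tr <- shared_truth()
  rep <- interaction_report(mc$open, tr$pose, tr$ligand,
                            membership = c("2o4" = "PyR1"))
  expect_equal(sum(rep$by_class), nrow(rep$contacts))
  ftsv <- tempfile(fileext = ".tsv")
  write_report(rep, ftsv)
  back <- utils::read.delim(ftsv)
  expect_equal(nrow(back), nrow(rep$contacts))
  fjson <- tempfile(fileext = ".json")
  write_report(rep, fjson)
  js <- jsonlite::read_json(fjson, simplifyVector = TRUE)
  expect_identical(js$state, "open_pm")
  expect_equal(nrow(js$contacts), nrow(rep$contacts))
})
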