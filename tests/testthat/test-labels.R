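test_that("labels parse in single, prefixed and dual notation", {
  p <- parse_label("M918/2k11")
  expect_equal(p$label$aa, "M")
  expect_equal(p$label$domain, 2L)
  expect_equal(p$label$segment, "k")
  expect_equal(p$label$index, 11L)
  expect_equal(p$native$resnum, 918L)

  p2 <- parse_label("V253/1k11")
  expect_equal(p2$label$aa, "V")
  expect_equal(p2$native$resnum, 253L)

  p3 <- parse_label("2i16")
  expect_true(is.na(p3$label$aa))
  expect_null(p3$native)

  expect_error(parse_label("2x11"), "segment")
  expect_error(parse_label("5k11"))
  expect_error(parse_label("2k0"))
})

test_that("format_label inverts parse_label on every atlas label", {
  atlas <- load_kdr_atlas()
  mm <- atlas$mutations[!is.na(atlas$mutations$universal), ]
  expect_gt(nrow(mm), 60)
  for (i in seq_len(nrow(mm))) {
    dual <- paste0(mm$wt[i], mm$native[i], "/", mm$universal[i])
    p <- parse_label(dual)
    expect_identical(format_label(p$label, p$native), dual)
    bare <- parse_label(mm$universal[i])
    expect_identical(format_label(bare$label), mm$universal[i])
  }
})

test_that("universal_label enforces its invariants", {
  expect_error(universal_label("M", 5, "k", 1), "domain")
  expect_error(universal_label("M", 2, "q", 1), "segment")
  expect_error(universal_label("M", 2, "k", 0), "index")
  l <- universal_label(NA, 3, "p", 47)
  expect_identical(format_label(l), "3p47")
})

test_that("segment annotation rejects overlaps and duplicate indices", {
  expect_error(segment_annotation(data.frame(
    domain = c(2, 2), segment = c("k", "o"), first = c(900, 910),
    last = c(920, 930), anchor = c(900, 910))), "overlap")
  expect_error(segment_annotation(data.frame(
    domain = c(1, 1), segment = c("i", "i"), first = c(392, 431),
    last = c(430, 440), anchor = c(392, 400))), "duplicate")
  ok <- segment_annotation(data.frame(
    domain = 1, segment = "k", first = 250, last = 260, anchor = 243))
  expect_s3_class(ok, "segment_annotation")
})

test_that("assign_labels maps native numbering through the anchors", {
  ann <- housefly_annotation()
  lm <- assign_labels(c(918L, 1014L, 253L, 410L, 929L, 1534L), ann)
  expect_identical(lm$label[match(918, lm$resno)], "2k11")
  expect_identical(lm$label[match(1014, lm$resno)], "2i16")
  expect_identical(lm$label[match(253, lm$resno)], "1k11")
  expect_identical(lm$label[match(410, lm$resno)], "1i19")
  expect_identical(lm$label[match(929, lm$resno)], "2o10")
  expect_identical(lm$label[match(1534, lm$resno)], "3i13")
  # outside every span: absent
  lm2 <- assign_labels(c(1L, 700L), ann)
  expect_equal(nrow(lm2), 0)
  # anchor == first: index 1
  ann1 <- segment_annotation(data.frame(domain = 1, segment = "k",
                                        first = 10, last = 20, anchor = 10))
  expect_identical(assign_labels(10L, ann1)$label, "1k1")
})

test_that("the packaged annotation reproduces every atlas dual label", {
  atlas <- load_kdr_atlas()
  mm <- atlas$mutations[!is.na(atlas$mutations$universal), ]
  lm <- assign_labels(mm$native, housefly_annotation(), aa = mm$wt)
  got <- lm$label[match(mm$native, lm$resno)]
  expect_identical(got, mm$universal)
})

test_that("translate_numbering follows pairwise alignments and flags gaps", {
  aln <- list(seqs = list(a = "ACDEFG", b = "ACDEFG"))
  p <- translate_numbering(native_position("a", 3), aln)
  expect_identical(p$reference, "b")
  expect_equal(p$resnum, 3L)
  # 5-residue insertion in the target before the position
  aln2 <- list(seqs = list(a = "-----ACDEFG", b = "VWXYZACDEFG"))
  p2 <- translate_numbering(native_position("a", 2), aln2)
  expect_equal(p2$resnum, 7L)
  # opposite a gap: explicit error
  aln3 <- list(seqs = list(a = "ACDEFG", b = "AC--FG"))
  expect_error(translate_numbering(native_position("a", 3), aln3),
               "gap")
})
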