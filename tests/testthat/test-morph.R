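test_that("null morph is an exact identity", {
  mc <- shared_channel()
  tg <- build_targets(mc$open, mc$open, "pm-ca")
  tj <- morph(mc$open, tg, morph_schedule(n_steps = 3))
  for (s in tj$structures)
    expect_lt(max(abs(coords(s) - coords(mc$open))), 1e-3)
  expect_true(all(tj$rmsd_to_target <= 1e-6))
  expect_true(tj$converged)
})

test_that("build_targets recovers the planted gate shift exactly", {
  mc <- shared_channel()
  sel <- atom_selection(segment = "i")
  tg <- build_targets(mc$open, mc$inactivated, sel)
  cur <- coords(mc$open)[tg$atom, , drop = FALSE]
  delta <- sqrt(rowSums((tg$xyz - cur)^2))
  # lower halves moved by exactly the prescribed shift, the rest by zero
  expect_setequal(round(unique(delta), 6), c(0, mc$info$gate_shift))
  expect_error(build_targets(mc$open, mc$open,
                             atom_selection(segment = "i", index = 99L)),
               "no paired atoms")
})

test_that("the gate-shift morph decays monotonically and converges", {
  mc <- shared_channel()
  tg <- build_targets(mc$open, mc$inactivated,
                      atom_selection(segment = c("i", "k")))
  tj <- morph(mc$open, tg, morph_schedule(n_steps = 10))
  expect_length(tj$structures, 11L)
  expect_true(all(diff(tj$rmsd_to_target) <= 1e-9))
  expect_lte(tj$rmsd_to_target[11L], 0.5)
  expect_true(tj$converged)
  # the pinned default tracks the pure linear interpolation exactly
  lin <- tj$rmsd_to_target[1L] * seq(1, 0, by = -0.1)
  expect_equal(tj$rmsd_to_target, lin, tolerance = 1e-6)
  # approximate reversibility
  final <- tj$structures[[11L]]
  back <- morph(final, build_targets(final, mc$open,
                                     atom_selection(segment = c("i", "k"))),
                morph_schedule(n_steps = 10))
  expect_lte(back$rmsd_to_target[11L], 1.0)
})

test_that("morphing with a bound ligand reports its energies per step", {
  mc <- shared_channel()
  tr <- shared_truth()
  tg <- build_targets(mc$open, mc$inactivated,
                      atom_selection(segment = c("i", "k")))
  tj <- morph(mc$open, tg, morph_schedule(n_steps = 4),
              ligands = list(list(ligand = tr$ligand, xyz = tr$pose)))
  expect_equal(dim(tj$ligand_energy), c(5L, 1L))
  expect_true(all(is.finite(tj$ligand_energy)))
  expect_true(all(is.finite(tj$energy)))
})

test_that("voltage-sensor deactivation shifts S4 down the pore axis", {
  mc <- shared_channel_s4()
  tj <- deactivate_vsm(mc$open, domain = 2, displacement = 4.5,
                       morph_schedule(n_steps = 5))
  ax <- pore_axis(mc$open)$axis
  labs <- assign_labels(mc$open, mc$annotation)
  s4 <- labs$resno[labs$domain == 2 & labs$segment == "s"]
  idx <- which(mc$open$atoms$resno %in% s4 & mc$open$atoms$elety == "CA")
  d0 <- colMeans(coords(mc$open)[idx, ])
  d1 <- colMeans(coords(tj$structures[[6L]])[idx, ])
  proj <- sum((d1 - d0) * ax)
  expect_lt(abs(proj - 4.5), 0.5)
  expect_identical(tj$structures[[6L]]$state, "open_pm_deactivated_vsm")
  # zero displacement leaves the structure unchanged
  tj0 <- deactivate_vsm(mc$open, domain = 2, displacement = 0,
                        morph_schedule(n_steps = 2))
  expect_lt(max(abs(coords(tj0$structures[[3L]]) - coords(mc$open))), 1e-3)
  expect_error(deactivate_vsm(mc$open, domain = 5), "domain")
  mc2 <- shared_channel()
  expect_error(deactivate_vsm(mc2$open, domain = 2), "S4")
})
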