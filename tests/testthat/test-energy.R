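dimer <- function(r, type = "CT") {
  at <- data.frame(name = c("A", "B"), element = "C", type = type,
                   charge = 0, resno = 1:2, unit = "receptor",
                   stringsAsFactors = FALSE)
  conformation(at, rbind(c(0, 0, 0), c(r, 0, 0)))
}

test_that("Lennard-Jones dimer energies match the closed form", {
  m <- default_energy_model()
  sig <- m$types$sigma[m$types$type == "CT"]
  eps <- m$types$eps[m$types$type == "CT"]
  e <- energy(dimer(2^(1 / 6) * sig), m)
  expect_equal(unname(e[["vdw"]]), -eps, tolerance = 1e-12)
  expect_equal(unname(e[["total"]]), -eps, tolerance = 1e-12)
  expect_equal(unname(energy(dimer(sig), m)[["vdw"]]), 0, tolerance = 1e-12)
})

test_that("an empty system has zero energy in every component", {
  at <- data.frame(name = character(), element = character(),
                   type = character(), charge = numeric(), resno = integer(),
                   unit = character(), stringsAsFactors = FALSE)
  e <- energy(conformation(at, matrix(0, 0, 3)))
  expect_true(all(e == 0))
})

test_that("energy decomposition matches the brute-force oracle", {
  m <- default_energy_model()
  for (s in 1:30) {
    conf <- random_conformation(sample(5:20, 1), seed = s)
    e <- energy(conf, m)
    o <- oracle_energy(conf, m)
    expect_equal(unname(e[names(o)]), unname(o), tolerance = 1e-9)
    expect_equal(unname(e[["total"]]),
                 sum(e[c("vdw", "coulomb", "torsion", "hbond", "xbond",
                         "angle", "restraint")]), tolerance = 1e-9)
  }
})

test_that("energy is invariant under global rigid motion", {
  m <- default_energy_model()
  conf <- random_conformation(12, seed = 7)
  base <- energy(conf, m)[["total"]]
  for (s in 1:10) {
    set.seed(s + 300)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, -180, 180)
    R <- pyrenav:::.rotmat_axis(ax, th)
    moved <- conf
    moved$xyz <- sweep(conf$xyz %*% t(R), 2, -rnorm(3, sd = 4))
    expect_lt(abs(energy(moved, m)[["total"]] - base), 1e-6)
  }
})

test_that("unknown atom types raise a parameterization error naming the atom", {
  at <- data.frame(name = "QQ1", element = "C", type = "NOPE", charge = 0,
                   resno = 1L, unit = "receptor", stringsAsFactors = FALSE)
  expect_error(energy(conformation(at, matrix(0, 1, 3))), "QQ1")
})

test_that("restraints follow k|x - x0|^2 and vanish at the target", {
  m <- default_energy_model()
  conf <- dimer(4)
  m1 <- with_restraints(m, matrix(c(0, 0, 0), 1), atom = 1L, k = 1)
  expect_equal(unname(energy(conf, m1)[["restraint"]]), 0)
  m2 <- with_restraints(m, matrix(c(2, 0, 0), 1), atom = 2L, k = 1)
  expect_equal(unname(energy(conf, m2)[["restraint"]]), 4.0,
               tolerance = 1e-12)
  m0 <- with_restraints(m, matrix(c(9, 9, 9), 1), atom = 2L, k = 0)
  expect_equal(energy(conf, m0), energy(conf, m))
  expect_error(energy(conf, with_restraints(m, matrix(0, 1, 3), atom = 99L)),
               "unknown atoms")
  # restrained minimization of a free atom lands on the target
  free <- conformation(
    data.frame(name = "A", element = "C", type = "CT", charge = 0,
               resno = 1L, unit = "receptor"),
    matrix(c(3, 2, 1), 1),
    dof = list(list(type = "rigid", atoms = 1L, translate_only = TRUE)))
  mt <- with_restraints(m, matrix(c(1, 1, 1), 1), atom = 1L, k = 5)
  r <- local_minimize(free, mt, tol = 1e-9, max_sweeps = 60)
  expect_lt(max(abs(r$conformation$xyz - c(1, 1, 1))), 1e-3)
})

test_that("local minimization finds the Lennard-Jones contact distance", {
  m <- default_energy_model()
  sig <- 2.0 / 2^(1 / 6)
  m$types$sigma[m$types$type == "CT"] <- sig
  conf <- conformation(
    data.frame(name = c("A", "B"), element = "C", type = "CT", charge = 0,
               resno = 1:2, unit = "receptor"),
    rbind(c(0, 0, 0), c(4, 0, 0)),
    dof = list(list(type = "rigid", atoms = 2L, translate_only = TRUE)))
  r <- local_minimize(conf, m, tol = 1e-9, max_sweeps = 80)
  sep <- sqrt(sum((r$conformation$xyz[2, ] - r$conformation$xyz[1, ])^2))
  expect_lt(abs(sep - 2.0), 1e-3)
  expect_lte(r$energy, energy(conf, m)[["total"]])
  # already at the minimum: unchanged within tolerance
  r2 <- local_minimize(r$conformation, m, tol = 1e-9, max_sweeps = 40)
  expect_lt(abs(r2$energy - r$energy), 1e-6)
})

test_that("a single torsion relaxes to the nearest planted minimum", {
  m <- default_energy_model()
  conf <- one_torsion_toy()
  # 1-degree scan over the rotatable DOF; minima located in dihedral space
  vgrid <- seq(-179, 180, 1)
  scan <- vapply(vgrid, function(v)
    energy(set_dof(conf, v), m)[["total"]], 0)
  min_v <- vgrid[which(diff(sign(diff(scan))) == 2) + 1L]
  minima <- vapply(min_v, function(v) {
    x <- set_dof(conf, v)$xyz
    oracle_dihedral(x[1, ], x[2, ], x[3, ], x[4, ]) * 180 / pi
  }, 0)
  for (start in c(-150, -90, -20, 40, 100, 170)) {
    r <- local_minimize(set_dof(conf, start), m, tol = 1e-8,
                        max_sweeps = 60, tor_window = 60)
    phi <- oracle_dihedral(r$conformation$xyz[1, ], r$conformation$xyz[2, ],
                           r$conformation$xyz[3, ],
                           r$conformation$xyz[4, ]) * 180 / pi
    expect_lt(min(abs((phi - minima + 180) %% 360 - 180)), 2)
  }
})

test_that("set_dof rebuilds deterministically and preserves bonds", {
  conf <- two_torsion_toy()
  a <- set_dof(conf, c(33, -71))
  b <- set_dof(conf, c(33, -71))
  expect_identical(a$xyz, b$xyz)
  blen <- function(x, conf) vapply(seq_len(nrow(conf$bonds)), function(i)
    sqrt(sum((x[conf$bonds[i, 1], ] - x[conf$bonds[i, 2], ])^2)), 0)
  expect_equal(blen(a$xyz, conf), blen(conf$ref_xyz, conf),
               tolerance = 1e-10)
  expect_equal(get_dof(a), c(33, -71))
})

test_that("greedy MCM is monotone, reproducible, and finds the toy optimum", {
  m <- default_energy_model()
  conf <- two_torsion_toy()
  sch <- mcm_schedule(n_steps = 12, seed = 42)
  r1 <- mc_minimize(conf, m, sch)
  r2 <- mc_minimize(conf, m, sch)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_true(all(diff(r1$trajectory) <= 1e-9))
  r3 <- mc_minimize(conf, m, mcm_schedule(n_steps = 12, seed = 43))
  expect_false(identical(r1$trajectory, r3$trajectory))
  # zero steps degenerate to plain local minimization
  r0 <- mc_minimize(conf, m, mcm_schedule(n_steps = 0, seed = 1))
  l0 <- local_minimize(conf, m, tol = 1e-4, max_sweeps = 10)
  expect_equal(r0$energy, l0$energy, tolerance = 1e-9)
  # global optimum against the exhaustive grid oracle
  gmin <- grid_scan_two_torsions(conf, m, step = 5)
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    start <- set_dof(conf, runif(2, -180, 180))
    r <- mc_minimize(start, m,
                     mcm_schedule(n_steps = 30, torsion_deg = 120, seed = s))
    if (r$energy <= gmin + 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("interaction energy equals the complex-minus-parts difference", {
  m <- default_energy_model()
  mc <- shared_channel()
  conf <- build_complex(mc$open, m, ligand = mc$info$ligand,
                        ligand_xyz = mc$info$planted_pose)
  li <- which(conf$atoms$unit == "ligand")
  e_int <- interaction_energy(conf, m)
  e_complex <- energy(conf, m)[["total"]]
  lig_only <- conf
  lig_only$atoms <- conf$atoms[li, ]
  lig_only$xyz <- conf$xyz[li, ]
  lig_only$ref_xyz <- conf$ref_xyz[li, ]
  lig_only$excl <- conf$excl[conf$excl[, 1] %in% li, , drop = FALSE] -
    (li[1L] - 1L)
  lig_only$bonds <- conf$bonds[conf$bonds[, 1] %in% li, , drop = FALSE] -
    (li[1L] - 1L)
  tt <- conf$tor_terms
  tt[c("i", "j", "k", "l")] <- tt[c("i", "j", "k", "l")] - (li[1L] - 1L)
  lig_only$tor_terms <- tt
  lig_only$xb_donors <- conf$xb_donors - (li[1L] - 1L)
  lig_only$dof <- list()
  rec_only <- conf
  rec_only$atoms <- conf$atoms[-li, ]
  rec_only$xyz <- conf$xyz[-li, ]
  rec_only$ref_xyz <- conf$ref_xyz[-li, ]
  rec_only$excl <- conf$excl[!(conf$excl[, 1] %in% li) &
                               !(conf$excl[, 2] %in% li), , drop = FALSE]
  rec_only$bonds <- conf$bonds[!(conf$bonds[, 1] %in% li) &
                                 !(conf$bonds[, 2] %in% li), , drop = FALSE]
  rec_only$tor_terms <- conf$tor_terms[0, ]
  rec_only$xb_donors <- matrix(integer(), 0, 2)
  rec_only$dof <- list()
  e_parts <- energy(lig_only, m)[["total"]] + energy(rec_only, m)[["total"]]
  # greedy tie-breaking in the hydrogen-bond saturation can reorder
  # energy-degenerate candidates between evaluations; the identity holds to
  # well below thermal noise
  expect_equal(e_int, e_complex - e_parts, tolerance = 1e-4)
})
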