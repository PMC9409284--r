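random_points <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 4), n, 3)
}

random_rigid <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, -pi, pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  rigid_transform(R, rnorm(3, sd = 5))
}

test_that("kabsch recovers identity and rigid motions exactly", {
  P <- random_points(10, 1)
  f <- kabsch(P, P)
  expect_equal(f$rmsd, 0, tolerance = 1e-10)
  expect_equal(f$transform$rotation, diag(3), tolerance = 1e-8)
  for (s in 1:20) {
    tr <- random_rigid(s)
    Q <- apply_transform(P, tr)
    expect_lt(kabsch(P, Q)$rmsd, 1e-8)
  }
})

test_that("kabsch matches the quaternion oracle on random point sets", {
  for (s in 1:100) {
    n <- sample(4:30, 1)
    P <- random_points(n, s)
    Q <- random_points(n, s + 1000)
    expect_equal(kabsch(P, Q)$rmsd, oracle_superpose(P, Q),
                 tolerance = 1e-8)
  }
})

test_that("kabsch rmsd is invariant under joint rigid motion", {
  P <- random_points(12, 3)
  Q <- random_points(12, 4)
  base <- kabsch(P, Q)$rmsd
  for (s in 1:25) {
    tr <- random_rigid(s + 50)
    expect_lt(abs(kabsch(apply_transform(P, tr),
                         apply_transform(Q, tr))$rmsd - base), 1e-8)
  }
})

test_that("fitting never increases RMSD beyond the unfitted value", {
  for (s in 1:20) {
    P <- random_points(8, s)
    Q <- random_points(8, s + 500)
    unfitted <- sqrt(mean(rowSums((P - Q)^2)))
    expect_lte(kabsch(P, Q)$rmsd, unfitted + 1e-12)
  }
})

test_that("kabsch rejects degenerate input", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(kabsch(line, line), "collinear")
  expect_error(kabsch(matrix(0, 4, 3), matrix(0, 5, 3)), "equal-size")
})

test_that("superpose on P1 aligns the gating states of the mini-channel", {
  mc <- shared_channel()
  # identical structures: zero everywhere
  self <- superpose(mc$open, mc$open, "p1-ca")
  expect_lt(self$rmsd, 1e-10)
  # P1 is shared by construction, the rest differs by the gate shift
  fit <- superpose(mc$inactivated, mc$open, "p1-ca")
  expect_lt(fit$rmsd, 1e-6)
  whole <- rmsd_subset(fit$structure, mc$open, "ca")
  expect_gt(whole, 0.5)
  expect_error(superpose(mc$open, mc$open,
                         atom_selection(segment = "p", index = 99L)),
               "no paired atoms")
})

test_that("rmsd_subset equals the direct formula", {
  mc <- shared_channel()
  shifted <- set_coords(mc$open,
                        sweep(coords(mc$open), 2, c(-1, 0, 0)))
  expect_equal(rmsd_subset(mc$open, shifted, "ca"), 1.0, tolerance = 1e-10)
  expect_equal(rmsd_subset(mc$open, mc$open, "ca"), 0)
  set.seed(9)
  jitter <- coords(mc$open) + matrix(rnorm(3 * nrow(mc$open$atoms), sd = 0.3),
                                     ncol = 3)
  j <- set_coords(mc$open, jitter)
  sel <- select_atoms(mc$open, "ca")
  direct <- sqrt(mean(rowSums((coords(mc$open)[sel$idx, ] -
                                 jitter[sel$idx, ])^2)))
  expect_equal(rmsd_subset(mc$open, j, "ca"), direct, tolerance = 1e-12)
})
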