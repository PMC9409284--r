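# Independent oracle implementations used to validate the package's fast
# paths.  These are deliberately written as straight-line code (explicit
# loops, closed forms) so they share nothing with the implementations they
# check.

# Horn's quaternion method for optimal rigid superposition
oracle_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  S <- t(Pc) %*% Qc
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[1, 3] + S[3, 1]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  fitted <- Qc  # rotate P onto Q
  rot <- Pc %*% t(R)
  sqrt(mean(rowSums((rot - Qc)^2)))
}

# brute-force nonbonded + bonded energy, explicit pair loops
oracle_energy <- function(conf, model) {
  n <- nrow(conf$atoms)
  ty <- match(conf$atoms$type, model$types$type)
  eps <- model$types$eps[ty]; sig <- model$types$sigma[ty]
  hbd <- model$types$hbd[ty]; hba <- model$types$hba[ty]
  q <- conf$atoms$charge
  rv <- model$vdw$radius[match(conf$atoms$element, model$vdw$element)]
  rv[is.na(rv)] <- 1.7
  x <- conf$xyz
  excl <- apply(conf$excl, 1, function(p) paste(sort(p), collapse = "-"))
  is_excl <- function(i, j) paste(sort(c(i, j)), collapse = "-") %in% excl
  vdw <- coul <- hb <- xb <- tor <- ang <- rst <- 0
  cand <- list()  # hydrogen-bond candidates awaiting donor/acceptor slots
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    r <- sqrt(sum((x[i, ] - x[j, ])^2))
    if (r > model$cutoff || is_excl(i, j)) next
    e <- sqrt(eps[i] * eps[j]); s <- (sig[i] + sig[j]) / 2
    lj_e <- 4 * e * ((s / r)^12 - (s / r)^6)
    if ((hbd[i] && hba[j]) || (hbd[j] && hba[i])) {
      t <- model$hb_r0 / r
      cand[[length(cand) + 1L]] <- list(
        i = i, j = j, hb = model$hb_depth * (5 * t^12 - 6 * t^10),
        lj = lj_e)
    } else {
      vdw <- vdw + lj_e
    }
    coul <- coul + model$kcoul * q[i] * q[j] / (4 * r^2)
  }
  # one bond per donor and per acceptor, best candidates first; the rest
  # fall back to Lennard-Jones
  if (length(cand)) {
    ord <- order(vapply(cand, `[[`, 0, "hb"))
    dused <- aused <- rep(FALSE, n)
    for (c0 in cand[ord]) {
      i <- c0$i; j <- c0$j; take <- FALSE
      if (c0$hb < c0$lj) {
        if (hbd[i] && hba[j] && !dused[i] && !aused[j]) {
          dused[i] <- aused[j] <- TRUE; take <- TRUE
        } else if (hbd[j] && hba[i] && !dused[j] && !aused[i]) {
          dused[j] <- aused[i] <- TRUE; take <- TRUE
        }
      }
      if (take) hb <- hb + c0$hb else vdw <- vdw + c0$lj
    }
  }
  if (nrow(conf$xb_donors)) for (p in seq_len(nrow(conf$xb_donors))) {
    ci <- conf$xb_donors[p, 1]; xi <- conf$xb_donors[p, 2]
    for (a in seq_len(n)) {
      if (a %in% c(ci, xi) || !hba[a] || is_excl(xi, a)) next
      r <- sqrt(sum((x[xi, ] - x[a, ])^2))
      if (r > model$cutoff) next
      v1 <- x[ci, ] - x[xi, ]; v2 <- x[a, ] - x[xi, ]
      cth <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      cmin <- cos(model$xb_angle_min * pi / 180)
      if (cth > cmin) next
      u <- min(1, (cmin - cth) / (cmin + 1))
      r0 <- rv[xi] + rv[a] - model$xb_pad
      t <- r0 / r
      xb <- xb + model$xb_depth * u^2 * (5 * t^12 - 6 * t^10)
    }
  }
  tt <- conf$tor_terms
  if (nrow(tt)) for (k in seq_len(nrow(tt))) {
    phi <- oracle_dihedral(x[tt$i[k], ], x[tt$j[k], ], x[tt$k[k], ],
                           x[tt$l[k], ])
    tor <- tor + tt$V[k] / 2 * (1 + cos(tt$n[k] * phi -
                                          tt$gamma[k] * pi / 180))
  }
  at <- conf$angle_terms
  if (nrow(at)) for (k in seq_len(nrow(at))) {
    v1 <- x[at$i[k], ] - x[at$j[k], ]; v2 <- x[at$k[k], ] - x[at$j[k], ]
    th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
    ang <- ang + at$kang[k] * (th - at$theta0[k] * pi / 180)^2
  }
  rr <- model$restraints
  if (nrow(rr)) for (k in seq_len(nrow(rr))) {
    d2 <- sum((x[rr$atom[k], ] - c(rr$x[k], rr$y[k], rr$z[k]))^2)
    rst <- rst + rr$k[k] * d2
  }
  c(vdw = vdw, coulomb = coul, torsion = tor, hbond = hb, xbond = xb,
    angle = ang, restraint = rst,
    total = vdw + coul + tor + hb + xb + ang + rst)
}

oracle_dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# brute-force residue contact oracle: all residue atoms vs all ligand atoms
oracle_contacts <- function(receptor, pose, cutoff, side_chain_only = TRUE) {
  at <- receptor$atoms
  pose <- as.matrix(pose)
  hits <- character()
  for (rn in unique(at$resno[!at$het])) {
    idx <- which(at$resno == rn & !at$het)
    if (side_chain_only) {
      sc <- idx[!(at$elety[idx] %in% c("N", "CA", "C", "O", "OXT"))]
      if (!length(sc)) sc <- idx[at$elety[idx] == "CA"]
      idx <- sc
    }
    found <- FALSE
    for (i in idx) for (j in seq_len(nrow(pose))) {
      d <- sqrt((at$x[i] - pose[j, 1])^2 + (at$y[i] - pose[j, 2])^2 +
                  (at$z[i] - pose[j, 3])^2)
      if (d <= cutoff + 1e-9) { found <- TRUE; break }
    }
    if (found) hits <- c(hits, as.character(rn))
  }
  hits
}

# a small random conformation of typed atoms for energy cross-checks
random_conformation <- function(n, seed, spread = 6) {
  set.seed(seed)
  types <- sample(c("CT", "CAr", "OC", "OH", "SM", "NC", "BR"), n,
                  replace = TRUE)
  el <- c(CT = "C", CAr = "C", OC = "O", OH = "O", SM = "S", NC = "N",
          BR = "Br")[types]
  at <- data.frame(name = paste0("A", seq_len(n)), element = unname(el),
                   type = types,
                   charge = round(stats::runif(n, -0.4, 0.4), 2),
                   resno = seq_len(n), unit = "receptor",
                   stringsAsFactors = FALSE)
  spread <- max(spread, 2.5 * n^(1 / 3))
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    repeat {
      pt <- stats::runif(3, 0, spread)
      if (i == 1 ||
          min(sqrt(colSums((t(xyz[seq_len(i - 1), , drop = FALSE]) -
                              pt)^2))) > 1.8) break
    }
    xyz[i, ] <- pt
  }
  bonds <- if (n >= 3) rbind(c(1L, 2L), c(2L, 3L)) else NULL
  conformation(at, xyz, bonds = bonds,
               xb_donors = if ("BR" %in% types) {
                 xi <- which(types == "BR")[1L]
                 ci <- which(types %in% c("CT", "CAr"))[1L]
                 if (!is.na(ci) && ci != xi) rbind(c(ci, xi)) else NULL
               })
}

# tiny toy: one rotatable torsion over a planted 3-fold profile
one_torsion_toy <- function() {
  at <- data.frame(name = c("A", "B", "C", "D"), element = "C", type = "CT",
                   charge = 0, resno = 1L, unit = "receptor",
                   stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 1.2, 0), c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.1, 0.6))
  conformation(at, xyz, bonds = rbind(c(1, 2), c(2, 3), c(3, 4)),
               dof = list(list(type = "torsion", a = 2L, b = 3L, moving = 4L)),
               tor_terms = data.frame(i = 1L, j = 2L, k = 3L, l = 4L,
                                      n = 3, V = 2.0, gamma = 0))
}

# two coupled torsions with an additional nonbonded end-to-end interaction:
# a small rugged landscape for the Monte Carlo minimizer
two_torsion_toy <- function() {
  at <- data.frame(name = c("A", "B", "C", "D", "E"), element = "C",
                   type = "CT", charge = c(0.3, 0, 0, 0, -0.3), resno = 1L,
                   unit = "receptor", stringsAsFactors = FALSE)
  xyz <- rbind(c(-1.0, 1.2, 0), c(0, 0, 0), c(1.5, 0, 0),
               c(2.3, 1.2, 0.2), c(3.6, 1.3, 0.9))
  conformation(at, xyz,
               bonds = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)),
               dof = list(
                 list(type = "torsion", a = 2L, b = 3L, moving = c(4L, 5L)),
                 list(type = "torsion", a = 3L, b = 4L, moving = 5L)),
               tor_terms = data.frame(i = c(1L, 2L), j = c(2L, 3L),
                                      k = c(3L, 4L), l = c(4L, 5L),
                                      n = c(3, 2), V = c(1.5, 1.0),
                                      gamma = c(0, 180)))
}

# exhaustive grid scan over the toy torsions (the global-minimum oracle)
grid_scan_two_torsions <- function(conf, model, step = 5) {
  grid <- seq(-180, 180 - step, by = step)
  best <- Inf
  for (t1 in grid) for (t2 in grid) {
    trial <- set_dof(conf, c(t1, t2))
    e <- energy(trial, model)[["total"]]
    if (e < best) best <- e
  }
  best
}

# expensive fixtures built once per test run
.shared <- new.env()
shared_channel <- function() {
  if (is.null(.shared$mc)) .shared$mc <- make_mini_channel()
  .shared$mc
}
shared_channel_s4 <- function() {
  if (is.null(.shared$mc4))
    .shared$mc4 <- make_mini_channel(mini_channel_params(include_s4 = TRUE))
  .shared$mc4
}
shared_truth <- function() {
  if (is.null(.shared$truth))
    .shared$truth <- make_docking_truth(shared_channel(), seed = 1)
  .shared$truth
}
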