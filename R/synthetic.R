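#' Parameters of the synthetic mini-channel
#'
#' The mini-channel is a test instrument, not a channel model: four
#' pseudo-symmetric domains, each with an S4-S5 linker helix (k), an outer
#' helix (o), an 8-residue re-entrant P-loop hairpin (p; a 5-residue P1
#' helix plus turn), and a pore-lining inner helix (i), built from ideal
#' alpha-helix geometry (1.5 A rise, 100 degrees twist per residue).
#' Two gating states are generated: they share the P1 coordinates exactly,
#' and differ only by a prescribed rigid radial shift of the cytoplasmic
#' halves of the inner helices (the gate) and a cytoplasmic displacement of
#' the linker helices.
#'
#' A lipid-facing pocket at the II/III domain interface carries planted
#' "sensing" residues: hosts on the k and o segments of domain 2 and the i
#' segment of domain 3 are chosen automatically so their side chains offer a
#' hydrogen-bond donor to each ligand acceptor (nitrile N, carbonyl O, ester
#' O) and a sigma-hole acceptor to each halogen, with the remaining
#' positions alanine.  This mirrors the composition of a pyrethroid receptor
#' site (linker, outer and inner helices of two adjacent domains) and makes
#' the planted pose a deep, specific energy minimum.
#'
#' @param res_per_helix Residues per k/o/i helix.
#' @param p_len,p1_len P-loop hairpin length and P1-helix length.
#' @param rise,twist,ca_radius Ideal helix geometry (A, degrees, A).
#' @param r_i,r_o,r_k,r_p,r_s4 Radial positions of the segment axes (A).
#' @param gate_radius_open,gate_radius_inactivated Axis radius of the inner
#'   helix lower halves in the two states (A); their difference is the
#'   planted gate shift.
#' @param k_shift Cytoplasmic displacement of the linker helices in the
#'   inactivated state (A).
#' @param include_s4 Add a peripheral S4 helix (3 arginines) per domain,
#'   for voltage-sensor fixtures.
#' @param ligand_kind Toy ligand the pocket is built around.
#' @param pocket_r,pocket_az,pocket_z Cylindrical position of the planted
#'   ligand anchor (A, degrees, A).
#' @param pose_spin Rotation of the planted ligand about its long axis
#'   (degrees).
#' @param seed Seed for the (small) stochastic elements of fixtures built on
#'   top of this channel.
#' @return A `mini_channel_params` list.
#' @export
mini_channel_params <- function(res_per_helix = 12L, p_len = 8L, p1_len = 5L,
                                rise = 1.5, twist = 100, ca_radius = 2.3,
                                r_i = 8, r_o = 17, r_k = 17.5, r_p = 11,
                                r_s4 = 22, gate_radius_open = 8,
                                gate_radius_inactivated = 5, k_shift = 1.5,
                                include_s4 = FALSE, ligand_kind = "type2",
                                pocket_r = 11.5, pocket_az = 145,
                                pocket_z = -4.5, pose_spin = 300,
                                seed = 1L) {
  stopifnot(res_per_helix >= 8L, p_len > p1_len, rise > 0, ca_radius > 0,
            r_i > 0, r_o > r_i, gate_radius_open != gate_radius_inactivated)
  structure(as.list(environment()), class = "mini_channel_params")
}

# cylindrical coordinates helper (azimuth in degrees)
.cyl <- function(r, az, z) {
  a <- az * pi / 180
  c(r * cos(a), r * sin(a), z)
}

# ideal alpha-helix C-alpha trace along `direction` from `origin`
.helix_ca <- function(n, origin, direction, rise, twist, ca_radius,
                      phase0 = 0) {
  d <- direction / sqrt(sum(direction^2))
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * d) * d; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  t(vapply(seq_len(n), function(i) {
    th <- (phase0 + (i - 1) * twist) * pi / 180
    origin + (i - 1) * rise * d + ca_radius * (cos(th) * e1 + sin(th) * e2)
  }, numeric(3)))
}

# reach of each side-chain template: distance CA -> contact-relevant tip
.SC_REACH <- c(ALA = 1.53, SER = 2.95, THR = 2.95, CYS = 3.34, MET = 4.87,
               LEU = 3.06, ASP = 3.84, ARG = 5.85, PHE = 4.42)
# minimum tip distance of the two-link arms (elbow fully folded)
.SC_REACH_MIN <- c(SER = 0.15, THR = 0.15, CYS = 0.3, MET = 1.25,
                   ARG = 2.9, ALA = 1.53, LEU = 1.6, ASP = 1.9, PHE = 2.0)

# direction from CA such that the side-chain tip (at fixed reach L) lands at
# distance `d` from the target: intersection of the reach sphere with the
# contact sphere around the target, tilted deterministically away from
# `away` (or +z)
.aim_direction <- function(ca, target, L, d, away = NULL) {
  v <- target - ca
  D <- sqrt(sum(v^2))
  u0 <- v / D
  cosphi <- (L^2 + D^2 - d^2) / (2 * L * D)
  if (cosphi >= 1 || D >= L + d) return(u0)  # best effort: straight at it
  cosphi <- max(cosphi, -1)
  w <- if (is.null(away)) c(0, 0, 1) else ca - away
  w <- w - sum(w * u0) * u0
  if (sqrt(sum(w^2)) < 1e-6) {
    w <- c(0, 0, 1) - u0[3] * u0
    if (sqrt(sum(w^2)) < 1e-6) w <- c(1, 0, 0) - u0[1] * u0
  }
  w <- w / sqrt(sum(w^2))
  cosphi * u0 + sqrt(1 - cosphi^2) * w
}

# exact two-link inverse kinematics: place the side-chain tip exactly at
# `tip` when it lies within the reach annulus, elbow chosen away from
# `away`.  Residues are modeled as an effective two-link arm
# (CA->elbow->tip); longer chains fill in the straight proximal stretch.
.side_chain_ik <- function(resname, ca, tip, away) {
  arms <- switch(resname,
    SER = c(1.53, 1.42), THR = c(1.53, 1.42), CYS = c(1.53, 1.81),
    MET = c(3.06, 1.81), NULL)
  if (is.null(arms)) return(NULL)
  l1 <- arms[1L]; l2 <- arms[2L]
  v <- tip - ca
  D <- sqrt(sum(v^2))
  if (D > l1 + l2 - 1e-6 || D < abs(l1 - l2) + 1e-6) return(NULL)
  u <- v / D
  a <- (l1^2 - l2^2 + D^2) / (2 * D)
  h <- sqrt(max(0, l1^2 - a^2))
  w <- (ca - away) - sum((ca - away) * u) * u
  if (sqrt(sum(w^2)) < 1e-6) w <- c(0, 0, 1) - u[3] * u
  w <- w / sqrt(sum(w^2))
  elbow <- ca + a * u + h * w
  ub <- (elbow - ca) / sqrt(sum((elbow - ca)^2))
  switch(resname,
    SER = list(CB = elbow, OG = tip),
    THR = list(CB = elbow, OG1 = tip),
    CYS = list(CB = elbow, SG = tip),
    MET = {
      cb <- ca + 1.53 * ub
      ve <- (ca - away) - sum((ca - away) * ub) * ub
      if (sqrt(sum(ve^2)) < 1e-6) ve <- c(0, 0, 1) - ub[3] * ub
      ve <- ve / sqrt(sum(ve^2))
      list(CB = cb, CG = elbow, SD = tip, CE = tip + 1.79 * ve)
    })
}

# side-chain heavy atoms grown from CA along direction u.
# Geometry is schematic (near-linear chains with fixed bond lengths); the
# detectors only use distances plus inferred-H directions, so this is enough
# to exercise every interaction class.
.side_chain <- function(resname, ca, toward, direction = NULL,
                        branch_hint = NULL) {
  u <- if (is.null(direction)) toward - ca else direction
  u <- u / sqrt(sum(u^2))
  ref <- if (!is.null(branch_hint)) branch_hint
         else if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- ref - sum(ref * u) * u
  if (sqrt(sum(v^2)) < 1e-6) v <- c(1, 0, 0) - u[1] * u
  v <- v / sqrt(sum(v^2))
  seg <- function(from, len) from + len * u
  switch(resname,
    ALA = list(CB = seg(ca, 1.53)),
    SER = { cb <- seg(ca, 1.53); list(CB = cb, OG = seg(cb, 1.42)) },
    THR = { cb <- seg(ca, 1.53); list(CB = cb, OG1 = seg(cb, 1.42)) },
    CYS = { cb <- seg(ca, 1.53); list(CB = cb, SG = seg(cb, 1.81)) },
    MET = { cb <- seg(ca, 1.53); cg <- seg(cb, 1.53); sd <- seg(cg, 1.81)
            list(CB = cb, CG = cg, SD = sd, CE = sd + 1.79 * v) },
    LEU = { cb <- seg(ca, 1.53); cg <- seg(cb, 1.53)
            list(CB = cb, CG = cg, CD1 = cg + 1.53 * (0.7 * u + 0.71 * v),
                 CD2 = cg + 1.53 * (0.7 * u - 0.71 * v)) },
    ASP = { cb <- seg(ca, 1.53); cg <- seg(cb, 1.53)
            list(CB = cb, CG = cg, OD1 = cg + 1.25 * (0.62 * u + 0.78 * v),
                 OD2 = cg + 1.25 * (0.62 * u - 0.78 * v)) },
    ARG = { cb <- seg(ca, 1.53); cg <- seg(cb, 1.53); cd <- seg(cg, 1.53)
            ne <- seg(cd, 1.46); cz <- seg(ne, 1.33)
            list(CB = cb, CG = cg, CD = cd, NE = ne, CZ = cz,
                 NH1 = cz + 1.33 * (0.5 * u + 0.87 * v),
                 NH2 = cz + 1.33 * (0.5 * u - 0.87 * v)) },
    PHE = { cb <- seg(ca, 1.53); cg <- seg(cb, 1.50)
            ring <- .aromatic_ring(cg, cb)
            stats::setNames(c(list(cb), lapply(1:6, function(i) ring[i, ])),
                            c("CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2")) },
    stop("no side-chain template for ", resname, call. = FALSE))
}

# the planted reference pose: ligand rotated so its long (+x) axis points
# extracellular (+z), spun about that axis, dropped into the II/III
# interface pocket
.planted_pose <- function(lig, p) {
  R <- matrix(c(0, 0, -1,   0, 1, 0,   1, 0, 0), 3, 3, byrow = TRUE)
  S <- .rotmat_axis(c(0, 0, 1), p$pose_spin)  # spin about the long axis
  xyz <- lig$xyz %*% t(S %*% R)
  anchor <- .cyl(p$pocket_r, p$pocket_az, p$pocket_z)
  sweep(xyz, 2L, xyz[1L, ] - anchor)  # put CF (atom 1) at the anchor
}

# specific interactions the pocket offers the ligand: one hydrogen-bond
# donor per acceptor, one sigma-hole acceptor per halogen
.pocket_specials <- function(lig) {
  sp <- list(
    list(kind = "hbond", res = c("ARG"), atom = "NN", d = 2.9),
    list(kind = "hbond", res = c("SER", "THR"), atom = "O1", d = 2.9),
    list(kind = "hbond", res = c("THR", "SER"), atom = "OE", d = 2.9),
    list(kind = "xbond", res = c("CYS", "MET"), atom = "X1", d = 3.5),
    list(kind = "xbond", res = c("SER", "CYS", "MET"), atom = "X2", d = 3.3))
  keep <- vapply(sp, function(s) s$atom %in% lig$atoms$name, TRUE)
  sp[keep]
}

#' Build the synthetic two-state mini-channel
#'
#' @param params A [mini_channel_params()].
#' @return A list with `open` and `inactivated` (two `channel_structure`s
#'   sharing P1 coordinates exactly), `annotation` (their
#'   `segment_annotation`), and `info` (pocket center, sensing residue
#'   labels, the nominal planted pose of the pocket ligand, the ligand, and
#'   the prescribed gate shift).
#' @export
make_mini_channel <- function(params = mini_channel_params()) {
  stopifnot(inherits(params, "mini_channel_params"))
  p <- params
  nres <- p$res_per_helix
  lig <- make_toy_ligand(p$ligand_kind)
  pose <- .planted_pose(lig, p)
  lig_centroid <- colMeans(pose)

  segs <- list()
  add_seg <- function(domain, code, n, ca) {
    segs[[length(segs) + 1L]] <<- list(domain = domain, code = code, n = n,
                                       ca = ca)
  }
  for (d in 1:4) {
    az <- (d - 1) * 90
    add_seg(d, "k", nres,
            .helix_ca(nres, .cyl(p$r_k, az + 10, -11),
                      .cyl(p$r_k, az + 62, 0) - .cyl(p$r_k, az + 10, 0),
                      p$rise, p$twist, p$ca_radius, phase0 = 15 * d))
    add_seg(d, "o", nres,
            .helix_ca(nres, .cyl(p$r_o, az + 40, -9.5), c(0, 0, 1),
                      p$rise, p$twist, p$ca_radius, phase0 = 40 * d))
    p1 <- .helix_ca(p$p1_len, .cyl(p$r_p, az + 20, 10),
                    .cyl(5, az + 20, 7) - .cyl(p$r_p, az + 20, 10),
                    p$rise, p$twist, p$ca_radius)
    turn <- t(vapply(seq_len(p$p_len - p$p1_len), function(i)
      .cyl(5.5 + i, az + 20 - 12 * i, 8.2), numeric(3)))
    add_seg(d, "p", p$p_len, rbind(p1, turn))
    add_seg(d, "i", nres,
            .helix_ca(nres, .cyl(p$r_i, az, 6), c(0, 0, -1),
                      p$rise, p$twist, p$ca_radius, phase0 = 25 * d))
    if (p$include_s4)
      add_seg(d, "s", nres,
              .helix_ca(nres, .cyl(p$r_s4, az + 20, -8), c(0, 0, 1),
                        p$rise, p$twist, p$ca_radius, phase0 = 10 * d))
  }
  seg_base <- c(k = 100L, o = 200L, p = 300L, i = 400L, s = 500L)
  annotation <- segment_annotation(do.call(rbind, lapply(segs, function(s)
    data.frame(domain = s$domain, segment = s$code,
               first = s$domain * 1000L + seg_base[[s$code]] + 1L,
               last = s$domain * 1000L + seg_base[[s$code]] + s$n,
               anchor = s$domain * 1000L + seg_base[[s$code]] + 1L))))
  ca_of <- function(domain, code, idx) {
    for (s in segs) if (s$domain == domain && s$code == code)
      return(s$ca[idx, ])
    stop("no such segment", call. = FALSE)
  }

  # --- assign pocket hosts -------------------------------------------------
  # candidate hosts: mid-helix positions on 2k, 2o and 3i facing the pocket
  cand <- list()
  for (sc in list(c(2, "k"), c(2, "o"), c(3, "i")))
    for (i in 2:(nres - 1L)) {
      lab <- paste0(sc[1L], sc[2L], i)
      cand[[lab]] <- list(domain = as.integer(sc[1L]), code = sc[2L],
                          idx = i, ca = ca_of(as.integer(sc[1L]), sc[2L], i))
    }
  seg_clear <- function(a, b, skip) {
    ab <- b - a; len2 <- sum(ab^2); dmin <- Inf
    for (k in seq_len(nrow(pose))) {
      if (k == skip) next
      t0 <- max(0, min(1, sum((pose[k, ] - a) * ab) / len2))
      dmin <- min(dmin, sqrt(sum((a + t0 * ab - pose[k, ])^2)))
    }
    dmin
  }
  cv1 <- pose[match("CV1", lig$atoms$name), ]
  plants <- list()
  used <- character()
  for (s in .pocket_specials(lig)) {
    ti <- match(s$atom, lig$atoms$name)
    T <- pose[ti, ]
    # for sigma-hole acceptors the geometric goal is the sigma-hole point:
    # on the C->X axis, `d` beyond the halogen
    Pstar <- if (s$kind == "xbond")
      T + s$d * (T - cv1) / sqrt(sum((T - cv1)^2)) else NULL
    best <- NULL; bests <- Inf; bestres <- s$res[1L]
    for (lab in setdiff(names(cand), used)) {
      ca <- cand[[lab]]$ca
      for (res in s$res) {
        L <- .SC_REACH[[res]]
        Lmin <- .SC_REACH_MIN[[res]]
        if (s$kind == "xbond") {
          # tip must sit exactly on the sigma-hole point
          Dst <- sqrt(sum((Pstar - ca)^2))
          mis <- max(0, Dst - L, Lmin - Dst)
          clear <- seg_clear(ca, Pstar, ti)
        } else {
          # tilted or folded arms reach anywhere in [L - d, L + d] of the
          # acceptor
          D <- sqrt(sum((T - ca)^2))
          mis <- max(0, D - (L + s$d), (L - s$d) - D)
          clear <- seg_clear(ca, T + s$d * (ca - T) / D, ti)
        }
        score <- mis + 6 * max(0, 3.1 - clear)
        if (score < bests) { bests <- score; best <- lab; bestres <- res }
      }
    }
    plants[[best]] <- list(res = bestres, target_atom = s$atom, d = s$d,
                           kind = s$kind, score = bests,
                           point_target = Pstar)
    used <- c(used, best)
  }
  # composition guarantee: a hydrophobic Met host on the linker helix
  if (!any(grepl("^2k", used))) {
    L <- .SC_REACH[["MET"]]
    best <- NULL; bests <- Inf; btarget <- NULL
    for (lab in setdiff(grep("^2k", names(cand), value = TRUE), used)) {
      ca <- cand[[lab]]$ca
      for (ti in seq_len(nrow(pose))) {
        D <- sqrt(sum((pose[ti, ] - ca)^2))
        mis <- abs(D - (L + 3.7))
        tip <- pose[ti, ] + 3.7 * (ca - pose[ti, ]) / D
        clear <- seg_clear(ca, tip, ti)
        score <- mis + 6 * max(0, 3.1 - clear)
        if (score < bests) { bests <- score; best <- lab
          btarget <- lig$atoms$name[ti] }
      }
    }
    plants[[best]] <- list(res = "MET", target_atom = btarget, d = 3.7,
                           kind = "vdw", score = bests)
    used <- c(used, best)
  }
  sensing <- used

  # hydrophobic sleeve: remaining interface positions wrap the planted pose
  # at van der Waals contact, giving the pocket shape complementarity (the
  # ligand-shaped void admits one insertion; alternatives clash)
  for (lab in setdiff(names(cand), used)) {
    ca <- cand[[lab]]$ca
    d2p <- sqrt(colSums((t(pose) - ca)^2))
    ti <- which.min(d2p)
    dmin <- d2p[ti]
    if (dmin < 3.2 || dmin > 8.6) next
    res <- if (dmin < 5.3) "ALA" else if (dmin < 6.9) "LEU" else "MET"
    tip <- pose[ti, ] + 3.9 * (ca - pose[ti, ]) / dmin
    clear <- seg_clear(ca, tip, ti)
    if (clear < 3.0) next
    plants[[lab]] <- list(res = res, target_atom = lig$atoms$name[ti],
                          d = 3.9, kind = "sleeve")
  }

  # structural H-bond pair exercised by residue_environment: pick the
  # domain-1 outer/inner residue pair whose anchors sit at the right
  # distance for two hydroxyls to meet at hydrogen-bond range
  bestp <- NULL; bestm <- Inf
  for (oi in 3:10) for (ii in 2:10) {
    D <- sqrt(sum((ca_of(1, "o", oi) - ca_of(1, "i", ii))^2))
    if (abs(D - 8.3) < bestm) { bestm <- abs(D - 8.3); bestp <- c(oi, ii) }
  }
  hb_o <- paste0("1o", bestp[1L]); hb_i <- paste0("1i", bestp[2L])
  plants[[hb_o]] <- list(res = "SER", point = ca_of(1, "i", bestp[2L]),
                         d = 5.85)
  plants[[hb_i]] <- list(res = "THR", point = ca_of(1, "o", bestp[1L]),
                         d = 5.85)
  hb_pair <- c(hb_o, hb_i)
  if (p$include_s4) {
    # salt-bridge pair: an acidic partner for the top voltage-sensing
    # arginine, stabilizing the "up" sensor conformation.  The arginine is
    # laid out first; the aspartate then aims its carboxylate at the
    # guanidinium carbon.
    caA <- ca_of(2, "o", 12); caR <- ca_of(2, "s", 11)
    uR <- .aim_direction(caR, caA, .SC_REACH[["ARG"]], 2.0)
    cz <- .side_chain("ARG", caR, direction = uR)$CZ
    uA <- .aim_direction(caA, cz, .SC_REACH[["ASP"]], 3.3)
    plants[["2s11"]] <- list(res = "ARG", direction = uR)
    plants[["2o12"]] <- list(res = "ASP", direction = uA)
  }

  build_atoms <- function() {
    rows <- list()
    eleno <- 0L
    for (s in segs) {
      for (i in seq_len(s$n)) {
        resno <- s$domain * 1000L + seg_base[[s$code]] + i
        lab <- paste0(s$domain, s$code, i)
        pl <- plants[[lab]]
        ca <- s$ca[i, ]
        if (is.null(pl)) {
          resname <- "ALA"
          # CB radially outward from the pore axis, flipped away from the
          # pocket if the default direction would clash with the ligand
          out <- c(ca[1], ca[2], 0)
          nrm <- sqrt(sum(out^2))
          u <- if (nrm < 1e-6) c(1, 0, 0) else out / nrm
          cb <- ca + 1.53 * u
          if (min(sqrt(colSums((t(pose) - cb)^2))) < 3.2) {
            u2 <- cb - lig_centroid
            u2[3] <- u2[3] * 0.2
            u <- u2 / sqrt(sum(u2^2))
          }
          sc <- .side_chain("ALA", ca, direction = u)
        } else {
          resname <- pl$res
          if (!is.null(pl$point_target)) {
            # land the tip exactly on the sigma-hole point when reachable
            sc <- .side_chain_ik(resname, ca, pl$point_target, lig_centroid)
            if (is.null(sc)) {
              u <- (pl$point_target - ca) /
                sqrt(sum((pl$point_target - ca)^2))
              sc <- .side_chain(resname, ca, direction = u,
                                branch_hint = ca - lig_centroid)
            }
          } else if (!is.null(pl$target_atom)) {
            tgt <- pose[match(pl$target_atom, lig$atoms$name), ]
            tip <- tgt + pl$d * (ca - tgt) / sqrt(sum((ca - tgt)^2))
            sc <- if (identical(pl$kind, "hbond"))
              .side_chain_ik(resname, ca, tip, lig_centroid) else NULL
            if (is.null(sc)) {
              u <- .aim_direction(ca, tgt, .SC_REACH[[resname]], pl$d,
                                  away = lig_centroid)
              sc <- .side_chain(resname, ca, direction = u,
                                branch_hint = ca - lig_centroid)
            }
          } else if (!is.null(pl$direction)) {
            sc <- .side_chain(resname, ca, direction = pl$direction)
          } else {
            u <- .aim_direction(ca, pl$point, .SC_REACH[[resname]], pl$d)
            sc <- .side_chain(resname, ca, direction = u)
          }
        }
        nm <- c("CA", names(sc))
        xyz <- rbind(ca, do.call(rbind, lapply(sc, as.numeric)))
        for (ai in seq_along(nm)) {
          eleno <- eleno + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            eleno = eleno, elety = nm[ai], resid = resname, resno = resno,
            x = xyz[ai, 1], y = xyz[ai, 2], z = xyz[ai, 3],
            elesy = .guess_element(nm[ai]), het = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  }
  atoms <- build_atoms()
  open <- channel_structure(atoms, state = "open_pm", annotation = annotation)

  # self-consistent settling: relax the ligand in the aimed pocket, re-aim
  # the planted side chains at the relaxed pose, and repeat until the
  # planted pose is the bottom of its own designed well
  model <- default_energy_model()
  lff <- .ligand_ff(lig, model)
  refresh_sigma_targets <- function() {
    cvp <- pose[match("CV1", lig$atoms$name), ]
    for (lab in names(plants)) {
      pl <- plants[[lab]]
      if (!is.null(pl$point_target)) {
        Tp <- pose[match(pl$target_atom, lig$atoms$name), ]
        plants[[lab]]$point_target <<-
          Tp + pl$d * (Tp - cvp) / sqrt(sum((Tp - cvp)^2))
      }
    }
  }
  for (pass in 1:6) {
    rff <- .receptor_ff(open, model, colMeans(pose), 18)
    relaxed <- .relax_until(lig, lff, rff, pose, model)$xyz
    moved <- sqrt(mean(rowSums((relaxed - pose)^2)))
    pose <- relaxed
    lig_centroid <- colMeans(pose)
    refresh_sigma_targets()
    atoms <- build_atoms()
    open <- channel_structure(atoms, state = "open_pm",
                              annotation = annotation)
    if (moved < 0.02) break
  }

  # inactivated: rigid radial shift of inner-helix lower halves plus a
  # cytoplasmic drop of the linker helices; P1 untouched by construction
  gate_shift <- p$gate_radius_open - p$gate_radius_inactivated
  atoms2 <- atoms
  lower <- atoms$resno %% 1000L >= 400L &
    (atoms$resno %% 100L) > p$res_per_helix / 2 & atoms$resno %% 1000L < 500L
  for (d in 1:4) {
    sel <- lower & atoms$resno %/% 1000L == d
    if (!any(sel)) next
    az <- (d - 1) * 90 * pi / 180
    shift <- -gate_shift * c(cos(az), sin(az), 0)  # radially inward
    atoms2$x[sel] <- atoms2$x[sel] + shift[1]
    atoms2$y[sel] <- atoms2$y[sel] + shift[2]
  }
  ksel <- atoms$resno %% 1000L >= 100L & atoms$resno %% 1000L < 200L
  atoms2$z[ksel] <- atoms2$z[ksel] - p$k_shift
  inact <- channel_structure(atoms2, state = "inactivated_pm",
                             annotation = annotation)

  info <- list(pocket_center = lig_centroid, planted_pose = pose,
               ligand = lig, sensing = sensing, plants = plants,
               hbond_pair = hb_pair,
               salt_bridge_pair = if (p$include_s4) c("2o12", "2s11"),
               gate_shift = gate_shift, params = p)
  list(open = open, inactivated = inact, annotation = annotation,
       info = info)
}

# repeated gentle line-search relaxation until the pose stops moving
.relax_until <- function(lig, lff, rff, pose, model, tol = 0.02,
                         max_iter = 30L) {
  cfg <- docking_config(n_sweeps = 4L, n_mc = 0L, trans_mag = 0.3,
                        rot_deg = 8, tor_deg = 12)
  ref <- NULL
  for (it in seq_len(max_iter)) {
    ref <- .refine_one(lig, lff, rff, pose, model, cfg)
    moved <- sqrt(mean(rowSums((ref$xyz - pose)^2)))
    pose <- ref$xyz
    if (moved < tol) break
  }
  ref
}

#' Planted docking truth
#'
#' Builds the ground-truth object the docking recovery tests score against:
#' the planted ligand pose relaxed to the bottom of its designed energy
#' well (so it is a genuine local minimum of the packaged force field), the
#' contact residues it realizes (verified with the brute-force contact
#' oracle at generation time), and the contacts expected to be lost or
#' weakened in the inactivated state.  Different seeds jitter the rotatable
#' torsions before relaxation, giving distinct conformers with the same
#' contact set.
#'
#' @param channel Output of [make_mini_channel()].
#' @param ligand Optional `ligand_topology` (defaults to the pocket ligand
#'   the channel was built around).
#' @param seed Integer seed for the torsion jitter.
#' @param model An `energy_model`.
#' @return A `planted_truth` list: `pose`, `expected_contacts`,
#'   `expected_lost` (labels lost or weakened after inactivation),
#'   `sensing_contacts` (sensing labels realized by the pose), `energy`
#'   (interaction energy), `ligand`.
#' @export
make_docking_truth <- function(channel, ligand = NULL, seed = 1L,
                               model = default_energy_model()) {
  if (is.null(channel$info))
    stop("channel has no planted pocket", call. = FALSE)
  lig <- ligand %||% channel$info$ligand
  pose0 <- channel$info$planted_pose
  open <- channel$open
  pose_j <- .with_seed(seed, {
    jit <- stats::runif(length(lig$torsions), -8, 8)
    xyz <- pose0
    for (t in seq_along(lig$torsions)) {
      tt <- lig$torsions[[t]]
      xyz <- .rotate_subset(xyz, tt$moving, xyz[tt$b, ],
                            xyz[tt$b, ] - xyz[tt$a, ], jit[t])
    }
    xyz
  })
  rff <- .receptor_ff(open, model, colMeans(pose_j), 18)
  lff <- .ligand_ff(lig, model)
  ref <- .relax_until(lig, lff, rff, pose_j, model)
  # thorough in-basin search: Monte Carlo kicks plus convergence, accepting
  # only candidates that stay in the planted basin
  kick_cfg <- docking_config(n_sweeps = 4L, n_mc = 6L, trans_mag = 0.8,
                             rot_deg = 25, tor_deg = 50)
  for (it in 1:15) {
    kick <- .refine_one(lig, lff, rff, ref$xyz, model, kick_cfg)
    conv <- .relax_until(lig, lff, rff, kick$xyz, model)
    if (conv$e_int < ref$e_int &&
        ligand_rmsd(lig, conv$xyz, pose0) < 3.0) ref <- conv
  }
  pose <- ref$xyz
  # local-minimum check: re-refining must not move the pose appreciably
  again <- .relax_until(lig, lff, rff, pose, model)$xyz
  drift <- sqrt(mean(rowSums((again - pose)^2)))
  if (drift > 0.3)
    stop("planted pose failed the local-minimum check (drift ",
         round(drift, 2), " A)", call. = FALSE)
  cc_open <- ligand_contacts(open, pose, lig, cutoff = 4)
  sensing <- channel$info$sensing
  realized <- intersect(sensing, cc_open$label)
  # the realized sensing set must keep the site's composition: linker,
  # outer and inner helix positions of the two pocket domains
  segs_hit <- unique(substr(realized, 2, 2))
  if (length(realized) < 3L || !all(c("k", "o", "i") %in%
                                    unique(substr(cc_open$label, 2, 2))))
    stop("planted pose does not realize a k/o/i sensing contact set (got: ",
         paste(realized, collapse = ", "), ")", call. = FALSE)
  rep_open <- interaction_report(open, pose, lig)
  rep_inact <- interaction_report(channel$inactivated, pose, lig)
  dd <- contact_diff(rep_open, rep_inact)
  lost <- unique(c(dd$lost$label, dd$weakened$label))
  conf <- build_complex(open, model, ligand = lig, ligand_xyz = pose)
  structure(list(pose = pose, expected_contacts = cc_open$label,
                 expected_lost = lost, sensing_contacts = realized,
                 energy = interaction_energy(conf, model), ligand = lig,
                 seed = seed),
            class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("<planted_truth> E_int ", round(x$energy, 2), " kcal/mol, contacts: ",
      paste(x$expected_contacts, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Write the synthetic fixture set to disk
#'
#' Emits the open and inactivated structures (PDB), the pocket ligand
#' (SDF), the segment annotation (TSV) and the planted truth (JSON) — the
#' full, regenerable input set for a pipeline run.
#'
#' @param dir Output directory (created if needed).
#' @param params A [mini_channel_params()].
#' @param seed Seed for [make_docking_truth()].
#' @return Invisibly, the list of written paths.
#' @export
write_fixtures <- function(dir, params = mini_channel_params(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mc <- make_mini_channel(params)
  tr <- make_docking_truth(mc, seed = seed)
  paths <- c(open = file.path(dir, "channel_open.pdb"),
             inact = file.path(dir, "channel_inactivated.pdb"),
             ligand = file.path(dir, "ligand.sdf"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.json"))
  write_structure(mc$open, paths[["open"]])
  write_structure(mc$inactivated, paths[["inact"]])
  ligand_to_sdf(mc$info$ligand, paths[["ligand"]])
  utils::write.table(mc$annotation, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(pose = tr$pose,
                            expected_contacts = tr$expected_contacts,
                            expected_lost = tr$expected_lost,
                            energy = tr$energy, seed = seed),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
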