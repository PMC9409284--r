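#' Energy of a conformation
#'
#' Full decomposition under the reduced force field.  The components are
#' `vdw`, `coulomb`, `torsion`, `hbond`, `xbond`, `angle`, `restraint` and
#' their sum `total`, all in kcal/mol.  Nonbonded terms use the model's
#' cutoff; 1-2 and 1-3 bonded pairs are excluded.
#'
#' @param conf A [conformation()].
#' @param model An [default_energy_model()] `energy_model`.
#' @param subset Optional integer atom indices restricting the evaluation.
#' @param mode 0 = all terms, 1 = terms touching `subset`, 2 = strictly
#'   cross terms between `subset` and the rest (nonbonded only).
#' @return Named numeric vector of components.
#' @export
energy <- function(conf, model = default_energy_model(), subset = integer(),
                   mode = 0L) {
  stopifnot(inherits(conf, "conformation"), inherits(model, "energy_model"))
  p <- .resolve_params(conf, model)
  rst <- model$restraints
  rst <- rst[rst$atom >= 1L & rst$atom <= nrow(conf$atoms), , drop = FALSE]
  if (nrow(model$restraints) && nrow(rst) < nrow(model$restraints))
    stop("restraint targets reference unknown atoms", call. = FALSE)
  tor <- conf$tor_terms; ang <- conf$angle_terms
  cpp_energy(conf$xyz, p$eps, p$sig, conf$atoms$charge, p$hbd, p$hba,
             conf$excl,
             as.matrix(tor[c("i", "j", "k", "l")]), tor$n, tor$V,
             tor$gamma * pi / 180,
             as.matrix(ang[c("i", "j", "k")]), ang$theta0 * pi / 180, ang$kang,
             as.integer(rst$atom), as.matrix(rst[c("x", "y", "z")]), rst$k,
             conf$xb_donors, p$hba, p$rvdw,
             model$cutoff, model$kcoul, model$hb_r0, model$hb_depth,
             model$xb_depth, cos(model$xb_angle_min * pi / 180), model$xb_pad,
             as.integer(subset), as.integer(mode))
}

#' Ligand-channel interaction energy
#'
#' The interaction energy is E(complex) - E(receptor alone) - E(ligand
#' alone), each term evaluated under the full model (restraints excluded —
#' they would cancel for purely pairwise terms and are not part of the
#' ligand-channel interaction).  Because the hydrogen-bond term saturates
#' donors and acceptors, this difference is computed literally from the
#' three evaluations rather than as a bare cross-term sum.
#'
#' @param conf A `conformation` containing a `"ligand"` unit.
#' @param model An `energy_model`.
#' @return Interaction energy in kcal/mol.
#' @export
interaction_energy <- function(conf, model = default_energy_model()) {
  lig <- which(conf$atoms$unit == "ligand")
  if (!length(lig)) stop("conformation has no ligand unit", call. = FALSE)
  m0 <- without_restraints(model)
  rec <- which(conf$atoms$unit != "ligand")
  unname(energy(conf, m0)[["total"]] -
           energy(conf, m0, subset = rec, mode = 3L)[["total"]] -
           energy(conf, m0, subset = lig, mode = 3L)[["total"]])
}

#' Local energy minimization by cyclic line searches
#'
#' Block coordinate descent in the conformation's generalized coordinates:
#' each scalar DOF (torsion angle, rigid translation component, rigid
#' rotation component) is line-searched in turn over a window that shrinks
#' across sweeps, using only the energy terms that the move can change.
#' Purely derivative-free and exactly reproducible.  The returned energy is
#' never above the starting energy (a move is applied only when it improves).
#'
#' @param conf A `conformation`.
#' @param model An `energy_model`.
#' @param tol Convergence tolerance on the total energy change per sweep,
#'   kcal/mol.
#' @param max_sweeps Sweep limit.
#' @param trans_window,rot_window,tor_window Initial half-widths of the line
#'   search windows (A, degrees, degrees).
#' @return List with `conformation`, `energy` (final total), `converged`.
#' @export
local_minimize <- function(conf, model = default_energy_model(), tol = 1e-4,
                           max_sweeps = 40, trans_window = 1.2,
                           rot_window = 30, tor_window = 60) {
  e0 <- energy(conf, model)[["total"]]
  if (!is.finite(e0)) stop("non-finite starting energy", call. = FALSE)
  if (!length(conf$dof))
    return(list(conformation = conf, energy = e0, converged = TRUE))
  start <- conf
  e_cur <- e0
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    shrink <- 0.65^((sweep - 1) %% 8)
    e_before <- e_cur
    for (bi in seq_along(conf$dof)) {
      b <- conf$dof[[bi]]
      ns <- if (b$type == "torsion") 1L
            else if (isTRUE(b$translate_only)) 3L else 6L
      sub <- .block_atoms(conf, bi)
      for (si in seq_len(ns)) {
        w <- if (b$type == "torsion") tor_window * shrink
             else if (si <= 3L) trans_window * shrink
             else rot_window * shrink
        f <- function(d) {
          trial <- .apply_scalar(conf, bi, si, d)
          energy(trial, model, subset = sub, mode = 1L)[["total"]]
        }
        f0 <- f(0)
        opt <- stats::optimize(f, c(-w, w), tol = 1e-6)
        if (opt$objective < f0 - 1e-12) {
          conf <- .apply_scalar(conf, bi, si, opt$minimum)
          e_cur <- e_cur + (opt$objective - f0)
        }
      }
    }
    if (abs(e_before - e_cur) < tol && sweep > 1L) { converged <- TRUE; break }
  }
  e_cur <- energy(conf, model)[["total"]]  # re-sync against drift
  if (e_cur > e0) return(list(conformation = start, energy = e0,
                              converged = converged))
  list(conformation = conf, energy = e_cur, converged = converged)
}

#' Monte Carlo minimization schedule
#'
#' @param n_steps Number of MC steps (random move + local minimization).
#' @param torsion_deg,trans,rot_deg Move magnitudes (degrees, A, degrees).
#' @param acceptance `"greedy"` (accept only downhill, the default) or
#'   `"metropolis"`.
#' @param temperature Metropolis temperature in kcal/mol (RT units).
#' @param tol,max_sweeps Passed to [local_minimize()] at each step.
#' @param seed Optional integer seed; fixing it makes the run bit-reproducible.
#' @return An `mcm_schedule` list.
#' @export
mcm_schedule <- function(n_steps = 20, torsion_deg = 60, trans = 0.8,
                         rot_deg = 25, acceptance = c("greedy", "metropolis"),
                         temperature = 0.6, tol = 1e-4, max_sweeps = 10,
                         seed = NULL) {
  acceptance <- match.arg(acceptance)
  stopifnot(n_steps >= 0, torsion_deg > 0, trans > 0, rot_deg > 0)
  structure(list(n_steps = as.integer(n_steps), torsion_deg = torsion_deg,
                 trans = trans, rot_deg = rot_deg, acceptance = acceptance,
                 temperature = temperature, tol = tol,
                 max_sweeps = as.integer(max_sweeps), seed = seed),
            class = "mcm_schedule")
}

# run expr under a locally seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% 2147483647)
  expr
}

#' Monte Carlo energy minimization
#'
#' The MCM loop: local minimization of the start, then repeated random moves
#' in generalized coordinates, each followed by local minimization, with
#' greedy (default) or Metropolis acceptance.  Under greedy acceptance the
#' accepted-energy trajectory is non-increasing by construction.
#'
#' @param conf A `conformation`.
#' @param model An `energy_model`.
#' @param schedule An [mcm_schedule()].
#' @return List with `conformation` (best found), `energy` (its total),
#'   `trajectory` (accepted minimum energies, starting with the minimized
#'   start) and `accepted` (logical per step).
#' @export
mc_minimize <- function(conf, model = default_energy_model(),
                        schedule = mcm_schedule()) {
  stopifnot(inherits(schedule, "mcm_schedule"))
  .with_seed(schedule$seed, {
    cur <- local_minimize(conf, model, tol = schedule$tol,
                          max_sweeps = schedule$max_sweeps)
    best <- cur
    traj <- cur$energy
    accepted <- logical(0)
    if (schedule$n_steps > 0L && length(conf$dof)) {
      for (step in seq_len(schedule$n_steps)) {
        trial <- cur$conformation
        for (bi in seq_along(trial$dof)) {
          b <- trial$dof[[bi]]
          if (b$type == "torsion") {
            if (stats::runif(1) < 0.7)
              trial <- .apply_scalar(trial, bi, 1L,
                                     stats::runif(1, -1, 1) * schedule$torsion_deg)
          } else {
            for (si in 1:3) trial <- .apply_scalar(trial, bi, si,
                                     stats::runif(1, -1, 1) * schedule$trans)
            for (si in 4:6) trial <- .apply_scalar(trial, bi, si,
                                     stats::runif(1, -1, 1) * schedule$rot_deg)
          }
        }
        res <- local_minimize(trial, model, tol = schedule$tol,
                              max_sweeps = schedule$max_sweeps)
        acc <- if (schedule$acceptance == "greedy") res$energy < cur$energy
               else res$energy < cur$energy ||
                 stats::runif(1) < exp((cur$energy - res$energy) / schedule$temperature)
        accepted <- c(accepted, acc)
        if (acc) {
          cur <- res
          if (res$energy < best$energy) best <- res
        }
        traj <- c(traj, cur$energy)
      }
    }
    list(conformation = best$conformation, energy = best$energy,
         trajectory = traj, accepted = accepted)
  })
}
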