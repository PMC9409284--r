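#' Geometric interaction criteria
#'
#' All thresholds live here, in one place: the literature-standard values
#' used by every detector.  Distances are heavy-atom distances; hydrogens
#' are never required (polar hydrogen positions are inferred along the
#' donor-acceptor direction when absent, which makes the angle test pass
#' trivially for inferred hydrogens).
#'
#' @return A named list: `contact` (4 A), `hbond_dist` (3.5 A), `hbond_angle`
#'   (120 deg), `xbond_pad` (0.2 A beyond the van der Waals radius sum),
#'   `xbond_angle` (140 deg), `salt_bridge` (4 A), `weakened` (0.5 A),
#'   `pi_stack` (5.5 A ring-centroid distance, reported descriptively only),
#'   `environment` (4.5 A).
#' @export
interaction_criteria <- function() {
  list(contact = 4.0, hbond_dist = 3.5, hbond_angle = 120,
       xbond_pad = 0.2, xbond_angle = 140, salt_bridge = 4.0,
       weakened = 0.5, pi_stack = 5.5, environment = 4.5)
}

.vdw_radius <- function(element) {
  tab <- utils::read.delim(system.file("extdata", "vdw_radii.tsv",
                                       package = "pyrenav", mustWork = TRUE))
  r <- tab$radius[match(element, tab$element)]
  r[is.na(r)] <- 1.7
  r
}

.angle_deg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  acos(max(-1, min(1, sum(v1 * v2) /
                     sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
}

#' Hydrogen-bond test
#'
#' True iff the donor-acceptor heavy-atom distance is at most 3.5 A and the
#' D-H...A angle is at least 120 degrees.  When no hydrogen position is
#' given, H is inferred along the D-to-A direction (the angle clause then
#' holds trivially, leaving the distance gate).
#'
#' @param d_xyz,a_xyz Donor and acceptor heavy-atom coordinates (length 3).
#' @param h_xyz Optional hydrogen coordinates.
#' @param criteria Threshold list from [interaction_criteria()].
#' @return Logical.
#' @export
detect_hbond <- function(d_xyz, a_xyz, h_xyz = NULL,
                         criteria = interaction_criteria()) {
  d_xyz <- as.numeric(d_xyz); a_xyz <- as.numeric(a_xyz)
  if (all(abs(d_xyz - a_xyz) < 1e-9))
    stop("donor and acceptor are the same atom", call. = FALSE)
  r <- sqrt(sum((d_xyz - a_xyz)^2))
  if (r > criteria$hbond_dist) return(FALSE)
  if (is.null(h_xyz)) return(TRUE)  # inferred H along D->A: angle is 180
  .angle_deg(d_xyz, as.numeric(h_xyz), a_xyz) >= criteria$hbond_angle
}

#' Halogen-bond test
#'
#' True iff X...A is within the sum of van der Waals radii plus 0.2 A and
#' the C-X...A angle is at least 140 degrees (sigma-hole directionality).
#'
#' @param c_xyz,x_xyz,a_xyz Coordinates of the carbon, the halogen, and the
#'   acceptor.
#' @param x_element Halogen element (`"Cl"`, `"Br"`, `"I"`).
#' @param a_element Acceptor element (`"S"`, `"O"`, `"N"`).
#' @param criteria Threshold list.
#' @return Logical.
#' @export
detect_halogen_bond <- function(c_xyz, x_xyz, a_xyz, x_element, a_element,
                                criteria = interaction_criteria()) {
  if (!x_element %in% c("Cl", "Br", "I"))
    stop("'", x_element, "' is not a halogen-bond donor element", call. = FALSE)
  if (!a_element %in% c("S", "O", "N")) return(FALSE)
  rmax <- sum(.vdw_radius(c(x_element, a_element))) + criteria$xbond_pad
  r <- sqrt(sum((as.numeric(x_xyz) - as.numeric(a_xyz))^2))
  if (r > rmax) return(FALSE)
  .angle_deg(as.numeric(c_xyz), as.numeric(x_xyz), as.numeric(a_xyz)) >=
    criteria$xbond_angle
}

#' Salt-bridge test
#'
#' True iff any carboxylate oxygen is within 4.0 A of any basic nitrogen.
#' Missing side-chain atoms give `NA` (indeterminate), never `FALSE`.
#'
#' @param acid_xyz Matrix of carboxylate O coordinates (Asp/Glu).
#' @param base_xyz Matrix of basic N coordinates (Arg guanidinium, Lys NZ).
#' @param criteria Threshold list.
#' @return Logical or `NA`.
#' @export
detect_salt_bridge <- function(acid_xyz, base_xyz,
                               criteria = interaction_criteria()) {
  acid_xyz <- rbind(acid_xyz); base_xyz <- rbind(base_xyz)
  if (!nrow(acid_xyz) || !nrow(base_xyz)) return(NA)
  d <- sqrt(outer(rowSums(acid_xyz^2), rowSums(base_xyz^2), "+") -
              2 * acid_xyz %*% t(base_xyz))
  any(d <= criteria$salt_bridge)
}

.BACKBONE <- c("N", "CA", "C", "O", "OXT")

# side-chain heavy atoms of each residue (CA stands in for glycine)
.side_chain_idx <- function(atoms, resno) {
  idx <- which(atoms$resno == resno & !atoms$het)
  sc <- idx[!(atoms$elety[idx] %in% .BACKBONE)]
  if (!length(sc)) sc <- idx[atoms$elety[idx] == "CA"]
  sc
}

# classify the residue-ligand interaction given the closest-approach pairs
.classify_contact <- function(structure, ridx, ligand, pose, model_types,
                              criteria) {
  at <- structure$atoms
  xyz <- coords(structure)
  # halogen bond: ligand C-X donors vs residue S/O/N acceptors
  if (nrow(ligand$xb_donors)) {
    acc <- ridx[at$elesy[ridx] %in% c("S", "O", "N")]
    for (p in seq_len(nrow(ligand$xb_donors))) {
      ci <- ligand$xb_donors[p, 1L]; xi <- ligand$xb_donors[p, 2L]
      for (a in acc)
        if (detect_halogen_bond(pose[ci, ], pose[xi, ], xyz[a, ],
                                ligand$atoms$element[xi], at$elesy[a],
                                criteria))
          return("xbond")
    }
  }
  # hydrogen bond: donor/acceptor flags come from the force-field types
  rty <- model_types$res[match(paste(at$resid[ridx], at$elety[ridx]),
                               model_types$key)]
  rhbd <- model_types$hbd[match(rty, model_types$type)]
  rhba <- model_types$hba[match(rty, model_types$type)]
  lhbd <- model_types$hbd[match(ligand$atoms$type, model_types$type)]
  lhba <- model_types$hba[match(ligand$atoms$type, model_types$type)]
  for (ii in seq_along(ridx)) for (jj in seq_len(nrow(pose))) {
    dn <- isTRUE(rhbd[ii]) && isTRUE(lhba[jj])
    an <- isTRUE(rhba[ii]) && isTRUE(lhbd[jj])
    if ((dn || an) &&
        sqrt(sum((xyz[ridx[ii], ] - pose[jj, ])^2)) <= criteria$hbond_dist)
      return("hbond")
  }
  # salt bridge: charged residue vs charged ligand group (toy ligands are
  # neutral, so this arm matters for charged custom ligands only)
  if (at$resid[ridx[1L]] %in% c("ASP", "GLU")) {
    ox <- ridx[at$elety[ridx] %in% c("OD1", "OD2", "OE1", "OE2")]
    bn <- which(ligand$atoms$element == "N" & ligand$atoms$formal > 0L)
    if (length(ox) && length(bn) &&
        isTRUE(detect_salt_bridge(xyz[ox, , drop = FALSE],
                                  pose[bn, , drop = FALSE], criteria)))
      return("salt_bridge")
  }
  "vdw"
}

#' Residues in contact with a ligand pose
#'
#' One record per residue having a side-chain heavy atom within `cutoff`
#' (inclusive) of any ligand heavy atom; glycine is represented by its
#' C-alpha.  Records carry the minimum distance, the closest atom pair, and
#' an interaction class (`xbond` > `hbond` > `salt_bridge` > `vdw`, first
#' satisfied wins), ordered by (domain, segment k<o<p<i, index) when the
#' structure is annotated, by residue number otherwise.
#'
#' @param receptor A `channel_structure`.
#' @param pose Ligand pose coordinates (n x 3).
#' @param ligand The `ligand_topology` the pose belongs to.
#' @param cutoff Contact cutoff in A (default 4, boundary inclusive).
#' @param side_chain_only Use side-chain atoms only (default `TRUE`,
#'   matching how binding-site figures draw contact residues); `FALSE`
#'   includes backbone atoms.
#' @param model An `energy_model` (typing source for H-bond roles).
#' @return A data.frame with columns `label`, `resno`, `resid`, `min_dist`,
#'   `res_atom`, `lig_atom`, `class`.
#' @export
ligand_contacts <- function(receptor, pose, ligand, cutoff = 4,
                            side_chain_only = TRUE,
                            model = default_energy_model()) {
  pose <- as.matrix(pose)
  criteria <- interaction_criteria()
  criteria$contact <- cutoff
  at <- receptor$atoms
  xyz <- coords(receptor)
  labs <- if (!is.null(receptor$annotation))
    assign_labels(receptor, receptor$annotation) else NULL
  model_types <- list(key = paste(model$residue_params$resid,
                                  model$residue_params$elety),
                      res = model$residue_params$type,
                      type = model$types$type, hbd = model$types$hbd,
                      hba = model$types$hba)
  out <- list()
  if (!nrow(pose)) {
    return(data.frame(label = character(), resno = integer(),
                      resid = character(), min_dist = numeric(),
                      res_atom = character(), lig_atom = character(),
                      class = character(), stringsAsFactors = FALSE))
  }
  for (rn in unique(at$resno[!at$het])) {
    ridx <- if (side_chain_only) .side_chain_idx(at, rn)
            else which(at$resno == rn & !at$het)
    if (!length(ridx)) next
    rx <- xyz[ridx, , drop = FALSE]
    d2 <- outer(rowSums(rx^2), rowSums(pose^2), "+") - 2 * rx %*% t(pose)
    dmin <- sqrt(max(0, min(d2)))
    if (dmin > cutoff + 1e-9) next
    w <- which(d2 == min(d2), arr.ind = TRUE)[1L, ]
    lab <- if (!is.null(labs)) labs$label[match(rn, labs$resno)] else NA
    out[[length(out) + 1L]] <- data.frame(
      label = if (is.na(lab)) NA_character_ else lab, resno = rn,
      resid = at$resid[ridx[1L]], min_dist = dmin,
      res_atom = at$elety[ridx[w[1L]]],
      lig_atom = ligand$atoms$name[w[2L]],
      class = .classify_contact(receptor, ridx, ligand, pose, model_types,
                                criteria),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(label = character(), resno = integer(), resid = character(),
               min_dist = numeric(), res_atom = character(),
               lig_atom = character(), class = character(),
               stringsAsFactors = FALSE)
  if (nrow(res) && !is.null(labs)) {
    m <- match(res$resno, labs$resno)
    segord <- match(labs$segment[m], c("k", "o", "p", "i"))
    o <- order(labs$domain[m], segord, labs$index[m], na.last = TRUE)
    res <- res[o, , drop = FALSE]
  } else if (nrow(res)) {
    res <- res[order(res$resno), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Interaction report for one ligand in one channel state
#'
#' @param receptor A `channel_structure`.
#' @param pose Ligand pose coordinates.
#' @param ligand A `ligand_topology`.
#' @param ligand_id Identifier tying reports of the same ligand together.
#' @param membership Optional label-to-site map (see [site_membership()])
#'   for per-site contact counts.
#' @param cutoff Contact cutoff (A).
#' @return An `interaction_report`: state tag, ligand id, the contact table,
#'   and summary counts per class and per site.
#' @export
interaction_report <- function(receptor, pose, ligand,
                               ligand_id = ligand$kind, membership = NULL,
                               cutoff = 4) {
  contacts <- ligand_contacts(receptor, pose, ligand, cutoff = cutoff)
  site <- if (!is.null(membership) && nrow(contacts))
    vapply(contacts$label, classify_site, "", membership = membership)
  else rep(NA_character_, nrow(contacts))
  contacts$site <- site
  structure(list(state = receptor$state, ligand_id = ligand_id,
                 contacts = contacts,
                 by_class = table(contacts$class),
                 by_site = table(site, useNA = "no")),
            class = "interaction_report")
}

#' @export
print.interaction_report <- function(x, ...) {
  cat("<interaction_report> state ", x$state, ", ligand ", x$ligand_id,
      ": ", nrow(x$contacts), " contact residues\n", sep = "")
  if (nrow(x$contacts)) print(x$contacts, digits = 3)
  invisible(x)
}

#' Contact gain/loss between two states
#'
#' Partitions the union of contact residues of two reports for the same
#' ligand into `retained`, `lost` (in `a` only), `gained` (in `b` only), and
#' flags retained contacts whose minimum distance grew by more than the
#' weakening threshold as `weakened`.
#'
#' @param a,b `interaction_report` objects (same ligand id).
#' @param criteria Threshold list (uses `weakened`, default 0.5 A).
#' @return List of data.frames `retained`, `lost`, `gained`, `weakened`.
#' @export
contact_diff <- function(a, b, criteria = interaction_criteria()) {
  stopifnot(inherits(a, "interaction_report"),
            inherits(b, "interaction_report"))
  if (!identical(a$ligand_id, b$ligand_id))
    stop("reports describe different ligands: '", a$ligand_id, "' vs '",
         b$ligand_id, "'", call. = FALSE)
  ka <- a$contacts$resno; kb <- b$contacts$resno
  lost <- a$contacts[!ka %in% kb, , drop = FALSE]
  gained <- b$contacts[!kb %in% ka, , drop = FALSE]
  ret <- a$contacts[ka %in% kb, , drop = FALSE]
  if (nrow(ret)) {
    d2 <- b$contacts$min_dist[match(ret$resno, kb)]
    ret$delta_dist <- d2 - ret$min_dist
    weak <- ret[ret$delta_dist > criteria$weakened, , drop = FALSE]
  } else {
    ret$delta_dist <- numeric(0)
    weak <- ret
  }
  list(retained = ret, lost = lost, gained = gained, weakened = weak)
}

#' Intersegment environment of a residue
#'
#' Neighboring residues within `cutoff` (minimum heavy-atom distance),
#' excluding sequential neighbors in the same segment (|delta index| <= 2)
#' so the report stays focused on intersegment packing, sorted by distance.
#' Each neighbor carries a detected interaction class: `hbond` when a
#' donor/acceptor atom pair of the two side chains passes the hydrogen-bond
#' gate, `salt_bridge` for Asp/Glu against Arg/Lys within the salt-bridge
#' gate, `pi_stack` (descriptive only) for two aromatic rings with centroids
#' within 5.5 A, else `vdw`.
#'
#' @param structure An annotated `channel_structure`.
#' @param label Universal label (string or `universal_label`).
#' @param cutoff Neighborhood cutoff in A (default 4.5).
#' @param model An `energy_model` (typing source).
#' @return Data.frame with `label`, `resno`, `resid`, `min_dist`, `class`.
#' @export
residue_environment <- function(structure, label, cutoff = 4.5,
                                model = default_energy_model()) {
  if (inherits(label, "universal_label")) label <- format_label(label)
  labs <- assign_labels(structure, structure$annotation)
  row <- match(sub("^[A-Z]", "", label), labs$label)
  if (is.na(row)) stop("label '", label, "' not present in structure",
                       call. = FALSE)
  rn <- labs$resno[row]
  at <- structure$atoms
  xyz <- coords(structure)
  criteria <- interaction_criteria()
  me <- .side_chain_idx(at, rn)
  mex <- xyz[me, , drop = FALSE]
  rp <- model$residue_params
  hb_flag <- function(idx) {
    ty <- rp$type[match(paste(at$resid[idx], at$elety[idx]),
                        paste(rp$resid, rp$elety))]
    m <- match(ty, model$types$type)
    list(hbd = model$types$hbd[m] %in% TRUE, hba = model$types$hba[m] %in% TRUE)
  }
  ring_centroid <- function(idx) {
    ring <- idx[at$elety[idx] %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")]
    if (length(ring) < 6L) return(NULL)
    colMeans(xyz[ring, , drop = FALSE])
  }
  out <- list()
  for (other in setdiff(unique(at$resno[!at$het]), rn)) {
    orow <- match(other, labs$resno)
    if (!is.na(orow) && !is.na(row) &&
        labs$domain[orow] == labs$domain[row] &&
        labs$segment[orow] == labs$segment[row] &&
        abs(labs$index[orow] - labs$index[row]) <= 2L) next
    oi <- .side_chain_idx(at, other)
    if (!length(oi)) next
    ox <- xyz[oi, , drop = FALSE]
    d2 <- outer(rowSums(mex^2), rowSums(ox^2), "+") - 2 * mex %*% t(ox)
    dmin <- sqrt(max(0, min(d2)))
    if (dmin > cutoff + 1e-9) next
    cls <- "vdw"
    fa <- hb_flag(me); fb <- hb_flag(oi)
    pairs <- which(outer(fa$hbd, fb$hba) | outer(fa$hba, fb$hbd),
                   arr.ind = TRUE)
    for (p in seq_len(nrow(pairs)))
      if (sqrt(d2[pairs[p, 1L], pairs[p, 2L]]) <= criteria$hbond_dist) {
        cls <- "hbond"; break
      }
    rr <- c(at$resid[me[1L]], at$resid[oi[1L]])
    if (any(rr %in% c("ASP", "GLU")) && any(rr %in% c("ARG", "LYS"))) {
      ai <- if (rr[1L] %in% c("ASP", "GLU")) me else oi
      bi <- setdiff(c(me, oi), ai)
      ox2 <- ai[at$elety[ai] %in% c("OD1", "OD2", "OE1", "OE2")]
      nn <- bi[at$elety[bi] %in% c("NE", "NH1", "NH2", "NZ")]
      if (length(ox2) && length(nn) &&
          isTRUE(detect_salt_bridge(xyz[ox2, , drop = FALSE],
                                    xyz[nn, , drop = FALSE], criteria)))
        cls <- "salt_bridge"
    }
    r1 <- ring_centroid(me); r2 <- ring_centroid(oi)
    if (cls == "vdw" && !is.null(r1) && !is.null(r2) &&
        sqrt(sum((r1 - r2)^2)) <= criteria$pi_stack)
      cls <- "pi_stack"
    out[[length(out) + 1L]] <- data.frame(
      label = if (is.na(orow)) NA_character_ else labs$label[orow],
      resno = other, resid = at$resid[oi[1L]], min_dist = dmin, class = cls,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(label = character(), resno = integer(), resid = character(),
               min_dist = numeric(), class = character(),
               stringsAsFactors = FALSE)
  res <- res[order(res$min_dist), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write an interaction report to TSV or JSON
#'
#' @param report An `interaction_report`.
#' @param path Output path; format chosen by extension (`.tsv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "interaction_report"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "tsv") {
    utils::write.table(report$contacts, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(list(state = report$state,
                              ligand_id = report$ligand_id,
                              contacts = report$contacts), path,
                         auto_unbox = TRUE, digits = NA)
  } else stop("unsupported report format '", ext, "'", call. = FALSE)
  invisible(path)
}
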