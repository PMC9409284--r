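#' Atom selections
#'
#' A deterministic predicate over (residue, atom name) pairs.  Selections can
#' be built explicitly with `atom_selection()` or given as one of the string
#' shorthands used throughout the pipeline:
#'
#' * `"ca"` — all protein C-alpha atoms (no annotation needed);
#' * `"pm-ca"` — C-alpha atoms of the pore-module segments (k, o, p, i);
#' * `"p1-ca"` — C-alpha atoms of the P1 helices, the most 3D-conserved part
#'   of P-loop channels and the default frame for superposition.  P1 is taken
#'   as the first `p1_len` residues of each p segment (default 5); the
#'   annotation, not secondary structure, defines the span;
#' * `"i-lower-ca"` — C-alpha atoms of the cytoplasmic halves of the inner
#'   helices (index above half the segment span), the part displaced by
#'   gating.
#'
#' @param segment Segment codes to keep (`NULL` = any).
#' @param domain Domains to keep (`NULL` = any).
#' @param index Universal indices to keep (`NULL` = any).
#' @param elety Atom names to keep (default `"CA"`).
#' @param p1_len Number of leading p-segment residues regarded as P1.
#' @return An `atom_selection` object.
#' @export
atom_selection <- function(segment = NULL, domain = NULL, index = NULL,
                           elety = "CA", p1_len = 5L) {
  structure(list(segment = segment, domain = domain, index = index,
                 elety = elety, p1_len = as.integer(p1_len)),
            class = "atom_selection")
}

.as_selection <- function(selection) {
  if (inherits(selection, "atom_selection")) return(selection)
  if (is.character(selection) && length(selection) == 1L) {
    return(switch(selection,
      "ca" = , "all-ca" = atom_selection(elety = "CA"),
      "pm-ca" = atom_selection(segment = c("k", "o", "p", "i")),
      "p1-ca" = structure(c(atom_selection(segment = "p"), list(p1 = TRUE)),
                          class = "atom_selection"),
      "i-lower-ca" = structure(c(atom_selection(segment = "i"), list(lower = TRUE)),
                               class = "atom_selection"),
      stop("unknown selection shorthand '", selection, "'", call. = FALSE)))
  }
  stop("selection must be an atom_selection or a shorthand string", call. = FALSE)
}

#' Select atoms from a structure
#'
#' @param structure A `channel_structure` (annotated unless the selection is
#'   purely by atom name).
#' @param selection An `atom_selection` or shorthand string.
#' @return A data.frame of selected atoms with columns `idx` (row in the atom
#'   table), `resno`, `elety`, and, when labeled, `domain`, `segment`,
#'   `index`, `label`; ordered by (domain, segment k<o<p<i, index, atom name)
#'   or by residue number for unlabeled selections.
#' @export
select_atoms <- function(structure, selection) {
  sel <- .as_selection(selection)
  a <- structure$atoms
  keep <- !a$het & a$elety %in% sel$elety
  needs_labels <- !is.null(sel$segment) || !is.null(sel$domain) ||
    !is.null(sel$index) || isTRUE(sel$p1) || isTRUE(sel$lower)
  if (!needs_labels) {
    out <- data.frame(idx = which(keep), resno = a$resno[keep],
                      elety = a$elety[keep], stringsAsFactors = FALSE)
    return(out[order(out$resno, out$elety), , drop = FALSE])
  }
  if (is.null(structure$annotation))
    stop("selection requires an annotated structure", call. = FALSE)
  labs <- assign_labels(structure, structure$annotation)
  m <- match(a$resno, labs$resno)
  keep <- keep & !is.na(m)
  lab <- labs[m[keep], , drop = FALSE]
  out <- data.frame(idx = which(keep), resno = a$resno[keep], elety = a$elety[keep],
                    domain = lab$domain, segment = lab$segment, index = lab$index,
                    label = lab$label, stringsAsFactors = FALSE)
  if (!is.null(sel$segment)) out <- out[out$segment %in% sel$segment, , drop = FALSE]
  if (!is.null(sel$domain)) out <- out[out$domain %in% sel$domain, , drop = FALSE]
  if (!is.null(sel$index)) out <- out[out$index %in% sel$index, , drop = FALSE]
  if (isTRUE(sel$p1)) out <- out[out$index <= sel$p1_len, , drop = FALSE]
  if (isTRUE(sel$lower)) {
    half <- stats::ave(out$index, out$domain, FUN = function(i) max(i) / 2)
    out <- out[out$index > half, , drop = FALSE]
  }
  segord <- match(out$segment, c("k", "o", "p", "i"))
  out[order(out$domain, segord, out$index, out$elety), , drop = FALSE]
}

#' Pair equivalent atoms of two structures under a selection
#'
#' Atoms are paired by identical universal label plus atom name when both
#' structures are annotated, by residue number plus atom name otherwise.
#' Unpaired atoms are dropped with a message stating the count, since
#' superposition across different channels routinely leaves unmatched spans.
#'
#' @param a,b `channel_structure` objects.
#' @param selection An `atom_selection` or shorthand.
#' @return A list with integer vectors `idx_a`, `idx_b` (paired atom rows)
#'   and `key` (the pairing keys).
#' @export
pair_selection <- function(a, b, selection) {
  sa <- select_atoms(a, selection)
  sb <- select_atoms(b, selection)
  key <- function(s) if ("label" %in% names(s)) paste(s$label, s$elety)
                     else paste(s$resno, s$elety)
  ka <- key(sa); kb <- key(sb)
  common <- intersect(ka, kb)
  if (!length(common)) stop("selection matches no paired atoms", call. = FALSE)
  dropped <- (length(ka) - length(common)) + (length(kb) - length(common))
  if (dropped > 0L) message("pair_selection: dropped ", dropped, " unpaired atoms")
  list(idx_a = sa$idx[match(common, ka)], idx_b = sb$idx[match(common, kb)],
       key = common)
}
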