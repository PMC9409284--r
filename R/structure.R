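#' Annotated channel structure
#'
#' The central structural container: a flat atom table plus a gating-state
#' tag and an optional [segment_annotation()].  Protein atoms link to
#' residues through `resno`; non-protein records (ligands, ions) are retained
#' as hetero atoms and never receive universal labels.
#'
#' State tags follow the prefix convention for channel models:
#' `inactivated_pm` (pore module inactivated), `open_pm`,
#' `open_to_inactivated` (re-inactivated in silico from the open model),
#' `open_pm_deactivated_vsm` (open pore, voltage sensors down), or `unknown`.
#'
#' @param atoms A data.frame with columns `eleno`, `elety` (atom name),
#'   `resid` (residue name), `resno`, `x`, `y`, `z`, `elesy` (element),
#'   `het` (logical).
#' @param state Gating-state tag.
#' @param annotation Optional `segment_annotation`.
#' @return An object of class `channel_structure`.
#' @export
channel_structure <- function(atoms, state = "unknown", annotation = NULL) {
  states <- c("inactivated_pm", "open_pm", "open_to_inactivated",
              "open_pm_deactivated_vsm", "unknown")
  if (!state %in% states)
    stop("state must be one of: ", paste(states, collapse = ", "), call. = FALSE)
  need <- c("eleno", "elety", "resid", "resno", "x", "y", "z", "elesy", "het")
  if (!all(need %in% names(atoms)))
    stop("atoms needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  atoms <- as.data.frame(atoms)[need]
  atoms$resno <- as.integer(atoms$resno)
  if (any(is.na(atoms$resno)))
    stop("every atom must link to a residue (non-NA resno)", call. = FALSE)
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("coordinates must be finite", call. = FALSE)
  if (!is.null(annotation)) annotation <- segment_annotation(annotation)
  structure(list(atoms = atoms, state = state, annotation = annotation),
            class = "channel_structure")
}

#' @export
print.channel_structure <- function(x, ...) {
  res <- structure_residues(x)
  cat("<channel_structure> ", nrow(x$atoms), " atoms, ", nrow(res),
      " residues, state: ", x$state, "\n", sep = "")
  invisible(x)
}

#' Residue table of a structure
#'
#' @param structure A `channel_structure`.
#' @param het Include hetero residues (default `FALSE`).
#' @return A data.frame with one row per residue: `resno`, `resid`, `aa`.
#' @export
structure_residues <- function(structure, het = FALSE) {
  a <- structure$atoms
  if (!het) a <- a[!a$het, , drop = FALSE]
  keep <- !duplicated(a$resno)
  aa <- suppressWarnings(bio3d::aa321(a$resid[keep]))
  aa[is.na(aa)] <- "X"
  data.frame(resno = a$resno[keep], resid = a$resid[keep], aa = aa,
             stringsAsFactors = FALSE)
}

#' Coordinates of a structure as an n x 3 matrix
#' @param structure A `channel_structure`.
#' @return Numeric matrix with columns x, y, z.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param structure A `channel_structure`.
#' @param xyz Numeric n x 3 matrix (same atom count and order).
#' @return The modified `channel_structure`.
#' @export
set_coords <- function(structure, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(structure$atoms) || ncol(xyz) != 3L)
    stop("xyz must be ", nrow(structure$atoms), " x 3", call. = FALSE)
  if (!all(is.finite(xyz))) stop("coordinates must be finite", call. = FALSE)
  structure$atoms$x <- xyz[, 1L]
  structure$atoms$y <- xyz[, 2L]
  structure$atoms$z <- xyz[, 3L]
  structure
}

.state_remark <- "REMARK 999 PYRENAV STATE"

#' Read a channel structure from PDB or mmCIF
#'
#' PDB reading is delegated to `bio3d` after a line-level sanity check so a
#' truncated ATOM record raises a parse error naming the line rather than a
#' silent partial structure.  mmCIF reading parses the `_atom_site` loop
#' directly; `auth_seq_id` is the authoritative residue numbering and a
#' mismatch with `label_seq_id` is reported via message.  A gating-state tag
#' written by [write_structure()] survives the round trip.
#'
#' @param path Path to the file.
#' @param format `"pdb"` or `"mmcif"` (default guessed from the extension).
#' @param annotation Optional `segment_annotation` to attach.
#' @return A `channel_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           annotation = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
              else if (ext %in% c("pdb", "ent")) "pdb"
              else stop("cannot guess format of '", path, "'; pass format=", call. = FALSE)
  }
  if (format == "pdb") .read_pdb(path, annotation) else .read_mmcif(path, annotation)
}

.read_pdb <- function(path, annotation) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in '", path, "'", call. = FALSE)
  bad <- which(rec & nchar(lines) < 54L)
  coordtxt <- substr(lines[rec], 31L, 54L)
  badnum <- which(rec)[is.na(suppressWarnings(as.numeric(substr(coordtxt, 1, 8)))) |
                       is.na(suppressWarnings(as.numeric(substr(coordtxt, 9, 16)))) |
                       is.na(suppressWarnings(as.numeric(substr(coordtxt, 17, 24))))]
  bad <- sort(unique(c(bad, badnum)))
  if (length(bad))
    stop("malformed ATOM/HETATM record at line ", bad[1L], " of '", path, "'",
         call. = FALSE)
  state <- "unknown"
  sl <- grep(.state_remark, lines, fixed = TRUE, value = TRUE)
  if (length(sl)) state <- trimws(sub(.state_remark, "", sl[1L], fixed = TRUE))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(eleno = a$eleno, elety = a$elety, resid = a$resid,
                      resno = a$resno, x = a$x, y = a$y, z = a$z,
                      elesy = ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
                                     .guess_element(a$elety), trimws(a$elesy)),
                      het = a$type == "HETATM", stringsAsFactors = FALSE)
  channel_structure(atoms, state = state, annotation = annotation)
}

.guess_element <- function(elety) {
  e <- sub("[0-9'*]+$", "", trimws(elety))
  two <- toupper(substr(e, 1, 2))
  out <- toupper(substr(e, 1, 1))
  out[two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "NA")] <-
    substr(e, 1, 2)[two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "NA")]
  # normalize case: first upper, second lower
  paste0(toupper(substr(out, 1, 1)), tolower(substr(out, 2, 2)))
}

.read_mmcif <- function(path, annotation) {
  lines <- readLines(path, warn = FALSE)
  # locate the atom_site loop
  li <- grep("^\\s*loop_\\s*$", lines)
  header <- integer(0); fields <- character(0)
  for (s in li) {
    j <- s + 1L
    f <- character(0)
    while (j <= length(lines) && grepl("^_", trimws(lines[j]))) {
      f <- c(f, trimws(lines[j])); j <- j + 1L
    }
    if (any(grepl("^_atom_site\\.", f))) { header <- j; fields <- f; break }
  }
  if (!length(header)) stop("no _atom_site loop in '", path, "'", call. = FALSE)
  fields <- sub("^_atom_site\\.", "", fields)
  rows <- list(); j <- header
  while (j <= length(lines)) {
    ln <- trimws(lines[j])
    if (!nzchar(ln) || grepl("^(#|loop_|_|data_)", ln)) break
    tok <- scan(text = ln, what = character(), quiet = TRUE)
    if (length(tok) != length(fields))
      stop("malformed _atom_site row at line ", j, " of '", path, "'", call. = FALSE)
    rows[[length(rows) + 1L]] <- tok
    j <- j + 1L
  }
  if (!length(rows)) stop("empty _atom_site loop in '", path, "'", call. = FALSE)
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  getcol <- function(nm, alt = NULL) {
    if (nm %in% fields) return(m[, nm])
    if (!is.null(alt) && alt %in% fields) return(m[, alt])
    stop("mmCIF '", path, "' lacks _atom_site.", nm, call. = FALSE)
  }
  resno_auth <- suppressWarnings(as.integer(getcol("auth_seq_id", "label_seq_id")))
  if (any(is.na(resno_auth)))
    stop("non-integer auth_seq_id in '", path, "'", call. = FALSE)
  if ("label_seq_id" %in% fields && "auth_seq_id" %in% fields) {
    lab <- suppressWarnings(as.integer(m[, "label_seq_id"]))
    if (any(!is.na(lab) & lab != resno_auth))
      message("mmCIF auth_seq_id and label_seq_id disagree; using auth_seq_id")
  }
  xyz <- apply(m[, c("Cartn_x", "Cartn_y", "Cartn_z"), drop = FALSE], 2, as.numeric)
  if (any(is.na(xyz))) stop("non-numeric coordinates in '", path, "'", call. = FALSE)
  atoms <- data.frame(
    eleno = seq_len(nrow(m)),
    elety = gsub('"', "", getcol("auth_atom_id", "label_atom_id")),
    resid = getcol("auth_comp_id", "label_comp_id"),
    resno = resno_auth,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    elesy = if ("type_symbol" %in% fields)
      paste0(toupper(substr(m[, "type_symbol"], 1, 1)),
             tolower(substr(m[, "type_symbol"], 2, 2)))
    else .guess_element(getcol("auth_atom_id", "label_atom_id")),
    het = getcol("group_PDB") == "HETATM",
    stringsAsFactors = FALSE)
  channel_structure(atoms, state = "unknown", annotation = annotation)
}

#' Write a channel structure to PDB
#'
#' The gating-state tag is stored in a `REMARK 999` line and restored by
#' [read_structure()].
#'
#' @param structure A `channel_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "channel_structure"))
  a <- structure$atoms
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp,
                   xyz = as.numeric(t(as.matrix(a[c("x", "y", "z")]))),
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = "A", elesy = a$elesy)
  body <- readLines(tmp, warn = FALSE)
  unlink(tmp)
  writeLines(c(paste(.state_remark, structure$state), body), path)
  invisible(path)
}
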