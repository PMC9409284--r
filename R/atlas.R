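#' The packaged kdr mutation atlas
#'
#' A machine-readable transcription of the four curated mutation tables:
#' knockdown-resistance (kdr) mutations within the PyR1/PyR2 pyrethroid
#' receptor sites (table 1), engineered substitutions within the sites
#' (table 2), kdr mutations beyond the sites (table 3), and engineered
#' substitutions beyond the sites (table 4).  Each record carries the native
#' house fly numbering, the universal label when the position lies in a
#' labeled segment, the substitution(s), species or channel, the site class,
#' and combination partners (multi-mutation rows are split into linked
#' records sharing a group id).
#'
#' @param paths Character vector of TSV paths (defaults to the packaged
#'   tables).
#' @return A `kdr_atlas` object: `mutations` (data.frame) and `membership`
#'   (a [site_membership()] compiled from the table 1/2 records).
#' @export
load_kdr_atlas <- function(paths = NULL) {
  if (is.null(paths))
    paths <- vapply(sprintf("atlas_table%d.tsv", 1:4), function(f)
      system.file("extdata", f, package = "pyrenav", mustWork = TRUE), "")
  rows <- list()
  for (path in paths) {
    tab <- utils::read.delim(path, colClasses = "character", fill = TRUE)
    if (!nrow(tab))
      stop("atlas table '", path, "' is empty", call. = FALSE)
    need <- c("table", "group", "raw", "wt", "native", "universal", "sub",
              "site", "species")
    if (!all(need %in% names(tab)))
      stop("atlas table '", path, "' lacks columns: ",
           paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
    for (i in seq_len(nrow(tab))) {
      r <- tab[i, ]
      if (!nzchar(r$raw) || !nzchar(r$wt) || !nzchar(r$sub))
        stop("malformed atlas row ", i, " in '", path, "'", call. = FALSE)
      if (nzchar(r$universal)) {
        # cross-check the dual label against the parser
        parsed <- parse_label(paste0(r$wt, r$native, "/", r$universal))
        stopifnot(parsed$label$aa == r$wt,
                  parsed$native$resnum == as.integer(r$native))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        table = r$table, group = paste(r$table, r$group), raw = r$raw,
        wt = r$wt,
        native = if (nzchar(r$native)) as.integer(r$native) else NA_integer_,
        universal = if (nzchar(r$universal)) r$universal else NA_character_,
        sub = r$sub, site = r$site,
        region = if ("region" %in% names(r) && nzchar(r$region)) r$region
                 else NA_character_,
        species = r$species,
        figures = if ("figures" %in% names(r) && nzchar(r$figures))
          r$figures else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  mutations <- do.call(rbind, rows)
  if (!nrow(mutations)) stop("atlas is empty", call. = FALSE)
  mutations$combination <- mutations$group %in%
    mutations$group[duplicated(mutations$group)]
  membership <- site_membership(mutations)
  structure(list(mutations = mutations, membership = membership),
            class = "kdr_atlas")
}

#' @export
print.kdr_atlas <- function(x, ...) {
  cat("<kdr_atlas> ", nrow(x$mutations), " mutation records (",
      sum(!is.na(x$mutations$universal)), " with universal labels), ",
      length(x$membership), " site-membership labels\n", sep = "")
  invisible(x)
}

#' Compile the label-to-site membership map
#'
#' Membership of the PyR1/PyR2 sites is per-label data compiled from the
#' curated records, never derived from segment identity: the IIS6 helix,
#' for instance, contributes its shallow positions (2i12-2i16) to PyR2 and
#' its deep positions (2i18-2i26) to PyR1, so any segment-level rule would
#' be wrong.  A label recorded under both sites is a load-time error.
#'
#' @param mutations Atlas mutation data.frame (columns `universal`, `site`).
#' @return Named character vector: label -> `"PyR1"` or `"PyR2"`.
#' @export
site_membership <- function(mutations) {
  rec <- mutations[!is.na(mutations$universal) &
                     mutations$site %in% c("PyR1", "PyR2"), ]
  out <- character()
  for (i in seq_len(nrow(rec))) {
    lab <- rec$universal[i]
    if (lab %in% names(out)) {
      if (out[[lab]] != rec$site[i])
        stop("conflicting site membership for ", lab, ": ", out[[lab]],
             " vs ", rec$site[i], call. = FALSE)
    } else out[[lab]] <- rec$site[i]
  }
  out
}

#' Classify a residue label against the receptor sites
#'
#' Exact lookup in the membership map; labels absent from both sites are
#' `"beyond"`.  A total function: any parseable label classifies.
#'
#' @param label Universal label (string, with or without the amino-acid
#'   prefix, or a `universal_label`).
#' @param membership Named vector from [site_membership()], or a
#'   `kdr_atlas`.
#' @return `"PyR1"`, `"PyR2"` or `"beyond"`.
#' @export
classify_site <- function(label, membership) {
  if (inherits(membership, "kdr_atlas")) membership <- membership$membership
  if (inherits(label, "universal_label")) label <- format_label(label)
  p <- parse_label(label)
  key <- paste0(p$label$domain, p$label$segment, p$label$index)
  if (key %in% names(membership)) unname(membership[[key]]) else "beyond"
}

#' Construct a kdr mutation record
#'
#' For building ad-hoc mutation sets (e.g. against synthetic channels); the
#' packaged atlas uses the same record layout.
#'
#' @param raw Raw label string (e.g. `"M918/2k11T"` or `"2o4A"`).
#' @param wt,sub Wild-type and substituted amino acids.
#' @param native Native residue number (or `NA`).
#' @param universal Universal label string (or `NA`).
#' @param species Species or channel name.
#' @param site Site class (`"PyR1"`, `"PyR2"`, `"beyond"`, `"linker_other"`).
#' @return A one-row mutation data.frame.
#' @export
kdr_mutation <- function(raw, wt, sub, native = NA, universal = NA,
                         species = "synthetic", site = "beyond") {
  data.frame(table = "custom", group = raw, raw = raw, wt = wt,
             native = as.integer(native), universal = universal, sub = sub,
             site = site, region = NA_character_, species = species,
             figures = NA_character_, combination = FALSE,
             stringsAsFactors = FALSE)
}

#' Structure-aware mutation report
#'
#' Resolves every atlas mutation in a labeled structure and reports, per
#' mutation: the site class, whether the wild-type residue directly
#' contacts a supplied ligand pose (with the minimum distance), and — for
#' mutations beyond the receptor sites — the intersegment environment of
#' the residue, whose contacts suggest how the substitution could
#' allosterically affect the sites.  Mutations at positions absent from the
#' structure (e.g. cytoplasmic segments outside the model) are listed
#' separately as unresolved.
#'
#' @param structure An annotated `channel_structure`.
#' @param atlas A `kdr_atlas`, or a mutation data.frame (e.g. from
#'   [kdr_mutation()]).
#' @param poses Optional list of `list(ligand = <ligand_topology>, xyz =
#'   <pose coordinates>)`.
#' @param cutoff Contact cutoff, A.
#' @param membership Optional membership map (defaults to the atlas's own
#'   when present).
#' @return A `mutation_report`: `resolved` (data.frame with one row per
#'   resolvable mutation record), `unresolved` (the rest), `environment`
#'   (named list of [residue_environment()] tables for beyond-site
#'   mutations).
#' @export
mutation_report <- function(structure, atlas, poses = NULL, cutoff = 4,
                            membership = NULL) {
  if (is.null(structure$annotation))
    stop("structure must be annotated to resolve universal labels",
         call. = FALSE)
  muts <- if (inherits(atlas, "kdr_atlas")) atlas$mutations else atlas
  if (is.null(membership) && inherits(atlas, "kdr_atlas"))
    membership <- atlas$membership
  if (is.null(membership)) membership <- character()
  labs <- assign_labels(structure, structure$annotation)
  contacts <- lapply(poses, function(p)
    ligand_contacts(structure, p$xyz, p$ligand, cutoff = cutoff))
  resolved <- list(); unresolved <- list(); envs <- list()
  for (i in seq_len(nrow(muts))) {
    m <- muts[i, ]
    row <- if (!is.na(m$universal)) match(m$universal, labs$label)
           else NA_integer_
    if (is.na(row)) {
      unresolved[[length(unresolved) + 1L]] <- m
      next
    }
    site <- if (m$site %in% c("PyR1", "PyR2")) m$site
            else classify_site(m$universal, membership)
    rec <- data.frame(m, resno = labs$resno[row],
                      site_class = site, stringsAsFactors = FALSE)
    if (!is.null(poses)) {
      hit <- FALSE; dmin <- NA_real_
      for (cc in contacts) {
        j <- match(m$universal, cc$label)
        if (!is.na(j)) {
          hit <- TRUE
          dmin <- min(dmin, cc$min_dist[j], na.rm = TRUE)
        }
      }
      rec$ligand_contact <- hit
      rec$min_dist <- dmin
    }
    resolved[[length(resolved) + 1L]] <- rec
    if (site == "beyond")
      envs[[m$universal]] <- residue_environment(structure, m$universal)
  }
  structure(list(
    resolved = if (length(resolved)) do.call(rbind, resolved) else NULL,
    unresolved = if (length(unresolved)) do.call(rbind, unresolved) else NULL,
    environment = envs), class = "mutation_report")
}

#' @export
print.mutation_report <- function(x, ...) {
  cat("<mutation_report> ", if (is.null(x$resolved)) 0 else nrow(x$resolved),
      " resolved, ",
      if (is.null(x$unresolved)) 0 else nrow(x$unresolved),
      " unresolved mutation records\n", sep = "")
  invisible(x)
}
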