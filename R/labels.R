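#' Universal residue labels for P-loop channels
#'
#' A universal label addresses a residue by the channel domain (1-4), the
#' segment type within the pore module region, and the relative position of
#' the residue within that segment.  Segment codes follow the established
#' nomenclature for P-loop channels: `k` = S4-S5 linker helix, `o` = outer
#' helix S5, `p` = P-loop, `i` = inner helix S6.  Labels such as `2k11`
#' (domain II, linker helix, position 11) are portable across channels with
#' different native numbering and highlight residues in symmetric positions
#' of the four domains.
#'
#' @param aa One-letter amino-acid code, or `NA` when unknown.
#' @param domain Integer domain number, 1 to 4.
#' @param segment Segment code, one of `"k"`, `"o"`, `"p"`, `"i"`.
#' @param index Positive integer position within the segment.
#' @return An object of class `universal_label`.
#' @examples
#' universal_label("M", 2, "k", 11)
#' @export
universal_label <- function(aa = NA_character_, domain, segment, index) {
  domain <- as.integer(domain)
  index <- as.integer(index)
  if (length(domain) != 1L || is.na(domain) || !domain %in% 1:4)
    stop("domain must be a single integer in 1..4", call. = FALSE)
  if (length(segment) != 1L || !segment %in% c("k", "o", "p", "i"))
    stop("segment must be one of 'k', 'o', 'p', 'i'", call. = FALSE)
  if (length(index) != 1L || is.na(index) || index < 1L)
    stop("index must be a positive integer", call. = FALSE)
  if (!is.na(aa)) {
    aa <- toupper(as.character(aa))
    if (!grepl("^[A-Z]$", aa)) stop("aa must be a one-letter code or NA", call. = FALSE)
  }
  structure(list(aa = aa, domain = domain, segment = segment, index = index),
            class = "universal_label")
}

#' @export
print.universal_label <- function(x, ...) {
  cat("<universal_label> ", format_label(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.universal_label <- function(x, ...) format_label(x)

#' Native sequence position
#'
#' A residue number in a named reference sequence (e.g. the house fly sodium
#' channel, GenBank X96668, which the mutation atlas uses as its common
#' numbering frame).
#'
#' @param reference Non-empty name of the reference sequence.
#' @param resnum Positive integer residue number.
#' @return An object of class `native_position`.
#' @export
native_position <- function(reference, resnum) {
  resnum <- as.integer(resnum)
  if (!is.character(reference) || length(reference) != 1L || !nzchar(reference))
    stop("reference must be a non-empty string", call. = FALSE)
  if (length(resnum) != 1L || is.na(resnum) || resnum < 1L)
    stop("resnum must be a positive integer", call. = FALSE)
  structure(list(reference = reference, resnum = resnum), class = "native_position")
}

#' @export
print.native_position <- function(x, ...) {
  cat("<native_position> ", x$reference, ":", x$resnum, "\n", sep = "")
  invisible(x)
}

#' Format a universal label (optionally in dual notation)
#'
#' Inverse of [parse_label()].  With a native position the dual notation
#' `"<aa><native>/<domain><segment><index>"` is produced (e.g. `"M918/2k11"`);
#' otherwise `"<aa><domain><segment><index>"` or `"<domain><segment><index>"`
#' when the amino acid is unknown.
#'
#' @param label A `universal_label`.
#' @param native Optional `native_position` for dual notation.
#' @return A single string.
#' @export
format_label <- function(label, native = NULL) {
  stopifnot(inherits(label, "universal_label"))
  core <- paste0(label$domain, label$segment, label$index)
  if (!is.null(native)) {
    stopifnot(inherits(native, "native_position"))
    aa <- if (is.na(label$aa)) "" else label$aa
    return(paste0(aa, native$resnum, "/", core))
  }
  if (is.na(label$aa)) core else paste0(label$aa, core)
}

#' Parse a residue label
#'
#' Accepts three forms: `"2k11"`, `"M2k11"`, and the dual notation
#' `"M918/2k11"` used throughout the mutation atlas, where the number before
#' the slash is the native residue number in a reference sequence.
#'
#' @param text A single label string.
#' @param reference Reference sequence name attached to the native half of a
#'   dual label (default `"housefly/X96668"`).
#' @return A list with elements `label` (a `universal_label`) and `native`
#'   (a `native_position`, or `NULL` for non-dual forms).
#' @examples
#' parse_label("M918/2k11")
#' parse_label("V253/1k11")
#' @export
parse_label <- function(text, reference = "housefly/X96668") {
  if (!is.character(text) || length(text) != 1L)
    stop("text must be a single string", call. = FALSE)
  m <- regexec("^([A-Za-z])?([0-9]+)/([1-4])([a-z])([0-9]+)$", text)
  g <- regmatches(text, m)[[1]]
  if (length(g)) {
    seg <- g[5]
    if (!seg %in% c("k", "o", "p", "i"))
      stop("invalid segment code '", seg, "' in label '", text, "'", call. = FALSE)
    aa <- if (nzchar(g[2])) toupper(g[2]) else NA_character_
    lab <- universal_label(aa, g[4], seg, g[6])
    return(list(label = lab, native = native_position(reference, as.integer(g[3]))))
  }
  m <- regexec("^([A-Za-z])?([1-4])([a-z])([0-9]+)$", text)
  g <- regmatches(text, m)[[1]]
  if (!length(g))
    stop("cannot parse residue label '", text, "'", call. = FALSE)
  seg <- g[4]
  if (!seg %in% c("k", "o", "p", "i"))
    stop("invalid segment code '", seg, "' in label '", text, "'", call. = FALSE)
  aa <- if (nzchar(g[2])) toupper(g[2]) else NA_character_
  list(label = universal_label(aa, g[3], seg, g[5]), native = NULL)
}

#' Segment annotation: native spans of the k/o/p/i segments
#'
#' An annotation table maps, for each channel domain, native residue-number
#' spans to segment types, and records for each span the `anchor`: the native
#' residue number that carries universal index 1.  The anchor may lie outside
#' the span itself (the labeling scheme's origin can precede the modeled or
#' tabulated stretch).  Several spans may describe one (domain, segment) pair
#' provided they do not overlap and do not assign one universal index twice;
#' this accommodates sub-regions whose printed indices are offset relative to
#' each other (as happens between the P1 and P2 halves of a P-loop).
#'
#' @param df A data.frame with columns `domain`, `segment`, `first`, `last`,
#'   `anchor`.
#' @return A validated `segment_annotation` (a data.frame subclass).
#' @export
segment_annotation <- function(df) {
  need <- c("domain", "segment", "first", "last", "anchor")
  if (!all(need %in% names(df)))
    stop("annotation needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[need]
  df$domain <- as.integer(df$domain)
  df$segment <- as.character(df$segment)
  for (col in c("first", "last", "anchor")) df[[col]] <- as.integer(df[[col]])
  if (any(!df$domain %in% 1:4)) stop("domain must be in 1..4", call. = FALSE)
  if (any(df$first > df$last)) stop("span first > last", call. = FALSE)
  # spans within one domain must not overlap
  for (d in unique(df$domain)) {
    sp <- df[df$domain == d, , drop = FALSE]
    sp <- sp[order(sp$first), , drop = FALSE]
    if (nrow(sp) > 1L && any(sp$first[-1L] <= sp$last[-nrow(sp)]))
      stop("overlapping segment spans in domain ", d, call. = FALSE)
  }
  # universal indices must be unique per (domain, segment)
  for (key in unique(paste(df$domain, df$segment))) {
    sp <- df[paste(df$domain, df$segment) == key, , drop = FALSE]
    idx <- unlist(lapply(seq_len(nrow(sp)), function(i)
      seq(sp$first[i], sp$last[i]) - sp$anchor[i] + 1L))
    if (anyDuplicated(idx))
      stop("duplicate universal indices for (domain, segment) ", key, call. = FALSE)
  }
  class(df) <- c("segment_annotation", "data.frame")
  df
}

#' Read a segment annotation from TSV
#'
#' @param path Path to a TSV file with columns `domain`, `segment`, `first`,
#'   `last`, `anchor`.
#' @return A `segment_annotation`.
#' @export
read_annotation <- function(path) {
  segment_annotation(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' The packaged house fly (X96668) segment annotation
#'
#' Anchors were solved from the dual labels printed in the mutation atlas
#' (e.g. 918 is 2k11, hence the domain-II linker-helix anchor is 908), and
#' reproduce every dual label in the packaged tables.
#'
#' @return A `segment_annotation`.
#' @export
housefly_annotation <- function() {
  read_annotation(system.file("extdata", "housefly_annotation.tsv",
                              package = "pyrenav", mustWork = TRUE))
}

#' Map native residue numbers to universal labels
#'
#' A residue at native number n falling inside a span of (domain d,
#' segment s) receives universal index n - anchor(d, s) + 1.  Residues
#' outside every span are absent from the returned map.
#'
#' @param structure A `channel_structure`, or an integer vector of native
#'   residue numbers.
#' @param annotation A `segment_annotation`.
#' @param aa Optional character vector of one-letter codes parallel to the
#'   residue numbers (used to fill the `aa` slot of the labels).
#' @return A data.frame with columns `resno`, `domain`, `segment`, `index`,
#'   `label` (formatted universal label).
#' @export
assign_labels <- function(structure, annotation, aa = NULL) {
  annotation <- segment_annotation(annotation)
  if (inherits(structure, "channel_structure")) {
    res <- structure_residues(structure)
    resno <- res$resno
    if (is.null(aa)) aa <- res$aa
  } else {
    resno <- as.integer(structure)
  }
  if (is.null(aa)) aa <- rep(NA_character_, length(resno))
  keep <- !duplicated(resno)
  resno <- resno[keep]; aa <- aa[keep]
  rows <- lapply(seq_along(resno), function(j) {
    r <- resno[j]
    sp <- annotation[annotation$first <= r & annotation$last >= r, , drop = FALSE]
    if (nrow(sp) == 0L) return(NULL)
    sp <- sp[1L, ]
    data.frame(resno = r, domain = sp$domain, segment = sp$segment,
               index = r - sp$anchor + 1L,
               aa = aa[j], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(resno = integer(), domain = integer(), segment = character(),
                      index = integer(), aa = character(), label = character(),
                      stringsAsFactors = FALSE))
  if (any(out$index < 1L))
    stop("annotation anchor yields non-positive universal index", call. = FALSE)
  out$label <- paste0(out$domain, out$segment, out$index)
  if (anyDuplicated(out[c("domain", "segment", "index")]))
    stop("annotation maps two residues to one universal label", call. = FALSE)
  out
}

#' Translate a native position between two aligned reference sequences
#'
#' @param pos A `native_position` in one of the two aligned sequences.
#' @param alignment A pairwise alignment: a named list of two equal-length
#'   gapped sequences (character strings, `-` for gaps), names being the
#'   reference names, together with `start` offsets (first residue number of
#'   each sequence; default 1).
#' @return The equivalent `native_position` in the other sequence.  Aligning
#'   to a gap column is an explicit error, never a silent shift.
#' @export
translate_numbering <- function(pos, alignment) {
  stopifnot(inherits(pos, "native_position"))
  seqs <- alignment$seqs %||% alignment
  if (!is.list(seqs) || length(seqs) != 2L || is.null(names(seqs)))
    stop("alignment must hold two named gapped sequences", call. = FALSE)
  starts <- alignment$start %||% stats::setNames(c(1L, 1L), names(seqs))
  if (!pos$reference %in% names(seqs))
    stop("position reference '", pos$reference, "' is not in the alignment", call. = FALSE)
  other <- setdiff(names(seqs), pos$reference)[1L]
  a <- strsplit(seqs[[pos$reference]], "")[[1L]]
  b <- strsplit(seqs[[other]], "")[[1L]]
  if (length(a) != length(b)) stop("aligned sequences differ in length", call. = FALSE)
  # residue numbers along the gapped source sequence
  na <- cumsum(a != "-") + starts[[pos$reference]] - 1L
  col <- which(a != "-" & na == pos$resnum)
  if (!length(col))
    stop("residue ", pos$resnum, " of ", pos$reference, " is outside the alignment",
         call. = FALSE)
  col <- col[1L]
  if (b[col] == "-")
    stop("no equivalent: residue ", pos$resnum, " of ", pos$reference,
         " aligns to a gap in ", other, call. = FALSE)
  nb <- cumsum(b != "-") + starts[[other]] - 1L
  native_position(other, nb[col])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
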