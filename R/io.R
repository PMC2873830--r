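# File I/O: PDB coordinates (via bio3d's fixed-column parser), xyz output,
# and the distance-list TSV format that serializes a sparse distance set.

#' Read atomic coordinates from a PDB file
#'
#' Parses the file with bio3d's fixed-column reader and applies a selection.
#' The default selection is: first model, ATOM records only, hydrogens
#' included, alternate-location indicator blank or "A".
#'
#' @param path path to a PDB file.
#' @param model 1-based model index for multi-model files.
#' @param hetatm include HETATM records.
#' @param hydrogens include hydrogen atoms (identified by the element
#'   column; atoms with no element symbol are kept).
#' @param altloc alternate-location codes to keep (besides blank).
#' @return A [structure3d()] with atoms in file order and a `labels` data
#'   frame carrying serial number, atom name, residue name/number, chain
#'   and element.
#' @export
read_pdb <- function(path, model = 1L, hetatm = FALSE, hydrogens = TRUE,
                     altloc = "A") {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e)
      stop_geobuild("geobuild_parse_error",
                    sprintf("cannot parse PDB file '%s': %s", path,
                            conditionMessage(e))))
  at <- pdb$atom
  nmodel <- nrow(pdb$xyz)
  if (model < 1L || model > nmodel)
    stop_geobuild("geobuild_parse_error",
                  sprintf("model %d requested but file has %d model(s)",
                          model, nmodel))
  co <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  keep <- at$type == "ATOM" | (hetatm & at$type == "HETATM")
  alt <- at$alt
  keep <- keep & (is.na(alt) | alt == "" | alt %in% altloc)
  if (!hydrogens) {
    ele <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
    keep <- keep & !(ele %in% c("H", "D"))
  }
  if (!any(keep))
    stop_geobuild("geobuild_parse_error", "selection matches no atoms")
  labels <- data.frame(eleno = at$eleno[keep], elety = at$elety[keep],
                       resid = at$resid[keep], chain = at$chain[keep],
                       resno = at$resno[keep], elesy = at$elesy[keep],
                       stringsAsFactors = FALSE)
  structure3d(co[keep, , drop = FALSE], labels = labels)
}

#' Write a reconstructed (or reference) structure to a file
#'
#' Positioned atoms are written in order; unpositioned atoms of a partial
#' reconstruction are omitted with a warning. PDB output uses the standard
#' fixed 8.3 coordinate columns; xyz output keeps 10 decimal places.
#'
#' @param x a [reconstruction_result()] or [structure3d()].
#' @param path output path.
#' @param format `"pdb"` or `"xyz"`.
#' @return The path, invisibly.
#' @export
write_structure <- function(x, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (inherits(x, "recon_result")) {
    if (x$status == "failed")
      stop_geobuild("geobuild_parse_error", "cannot write a failed reconstruction")
    if (!all(x$positioned))
      warning(sprintf("%d unpositioned atom(s) omitted from output",
                      sum(!x$positioned)))
    co <- x$structure$coords[x$positioned, , drop = FALSE]
    labels <- x$structure$labels[x$positioned, , drop = FALSE]
  } else {
    co <- x$coords
    labels <- x$labels
  }
  n <- nrow(co)
  if (format == "xyz") {
    lines <- c(as.character(n), "generated by geobuild",
               sprintf("%s %.10f %.10f %.10f",
                       if (!is.null(labels) && "elesy" %in% names(labels))
                         ifelse(is.na(labels$elesy) | labels$elesy == "",
                                "X", labels$elesy) else rep("X", n),
                       co[, 1], co[, 2], co[, 3]))
    writeLines(lines, path)
  } else {
    elety <- if (!is.null(labels) && "elety" %in% names(labels))
      labels$elety else rep("CA", n)
    resid <- if (!is.null(labels) && "resid" %in% names(labels))
      labels$resid else rep("GLY", n)
    resno <- if (!is.null(labels) && "resno" %in% names(labels))
      labels$resno else seq_len(n)
    bio3d::write.pdb(file = path, xyz = as.vector(t(co)), elety = elety,
                     resid = resid, resno = resno)
  }
  invisible(path)
}

#' Read an xyz coordinate file
#'
#' @param path path to an xyz file (count line, comment line, then
#'   `element x y z` records).
#' @return A [structure3d()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop_geobuild("geobuild_parse_error", "xyz file too short")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || length(lines) < n + 2L)
    stop_geobuild("geobuild_parse_error", "malformed xyz header")
  parts <- strsplit(trimws(lines[3:(n + 2L)]), "\\s+")
  bad <- vapply(parts, length, integer(1)) < 4L
  if (any(bad))
    stop_geobuild("geobuild_parse_error", "malformed xyz record")
  co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(co)))
    stop_geobuild("geobuild_parse_error", "non-numeric xyz coordinates")
  structure3d(co, labels = data.frame(
    elesy = vapply(parts, `[[`, character(1), 1L), stringsAsFactors = FALSE))
}

#' Read and write the distance-list format
#'
#' A plain TSV serialization of a sparse distance set: a header line
#' `#n=<atom count>`, then one line per unordered pair,
#' `i<TAB>j<TAB>distance`, with 1-based atom indices and distances printed
#' with 17 significant digits so the round-trip is exact.
#'
#' @param path file path.
#' @return `read_distance_list` returns a [sparse_distance_set()];
#'   `write_distance_list` returns `path` invisibly.
#' @export
read_distance_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L || !grepl("^#n=\\d+$", lines[1L]))
    stop_geobuild("geobuild_parse_error",
                  "distance list must start with a '#n=<count>' header")
  n <- as.integer(sub("^#n=", "", lines[1L]))
  body <- lines[-1L]
  if (length(body) == 0L)
    return(sparse_distance_set(integer(0), integer(0), numeric(0), n = n))
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(vapply(parts, length, integer(1)) != 3L))
    stop_geobuild("geobuild_parse_error", "each line must be i<TAB>j<TAB>distance")
  i <- as.integer(vapply(parts, `[[`, character(1), 1L))
  j <- as.integer(vapply(parts, `[[`, character(1), 2L))
  d <- as.numeric(vapply(parts, `[[`, character(1), 3L))
  if (any(is.na(i)) || any(is.na(j)) || any(is.na(d)))
    stop_geobuild("geobuild_parse_error", "malformed distance-list record")
  if (any(i == j))
    stop_geobuild("geobuild_parse_error", "self-pair (i == j) in distance list")
  if (any(i < 1L) || any(j < 1L) || any(i > n) || any(j > n))
    stop_geobuild("geobuild_index_error", "atom index out of range")
  sparse_distance_set(i, j, d, n = n)
}

#' @rdname read_distance_list
#' @param dset a [sparse_distance_set()].
#' @export
write_distance_list <- function(dset, path) {
  e <- dset$entries
  writeLines(c(sprintf("#n=%d", dset$n),
               sprintf("%d\t%d\t%.17g", e$i, e$j, e$d)), path)
  invisible(path)
}
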