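#' Read a mesh file (OBJ or STL)
#'
#' OBJ is the canonical interchange format: it is indexed, so vertex order
#' — and with it anatomical correspondence — survives a write/read round
#' trip exactly. STL (ascii or binary, auto-detected) is a triangle soup;
#' on read, vertices are deduplicated by bitwise-equal coordinates in
#' order of first appearance, a deterministic rule that restores the
#' original indexing for meshes this package wrote.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"obj"`, `"stl"` or `NULL` (infer).
#' @param label mesh label; defaults to the file name without extension.
#' @return a [tri_mesh()].
#' @export
read_mesh <- function(path, format = NULL, label = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  if (is.null(label))
    label <- tools::file_path_sans_ext(basename(path))
  switch(format,
         obj = .read_obj(path, label),
         stl = .read_stl(path, label),
         stop(sprintf("unsupported mesh format '%s'", format)))
}

#' Write a mesh file (OBJ or STL)
#'
#' OBJ vertices are written with 17 significant digits so that reading the
#' file back reproduces the coordinates bit-exact. Binary STL stores
#' float32 and is provided for scanner-toolchain compatibility only.
#'
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @param format `"obj"`, `"stl"` (binary) , `"stl-ascii"`, or `NULL`
#'   (infer from extension; `.stl` means binary).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         obj = .write_obj(mesh, path),
         stl = .write_stl_binary(mesh, path),
         `stl-ascii` = .write_stl_ascii(mesh, path),
         stop(sprintf("unsupported mesh format '%s'", format)))
  invisible(path)
}

.write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hingefit OBJ (mm); orientation: Forward -Z, Up Y"),
             con)
  writeLines(sprintf("v %.17g %.17g %.17g",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  if (nrow(mesh$faces) > 0L)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
}

.read_obj <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L) stop(sprintf("malformed OBJ '%s': no vertices", path))
  V <- matrix(as.numeric(unlist(strsplit(trimws(sub("^v ", "", vl)),
                                         "[[:space:]]+"))),
              ncol = 3, byrow = TRUE)
  if (length(fl) > 0L) {
    toks <- strsplit(trimws(sub("^f ", "", fl)), "[[:space:]]+")
    F <- t(vapply(toks, function(tk)
      as.integer(sub("/.*$", "", tk[1:3])), integer(3)))
  } else F <- matrix(integer(0), 0, 3)
  tri_mesh(V, F, label = label)
}

.write_stl_ascii <- function(mesh, path) {
  if (nrow(mesh$faces) == 0L) stop("STL requires faces")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$label), con)
  for (k in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[k, ], , drop = FALSE]
    n <- .face_normal(tri)
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.17g %.17g %.17g",
                         tri[, 1], tri[, 2], tri[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", mesh$label), con)
}

.write_stl_binary <- function(mesh, path) {
  if (nrow(mesh$faces) == 0L) stop("STL requires faces")
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("hingefit binary STL (mm)", width = -80))
  writeBin(header[1:80], con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "little")
  for (k in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[k, ], , drop = FALSE]
    n <- .face_normal(tri)
    writeBin(as.numeric(c(n, t(tri))), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
}

.face_normal <- function(tri) {
  a <- tri[2, ] - tri[1, ]; b <- tri[3, ] - tri[1, ]
  n <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  ln <- sqrt(sum(n^2))
  if (ln < 1e-30) c(0, 0, 0) else n / ln
}

.read_stl <- function(path, label) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  is_ascii <- identical(rawToChar(head[1:5]), "solid")
  if (is_ascii) {
    # a binary file could begin with 'solid'; check the facet count
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    sz <- file.size(path)
    if (length(ntri) == 1 && !is.na(ntri) && sz == 84 + 50 * ntri)
      is_ascii <- FALSE
  }
  close(con)
  tris <- if (is_ascii) .read_stl_ascii_tris(path) else .read_stl_binary_tris(path)
  # deduplicate by bitwise-equal coordinates, order of first appearance
  key <- apply(tris, 1, function(r) paste(sprintf("%a", r), collapse = "|"))
  first <- !duplicated(key)
  V <- tris[first, , drop = FALSE]
  idx <- match(key, key[first])
  F <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_mesh(V, F, label = label)
}

.read_stl_ascii_tris <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^[[:space:]]*vertex", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop(sprintf("malformed ascii STL '%s'", path))
  matrix(as.numeric(unlist(strsplit(trimws(sub("^[[:space:]]*vertex", "", vl)),
                                    "[[:space:]]+"))),
         ncol = 3, byrow = TRUE)
}

.read_stl_binary_tris <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  out <- matrix(0, 3 * ntri, 3)
  for (k in seq_len(ntri)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "raw", 2)
    out[(3 * k - 2):(3 * k), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  out
}

#' Write axes to CSV
#'
#' One axis per record: `label`, `source`, start/end coordinates in mm and
#' the label of the reference mesh the axis was canonicalized against.
#'
#' @param axes list of [axis_line()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_axes_csv <- function(axes, path) {
  df <- do.call(rbind, lapply(axes, function(a) data.frame(
    label = a$label, source = a$source,
    start_x = a$start[1], start_y = a$start[2], start_z = a$start[3],
    end_x = a$end[1], end_y = a$end[2], end_z = a$end[3],
    reference = a$reference, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read axes from CSV
#'
#' Records whose endpoint separation deviates from the canonical 200 mm by
#' more than `tol_200` are rejected with an explicit error (non-canonical
#' published rows are flagged, never silently renormalized). Set
#' `require_canonical = FALSE` to load raw segments.
#'
#' @param path CSV path as written by [write_axes_csv()].
#' @param require_canonical enforce the 200 mm parameterization (default
#'   TRUE).
#' @param tol_200 allowed deviation from 200 mm (default 0.1).
#' @return list of [axis_line()] objects (canonicalization metadata
#'   restored from the `reference` column when present).
#' @export
read_axes_csv <- function(path, require_canonical = TRUE, tol_200 = 0.1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "source", "start_x", "start_y", "start_z",
            "end_x", "end_y", "end_z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("axis CSV '%s' missing fields: %s", path,
                 paste(miss, collapse = ", ")))
  lapply(seq_len(nrow(df)), function(i) {
    st <- as.numeric(df[i, c("start_x", "start_y", "start_z")])
    en <- as.numeric(df[i, c("end_x", "end_y", "end_z")])
    len <- sqrt(sum((en - st)^2))
    if (require_canonical && abs(len - 200) > tol_200)
      stop(sprintf("axis '%s': endpoint separation %.3f mm deviates from the canonical 200 mm",
                   df$label[i], len))
    a <- axis_line(st, en, source = df$source[i], label = df$label[i])
    if (!is.null(df$reference) && !is.na(df$reference[i])) {
      a$canonical <- require_canonical
      a$reference <- df$reference[i]
    }
    a
  })
}

#' Export an axis cloud as an OBJ line scene
#'
#' Writes each axis as a two-vertex line element, in the "Forward: -Z,
#' Up: Y" orientation convention, for inspection in any 3D viewer.
#'
#' @param axes list of [axis_line()] objects.
#' @param path output `.obj` path.
#' @return `path`, invisibly.
#' @export
write_axes_obj <- function(axes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# hingefit axis cloud (mm); orientation: Forward -Z, Up Y", con)
  for (k in seq_along(axes)) {
    a <- axes[[k]]
    writeLines(c(sprintf("o %s", if (nzchar(a$label)) a$label else paste0("axis_", k)),
                 sprintf("v %.17g %.17g %.17g", a$start[1], a$start[2], a$start[3]),
                 sprintf("v %.17g %.17g %.17g", a$end[1], a$end[2], a$end[3]),
                 sprintf("l %d %d", 2 * k - 1, 2 * k)), con)
  }
  invisible(path)
}

#' Load a supplementary results table exported to CSV
#'
#' Schema-tolerant ingestion of published result workbooks (deviation
#' sheets and axis-coordinate sheets) after export to CSV. Column names
#' are matched case-insensitively through an explicit `mapping`; schema
#' mismatches are reported field by field.
#'
#' @param path CSV path.
#' @param type `"deviation"` (pair label + deviation value columns) or
#'   `"axes"` (label, source and six endpoint coordinates).
#' @param mapping named character vector mapping required fields to column
#'   names in the file; defaults assume the package's own export names.
#' @return a `data.frame` of typed records; for `type = "axes"` also an
#'   `axes` attribute holding [axis_line()] objects.
#' @export
load_supplement <- function(path, type = c("deviation", "axes"),
                            mapping = NULL) {
  type <- match.arg(type)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop(sprintf("supplement '%s' is empty", path))
  need <- switch(type,
    deviation = c(pair = "pair", value = "value"),
    axes = c(label = "label", source = "source",
             start_x = "start_x", start_y = "start_y", start_z = "start_z",
             end_x = "end_x", end_y = "end_y", end_z = "end_z"))
  if (!is.null(mapping)) need[names(mapping)] <- mapping
  lw <- tolower(names(df))
  pos <- match(tolower(need), lw)
  if (anyNA(pos)) {
    bad <- need[is.na(pos)]
    stop(sprintf("supplement '%s' schema mismatch; missing columns: %s",
                 path, paste(sprintf("%s (-> %s)", names(bad), bad),
                             collapse = ", ")))
  }
  out <- df[, pos, drop = FALSE]
  names(out) <- names(need)
  if (type == "deviation") {
    out$value <- as.numeric(out$value)
    if (anyNA(out$value))
      stop(sprintf("supplement '%s': non-numeric deviation values", path))
  } else {
    num <- c("start_x", "start_y", "start_z", "end_x", "end_y", "end_z")
    for (cc in num) out[[cc]] <- as.numeric(out[[cc]])
    if (anyNA(out[num]))
      stop(sprintf("supplement '%s': non-numeric axis coordinates", path))
    attr(out, "axes") <- lapply(seq_len(nrow(out)), function(i)
      axis_line(unlist(out[i, c("start_x", "start_y", "start_z")]),
                unlist(out[i, c("end_x", "end_y", "end_z")]),
                source = out$source[i], label = out$label[i]))
  }
  out
}

#' Serialize a synthetic scan session to a directory
#'
#' Writes the twelve scans as order-preserving OBJ files, the reference
#' and truth axes as CSV, the scenario (including the seed) as JSON, and a
#' manifest with MD5 checksums so a rerun can be verified byte for byte.
#'
#' @param session a `scan_session` from [make_session()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (lab in names(session$scans)) {
    f <- file.path(dir, paste0(lab, ".obj"))
    write_mesh(session$scans[[lab]], f)
    files <- c(files, f)
  }
  f <- file.path(dir, "base.obj")
  write_mesh(session$base_mesh, f); files <- c(files, f)
  f <- file.path(dir, "axes.csv")
  write_axes_csv(c(list(session$truth_axis), session$modjaw_axes), f)
  files <- c(files, f)
  f <- file.path(dir, "scenario.json")
  jsonlite::write_json(unclass(session$scenario), f, auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, f)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
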