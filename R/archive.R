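# OMEX (COMBINE archive) input/output and file hygiene.
#
# An archive is a list of entries (location, format URI, master flag, raw
# content) plus a flag recording whether a manifest was present on disk.
# Legacy entries without a manifest are tolerated: formats are then inferred
# from extension and, for .xml, by sniffing the root element.

FMT_SBML     <- "http://identifiers.org/combine.specifications/sbml"
FMT_SEDML    <- "http://identifiers.org/combine.specifications/sed-ml"
FMT_MANIFEST <- "http://identifiers.org/combine.specifications/omex-manifest"
FMT_BINARY   <- "http://purl.org/NET/mediatypes/application/octet-stream"

#' Create an archive entry
#'
#' @param location relative path inside the archive ('/' separators, no
#'   leading '/').
#' @param content raw vector (file bytes) or a character scalar which is
#'   UTF-8 encoded.
#' @param format COMBINE format identifier URI; inferred from the content
#'   and extension when `NULL`.
#' @param is_master logical; marks the archive's master file in the manifest.
#' @return an object of class `omex_entry`.
#' @export
archive_entry <- function(location, content, format = NULL, is_master = FALSE) {
  if (!is.character(location) || length(location) != 1L || !nzchar(location))
    stop("entry location must be a non-empty string", call. = FALSE)
  if (startsWith(location, "/"))
    stop("entry location must not start with '/': ", location, call. = FALSE)
  if (is.character(content)) content <- charToRaw(paste(content, collapse = "\n"))
  stopifnot(is.raw(content))
  if (is.null(format)) format <- infer_format(location, content)
  structure(list(location = location, format = format,
                 is_master = isTRUE(is_master), content = content),
            class = "omex_entry")
}

#' Create an in-memory OMEX archive
#'
#' @param entries list of [archive_entry()] objects (the manifest itself is
#'   never stored as an entry; it is regenerated on write).
#' @param manifest_present logical, whether a manifest was present when read.
#' @return an object of class `omex_archive`.
#' @export
new_archive <- function(entries, manifest_present = TRUE) {
  stopifnot(is.list(entries))
  locs <- vapply(entries, function(e) e$location, "")
  if (anyDuplicated(locs))
    stop("duplicate entry locations: ",
         paste(unique(locs[duplicated(locs)]), collapse = ", "), call. = FALSE)
  n_master <- sum(vapply(entries, function(e) isTRUE(e$is_master), TRUE))
  if (n_master > 1L)
    stop("at most one entry may be flagged master", call. = FALSE)
  structure(list(entries = entries, manifest_present = isTRUE(manifest_present)),
            class = "omex_archive")
}

#' @export
print.omex_archive <- function(x, ...) {
  cat("<omex_archive> ", length(x$entries), " entries",
      if (!x$manifest_present) " (no manifest on read)", "\n", sep = "")
  for (e in x$entries)
    cat(sprintf("  %-30s %6d B  %s%s\n", e$location, length(e$content),
                short_format(e$format), if (e$is_master) "  [master]" else ""))
  invisible(x)
}

short_format <- function(uri) {
  if (grepl("sed-?ml", uri)) "SED-ML"
  else if (grepl("specifications/sbml", uri)) "SBML"
  else if (grepl("omex-manifest", uri)) "manifest"
  else "other"
}

format_is_sbml  <- function(uri) grepl("specifications/sbml", uri, fixed = FALSE)
format_is_sedml <- function(uri) grepl("specifications/sed-?ml", uri)

archive_locations <- function(archive) {
  vapply(archive$entries, function(e) e$location, "")
}

archive_get <- function(archive, location) {
  for (e in archive$entries) if (e$location == location) return(e)
  NULL
}

archive_set <- function(archive, entry) {
  locs <- archive_locations(archive)
  i <- match(entry$location, locs)
  if (is.na(i)) archive$entries[[length(archive$entries) + 1L]] <- entry
  else archive$entries[[i]] <- entry
  archive
}

sniff_root <- function(content) {
  doc <- tryCatch(xml2::read_xml(content), error = function(e) NULL)
  if (is.null(doc)) return(NA_character_)
  xml2::xml_name(xml2::xml_root(doc))
}

infer_format <- function(location, content) {
  ext <- tolower(tools::file_ext(location))
  if (ext == "sedml") return(FMT_SEDML)
  if (ext %in% c("xml", "sbml")) {
    root <- sniff_root(content)
    if (identical(root, "sbml")) return(FMT_SBML)
    if (identical(root, "sedML")) return(FMT_SEDML)
    if (identical(root, "omexManifest")) return(FMT_MANIFEST)
  }
  FMT_BINARY
}

parse_manifest <- function(content) {
  doc <- xml2::read_xml(content)
  xml2::xml_ns_strip(doc)
  contents <- xml2::xml_find_all(doc, ".//content")
  data.frame(
    location = sub("^\\./", "", xml2::xml_attr(contents, "location")),
    format = xml2::xml_attr(contents, "format"),
    master = tolower(xml2::xml_attr(contents, "master")) %in% "true",
    stringsAsFactors = FALSE
  )
}

build_manifest <- function(archive) {
  doc <- xml2::xml_new_root(
    "omexManifest",
    xmlns = "http://identifiers.org/combine.specifications/omex-manifest")
  xml2::xml_add_child(doc, "content", location = "./manifest.xml",
                      format = FMT_MANIFEST)
  for (e in archive$entries) {
    node <- xml2::xml_add_child(doc, "content",
                                location = paste0("./", e$location),
                                format = e$format)
    if (isTRUE(e$is_master)) xml2::xml_set_attr(node, "master", "true")
  }
  charToRaw(as.character(doc))
}

#' Read an OMEX archive (or bare SBML/SED-ML file)
#'
#' ZIP containers are unpacked into entries; a `manifest.xml` at the root is
#' consumed (formats and master flags taken from it) and `manifest_present`
#' set accordingly. A bare SBML or SED-ML file is wrapped as a one-entry
#' archive for convenience.
#'
#' @param path path to an OMEX/ZIP file or a single SBML/SED-ML file.
#' @return an `omex_archive`.
#' @export
read_archive <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!is_zip_file(path)) {
    content <- readBin(path, "raw", n = file.size(path))
    fmt <- infer_format(basename(path), content)
    if (identical(fmt, FMT_BINARY))
      stop("archive error: ", path,
           " is neither a ZIP container nor an SBML/SED-ML file", call. = FALSE)
    return(new_archive(list(archive_entry(basename(path), content, fmt)),
                       manifest_present = FALSE))
  }
  members <- zip_read(path)
  mi <- match("manifest.xml", names(members))
  manifest_present <- !is.na(mi)
  man <- NULL
  if (manifest_present) {
    man <- parse_manifest(members[[mi]])
    members <- members[-mi]
    man <- man[!(man$location %in% c("manifest.xml", ".")), , drop = FALSE]
    missing <- setdiff(man$location, names(members))
    if (length(missing))
      stop("archive error: manifest references absent files: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!length(members)) stop("archive error: empty ZIP container", call. = FALSE)
  entries <- vector("list", length(members))
  for (i in seq_along(members)) {
    loc <- names(members)[i]
    fmt <- NULL; master <- FALSE
    if (!is.null(man)) {
      j <- match(loc, man$location)
      if (!is.na(j)) { fmt <- man$format[j]; master <- man$master[j] }
    }
    entries[[i]] <- archive_entry(loc, members[[i]], format = fmt,
                                  is_master = master)
  }
  new_archive(entries, manifest_present = manifest_present)
}

#' Write an OMEX archive
#'
#' The manifest is regenerated from the entry list so that
#' `read_archive(write_archive(a))` is semantically equal to `a`.
#'
#' @param archive an `omex_archive`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_archive <- function(archive, path) {
  stopifnot(inherits(archive, "omex_archive"))
  # re-validate invariants before touching the filesystem
  archive <- new_archive(archive$entries, archive$manifest_present)
  files <- list(manifest.xml = build_manifest(archive))
  for (e in archive$entries) files[[e$location]] <- e$content
  zip_write(path, files)
  invisible(path)
}

#' Scan an archive for file-hygiene defects
#'
#' Flags zero-length entries, filenames containing characters outside
#' `[A-Za-z0-9._-]`, and SED-ML content not carrying the `.sedml` extension.
#'
#' @param archive an `omex_archive`.
#' @return a data.frame with columns `location`, `kind`, `suggested_fix`.
#' @export
hygiene_scan <- function(archive) {
  issues <- list()
  add <- function(location, kind, fix = NA_character_)
    issues[[length(issues) + 1L]] <<- data.frame(
      location = location, kind = kind, suggested_fix = fix,
      stringsAsFactors = FALSE)
  for (e in archive$entries) {
    if (length(e$content) == 0L) add(e$location, "zero_length")
    base <- basename(e$location)
    if (grepl("[^A-Za-z0-9._-]", base)) {
      add(e$location, "illegal_chars",
          file.path_drop_dot(dirname(e$location),
                             gsub("[^A-Za-z0-9._-]", "_", base)))
    }
    if (format_is_sedml(e$format) && !grepl("\\.sedml$", e$location)) {
      add(e$location, "nonstandard_extension",
          paste0(tools::file_path_sans_ext(e$location), ".sedml"))
    }
  }
  if (!length(issues))
    return(data.frame(location = character(), kind = character(),
                      suggested_fix = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, issues)
  out[order(out$location, out$kind), , drop = FALSE]
}

file.path_drop_dot <- function(dir, base) {
  if (dir == ".") base else file.path(dir, base)
}

#' Normalize archive filenames
#'
#' Applies the fixes suggested by [hygiene_scan()]: zero-length entries are
#' removed, illegal characters replaced by `_`, SED-ML files renamed to
#' `.sedml`. Internal references (SED-ML model `source` attributes) are
#' rewritten to the new names. Idempotent.
#'
#' @param archive an `omex_archive`.
#' @return list with elements `archive` (the normalized archive) and
#'   `renames` (data.frame old/new).
#' @export
normalize_filenames <- function(archive) {
  issues <- hygiene_scan(archive)
  renames <- data.frame(old = character(), new = character(),
                        stringsAsFactors = FALSE)
  drop <- issues$location[issues$kind == "zero_length"]
  mapping <- character(0)
  for (i in seq_len(nrow(issues))) {
    if (issues$kind[i] == "zero_length") next
    old <- issues$location[i]
    new <- issues$suggested_fix[i]
    # chain fixes when one file has several issues
    if (old %in% names(mapping)) {
      prev <- mapping[[old]]
      new <- if (issues$kind[i] == "nonstandard_extension")
        paste0(tools::file_path_sans_ext(prev), ".sedml")
      else file.path_drop_dot(dirname(prev),
                              gsub("[^A-Za-z0-9._-]", "_", basename(prev)))
    }
    mapping[old] <- new
  }
  if (length(mapping)) {
    keep_locs <- setdiff(archive_locations(archive), drop)
    finals <- ifelse(keep_locs %in% names(mapping),
                     mapping[keep_locs], keep_locs)
    if (anyDuplicated(finals)) {
      dup <- finals[duplicated(finals)][1L]
      srcs <- keep_locs[finals == dup]
      stop("rename collision: ", paste(srcs, collapse = " and "),
           " both normalize to ", dup, call. = FALSE)
    }
  }
  entries <- list()
  for (e in archive$entries) {
    if (e$location %in% drop) next
    old <- e$location
    if (old %in% names(mapping)) {
      e$location <- mapping[[old]]
      renames <- rbind(renames, data.frame(old = old, new = e$location,
                                           stringsAsFactors = FALSE))
    }
    entries[[length(entries) + 1L]] <- e
  }
  out <- new_archive(entries, archive$manifest_present)
  # rewrite SED-ML model sources that named a renamed or removed file
  if (nrow(renames)) {
    for (i in seq_along(out$entries)) {
      e <- out$entries[[i]]
      if (!format_is_sedml(e$format)) next
      doc <- tryCatch(parse_sedml(e$content), error = function(err) NULL)
      if (is.null(doc)) next
      touched <- FALSE
      for (j in seq_along(doc$models)) {
        src <- sub("^\\./", "", doc$models[[j]]$source)
        k <- match(src, renames$old)
        if (!is.na(k)) { doc$models[[j]]$source <- renames$new[k]; touched <- TRUE }
      }
      if (touched) {
        e$content <- write_sedml(doc)
        out$entries[[i]] <- e
      }
    }
  }
  list(archive = out, renames = renames)
}
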