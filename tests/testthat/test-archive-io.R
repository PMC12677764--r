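test_that("archives round-trip through ZIP with a regenerated manifest", {
  a <- fx("decay1")
  tf <- withr::local_tempfile(fileext = ".omex")
  write_archive(a, tf)
  b <- read_archive(tf)
  expect_true(b$manifest_present)
  expect_setequal(vapply(b$entries, `[[`, "", "location"),
                  vapply(a$entries, `[[`, "", "location"))
  for (e in a$entries) {
    got <- archive_get(b, e$location)
    expect_identical(got$content, e$content)
    expect_identical(got$format, e$format)
  }
  # master flag is recorded in the manifest and survives the round trip
  master_locs <- function(x) vapply(Filter(function(e) e$is_master,
                                           x$entries), `[[`, "", "location")
  expect_identical(master_locs(b), master_locs(a))
})

test_that("a ZIP without manifest is tolerated with formats inferred", {
  a <- fx("decay1")
  tf <- withr::local_tempfile(fileext = ".zip")
  files <- list()
  for (e in a$entries) files[[e$location]] <- e$content
  sedverify:::zip_write(tf, files)
  b <- read_archive(tf)
  expect_false(b$manifest_present)
  sed <- Filter(function(e) grepl("sedml$", e$location), b$entries)[[1]]
  expect_match(sed$format, "sed-ml")
  sb <- Filter(function(e) grepl("xml$", e$location), b$entries)[[1]]
  expect_match(sb$format, "specifications/sbml")
})

test_that("bare SBML files are wrapped as one-entry archives", {
  a <- fx("decay1")
  tf <- withr::local_tempfile(fileext = ".xml")
  writeBin(sedverify:::find_sbml_entries(a)[[1]]$content, tf)
  b <- read_archive(tf)
  expect_length(b$entries, 1L)
  expect_false(b$manifest_present)
  expect_match(b$entries[[1]]$format, "specifications/sbml")
})

test_that("degenerate containers are rejected", {
  tf <- withr::local_tempfile(fileext = ".zip")
  con <- file(tf, "wb")
  # an EOCD-only (empty) ZIP
  writeBin(c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), raw(18)), con)
  close(con)
  expect_error(read_archive(tf), "empty|unreadable")
  expect_error(read_archive(tempfile()), "no such file")
  expect_error(new_archive(list(archive_entry("a.xml", "x"),
                                archive_entry("a.xml", "y"))),
               "duplicate entry locations")
})

test_that("a manifest referencing absent files is an archive error", {
  tf <- withr::local_tempfile(fileext = ".omex")
  manifest <- paste0(
    '<omexManifest xmlns="http://identifiers.org/combine.specifications/omex-manifest">',
    '<content location="./present.xml" format="http://identifiers.org/combine.specifications/sbml"/>',
    '<content location="./ghost.xml" format="http://identifiers.org/combine.specifications/sbml"/>',
    '</omexManifest>')
  sedverify:::zip_write(tf, list(
    manifest.xml = charToRaw(manifest),
    present.xml = charToRaw("<sbml/>")))
  expect_error(read_archive(tf), "ghost\\.xml")
})

test_that("hygiene_scan flags zero-length, misnamed and illegal entries", {
  sed_bytes <- sedverify:::find_sedml_entry(fx("decay1"))$content
  a <- new_archive(list(
    archive_entry("exp.xml", sed_bytes,
                  "http://identifiers.org/combine.specifications/sed-ml"),
    archive_entry("empty.dat", raw(0)),
    archive_entry("bad name!.txt", "x")))
  issues <- hygiene_scan(a)
  expect_setequal(issues$kind,
                  c("nonstandard_extension", "zero_length", "illegal_chars"))
  expect_identical(issues$suggested_fix[issues$kind == "nonstandard_extension"],
                   "exp.sedml")
  expect_identical(nrow(hygiene_scan(fx("decay1"))), 0L)
})

test_that("normalize_filenames applies fixes, rewrites references, and is idempotent", {
  a <- fx("decay1")
  sed <- sedverify:::find_sedml_entry(a)
  sbml <- sedverify:::find_sbml_entries(a)[[1]]
  doc <- parse_sedml(sed$content)
  doc$models[[1]]$source <- "model one.xml"   # illegal space
  messy <- new_archive(list(
    archive_entry("model one.xml", sbml$content, sbml$format),
    archive_entry("exp.xml", write_sedml(doc),
                  "http://identifiers.org/combine.specifications/sed-ml"),
    archive_entry("junk.dat", raw(0))))
  res <- normalize_filenames(messy)
  locs <- vapply(res$archive$entries, `[[`, "", "location")
  expect_setequal(locs, c("model_one.xml", "exp.sedml"))
  doc2 <- parse_sedml(archive_get(res$archive, "exp.sedml")$content)
  expect_identical(doc2$models[[1]]$source, "model_one.xml")
  expect_identical(nrow(hygiene_scan(res$archive)), 0L)
  # idempotent
  res2 <- normalize_filenames(res$archive)
  expect_identical(nrow(res2$renames), 0L)
  expect_length(res2$archive$entries, 2L)
})

test_that("rename collisions are reported with both sources", {
  sed_bytes <- sedverify:::find_sedml_entry(fx("decay1"))$content
  a <- new_archive(list(
    archive_entry("a.xml", sed_bytes,
                  "http://identifiers.org/combine.specifications/sed-ml"),
    archive_entry("a.sedml", sed_bytes,
                  "http://identifiers.org/combine.specifications/sed-ml")))
  expect_error(normalize_filenames(a), "collision.*a\\.xml.*a\\.sedml")
})
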