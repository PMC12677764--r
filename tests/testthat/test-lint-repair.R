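CORRUPT_RULES <- paste0("R", c(1:8, 10))

test_that("lint detects exactly the injected rule and nothing on clean archives", {
  for (nm in c("decay2", "net")) {
    x <- fx(nm)
    expect_identical(nrow(lint(x)), 0L)   # specificity
    for (r in CORRUPT_RULES) {
      issues <- lint(corrupt_archive(x, r))
      expect_identical(unique(issues$rule_id), r)  # sensitivity
      expect_gte(nrow(issues), 1L)
    }
  }
})

test_that("repair fixes every repairable defect and is idempotent", {
  x <- fx("decay2")
  for (r in CORRUPT_RULES) {
    pol <- repair_policy(clamp_points = identical(r, "R7"))
    res <- repair(corrupt_archive(x, r), pol)
    expect_gte(nrow(res$actions), 1L)
    expect_true(all(res$actions$rule_id == r))
    after <- lint(res$archive, pol)
    expect_identical(nrow(after[after$repairable, ]), 0L)
    again <- repair(res$archive, pol)
    expect_identical(nrow(again$actions), 0L)
  }
  # clean archive: repair is the identity with an empty action list
  res0 <- repair(x)
  expect_identical(nrow(res0$actions), 0L)
})

test_that("semantics-preserving repairs leave execution output bit-identical", {
  x <- fx("decay2")
  baseline <- execute_experiment(x, "rk")
  expect_identical(baseline$status, "succeeded")
  for (r in c("R1", "R4", "R5", "R10")) {
    repaired <- repair(corrupt_archive(x, r))$archive
    res <- execute_experiment(repaired, "rk")
    expect_identical(res$reports, baseline$reports)
    expect_identical(res$column_labels, baseline$column_labels)
  }
})

test_that("model sources resolve trivially with one SBML file and by coverage with two", {
  x <- fx("decay2")
  ca <- corrupt_archive(x, "R1")
  doc <- fixture_doc(ca)
  res <- resolve_model_source(doc, ca)
  expect_identical(res$map$model1, "decay_chain_2.xml")

  # two candidates: only one contains the species the document references
  other <- sedverify:::find_sbml_entries(fx("osc"))[[1]]
  two <- sedverify:::archive_set(ca, archive_entry("other_model.xml",
                                                   other$content,
                                                   other$format))
  res2 <- resolve_model_source(fixture_doc(two), two)
  expect_identical(res2$map$model1, "decay_chain_2.xml")
  # coverage oracle: exhaustive id intersection must agree with the scores
  doc_ids <- c("X0", "X1", "X2")
  info_a <- parse_sbml_info(archive_get(two, "decay_chain_2.xml")$content)
  info_b <- parse_sbml_info(archive_get(two, "other_model.xml")$content)
  cov_a <- mean(doc_ids %in% sedverify:::sbml_ids(info_a))
  cov_b <- mean(doc_ids %in% sedverify:::sbml_ids(info_b))
  expect_gt(cov_a, cov_b)
  sc <- res2$scores
  expect_equal(sc$coverage[sc$candidate == "decay_chain_2.xml"], cov_a)
  expect_equal(sc$coverage[sc$candidate == "other_model.xml"], cov_b)

  # two identical candidates with equally distant names: unresolvable tie
  sbml_bytes <- archive_get(ca, "decay_chain_2.xml")$content
  tie <- new_archive(list(
    archive_entry("candidate_a.xml", sbml_bytes, sedverify:::FMT_SBML),
    archive_entry("candidate_b.xml", sbml_bytes, sedverify:::FMT_SBML),
    sedverify:::find_sedml_entry(ca)))
  res3 <- resolve_model_source(fixture_doc(tie), tie)
  expect_true(is.na(res3$map$model1))
  expect_match(res3$note, "tie")
})

test_that("fix_targets canonicalizes resolvable pointers and prunes dead content", {
  x <- fx("decay2")
  doc <- fixture_doc(x)
  info <- fixture_info(x)
  # no-op on an all-canonical document
  clean <- fix_targets(doc, info)
  expect_identical(nrow(clean$actions), 0L)

  doc$data_generators[[2]]$variables[[1]]$target <-
    "/sbml/model/listOfSpecies/species[@id='X0']"
  res <- fix_targets(doc, info)
  expect_identical(res$actions$rule_id, "R5")
  expect_identical(
    res$doc$data_generators[[2]]$variables[[1]]$target,
    "/sbml:sbml/sbml:model/sbml:listOfSpecies/sbml:species[@id='X0']")

  doc2 <- fixture_doc(x)
  doc2$data_generators[[2]]$variables[[1]]$target <-
    "/sbml:sbml/sbml:model/sbml:listOfSpecies/sbml:species[@id='S99']"
  res2 <- fix_targets(doc2, info)
  expect_identical(res2$actions$rule_id, "R2")
  ids <- vapply(res2$doc$data_generators, `[[`, "", "id")
  expect_false("dg_X0" %in% ids)
  report <- Filter(function(o) o$kind == "report", res2$doc$outputs)[[1]]
  expect_false("dg_X0" %in% vapply(report$datasets, `[[`, "", "data_ref"))
  plot <- Filter(function(o) o$kind == "plot2d", res2$doc$outputs)[[1]]
  expect_false("dg_X0" %in% vapply(plot$curves, `[[`, "", "y_ref"))
})

test_that("clamp_output_points warns by default and clamps only when opted in", {
  doc <- fixture_doc(fx("decay1"))
  doc$simulations[[1]]$number_of_points <- 2e6
  off <- clamp_output_points(doc, repair_policy())
  expect_identical(off$issues$rule_id, "R7")
  expect_equal(off$doc$simulations[[1]]$number_of_points, 2e6)
  on <- clamp_output_points(doc, repair_policy(clamp_points = TRUE))
  expect_identical(on$actions$rule_id, "R7")
  expect_equal(on$doc$simulations[[1]]$number_of_points, 10000)
  # within the cap: nothing happens
  doc$simulations[[1]]$number_of_points <- 100
  none <- clamp_output_points(doc, repair_policy(clamp_points = TRUE))
  expect_identical(nrow(none$actions), 0L)
  expect_identical(nrow(none$issues), 0L)
})

test_that("R7-corrupted archives become runnable again after clamping", {
  ca <- corrupt_archive(fx("decay1"), "R7")
  rp <- repair(ca, repair_policy(clamp_points = TRUE))
  res <- execute_experiment(rp$archive, "rk")
  expect_identical(res$status, "succeeded")
  expect_identical(nrow(res$reports$report1), 10001L)
})

test_that("unused non-finite parameters are zeroed; referenced ones stay put", {
  xml <- sub("</listOfParameters>",
             '<parameter id="ghost" value="INF" constant="true"/></listOfParameters>',
             sbml_with(simple_reaction))
  info <- parse_sbml_info(xml)
  fixed <- fix_nonfinite_params(info, charToRaw(xml))
  expect_identical(fixed$actions$rule_id, "R8")
  info2 <- parse_sbml_info(fixed$sbml)
  ghost <- Filter(function(p) p$id == "ghost", info2$parameters)[[1]]
  expect_identical(ghost$value, 0)

  # referenced: k is used by the kinetic law, so a non-finite k is untouched
  xml_used <- sub('id="k" value="0.5"', 'id="k" value="NaN"',
                  sbml_with(simple_reaction))
  info3 <- parse_sbml_info(xml_used)
  res3 <- fix_nonfinite_params(info3, charToRaw(xml_used))
  expect_identical(nrow(res3$actions), 0L)
  expect_identical(res3$sbml, charToRaw(xml_used))

  # all-finite model: identity
  ok <- fix_nonfinite_params(info2, fixed$sbml)
  expect_identical(nrow(ok$actions), 0L)
})

test_that("URN annotations rewrite to identifiers.org URLs with percent-decoding", {
  mk <- function(urn) charToRaw(sprintf(
    '<sbml><annotation><rdf:li rdf:resource="%s"/></annotation></sbml>', urn))
  res <- urn_to_url(mk("urn:miriam:pubmed:12345"))
  expect_match(rawToChar(res$sbml), "https://identifiers.org/pubmed:12345",
               fixed = TRUE)
  res2 <- urn_to_url(mk("urn:miriam:obo.go:GO%3A0006915"))
  expect_match(rawToChar(res2$sbml), "https://identifiers.org/GO:0006915",
               fixed = TRUE)
  # URL-form resources are untouched
  url <- mk("https://identifiers.org/GO:0006915")
  res3 <- urn_to_url(url)
  expect_identical(res3$sbml, url)
  expect_identical(nrow(res3$actions), 0L)
})

test_that("inconsistent simulation settings split into repairable and fatal", {
  x <- fx("decay1")
  doc <- fixture_doc(x)
  doc$simulations[[1]]$output_end_time <- -5   # end < start: unrepairable
  e <- sedverify:::find_sedml_entry(x)
  e$content <- write_sedml(doc)
  broken <- sedverify:::archive_set(x, e)
  issues <- lint(broken)
  expect_identical(issues$rule_id, "R6")
  expect_false(any(issues$repairable))
  rp <- repair(broken)
  expect_identical(nrow(rp$actions), 0L)
  expect_identical(lint(rp$archive)$rule_id, "R6")
})

test_that("zero-length entries are removed by repair via the hygiene rule", {
  x <- sedverify:::archive_set(fx("decay1"),
                               archive_entry("empty.txt", raw(0)))
  issues <- lint(x)
  expect_identical(issues$rule_id, "R9")
  rp <- repair(x)
  expect_identical(rp$actions$rule_id, "R9")
  expect_false("empty.txt" %in%
                 vapply(rp$archive$entries, `[[`, "", "location"))
  expect_identical(nrow(lint(rp$archive)), 0L)
})
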