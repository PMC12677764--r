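test_that("atol_vector scales by initial values with a floor at the factor", {
  s <- tolerance_settings(atol_factor = 1e-12)
  expect_equal(atol_vector(s, c(2, 0.5, 0)), c(2e-12, 5e-13, 1e-12))
  expect_equal(atol_vector(s, c(1, 1, 1)), rep(1e-12, 3))
  expect_equal(atol_vector(s, c(-2, 0)), c(2e-12, 1e-12))
  expect_error(atol_vector(tolerance_settings(use_atol_vector = FALSE), 1))
})

test_that("compile_ode produces mass-action derivatives and refuses hard features", {
  ode <- compile_ode(parse_sbml_info(sbml_with(simple_reaction)))
  expect_identical(ode$state_ids, c("A", "B"))
  expect_equal(ode$rhs(0, c(10, 0)), c(-5, 5))   # k=0.5
  expect_equal(ode$rhs(3, c(4, 6)), c(-2, 2))

  alg <- '<listOfRules><algebraicRule>
    <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><minus/><ci>A</ci><ci>B</ci></apply>
    </math></algebraicRule></listOfRules>'
  err <- tryCatch(compile_ode(parse_sbml_info(sbml_with(alg))),
                  condition = function(c) c)
  expect_s3_class(err, "sedverify_unsupported")
  expect_identical(err$tags, "algebraic_rules")
})

test_that("concentration-framed species divide by compartment size", {
  xml <- sbml_with(simple_reaction)
  xml <- sub('size="1"', 'size="2"', xml)
  xml <- sub('initialAmount="10"', 'initialConcentration="10"', xml)
  info <- parse_sbml_info(xml)
  ode <- compile_ode(info)
  # initial amount = conc * volume = 20; reported back as concentration
  expect_equal(unname(ode$initial_state[["A"]]), 20)
  rep0 <- ode$report(0, ode$initial_state)
  expect_equal(rep0$A, 10)
  # kinetic law sees the concentration: rate = k * [A] = 0.5 * 10 = 5
  expect_equal(ode$rhs(0, ode$initial_state), c(-5, 5))
})

test_that("both engines track the decay-chain closed form to 1e-6 relative", {
  for (nm in c("decay1", "decay3")) {
    a <- fx(nm)
    rates <- switch(nm, decay1 = 0.1, decay3 = c(0.1, 0.3, 0.7))
    for (eng in c("rk", "stiff")) {
      res <- execute_experiment(a, eng)
      expect_identical(res$status, "succeeded")
      m <- res$reports$report1
      exact <- analytic_solution(rates, m[, "time"])
      rel <- abs(m[, colnames(exact)] - exact) / pmax(abs(exact), 1e-8)
      expect_lt(max(rel), 1e-6)
    }
  }
})

test_that("the reported time column is the constructed uniform grid, bit for bit", {
  res <- execute_experiment(fx("decay1"), "rk")
  expect_identical(unname(res$reports$report1[, "time"]),
                   seq(0, 10, length.out = 101))
})

test_that("promote_local_params rewrites laws and handles collisions", {
  local_rx <- sub("</kineticLaw>",
                  '<listOfLocalParameters><localParameter id="kl" value="2"/></listOfLocalParameters></kineticLaw>',
                  simple_reaction)
  local_rx <- sub("<ci>k</ci>", "<ci>kl</ci>", local_rx)
  info <- parse_sbml_info(sbml_with(local_rx))
  p <- promote_local_params(info)
  expect_length(p$local_parameters, 0L)
  ids <- vapply(p$parameters, `[[`, "", "id")
  expect_true("J1_kl" %in% ids)
  # law now references the promoted global: rate = 2 * A
  ode <- compile_ode(p)
  expect_equal(ode$rhs(0, c(10, 0)), c(-20, 20))
  # xpath to the local parameter re-resolves to the promoted global
  ref <- resolve_xpath(
    "/sbml/model/listOfReactions/reaction[@id='J1']/kineticLaw/listOfLocalParameters/localParameter[@id='kl']",
    p)
  expect_identical(ref$kind, "parameter")
  expect_identical(ref$id, "J1_kl")

  # collision: an existing global named J1_kl forces the _2 suffix
  xml2 <- sub('<parameter id="k" value="0.5"',
              '<parameter id="J1_kl" value="9"', sbml_with(local_rx))
  p2 <- promote_local_params(parse_sbml_info(xml2))
  expect_true("J1_kl_2" %in% vapply(p2$parameters, `[[`, "", "id"))
  # no locals: identity
  info0 <- parse_sbml_info(sbml_with(simple_reaction))
  expect_identical(promote_local_params(info0), info0)
})

test_that("fold_initial_assignments evaluates chains in topological order", {
  ias <- '<listOfInitialAssignments>
    <initialAssignment symbol="B">
      <math xmlns="http://www.w3.org/1998/Math/MathML">
        <apply><plus/><ci>A</ci><cn>1</cn></apply></math>
    </initialAssignment>
    <initialAssignment symbol="A">
      <math xmlns="http://www.w3.org/1998/Math/MathML">
        <apply><times/><cn>2</cn><ci>k</ci></apply></math>
    </initialAssignment>
  </listOfInitialAssignments>'
  info <- parse_sbml_info(sbml_with(paste0(simple_reaction, ias)))
  # k = 0.5: A := 2*0.5 = 1 (folded first), then B := A + 1 = 2
  folded <- fold_initial_assignments(info)
  expect_length(folded$initial_assignments, 0L)
  env <- sedverify:::initial_env(folded)
  expect_equal(env$A, 1)
  expect_equal(env$B, 2)
  # no assignments: identity
  info0 <- parse_sbml_info(sbml_with(simple_reaction))
  expect_identical(fold_initial_assignments(info0), info0)
  # cycle detection names the members
  cyc <- '<listOfInitialAssignments>
    <initialAssignment symbol="A">
      <math xmlns="http://www.w3.org/1998/Math/MathML"><ci>B</ci></math>
    </initialAssignment>
    <initialAssignment symbol="B">
      <math xmlns="http://www.w3.org/1998/Math/MathML"><ci>A</ci></math>
    </initialAssignment>
  </listOfInitialAssignments>'
  expect_error(fold_initial_assignments(parse_sbml_info(sbml_with(cyc))),
               "cyclic.*A.*B")
})

test_that("initial assignments are honored by compilation without folding", {
  ia <- '<listOfInitialAssignments>
    <initialAssignment symbol="A">
      <math xmlns="http://www.w3.org/1998/Math/MathML">
        <apply><times/><cn>6</cn><ci>k</ci></apply></math>
    </initialAssignment>
  </listOfInitialAssignments>'
  info <- parse_sbml_info(sbml_with(paste0(simple_reaction, ia)))
  ode <- compile_ode(info)
  expect_equal(unname(ode$initial_state[["A"]]), 3)  # 6 * 0.5
})

test_that("unsupported features surface as failed_unsupported run results", {
  delay_law <- '<listOfReactions>
    <reaction id="J1" reversible="false" fast="false">
      <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
      <listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>
      <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">
        <apply><times/><ci>k</ci>
          <apply><csymbol definitionURL="http://www.sbml.org/sbml/symbols/delay">delay</csymbol>
            <ci>A</ci><cn>1</cn></apply></apply>
      </math></kineticLaw>
    </reaction>
  </listOfReactions>'
  bytes <- charToRaw(sbml_with(delay_law))
  info <- parse_sbml_info(bytes)
  doc <- generate_template(info, "m.xml")
  archive <- new_archive(list(
    archive_entry("m.xml", bytes, sedverify:::FMT_SBML),
    archive_entry("m.sedml", write_sedml(doc), sedverify:::FMT_SEDML)))
  for (eng in c("rk", "stiff")) {
    res <- execute_experiment(archive, eng)
    expect_identical(res$status, "failed_unsupported")
    expect_true("delay_csymbol" %in% res$unsupported_tags)
    expect_length(res$reports, 0L)
  }
})

test_that("repeated tasks stack iterations along the outer dimension", {
  a <- fx("decay1")
  doc <- fixture_doc(a)
  doc$tasks[[2]] <- list(
    type = "repeat", id = "rt1",
    range = list(type = "vector", id = "r1", values = c(1, 2)),
    range_variable = "r1",
    changes = list(list(
      target = "/sbml:sbml/sbml:model/sbml:listOfParameters/sbml:parameter[@id='k1']",
      math = sedverify:::m_sym("r1"))),
    subtasks = "task1", reset_model = TRUE)
  models <- list(model1 = fixture_info(a))
  res <- run_task(doc, "rt1", get_engine("rk"), tolerance_settings(), models)
  expect_identical(res$iterations, 2L)
  expect_identical(nrow(res$states), 202L)
  # each iteration is the solution under its own rate constant
  x0 <- res$lookup(
    target = "/sbml:sbml/sbml:model/sbml:listOfSpecies/sbml:species[@id='X0']")
  expect_equal(x0[101], 10 * exp(-1 * 10), tolerance = 1e-6)
  expect_equal(x0[202], 10 * exp(-2 * 10), tolerance = 1e-4)
})

test_that("steady-state simulations converge to the terminal species", {
  a <- fx("decay2")
  doc <- fixture_doc(a)
  doc$simulations[[2]] <- list(type = "steady", id = "ss1",
                               algorithm = list(kisao_id = "KISAO:0000019",
                                                parameters = character(0)))
  doc$tasks[[2]] <- list(type = "task", id = "ss_task", model_ref = "model1",
                         simulation_ref = "ss1")
  models <- list(model1 = fixture_info(a))
  for (eng in c("rk", "stiff")) {
    res <- run_task(doc, "ss_task", get_engine(eng), tolerance_settings(),
                    models)
    expect_identical(nrow(res$states), 1L)
    x2 <- res$lookup(
      target = "/sbml:sbml/sbml:model/sbml:listOfSpecies/sbml:species[@id='X2']")
    expect_equal(x2, 10, tolerance = 1e-4)
  }
})

test_that("the implicit engine needs far fewer steps on the stiff fixture", {
  rk <- execute_experiment(fx("stiff"), "rk")
  st <- execute_experiment(fx("stiff"), "stiff")
  expect_identical(rk$status, "succeeded")
  expect_identical(st$status, "succeeded")
  expect_lt(st$nsteps, rk$nsteps / 10)
})

test_that("requested constant parameters appear as constant columns", {
  a <- fx("decay1")
  doc <- fixture_doc(a)
  doc$data_generators[[4]] <- list(
    id = "dg_k", variables = list(list(
      id = "var_k", task_ref = "task1",
      target = "/sbml:sbml/sbml:model/sbml:listOfParameters/sbml:parameter[@id='k1']",
      symbol = NA_character_)),
    math = sedverify:::m_sym("var_k"))
  doc$outputs[[1]]$datasets[[4]] <- list(label = "k1", data_ref = "dg_k")
  e <- sedverify:::find_sedml_entry(a)
  e$content <- write_sedml(doc)
  a <- sedverify:::archive_set(a, e)
  res <- execute_experiment(a, "rk")
  expect_identical(res$status, "succeeded")
  expect_equal(unname(res$reports$report1[, "k1"]), rep(0.1, 101))
})
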