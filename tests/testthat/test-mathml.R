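m_num <- sedverify:::m_num
m_sym <- sedverify:::m_sym
m_time <- sedverify:::m_time
m_apply <- sedverify:::m_apply
m_piecewise <- sedverify:::m_piecewise

test_that("eval_math computes arithmetic, piecewise and constants", {
  expect_identical(eval_math(m_apply("exp", m_num(0))), 1)
  expect_identical(
    eval_math(m_apply("divide",
                      m_apply("power", m_num(2), m_num(10)), m_num(4))), 256)
  pw <- m_piecewise(list(list(value = m_num(1),
                              cond = m_apply("lt", m_time(), m_num(5)))),
                    m_num(3))
  expect_identical(eval_math(pw, list(time = 6)), 3)
  expect_identical(eval_math(pw, list(time = 2)), 1)
  expect_equal(eval_math(m_apply("root", m_num(3), m_num(27))), 3)
  expect_equal(eval_math(m_apply("log", m_num(10), m_num(1000))), 3)
  expect_identical(eval_math(m_apply("min", m_num(3), m_num(-1), m_num(2))), -1)
  expect_identical(eval_math(m_apply("xor", m_num(1), m_num(1), m_num(1))), 1)
  # IEEE semantics for non-finite intermediates
  expect_identical(eval_math(m_apply("divide", m_num(1), m_num(0))), Inf)
  expect_true(is.nan(eval_math(m_apply("minus", m_num(Inf), m_num(Inf)))))
})

test_that("unbound symbols and unsupported operators are named in errors", {
  expect_error(eval_math(m_sym("k_missing")), "k_missing")
  expect_error(eval_math(m_apply("factorial", m_num(3))), "factorial")
})

test_that("content MathML parses from XML including csymbols and e-notation", {
  parse_math_str <- function(s) {
    doc <- xml2::read_xml(paste0(
      '<math xmlns="http://www.w3.org/1998/Math/MathML">', s, "</math>"))
    xml2::xml_ns_strip(doc)
    sedverify:::parse_mathml(doc)
  }
  ast <- parse_math_str("<apply><times/><ci>k</ci><ci>A</ci></apply>")
  expect_equal(eval_math(ast, list(k = 2, A = 5)), 10)
  ast <- parse_math_str('<cn type="e-notation">1<sep/>-3</cn>')
  expect_equal(eval_math(ast), 1e-3)
  ast <- parse_math_str('<cn type="rational">3<sep/>4</cn>')
  expect_equal(eval_math(ast), 0.75)
  ast <- parse_math_str(
    '<csymbol definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol>')
  expect_equal(eval_math(ast, list(time = 7)), 7)
  expect_error(parse_math_str("<vector><cn>1</cn></vector>"), "vector")
})

test_that("MathML writing round-trips through the parser", {
  asts <- list(
    m_apply("plus", m_sym("a"), m_apply("times", m_num(2), m_sym("b"))),
    m_piecewise(list(list(value = m_sym("a"),
                          cond = m_apply("geq", m_time(), m_num(1)))),
                m_apply("root", m_num(3), m_sym("b"))),
    m_apply("log", m_num(10), m_apply("abs", m_sym("a"))))
  env <- list(a = 2.5, b = 7, time = 3)
  for (ast in asts) {
    doc <- xml2::xml_new_root("wrap")
    sedverify:::append_mathml(doc, ast)
    xml2::xml_ns_strip(doc)
    back <- sedverify:::parse_mathml(xml2::xml_find_first(doc, "./math"))
    expect_equal(eval_math(back, env), eval_math(ast, env))
  }
})

# --- property test: eval_math against an independent brute-force oracle ----

# The oracle translates the AST to an R expression *string* and evaluates it
# with plain base R, sharing no code with eval_math or math_to_expr.
oracle_string <- function(ast) {
  switch(ast$kind,
    num = sprintf("(%.17g)", ast$value),
    sym = ast$id,
    time = "time",
    piecewise = {
      out <- oracle_string(ast$otherwise)
      for (p in rev(ast$pieces))
        out <- sprintf("(if (isTRUE((%s) != 0)) (%s) else (%s))",
                       oracle_string(p$cond), oracle_string(p$value), out)
      out
    },
    apply = {
      a <- vapply(ast$args, oracle_string, "")
      switch(ast$op,
        plus = paste0("(", paste(a, collapse = "+"), ")"),
        minus = if (length(a) == 1) paste0("(-", a, ")")
                else paste0("(", a[1], "-", a[2], ")"),
        times = paste0("(", paste(a, collapse = "*"), ")"),
        divide = paste0("(", a[1], "/", a[2], ")"),
        power = paste0("(", a[1], ")^(", a[2], ")"),
        exp = paste0("exp(", a[1], ")"),
        ln = paste0("log(", a[1], ")"),
        abs = paste0("abs(", a[1], ")"),
        floor = paste0("floor(", a[1], ")"),
        ceiling = paste0("ceiling(", a[1], ")"),
        sin = paste0("sin(", a[1], ")"),
        cos = paste0("cos(", a[1], ")"),
        tanh = paste0("tanh(", a[1], ")"),
        min = paste0("min(", paste(a, collapse = ","), ")"),
        max = paste0("max(", paste(a, collapse = ","), ")"),
        lt = paste0("as.numeric((", a[1], ") < (", a[2], "))"),
        leq = paste0("as.numeric((", a[1], ") <= (", a[2], "))"),
        gt = paste0("as.numeric((", a[1], ") > (", a[2], "))"),
        geq = paste0("as.numeric((", a[1], ") >= (", a[2], "))"),
        and = paste0("as.numeric(all(",
                     paste(sprintf("(%s) != 0", a), collapse = ","), "))"),
        or = paste0("as.numeric(any(",
                    paste(sprintf("(%s) != 0", a), collapse = ","), "))"),
        not = paste0("as.numeric((", a[1], ") == 0)"),
        stop("oracle: unsupported ", ast$op))
    })
}

random_ast <- function(depth) {
  if (depth <= 0 || runif(1) < 0.3) {
    pick <- runif(1)
    if (pick < 0.45) return(m_num(round(runif(1, -5, 5), 3)))
    if (pick < 0.9) return(m_sym(sample(c("a", "b", "x"), 1)))
    return(m_time())
  }
  op <- sample(c("plus", "minus", "times", "divide", "power", "exp", "ln",
                 "abs", "floor", "ceiling", "sin", "cos", "tanh", "min",
                 "max", "lt", "leq", "gt", "geq", "and", "or", "not",
                 "piecewise"), 1)
  if (op == "piecewise")
    return(m_piecewise(list(list(value = random_ast(depth - 1),
                                 cond = random_ast(depth - 1))),
                       random_ast(depth - 1)))
  nargs <- switch(op,
    exp = , ln = , abs = , floor = , ceiling = , sin = , cos = ,
    tanh = , not = 1L,
    divide = , power = , lt = , leq = , gt = , geq = 2L,
    sample(2:3, 1))
  do.call(sedverify:::m_apply,
          c(list(op), replicate(nargs, random_ast(depth - 1),
                                simplify = FALSE)))
}

test_that("eval_math agrees with a brute-force interpreter on 1000 random trees", {
  set.seed(42)
  n_checked <- 0L
  for (i in 1:1000) {
    ast <- random_ast(3)
    env <- list(a = runif(1, -3, 3), b = runif(1, 0.1, 4),
                x = runif(1, -2, 2), time = runif(1, 0, 10))
    # NaNs from domain crossings (log of a negative, etc.) are expected;
    # both routes must produce the same one
    got <- suppressWarnings(eval_math(ast, env))
    want <- suppressWarnings(eval(parse(text = oracle_string(ast)),
                                  envir = env))
    n_checked <- n_checked + 1L
    if (is.nan(got) || is.nan(want)) {
      expect_true(is.nan(got) && is.nan(want))
    } else if (!is.finite(got) || !is.finite(want)) {
      expect_identical(got, want)
    } else {
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  expect_identical(n_checked, 1000L)
})
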