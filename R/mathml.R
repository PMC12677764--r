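# Content-MathML subset: AST constructors, parser, writer, interpreter, and a
# compiler to R expressions (used for fast right-hand-side and data-generator
# evaluation).  The AST is a plain list tree:
#   list(kind = "num",  value = <double>)
#   list(kind = "sym",  id = <string>)
#   list(kind = "time")
#   list(kind = "apply", op = <string>, args = list(<ast>...))
#   list(kind = "piecewise", pieces = list(list(value=, cond=)...), otherwise =)

m_num  <- function(x) list(kind = "num", value = as.numeric(x))
m_sym  <- function(id) list(kind = "sym", id = id)
m_time <- function() list(kind = "time")
m_apply <- function(op, ...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && is.null(args[[1]]$kind))
    args <- args[[1]]
  list(kind = "apply", op = op, args = args)
}
m_piecewise <- function(pieces, otherwise) {
  list(kind = "piecewise", pieces = pieces, otherwise = otherwise)
}

MATH_UNARY <- c("exp", "ln", "log", "abs", "floor", "ceiling", "not",
                "sin", "cos", "tan", "sec", "csc", "cot",
                "arcsin", "arccos", "arctan", "arcsec", "arccsc", "arccot",
                "sinh", "cosh", "tanh", "sech", "csch", "coth",
                "arcsinh", "arccosh", "arctanh", "arcsech", "arccsch", "arccoth")
MATH_NARY  <- c("plus", "minus", "times", "divide", "power", "root",
                "min", "max", "and", "or", "xor",
                "lt", "leq", "gt", "geq", "eq", "neq")
MATH_OPS   <- c(MATH_UNARY, MATH_NARY)

MATH_CONSTANTS <- list(pi = pi, exponentiale = exp(1), true = 1, false = 0,
                       infinity = Inf, notanumber = NaN)

TIME_URLS <- c("http://www.sbml.org/sbml/symbols/time", "urn:sedml:symbol:time")
DELAY_URL <- "http://www.sbml.org/sbml/symbols/delay"

## ---- parsing -------------------------------------------------------------

# `node` is expected to come from a namespace-stripped document; pass the
# <math> element or any single MathML expression element.
parse_mathml <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L)
      stop("malformed math: <math> must contain exactly one expression",
           call. = FALSE)
    return(parse_mathml(kids[[1]]))
  }
  switch(nm,
    cn = parse_cn(node),
    ci = m_sym(trimws(xml2::xml_text(node))),
    csymbol = {
      url <- xml2::xml_attr(node, "definitionURL")
      if (!is.na(url) && (url %in% TIME_URLS || grepl("symbols/time", url)))
        m_time()
      else if (!is.na(url) && grepl("delay", url))
        m_apply("delay", lapply(xml2::xml_children(node), parse_mathml))
      else stop("unsupported csymbol: ", url, call. = FALSE)
    },
    apply = parse_apply(node),
    piecewise = parse_piecewise(node),
    pi = m_num(pi),
    exponentiale = m_num(exp(1)),
    true = m_num(1),
    false = m_num(0),
    infinity = m_num(Inf),
    notanumber = m_num(NaN),
    stop("unsupported MathML element <", nm, ">", call. = FALSE)
  )
}

parse_cn <- function(node) {
  type <- xml2::xml_attr(node, "type")
  if (!is.na(type) && type %in% c("e-notation", "rational")) {
    parts <- xml2::xml_contents(node)
    texts <- trimws(vapply(parts, xml2::xml_text, ""))
    nums <- as.numeric(texts[nzchar(texts)])
    if (length(nums) != 2L || anyNA(nums))
      stop("malformed <cn type='", type, "'>", call. = FALSE)
    if (type == "e-notation") return(m_num(nums[1] * 10^nums[2]))
    return(m_num(nums[1] / nums[2]))
  }
  val <- suppressWarnings(as.numeric(trimws(xml2::xml_text(node))))
  if (is.na(val) && trimws(xml2::xml_text(node)) != "NaN")
    stop("malformed <cn>: ", xml2::xml_text(node), call. = FALSE)
  m_num(val)
}

parse_apply <- function(node) {
  kids <- xml2::xml_children(node)
  if (!length(kids)) stop("empty <apply>", call. = FALSE)
  opname <- xml2::xml_name(kids[[1]])
  rest <- kids[-1]
  # qualifiers
  if (opname == "root") {
    degree <- m_num(2)
    operands <- list()
    for (k in rest) {
      if (xml2::xml_name(k) == "degree")
        degree <- parse_mathml(xml2::xml_children(k)[[1]])
      else operands[[length(operands) + 1L]] <- parse_mathml(k)
    }
    return(m_apply("root", c(list(degree), operands)))
  }
  if (opname == "log") {
    base <- m_num(10)
    operands <- list()
    for (k in rest) {
      if (xml2::xml_name(k) == "logbase")
        base <- parse_mathml(xml2::xml_children(k)[[1]])
      else operands[[length(operands) + 1L]] <- parse_mathml(k)
    }
    return(m_apply("log", c(list(base), operands)))
  }
  if (opname == "csymbol") {
    url <- xml2::xml_attr(kids[[1]], "definitionURL")
    if (!is.na(url) && grepl("delay", url))
      return(m_apply("delay", lapply(rest, parse_mathml)))
    stop("unsupported csymbol operator: ", url, call. = FALSE)
  }
  if (!(opname %in% MATH_OPS))
    stop("unsupported MathML operator <", opname, ">", call. = FALSE)
  m_apply(opname, lapply(rest, parse_mathml))
}

parse_piecewise <- function(node) {
  pieces <- list()
  otherwise <- NULL
  for (k in xml2::xml_children(node)) {
    nm <- xml2::xml_name(k)
    kk <- xml2::xml_children(k)
    if (nm == "piece") {
      pieces[[length(pieces) + 1L]] <-
        list(value = parse_mathml(kk[[1]]), cond = parse_mathml(kk[[2]]))
    } else if (nm == "otherwise") {
      otherwise <- parse_mathml(kk[[1]])
    }
  }
  if (is.null(otherwise)) otherwise <- m_num(NaN)
  m_piecewise(pieces, otherwise)
}

# parse a <math> child of `parent` (stripped doc); NULL if absent
parse_math_child <- function(parent) {
  m <- xml2::xml_find_first(parent, "./math")
  if (inherits(m, "xml_missing")) return(NULL)
  parse_mathml(m)
}

## ---- writing -------------------------------------------------------------

MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

# append the MathML serialization of `ast` (wrapped in <math>) to xml node
append_mathml <- function(parent, ast) {
  math <- xml2::xml_add_child(parent, "math", xmlns = MATHML_NS)
  append_math_node(math, ast)
  math
}

append_math_node <- function(parent, ast) {
  switch(ast$kind,
    num = {
      v <- ast$value
      if (is.nan(v)) xml2::xml_add_child(parent, "notanumber")
      else if (is.infinite(v)) xml2::xml_add_child(parent, "infinity")
      else xml2::xml_add_child(parent, "cn", format_num(v))
    },
    sym = xml2::xml_add_child(parent, "ci", paste0(" ", ast$id, " ")),
    time = xml2::xml_add_child(parent, "csymbol", " time ",
                               encoding = "text",
                               definitionURL = "urn:sedml:symbol:time"),
    apply = {
      ap <- xml2::xml_add_child(parent, "apply")
      args <- ast$args
      if (ast$op == "root") {
        xml2::xml_add_child(ap, "root")
        dg <- xml2::xml_add_child(ap, "degree")
        append_math_node(dg, args[[1]])
        args <- args[-1]
      } else if (ast$op == "log") {
        xml2::xml_add_child(ap, "log")
        lb <- xml2::xml_add_child(ap, "logbase")
        append_math_node(lb, args[[1]])
        args <- args[-1]
      } else {
        xml2::xml_add_child(ap, ast$op)
      }
      for (a in args) append_math_node(ap, a)
      ap
    },
    piecewise = {
      pw <- xml2::xml_add_child(parent, "piecewise")
      for (p in ast$pieces) {
        pc <- xml2::xml_add_child(pw, "piece")
        append_math_node(pc, p$value)
        append_math_node(pc, p$cond)
      }
      ot <- xml2::xml_add_child(pw, "otherwise")
      append_math_node(ot, ast$otherwise)
      pw
    },
    stop("unknown AST kind: ", ast$kind, call. = FALSE)
  )
}

format_num <- function(v) {
  if (is.finite(v) && v == round(v) && abs(v) < 1e15)
    sprintf("%d", as.integer64_safe(v))
  else sprintf("%.17g", v)
}

as.integer64_safe <- function(v) {
  if (abs(v) <= .Machine$integer.max) as.integer(v) else v
}

## ---- evaluation ----------------------------------------------------------

#' Evaluate a MathML expression
#'
#' Direct recursive interpretation of the AST. Every free symbol must be
#' bound in `env`; the MathML time csymbol reads the binding named `"time"`.
#' Relational and logical operators return 1/0; IEEE semantics apply to
#' non-finite intermediates.
#'
#' @param expr a MathML AST (as produced by the SED-ML/SBML parsers).
#' @param env named list or numeric vector of symbol bindings.
#' @return a numeric scalar.
#' @export
eval_math <- function(expr, env = list()) {
  ev <- function(a) {
    switch(a$kind,
      num = a$value,
      sym = {
        v <- env[[a$id]]
        if (is.null(v)) stop("unbound symbol: ", a$id, call. = FALSE)
        as.numeric(v)
      },
      time = {
        v <- env[["time"]]
        if (is.null(v)) stop("unbound symbol: time", call. = FALSE)
        as.numeric(v)
      },
      piecewise = {
        for (p in a$pieces) {
          if (isTRUE(ev(p$cond) != 0)) return(ev(p$value))
        }
        ev(a$otherwise)
      },
      apply = {
        op <- a$op
        vals <- lapply(a$args, ev)
        apply_op(op, vals)
      },
      stop("unknown AST kind: ", a$kind, call. = FALSE)
    )
  }
  ev(expr)
}

apply_op <- function(op, vals) {
  v1 <- if (length(vals) >= 1) vals[[1]] else NULL
  v2 <- if (length(vals) >= 2) vals[[2]] else NULL
  num <- function(x) as.numeric(x)
  switch(op,
    plus = num(Reduce(`+`, vals, 0)),
    minus = if (length(vals) == 1L) -v1 else v1 - v2,
    times = num(Reduce(`*`, vals, 1)),
    divide = v1 / v2,
    power = v1 ^ v2,
    root = v2 ^ (1 / v1),          # args: (degree, operand)
    exp = exp(v1),
    ln = log(v1),
    log = log(v2, base = v1),      # args: (base, operand)
    abs = abs(v1),
    floor = floor(v1),
    ceiling = ceiling(v1),
    sin = sin(v1), cos = cos(v1), tan = tan(v1),
    sec = 1 / cos(v1), csc = 1 / sin(v1), cot = 1 / tan(v1),
    arcsin = asin(v1), arccos = acos(v1), arctan = atan(v1),
    arcsec = acos(1 / v1), arccsc = asin(1 / v1), arccot = atan(1 / v1),
    sinh = sinh(v1), cosh = cosh(v1), tanh = tanh(v1),
    sech = 1 / cosh(v1), csch = 1 / sinh(v1), coth = 1 / tanh(v1),
    arcsinh = asinh(v1), arccosh = acosh(v1), arctanh = atanh(v1),
    arcsech = acosh(1 / v1), arccsch = asinh(1 / v1), arccoth = atanh(1 / v1),
    min = num(do.call(min, vals)),
    max = num(do.call(max, vals)),
    lt = num(v1 < v2), leq = num(v1 <= v2),
    gt = num(v1 > v2), geq = num(v1 >= v2),
    eq = num(v1 == v2), neq = num(v1 != v2),
    and = num(all(vapply(vals, function(x) x != 0, TRUE))),
    or = num(any(vapply(vals, function(x) x != 0, TRUE))),
    not = num(v1 == 0),
    xor = num(sum(vapply(vals, function(x) x != 0, TRUE)) %% 2 == 1),
    delay = stop("delay csymbol cannot be evaluated (unsupported feature)",
                 call. = FALSE),
    stop("unsupported operator: ", op, call. = FALSE)
  )
}

## ---- compilation to R expressions ---------------------------------------

# Environment of helper functions available to compiled math expressions.
# pmin/pmax/ifelse keep compiled expressions vectorized so data generators
# can be evaluated over whole trajectory columns at once.
math_fun_env <- local({
  e <- new.env(parent = baseenv())
  e$sec <- function(x) 1 / cos(x);  e$csc <- function(x) 1 / sin(x)
  e$cot <- function(x) 1 / tan(x)
  e$arcsec <- function(x) acos(1 / x); e$arccsc <- function(x) asin(1 / x)
  e$arccot <- function(x) atan(1 / x)
  e$sech <- function(x) 1 / cosh(x); e$csch <- function(x) 1 / sinh(x)
  e$coth <- function(x) 1 / tanh(x)
  e$arcsech <- function(x) acosh(1 / x); e$arccsch <- function(x) asinh(1 / x)
  e$arccoth <- function(x) atanh(1 / x)
  e$xor_n <- function(...) as.numeric(Reduce(function(a, b) xor(a != 0, b != 0),
                                             list(...), FALSE))
  for (f in c("exp", "log", "abs", "floor", "ceiling", "sqrt",
              "sin", "cos", "tan", "asin", "acos", "atan",
              "sinh", "cosh", "tanh", "asinh", "acosh", "atanh",
              "pmin", "pmax", "ifelse", "is.na", "+", "-", "*", "/", "^",
              "<", "<=", ">", ">=", "==", "!=", "&", "|", "!", "("))
    assign(f, get(f, baseenv()), envir = e)
  e
})

# Translate an AST into an R language object evaluating in math_fun_env
# children. Symbol ids map to variables of the same name; time to `time`.
math_to_expr <- function(ast) {
  switch(ast$kind,
    num = ast$value,
    sym = as.name(ast$id),
    time = as.name("time"),
    piecewise = {
      # a NaN condition selects the fallback branch, matching eval_math
      out <- math_to_expr(ast$otherwise)
      for (p in rev(ast$pieces)) {
        cnd <- math_to_expr(p$cond)
        test <- call("&", call("!", call("is.na", cnd)), call("!=", cnd, 0))
        out <- call("ifelse", test, math_to_expr(p$value), out)
      }
      out
    },
    apply = {
      args <- lapply(ast$args, math_to_expr)
      op <- ast$op
      bin <- function(fn) Reduce(function(a, b) call(fn, a, b), args)
      switch(op,
        plus = if (length(args) == 0L) 0 else bin("+"),
        minus = if (length(args) == 1L) call("-", args[[1]]) else bin("-"),
        times = if (length(args) == 0L) 1 else bin("*"),
        divide = bin("/"),
        power = bin("^"),
        root = call("^", args[[2]], call("/", 1, args[[1]])),
        log = call("/", call("log", args[[2]]), call("log", args[[1]])),
        ln = call("log", args[[1]]),
        min = Reduce(function(a, b) call("pmin", a, b), args),
        max = Reduce(function(a, b) call("pmax", a, b), args),
        lt = call("+", 0, bin("<")), leq = call("+", 0, bin("<=")),
        gt = call("+", 0, bin(">")), geq = call("+", 0, bin(">=")),
        eq = call("+", 0, bin("==")), neq = call("+", 0, bin("!=")),
        and = call("+", 0, Reduce(function(a, b)
          call("&", call("!=", a, 0), call("!=", b, 0)), args)),
        or = call("+", 0, Reduce(function(a, b)
          call("|", call("!=", a, 0), call("!=", b, 0)), args)),
        not = call("+", 0, call("==", args[[1]], 0)),
        xor = as.call(c(as.name("xor_n"), args)),
        arcsin = call("asin", args[[1]]), arccos = call("acos", args[[1]]),
        arctan = call("atan", args[[1]]),
        arcsinh = call("asinh", args[[1]]), arccosh = call("acosh", args[[1]]),
        arctanh = call("atanh", args[[1]]),
        delay = stop("delay csymbol cannot be compiled (unsupported feature)",
                     call. = FALSE),
        as.call(c(as.name(op), args))
      )
    },
    stop("unknown AST kind", call. = FALSE)
  )
}

# collect free symbol ids (excluding time) from an AST
math_symbols <- function(ast) {
  switch(ast$kind,
    num = character(0),
    time = character(0),
    sym = ast$id,
    apply = unique(unlist(lapply(ast$args, math_symbols))),
    piecewise = unique(c(
      unlist(lapply(ast$pieces, function(p)
        c(math_symbols(p$value), math_symbols(p$cond)))),
      math_symbols(ast$otherwise))),
    character(0)
  )
}

# TRUE if the AST contains a delay csymbol application
math_has_delay <- function(ast) {
  switch(ast$kind,
    apply = ast$op == "delay" || any(vapply(ast$args, math_has_delay, TRUE)),
    piecewise = any(vapply(ast$pieces, function(p)
      math_has_delay(p$value) || math_has_delay(p$cond), TRUE)) ||
      math_has_delay(ast$otherwise),
    FALSE
  )
}

# structural normal form for semantic comparison: drop environments, keep
# numbers as doubles
math_canonical <- function(ast) {
  if (is.null(ast)) return(NULL)
  switch(ast$kind,
    num = list("num", ast$value),
    sym = list("sym", ast$id),
    time = list("time"),
    apply = list("apply", ast$op, lapply(ast$args, math_canonical)),
    piecewise = list("piecewise",
                     lapply(ast$pieces, function(p)
                       list(math_canonical(p$value), math_canonical(p$cond))),
                     math_canonical(ast$otherwise))
  )
}
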