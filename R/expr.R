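#' @useDynLib boolsig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn `%||%`
#' @importFrom tibble tibble as_tibble
NULL

# Boolean expressions are stored as ordinary R language objects over the
# operators `&`, `|`, `!`, variable symbols and the constants TRUE/FALSE.
# evaluate() is therefore just eval() in an environment of (possibly
# vectorised) logical columns, which is what makes whole-state-space
# evaluation cheap.

#' Tokenize a Boolean rule string
#'
#' @param text a rule expression in the `AND`/`OR`/`NOT` dialect.
#' @return a data frame of tokens with their character positions.
#' @keywords internal
bool_tokenize <- function(text) {
  pat <- "\\(|\\)|[A-Za-z0-9_]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(), pos = integer()))
  }
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  # reject stray characters (anything not matched, other than whitespace)
  rest <- text
  regmatches(rest, gregexpr(pat, rest)) <- list(rep("", length(toks)))
  rest <- gsub("\\s", "", rest)
  if (nzchar(rest)) {
    abort(sprintf("unexpected character(s) in rule: '%s'", rest))
  }
  data.frame(token = toks, pos = as.integer(m), stringsAsFactors = FALSE)
}

#' Parse a Boolean rule expression
#'
#' Parses the `AND`/`OR`/`NOT` rule dialect (case-insensitive keywords,
#' parentheses, constants `0`/`1`) into an R expression over `&`, `|`, `!`.
#' Operator precedence is `NOT` > `AND` > `OR`, left-associative.
#'
#' @param text the rule right-hand side, e.g.
#'   `"NOT (Ceramide OR Apoptosis)"`.
#' @param vocabulary optional character vector of declared node names; any
#'   other name is an error.
#' @return an unevaluated R expression (a call, symbol or logical constant).
#' @examples
#' e <- parse_rule("(Ceramide OR (Fas AND NOT FLIP)) AND NOT Apoptosis")
#' write_rule(e)
#' @export
parse_rule <- function(text, vocabulary = NULL) {
  tk <- bool_tokenize(text)
  toks <- tk$token
  pos <- tk$pos
  i <- 0L
  n <- length(toks)
  peek <- function() if (i < n) toks[i + 1L] else NA_character_
  advance <- function() {
    i <<- i + 1L
    toks[i]
  }
  expect_more <- function(what) {
    if (i >= n) abort(sprintf("unexpected end of rule: expected %s", what))
  }
  is_kw <- function(t, kw) !is.na(t) && toupper(t) == kw

  parse_or <- function() {
    e <- parse_and()
    while (is_kw(peek(), "OR")) {
      advance()
      e <- call("|", e, parse_and())
    }
    e
  }
  parse_and <- function() {
    e <- parse_not()
    while (is_kw(peek(), "AND")) {
      advance()
      e <- call("&", e, parse_not())
    }
    e
  }
  parse_not <- function() {
    if (is_kw(peek(), "NOT")) {
      advance()
      expect_more("an operand after NOT")
      return(call("!", parse_not()))
    }
    parse_atom()
  }
  parse_atom <- function() {
    expect_more("an operand")
    t <- advance()
    if (t == "(") {
      e <- parse_or()
      expect_more("')'")
      if (advance() != ")") {
        abort(sprintf("unbalanced parentheses near position %d", pos[i]))
      }
      return(e)
    }
    if (t == ")") {
      abort(sprintf("unbalanced parentheses at position %d", pos[i]))
    }
    if (t %in% c("0", "1")) {
      return(t == "1")
    }
    if (toupper(t) %in% c("AND", "OR", "NOT")) {
      abort(sprintf("misplaced operator '%s' at position %d", t, pos[i]))
    }
    if (!is.null(vocabulary) && !(t %in% vocabulary)) {
      abort(sprintf("undeclared name '%s' at position %d", t, pos[i]))
    }
    as.symbol(t)
  }

  if (n == 0L) abort("empty rule expression")
  e <- parse_or()
  if (i < n) {
    abort(sprintf("trailing input '%s' at position %d", toks[i + 1L], pos[i + 1L]))
  }
  e
}

#' Write a Boolean expression back to the rule dialect
#'
#' @param expr an expression from [parse_rule()] or built programmatically.
#' @return a single string; `write_rule(parse_rule(x))` is semantically
#'   equivalent to `x`.
#' @export
write_rule <- function(expr) {
  wrap <- function(e, parent_op) {
    s <- render(e)
    op <- expr_op(e)
    need <- (parent_op == "!" && op %in% c("&", "|")) ||
      (parent_op == "&" && op == "|")
    if (need) paste0("(", s, ")") else s
  }
  render <- function(e) {
    if (is.logical(e)) {
      return(if (e) "1" else "0")
    }
    if (is.symbol(e)) {
      return(as.character(e))
    }
    op <- expr_op(e)
    switch(op,
      "!" = paste0("NOT ", wrap(e[[2]], "!")),
      "&" = paste(wrap(e[[2]], "&"), "AND", wrap(e[[3]], "&")),
      "|" = paste(wrap(e[[2]], "|"), "OR", wrap(e[[3]], "|")),
      abort(sprintf("unsupported operator '%s' in expression", op))
    )
  }
  render(expr)
}

expr_op <- function(e) {
  if (is.call(e)) as.character(e[[1]]) else ""
}

#' Variables of a Boolean expression
#'
#' @param expr a Boolean expression.
#' @return character vector of distinct variable names, in order of first
#'   appearance.
#' @export
rule_vars <- function(expr) {
  out <- character()
  walk <- function(e) {
    if (is.symbol(e)) {
      out[[length(out) + 1L]] <<- as.character(e)
    } else if (is.call(e)) {
      for (k in seq.int(2L, length(e))) walk(e[[k]])
    }
  }
  walk(expr)
  unique(out)
}

#' Evaluate a Boolean expression
#'
#' Standard Boolean semantics. `assignment` may contain logical or 0/1
#' vectors of common length, in which case the rule is evaluated elementwise
#' (used internally to evaluate a rule over an entire state space at once).
#'
#' @param expr a Boolean expression.
#' @param assignment a named list / vector mapping every variable of `expr`
#'   to 0/1 (or logical) values.
#' @return integer 0/1 vector.
#' @export
eval_rule <- function(expr, assignment) {
  vars <- rule_vars(expr)
  missing <- setdiff(vars, names(assignment))
  if (length(missing) > 0L) {
    abort(sprintf(
      "assignment is missing variable(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  env <- list2env(lapply(as.list(assignment)[vars], function(v) as.logical(v)),
    parent = baseenv()
  )
  as.integer(eval(expr, env))
}

#' Substitute a partial assignment and simplify
#'
#' Replaces the given variables by constants and simplifies using constant
#' propagation, idempotence, absorption and the complement law. The result
#' contains none of the substituted variables and agrees with the original
#' expression on every completion of the partial assignment; a fully
#' determined expression collapses to `TRUE`/`FALSE`.
#'
#' @param expr a Boolean expression.
#' @param partial named 0/1 (or logical) vector; may be empty.
#' @return a simplified expression.
#' @export
simplify_rule <- function(expr, partial = integer()) {
  part <- lapply(as.list(partial), function(v) isTRUE(as.logical(v)))
  simp <- function(e) {
    if (is.logical(e)) {
      return(e)
    }
    if (is.symbol(e)) {
      nm <- as.character(e)
      if (nm %in% names(part)) {
        return(part[[nm]])
      }
      return(e)
    }
    op <- expr_op(e)
    if (op == "!") {
      s <- simp(e[[2]])
      if (is.logical(s)) {
        return(!s)
      }
      if (expr_op(s) == "!") {
        return(s[[2]])
      }
      return(call("!", s))
    }
    if (!op %in% c("&", "|")) {
      abort(sprintf("unsupported operator '%s'", op))
    }
    dominant <- (op == "|") # value that absorbs the whole expression
    args <- flatten_op(e, op)
    args <- lapply(args, simp)
    keep <- list()
    keys <- character()
    for (a in args) {
      if (is.logical(a)) {
        if (a == dominant) {
          return(dominant)
        }
        next # neutral element
      }
      k <- expr_key(a)
      if (!(k %in% keys)) {
        keep[[length(keep) + 1L]] <- a
        keys[[length(keys) + 1L]] <- k
      }
    }
    # complement law: x op !x
    for (a in keep) {
      nk <- if (expr_op(a) == "!") expr_key(a[[2]]) else expr_key(call("!", a))
      if (nk %in% keys) {
        return(dominant)
      }
    }
    # absorption: within AND drop args that are ORs containing another arg
    # (x & (x | y) = x), dually for OR
    inner_op <- if (op == "&") "|" else "&"
    lits <- keys
    drop <- logical(length(keep))
    for (j in seq_along(keep)) {
      a <- keep[[j]]
      if (expr_op(a) == inner_op) {
        inner_keys <- vapply(flatten_op(a, inner_op), expr_key, "")
        if (any(inner_keys %in% lits[!drop & seq_along(lits) != j])) {
          drop[j] <- TRUE
        }
      }
    }
    keep <- keep[!drop]
    if (length(keep) == 0L) {
      return(!dominant)
    }
    if (length(keep) == 1L) {
      return(keep[[1L]])
    }
    Reduce(function(x, y) call(op, x, y), keep)
  }
  simp(expr)
}

flatten_op <- function(e, op) {
  if (expr_op(e) == op) {
    c(flatten_op(e[[2]], op), flatten_op(e[[3]], op))
  } else {
    list(e)
  }
}

expr_key <- function(e) paste(deparse(e), collapse = " ")

# ---- canonical (OR-of-ANDs) form --------------------------------------------

#' Canonical OR-of-ANDs form of a Boolean rule
#'
#' Converts an expression to negation-normal form, distributes to a
#' disjunction of AND-clauses, removes contradictory clauses, applies
#' absorption (no clause is a superset of another) and orders literals and
#' clauses lexicographically. A literal is written `"A"` (plain) or `"~A"`
#' (negated).
#'
#' @param expr a non-constant Boolean expression (or rule text).
#' @param target optional node name the rule feeds.
#' @return an object of class `canonical_rule`: a list with elements
#'   `target` and `clauses` (list of character vectors of literals).
#' @examples
#' to_canonical(parse_rule("(A AND B) OR C"))
#' @export
to_canonical <- function(expr, target = NULL) {
  if (is.character(expr)) expr <- parse_rule(expr)
  expr <- simplify_rule(expr)
  if (is.logical(expr)) {
    abort("cannot canonicalize a constant expression; handle constants first")
  }
  clauses <- dnf_clauses(expr)
  new_canonical_rule(target, clauses)
}

new_canonical_rule <- function(target, clauses) {
  clauses <- lapply(clauses, function(cl) sort(unique(cl)))
  clauses <- unique(clauses)
  # absorption
  keep <- rep(TRUE, length(clauses))
  for (j in seq_along(clauses)) {
    for (k in seq_along(clauses)) {
      if (j != k && keep[k] && keep[j] &&
        all(clauses[[k]] %in% clauses[[j]]) &&
        length(clauses[[k]]) < length(clauses[[j]])) {
        keep[j] <- FALSE
        break
      }
    }
  }
  clauses <- clauses[keep]
  ord <- order(vapply(clauses, function(cl) paste(cl, collapse = "\x01"), ""))
  structure(
    list(target = target, clauses = clauses[ord]),
    class = "canonical_rule"
  )
}

# negation-normal form + distribution; clauses as literal character vectors
dnf_clauses <- function(expr, negated = FALSE) {
  if (is.logical(expr)) {
    val <- xor(expr, negated)
    return(if (val) list(character()) else list())
  }
  if (is.symbol(expr)) {
    lit <- if (negated) paste0("~", as.character(expr)) else as.character(expr)
    return(list(lit))
  }
  op <- expr_op(expr)
  if (op == "!") {
    return(dnf_clauses(expr[[2]], !negated))
  }
  eff <- if (negated) c("&" = "|", "|" = "&")[[op]] else op
  a <- dnf_clauses(expr[[2]], negated)
  b <- dnf_clauses(expr[[3]], negated)
  if (eff == "|") {
    return(c(a, b))
  }
  # AND: cartesian product, dropping contradictions
  out <- list()
  for (x in a) {
    for (y in b) {
      cl <- unique(c(x, y))
      bases <- sub("^~", "", cl)
      if (anyDuplicated(bases)) next # contains l and ~l
      out[[length(out) + 1L]] <- cl
    }
  }
  out
}

#' @export
print.canonical_rule <- function(x, ...) {
  tgt <- x$target %||% "<rule>"
  cls <- vapply(
    x$clauses,
    function(cl) paste0("{", paste(cl, collapse = ", "), "}"), ""
  )
  cat(tgt, "=", paste(cls, collapse = " | "), "\n")
  invisible(x)
}

#' Logical complement of a canonical rule
#'
#' @param rule a `canonical_rule`.
#' @return the canonical form of its negation; the target (if any) is
#'   prefixed with `~`.
#' @export
negate_rule <- function(rule) {
  stopifnot(inherits(rule, "canonical_rule"))
  e <- canonical_to_expr(rule)
  tgt <- if (is.null(rule$target)) NULL else flip_vertex(rule$target)
  to_canonical(call("!", e), target = tgt)
}

flip_vertex <- function(v) {
  ifelse(startsWith(v, "~"), substring(v, 2L), paste0("~", v))
}

#' Rebuild an expression from a canonical rule
#'
#' @param rule a `canonical_rule`.
#' @return a Boolean expression equivalent to the rule.
#' @export
canonical_to_expr <- function(rule) {
  lit_expr <- function(l) {
    if (startsWith(l, "~")) call("!", as.symbol(substring(l, 2L))) else as.symbol(l)
  }
  clause_expr <- function(cl) {
    Reduce(function(x, y) call("&", x, y), lapply(cl, lit_expr))
  }
  if (length(rule$clauses) == 0L) {
    return(FALSE)
  }
  Reduce(function(x, y) call("|", x, y), lapply(rule$clauses, clause_expr))
}
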