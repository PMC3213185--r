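test_that("parser handles the rule dialect with NOT > AND > OR precedence", {
  e <- parse_rule("NOT (Ceramide OR Apoptosis)")
  expect_identical(e, call("!", quote(Ceramide | Apoptosis)))

  expect_identical(parse_rule("A", vocabulary = "A"), quote(A))

  disc <- parse_rule("(Ceramide OR (Fas AND NOT FLIP)) AND NOT Apoptosis")
  expect_length(rule_vars(disc), 4L)
  # truth table matches direct evaluation of the nested expression
  direct <- function(C, F2, FL, A) {
    as.integer((C | (F2 & !FL)) & !A)
  }
  g <- expand.grid(C = 0:1, F2 = 0:1, FL = 0:1, A = 0:1)
  got <- vapply(seq_len(nrow(g)), function(i) {
    eval_rule(disc, list(
      Ceramide = g$C[i], Fas = g$F2[i], FLIP = g$FL[i], Apoptosis = g$A[i]
    ))
  }, integer(1))
  expect_identical(got, direct(g$C, g$F2, g$FL, g$A))

  # precedence without parentheses: NOT binds tightest, then AND, then OR
  expect_true(exprs_equivalent(
    parse_rule("A OR B AND NOT C"),
    quote(A | (B & !C))
  ))
  # keywords are case-insensitive
  expect_true(exprs_equivalent(
    parse_rule("a and not b or c", vocabulary = c("a", "b", "c")),
    quote((a & !b) | c)
  ))
})

test_that("parse errors name the offending token or position", {
  expect_error(parse_rule("A AND Bx", vocabulary = c("A", "B")), "Bx")
  expect_error(parse_rule("(A OR B"), "parenthes|end of rule")
  expect_error(parse_rule("A OR B)"), "position")
  expect_error(parse_rule("A OR"), "end of rule")
  expect_error(parse_rule(""), "empty")
})

test_that("write_rule round-trips through the parser", {
  withr::with_seed(11, {
    for (i in 1:40) {
      e <- random_expr(c("A", "B", "C", "D"), depth = 4)
      e2 <- parse_rule(write_rule(e))
      expect_true(exprs_equivalent(e, e2))
    }
  })
})

test_that("evaluation follows standard Boolean semantics", {
  disc <- parse_rule("(Ceramide OR (Fas AND NOT FLIP)) AND NOT Apoptosis")
  expect_identical(
    eval_rule(disc, list(Ceramide = 0, Fas = 1, FLIP = 1, Apoptosis = 0)),
    0L
  )
  expect_identical(eval_rule(TRUE, list()), 1L)
  apo <- parse_rule("DISC OR Apoptosis")
  expect_identical(eval_rule(apo, list(DISC = 0, Apoptosis = 1)), 1L)
  expect_error(eval_rule(apo, list(DISC = 0)), "Apoptosis")
})

test_that("substitution removes variables and preserves semantics", {
  e <- parse_rule("Stimuli AND NOT CTLA4")
  s <- simplify_rule(e, c(Stimuli = 1))
  expect_false("Stimuli" %in% rule_vars(s))
  expect_true(exprs_equivalent(s, quote(!CTLA4)))

  expect_identical(simplify_rule(parse_rule("A AND NOT A")), FALSE)

  disc <- parse_rule("(Ceramide OR (Fas AND NOT FLIP)) AND NOT Apoptosis")
  expect_identical(simplify_rule(disc, c(Apoptosis = 1)), FALSE)

  # partial substitutions agree with the original on every completion
  withr::with_seed(5, {
    for (i in 1:25) {
      e <- random_expr(c("A", "B", "C", "D", "E"), depth = 4)
      part <- c(A = sample(0:1, 1), C = sample(0:1, 1))
      s <- simplify_rule(e, part)
      rest <- setdiff(rule_vars(e), names(part))
      grid <- expand.grid(rep(list(0:1), length(rest)))
      names(grid) <- rest
      for (r in seq_len(max(nrow(grid), 1))) {
        comp <- if (length(rest)) as.list(grid[r, , drop = FALSE]) else list()
        v1 <- eval_rule(e, c(as.list(part), comp))
        v2 <- if (is.logical(s)) as.integer(s) else eval_rule(s, comp)
        expect_identical(v1, v2)
      }
      # idempotence for a fixed partial assignment
      s2 <- if (is.logical(s)) s else simplify_rule(s, part)
      expect_true(identical(s, s2) ||
        exprs_equivalent(s, s2))
    }
  })
})

test_that("canonicalization produces absorbed OR-of-ANDs equivalent to the rule", {
  c1 <- to_canonical("(A AND B) OR C")
  expect_identical(c1$clauses, list(c("A", "B"), "C"))

  c2 <- to_canonical("NOT (A OR B)")
  expect_identical(c2$clauses, list(c("~A", "~B")))

  disc <- parse_rule("(Ceramide OR (Fas AND NOT FLIP)) AND NOT Apoptosis")
  c3 <- to_canonical(disc)
  expect_setequal(
    vapply(c3$clauses, paste, "", collapse = "&"),
    c("Ceramide&~Apoptosis", "Fas&~Apoptosis&~FLIP")
  )
  expect_true(exprs_equivalent(disc, canonical_to_expr(c3)))

  expect_error(to_canonical(parse_rule("A OR NOT A")), "constant")

  # absorption: no clause is a superset of another
  c4 <- to_canonical("A OR (A AND B)")
  expect_identical(c4$clauses, list("A"))
})

test_that("negation of canonical rules complements their semantics exactly", {
  expect_identical(negate_rule(to_canonical("A"))$clauses, list("~A"))
  expect_identical(
    negate_rule(to_canonical("A AND B"))$clauses,
    list("~A", "~B")
  )
  disc <- parse_rule("(Ceramide OR (Fas AND NOT FLIP)) AND NOT Apoptosis")
  nd <- negate_rule(to_canonical(disc))
  expect_true(exprs_equivalent(canonical_to_expr(nd), call("!", disc)))
  # double negation restores the truth table
  dd <- negate_rule(nd)
  expect_true(exprs_equivalent(canonical_to_expr(dd), disc))
})

test_that("canonicalization and negation preserve semantics on random rules", {
  withr::with_seed(23, {
    vars <- c("A", "B", "C", "D", "E", "F")
    for (i in 1:30) {
      e <- random_expr(vars, depth = 4)
      s <- simplify_rule(e)
      if (is.logical(s)) next
      cc <- to_canonical(s)
      expect_true(exprs_equivalent(e, canonical_to_expr(cc)))
      expect_true(exprs_equivalent(
        call("!", e),
        canonical_to_expr(negate_rule(cc))
      ))
    }
  })
})
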