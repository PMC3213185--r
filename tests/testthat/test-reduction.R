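test_that("survival-clause stripping substitutes death = OFF everywhere else", {
  net <- load_tlgl("tlgl6")
  s <- strip_survival_clause(net)
  expect_true(exprs_equivalent(
    s$rules$DISC,
    parse_rule("Ceramide OR (Fas AND NOT FLIP)")
  ))
  # the death node's own rule is untouched
  expect_identical(s$rules$Apoptosis, net$rules$Apoptosis)
  # rules not mentioning the death node are unchanged
  toy <- boolean_network(list(A = "B", B = "A AND NOT Apoptosis",
                              Apoptosis = "A"))
  st <- strip_survival_clause(toy)
  expect_identical(st$rules$A, toy$rules$A)
  expect_error(
    strip_survival_clause(motif_network("mutual-inhibition")),
    "Apoptosis"
  )
})

test_that("logical steady state analysis stabilizes 36 of the 60 T-LGL nodes", {
  net <- load_tlgl("tlgl60")
  tr <- logical_steady_state(strip_survival_clause(net))
  expect_length(tr$stabilized, 36L)
  expect_length(tr$residual$nodes, 18L)
  expect_identical(tr$stabilized[["Proliferation"]], 0L)
  expect_identical(tr$stabilized[["Cytoskeleton_signaling"]], 1L)
  expect_setequal(tr$residual$nodes, load_tlgl("tlgl18")$nodes)
})

test_that("stabilization is simple for chains and errors on contradictions", {
  net <- read_boolean_network(text = c("#@ source S = 1", "A* = S"))
  tr <- logical_steady_state(net)
  expect_identical(tr$stabilized, c(A = 1L))
  expect_null(tr$residual)
  expect_error(logical_steady_state(net, frozen = c(S = 0)), "contradictory")
})

test_that("stabilized values are update-order independent", {
  net <- load_tlgl("tlgl60")
  s <- strip_survival_clause(net)
  ref <- logical_steady_state(s)$stabilized
  withr::with_seed(7, {
    for (i in 1:3) {
      perm <- sample(s$nodes)
      shuffled <- boolean_network(
        s$rules[intersect(perm, names(s$rules))],
        s$sources,
        nodes = perm
      )
      got <- logical_steady_state(shuffled)$stabilized
      expect_identical(got[sort(names(got))], ref[sort(names(ref))])
    }
  })
})

test_that("mediator elimination reproduces the published 6-node sub-network", {
  bottom <- tlgl_bottom16()
  red <- remove_mediators(bottom,
    protect = "Apoptosis", also_remove = "P2",
    prefer = c("sFas", "MCL1", "IAP", "GPCR", "SMAD", "CREB",
               "BID", "Caspase", "IFNG")
  )
  n6 <- load_tlgl("tlgl6")
  expect_setequal(red$residual$nodes, n6$nodes)
  for (n in n6$nodes) {
    expect_true(exprs_equivalent(red$residual$rules[[n]], n6$rules[[n]]))
  }
  # P2's removal is annotated as a requested self-loop removal
  p2 <- red$removed[[1]]
  expect_identical(p2$node, "P2")
  expect_match(p2$note, "self-regulating")
})

test_that("a chain collapses and self-loops are never auto-removed", {
  chain <- boolean_network(
    list(B = "A", C = "B"),
    sources = c(A = NA)
  )
  red <- remove_mediators(chain, protect = "C")
  expect_true(exprs_equivalent(red$residual$rules$C, quote(A)))

  selfy <- boolean_network(list(A = "A OR B", B = "C", C = "B"))
  red2 <- remove_mediators(selfy, protect = character())
  expect_true("A" %in% red2$residual$nodes) # self-loop kept
})

test_that("reduction preserves fixed points of random networks (projection)", {
  withr::with_seed(99, {
    for (i in 1:20) {
      net <- random_boolean_network(
        sample(6:10, 1),
        n_sources = 2, p_negate = 0.4, p_self = 0.15
      )
      full_fp <- oracle_fixed_points(net)
      red <- remove_mediators(net, protect = character())
      res <- red$residual
      if (is.null(res)) next
      kept <- free_nodes(res)
      proj <- sort(unique(vapply(full_fp, function(s) {
        bits <- stats::setNames(
          as.integer(strsplit(s, "")[[1]]), free_nodes(net)
        )
        paste(bits[kept], collapse = "")
      }, "")))
      expect_identical(sort(fixed_points(res)), proj)
    }
  })
})

test_that("stabilized nodes hold their value in every attractor", {
  withr::with_seed(17, {
    for (i in 1:12) {
      net <- random_boolean_network(8, n_sources = 2, p_negate = 0.4)
      tr <- logical_steady_state(net)
      if (length(tr$stabilized) == 0L) next
      stg <- build_stg(net)
      att <- attractors(stg)
      for (k in seq_len(nrow(att))) {
        for (s in att$states[[k]]) {
          bits <- stats::setNames(
            as.integer(strsplit(s, "")[[1]]), free_nodes(net)
          )
          expect_identical(
            bits[names(tr$stabilized)],
            stats::setNames(tr$stabilized, names(tr$stabilized))
          )
        }
      }
    }
  })
})

test_that("reduced fixed points reconstruct to verified full fixed points", {
  bottom <- tlgl_bottom16()
  red <- remove_mediators(bottom,
    protect = "Apoptosis", also_remove = "P2",
    prefer = c("sFas", "MCL1", "IAP", "GPCR", "SMAD", "CREB",
               "BID", "Caspase", "IFNG")
  )
  n6order <- red$residual$nodes
  disease <- stats::setNames(
    as.integer(strsplit("110000", "")[[1]]),
    c("S1P", "FLIP", "Fas", "Ceramide", "DISC", "Apoptosis")
  )
  full <- reconstruct_state(red, disease[n6order], bottom)
  on <- names(full)[full == 1L]
  expect_setequal(on, c("sFas", "GPCR", "S1P", "SMAD", "MCL1", "FLIP", "IAP"))

  normal <- stats::setNames(
    as.integer(strsplit("000001", "")[[1]]),
    c("S1P", "FLIP", "Fas", "Ceramide", "DISC", "Apoptosis")
  )
  fulln <- reconstruct_state(red, normal[n6order], bottom)
  expect_identical(names(fulln)[fulln == 1L], "Apoptosis")

  # identity: an empty trace returns the input state
  empty <- remove_mediators(load_tlgl("tlgl6"), protect = load_tlgl("tlgl6")$nodes)
  st <- reconstruct_state(empty, disease, load_tlgl("tlgl6"))
  expect_identical(st[names(disease)], disease)

  # a non-fixed-point reduced state is rejected with guidance
  bad <- stats::setNames(c(1L, 1L, 1L, 1L, 1L, 0L), n6order)
  expect_error(reconstruct_state(red, bad, bottom), "not a fixed point")
})
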