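test_that("GA successors update one node at a time", {
  net <- load_tlgl("tlgl6")
  fixed <- ga_successors(net, "110000")
  expect_true(all(fixed$successor == "110000"))

  zero <- ga_successors(net, "000000")
  expect_setequal(
    unique(zero$successor),
    c("100000", "010000", "001000", "000000")
  )
  # self-loops for the three nodes whose update leaves 000000 unchanged
  expect_identical(sum(zero$successor == "000000"), 3L)

  toggle <- boolean_network(list(A = "NOT A"))
  expect_identical(ga_successors(toggle, "0")$successor, "1")
})

test_that("the state transition graph has 2^f states and f edges per state", {
  net <- load_tlgl("tlgl6")
  stg <- build_stg(net)
  expect_identical(nrow(stg$succ), 64L)
  expect_identical(ncol(stg$succ), 6L)

  const <- boolean_network(list(A = TRUE))
  expect_identical(nrow(build_stg(const)$succ), 2L)

  expect_error(build_stg(load_tlgl("tlgl60"), cap = 20), "reduce")
})

test_that("attractors are the terminal SCCs: T-LGL fixed points and the toggle", {
  stg <- build_stg(load_tlgl("tlgl6"))
  att <- attractors(stg)
  expect_identical(att$class, c("fixed-point", "fixed-point"))
  expect_setequal(unlist(att$states), c("000001", "110000"))

  # TCR/CTLA4 negative feedback: one 4-state complex attractor with mean ON
  # fraction 0.5 for both nodes
  fb <- boolean_network(list(TCR = "NOT CTLA4", CTLA4 = "TCR"))
  afb <- attractors(build_stg(fb))
  expect_identical(nrow(afb), 1L)
  expect_identical(afb$class, "complex")
  expect_identical(afb$n_states, 4L)
  expect_identical(unname(afb$on_fraction[[1]]), c(0.5, 0.5))

  self <- boolean_network(list(A = "A"))
  expect_setequal(unlist(attractors(build_stg(self))$states), c("0", "1"))
})

test_that("analytic fixed points match STG, brute-force and synchronous oracles", {
  expect_setequal(fixed_points(load_tlgl("tlgl6")), c("000001", "110000"))

  bottom <- tlgl_bottom16()
  fp16 <- fixed_points(bottom)
  expect_identical(length(fp16), 3L)
  # the two disease fixed points differ only in P2
  apo <- match("Apoptosis", free_nodes(bottom))
  p2 <- match("P2", free_nodes(bottom))
  disease <- fp16[substr(fp16, apo, apo) == "0"]
  expect_identical(length(disease), 2L)
  strip_p2 <- function(s) paste0(substr(s, 1, p2 - 1), substring(s, p2 + 1))
  expect_identical(strip_p2(disease[1]), strip_p2(disease[2]))

  expect_identical(fixed_points(boolean_network(list(A = "NOT A"))), character())

  withr::with_seed(41, {
    for (i in 1:15) {
      net <- random_boolean_network(
        sample(5:9, 1),
        n_sources = 1, p_negate = 0.4, p_self = 0.2
      )
      fp <- sort(fixed_points(net))
      expect_identical(fp, oracle_fixed_points(net))
      expect_identical(fp, oracle_sync_fixed_points(net))
      stg_fp <- attractors(build_stg(net))
      expect_identical(
        sort(as.character(unlist(stg_fp$states[stg_fp$class == "fixed-point"]))),
        fp
      )
      # the constraint solver agrees with exhaustive enumeration
      expect_identical(sort(fixed_points(net, cap = 0L)), fp)
    }
  })
})

test_that("exclusive basins are exact: 36/64 normal, 3/64 disease, 25 overlap", {
  stg <- build_stg(load_tlgl("tlgl6"))
  bas <- basin_partition(stg)
  tab <- bas$table
  normal <- tab[tab$attractor_state == "000001", ]
  disease <- tab[tab$attractor_state == "110000", ]
  expect_identical(normal$n_exclusive, 36L)
  expect_identical(round(normal$percent), 56)
  expect_identical(disease$n_exclusive, 3L)
  expect_identical(round(disease$percent), 5)
  expect_identical(bas$overlap$n, 25L)

  # every state with the death node ON lies in the normal exclusive basin
  states <- bas$states
  apop_on <- substr(states, 6, 6) == "1"
  only_normal <- bas$reaches[, tab$attractor_state == "000001"] &
    rowSums(bas$reaches) == 1L
  expect_true(all(only_normal[apop_on]))

  # single-attractor system: the exclusive basin is the whole state space
  one <- boolean_network(list(A = "B OR A", B = "A OR B"))
  b1 <- basin_partition(build_stg(one))
  expect_identical(sum(b1$table$n_exclusive), nrow(b1$reaches))
})

test_that("absorption probabilities solve the GA Markov chain exactly", {
  stg <- build_stg(load_tlgl("tlgl6"))
  att <- attractors(stg)
  ab <- absorption_probabilities(stg, att)
  # rows sum to one
  p <- as.matrix(ab[, -1])
  expect_true(all(abs(rowSums(p) - 1) < 1e-10))
  # exclusive-basin states absorb with probability one
  bas <- basin_partition(stg, att)
  excl_d <- bas$reaches[, 2] & rowSums(bas$reaches) == 1L
  dstates <- bas$states[excl_d]
  expect_true(all(abs(ab$p_110000[ab$state %in% dstates] - 1) < 1e-10))

  # the top shared-state probabilities: two at 3/4 and one at 25/36
  shared <- ab[rowSums(bas$reaches)[match(ab$state, bas$states)] > 1L, ]
  top <- sort(shared$p_110000, decreasing = TRUE)[1:3]
  expect_equal(top, c(3 / 4, 3 / 4, 25 / 36), tolerance = 1e-12)

  # Monte-Carlo oracle agrees within 3 standard errors
  withr::with_seed(2024, {
    for (s in c("010000", "000000")) {
      pexact <- ab$p_110000[ab$state == s]
      n_runs <- 400
      phat <- mc_absorption(load_tlgl("tlgl6"), s, "110000", n_runs = n_runs)
      se <- sqrt(pexact * (1 - pexact) / n_runs)
      expect_lt(abs(phat - pexact), 3 * se)
    }
  })
})

test_that("self-loops change neither exclusive basins nor absorption", {
  stg <- build_stg(load_tlgl("tlgl6"))
  att <- attractors(stg)
  bas <- basin_partition(stg, att)
  ab <- absorption_probabilities(stg, att)

  # renormalized chain without self-loops, built independently
  states <- bas$states
  n <- length(states)
  f <- ncol(stg$succ)
  fp_idx <- match(vapply(att$states, `[[`, "", 1), states)
  transient <- setdiff(seq_len(n), fp_idx)
  P <- matrix(0, n, n)
  for (j in seq_len(f)) {
    for (i in seq_len(n)) P[i, stg$succ[i, j]] <- P[i, stg$succ[i, j]] + 1 / f
  }
  diag(P)[transient] <- 0
  P[transient, ] <- P[transient, ] / rowSums(P[transient, , drop = FALSE])
  Q <- P[transient, transient]
  R <- P[transient, fp_idx]
  B <- solve(diag(length(transient)) - Q, R)
  expect_equal(unname(B[, 2]), ab$p_110000, tolerance = 1e-10)
})
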