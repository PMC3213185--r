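# In-silico perturbation screening. A permanent perturbation fixes one node
# in the opposite of its disease steady-state value (knockout for ON nodes,
# over-expression for OFF nodes) and asks which attractors the system
# retains when all possible initial states are considered.

#' Apply a node perturbation
#'
#' @param net a `boolean_network`.
#' @param node node to perturb; must not be a frozen source.
#' @param value 0 (knockout) or 1 (over-expression).
#' @param mode `"fix"` removes the node from the update set permanently;
#'   `"flip"` leaves the network unchanged and returns a start state with
#'   the node's value flipped once.
#' @param state for `mode = "flip"`: the state to flip (named 0/1 vector).
#' @return for `"fix"`: a `boolean_network` with the node frozen; for
#'   `"flip"`: `list(network = net, state = <flipped state>)`.
#' @export
apply_perturbation <- function(net, node, value, mode = c("fix", "flip"),
                               state = NULL) {
  mode <- match.arg(mode)
  if (!(node %in% net$nodes)) abort(sprintf("unknown node '%s'", node))
  if (node %in% names(frozen_assignment(net))) {
    abort(sprintf("'%s' is a frozen source and cannot be perturbed", node))
  }
  if (mode == "flip") {
    if (is.null(state)) abort("mode = \"flip\" needs a start state")
    state[[node]] <- value %||% (1L - state[[node]])
    return(list(network = net, state = state))
  }
  rules <- net$rules[setdiff(names(net$rules), node)]
  sources <- c(net$sources, stats::setNames(as.integer(value), node))
  boolean_network(rules, sources, nodes = net$nodes)
}

# ---- trap spaces -------------------------------------------------------------

#' Find a trap subcube with a seed assignment
#'
#' Searches for a closed partial assignment (a subcube such that every
#' assigned node's rule is constant and equal to its assigned value,
#' independent of the unassigned nodes) extending `seed`. A trap subcube
#' contains at least one attractor, and every attractor confined to a
#' subcube is found this way; the search is a stable-motif-style
#' branch-and-propagate over \{0, 1, free\}.
#'
#' @param net a `boolean_network` (the residual of a reduction, typically).
#' @param seed named 0/1 vector the trap must contain, e.g.
#'   `c(Apoptosis = 0)`.
#' @return a named integer vector (the closed assignment) or `NULL` when no
#'   such trap exists.
#' @export
find_trap_space <- function(net, seed) {
  fn <- free_nodes(net)
  base <- frozen_assignment(net)
  rules <- net$rules
  seed <- stats::setNames(as.integer(seed), names(seed))

  result <- NULL
  recurse <- function(sigma, osc) {
    repeat {
      offender <- NULL
      for (v in names(sigma)) {
        r <- rules[[v]]
        if (is.null(r)) next # free source: always consistent
        s <- simplify_rule(r, c(base, sigma))
        if (is.logical(s)) {
          if (as.integer(s) != sigma[[v]]) {
            return(FALSE)
          }
          next
        }
        vs <- setdiff(rule_vars(s), c(names(sigma), osc))
        if (length(vs) == 0L) {
          return(FALSE) # cannot settle: all remaining vars marked free
        }
        offender <- vs[[1L]]
        break
      }
      if (is.null(offender)) {
        result <<- sigma
        return(TRUE)
      }
      for (choice in list(0L, 1L, NA)) {
        if (is.na(choice)) {
          if (recurse(sigma, c(osc, offender))) {
            return(TRUE)
          }
        } else {
          s2 <- sigma
          s2[[offender]] <- choice
          if (recurse(s2, osc)) {
            return(TRUE)
          }
        }
      }
      return(FALSE)
    }
  }
  recurse(seed, character())
  result
}

# dependency ancestors of a target node within a network
node_ancestors <- function(net, target) {
  deps <- lapply(net$rules, function(r) intersect(rule_vars(r), net$nodes))
  anc <- target
  repeat {
    grow <- unique(unlist(deps[intersect(anc, names(deps))]))
    grow <- setdiff(grow, anc)
    if (length(grow) == 0L) break
    anc <- c(anc, grow)
  }
  anc
}

restrict_network <- function(net, nodes) {
  boolean_network(net$rules[intersect(nodes, names(net$rules))],
    sources = integer(),
    nodes = intersect(net$nodes, nodes)
  )
}

# states of an stg consistent with a partial assignment (indices)
cube_states <- function(stg, sigma) {
  sigma <- sigma[intersect(names(sigma), stg$free)]
  sm <- state_matrix(length(stg$free))
  ok <- rep(TRUE, nrow(sm))
  for (nm in names(sigma)) {
    ok <- ok & sm[, match(nm, stg$free)] == sigma[[nm]]
  }
  which(ok)
}

# states that can reach any of `targets` (backward closure, vectorized)
can_reach <- function(stg, targets) {
  r <- rep(FALSE, nrow(stg$succ))
  r[targets] <- TRUE
  repeat {
    prev <- r
    for (j in seq_len(ncol(stg$succ))) {
      r <- r | r[stg$succ[, j]]
    }
    if (identical(r, prev)) break
  }
  r
}

#' Classify the outcome of a permanent node perturbation
#'
#' Runs the full pipeline: remove the survival clause, freeze the sources
#' and the perturbed node, apply logical steady state analysis, restore the
#' survival clause on the residual, and decide which attractors survive.
#' The disease attractor is detected as a trap subcube with the death node
#' OFF; the exclusive basin of the normal (death-ON) attractor is measured
#' on the reduced state transition graph of the death node's regulatory
#' ancestors.
#'
#' Outcomes: `"normal"` (only the death-ON attractor remains), `"both"`,
#' or `"disease"` (the normal attractor is not reachable from any
#' biologically relevant, death-OFF, initial state).
#'
#' @param net the full `boolean_network` (e.g. `load_tlgl("tlgl60")`).
#' @param node node to perturb.
#' @param value the permanent value (opposite of the disease state).
#' @param survival_node the death output node.
#' @param stg_cap maximum free nodes for the reduced basin computation.
#' @return a one-row tibble: `node`, `value`, `outcome`,
#'   `basin_normal_pct`, `n_stabilized`, `n_residual`, `oscillating`
#'   (list), `method`.
#' @export
classify_outcome <- function(net, node, value, survival_node = "Apoptosis",
                             stg_cap = 20L) {
  stripped <- strip_survival_clause(net, survival_node)
  frozen <- c(
    frozen_assignment(net),
    stats::setNames(as.integer(value), node)
  )
  pert <- apply_perturbation(stripped, node, value)
  tr <- logical_steady_state(pert)
  known <- c(frozen_assignment(net), tr$stabilized,
             stats::setNames(as.integer(value), node))

  row <- function(outcome, pct, osc, method, n_res) {
    tibble(
      node = node, value = as.integer(value), outcome = outcome,
      basin_normal_pct = pct,
      n_stabilized = length(tr$stabilized), n_residual = n_res,
      oscillating = list(osc), method = method
    )
  }

  if (survival_node %in% names(known) && known[[survival_node]] == 1L) {
    return(row("normal", 100, character(), "steady-state", 0L))
  }

  # residual with the survival clause restored
  res_nodes <- setdiff(net$nodes, names(known))
  res_rules <- lapply(
    net$rules[intersect(res_nodes, names(net$rules))],
    simplify_rule,
    partial = known
  )
  residual <- boolean_network(res_rules, sources = integer(), nodes = res_nodes)
  n_res <- length(res_nodes)

  apo_rule <- residual$rules[[survival_node]]
  if (identical(apo_rule, as.symbol(survival_node))) {
    # the death node can never fire: the normal state, although a fixed
    # point, is cut off from every death-OFF initial state
    return(row("disease", 0, character(), "steady-state", n_res))
  }

  sigma <- find_trap_space(residual, stats::setNames(0L, survival_node))
  if (is.null(sigma)) {
    return(row("normal", 100, character(), "trap-space", n_res))
  }

  # oscillating nodes: residual nodes not forced by the trap whose rules do
  # not reduce to pure self-dependence (those are bistable memories)
  sig <- sigma
  repeat {
    forced <- FALSE
    for (v in setdiff(res_nodes, names(sig))) {
      s <- simplify_rule(residual$rules[[v]], sig)
      if (is.logical(s)) {
        sig[[v]] <- as.integer(s)
        forced <- TRUE
      }
    }
    if (!forced) break
  }
  osc <- character()
  for (v in setdiff(res_nodes, names(sig))) {
    s <- simplify_rule(residual$rules[[v]], sig)
    if (!identical(s, as.symbol(v))) osc <- c(osc, v)
  }

  # basin of the normal attractor on the reduced ancestor sub-network
  anc <- node_ancestors(residual, survival_node)
  sub <- restrict_network(residual, anc)
  red <- remove_mediators(sub, protect = survival_node)
  subnet <- red$residual
  pct <- NA_real_
  method <- "trap-space"
  if (!is.null(subnet) && length(free_nodes(subnet)) <= stg_cap) {
    stg <- build_stg(subnet, cap = stg_cap)
    cube <- sigma[intersect(names(sigma), stg$free)]
    reach_disease <- can_reach(stg, cube_states(stg, cube))
    pct <- 100 * sum(!reach_disease) / nrow(stg$succ)
    method <- "trap-space+stg"
  }
  row("both", pct, osc, method, n_res)
}

#' Disease steady state of a survival network
#'
#' Computes the stabilized values plus the disease trap of the residual
#' (death node OFF). Bistable memory nodes take their ON branch; nodes
#' oscillating in the disease attractor are `NA`.
#'
#' @param net the full `boolean_network`.
#' @param survival_node the death output node.
#' @return named integer vector over all non-source nodes (`NA` =
#'   oscillates).
#' @export
disease_steady_state <- function(net, survival_node = "Apoptosis") {
  stripped <- strip_survival_clause(net, survival_node)
  tr <- logical_steady_state(stripped)
  known <- c(frozen_assignment(net), tr$stabilized)
  res_nodes <- setdiff(net$nodes, names(known))
  res_rules <- lapply(
    net$rules[intersect(res_nodes, names(net$rules))],
    simplify_rule,
    partial = known
  )
  residual <- boolean_network(res_rules, sources = integer(), nodes = res_nodes)
  sigma <- find_trap_space(residual, stats::setNames(0L, survival_node))
  if (is.null(sigma)) {
    abort("network has no disease (death-OFF) attractor")
  }
  state <- c(tr$stabilized, sigma)
  repeat {
    forced <- FALSE
    for (v in setdiff(res_nodes, names(state))) {
      s <- simplify_rule(residual$rules[[v]], state[res_nodes[res_nodes %in% names(state)]])
      if (is.logical(s)) {
        state[[v]] <- as.integer(s)
        forced <- TRUE
      }
    }
    if (!forced) break
  }
  for (v in setdiff(res_nodes, names(state))) {
    s <- simplify_rule(residual$rules[[v]], state[intersect(res_nodes, names(state))])
    state[[v]] <- if (identical(s, as.symbol(v))) 1L else NA_integer_
  }
  out <- state[setdiff(net$nodes, names(frozen_assignment(net)))]
  stats::setNames(as.integer(out), names(out))
}

#' Systematic permanent-perturbation scan
#'
#' Fixes each eligible node in the opposite of its disease steady-state
#' value and classifies the outcome. Eligible nodes exclude the frozen
#' sources, the designated output nodes, and nodes that oscillate in the
#' disease attractor.
#'
#' @param net the full `boolean_network`.
#' @param disease_state named vector from [disease_steady_state()]
#'   (computed if missing).
#' @param outputs output nodes excluded from perturbation.
#' @param survival_node the death output node.
#' @param nodes optional explicit node subset.
#' @return a tibble with one row per perturbed node (see
#'   [classify_outcome()]), ordered by decreasing outcome severity.
#' @export
perturbation_scan <- function(net, disease_state = NULL,
                              outputs = intersect(
                                c("Apoptosis", "Proliferation",
                                  "Cytoskeleton_signaling"),
                                net$nodes
                              ),
                              survival_node = "Apoptosis",
                              nodes = NULL) {
  disease_state <- disease_state %||% disease_steady_state(net, survival_node)
  eligible <- nodes %||% setdiff(
    net$nodes,
    c(names(frozen_assignment(net)), outputs,
      names(disease_state)[is.na(disease_state)])
  )
  rows <- purrr::map(eligible, function(n) {
    classify_outcome(net, n, 1L - disease_state[[n]],
      survival_node = survival_node
    )
  })
  out <- dplyr::bind_rows(rows)
  out$outcome <- factor(out$outcome, levels = c("normal", "both", "disease"))
  dplyr::arrange(out, .data$outcome, dplyr::desc(.data$basin_normal_pct))
}

#' Compare structural and dynamic perturbation classifications
#'
#' Uses the dynamic classification as the standard: a node is
#' dynamic-positive when its perturbation leaves only the normal attractor.
#' The structural classification calls a node positive when its importance
#' value exceeds a threshold. Sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), reported over a threshold grid for both the cascading and
#' (optionally) non-cascading importance variants.
#'
#' @param importance tibble from [importance_scan()] (columns `node`,
#'   `importance`).
#' @param scan tibble from [perturbation_scan()] (columns `node`,
#'   `outcome`).
#' @param thresholds numeric grid.
#' @return tibble: `threshold`, `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`.
#' @export
compare_structural_dynamic <- function(importance, scan,
                                       thresholds = seq(0, 1, by = 0.05)) {
  extra <- setdiff(importance$node, scan$node)
  missing <- setdiff(scan$node, importance$node)
  if (length(extra) > 0L || length(missing) > 0L) {
    abort(sprintf(
      "candidate sets differ; only in importance: %s; only in scan: %s",
      paste(extra, collapse = ",") %|e|% "-",
      paste(missing, collapse = ",") %|e|% "-"
    ))
  }
  merged <- dplyr::inner_join(
    importance[, c("node", "importance")],
    scan[, c("node", "outcome")],
    by = "node"
  )
  pos <- merged$outcome == "normal"
  purrr::map_dfr(thresholds, function(th) {
    shat <- merged$importance > th
    tibble(
      threshold = th,
      tp = sum(shat & pos), fp = sum(shat & !pos),
      tn = sum(!shat & !pos), fn = sum(!shat & pos),
      sensitivity = sum(shat & pos) / sum(pos),
      specificity = sum(!shat & !pos) / sum(!pos)
    )
  })
}

`%|e|%` <- function(x, y) if (nzchar(x)) x else y
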