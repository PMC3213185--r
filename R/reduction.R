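# Two-step network reduction: (1) logical steady state analysis — iterative
# constant propagation from the frozen sources, which identifies nodes whose
# state stabilizes regardless of update order or initial condition; (2)
# elimination of simple mediator nodes (no self-loop, in- or out-degree at
# most one) by substituting their rule into their targets. Step (1) values
# hold in every attractor; step (2) preserves the fixed points.

#' Remove the global survival clause from a network
#'
#' Substitutes `node = 0` into every rule except `node`'s own, which removes
#' the `AND NOT Apoptosis` conjunct that the survival model attaches to every
#' rule. This isolates the dynamics of the living cell (the trajectory up to
#' the first activation of the death output).
#'
#' @param net a `boolean_network` containing `node`.
#' @param node the death/output node carrying the survival clause.
#' @return a `boolean_network` with the clause removed everywhere else.
#' @export
strip_survival_clause <- function(net, node = "Apoptosis") {
  if (!(node %in% net$nodes)) {
    abort(sprintf("network has no node named '%s'", node))
  }
  part <- stats::setNames(0L, node)
  rules <- net$rules
  for (nm in names(rules)) {
    if (nm != node) rules[[nm]] <- simplify_rule(rules[[nm]], part)
  }
  boolean_network(rules, net$sources, nodes = net$nodes)
}

#' Logical steady state analysis
#'
#' Iteratively substitutes all known constant node states into all rules
#' until no further rule collapses to a constant. Stabilized values are
#' update-order independent and hold in every attractor of the network.
#'
#' @param net a `boolean_network`.
#' @param frozen named 0/1 vector of frozen nodes; defaults to the network's
#'   frozen sources. Values for nodes that are already frozen differently
#'   are an error.
#' @return a `reduction_trace`: list with `stabilized` (named integer),
#'   `rounds` (stabilization round per node), `residual` (a
#'   `boolean_network` over the non-stabilized nodes), `removed` (empty
#'   here; filled by [remove_mediators()]).
#' @export
logical_steady_state <- function(net, frozen = frozen_assignment(net)) {
  frozen <- stats::setNames(as.integer(frozen), names(frozen))
  base <- frozen_assignment(net)
  clash <- intersect(names(frozen), names(base))
  if (any(frozen[clash] != base[clash])) {
    bad <- clash[frozen[clash] != base[clash]]
    abort(sprintf(
      "contradictory frozen assignment for: %s",
      paste(bad, collapse = ", ")
    ))
  }
  known <- c(base, frozen[setdiff(names(frozen), names(base))])
  rules <- net$rules
  # a perturbation may freeze a regulated node: drop its rule
  rules <- rules[setdiff(names(rules), names(known))]
  rounds <- stats::setNames(
    rep(0L, length(known)), names(known)
  )
  round <- 0L
  repeat {
    round <- round + 1L
    changed <- FALSE
    for (nm in names(rules)) {
      s <- simplify_rule(rules[[nm]], known)
      rules[[nm]] <- s
      if (is.logical(s)) {
        known[[nm]] <- as.integer(s)
        rounds[[nm]] <- round
        rules[[nm]] <- NULL
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  residual_nodes <- setdiff(net$nodes, names(known))
  residual <- if (length(rules) > 0L) {
    boolean_network(rules, sources = integer(), nodes = residual_nodes)
  } else {
    NULL
  }
  new_reduction_trace(
    stabilized = known[setdiff(names(known), names(base))],
    rounds = rounds[setdiff(names(known), names(base))],
    residual = residual,
    removed = list(),
    input = net
  )
}

new_reduction_trace <- function(stabilized, rounds, residual, removed, input) {
  structure(
    list(
      stabilized = stabilized, rounds = rounds,
      residual = residual, removed = removed, input = input
    ),
    class = "reduction_trace"
  )
}

#' @export
print.reduction_trace <- function(x, ...) {
  cat(sprintf(
    "<reduction_trace> %d stabilized, %d mediators removed, residual %s\n",
    length(x$stabilized), length(x$removed),
    if (is.null(x$residual)) "empty" else paste(length(x$residual$nodes), "nodes")
  ))
  invisible(x)
}

#' @export
tidy.reduction_trace <- function(x, ...) {
  dplyr::bind_rows(
    tibble(
      node = names(x$stabilized),
      action = "stabilized",
      value = as.integer(x$stabilized),
      round = as.integer(x$rounds[names(x$stabilized)]),
      rule = NA_character_
    ),
    tibble(
      node = vapply(x$removed, function(r) r$node, ""),
      action = "mediator-removed",
      value = NA_integer_,
      round = NA_integer_,
      rule = vapply(x$removed, function(r) write_rule(r$rule), "")
    )
  )
}

# in/out degrees of a residual network (free-node dependencies only)
node_degrees <- function(net) {
  deps <- lapply(net$rules, function(r) intersect(rule_vars(r), net$nodes))
  nodes <- net$nodes
  indeg <- vapply(nodes, function(n) {
    if (n %in% names(deps)) length(setdiff(deps[[n]], n)) else 0L
  }, integer(1))
  outdeg <- vapply(nodes, function(n) {
    sum(vapply(
      names(deps),
      function(m) m != n && n %in% deps[[m]], logical(1)
    ))
  }, integer(1))
  selfloop <- vapply(nodes, function(n) {
    n %in% names(deps) && n %in% deps[[n]]
  }, logical(1))
  list(indeg = indeg, outdeg = outdeg, selfloop = selfloop, deps = deps)
}

# replace occurrences of variable `name` inside `e` by expression `repl`
substitute_expr <- function(e, name, repl) {
  if (is.symbol(e)) {
    if (as.character(e) == name) {
      return(repl)
    }
    return(e)
  }
  if (is.call(e)) {
    for (k in seq.int(2L, length(e))) {
      e[[k]] <- substitute_expr(e[[k]], name, repl)
    }
  }
  e
}

#' Eliminate simple mediator nodes
#'
#' Iteratively removes nodes without a self-loop whose in-degree or
#' out-degree is at most one, substituting each removed node's rule into its
#' targets' rules and re-simplifying. This preserves the fixed points of the
#' system (reduced fixed points are the projections of full fixed points).
#' Self-regulating nodes are never removed automatically; a node listed in
#' `also_remove` is eliminated on request even if it carries a self-loop,
#' with its self-dependency resolved by case analysis being left to the
#' caller (the removal is annotated in the trace).
#'
#' @param net a `boolean_network` with no frozen constants left (run
#'   [logical_steady_state()] first).
#' @param protect nodes never removed; defaults to the conventional output
#'   nodes present in the network.
#' @param also_remove nodes to remove by explicit request (e.g. the virtual
#'   node P2, whose self-loop only encodes a memory effect).
#' @param prefer optional character vector: try these nodes first, in order,
#'   so a published elimination order can be reproduced.
#' @return a `reduction_trace` whose `removed` field lists each eliminated
#'   node with the rule that was substituted for it.
#' @export
remove_mediators <- function(net,
                             protect = intersect(
                               c("Apoptosis", "Proliferation",
                                 "Cytoskeleton_signaling"),
                               net$nodes
                             ),
                             also_remove = character(),
                             prefer = character()) {
  rules <- net$rules
  nodes <- net$nodes
  removed <- list()

  resimplify <- function(e) {
    s <- simplify_rule(e)
    if (is.logical(s)) {
      return(s)
    }
    canonical_to_expr(to_canonical(s))
  }

  drop_node <- function(nm, subst_with = NULL, record = NULL,
                        note = NA_character_) {
    rule <- record %||% rules[[nm]]
    repl <- subst_with %||% rules[[nm]]
    for (tgt in names(rules)) {
      if (tgt != nm && nm %in% rule_vars(rules[[tgt]])) {
        rules[[tgt]] <<- resimplify(substitute_expr(rules[[tgt]], nm, repl))
      }
    }
    rules[[nm]] <<- NULL
    nodes <<- setdiff(nodes, nm)
    removed[[length(removed) + 1L]] <<- list(node = nm, rule = rule, note = note)
  }

  for (nm in also_remove) {
    if (!(nm %in% nodes) || length(rules) == 0L) next
    cur <- boolean_network(rules, sources = net$sources, nodes = nodes)
    deg <- node_degrees(cur)
    if (deg$selfloop[[nm]]) {
      # a self-sustaining memory node: its targets see the OFF branch (the
      # memory has no influence on which attractor is reached, only on the
      # removed node's own recorded history)
      branch <- simplify_rule(substitute_expr(rules[[nm]], nm, FALSE))
      drop_node(nm,
        subst_with = FALSE, record = branch,
        note = "requested removal of self-regulating node (OFF branch)"
      )
    } else {
      drop_node(nm, note = "requested removal")
    }
  }

  repeat {
    if (length(rules) == 0L) break
    cur <- boolean_network(rules, sources = net$sources, nodes = nodes)
    deg <- node_degrees(cur)
    cand <- nodes[
      !(nodes %in% protect) & !deg$selfloop[nodes] &
        nodes %in% names(rules) &
        (deg$indeg[nodes] <= 1L | deg$outdeg[nodes] <= 1L)
    ]
    # a simple mediator must not sit on a feedback loop whose elimination
    # would create a new self-loop on a target (e.g. a 2-cycle partner)
    ok <- vapply(cand, function(n) {
      regs <- rule_vars(rules[[n]])
      tgts <- names(rules)[vapply(
        names(rules),
        function(m) m != n && n %in% rule_vars(rules[[m]]), logical(1)
      )]
      loopy <- intersect(tgts, regs)
      all(vapply(loopy, function(t) t %in% rule_vars(rules[[t]]), logical(1)))
    }, logical(1))
    cand <- cand[ok]
    cand <- c(intersect(prefer, cand), setdiff(cand, prefer))
    if (length(cand) == 0L) break
    drop_node(cand[[1L]])
  }

  residual <- if (length(rules) > 0L) {
    boolean_network(rules, sources = net$sources, nodes = nodes)
  } else {
    NULL
  }
  new_reduction_trace(
    stabilized = integer(), rounds = integer(),
    residual = residual, removed = removed, input = net
  )
}

#' Reconstruct a full-network state from a reduced one
#'
#' Extends a fixed point of a reduced network back to the full network:
#' stabilized nodes take their stabilized values, and removed mediators are
#' evaluated in reverse elimination order from their recorded rules. The
#' result is verified to be a fixed point of the full network.
#'
#' @param traces a `reduction_trace` or list of traces in the order they
#'   were applied (e.g. the LSSA trace then the mediator trace).
#' @param reduced_state named 0/1 vector (or bit string) over the final
#'   residual's free nodes.
#' @param full_network the original `boolean_network`.
#' @return named integer 0/1 vector over all nodes of `full_network`.
#' @export
reconstruct_state <- function(traces, reduced_state, full_network) {
  if (inherits(traces, "reduction_trace")) traces <- list(traces)
  if (is.character(reduced_state)) {
    last <- traces[[length(traces)]]
    nodes <- last$residual$nodes
    reduced_state <- stats::setNames(
      as.integer(strsplit(reduced_state, "")[[1]]), nodes
    )
  }
  state <- c(
    frozen_assignment(full_network),
    stats::setNames(as.integer(reduced_state), names(reduced_state))
  )
  for (tr in rev(traces)) {
    for (rm in rev(tr$removed)) {
      state[[rm$node]] <- eval_rule(rm$rule, state)
    }
    if (length(tr$stabilized) > 0L) {
      state <- c(state, tr$stabilized[setdiff(names(tr$stabilized), names(state))])
    }
  }
  missing <- setdiff(full_network$nodes, names(state))
  if (length(missing) > 0L) {
    abort(sprintf(
      "reconstruction incomplete; missing node(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  state <- state[full_network$nodes]
  # verify fixed point
  for (nm in names(full_network$rules)) {
    v <- eval_rule(full_network$rules[[nm]], state)
    if (v != state[[nm]]) {
      abort(sprintf(
        paste0(
          "reconstructed state is not a fixed point (node '%s' updates ",
          "%d -> %d); the reduced state is likely part of a complex ",
          "attractor - analyze the state transition graph instead"
        ),
        nm, state[[nm]], v
      ))
    }
  }
  state
}
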