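# Independent brute-force oracles used to validate the fast implementations.

# full truth table of an expression over the given variables, one state at a
# time (independent of the vectorized evaluation path)
oracle_truth_table <- function(expr, vars) {
  grid <- expand.grid(rep(list(0:1), length(vars)))
  names(grid) <- vars
  vapply(seq_len(nrow(grid)), function(i) {
    eval_rule(expr, as.list(grid[i, , drop = FALSE]))
  }, integer(1))
}

exprs_equivalent <- function(e1, e2, vars = union(rule_vars(e1), rule_vars(e2))) {
  if (length(vars) == 0L) {
    return(identical(isTRUE(e1), isTRUE(e2)))
  }
  identical(oracle_truth_table(e1, vars), oracle_truth_table(e2, vars))
}

# fixed points by explicit state-by-state check
oracle_fixed_points <- function(net) {
  fn <- free_nodes(net)
  frozen <- frozen_assignment(net)
  grid <- expand.grid(rep(list(0:1), length(fn)))
  names(grid) <- fn
  fps <- character()
  for (i in seq_len(nrow(grid))) {
    st <- as.list(grid[i, , drop = FALSE])
    env <- c(st, as.list(frozen))
    ok <- TRUE
    for (n in fn) {
      v <- if (n %in% names(net$rules)) eval_rule(net$rules[[n]], env) else st[[n]]
      if (v != st[[n]]) {
        ok <- FALSE
        break
      }
    }
    if (ok) fps <- c(fps, paste(unlist(st), collapse = ""))
  }
  sort(fps)
}

# one synchronous update step (all nodes simultaneously)
sync_step <- function(net, state) {
  fn <- free_nodes(net)
  env <- c(as.list(state), as.list(frozen_assignment(net)))
  out <- state
  for (n in fn) {
    if (n %in% names(net$rules)) out[[n]] <- eval_rule(net$rules[[n]], env)
  }
  out
}

# fixed points under synchronous update (states with sync_step(s) == s)
oracle_sync_fixed_points <- function(net) {
  fn <- free_nodes(net)
  grid <- expand.grid(rep(list(0:1), length(fn)))
  names(grid) <- fn
  fps <- character()
  for (i in seq_len(nrow(grid))) {
    st <- stats::setNames(as.integer(grid[i, ]), fn)
    if (identical(sync_step(net, st), st)) {
      fps <- c(fps, paste(st, collapse = ""))
    }
  }
  sort(fps)
}

# simple-path count by naive recursive enumeration over an edge data frame
oracle_count_paths <- function(edges, from, to) {
  adj <- split(edges$to, edges$from)
  count <- 0L
  onpath <- character()
  dfs <- function(u) {
    if (u == to) {
      count <<- count + 1L
      return(invisible(NULL))
    }
    onpath <<- c(onpath, u)
    for (w in adj[[u]] %||% character()) {
      if (!(w %in% onpath)) dfs(w)
    }
    onpath <<- onpath[-length(onpath)]
  }
  if (from %in% names(adj) || from == to) dfs(from)
  count
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random Boolean expression tree over the given variables
random_expr <- function(vars, depth = 3) {
  if (depth == 0L || stats::runif(1) < 0.3) {
    return(as.symbol(sample(vars, 1)))
  }
  op <- sample(c("&", "|", "!"), 1)
  if (op == "!") {
    return(call("!", random_expr(vars, depth - 1L)))
  }
  call(op, random_expr(vars, depth - 1L), random_expr(vars, depth - 1L))
}

# Monte-Carlo estimate of the absorption probability into a fixed point
mc_absorption <- function(net, start, target_fp, n_runs = 400, max_steps = 400) {
  fn <- free_nodes(net)
  frozen <- frozen_assignment(net)
  hits <- 0L
  for (r in seq_len(n_runs)) {
    st <- stats::setNames(as.integer(strsplit(start, "")[[1]]), fn)
    for (step in seq_len(max_steps)) {
      n <- sample(fn, 1)
      if (n %in% names(net$rules)) {
        st[[n]] <- eval_rule(net$rules[[n]], c(as.list(st), as.list(frozen)))
      }
      key <- paste(st, collapse = "")
      if (key == target_fp) {
        hits <- hits + 1L
        break
      }
    }
  }
  hits / n_runs
}

tlgl6_text <- c(
  "S1P* = NOT (Ceramide OR Apoptosis)",
  "FLIP* = NOT (DISC OR Apoptosis)",
  "Fas* = NOT (S1P OR Apoptosis)",
  "Ceramide* = Fas AND NOT (S1P OR Apoptosis)",
  "DISC* = (Ceramide OR (Fas AND NOT FLIP)) AND NOT Apoptosis",
  "Apoptosis* = DISC OR Apoptosis"
)

# the published dynamic therapeutic targets (perturbations whose outcome is
# the normal fixed point only)
dynamic_targets15 <- c(
  "DISC", "Ceramide", "Caspase", "SPHK1", "S1P", "PDGFR", "GAP", "RAS",
  "MEK", "ERK", "IL2RBT", "IL2RB", "STAT3", "BID", "MCL1"
)

tlgl_bottom16 <- function() {
  net18 <- load_tlgl("tlgl18")
  boolean_network(net18$rules[setdiff(names(net18$rules), c("TCR", "CTLA4"))])
}

tlgl_expanded <- function() {
  expand_network(load_tlgl("tlgl60"),
    free_inputs = "PDGF", outputs = "~Apoptosis",
    survival_node = "Apoptosis"
  )
}

tlgl_candidates <- function(net = load_tlgl("tlgl60")) {
  ds <- disease_steady_state(net)
  keep <- setdiff(
    names(ds),
    c("Apoptosis", "Proliferation", "Cytoskeleton_signaling", "TCR", "CTLA4")
  )
  perturbation_candidates(ds[keep])
}
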