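## ---- Influence diagram primitives -----------------------------------------
## A minimal discrete influence diagram: chance nodes with conditional
## probability tables (CPTs), decision nodes with alternatives, utility nodes
## with value tables. CPT and utility rows are ordered as expand.grid over
## the parent state lists in declared parent order (first parent varying
## fastest).

#' Construct a chance node
#'
#' @param name node identifier.
#' @param states ordered character vector of state labels.
#' @param parents character vector of parent node names (chance or decision).
#' @param cpt numeric matrix, one column per state, one row per parent-state
#'   combination (a single row for root nodes); rows sum to 1.
#' @param values optional numeric value per state, enabling expectations of
#'   the node itself.
#' @return A `chance_node` list.
#' @export
chance_node <- function(name, states, parents = character(), cpt,
                        values = NULL) {
  cpt <- matrix(as.numeric(cpt), ncol = length(states))
  structure(list(name = name, states = states, parents = parents,
                 cpt = cpt, values = values),
            class = "chance_node")
}

#' Construct a decision node
#'
#' @param name node identifier.
#' @param alternatives character vector of unique alternative labels.
#' @return A `decision_node` list.
#' @export
decision_node <- function(name, alternatives) {
  if (!length(alternatives) || anyDuplicated(alternatives))
    stop("alternatives must be non-empty and unique", call. = FALSE)
  structure(list(name = name, alternatives = alternatives),
            class = "decision_node")
}

#' Construct a utility node
#'
#' @param name node identifier.
#' @param parents character vector of parent node names.
#' @param table numeric vector of money values, one per parent-state
#'   combination (ordered as expand.grid over parent states, first parent
#'   varying fastest).
#' @return A `utility_node` list.
#' @export
utility_node <- function(name, parents, table) {
  structure(list(name = name, parents = parents, table = as.numeric(table)),
            class = "utility_node")
}

#' Assemble an influence diagram
#'
#' @param chance list of [chance_node()] objects.
#' @param decision list of [decision_node()] objects.
#' @param utility list of [utility_node()] objects.
#' @return An `influence_diagram` object.
#' @export
influence_diagram <- function(chance = list(), decision = list(),
                              utility = list()) {
  name_of <- function(x) vapply(x, `[[`, character(1), "name")
  structure(list(
    chance = setNames(chance, name_of(chance)),
    decision = setNames(decision, name_of(decision)),
    utility = setNames(utility, name_of(utility))
  ), class = "influence_diagram")
}

node_states <- function(diagram, name) {
  if (name %in% names(diagram$chance)) return(diagram$chance[[name]]$states)
  if (name %in% names(diagram$decision))
    return(diagram$decision[[name]]$alternatives)
  stop(sprintf("unknown node '%s'", name), call. = FALSE)
}

## Topological order of chance nodes (decision nodes are roots).
topological_order <- function(diagram) {
  nodes <- names(diagram$chance)
  deps <- lapply(diagram$chance, function(nd)
    intersect(nd$parents, nodes))
  order <- character(0)
  remaining <- nodes
  repeat {
    ready <- remaining[vapply(remaining, function(n)
      all(deps[[n]] %in% order), logical(1))]
    if (!length(ready)) break
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining))
    stop("diagram is cyclic: ", paste(remaining, collapse = ", "),
         call. = FALSE)
  order
}

#' Structural validation of an influence diagram
#'
#' Returns (rather than raises) a list of violations: unresolvable parents,
#' CPT dimension mismatches, CPT rows not summing to 1, utility tables not
#' covering all parent combinations, cycles among chance nodes, and utility
#' nodes used as parents.
#'
#' @param diagram an `influence_diagram`.
#' @param tol row-normalization tolerance.
#' @return Character vector of human-readable violations; empty if valid.
#' @export
validate_diagram <- function(diagram, tol = 1e-9) {
  v <- character(0)
  known <- c(names(diagram$chance), names(diagram$decision))
  all_parents <- function(nd) nd$parents %||% character()

  for (nd in c(diagram$chance, diagram$utility)) {
    bad <- setdiff(all_parents(nd), known)
    for (b in bad) {
      if (b %in% names(diagram$utility))
        v <- c(v, sprintf("node '%s': utility node '%s' used as parent",
                          nd$name, b))
      else
        v <- c(v, sprintf("node '%s': unresolvable parent '%s'", nd$name, b))
    }
  }

  for (nd in diagram$chance) {
    if (nd$name %in% all_parents(nd))
      v <- c(v, sprintf("node '%s': self-edge", nd$name))
    ok_parents <- intersect(all_parents(nd), known)
    expected_rows <- prod(vapply(ok_parents, function(p)
      length(node_states(diagram, p)), numeric(1)))
    if (nrow(nd$cpt) != expected_rows) {
      v <- c(v, sprintf("node '%s': CPT has %d rows, expected %d",
                        nd$name, nrow(nd$cpt), expected_rows))
      next
    }
    sums <- rowSums(nd$cpt)
    bad_rows <- which(abs(sums - 1) > tol)
    for (i in bad_rows)
      v <- c(v, sprintf("node '%s': CPT row %d sums to %.6f, not 1",
                        nd$name, i, sums[i]))
    if (any(nd$cpt < -tol | nd$cpt > 1 + tol))
      v <- c(v, sprintf("node '%s': CPT entries outside [0, 1]", nd$name))
  }

  for (nd in diagram$utility) {
    ok_parents <- intersect(nd$parents, known)
    expected <- prod(vapply(ok_parents, function(p)
      length(node_states(diagram, p)), numeric(1)))
    if (length(nd$table) != expected)
      v <- c(v, sprintf("utility '%s': table has %d entries, expected %d",
                        nd$name, length(nd$table), expected))
  }

  cyc <- tryCatch({ topological_order(diagram); NULL },
                  error = function(e) conditionMessage(e))
  if (!is.null(cyc)) v <- c(v, cyc)
  v
}

## Row index into a CPT/utility table for given parent state indices.
## idx: named list/data.frame of integer state indices per parent.
combo_index <- function(diagram, parents, idx) {
  if (!length(parents)) return(rep(1L, max(1L, nrow(as.data.frame(idx)))))
  sizes <- vapply(parents, function(p) length(node_states(diagram, p)),
                  numeric(1))
  out <- 1L
  mult <- 1L
  for (j in seq_along(parents)) {
    out <- out + (idx[[parents[j]]] - 1L) * mult
    mult <- mult * sizes[j]
  }
  out
}

## Joint distribution over all chance-node state combinations for a fixed
## decision. Returns list(grid = integer index data.frame, prob = vector).
enumerate_joint <- function(diagram, decision = NULL, evidence = list()) {
  if (length(diagram$decision)) {
    if (is.null(decision))
      stop("usage error: this diagram has a decision node; ",
           "select an alternative via `decision`", call. = FALSE)
    dn <- diagram$decision[[1]]
    if (!decision %in% dn$alternatives)
      stop(sprintf("unknown decision alternative '%s'", decision),
           call. = FALSE)
  }
  order <- topological_order(diagram)
  state_idx <- lapply(order, function(n)
    seq_along(diagram$chance[[n]]$states))
  names(state_idx) <- order
  grid <- do.call(expand.grid, c(state_idx, KEEP.OUT.ATTRS = FALSE))

  prob <- rep(1, nrow(grid))
  for (n in order) {
    nd <- diagram$chance[[n]]
    idx <- grid[intersect(nd$parents, names(grid))]
    for (p in setdiff(nd$parents, names(grid))) {     # decision parent
      idx[[p]] <- rep.int(match(decision, diagram$decision[[p]]$alternatives),
                          nrow(grid))
    }
    rows <- combo_index(diagram, nd$parents, idx)
    prob <- prob * nd$cpt[cbind(rows, grid[[n]])]
  }

  for (ev in names(evidence)) {
    if (ev %in% names(diagram$decision))
      stop("usage error: set the decision via `decision`, not evidence",
           call. = FALSE)
    states <- node_states(diagram, ev)
    s <- match(evidence[[ev]], states)
    if (is.na(s))
      stop(sprintf("unknown state '%s' for node '%s'", evidence[[ev]], ev),
           call. = FALSE)
    prob[grid[[ev]] != s] <- 0
  }
  z <- sum(prob)
  if (z <= 0) stop("evidence has zero probability", call. = FALSE)
  list(grid = grid, prob = prob / z)
}

## Numeric value of a target node per joint-state row.
target_values <- function(diagram, target, grid, decision) {
  if (target %in% names(diagram$utility)) {
    nd <- diagram$utility[[target]]
    idx <- grid[intersect(nd$parents, names(grid))]
    for (p in setdiff(nd$parents, names(grid)))
      idx[[p]] <- rep.int(match(decision, diagram$decision[[p]]$alternatives),
                          nrow(grid))
    return(nd$table[combo_index(diagram, nd$parents, idx)])
  }
  if (target %in% names(diagram$chance)) {
    nd <- diagram$chance[[target]]
    if (is.null(nd$values))
      stop(sprintf("chance node '%s' has no numeric state values", target),
           call. = FALSE)
    return(nd$values[grid[[target]]])
  }
  stop(sprintf("unknown node '%s'", target), call. = FALSE)
}

#' Exact expectation by enumeration
#'
#' Computes the expectation of a utility node, or of a numeric-valued chance
#' node, by summing over all unobserved chance-node state combinations.
#' Deterministic.
#'
#' @param diagram an `influence_diagram`.
#' @param target name of a utility node or numeric-valued chance node.
#' @param evidence named list mapping chance-node names to observed states.
#' @param decision decision alternative label (required when the diagram has
#'   a decision node).
#' @return The exact expected value.
#' @export
expected_value <- function(diagram, target, evidence = list(),
                           decision = NULL) {
  joint <- enumerate_joint(diagram, decision = decision, evidence = evidence)
  vals <- target_values(diagram, target, joint$grid, decision)
  sum(joint$prob * vals)
}

#' Marginal distribution of one node by enumeration
#'
#' @inheritParams expected_value
#' @param node a chance-node name.
#' @return Named probability vector over the node's states.
#' @export
node_marginal <- function(diagram, node, evidence = list(), decision = NULL) {
  joint <- enumerate_joint(diagram, decision = decision, evidence = evidence)
  states <- node_states(diagram, node)
  p <- vapply(seq_along(states), function(s)
    sum(joint$prob[joint$grid[[node]] == s]), numeric(1))
  setNames(p, states)
}

#' Ancestral Monte-Carlo sampling of an influence diagram
#'
#' Draws `n` joint samples of all chance nodes by ancestral sampling under a
#' fixed decision, and evaluates every utility node on each sample.
#' Identical seeds give identical tables.
#'
#' @param diagram an `influence_diagram`.
#' @param n number of samples (> 0).
#' @param seed integer seed for the sampler.
#' @param decision decision alternative label.
#' @return Data frame with one character column per chance node (sampled
#'   state labels) and one numeric column per utility node; the seed is
#'   recorded in attribute `"seed"`.
#' @export
sample_network <- function(diagram, n, seed, decision = NULL) {
  if (n <= 0) stop("usage error: n must be positive", call. = FALSE)
  if (length(diagram$decision) && is.null(decision))
    stop("usage error: select a decision alternative", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  order <- topological_order(diagram)
  idx <- list()
  for (nm in order) {
    nd <- diagram$chance[[nm]]
    pidx <- data.frame(row.names = seq_len(n))
    for (p in intersect(nd$parents, names(idx))) pidx[[p]] <- idx[[p]]
    for (p in setdiff(nd$parents, names(idx)))
      pidx[[p]] <- rep.int(match(decision,
                                 diagram$decision[[p]]$alternatives), n)
    rows <- if (length(nd$parents)) combo_index(diagram, nd$parents, pidx)
            else rep(1L, n)
    cum <- nd$cpt %*% upper.tri(diag(ncol(nd$cpt)), diag = TRUE)
    u <- stats::runif(n)
    idx[[nm]] <- as.integer(rowSums(u > cum[rows, , drop = FALSE])) + 1L
  }

  out <- as.data.frame(lapply(order, function(nm)
    diagram$chance[[nm]]$states[idx[[nm]]]), col.names = order,
    stringsAsFactors = FALSE)
  for (un in names(diagram$utility)) {
    nd <- diagram$utility[[un]]
    pidx <- data.frame(row.names = seq_len(n))
    for (p in intersect(nd$parents, names(idx))) pidx[[p]] <- idx[[p]]
    for (p in setdiff(nd$parents, names(idx)))
      pidx[[p]] <- rep.int(match(decision,
                                 diagram$decision[[p]]$alternatives), n)
    out[[un]] <- nd$table[combo_index(diagram, nd$parents, pidx)]
  }
  attr(out, "seed") <- seed
  out
}

#' Serialize an influence diagram to JSON
#'
#' Writes nodes, states, parents and probability/value tables as a plain
#' JSON structure for inspection and testing.
#'
#' @param diagram an `influence_diagram`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
diagram_to_json <- function(diagram, path = NULL) {
  obj <- list(
    chance = lapply(diagram$chance, function(nd)
      list(states = nd$states, parents = nd$parents,
           cpt = apply(nd$cpt, 1, as.numeric, simplify = FALSE),
           values = nd$values)),
    decision = lapply(diagram$decision, function(nd)
      list(alternatives = nd$alternatives)),
    utility = lapply(diagram$utility, function(nd)
      list(parents = nd$parents, table = nd$table))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
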