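#' Transition probability matrix of a rate matrix over time t
#'
#' Computes `P(t) = expm(Q t)` by eigendecomposition of `Q` (with a
#' scaling-and-squaring fallback when `Q` is near-defective).  `t = 0`
#' returns the identity without an exponential call, so zero-length branches
#' cost nothing and transmit states unchanged.
#'
#' @param Q Square rate matrix (rows sum to zero).
#' @param t Non-negative time (Myr).
#' @return Stochastic matrix: rows sum to 1, entries in `[0, 1]`.
#' @export
transition_matrix <- function(Q, t) {
  if (t < 0) abort("t must be non-negative")
  P <- cpp_pmats(as.matrix(Q), t)[, , 1]
  dimnames(P) <- dimnames(Q)
  P
}

#' Conditional likelihood vectors for the tips
#'
#' An observed state places unit mass on every composite state whose
#' observed part matches; an unknown (`NA`) tip is fully ambiguous and gets
#' an all-ones vector.
#'
#' @param traits Trait tibble (`tip`, `state`; `NA` = unknown).
#' @param model A `rate_model`.
#' @return Numeric matrix, composite states x tips (named columns).
#' @export
tip_partials <- function(traits, model) {
  sp <- model$space
  if (any(!is.na(traits$state) & (traits$state < 0 | traits$state >= sp$n_obs))) {
    abort("trait states outside the model's observed state space")
  }
  out <- vapply(traits$state, function(s) {
    if (is.na(s)) rep(1, sp$n_states) else as.numeric(sp$obs == s)
  }, numeric(sp$n_states))
  dimnames(out) <- list(sp$labels, traits$tip)
  out
}

#' Constrain the composite states allowed at a node
#'
#' Used to fix an ancestor: e.g. `node_constraint(node, observed = 1)`
#' forces the node to be trait-present in any rate class, mirroring a
#' fixed-ancestral-state analysis.  Disallowed states have their partial
#' likelihood zeroed at that node before the pruning pass combines it.
#'
#' @param node Node id (tips allowed).
#' @param observed Observed-state code(s) to allow (any class), or `NULL`.
#' @param states Explicit composite-state indices to allow, or `NULL`.
#'   Exactly one of `observed`/`states` must be given.
#' @return A `node_constraint` object.
#' @export
node_constraint <- function(node, observed = NULL, states = NULL) {
  if (is.null(observed) == is.null(states)) {
    abort("give exactly one of 'observed' or 'states'")
  }
  structure(list(node = as.integer(node), observed = observed, states = states),
            class = "node_constraint")
}

constraint_mask <- function(constraint, model) {
  sp <- model$space
  if (!is.null(constraint$states)) {
    if (!length(constraint$states) || any(constraint$states < 1 | constraint$states > sp$n_states)) {
      abort("constraint states outside the composite state space")
    }
    mask <- rep(0, sp$n_states)
    mask[constraint$states] <- 1
  } else {
    mask <- as.numeric(sp$obs %in% constraint$observed)
    if (!any(mask > 0)) abort("constraint allows no composite state")
  }
  mask
}

root_prior_vector <- function(root_prior, model, root_partial = NULL) {
  sp <- model$space
  if (is.numeric(root_prior)) {
    if (length(root_prior) != sp$n_states) abort("root prior vector length mismatch")
    if (any(root_prior < 0)) abort("root prior must be non-negative")
    s <- sum(root_prior)
    if (abs(s - 1) > 1e-8) abort("root prior must sum to 1")
    return(root_prior / s)
  }
  switch(root_prior,
    flat = rep(1 / sp$n_states, sp$n_states),
    stationary = abort("stationary prior is resolved inside tree_loglik"),
    fitzjohn = {
      if (is.null(root_partial) || sum(root_partial) <= 0) {
        rep(1 / sp$n_states, sp$n_states)
      } else {
        root_partial / sum(root_partial)
      }
    },
    abort(paste0("unknown root prior: ", root_prior))
  )
}

stationary_distribution <- function(Q) {
  s <- nrow(Q)
  A <- rbind(t(Q), rep(1, s))
  b <- c(rep(0, s), 1)
  pi <- tryCatch(as.numeric(qr.solve(A, b)), error = function(e) rep(1 / s, s))
  pi[pi < 0] <- 0
  if (sum(pi) <= 0) pi <- rep(1, s)
  pi / sum(pi)
}

# Precompiled likelihood closure: tip partials, constraint masks and the
# postorder edge list are computed once; each call only assembles Q and
# runs the C++ pruning pass.  Used by the optimizer and the grid scan.
loglik_factory <- function(phy, traits, model, root_prior = "flat",
                           constraints = NULL) {
  sp <- model$space
  ntip <- ape::Ntip(phy)
  nn <- n_nodes_total(phy)
  idx <- match(phy$tip.label, traits$tip)
  if (anyNA(idx)) {
    abort(paste0("tips without a trait entry: ",
                 paste(phy$tip.label[is.na(idx)], collapse = ", ")))
  }
  partials <- matrix(1, sp$n_states, nn)
  partials[, seq_len(ntip)] <- tip_partials(traits[idx, ], model)
  if (!is.null(constraints)) {
    if (inherits(constraints, "node_constraint")) constraints <- list(constraints)
    for (cn in constraints) {
      if (cn$node < 1 || cn$node > nn) abort("constraint node not in tree")
      partials[, cn$node] <- partials[, cn$node] * constraint_mask(cn, model)
    }
  }
  po <- postorder_edges(phy)
  rt <- root_node(phy)
  function(theta) {
    Q <- assemble_Q(model, theta)
    res <- cpp_pruning(po$edge, po$length, partials, Q, FALSE)
    d <- res$partials[, rt]
    pi <- if (identical(root_prior, "stationary")) {
      stationary_distribution(Q)
    } else {
      root_prior_vector(root_prior, model, root_partial = d)
    }
    L <- sum(pi * d)
    if (L <= 0) -Inf else log(L) + res$logscale
  }
}

# Shared plumbing: postorder pruning pass given assembled Q.
pruning_pass <- function(phy, traits, model, Q, constraints = NULL,
                         details = FALSE) {
  sp <- model$space
  ntip <- ape::Ntip(phy)
  nn <- n_nodes_total(phy)

  idx <- match(phy$tip.label, traits$tip)
  if (anyNA(idx)) {
    abort(paste0("tips without a trait entry: ",
                 paste(phy$tip.label[is.na(idx)], collapse = ", ")))
  }
  partials <- matrix(1, sp$n_states, nn)
  partials[, seq_len(ntip)] <- tip_partials(traits[idx, ], model)

  if (!is.null(constraints)) {
    if (inherits(constraints, "node_constraint")) constraints <- list(constraints)
    for (cn in constraints) {
      if (cn$node < 1 || cn$node > nn) abort("constraint node not in tree")
      partials[, cn$node] <- partials[, cn$node] * constraint_mask(cn, model)
    }
  }

  po <- postorder_edges(phy)
  res <- cpp_pruning(po$edge, po$length, partials, Q, details)
  res$edge <- po$edge
  res$edge_length <- po$length
  res$tip_partials <- partials
  res
}

#' Log-likelihood of tip data under a rate model (pruning algorithm)
#'
#' Post-order pruning with per-node rescaling; node constraints are applied
#' by zeroing disallowed composite states before a node's partial is
#' combined, and the root is handled according to `root_prior`.  Data that
#' are impossible under the model/constraints yield `-Inf` with
#' `impossible = TRUE` rather than an error.
#'
#' @param phy A rooted `phylo` with branch lengths in time units.
#' @param traits Trait tibble covering every tip (`NA` = unknown).
#' @param model A `rate_model`.
#' @param theta Rate vector (events/Myr).
#' @param root_prior `"flat"` (default), `"stationary"`, `"fitzjohn"`, or an
#'   explicit probability vector over composite states.
#' @param constraints A `node_constraint` or list of them, or `NULL`.
#' @return A `lik_result` list: `loglik`, `root_partial`, `logscale`,
#'   `root_prior_used`, `impossible`.
#' @export
tree_loglik <- function(phy, traits, model, theta, root_prior = "flat",
                        constraints = NULL) {
  Q <- assemble_Q(model, theta)
  res <- pruning_pass(phy, traits, model, Q, constraints)
  rt <- root_node(phy)
  d <- res$partials[, rt]

  pi <- if (identical(root_prior, "stationary")) {
    stationary_distribution(Q)
  } else {
    root_prior_vector(root_prior, model, root_partial = d)
  }
  L <- sum(pi * d)
  loglik <- if (L <= 0) -Inf else log(L) + res$logscale
  structure(
    list(
      loglik = loglik,
      root_partial = d,
      logscale = res$logscale,
      root_prior_used = if (is.character(root_prior)) root_prior else "user-vector",
      prior_vector = pi,
      impossible = !is.finite(loglik)
    ),
    class = "lik_result"
  )
}

#' @export
print.lik_result <- function(x, ...) {
  cat("<lik_result> lnL = ", format(x$loglik, digits = 10),
      "  (root prior: ", x$root_prior_used, ")\n", sep = "")
  invisible(x)
}
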