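#' Marginal ancestral state reconstruction
#'
#' Up-down algorithm: the post-order (pruning) pass supplies tipward
#' conditional likelihoods, a pre-order pass propagates rootward
#' information, and their product, normalised, is the posterior probability
#' of each composite state at every node given all tip data.
#'
#' @param phy Rooted `phylo`.
#' @param traits Trait tibble covering all tips.
#' @param model A `rate_model`.
#' @param theta Fitted rate vector.
#' @param root_prior As in [tree_loglik()].
#' @param constraints Optional node constraint(s).
#' @return A `reconstruction` (mode `"marginal"`) whose `probs` is a tibble
#'   with one row per node and one column per composite state.
#' @export
marginal_reconstruct <- function(phy, traits, model, theta,
                                 root_prior = "flat", constraints = NULL) {
  Q <- assemble_Q(model, theta)
  res <- pruning_pass(phy, traits, model, Q, constraints, details = TRUE)
  rt <- root_node(phy)
  nn <- n_nodes_total(phy)
  s <- model$space$n_states

  d <- res$partials[, rt]
  pi <- if (identical(root_prior, "stationary")) {
    stationary_distribution(Q)
  } else {
    root_prior_vector(root_prior, model, root_partial = d)
  }
  if (sum(pi * d) <= 0) abort("data impossible under this model/constraints")

  edge <- res$edge
  W <- res$W
  P <- res$P
  # edges grouped by parent for sibling-exclusion products
  by_parent <- split(seq_len(nrow(edge)), edge[, 1])

  down <- matrix(0, s, nn)
  down[, rt] <- pi
  # pre-order = reverse post-order
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    sibs <- setdiff(by_parent[[as.character(p)]], e)
    excl <- res$tip_partials[, p]  # constraint mask / internal ones
    for (e2 in sibs) excl <- excl * W[, e2]
    v <- as.numeric(crossprod(P[, , e], down[, p] * excl))
    m <- max(v)
    down[, ch] <- if (m > 0) v / m else v
  }

  probs <- res$partials * down
  cs <- colSums(probs)
  if (any(cs <= 0)) abort("zero posterior mass at some node (impossible data)")
  probs <- sweep(probs, 2, cs, "/")

  out <- tibble::as_tibble(t(probs), .name_repair = "minimal")
  names(out) <- model$space$labels
  out <- dplyr::bind_cols(tibble::tibble(node = seq_len(nn)), out)
  structure(
    list(mode = "marginal", probs = out, model = model, theta = theta,
         root_prior = if (is.character(root_prior)) root_prior else "user-vector",
         loglik = log(sum(pi * d)) + res$logscale),
    class = "reconstruction"
  )
}

#' Joint ancestral state reconstruction (max-product dynamic program)
#'
#' Finds the single assignment of composite states to all nodes that
#' maximises their joint probability given the tip data, by the standard
#' max-product tree DP with back-pointers (generalised to polytomies); the
#' root maximisation includes the root prior.  Ties are broken
#' deterministically by lowest composite-state index and logged.
#'
#' @inheritParams marginal_reconstruct
#' @return A `reconstruction` (mode `"joint"`) with `states` (per-node
#'   composite state index and label), `log_joint` (log of prior times path
#'   probabilities of the optimum) and `ties` (tibble of tied nodes).
#' @export
joint_reconstruct <- function(phy, traits, model, theta,
                              root_prior = "flat", constraints = NULL) {
  Q <- assemble_Q(model, theta)
  res <- pruning_pass(phy, traits, model, Q, constraints, details = TRUE)
  rt <- root_node(phy)
  nn <- n_nodes_total(phy)
  s <- model$space$n_states
  edge <- res$edge

  pi <- if (identical(root_prior, "stationary")) {
    stationary_distribution(Q)
  } else if (identical(root_prior, "fitzjohn")) {
    root_prior_vector("fitzjohn", model, root_partial = res$partials[, rt])
  } else {
    root_prior_vector(root_prior, model)
  }

  logP <- log(res$P)
  nodeL <- log(res$tip_partials)  # 0 / -Inf pattern at tips and masks
  bp <- vector("list", nn)
  tol <- 1e-12
  ties <- list()

  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    # C[sp] = max_sc logP[sp, sc] + nodeL[sc]; back-pointer per parent state
    scores <- sweep(logP[, , e], 2, nodeL[, ch], "+")
    Cc <- apply(scores, 1, max)
    arg <- rep(1L, s)
    # deterministic lowest-index tie-break + tie logging
    for (sp_i in seq_len(s)) {
      if (!is.finite(Cc[sp_i])) next  # parent state unusable; never followed
      tied <- which(scores[sp_i, ] >= Cc[sp_i] - tol)
      arg[sp_i] <- tied[1]
      if (length(tied) > 1L) {
        ties[[length(ties) + 1L]] <- tibble::tibble(
          node = ch, parent_state = sp_i, tied_states = list(tied)
        )
      }
    }
    bp[[ch]] <- arg
    nodeL[, p] <- nodeL[, p] + Cc
  }

  root_scores <- log(pi) + nodeL[, rt]
  if (all(!is.finite(root_scores))) abort("data impossible under this model/constraints")
  best_root <- which(root_scores >= max(root_scores) - tol)
  if (length(best_root) > 1L) {
    ties[[length(ties) + 1L]] <- tibble::tibble(
      node = rt, parent_state = NA_integer_, tied_states = list(best_root)
    )
  }
  assign <- integer(nn)
  assign[rt] <- best_root[1]
  for (e in rev(seq_len(nrow(edge)))) {  # pre-order
    p <- edge[e, 1]; ch <- edge[e, 2]
    assign[ch] <- bp[[ch]][assign[p]]
  }

  states <- tibble::tibble(
    node = seq_len(nn),
    state = assign,
    label = model$space$labels[assign],
    observed = model$space$obs[assign],
    class = model$space$classes[model$space$class[assign]]
  )
  structure(
    list(mode = "joint", states = states, model = model, theta = theta,
         log_joint = max(root_scores),
         ties = if (length(ties)) dplyr::bind_rows(ties) else tibble::tibble(),
         root_prior = if (is.character(root_prior)) root_prior else "user-vector"),
    class = "reconstruction"
  )
}

#' Collapse composite states to observed states
#'
#' Hidden classes are nuisance structure when reporting trait history:
#' joint assignments map to their observed part, and marginal probabilities
#' sum over classes.
#'
#' @param rec A `reconstruction`.
#' @return For joint mode, a tibble `node`, `observed` (code) and
#'   `observed_label`; for marginal mode additionally one probability
#'   column per observed state.
#' @export
collapse_to_observed <- function(rec) {
  stopifnot(inherits(rec, "reconstruction"))
  sp <- rec$model$space
  if (rec$mode == "joint") {
    tibble::tibble(
      node = rec$states$node,
      observed = rec$states$observed,
      observed_label = sp$obs_labels[rec$states$observed + 1L]
    )
  } else {
    pm <- as.matrix(rec$probs[, -1])
    obs_p <- vapply(seq_len(sp$n_obs) - 1L, function(o) {
      rowSums(pm[, sp$obs == o, drop = FALSE])
    }, numeric(nrow(pm)))
    colnames(obs_p) <- sp$obs_labels
    out <- tibble::tibble(
      node = rec$probs$node,
      observed = max.col(obs_p, ties.method = "first") - 1L,
      observed_label = sp$obs_labels[max.col(obs_p, ties.method = "first")]
    )
    dplyr::bind_cols(out, tibble::as_tibble(obs_p))
  }
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("<reconstruction> mode = ", x$mode, ", model = ", x$model$name, "\n", sep = "")
  if (x$mode == "joint") {
    cat("  log joint score: ", format(x$log_joint, digits = 10),
        if (nrow(x$ties)) paste0("  (", nrow(x$ties), " ties logged)"), "\n", sep = "")
  } else {
    cat("  lnL of data: ", format(x$loglik, digits = 10), "\n", sep = "")
  }
  invisible(x)
}

#' Write a reconstruction as an annotated newick tree
#'
#' Internal node labels carry the observed-state call at each node, so the
#' reconstruction can travel with the topology into standard tree viewers.
#'
#' @param rec A joint-mode `reconstruction` (marginal calls use the
#'   highest-probability observed state).
#' @param phy The tree the reconstruction was computed on.
#' @param file Optional output path.
#' @return Newick string, invisibly when written to file.
#' @export
write_annotated_newick <- function(rec, phy, file = NULL) {
  calls <- collapse_to_observed(rec)
  ntip <- ape::Ntip(phy)
  phy$node.label <- calls$observed_label[calls$node > ntip]
  write_newick(phy, file = file)
}
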