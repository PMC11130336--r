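#' Simulate an ultrametric birth-death tree
#'
#' Constant-rate birth-death tree conditioned on `n_tips` surviving tips
#' (via [ape::rphylo()]); tip labels are `t1..tn` and all root-to-tip path
#' lengths are equal.  Deterministic given `seed`.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth,death Speciation and extinction rates (events/Myr);
#'   `birth > death >= 0`.
#' @param seed RNG seed.
#' @return A rooted ultrametric `phylo`.
#' @export
simulate_tree <- function(n_tips, birth = 0.1, death = 0, seed = 1) {
  if (n_tips < 2) abort("n_tips must be at least 2")
  if (death < 0 || birth <= death) abort("need birth > death >= 0")
  set.seed(seed)
  phy <- ape::rphylo(n_tips, birth = birth, death = death)
  phy$tip.label <- paste0("t", seq_len(n_tips))
  phy
}

#' Simulate a trait history along a tree with event-level truth
#'
#' Exact continuous-time simulation: along every edge, waiting times are
#' exponential with the current composite state's total exit rate and the
#' destination is drawn by relative rates (Gillespie along branches).  The
#' full event chain is recorded, so reconstruction and counting methods can
#' be validated against ground truth rather than against themselves.
#'
#' `clade_states` forces the composite state at the top of chosen subtrees
#' (after the parent edge has been simulated), emulating clade-localised
#' innovations such as a precursor state arising at one ancestor.
#'
#' @param phy Rooted `phylo`.
#' @param model A `rate_model`.
#' @param theta Rate vector (events/Myr).
#' @param root_state Composite state index at the root.
#' @param seed RNG seed.
#' @param clade_states Optional named integer vector: node id (as name) ->
#'   forced composite state at that node.
#' @return A `sim_history`: `traits` tibble (tip, observed state),
#'   `node_states` (true composite state per node), `events` tibble (edge,
#'   child node, time along edge, from, to), `edge_obs_changes` (true count
#'   of observed-state changes per edge row of `phy$edge`), `seed`,
#'   `theta`, model name.
#' @export
simulate_trait_history <- function(phy, model, theta, root_state = 1,
                                   seed = 1, clade_states = NULL) {
  sp <- model$space
  Q <- assemble_Q(model, theta)
  s <- sp$n_states
  if (root_state < 1 || root_state > s) abort("root_state outside the state space")
  nn <- n_nodes_total(phy)
  rt <- root_node(phy)
  set.seed(seed)

  node_state <- integer(nn)
  node_state[rt] <- as.integer(root_state)
  forced <- if (!is.null(clade_states)) {
    setNames(as.integer(clade_states), names(clade_states))
  } else NULL
  if (!is.null(forced) && as.character(rt) %in% names(forced)) {
    node_state[rt] <- forced[[as.character(rt)]]
  }

  edge <- phy$edge
  elen <- phy$edge.length
  # pre-order (reverse post-order) so each parent state is known first
  po <- postorder_edges(phy)
  events <- list()
  edge_obs_changes <- integer(nrow(edge))
  # map rows of the postorder edge matrix back to phy$edge rows
  key <- paste(edge[, 1], edge[, 2])
  po_to_phy <- match(paste(po$edge[, 1], po$edge[, 2]), key)

  for (e in rev(seq_len(nrow(po$edge)))) {
    phy_e <- po_to_phy[e]
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    st <- node_state[p]
    t_now <- 0
    len <- po$length[e]
    repeat {
      exit <- -Q[st, st]
      if (exit <= 0) break
      dt <- stats::rexp(1, exit)
      if (t_now + dt > len) break
      t_now <- t_now + dt
      rates <- Q[st, ]
      rates[st] <- 0
      to <- sample.int(s, 1, prob = rates)
      events[[length(events) + 1L]] <- tibble::tibble(
        edge = phy_e, child = ch, time = t_now, from = st, to = to
      )
      if (sp$obs[st] != sp$obs[to]) {
        edge_obs_changes[phy_e] <- edge_obs_changes[phy_e] + 1L
      }
      st <- to
    }
    node_state[ch] <- st
    if (!is.null(forced) && as.character(ch) %in% names(forced)) {
      node_state[ch] <- forced[[as.character(ch)]]
    }
  }

  ntip <- ape::Ntip(phy)
  traits <- tibble::tibble(
    tip = phy$tip.label,
    state = sp$obs[node_state[seq_len(ntip)]]
  )
  attr(traits, "n_obs") <- sp$n_obs
  structure(
    list(
      traits = traits,
      node_states = node_state,
      events = if (length(events)) dplyr::bind_rows(events) else
        tibble::tibble(edge = integer(), child = integer(), time = numeric(),
                       from = integer(), to = integer()),
      edge_obs_changes = edge_obs_changes,
      seed = seed, theta = theta, model = model$name
    ),
    class = "sim_history"
  )
}

#' Mask a fraction of tip states as unknown
#'
#' @param traits Trait tibble.
#' @param fraction Fraction of tips set to unknown (`0 <= fraction < 1`);
#'   the count is `round(fraction * n)`.
#' @param seed RNG seed (same seed, same mask).
#' @return The trait tibble with the chosen `state` entries set to `NA`.
#' @export
mask_states <- function(traits, fraction, seed = 1) {
  if (fraction < 0 || fraction >= 1) abort("fraction must be in [0, 1)")
  n <- nrow(traits)
  n_mask <- round(fraction * n)
  if (n_mask > 0) {
    set.seed(seed)
    traits$state[sample.int(n, n_mask)] <- NA_integer_
  }
  traits
}

#' Default rate profile for the two-step pathway generator
#'
#' Rates (events/Myr) for a binary three-class model whose qualitative
#' ordering matches the inferred two-step pathway: gain from the
#' intermediary class is 10x faster than the precursor -> intermediary
#' shift; loss of the trait is 150x slower than gain; the precursor loses
#' lability (falls into the absorbing non-precursor class) more readily
#' than it gains it; and the intermediary is as likely to fall back to the
#' precursor as it is to gain the trait.
#'
#' @return Named numeric vector of the six non-zero rates.
#' @export
nfc_rate_profile <- function() {
  gain_inter <- 0.02
  c(
    gain_intermediary = gain_inter,          # absent|R3 -> present|R3
    prec_to_inter = gain_inter / 10,         # absent|R2 -> absent|R3
    prec_to_nonprec = 2 * gain_inter / 10,   # absent|R2 -> absent|R1 (lability lost)
    inter_to_prec = gain_inter,              # absent|R3 -> absent|R2
    loss = gain_inter / 150,                 # present|R3 -> absent|R3
    present_to_nonprec_class = gain_inter / 150  # present class decay toward R1
  )
}

# Build (model, theta) for the generator from a named profile.
nfc_generator_model <- function(profile = nfc_rate_profile()) {
  model <- build_hidden_rates_model(2, 3, no_gain_class = "R1")
  sp <- model$space
  theta <- rep(0, model$n_par)
  setq <- function(o_from, r_from, o_to, r_to, v) {
    i <- composite_index(sp, o_from, r_from)
    j <- composite_index(sp, o_to, r_to)
    idx <- model$index[i, j]
    stopifnot(idx > 0)
    theta[idx] <<- v
  }
  setq(0L, 3L, 1L, 3L, profile[["gain_intermediary"]])
  setq(0L, 2L, 0L, 3L, profile[["prec_to_inter"]])
  setq(0L, 2L, 0L, 1L, profile[["prec_to_nonprec"]])
  setq(0L, 3L, 0L, 2L, profile[["inter_to_prec"]])
  setq(1L, 3L, 0L, 3L, profile[["loss"]])
  setq(1L, 3L, 1L, 1L, profile[["present_to_nonprec_class"]])
  list(model = model, theta = theta)
}

#' Generate a fixture emulating the nitrogen-fixing clade's structure
#'
#' Simulates an ultrametric tree, seeds the precursor state at the ancestor
#' of an ingroup clade (roughly half the tips) while the rest of the tree
#' starts in the absorbing non-precursor state, and runs the two-step
#' pathway model forward.  The truth must contain at least `min_gains`
#' distinct observed gains; otherwise the history is regenerated with an
#' incremented seed (count reported), so the fixture always exercises the
#' multiple-gain regime the generator is meant to emulate.
#'
#' @param n_tips Number of tips (>= 100; default 1000).
#' @param profile Named rate vector as from [nfc_rate_profile()].
#' @param unknown_fraction Fraction of tips masked to unknown
#'   (default 0.05, a realistic level of unscored genera).
#' @param seed Master seed; named substreams for tree, history and mask are
#'   derived from it.
#' @param min_gains Minimum number of true observed gains (default 2).
#' @param max_regen Maximum history regenerations before erroring.
#' @param birth,death Tree simulation rates.
#' @return A `fixture_bundle`: `phy`, `traits` (masked), `traits_full`,
#'   `history`, `model`, `theta`, `clades` (outgroup/ingroup tip labels),
#'   `ingroup_mrca`, `n_regen`, `seed`.
#' @export
make_nfc_like_fixture <- function(n_tips = 1000, profile = nfc_rate_profile(),
                                  unknown_fraction = 0.05, seed = 1,
                                  min_gains = 2, max_regen = 50,
                                  birth = 0.1, death = 0.025) {
  if (n_tips < 100) abort("n_tips must be at least 100 for an NFC-like fixture")
  phy <- simulate_tree(n_tips, birth = birth, death = death, seed = seed * 19 + 1)
  gm <- nfc_generator_model(profile)
  sp <- gm$model$space

  # ingroup = internal node whose clade is closest to half the tips
  internal <- (ape::Ntip(phy) + 2L):n_nodes_total(phy)
  sizes <- vapply(internal, function(nd) length(clade_tips(phy, nd)), integer(1))
  ingroup_mrca <- internal[which.min(abs(sizes - n_tips / 2))]
  ingroup_tips <- phy$tip.label[clade_tips(phy, ingroup_mrca)]
  outgroup_tips <- setdiff(phy$tip.label, ingroup_tips)

  root_np <- composite_index(sp, 0L, 1L)      # absent, non-precursor
  ingroup_prec <- composite_index(sp, 0L, 2L) # absent, precursor

  n_regen <- 0L
  repeat {
    hist_seed <- seed * 19 + 2 + n_regen
    history <- simulate_trait_history(
      phy, gm$model, gm$theta, root_state = root_np, seed = hist_seed,
      clade_states = setNames(ingroup_prec, ingroup_mrca)
    )
    true_gains <- sum(history$events$from %in% which(sp$obs == 0L) &
                        history$events$to %in% which(sp$obs == 1L))
    if (true_gains >= min_gains) break
    n_regen <- n_regen + 1L
    if (n_regen > max_regen) {
      abort(paste0("could not obtain >= ", min_gains, " gains in ",
                   max_regen, " regenerations"))
    }
  }
  traits <- mask_states(history$traits, unknown_fraction, seed = seed * 19 + 1000)
  structure(
    list(
      phy = phy, traits = traits, traits_full = history$traits,
      history = history, model = gm$model, theta = gm$theta,
      clades = list(outgroup = outgroup_tips, ingroup = ingroup_tips),
      ingroup_mrca = ingroup_mrca, n_regen = n_regen, seed = seed
    ),
    class = "fixture_bundle"
  )
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture_bundle> ", ape::Ntip(x$phy), " tips, ingroup of ",
      length(x$clades$ingroup), " at node ", x$ingroup_mrca,
      ", ", x$n_regen, " regenerations\n", sep = "")
  invisible(x)
}

#' Serialize a fixture bundle to a directory of plain-text files
#'
#' Writes `tree.nwk`, `traits.csv`, `truth.json`, `model.json` and a small
#' `README` listing the generator parameters.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(bundle$phy, file.path(dir, "tree.nwk"))
  tr <- bundle$traits
  tr$state <- ifelse(is.na(tr$state), "?", as.character(tr$state))
  readr::write_csv(tr, file.path(dir, "traits.csv"))
  jsonlite::write_json(
    list(
      node_states = bundle$history$node_states,
      events = bundle$history$events,
      edge_obs_changes = bundle$history$edge_obs_changes,
      seed = bundle$seed, n_regen = bundle$n_regen
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  model_to_json(bundle$model, theta = bundle$theta,
                file = file.path(dir, "model.json"))
  writeLines(c(
    "NFC-like synthetic fixture",
    paste0("tips: ", ape::Ntip(bundle$phy)),
    paste0("seed: ", bundle$seed),
    paste0("ingroup MRCA node: ", bundle$ingroup_mrca),
    paste0("regenerations: ", bundle$n_regen)
  ), file.path(dir, "README"))
  invisible(dir)
}
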