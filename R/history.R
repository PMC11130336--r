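#' Count observed-state transitions along edges of a joint reconstruction
#'
#' Every edge whose parent and child differ in observed state (after
#' collapsing hidden classes) contributes one event; gains are
#' absent -> present changes and losses the reverse.  Because an edge can
#' hide a change-and-reversal, these tallies are conservative minima, which
#' the returned object flags.
#'
#' @param phy Rooted `phylo`.
#' @param rec A joint-mode `reconstruction` on `phy`.
#' @return A `transition_summary`: `events` tibble (edge, parent, child,
#'   from/to observed state), `totals` tibble per directed observed pair
#'   with gain/loss annotation, `n_gains`, `n_losses`, `minimum_counts =
#'   TRUE`.
#' @export
count_transitions <- function(phy, rec) {
  stopifnot(inherits(rec, "reconstruction"))
  if (rec$mode != "joint") {
    abort("count_transitions needs a joint reconstruction (marginal given)")
  }
  sp <- rec$model$space
  obs <- rec$states$observed[order(rec$states$node)]
  em <- phy$edge
  from <- obs[em[, 1]]
  to <- obs[em[, 2]]
  changed <- which(from != to)
  events <- tibble::tibble(
    edge = changed,
    parent = em[changed, 1],
    child = em[changed, 2],
    from = from[changed],
    to = to[changed],
    from_label = sp$obs_labels[from[changed] + 1L],
    to_label = sp$obs_labels[to[changed] + 1L]
  )
  totals <- events |>
    dplyr::count(.data$from, .data$to, .data$from_label, .data$to_label,
                 name = "n") |>
    dplyr::arrange(.data$from, .data$to)
  n_gains <- sum(events$from == 0L & events$to > 0L)
  n_losses <- sum(events$from > 0L & events$to == 0L)
  structure(
    list(events = events, totals = totals,
         n_gains = n_gains, n_losses = n_losses,
         minimum_counts = TRUE, n_edges = nrow(em)),
    class = "transition_summary"
  )
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("<transition_summary> ", nrow(x$events), " events on ", x$n_edges,
      " edges: ", x$n_gains, " gains, ", x$n_losses, " losses",
      " (minimum-change counts)\n", sep = "")
  invisible(x)
}

#' Tabulate transition events by named clade
#'
#' Each event is assigned to the smallest named clade whose subtree
#' contains the event's edge (both endpoints); events outside all named
#' clades fall into an `"(unassigned)"` row, so the clade totals always
#' conserve the overall gain/loss counts.
#'
#' @param phy Rooted `phylo`.
#' @param summary A `transition_summary`.
#' @param clades Named list: clade name -> character vector of tip labels
#'   whose MRCA defines the clade.
#' @return Tibble with columns `clade`, `gains`, `losses`, `events`.
#' @export
tabulate_clade_events <- function(phy, summary, clades) {
  stopifnot(inherits(summary, "transition_summary"))
  mrcas <- purrr::imap_int(clades, function(tips, nm) as.integer(find_mrca(phy, tips)))
  sizes <- purrr::map_int(mrcas, function(nd) length(clade_tips(phy, nd)))
  # membership: a node is inside a clade when the clade MRCA lies on its root path
  assign_clade <- function(parent_node) {
    path <- root_path(phy, parent_node)
    hit <- names(mrcas)[mrcas %in% path]
    if (!length(hit)) return("(unassigned)")
    hit[which.min(sizes[hit])]
  }
  ev <- summary$events
  cl <- if (nrow(ev)) vapply(ev$parent, assign_clade, character(1)) else character(0)
  ev$clade <- cl
  base <- tibble::tibble(clade = c(names(clades), "(unassigned)"))
  tab <- ev |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(
      gains = sum(.data$from == 0L & .data$to > 0L),
      losses = sum(.data$from > 0L & .data$to == 0L),
      events = dplyr::n()
    )
  out <- dplyr::left_join(base, tab, by = "clade") |>
    dplyr::mutate(dplyr::across(c("gains", "losses", "events"),
                                ~ dplyr::coalesce(.x, 0L)))
  out
}

#' Label the hidden classes of a fitted three-class binary model
#'
#' Heuristic naming of the roles in the two-step pathway: the class whose
#' exit rates from the absent state are all negligible is the
#' "non-precursor" (an absorbing absent state with no path to gain); the
#' class with the largest gain rate is the "intermediary"; the remaining
#' class is the "precursor".
#'
#' @param fit An `hrm_fit` of a binary three-class hidden-rates model.
#' @param negligible Rate (events/Myr) below which an exit is treated as
#'   absent (default `1e-6`).
#' @return Tibble `class`, `role`, `gain_rate`, `absent_exit_rate`, with
#'   the threshold used in attribute `negligible`.
#' @export
label_rate_classes <- function(fit, negligible = 1e-6) {
  stopifnot(inherits(fit, "hrm_fit"))
  sp <- fit$model$space
  if (sp$n_obs != 2L || sp$n_classes != 3L) {
    abort("label_rate_classes expects a binary model with 3 rate classes")
  }
  Q <- assemble_Q(fit$model, fit$theta)
  absent_idx <- which(sp$obs == 0L)
  gain_rate <- vapply(seq_len(3), function(r) {
    i <- composite_index(sp, 0L, r); j <- composite_index(sp, 1L, r)
    Q[i, j]
  }, numeric(1))
  absent_exit <- vapply(seq_len(3), function(r) {
    i <- composite_index(sp, 0L, r)
    sum(Q[i, -i])
  }, numeric(1))
  roles <- rep(NA_character_, 3)
  np <- which(absent_exit < negligible)
  if (length(np) != 1L) {
    abort(paste0(
      "class roles not uniquely assignable: absent-state exit rates are ",
      paste(format(absent_exit, digits = 4), collapse = ", "),
      " (need exactly one below ", negligible, ")"
    ))
  }
  roles[np] <- "non-precursor"
  rest <- setdiff(1:3, np)
  gr <- gain_rate[rest]
  if (abs(gr[1] - gr[2]) < negligible) {
    abort(paste0(
      "class roles not uniquely assignable: gain rates tied at ",
      paste(format(gr, digits = 4), collapse = ", ")
    ))
  }
  inter <- rest[which.max(gr)]
  roles[inter] <- "intermediary"
  roles[setdiff(rest, inter)] <- "precursor"
  out <- tibble::tibble(
    class = sp$classes, role = roles,
    gain_rate = gain_rate, absent_exit_rate = absent_exit
  )
  attr(out, "negligible") <- negligible
  out
}

#' Scan a grid of gain/loss rates for a focal ancestor
#'
#' Anchors the grid at the MLE of a one-class (no hidden states) binary
#' model, generates an even spread of (gain, loss) pairs that includes the
#' MLE pair, and for each pair computes the data log-likelihood and the
#' focal node's marginal observed-state probabilities — the evidence scan
#' for whether an ancestor possessed or lacked the trait across rate
#' regimes.
#'
#' @param phy Rooted `phylo`.
#' @param traits Binary trait tibble.
#' @param focal_node Node id of the ancestor of interest (use
#'   [find_mrca()]).
#' @param n_grid Number of (gain, loss) records (default 100).
#' @param span Decades spanned either side of the MLE on the log10 scale
#'   (default 2: rates from x1e-2 to x1e2 of the MLE).
#' @param layout `"pairs"` (default): `n_grid` couples sweeping gain up as
#'   loss comes down, so the loss/gain ratio runs from `10^(-2 span)` to
#'   `10^(2 span)`; `"factorial"`: a `sqrt(n_grid)`-per-axis lattice.
#' @param seed Seed for the anchoring fit's restarts.
#' @param n_restarts Restarts of the anchoring fit.
#' @param root_prior As in [tree_loglik()].
#' @return A `rate_grid`: `records` tibble (`gain`, `loss`, `loglik`, one
#'   probability column per observed state, `is_mle`), `focal_node`,
#'   `anchor_fit`.
#' @export
rate_grid_scan <- function(phy, traits, focal_node, n_grid = 100, span = 2,
                           layout = c("pairs", "factorial"), seed = 1,
                           n_restarts = 5, root_prior = "flat") {
  layout <- match.arg(layout)
  if (n_grid < 1) abort("empty grid spec")
  if (focal_node < 1 || focal_node > n_nodes_total(phy)) abort("unknown focal node")
  model <- build_hidden_rates_model(2, 1)
  anchor <- fit_model(phy, traits, model, n_restarts = n_restarts,
                      seed = seed, root_prior = root_prior)
  g0 <- anchor$theta[[1]]; l0 <- anchor$theta[[2]]

  if (layout == "pairs") {
    off_g <- seq(-span, span, length.out = n_grid)
    off_l <- rev(off_g)
    # force the exact MLE pair into the grid at the most central record
    mid <- which.min(abs(off_g) + abs(off_l))
    off_g[mid] <- 0; off_l[mid] <- 0
    pairs <- tibble::tibble(gain = g0 * 10^off_g, loss = l0 * 10^off_l)
  } else {
    m <- max(2L, round(sqrt(n_grid)))
    off <- seq(-span, span, length.out = m)
    off[which.min(abs(off))] <- 0
    pairs <- tidyr::expand_grid(gain = g0 * 10^off, loss = l0 * 10^off)
  }

  recs <- purrr::pmap_dfr(pairs, function(gain, loss) {
    rec <- marginal_reconstruct(phy, traits, model, c(gain, loss),
                                root_prior = root_prior)
    pr <- ancestor_probability(rec, focal_node)
    out <- tibble::tibble(gain = gain, loss = loss, loglik = rec$loglik)
    dplyr::bind_cols(out, tibble::as_tibble(as.list(pr)))
  })
  recs$is_mle <- recs$gain == g0 & recs$loss == l0
  structure(
    list(records = recs, focal_node = as.integer(focal_node),
         anchor_fit = anchor, layout = layout, span = span),
    class = "rate_grid"
  )
}

#' @export
print.rate_grid <- function(x, ...) {
  cat("<rate_grid> ", nrow(x$records), " (gain, loss) records, focal node ",
      x$focal_node, ", layout '", x$layout, "'\n", sep = "")
  invisible(x)
}

#' Observed-state probabilities of a node under a marginal reconstruction
#'
#' @param rec A marginal-mode `reconstruction`.
#' @param node Node id.
#' @return Named numeric vector of observed-state probabilities (sums
#'   to 1).
#' @export
ancestor_probability <- function(rec, node) {
  stopifnot(inherits(rec, "reconstruction"))
  if (rec$mode != "marginal") abort("ancestor_probability needs a marginal reconstruction")
  obs <- collapse_to_observed(rec)
  row <- obs[obs$node == node, ]
  if (!nrow(row)) abort(paste0("unknown node: ", node))
  sp <- rec$model$space
  setNames(as.numeric(row[1, sp$obs_labels]), sp$obs_labels)
}
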