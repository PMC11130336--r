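make_joint_fixture <- function() {
  # root absent; the (D,E) cherry present: exactly one gain on its stem
  phy <- read_newick("(((D:1,E:1):1,C:2):1,(A:1,B:1):2);")
  traits <- tibble::tibble(
    tip = c("A", "B", "C", "D", "E"),
    state = c(0L, 0L, 0L, 1L, 1L)
  )
  m <- build_hidden_rates_model(2, 1)
  rec <- joint_reconstruct(phy, traits, m, c(0.02, 0.02))
  list(phy = phy, traits = traits, m = m, rec = rec)
}

test_that("transition counting finds gains and losses on edges", {
  fx <- make_joint_fixture()
  cnt <- count_transitions(fx$phy, fx$rec)
  expect_equal(cnt$n_gains, 1)
  expect_equal(cnt$n_losses, 0)
  expect_true(cnt$minimum_counts)
  expect_equal(nrow(cnt$events), sum(cnt$totals$n))
  expect_lte(cnt$n_gains + cnt$n_losses, cnt$n_edges)
  # the gain sits on the stem of the (D,E) cherry
  expect_equal(cnt$events$child, find_mrca(fx$phy, c("D", "E")))

  # uniform reconstruction: no events at all
  phy <- simulate_tree(10, seed = 4)
  tr <- tibble::tibble(tip = phy$tip.label, state = 1L)
  rec <- joint_reconstruct(phy, tr, fx$m, c(0.1, 0.1))
  cnt0 <- count_transitions(phy, rec)
  expect_equal(nrow(cnt0$events), 0)
  expect_equal(cnt0$n_gains + cnt0$n_losses, 0)

  mrec <- marginal_reconstruct(fx$phy, fx$traits, fx$m, c(0.02, 0.02))
  expect_error(count_transitions(fx$phy, mrec), "joint")
})

test_that("clade tabulation assigns events to smallest clades and conserves totals", {
  fx <- make_joint_fixture()
  cnt <- count_transitions(fx$phy, fx$rec)
  tab <- tabulate_clade_events(fx$phy, cnt, list(
    ingroup = c("C", "D", "E"),
    cherry = c("D", "E")
  ))
  # the gain on the cherry stem belongs to 'ingroup' (its parent node is the
  # ingroup MRCA, outside the cherry subtree)
  expect_equal(tab$gains[tab$clade == "ingroup"], 1)
  expect_equal(tab$gains[tab$clade == "cherry"], 0)
  expect_equal(sum(tab$gains), cnt$n_gains)
  expect_equal(sum(tab$losses), cnt$n_losses)

  # an event outside all named clades lands in the catch-all row
  tab2 <- tabulate_clade_events(fx$phy, cnt, list(pair = c("A", "B")))
  expect_equal(tab2$events[tab2$clade == "(unassigned)"], 1)
  expect_error(tabulate_clade_events(fx$phy, cnt, list(x = c("A", "ZZZ"))),
               "unknown tip")
})

test_that("rate-class labelling follows the two-step pathway signature", {
  m <- build_hidden_rates_model(2, 3)
  theta <- rep(0, m$n_par)
  fit <- structure(list(model = m, theta = theta), class = "hrm_fit")
  sp <- m$space
  setq <- function(th, i, j, v) { th[m$index[i, j]] <- v; th }
  ci <- function(o, r) hiddenrates:::composite_index(sp, o, r)
  # R1 absorbing-absent, R2 precursor, R3 intermediary with the fast gain
  theta <- setq(theta, ci(0, 2), ci(0, 3), 0.002)  # precursor -> intermediary
  theta <- setq(theta, ci(0, 2), ci(0, 1), 0.004)  # precursor -> non-precursor
  theta <- setq(theta, ci(0, 3), ci(1, 3), 0.02)   # gain from intermediary
  theta <- setq(theta, ci(0, 3), ci(0, 2), 0.02)
  fit$theta <- theta
  lab <- label_rate_classes(fit)
  expect_equal(lab$role, c("non-precursor", "precursor", "intermediary"))
  expect_equal(lab$gain_rate[3] / lab$absent_exit_rate[2], 0.02 / 0.006,
               tolerance = 1e-12)

  # symmetric classes cannot be labelled
  fit$theta <- rep(0.01, m$n_par)
  expect_error(label_rate_classes(fit), "not uniquely")
})

test_that("rate grid scan anchors at the MLE and reports proper records", {
  phy <- simulate_tree(80, seed = 31)
  m1 <- build_hidden_rates_model(2, 1)
  sim <- simulate_trait_history(phy, m1, c(0.05, 0.02), root_state = 1, seed = 32)
  focal <- find_mrca(phy, phy$tip.label[1:10])

  # single-point grid: the MLE record must match direct computation exactly
  g1 <- rate_grid_scan(phy, sim$traits, focal, n_grid = 1, seed = 5, n_restarts = 3)
  expect_equal(nrow(g1$records), 1)
  expect_true(g1$records$is_mle)
  expect_equal(g1$records$loglik, g1$anchor_fit$loglik, tolerance = 1e-9)
  direct <- marginal_reconstruct(phy, sim$traits, m1, g1$anchor_fit$theta)
  expect_equal(
    c(g1$records$absent, g1$records$present),
    unname(ancestor_probability(direct, focal))
  )

  # default spec: exactly 100 (gain, loss) records, one of them the MLE pair
  g100 <- rate_grid_scan(phy, sim$traits, focal, seed = 5, n_restarts = 3)
  expect_equal(nrow(g100$records), 100)
  expect_equal(sum(g100$records$is_mle), 1)
  expect_true(all(abs(g100$records$absent + g100$records$present - 1) < 1e-10))
  # factorial layout is available too
  g9 <- rate_grid_scan(phy, sim$traits, focal, n_grid = 9, layout = "factorial",
                       seed = 5, n_restarts = 2)
  expect_equal(nrow(g9$records), 9)
  expect_error(rate_grid_scan(phy, sim$traits, focal, n_grid = 0), "empty")
})

test_that("focal present-probability falls as the loss/gain ratio grows", {
  # all-absent outgroup, mixed ingroup
  phy <- simulate_tree(60, seed = 41)
  ingroup_node <- find_mrca(phy, phy$tip.label[1:20])
  ing <- hiddenrates:::clade_tips(phy, ingroup_node)
  st <- rep(0L, 60)
  st[ing[seq(1, length(ing), by = 2)]] <- 1L
  traits <- tibble::tibble(tip = phy$tip.label, state = st)
  g <- rate_grid_scan(phy, traits, ingroup_node, n_grid = 25, seed = 6,
                      n_restarts = 2)
  ord <- order(g$records$loss / g$records$gain)
  pp <- g$records$present[ord]
  expect_true(all(diff(pp) <= 1e-9))
})

test_that("ancestor probabilities are proper and honour constraints", {
  inst <- rand_instance(61, n_obs = 2, n_classes = 2)
  rec <- marginal_reconstruct(inst$phy, inst$traits, inst$model, inst$theta)
  rt <- root_node(inst$phy)
  pr <- ancestor_probability(rec, rt)
  expect_equal(sum(pr), 1, tolerance = 1e-10)
  # against the enumeration posterior, collapsed over classes
  oracle <- enum_marginal(inst$phy, inst$traits, inst$model, inst$theta)
  sp <- inst$model$space
  expect_equal(unname(pr),
               as.numeric(tapply(oracle[, rt], sp$obs, sum)),
               tolerance = 1e-8)
  # constrained node has probability 1 on the forced state
  recc <- marginal_reconstruct(inst$phy, inst$traits, inst$model, inst$theta,
                               constraints = node_constraint(rt, observed = 1))
  expect_equal(unname(ancestor_probability(recc, rt)["present"]), 1)
  expect_error(ancestor_probability(rec, 10000), "unknown node")
  expect_error(ancestor_probability(joint_reconstruct(
    inst$phy, inst$traits, inst$model, inst$theta), rt), "marginal")
})
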