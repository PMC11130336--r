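test_that("simulated trees are ultrametric, sized and reproducible", {
  phy <- simulate_tree(50, seed = 9)
  expect_equal(ape::Ntip(phy), 50)
  depths <- ape::node.depth.edgelength(phy)[1:50]
  expect_lt(diff(range(depths)), 1e-9)
  expect_identical(write_newick(simulate_tree(50, seed = 9)), write_newick(phy))
  expect_false(identical(write_newick(simulate_tree(50, seed = 10)),
                         write_newick(phy)))
  expect_error(simulate_tree(1), "at least 2")
  expect_error(simulate_tree(10, birth = 0.1, death = 0.2), "birth > death")
})

test_that("zero rates propagate the root state without events", {
  phy <- simulate_tree(20, seed = 1)
  m <- build_hidden_rates_model(2, 2)
  sim <- simulate_trait_history(phy, m, rep(0, m$n_par), root_state = 3, seed = 2)
  expect_equal(nrow(sim$events), 0)
  expect_true(all(sim$node_states == 3))
  expect_true(all(sim$traits$state == m$space$obs[3]))
})

test_that("trait histories are internally consistent", {
  phy <- simulate_tree(40, seed = 3)
  m <- build_hidden_rates_model(2, 2)
  set.seed(100)
  theta <- runif(m$n_par, 0.01, 0.2)
  sim <- simulate_trait_history(phy, m, theta, root_state = 1, seed = 4)

  # tip states equal the endpoint of each tip edge's event chain
  ntip <- ape::Ntip(phy)
  expect_equal(sim$traits$state, m$space$obs[sim$node_states[seq_len(ntip)]])
  for (e in seq_len(nrow(phy$edge))) {
    ev <- sim$events[sim$events$edge == e, ]
    start <- sim$node_states[phy$edge[e, 1]]
    end <- if (nrow(ev)) ev$to[nrow(ev)] else start
    expect_equal(sim$node_states[phy$edge[e, 2]], end)
    if (nrow(ev)) {
      expect_true(all(ev$time >= 0 & ev$time <= phy$edge.length[e]))
      expect_equal(ev$from[1], start)
      # chain continuity
      if (nrow(ev) > 1) expect_equal(ev$from[-1], ev$to[-nrow(ev)])
    }
    # truth conservation: per-edge observed changes bound the endpoint difference
    diff_obs <- m$space$obs[sim$node_states[phy$edge[e, 1]]] !=
      m$space$obs[sim$node_states[phy$edge[e, 2]]]
    expect_gte(sim$edge_obs_changes[e], as.integer(diff_obs))
  }
  # event times within edges, deterministic under the seed
  sim2 <- simulate_trait_history(phy, m, theta, root_state = 1, seed = 4)
  expect_equal(sim2$events, sim$events)
})

test_that("event counts match the Markov expectation on a star tree", {
  # 10,000 iid edges of length T from one simulate call (star phylogeny);
  # oracle: E[N] = int_0^T sum_s p_s(t) * exit_s dt, closed form for 2 states
  n <- 10000
  T_len <- 1.5
  q01 <- 2; q10 <- 1
  star <- ape::read.tree(text = paste0(
    "(", paste0("t", seq_len(n), ":", T_len, collapse = ","), ");"
  ))
  m <- build_hidden_rates_model(2, 1)
  sim <- simulate_trait_history(star, m, c(q01, q10), root_state = 1, seed = 12)
  counts <- tabulate(sim$events$edge, nbins = n)

  # closed form: p0(t) = pi0 + (1 - pi0) exp(-(q01+q10) t), exit0 = q01, exit1 = q10
  r <- q01 + q10
  pi0 <- q10 / r
  int_p0 <- pi0 * T_len + (1 - pi0) * (1 - exp(-r * T_len)) / r
  expected <- q01 * int_p0 + q10 * (T_len - int_p0)
  se <- stats::sd(counts) / sqrt(n)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("masking unknowns is exact, seeded and bounded", {
  traits <- tibble::tibble(tip = paste0("t", 1:100), state = rep(0:1, 50))
  expect_identical(mask_states(traits, 0), traits)
  m50 <- mask_states(traits, 0.5, seed = 3)
  expect_equal(sum(is.na(m50$state)), 50)
  expect_identical(mask_states(traits, 0.5, seed = 3), m50)
  expect_error(mask_states(traits, 1), "fraction")
})

test_that("the NFC-like fixture encodes the two-step pathway structure", {
  fx <- make_nfc_like_fixture(n_tips = 150, unknown_fraction = 0.1, seed = 2)
  sp <- fx$model$space
  ev <- fx$history$events
  true_gains <- sum(sp$obs[ev$from] == 0 & sp$obs[ev$to] == 1)
  expect_gte(true_gains, 2)
  expect_equal(sum(is.na(fx$traits$state)), round(0.1 * 150))

  # outgroup starts (and stays) in the absorbing non-precursor absent state
  out_states <- fx$traits_full$state[fx$traits_full$tip %in% fx$clades$outgroup]
  expect_true(all(out_states == 0L))

  # generating rates respect the published orderings
  prof <- nfc_rate_profile()
  expect_equal(prof[["gain_intermediary"]] / prof[["prec_to_inter"]], 10)
  expect_equal(prof[["gain_intermediary"]] / prof[["loss"]], 150)
  expect_gt(prof[["prec_to_nonprec"]], prof[["prec_to_inter"]])
  expect_equal(prof[["inter_to_prec"]], prof[["gain_intermediary"]])

  # fixture serialization produces readable plain-text artifacts
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  expect_true(all(file.exists(file.path(
    dir, c("tree.nwk", "traits.csv", "truth.json", "model.json", "README")
  ))))
  phy2 <- read_newick(file.path(dir, "tree.nwk"))
  expect_equal(ape::Ntip(phy2), 150)
  tr2 <- read_trait_table(file.path(dir, "traits.csv"))
  expect_equal(sum(is.na(tr2$state)), sum(is.na(fx$traits$state)))
})

test_that("low-rate histories are recovered exactly by joint counting", {
  # calibration: when changes are rare, counted gains equal true gains
  m <- build_hidden_rates_model(2, 1)
  hits <- 0
  for (s in 1:10) {
    phy <- simulate_tree(150, seed = 500 + s)
    # ~0.7 expected events per whole tree: far below 0.02 events per edge
    theta <- c(2, 1) / (3 * sum(phy$edge.length))
    sim <- simulate_trait_history(phy, m, theta, root_state = 1, seed = 600 + s)
    rec <- joint_reconstruct(phy, sim$traits, m, theta)
    cnt <- count_transitions(phy, rec)
    sp <- m$space
    tg <- sum(sp$obs[sim$events$from] == 0 & sp$obs[sim$events$to] == 1)
    if (cnt$n_gains == tg) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
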