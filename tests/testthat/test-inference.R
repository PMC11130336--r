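# Small shared fixture: a 60-tip tree with a simulated binary history.
local_fit_fixture <- local({
  phy <- simulate_tree(60, seed = 21)
  m1 <- build_hidden_rates_model(2, 1)
  sim <- simulate_trait_history(phy, m1, c(0.05, 0.02), root_state = 1, seed = 22)
  list(phy = phy, traits = sim$traits, m1 = m1)
})

test_that("fit_model finds the optimum and reports it consistently", {
  fx <- local_fit_fixture
  fit <- fit_model(fx$phy, fx$traits, fx$m1, n_restarts = 4, seed = 3)
  # reported lnL reproduces at the returned rates
  redo <- tree_loglik(fx$phy, fx$traits, fx$m1, fit$theta)$loglik
  expect_equal(fit$loglik, redo, tolerance = 1e-6)
  expect_equal(fit$AIC, 2 * fit$k - 2 * fit$loglik)
  expect_equal(nrow(fit$restarts), 4)
  expect_true(all(fit$theta >= fit$bounds[1] & fit$theta <= fit$bounds[2]))
  # deterministic given the seed
  fit2 <- fit_model(fx$phy, fx$traits, fx$m1, n_restarts = 4, seed = 3)
  expect_equal(fit2$theta, fit$theta)
  expect_equal(fit2$loglik, fit$loglik)

  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(sort(unique(td$parameter)), c("q1", "q2"))
  expect_equal(glance(fit)$AIC, fit$AIC)
})

test_that("monomorphic data drive the change rate to the boundary", {
  phy <- simulate_tree(30, seed = 5)
  traits <- tibble::tibble(tip = phy$tip.label, state = 0L)
  m <- build_hidden_rates_model(2, 1)
  fit <- fit_model(phy, traits, m, n_restarts = 3, seed = 1)
  # the gain rate collapses to the lower bound
  expect_lt(fit$theta[["q1"]], 1e-7)
  # with no change allowed at all, lnL is exactly the prior mass on 'absent'
  expect_equal(tree_loglik(phy, traits, m, c(0, 0))$loglik, log(0.5))
  # the free fit can only beat that (a huge loss rate soaks up the
  # root-present prior mass), up to the flat-prior ceiling of 0
  expect_gte(fit$loglik, log(0.5) - 1e-9)
  expect_lte(fit$loglik, 0)
})

test_that("more restarts never worsen the reported likelihood", {
  fx <- local_fit_fixture
  f2 <- fit_model(fx$phy, fx$traits, fx$m1, n_restarts = 2, seed = 9)
  f5 <- fit_model(fx$phy, fx$traits, fx$m1, n_restarts = 5, seed = 9)
  expect_gte(f5$loglik, f2$loglik - 1e-9)
})

test_that("extra rate classes cannot reduce the maximized likelihood", {
  fx <- local_fit_fixture
  f1 <- fit_model(fx$phy, fx$traits, fx$m1, n_restarts = 3, seed = 2)
  f2 <- fit_model(fx$phy, fx$traits, build_hidden_rates_model(2, 2),
                  n_restarts = 4, seed = 2)
  expect_gte(f2$loglik, f1$loglik - 1e-3)
})

test_that("aic_table computes, orders and ties correctly", {
  mk <- function(name, k, ll) {
    structure(list(model = list(name = name), k = k, loglik = ll,
                   AIC = 2 * k - 2 * ll, AICc = NA_real_,
                   restarts = tibble::tibble(), constrained = FALSE),
              class = "hrm_fit")
  }
  # k = 2, lnL = -10 -> AIC 24
  expect_equal(mk("a", 2, -10)$AIC, 24)
  tab1 <- aic_table(list(mk("only", 3, -5)))
  expect_equal(tab1$delta_AIC, 0)
  tab <- aic_table(list(mk("big", 4, -8), mk("small", 2, -10), mk("best", 2, -9)))
  expect_equal(tab$model, c("best", "small", "big"))
  expect_equal(tab$delta_AIC, c(0, 2, 2))
  # AIC tie between 'small' (k=2) and 'big' (k=4): fewer parameters first
  tab2 <- aic_table(list(mk("big", 4, -8), mk("small", 2, -10)))
  expect_equal(tab2$model, c("small", "big"))
})

test_that("fixed-node fits are flagged, bounded by the free fit, and fail on impossible data", {
  fx <- local_fit_fixture
  free <- fit_model(fx$phy, fx$traits, fx$m1, n_restarts = 3, seed = 4)
  node <- find_mrca(fx$phy, fx$phy$tip.label[1:5])
  jr <- joint_reconstruct(fx$phy, fx$traits, fx$m1, free$theta)
  jstate <- jr$states$observed[jr$states$node == node]
  fit_same <- fit_with_fixed_node(fx$phy, fx$traits, fx$m1, node,
                                  observed = jstate, n_restarts = 3, seed = 4)
  fit_opp <- fit_with_fixed_node(fx$phy, fx$traits, fx$m1, node,
                                 observed = 1 - jstate, n_restarts = 3, seed = 4)
  expect_true(fit_same$constrained)
  expect_lte(fit_same$loglik, free$loglik + 1e-6)
  expect_lte(fit_opp$loglik, free$loglik + 1e-6)
  # fixing the node at its reconstructed state costs less than the opposite
  expect_gt(fit_same$loglik, fit_opp$loglik)

  # a constraint contradicting an observed tip is impossible for every theta
  phy <- read_newick("(A:1,B:1);")
  traits <- tibble::tibble(tip = c("A", "B"), state = c(0L, 0L))
  expect_error(
    fit_with_fixed_node(phy, traits, build_hidden_rates_model(2, 1),
                        node = which(phy$tip.label == "A"), observed = 1,
                        n_restarts = 1, seed = 1),
    "impossible"
  )
})

test_that("delta-2 region covers the MLE, respects delta and is reproducible", {
  fx <- local_fit_fixture
  fit <- fit_model(fx$phy, fx$traits, fx$m1, n_restarts = 3, seed = 6)
  cr <- sample_confidence_region(fx$phy, fx$traits, fit, n_samples = 100, seed = 8)
  expect_true(all(cr$samples$loglik >= cr$loglik_max - cr$delta - 1e-9))
  expect_true(all(cr$ranges$lower <= fit$theta & fit$theta <= cr$ranges$upper))
  cr2 <- sample_confidence_region(fx$phy, fx$traits, fit, n_samples = 100, seed = 8)
  expect_equal(cr2$ranges, cr$ranges)
  expect_equal(dim(cr$cov), c(2, 2))
})

test_that("1-parameter region endpoints match a direct likelihood profile", {
  fx <- local_fit_fixture
  m_eq <- build_hidden_rates_model(2, 1, equal_rates = TRUE)
  expect_equal(count_free_params(m_eq), 1)
  fit <- fit_model(fx$phy, fx$traits, m_eq, n_restarts = 3, seed = 2)
  cr <- sample_confidence_region(fx$phy, fx$traits, fit, n_samples = 50, seed = 3)
  # dense grid profile of the single rate
  grid <- 10^seq(log10(fit$theta) - 2, log10(fit$theta) + 2, length.out = 2001)
  lls <- vapply(grid, function(q) {
    tree_loglik(fx$phy, fx$traits, m_eq, q)$loglik
  }, numeric(1))
  inside <- grid[lls >= max(fit$loglik, max(lls)) - 2]
  expect_lt(abs(log10(cr$ranges$lower) - log10(min(inside))), 0.02)
  expect_lt(abs(log10(cr$ranges$upper) - log10(max(inside))), 0.02)
})
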