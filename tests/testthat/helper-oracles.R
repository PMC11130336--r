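# Brute-force oracles, independent of the pruning/DP code paths: internal
# node states are enumerated exhaustively; tips are handled analytically
# (summed for likelihoods/marginals, maximised for joint scores).

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_instance <- function(seed, max_tips = 6, n_obs = NULL, n_classes = NULL,
                          unknown_prob = 0.2) {
  set.seed(seed)
  ntip <- sample(3:max_tips, 1)
  phy <- ape::rtree(ntip)
  if (runif(1) < 0.3) phy <- ape::di2multi(phy, tol = 0.3)  # some polytomies
  if (is.null(n_obs)) n_obs <- sample(2:3, 1)
  if (is.null(n_classes)) n_classes <- sample.int(6 %/% n_obs, 1)
  model <- build_hidden_rates_model(n_obs, n_classes)
  theta <- 10^runif(model$n_par, -1.3, 0.3)
  states <- sample(0:(n_obs - 1), ntip, replace = TRUE)
  states[runif(ntip) < unknown_prob] <- NA
  traits <- tibble::tibble(tip = phy$tip.label, state = as.integer(states))
  list(phy = phy, model = model, theta = theta, traits = traits)
}

enum_setup <- function(phy, traits, model, theta) {
  Q <- assemble_Q(model, theta)
  edge <- phy$edge
  P <- lapply(seq_len(nrow(edge)), function(e) {
    transition_matrix(Q, phy$edge.length[e])
  })
  tp <- tip_partials(traits[match(phy$tip.label, traits$tip), ], model)
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  internal <- (ntip + 1):nn
  s <- model$space$n_states
  grid <- as.matrix(expand.grid(rep(list(seq_len(s)), length(internal))))
  list(edge = edge, P = P, tp = tp, ntip = ntip, nn = nn,
       internal = internal, s = s, grid = grid)
}

# weight of every internal-node assignment, tips summed out
enum_weights <- function(su, prior, masks = NULL) {
  grid <- su$grid
  w <- prior[grid[, 1]]  # first internal node is the root (ntip + 1)
  if (!is.null(masks)) {
    for (i in seq_along(su$internal)) {
      w <- w * masks[cbind(grid[, i], rep(su$internal[i], nrow(grid)))]
    }
  }
  for (e in seq_len(nrow(su$edge))) {
    p <- su$edge[e, 1]; ch <- su$edge[e, 2]
    pi <- match(p, su$internal)
    if (ch > su$ntip) {
      ci <- match(ch, su$internal)
      w <- w * su$P[[e]][cbind(grid[, pi], grid[, ci])]
    } else {
      m <- as.numeric(su$P[[e]] %*% su$tp[, ch])
      w <- w * m[grid[, pi]]
    }
  }
  w
}

enum_loglik <- function(phy, traits, model, theta, prior = NULL,
                        masks = NULL) {
  su <- enum_setup(phy, traits, model, theta)
  prior <- prior %||% rep(1 / su$s, su$s)
  log(sum(enum_weights(su, prior, masks)))
}

# posterior state probabilities for every node (tips included)
enum_marginal <- function(phy, traits, model, theta, prior = NULL) {
  su <- enum_setup(phy, traits, model, theta)
  prior <- prior %||% rep(1 / su$s, su$s)
  w <- enum_weights(su, prior)
  total <- sum(w)
  post <- matrix(0, su$s, su$nn)
  for (i in seq_along(su$internal)) {
    agg <- tapply(w, su$grid[, i], sum)
    post[as.integer(names(agg)), su$internal[i]] <- agg / total
  }
  for (e in seq_len(nrow(su$edge))) {
    ch <- su$edge[e, 2]
    if (ch > su$ntip) next
    pi <- match(su$edge[e, 1], su$internal)
    m <- as.numeric(su$P[[e]] %*% su$tp[, ch])
    w_no <- ifelse(m[su$grid[, pi]] > 0, w / m[su$grid[, pi]], 0)
    for (s_i in seq_len(su$s)) {
      post[s_i, ch] <- sum(w_no * su$P[[e]][su$grid[, pi], s_i] *
                             su$tp[s_i, ch]) / total
    }
  }
  post
}

# maximum joint log-probability over all composite assignments
enum_joint_max <- function(phy, traits, model, theta, prior = NULL) {
  su <- enum_setup(phy, traits, model, theta)
  prior <- prior %||% rep(1 / su$s, su$s)
  grid <- su$grid
  w <- prior[grid[, 1]]
  for (e in seq_len(nrow(su$edge))) {
    p <- su$edge[e, 1]; ch <- su$edge[e, 2]
    pi <- match(p, su$internal)
    if (ch > su$ntip) {
      ci <- match(ch, su$internal)
      w <- w * su$P[[e]][cbind(grid[, pi], grid[, ci])]
    } else {
      mm <- apply(su$P[[e]] * rep(su$tp[, ch], each = su$s), 1, max)
      w <- w * mm[grid[, pi]]
    }
  }
  log(max(w))
}

# log joint probability of one full assignment (all nodes, tips included)
score_assignment <- function(phy, traits, model, theta, assign, prior = NULL) {
  su <- enum_setup(phy, traits, model, theta)
  prior <- prior %||% rep(1 / su$s, su$s)
  lp <- log(prior[assign[su$ntip + 1L]])
  for (e in seq_len(nrow(su$edge))) {
    p <- su$edge[e, 1]; ch <- su$edge[e, 2]
    lp <- lp + log(su$P[[e]][assign[p], assign[ch]])
    if (ch <= su$ntip) lp <- lp + log(su$tp[assign[ch], ch])
  }
  lp
}
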