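#' Maximum-likelihood fit of a rate model
#'
#' Rates are optimised on the log10 scale by Nelder-Mead simplex search from
#' random log-uniform starting points, the standard recipe for these flat,
#' multi-modal likelihood surfaces.  Restart seeds are derived from the
#' master seed by a counter, so the full trajectory of every restart is
#' reproducible and adding restarts can only improve (never change
#' previously computed) results.
#'
#' @param phy Rooted `phylo`, branch lengths in Myr.
#' @param traits Trait tibble covering all tips.
#' @param model A `rate_model`.
#' @param n_restarts Number of random restarts (the published analyses of
#'   this model family typically use 100; smaller values are fine for
#'   simulated data).
#' @param seed Master seed; restart `i` uses `seed + i`.
#' @param bounds Length-2 rate bounds (events/Myr) enforced during search.
#' @param start_range Range from which log-uniform random starts are drawn;
#'   defaults to `c(1e-5, 1)`, a biologically plausible window narrower
#'   than the hard bounds.
#' @param root_prior Root prior passed to [tree_loglik()].
#' @param constraints Optional node constraint(s) applied inside every
#'   likelihood evaluation.
#' @param maxit Maximum simplex iterations per restart (default scales with
#'   the number of parameters).
#' @return An `hrm_fit`: `theta` (named rates), `loglik`, `k`, `AIC`,
#'   `AICc`, `restarts` tibble (seed, start, end lnL, convergence),
#'   `model`, `root_prior`, `constrained`.
#' @export
fit_model <- function(phy, traits, model, n_restarts = 10, seed = 1,
                      bounds = model$bounds, start_range = c(1e-5, 1),
                      root_prior = "flat", constraints = NULL,
                      maxit = NULL) {
  stopifnot(n_restarts >= 1)
  k <- model$n_par
  lb <- log10(bounds[1]); ub <- log10(bounds[2])
  maxit <- maxit %||% max(500L, 250L * k)

  llfun <- loglik_factory(phy, traits, model, root_prior, constraints)
  Qfun <- function(x) {
    xc <- pmin(pmax(x, lb), ub)
    ll <- llfun(10^xc)
    # soft penalty keeps the simplex inside bounds without a hard wall
    -(ll) + 1e4 * sum((x - xc)^2)
  }

  restarts <- vector("list", n_restarts)
  best <- NULL
  n_fail <- 0L
  for (i in seq_len(n_restarts)) {
    rs <- seed + i
    set.seed(rs)
    x0 <- runif(k, log10(start_range[1]), log10(start_range[2]))
    opt <- tryCatch(
      if (k == 1L) {
        optim(x0, Qfun, method = "Brent", lower = lb, upper = ub,
              control = list(maxit = maxit))
      } else {
        optim(x0, Qfun, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-10))
      },
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value)) {
      n_fail <- n_fail + 1L
      restarts[[i]] <- tibble::tibble(
        restart = i, seed = rs, start = list(10^x0),
        loglik = NA_real_, converged = FALSE
      )
      next
    }
    restarts[[i]] <- tibble::tibble(
      restart = i, seed = rs, start = list(10^x0),
      loglik = -opt$value, converged = opt$convergence == 0
    )
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    abort(paste0("optimizer failed on all ", n_restarts, " restarts (",
                 n_fail, " errors)"))
  }
  # polish the winning restart
  if (k > 1L) {
    pol <- optim(best$par, Qfun, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-12))
    if (pol$value < best$value) best <- pol
  }

  x <- pmin(pmax(best$par, lb), ub)
  theta <- 10^x
  names(theta) <- paste0("q", seq_len(k))
  ll <- llfun(theta)
  n_tip <- ape::Ntip(phy)
  structure(
    list(
      model = model, theta = theta, loglik = ll, k = k,
      AIC = 2 * k - 2 * ll,
      AICc = 2 * k - 2 * ll + 2 * k * (k + 1) / max(n_tip - k - 1, 1),
      restarts = dplyr::bind_rows(restarts),
      root_prior = if (is.character(root_prior)) root_prior else "user-vector",
      constrained = !is.null(constraints),
      constraints = constraints,
      bounds = bounds, seed = seed, n_tip = n_tip
    ),
    class = "hrm_fit"
  )
}

#' @export
print.hrm_fit <- function(x, ...) {
  cat("<hrm_fit> ", x$model$name, if (x$constrained) " [constrained]", "\n", sep = "")
  cat("  lnL = ", format(x$loglik, digits = 10),
      ",  k = ", x$k, ",  AIC = ", format(x$AIC, digits = 10), "\n", sep = "")
  cat("  rates (events/Myr): ",
      paste(format(x$theta, digits = 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' AIC model comparison table
#'
#' @param ... `hrm_fit` objects (or a single list of them).
#' @return Tibble with columns `model`, `k`, `loglik`, `AIC`, `AICc`,
#'   `delta_AIC`, sorted best-first; AIC ties are broken by fewer
#'   parameters.
#' @export
aic_table <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "hrm_fit")) fits <- fits[[1]]
  stopifnot(length(fits) >= 1)
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      model = f$model$name, k = f$k, loglik = f$loglik,
      AIC = f$AIC, AICc = f$AICc, constrained = f$constrained
    )
  })
  tab <- dplyr::arrange(tab, .data$AIC, .data$k)
  dplyr::mutate(tab, delta_AIC = .data$AIC - .data$AIC[1], .after = "AIC")
}

#' Maximum-likelihood fit with a fixed ancestral state
#'
#' Convenience wrapper for the fixed-ancestor analysis: the constraint is
#' applied inside every likelihood evaluation, so rates adapt to the forced
#' state.  The constrained lnL can never exceed the unconstrained one.
#'
#' @inheritParams fit_model
#' @param node Node id to constrain (use [find_mrca()] to locate it).
#' @param observed Observed-state code(s) the node is fixed to (any class).
#' @return An `hrm_fit` with `constrained = TRUE`.
#' @export
fit_with_fixed_node <- function(phy, traits, model, node, observed, ...) {
  cn <- node_constraint(node, observed = observed)
  probe <- tree_loglik(phy, traits, model,
                       theta = rep(0.01, model$n_par), constraints = cn)
  if (probe$impossible) {
    abort("constraint makes the data impossible under this model structure")
  }
  fit <- fit_model(phy, traits, model, constraints = cn, ...)
  if (!is.finite(fit$loglik)) {
    abort("constraint makes the data impossible for every rate vector tried")
  }
  fit
}

#' Sample the delta-2 likelihood confidence region
#'
#' Random-walk sampling in log-rate space around the MLE, accepting points
#' whose log-likelihood is within `delta` units of the maximum (the
#' "dentist" approach).  Per-parameter ranges over accepted samples give
#' marginal confidence intervals, and the covariance of accepted samples
#' exposes likelihood ridges from covarying parameters.
#'
#' @param phy,traits Data the fit was computed on.
#' @param fit An `hrm_fit`.
#' @param delta Log-likelihood drop defining the region (default 2).
#' @param n_samples Number of proposals.
#' @param seed RNG seed.
#' @return A `conf_region`: `samples` tibble (accepted `theta`, `loglik`),
#'   `ranges` tibble (per-parameter min/max), `cov` (log10-scale covariance
#'   of accepted samples), `delta`, `loglik_max`.
#' @export
sample_confidence_region <- function(phy, traits, fit, delta = 2,
                                     n_samples = 400, seed = 1) {
  stopifnot(inherits(fit, "hrm_fit"), is.finite(fit$loglik))
  model <- fit$model
  k <- model$n_par
  lb <- log10(fit$bounds[1]); ub <- log10(fit$bounds[2])
  ll0 <- loglik_factory(phy, traits, model, fit$root_prior, fit$constraints)
  llfun <- function(x) ll0(10^x)
  set.seed(seed)
  x0 <- log10(fit$theta)
  ll_max <- fit$loglik
  acc <- list(list(x = x0, ll = fit$loglik))

  # Stage 1: profile each parameter to the delta boundary (others at the
  # MLE) by doubling then bisection.  The crossing points are accepted
  # samples and calibrate the walk's per-parameter step size.
  half_width <- matrix(NA_real_, k, 2)
  for (i in seq_len(k)) {
    for (dir in 1:2) {
      sgn <- c(-1, 1)[dir]
      h <- 0.01
      lim <- if (sgn < 0) x0[i] - lb else ub - x0[i]
      while (h < lim) {
        xp <- x0; xp[i] <- x0[i] + sgn * h
        if (!is.finite(llfun(xp)) || llfun(xp) < ll_max - delta) break
        h <- h * 2
      }
      h <- min(h, lim)
      lo <- 0; hi <- h
      for (b in 1:25) {
        mid <- (lo + hi) / 2
        xp <- x0; xp[i] <- x0[i] + sgn * mid
        llp <- llfun(xp)
        if (is.finite(llp) && llp >= ll_max - delta) lo <- mid else hi <- mid
      }
      xp <- x0; xp[i] <- x0[i] + sgn * lo
      acc[[length(acc) + 1L]] <- list(x = xp, ll = llfun(xp))
      half_width[i, dir] <- lo
    }
  }
  steps <- pmax(rowMeans(half_width) / 2, 1e-4)

  # Stage 2: random walk inside the region to pick up parameter
  # correlations (likelihood ridges) the axis profiles cannot see.
  x <- x0
  for (i in seq_len(n_samples)) {
    xp <- pmin(pmax(x + rnorm(k, 0, steps), lb), ub)
    llp <- llfun(xp)
    if (is.finite(llp) && llp >= ll_max - delta) {
      x <- xp
      acc[[length(acc) + 1L]] <- list(x = x, ll = llp)
      if (llp > ll_max + 1e-6) {
        warn("confidence-region sampling found a higher likelihood than the fit; region re-centred")
        ll_max <- llp
      }
    } else if (runif(1) < 0.5) {
      x <- x0  # restart at the MLE so excursions cannot strand the walk
    }
  }
  if (length(acc) <= 1L && n_samples > 0) {
    abort("no samples accepted within delta; is the input really an MLE?")
  }
  X <- do.call(rbind, lapply(acc, function(a) a$x))
  lls <- vapply(acc, function(a) a$ll, numeric(1))
  keep <- lls >= ll_max - delta  # re-filter in case the max moved
  X <- X[keep, , drop = FALSE]; lls <- lls[keep]
  theta_mat <- 10^X
  colnames(theta_mat) <- names(fit$theta)
  samples <- tibble::as_tibble(theta_mat)
  samples$loglik <- lls
  ranges <- tibble::tibble(
    parameter = names(fit$theta),
    mle = unname(fit$theta),
    lower = apply(theta_mat, 2, min),
    upper = apply(theta_mat, 2, max)
  )
  structure(
    list(samples = samples, ranges = ranges,
         cov = cov(X), delta = delta, loglik_max = ll_max, seed = seed),
    class = "conf_region"
  )
}

#' @export
print.conf_region <- function(x, ...) {
  cat("<conf_region> delta = ", x$delta, ", ", nrow(x$samples),
      " accepted samples, lnL_max = ", format(x$loglik_max, digits = 10),
      "\n", sep = "")
  print(x$ranges)
  invisible(x)
}
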