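#' Rate models with hidden rate classes
#'
#' A rate model pairs a composite state space (observed states crossed with
#' hidden rate classes) with a parameter-index matrix `M`: entry `M[i, j]`
#' is 0 where the instantaneous transition i -> j is forbidden and the index
#' of a free rate parameter otherwise.  Distinct indices are distinct free
#' parameters, so "unequal rates" structures are the default.  Simultaneous
#' change of observed state and class ("dual" transitions) is forbidden
#' unless explicitly requested: composite dynamics move either along the
#' observed axis (gain/loss within a class) or along the class axis.
#'
#' @name rate_model
NULL

state_space <- function(obs_labels, n_classes) {
  n_obs <- length(obs_labels)
  classes <- paste0("R", seq_len(n_classes))
  grid <- expand.grid(obs = seq_len(n_obs), class = seq_len(n_classes))
  labels <- paste0(obs_labels[grid$obs], "|", classes[grid$class])
  list(
    obs_labels = obs_labels, classes = classes,
    n_obs = n_obs, n_classes = n_classes,
    obs = grid$obs - 1L,      # observed part of each composite state (0-based code)
    class = grid$class,       # class part (1-based)
    labels = labels,
    n_states = n_obs * n_classes
  )
}

new_rate_model <- function(space, index, name,
                           bounds = c(1e-9, 100)) {
  dimnames(index) <- list(space$labels, space$labels)
  structure(
    list(
      space = space, index = index, name = name,
      n_par = max(index), bounds = bounds
    ),
    class = "rate_model"
  )
}

composite_index <- function(space, obs, class) {
  # obs is the 0-based observed code, class the 1-based class id
  (class - 1L) * space$n_obs + obs + 1L
}

#' Build a hidden-rates model
#'
#' All observed-state changes are allowed within every class and all
#' directed class changes within every observed state, each with its own
#' rate parameter.  Naming a `no_gain_class` forbids the gain transition
#' (absent -> present) inside that class, encoding prior knowledge that the
#' trait cannot be gained in part of the tree.
#'
#' @param n_obs Number of observed states (2 or 3).
#' @param n_classes Number of hidden rate classes (1 to 5).
#' @param no_gain_class Optional class label (e.g. `"R3"`) or index in which
#'   the absent -> present transition is forbidden; binary spaces only.
#' @param equal_rates If `TRUE`, gain and loss share one rate per class
#'   (binary spaces only); the default leaves every transition free.
#' @param obs_labels Labels for the observed states.
#' @return A `rate_model`.
#' @examples
#' m <- build_hidden_rates_model(2, 3)
#' count_free_params(m) # 18
#' @export
build_hidden_rates_model <- function(n_obs = 2, n_classes = 1,
                                     no_gain_class = NULL,
                                     equal_rates = FALSE,
                                     obs_labels = NULL) {
  if (!n_obs %in% c(2L, 3L)) abort("n_obs must be 2 or 3")
  if (!(n_classes %in% 1:5)) abort("n_classes must be between 1 and 5")
  obs_labels <- obs_labels %||%
    if (n_obs == 2) c("absent", "present") else c("absent", "actinorhizal", "rhizobial")
  sp <- state_space(obs_labels, n_classes)

  ng <- NULL
  if (!is.null(no_gain_class)) {
    if (n_obs != 2) abort("no_gain_class is only defined for binary traits")
    ng <- if (is.character(no_gain_class)) match(no_gain_class, sp$classes) else as.integer(no_gain_class)
    if (is.na(ng) || ng < 1 || ng > n_classes) {
      abort(paste0("no_gain_class not among classes ", paste(sp$classes, collapse = ", ")))
    }
  }

  M <- matrix(0L, sp$n_states, sp$n_states)
  p <- 0L
  for (r in seq_len(n_classes)) {
    shared <- NULL
    for (o_from in seq_len(n_obs) - 1L) {
      for (o_to in seq_len(n_obs) - 1L) {
        if (o_from == o_to) next
        if (!is.null(ng) && r == ng && o_from == 0L && o_to == 1L) next
        i <- composite_index(sp, o_from, r)
        j <- composite_index(sp, o_to, r)
        if (equal_rates && n_obs == 2) {
          if (is.null(shared)) { p <- p + 1L; shared <- p }
          M[i, j] <- shared
        } else {
          p <- p + 1L
          M[i, j] <- p
        }
      }
    }
  }
  for (o in seq_len(n_obs) - 1L) {
    for (r_from in seq_len(n_classes)) {
      for (r_to in seq_len(n_classes)) {
        if (r_from == r_to) next
        p <- p + 1L
        M[composite_index(sp, o, r_from), composite_index(sp, o, r_to)] <- p
      }
    }
  }
  nm <- paste0(
    "hidden_rates_", n_obs, "obs_", n_classes, "class",
    if (!is.null(ng)) paste0("_nogain", sp$classes[ng]) else "",
    if (equal_rates) "_equal" else ""
  )
  mod <- new_rate_model(sp, M, nm)
  mod$no_gain_class <- if (!is.null(ng)) sp$classes[ng] else NULL
  mod
}

#' Build the classical two-class precursor model
#'
#' Binary trait, two classes: a non-precursor absent state, a precursor
#' absent state that can interconvert with it, gain of the trait from the
#' precursor class only, and loss back to the precursor class.  Four free
#' rates; all other transitions forbidden.
#'
#' @return A `rate_model`.
#' @export
build_precursor_model <- function() {
  sp <- state_space(c("absent", "present"), 2)
  # classes: R1 = non-precursor, R2 = precursor
  M <- matrix(0L, 4, 4)
  a1 <- composite_index(sp, 0L, 1L); a2 <- composite_index(sp, 0L, 2L)
  p2 <- composite_index(sp, 1L, 2L)
  M[a1, a2] <- 1L   # non-precursor -> precursor
  M[a2, a1] <- 2L   # precursor -> non-precursor
  M[a2, p2] <- 3L   # gain, precursor class only
  M[p2, a2] <- 4L   # loss, back to the precursor class
  mod <- new_rate_model(sp, M, "precursor_two_class")
  mod$class_roles <- c(R1 = "non-precursor", R2 = "precursor")
  mod
}

#' Build the three-state stepwise pathway model
#'
#' Observed states absent / actinorhizal / rhizobial with two rate classes.
#' Actinorhizal symbiosis can only be gained from the precursor class of the
#' absent state, and rhizobial symbiosis only from the actinorhizal state —
#' the scenario in which rhizobial nodules derive from an actinorhizal
#' ancestor.  The direct absent -> rhizobial transition is forbidden.
#' Losses retrace the pathway (rhizobial -> actinorhizal -> absent in the
#' precursor class).
#'
#' @return A `rate_model`.
#' @export
build_three_state_pathway_model <- function() {
  sp <- state_space(c("absent", "actinorhizal", "rhizobial"), 2)
  M <- matrix(0L, 6, 6)
  a1 <- composite_index(sp, 0L, 1L); a2 <- composite_index(sp, 0L, 2L)
  act2 <- composite_index(sp, 1L, 2L); rhi2 <- composite_index(sp, 2L, 2L)
  M[a1, a2] <- 1L     # non-precursor -> precursor (absent)
  M[a2, a1] <- 2L     # precursor -> non-precursor (absent)
  M[a2, act2] <- 3L   # gain actinorhizal from precursor
  M[act2, a2] <- 4L   # loss actinorhizal
  M[act2, rhi2] <- 5L # gain rhizobial from actinorhizal
  M[rhi2, act2] <- 6L # loss rhizobial back to actinorhizal
  mod <- new_rate_model(sp, M, "three_state_pathway")
  mod$class_roles <- c(R1 = "non-precursor", R2 = "precursor")
  mod
}

#' Assemble the instantaneous rate matrix Q
#'
#' @param model A `rate_model`.
#' @param theta Numeric vector of rates (events per Myr), one per free
#'   parameter.
#' @return Square numeric matrix with rows summing to zero; forbidden
#'   transitions are exactly zero.
#' @export
assemble_Q <- function(model, theta) {
  if (length(theta) != model$n_par) {
    abort(paste0("theta has length ", length(theta), ", model needs ", model$n_par))
  }
  if (any(theta < 0)) abort("rates must be non-negative")
  M <- model$index
  Q <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  nz <- which(M > 0, arr.ind = TRUE)
  Q[nz] <- theta[M[nz]]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Number of free rate parameters in a model
#' @param model A `rate_model`.
#' @return Integer count of distinct parameter indices.
#' @export
count_free_params <- function(model) as.integer(model$n_par)

#' @export
print.rate_model <- function(x, ...) {
  cat("<rate_model> ", x$name, "\n", sep = "")
  cat("  observed states: ", paste(x$space$obs_labels, collapse = ", "), "\n", sep = "")
  cat("  rate classes:    ", x$space$n_classes,
      " (composite states: ", x$space$n_states, ")\n", sep = "")
  cat("  free parameters: ", x$n_par, "\n", sep = "")
  invisible(x)
}

#' Serialize a rate model (with optional rates) to JSON
#'
#' @param model A `rate_model`.
#' @param theta Optional rate vector stored alongside the structure.
#' @param file Optional path; when `NULL` the JSON string is returned.
#' @return JSON string, invisibly when written to file.
#' @export
model_to_json <- function(model, theta = NULL, file = NULL) {
  obj <- list(
    name = model$name,
    obs_labels = model$space$obs_labels,
    n_classes = model$space$n_classes,
    index = model$index,
    bounds = model$bounds,
    theta = theta
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Rebuild a rate model from its JSON serialization
#' @param x JSON string or path to a JSON file.
#' @return A list with elements `model` (the `rate_model`) and `theta`
#'   (rates, or `NULL` if none were stored).
#' @export
model_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  sp <- state_space(obj$obs_labels, obj$n_classes)
  idx <- matrix(as.integer(obj$index), sp$n_states, sp$n_states)
  mod <- new_rate_model(sp, idx, obj$name, bounds = obj$bounds)
  list(model = mod, theta = obj$theta)
}
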