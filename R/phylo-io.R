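#' Read a rooted phylogeny from newick text or a file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the package relies on: a single root, unique non-empty tip
#' labels, and finite non-negative branch lengths.  Quoted labels, square
#' bracket comments and polytomies are accepted; branch lengths absent from
#' the input are defaulted (every edge gets `default_length`).
#'
#' @param x Path to a newick file, or a newick string (detected by the
#'   presence of a terminal `";"`).
#' @param default_length Branch length assigned to every edge when the input
#'   carries none.
#' @return An object of class `phylo`, rooted, with `edge.length` set.
#' @examples
#' phy <- read_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(phy)
#' @export
read_newick <- function(x, default_length = 1) {
  txt <- if (length(x) == 1 && grepl(";", x, fixed = TRUE)) x else {
    paste(readLines(x, warn = FALSE), collapse = "")
  }
  if (!identical(nchar(gsub("[^(]", "", txt)), nchar(gsub("[^)]", "", txt)))) {
    abort("unbalanced parentheses in newick input")
  }
  phy <- tryCatch(ape::read.tree(text = txt),
    error = function(e) abort(paste0("newick parse error: ", conditionMessage(e)))
  )
  if (is.null(phy)) abort("newick parse error: input produced no tree")
  validate_phylogeny(phy, default_length = default_length)
}

validate_phylogeny <- function(phy, default_length = 1) {
  if (!inherits(phy, "phylo")) abort("not a 'phylo' object")
  if (is.null(phy$edge.length)) {
    phy$edge.length <- rep(default_length, nrow(phy$edge))
  }
  if (anyNA(phy$edge.length) || any(!is.finite(phy$edge.length))) {
    abort("non-finite branch lengths")
  }
  neg <- which(phy$edge.length < 0)
  if (length(neg)) {
    abort(paste0(
      "negative branch length on edge to node ",
      paste(phy$edge[neg, 2], collapse = ", ")
    ))
  }
  labs <- phy$tip.label
  if (any(!nzchar(labs))) abort("empty tip label")
  if (anyDuplicated(labs)) {
    abort(paste0(
      "duplicate tip labels: ",
      paste(unique(labs[duplicated(labs)]), collapse = ", ")
    ))
  }
  # exactly one root (a node that is nobody's child); basal polytomies are
  # fine, so ape::is.rooted (which demands a dichotomous root) is not used
  roots <- setdiff(phy$edge[, 1], phy$edge[, 2])
  if (length(roots) != 1L) abort("tree must have exactly one root")
  phy
}

#' Write a phylogeny as newick text
#'
#' Labels are emitted unquoted when safe (ape quotes them otherwise).  The
#' single-tip corner case is written as `(A:1);` so that it round-trips
#' through [read_newick()].
#'
#' @param phy A `phylo` object.
#' @param file Optional path; when `NULL` the newick string is returned.
#' @param digits Number of significant digits for branch lengths.
#' @return The newick string, invisibly when written to `file`.
#' @export
write_newick <- function(phy, file = NULL, digits = 10) {
  txt <- ape::write.tree(phy, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a tip-to-trait table
#'
#' Expects a delimited file (or data frame) with columns `tip` and `state`.
#' States are coded `0` (absent), `1` (present; actinorhizal in the ternary
#' space) and `2` (rhizobial, ternary only); any of `"?"`, `"NA"`, `""` or a
#' missing value records an unknown.  Unknown tips are retained, never
#' dropped: they enter the likelihood as fully ambiguous.
#'
#' @param x Path to a CSV/TSV file, or a data frame with columns
#'   `tip` and `state` (extra columns are ignored).
#' @param n_obs Number of observed states in the declared space: 2 (binary
#'   absent/present) or 3 (absent/actinorhizal/rhizobial).
#' @return A tibble with columns `tip` (character) and `state` (integer,
#'   `NA` for unknown), carrying the state-space size in attribute `n_obs`.
#' @export
read_trait_table <- function(x, n_obs = 2) {
  stopifnot(n_obs %in% c(2L, 3L))
  df <- if (is.data.frame(x)) {
    tibble::as_tibble(x)
  } else {
    readr::read_delim(x,
      delim = if (grepl("\\.tsv$", x)) "\t" else ",",
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  }
  if (!all(c("tip", "state") %in% names(df))) {
    abort("trait table needs columns 'tip' and 'state'")
  }
  if (anyDuplicated(df$tip)) {
    abort(paste0(
      "duplicate tip labels in trait table: ",
      paste(unique(df$tip[duplicated(df$tip)]), collapse = ", ")
    ))
  }
  raw <- trimws(as.character(df$state))
  unknown <- is.na(raw) | raw %in% c("?", "NA", "na", "")
  state <- suppressWarnings(as.integer(raw))
  bad <- which(!unknown & (is.na(state) | state < 0 | state >= n_obs))
  if (length(bad)) {
    abort(paste0(
      "state codes outside the declared space in rows: ",
      paste(bad, collapse = ", "), " (values: ",
      paste(unique(raw[bad]), collapse = ", "), ")"
    ))
  }
  state[unknown] <- NA_integer_
  out <- tibble::tibble(tip = as.character(df$tip), state = state)
  attr(out, "n_obs") <- as.integer(n_obs)
  out
}

#' Most recent common ancestor of a set of tips
#'
#' @param phy A `phylo` object.
#' @param tips Character vector of tip labels (length >= 1).  A single tip
#'   returns that tip's own node id.
#' @return Integer node id in `phy`'s node numbering.
#' @export
find_mrca <- function(phy, tips) {
  idx <- match(tips, phy$tip.label)
  if (anyNA(idx)) {
    abort(paste0("unknown tip label(s): ", paste(tips[is.na(idx)], collapse = ", ")))
  }
  if (length(unique(idx)) == 1L) return(idx[[1]])
  ape::getMRCA(phy, unique(idx))
}

#' Backfill unscored tips from state-uniform clades
#'
#' Implements phylogeny-informed trait scoring: an unscored tip takes the
#' state of its closest relatives when the smallest enclosing clade holding
#' at least `min_scored` scored tips is uniform in state; tips in mixed
#' regions of the tree stay unknown.  Already-scored tips are never changed,
#' so the procedure is idempotent and the unknown set can only shrink.
#'
#' @param phy A `phylo` object.
#' @param traits Trait tibble as returned by [read_trait_table()]; tips of
#'   `phy` absent from the table are treated as unscored.
#' @param min_scored Minimum number of scored tips a clade must contain
#'   before it can donate its state.
#' @param policy `"uniform"` (assign only when every scored tip in the clade
#'   agrees) or `"majority"` (assign the majority state of the smallest
#'   clade with `min_scored` scored tips; ties stay unknown).
#' @return A tibble with one row per tree tip: `tip`, `state`, and `source`
#'   (`"observed"`, `"backfilled"` or `"unknown"`); `n_obs` attribute kept.
#' @export
backfill_uniform_clades <- function(phy, traits, min_scored = 1,
                                    policy = c("uniform", "majority")) {
  policy <- match.arg(policy)
  missing_tips <- setdiff(traits$tip, phy$tip.label)
  if (length(missing_tips)) {
    abort(paste0("trait table tips absent from tree: ",
                 paste(missing_tips, collapse = ", ")))
  }
  ntip <- ape::Ntip(phy)
  state <- rep(NA_integer_, ntip)
  state[match(traits$tip, phy$tip.label)] <- traits$state

  parent <- integer(n_nodes_total(phy))
  parent[phy$edge[, 2]] <- phy$edge[, 1]

  filled <- state
  source <- ifelse(is.na(state), "unknown", "observed")
  for (i in which(is.na(state))) {
    nd <- parent[i]
    while (nd != 0L) {
      sts <- state[clade_tips(phy, nd)]
      sts <- sts[!is.na(sts)]
      if (length(sts) >= min_scored) {
        u <- unique(sts)
        if (policy == "uniform") {
          if (length(u) == 1L) {
            filled[i] <- u
            source[i] <- "backfilled"
          }
        } else {
          tab <- table(sts)
          top <- tab[tab == max(tab)]
          if (length(top) == 1L) {
            filled[i] <- as.integer(names(top))
            source[i] <- "backfilled"
          }
        }
        break
      }
      nd <- parent[nd]
    }
  }
  out <- tibble::tibble(tip = phy$tip.label, state = filled, source = source)
  attr(out, "n_obs") <- attr(traits, "n_obs") %||% 2L
  out
}
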