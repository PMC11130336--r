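# Internal helpers shared across modules.

n_nodes_total <- function(phy) ape::Ntip(phy) + phy$Nnode

#' Root node id of a phylogeny
#'
#' In `ape`'s node numbering the root is always `Ntip + 1`; exposed because
#' focal-node arguments throughout the package take node ids.
#'
#' @param phy A `phylo` object.
#' @return Integer node id of the root.
#' @export
root_node <- function(phy) ape::Ntip(phy) + 1L

# Post-order edge matrix (parents appear after all their descendants).
postorder_edges <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  list(edge = po$edge, length = po$edge.length)
}

# Children listed per node, derived from the edge matrix.
children_map <- function(phy) {
  split(phy$edge[, 2], phy$edge[, 1])
}

# Path of nodes from the root down to `node` (inclusive).
root_path <- function(phy, node) {
  parent <- integer(n_nodes_total(phy))
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  path <- node
  while (parent[path[1]] != 0L) path <- c(parent[path[1]], path)
  path
}

# Tip indices descending from `node` (node itself if a tip).
clade_tips <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  if (node <= ntip) return(node)
  kids <- children_map(phy)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]
    stack <- stack[-1]
    if (nd <= ntip) out <- c(out, nd) else stack <- c(stack, kids[[as.character(nd)]])
  }
  sort(out)
}

# Tiny FNV-1a checksum for provenance stamps (hex string).
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256); keeps h a double-safe 32-bit value
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit multiply by 16777619 (= 2^24 + 403) without double overflow
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
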