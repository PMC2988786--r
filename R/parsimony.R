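# Children of each node from an ape::phylo edge matrix.
phylo_children <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  kids
}

# Resolve a node reference (leaf label, internal label, "root", or numeric
# ape node id) to an ape node id.
resolve_node <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (node < 1L || node > ntip + tree$Nnode) stop("node id out of range")
    return(node)
  }
  if (identical(node, "root")) return(root)
  i <- match(node, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(node, tree$node.label)
    if (!is.na(j)) return(ntip + j)
  }
  stop("unknown node label: ", node)
}

node_name <- function(tree, id) {
  ntip <- ape::Ntip(tree)
  if (id <= ntip) return(tree$tip.label[id])
  if (!is.null(tree$node.label) && nzchar(tree$node.label[id - ntip]))
    return(tree$node.label[id - ntip])
  if (id == ntip + 1L) return("root")
  paste0("node", id)
}

# Number of present leaves in the subtree of each node (postorder sum).
subtree_present_counts <- function(tree, presence) {
  tree <- stats::reorder(tree, "cladewise")
  ntip <- ape::Ntip(tree)
  counts <- integer(ntip + tree$Nnode)
  counts[seq_len(ntip)] <- as.integer(presence[tree$tip.label])
  for (e in rev(seq_len(nrow(tree$edge))))     # ape edges are preorder
    counts[tree$edge[e, 1L]] <- counts[tree$edge[e, 1L]] +
      counts[tree$edge[e, 2L]]
  counts
}

leaves_under <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  out <- integer()
  stack <- node
  kids <- phylo_children(tree)
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    if (v <= ntip) out <- c(out, v) else stack <- c(stack, kids[[v]])
  }
  out
}

#' Dollo gain/loss counts for a candidate origin node
#'
#' Under Dollo parsimony the gene is gained exactly once, on the candidate
#' origin node, and may be lost any number of times below it. Losses are
#' counted per edge: one loss event covers an entire absent clade (a maximal
#' subtree containing no present leaf). The scenario is infeasible when any
#' present leaf lies outside the origin's subtree.
#'
#' @param tree A rooted [ape::phylo] species tree.
#' @param presence Named logical vector over the tree's leaves
#'   (see [read_presence_table()]).
#' @param origin Node reference: a leaf label, an internal node label,
#'   `"root"`, or an ape node id.
#' @return An object of class `scenario_result`: list with `origin`,
#'   `gains`, `losses`, `total`, `feasible`.
#' @export
dollo_counts <- function(tree, presence, origin) {
  presence <- validate_presence(presence, tree)
  if (!any(presence)) stop("presence map has no present taxon")
  org <- resolve_node(tree, origin)
  counts <- subtree_present_counts(tree, presence)
  outside_present <- sum(presence) - counts[org]
  feasible <- outside_present == 0L
  if (!feasible) {
    return(structure(list(origin = node_name(tree, org),
                          gains = NA_integer_, losses = NA_integer_,
                          total = NA_integer_, feasible = FALSE),
                     class = "scenario_result"))
  }
  # Loss edges: child subtrees with zero present leaves hanging off a
  # lineage that still retains the gene.
  kids <- phylo_children(tree)
  losses <- 0L
  stack <- org
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    for (ch in kids[[v]]) {
      if (counts[ch] == 0L) losses <- losses + 1L
      else stack <- c(stack, ch)
    }
  }
  structure(list(origin = node_name(tree, org), gains = 1L,
                 losses = losses, total = 1L + losses, feasible = TRUE),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  if (x$feasible)
    cat(sprintf("<scenario> origin=%s gains=%d losses=%d total=%d\n",
                x$origin, x$gains, x$losses, x$total))
  else
    cat(sprintf("<scenario> origin=%s infeasible\n", x$origin))
  invisible(x)
}

#' Minimum state changes under unordered two-state parsimony
#'
#' Computes the Fitch/Sankoff minimum number of presence/absence state
#' changes on a rooted tree (unit cost, unordered; exact on polytomies).
#' Serves as a lower bound: any feasible Dollo scenario has total events
#' at least this minimum.
#'
#' @inheritParams dollo_counts
#' @return Integer minimum number of state changes, assuming the root state
#'   is free (the cheaper of absent/present at the root).
#' @export
fitch_min_events <- function(tree, presence) {
  presence <- validate_presence(presence, tree)
  tree <- stats::reorder(tree, "cladewise")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  # cost[v, s]: minimal changes in subtree of v given state s (1=absent,
  # 2=present)
  cost <- matrix(0, nn, 2L)
  cost[seq_len(ntip), 1L] <- ifelse(presence[tree$tip.label], Inf, 0)
  cost[seq_len(ntip), 2L] <- ifelse(presence[tree$tip.label], 0, Inf)
  for (e in rev(seq_len(nrow(tree$edge)))) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    cost[par, 1L] <- cost[par, 1L] + min(cost[ch, 1L], cost[ch, 2L] + 1)
    cost[par, 2L] <- cost[par, 2L] + min(cost[ch, 2L], cost[ch, 1L] + 1)
  }
  as.integer(min(cost[ntip + 1L, ]))
}

#' Rank gene-family-origin scenarios
#'
#' Evaluates [dollo_counts()] for each candidate origin and returns the
#' feasible scenarios ordered by total event count (ascending). Scenarios
#' tied on total events are flagged.
#'
#' @inheritParams dollo_counts
#' @param origins Vector of candidate origin node references.
#' @return A data.frame: origin, gains, losses, total, feasible, tie —
#'   feasible scenarios first, sorted by total events.
#' @export
rank_scenarios <- function(tree, presence, origins) {
  stopifnot(length(origins) >= 1L)
  res <- lapply(origins, function(o) dollo_counts(tree, presence, o))
  df <- do.call(rbind, lapply(res, function(r)
    data.frame(origin = r$origin, gains = r$gains, losses = r$losses,
               total = r$total, feasible = r$feasible,
               stringsAsFactors = FALSE)))
  if (!any(df$feasible)) stop("no feasible origin scenario among candidates")
  df <- df[order(!df$feasible, df$total), , drop = FALSE]
  tot_feas <- df$total[df$feasible]
  dup_tot <- unique(tot_feas[duplicated(tot_feas)])
  df$tie <- df$feasible & df$total %in% dup_tot
  rownames(df) <- NULL
  df
}
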