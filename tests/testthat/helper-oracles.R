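# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive: direct enumeration, no sharing of code paths with the
# implementation they check.

AA20_T <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AAX_T <- c(AA20_T, "X")

random_aa <- function(n, alphabet = AA20_T) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# All (c1, c2, h1, h2) quadruples satisfying the spacing bounds, by direct
# filtering of the C-pair x H-pair cross product.
oracle_c2h2 <- function(seq, params = scan_params()) {
  chars <- strsplit(seq, "")[[1]]
  cp <- which(chars == "C"); hp <- which(chars == "H")
  if (length(cp) < 2L || length(hp) < 2L)
    return(data.frame(c1 = integer(), c2 = integer(),
                      h1 = integer(), h2 = integer()))
  g <- expand.grid(c1 = cp, c2 = cp, h1 = hp, h2 = hp)
  keep <- g$c2 - g$c1 - 1L >= params$cc_min &
    g$c2 - g$c1 - 1L <= params$cc_max &
    g$h1 - g$c2 - 1L >= params$ch_min &
    g$h1 - g$c2 - 1L <= params$ch_max &
    g$h2 - g$h1 - 1L >= params$hh_min &
    g$h2 - g$h1 - 1L <= params$hh_max
  g <- g[keep, , drop = FALSE]
  g <- g[order(g$c1, g$c2, g$h1, g$h2), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# Best chain of n hits by exhaustive search over all subsets; returns the
# optimal (span, start) pair, or NULL.
oracle_chain_score <- function(hits, n, max_linker) {
  m <- nrow(hits)
  if (m < n) return(NULL)
  best <- NULL
  for (sub in utils::combn(m, n, simplify = FALSE)) {
    h <- hits[sub, , drop = FALSE]
    h <- h[order(h$c1), , drop = FALSE]
    gaps <- if (n > 1L) h$c1[-1L] - h$h2[-n] - 1L else integer()
    if (any(gaps < 0L | gaps > max_linker)) next
    cand <- c(span = h$h2[n] - h$c1[1L] + 1L, start = h$c1[1L])
    if (is.null(best) || cand["span"] < best["span"] ||
        (cand["span"] == best["span"] && cand["start"] < best["start"]))
      best <- cand
  }
  best
}

# Per-window motif scan: every (offset, spacer) scored independently.
oracle_scan_motif <- function(region, pat) {
  grp <- similarity_grouping()
  chars <- strsplit(region, "")[[1]]
  n <- nchar(region)
  sets <- c(pat$pre, pat$post)
  rows <- list(); k <- 0L
  for (sp in pat$spacer_min:pat$spacer_max) {
    w <- length(pat$pre) + sp + length(pat$post)
    if (w > n) next
    for (st in 1:(n - w + 1L)) {
      dj <- c(seq_along(pat$pre),
              length(pat$pre) + sp + seq_along(pat$post)) - 1L
      qc <- chars[st + dj]
      id <- sim <- logical(length(qc))
      for (j in seq_along(qc)) {
        if (qc[j] == "X") next
        id[j] <- qc[j] %in% sets[[j]]
        cls <- grp[qc[j]]
        sim[j] <- id[j] ||
          (!is.na(cls) && any(grp[sets[[j]]] == cls, na.rm = TRUE))
      }
      k <- k + 1L
      rows[[k]] <- data.frame(start = st, spacer = sp,
                              identity = 100 * sum(id) / length(qc),
                              similarity = 100 * sum(sim) / length(qc))
    }
  }
  if (k == 0L) return(data.frame(start = integer(), spacer = integer(),
                                 identity = numeric(),
                                 similarity = numeric()))
  do.call(rbind, rows)
}

# Exhaustive Dollo: enumerate every subset of edges below `origin` as loss
# edges; a leaf retains the gene iff its path from the origin carries no
# loss edge. Returns minimal loss count (the gain is fixed at 1), or NA if
# infeasible (a present leaf outside the origin subtree).
oracle_dollo_losses <- function(tree, presence, origin) {
  presence <- presence[tree$tip.label]
  ntip <- ape::Ntip(tree)
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  org <- if (identical(origin, "root")) ntip + 1L else {
    i <- match(origin, tree$tip.label)
    if (!is.na(i)) i
    else ntip + match(origin, tree$node.label)
  }
  # edges strictly below org
  below <- logical(ntip + tree$Nnode)
  below[org] <- TRUE
  for (e in seq_len(nrow(tree$edge)))   # cladewise: parents precede children
    if (below[tree$edge[e, 1L]]) below[tree$edge[e, 2L]] <- TRUE
  sub_edges <- which(below[tree$edge[, 1L]])
  # path matrix: leaf x edge
  inside_leaves <- which(below[seq_len(ntip)])
  if (any(presence[!below[seq_len(ntip)]])) return(NA_integer_)
  M <- matrix(0L, length(inside_leaves), length(sub_edges))
  for (li in seq_along(inside_leaves)) {
    v <- inside_leaves[li]
    while (v != org) {
      e <- which(tree$edge[, 2L] == v)
      j <- match(e, sub_edges)
      M[li, j] <- 1L
      v <- parent[v]
    }
  }
  E <- length(sub_edges)
  want <- as.integer(presence[inside_leaves])
  if (E == 0L)   # origin is a leaf: no edges below, zero losses if present
    return(if (all(want == 1L)) 0L else NA_integer_)
  best <- NA_integer_
  S <- vapply(0:(2^E - 1L), function(mask) as.integer(intToBits(mask)[1:E]),
              integer(E))
  hitcounts <- M %*% S                       # leaves x subsets
  retained <- hitcounts == 0L
  valid <- colSums(retained == (want == 1L)) == length(want)
  if (any(valid)) best <- min(colSums(S[, valid, drop = FALSE]))
  best
}

# Random rooted tree with unique labelled leaves and labelled internals.
random_rooted_tree <- function(nleaf) {
  tr <- ape::rtree(nleaf, rooted = TRUE)
  tr$node.label <- paste0("n", seq_len(tr$Nnode))
  tr
}

paper_topology <- function() {
  read_newick(paste0("(Porifera,(Ctenophora,(Placozoa,",
                     "(Cnidaria,Bilateria)Cni_Bil)Pla_Cni_Bil)",
                     "post_Ctenophora)Metazoa;"))
}

paper_presence <- function() {
  c(Porifera = FALSE, Ctenophora = FALSE, Placozoa = TRUE,
    Cnidaria = TRUE, Bilateria = TRUE)
}
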