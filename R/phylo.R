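# Maximum-parsimony phylogeny reconstruction from a binary mutation x region
# presence matrix, with a germline (all-absent) outgroup rooting the tree.
#
# Topologies are represented during the search as nested lists: a leaf is an
# integer index into the (collapsed) region profiles; an internal node is a
# list of its two children. Fitch scoring is vectorized over mutations using
# 2-bit state sets (1 = absent, 2 = present, 3 = either).

# All rooted leaf-labeled binary topologies over `leaves`, by stepwise
# insertion. For k leaves there are (2k-3)!! of them.
.all_rooted_topologies <- function(leaves) {
  trees <- list(leaves[1])
  for (leaf in leaves[-1]) {
    trees <- unlist(lapply(trees, .insert_leaf_everywhere, leaf = leaf),
                    recursive = FALSE)
  }
  trees
}

# Every tree obtained by attaching `leaf` on one edge of `tree`, including
# above its root (which is the trunk edge of the region subtree).
.insert_leaf_everywhere <- function(tree, leaf) {
  out <- list(list(tree, leaf))
  if (is.list(tree)) {
    for (i in 1:2) {
      for (sub in .insert_leaf_everywhere(tree[[i]], leaf)) {
        t2 <- tree
        t2[[i]] <- sub
        out[[length(out) + 1L]] <- t2
      }
    }
  }
  out
}

# Bottom-up Fitch pass. leaf_sets: list over leaf indices of integer vectors
# (one entry per mutation; 1 = absent, 2 = present). Returns the root state
# sets and the per-mutation union (state-change) counts.
.fitch_up <- function(tree, leaf_sets) {
  if (!is.list(tree)) {
    return(list(set = leaf_sets[[tree]],
                changes = integer(length(leaf_sets[[tree]]))))
  }
  a <- .fitch_up(tree[[1]], leaf_sets)
  b <- .fitch_up(tree[[2]], leaf_sets)
  inter <- bitwAnd(a$set, b$set)
  empty <- inter == 0L
  set <- ifelse(empty, bitwOr(a$set, b$set), inter)
  list(set = set, changes = a$changes + b$changes + empty)
}

# Parsimony score of a rooted region topology with a germline outgroup fixed
# at the absent state: Fitch change count plus one change on the trunk edge
# for every mutation whose root set excludes "absent".
.score_topology <- function(tree, leaf_sets, weights) {
  f <- .fitch_up(tree, leaf_sets)
  trunk_change <- bitwAnd(f$set, 1L) == 0L
  sum((f$changes + trunk_change) * weights)
}

# Canonical label-sorted Newick-like string of a topology (no lengths);
# used for the deterministic lexicographic tie-break.
.canonical_string <- function(tree, labels) {
  if (!is.list(tree)) return(labels[tree])
  kids <- sort(c(.canonical_string(tree[[1]], labels),
                 .canonical_string(tree[[2]], labels)))
  paste0("(", paste(kids, collapse = ","), ")")
}

# Branch-and-bound over stepwise leaf insertion. The Fitch score of a
# partial tree (a leaf subset) never exceeds the score of any completion,
# so branches scoring strictly above the incumbent are pruned; ties are
# kept so the lexicographic tie-break sees every optimum.
.bnb_topologies <- function(n_leaves, leaf_sets, weights) {
  best <- list(score = Inf, trees = list())
  recurse <- function(tree, next_leaf) {
    s <- .score_topology(tree, leaf_sets, weights)
    if (s > best$score) return()
    if (next_leaf > n_leaves) {
      if (s < best$score) {
        best$score <<- s
        best$trees <<- list(tree)
      } else {
        best$trees[[length(best$trees) + 1L]] <<- tree
      }
      return()
    }
    for (t2 in .insert_leaf_everywhere(tree, next_leaf)) {
      recurse(t2, next_leaf + 1L)
    }
  }
  recurse(1L, 2L)
  best
}

#' Reconstruct a maximum-parsimony tumor phylogeny for one patient
#'
#' Builds the rooted maximum-parsimony tree over a patient's tumor regions
#' from the binary presence matrix, with the germline (no somatic
#' mutations) as outgroup root. The search is exact: all rooted
#' leaf-labeled topologies are enumerated for up to 6 distinct region
#' profiles, and branch-and-bound with the monotone Fitch bound is used for
#' 7-10. Regions with identical mutation profiles are collapsed before the
#' search and re-attached as zero-length cherries. Among equally
#' parsimonious topologies the one with the lexicographically smallest
#' canonical (label-sorted) Newick string is returned, making results
#' deterministic.
#'
#' Mutations are assigned to edges by a two-state minimum-change dynamic
#' program (Sankoff) with the root fixed at the germline state and
#' traceback ties resolved toward the parent state; an edge's length is
#' the number of mutations changing state on it, so the sum of edge
#' lengths equals the parsimony score, the trunk edge leaving the
#' germline root carries exactly the trunk (all-regions) mutations, and a
#' mutation occupies exactly one edge precisely when it needs no
#' homoplasy on the chosen tree. Somatic gains are treated as effectively
#' irreversible: loss (back-mutation) edges arise only for characters
#' incompatible with the tree, and they count toward the score.
#'
#' @param mat Binary presence matrix from [build_mutation_matrix()]
#'   (mutations x regions, no all-zero rows, at most 10 regions).
#' @param patient_id Optional patient label stored on the tree.
#' @return Object of class `mrith_tree`: list with `patient_id`,
#'   `region_ids`, `edges` (data frame `parent`, `child`, `parent_label`,
#'   `child_label`, `length`), `edge_mutations` (list of variant-key
#'   vectors parallel to `edges`), `parsimony_score`, `trunk_len`,
#'   `n_trunk`, `pattern` (`"LINEAR"`/`"BRANCHED"`), `newick`.
#' @export
build_phylogenetic_tree <- function(mat, patient_id = NA_character_) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) == 0) stop("empty mutation matrix: no tree to build")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("R", seq_len(ncol(mat)))
  if (is.null(rownames(mat))) rownames(mat) <- paste0("m", seq_len(nrow(mat)))
  if (any(rowSums(mat) == 0)) stop("matrix has an all-zero mutation row")
  n_regions <- ncol(mat)
  if (n_regions > 10) {
    stop("more than 10 regions: exact parsimony search is not attempted; ",
         "subsample regions first")
  }

  # Collapse identical region profiles (columns).
  prof <- apply(mat, 2, paste, collapse = "")
  groups <- split(colnames(mat), prof)
  groups <- lapply(groups, sort)
  # Deterministic group order: by the smallest member label.
  groups <- groups[order(vapply(groups, `[`, "", 1))]
  reps <- vapply(groups, `[`, "", 1)
  cmat <- mat[, reps, drop = FALSE]
  n_leaves <- ncol(cmat)
  group_labels <- vapply(groups, `[`, "", 1)

  # Unique mutation rows with multiplicities, for the search only.
  rowpat <- apply(cmat, 1, paste, collapse = "")
  urows <- !duplicated(rowpat)
  umat <- cmat[urows, , drop = FALSE]
  weights <- as.integer(table(rowpat)[apply(umat, 1, paste, collapse = "")])
  leaf_sets <- lapply(seq_len(n_leaves),
                      function(j) ifelse(umat[, j] == 1L, 2L, 1L))

  if (n_leaves == 1) {
    topo <- 1L
    score <- sum(weights)  # every mutation gained once on the trunk
  } else if (n_leaves <= 6) {
    topos <- .all_rooted_topologies(seq_len(n_leaves))
    scores <- vapply(topos, .score_topology, numeric(1),
                     leaf_sets = leaf_sets, weights = weights)
    score <- min(scores)
    cand <- topos[scores == score]
    strs <- vapply(cand, .canonical_string, "", labels = group_labels)
    topo <- cand[[which(strs == min(strs))[1]]]
  } else {
    best <- .bnb_topologies(n_leaves, leaf_sets, weights)
    score <- best$score
    strs <- vapply(best$trees, .canonical_string, "", labels = group_labels)
    topo <- best$trees[[which(strs == min(strs))[1]]]
  }

  tree <- .assemble_tree(topo, cmat, groups, group_labels, mat)
  tree$patient_id <- patient_id
  tree$parsimony_score <- as.integer(score)
  tree$pattern <- classify_evolution_pattern(mat)
  stopifnot(sum(tree$edges$length) == score)
  tree$newick <- .newick_string(tree)
  class(tree) <- "mrith_tree"
  tree
}

# Turn the winning topology into an explicit node/edge table with
# per-mutation minimum-change edge assignments (on the full, uncollapsed
# mutation set) and expand collapsed region groups into zero-length
# cherries. Assignment is a two-state Sankoff DP with the germline root
# forced to "absent" and traceback ties resolved toward the parent state,
# so the trunk edge carries exactly the truly clonal (all-regions)
# mutations even when homoplasy is present.
.assemble_tree <- function(topo, cmat, groups, group_labels, full_mat) {
  m <- nrow(cmat)
  BIG <- 1e9

  nodes <- data.frame(id = 1L, label = "germline", is_leaf = FALSE,
                      stringsAsFactors = FALSE)
  edges <- data.frame(parent = integer(0), child = integer(0),
                      stringsAsFactors = FALSE)
  cost0 <- list(); cost1 <- list()  # per-node min changes below, by state
  next_id <- 2L

  # Bottom-up: create nodes, record Sankoff costs. Children are ordered by
  # canonical string so the emitted structure is deterministic.
  build <- function(t) {
    id <- next_id; next_id <<- next_id + 1L
    if (!is.list(t)) {
      nodes[nrow(nodes) + 1L, ] <<- list(id, group_labels[t], TRUE)
      present <- cmat[, t] == 1L
      cost0[[id]] <<- ifelse(present, BIG, 0)
      cost1[[id]] <<- ifelse(present, 0, BIG)
      return(id)
    }
    strs <- vapply(t, .canonical_string, "", labels = group_labels)
    t <- t[order(strs)]
    nodes[nrow(nodes) + 1L, ] <<- list(id, NA_character_, FALSE)
    kids <- lapply(t, build)
    for (k in kids) edges[nrow(edges) + 1L, ] <<- list(id, as.integer(k))
    c0 <- 0; c1 <- 0
    for (k in kids) {
      k <- as.integer(k)
      c0 <- c0 + pmin(cost0[[k]], cost1[[k]] + 1)
      c1 <- c1 + pmin(cost1[[k]], cost0[[k]] + 1)
    }
    cost0[[id]] <<- c0
    cost1[[id]] <<- c1
    id
  }
  subroot <- as.integer(build(topo))
  edges <- rbind(data.frame(parent = 1L, child = subroot), edges)

  # Topological (parent-before-child) edge order.
  done <- 1L
  ord <- integer(0)
  remaining <- seq_len(nrow(edges))
  while (length(remaining)) {
    sel <- remaining[edges$parent[remaining] %in% done]
    ord <- c(ord, sel)
    done <- c(done, edges$child[sel])
    remaining <- setdiff(remaining, sel)
  }
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL

  # Traceback: germline fixed at "absent" (state 0); a child takes the
  # cheaper state, keeping the parent's on ties (changes are deferred away
  # from the root, so the trunk stays free of homoplasy).
  states <- matrix(NA_integer_, nrow = max(nodes$id), ncol = m)
  states[1L, ] <- 0L
  for (i in seq_len(nrow(edges))) {
    p <- edges$parent[i]; ch <- edges$child[i]
    ps <- states[p, ]
    t0 <- cost0[[ch]] + (ps != 0L)
    t1 <- cost1[[ch]] + (ps != 1L)
    states[ch, ] <- ifelse(t0 < t1, 0L, ifelse(t1 < t0, 1L, ps))
  }

  # Edge lengths and mutation assignments (cmat rows are the full mutation
  # set, only the columns were collapsed).
  edge_mut <- vector("list", nrow(edges))
  lens <- integer(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    changed <- states[edges$parent[i], ] != states[edges$child[i], ]
    edge_mut[[i]] <- rownames(cmat)[changed]
    lens[i] <- sum(changed)
  }
  edges$length <- lens

  # Expand collapsed groups: a leaf standing for k > 1 identical regions
  # becomes an internal node with k zero-length leaf children.
  for (gi in seq_along(groups)) {
    members <- groups[[gi]]
    if (length(members) == 1) next
    leaf_id <- nodes$id[!is.na(nodes$label) & nodes$label == group_labels[gi]]
    nodes$label[nodes$id == leaf_id] <- NA_character_
    nodes$is_leaf[nodes$id == leaf_id] <- FALSE
    for (r in members) {
      id <- next_id; next_id <- id + 1L
      nodes[nrow(nodes) + 1L, ] <- list(id, r, TRUE)
      edges[nrow(edges) + 1L, ] <- list(leaf_id, id, 0L)
      edge_mut[[length(edge_mut) + 1L]] <- character(0)
    }
  }

  labmap <- structure(nodes$label, names = as.character(nodes$id))
  edges$parent_label <- unname(labmap[as.character(edges$parent)])
  edges$child_label <- unname(labmap[as.character(edges$child)])
  edges <- edges[c("parent", "child", "parent_label", "child_label", "length")]

  trunk_i <- which(edges$parent == 1L)
  list(region_ids = sort(colnames(full_mat)),
       nodes = nodes, edges = edges, edge_mutations = edge_mut,
       trunk_len = edges$length[trunk_i],
       n_trunk = sum(rowSums(full_mat) == ncol(full_mat)))
}

# Newick serialization with mutation-count branch lengths and the root
# labeled "germline". Children are emitted sorted by their subtree string.
.newick_string <- function(tree) {
  edges <- tree$edges
  kids_of <- split(seq_len(nrow(edges)), edges$parent)
  render <- function(node_id) {
    ki <- kids_of[[as.character(node_id)]]
    if (is.null(ki)) {
      return(tree$nodes$label[tree$nodes$id == node_id])
    }
    subs <- vapply(ki, function(i) {
      paste0(render(edges$child[i]), ":", edges$length[i])
    }, "")
    paste0("(", paste(sort(subs), collapse = ","), ")")
  }
  paste0(render(1L), "germline;")
}

#' Write a tumor phylogeny as Newick
#'
#' Branch lengths are mutation counts; the root is labeled `germline`.
#' Re-reading the file (e.g. with `ape::read.tree`) reproduces the topology
#' and edge lengths exactly.
#'
#' @param tree An `mrith_tree` from [build_phylogenetic_tree()].
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "mrith_tree"))
  leaves <- tree$nodes$label[tree$nodes$is_leaf]
  if (any(is.na(leaves) | !nzchar(leaves))) stop("unnamed leaf")
  writeLines(tree$newick, path, sep = "\n")
  invisible(path)
}

#' Classify a patient's evolution pattern as linear or branched
#'
#' The pattern is read from the distinct subclonal presence patterns
#' (unique matrix rows excluding the all-ones trunk row): if every pair is
#' nested under subset inclusion the subclones form a single chain and the
#' evolution is `LINEAR`; any non-nested pair makes it `BRANCHED`. A tumor
#' with no branch mutations is `LINEAR`.
#'
#' @param mat Binary presence matrix.
#' @return `"LINEAR"` or `"BRANCHED"`.
#' @export
classify_evolution_pattern <- function(mat) {
  stopifnot(is.matrix(mat))
  branch <- mat[rowSums(mat) < ncol(mat), , drop = FALSE]
  if (nrow(branch) == 0) return("LINEAR")
  pats <- unique(as.data.frame(branch))
  n <- nrow(pats)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- as.integer(pats[i, ]); b <- as.integer(pats[j, ])
        if (any(a > b) && any(b > a)) return("BRANCHED")
      }
    }
  }
  "LINEAR"
}

#' Trunk fraction of a phylogeny
#'
#' Length of the trunk edge (germline to the tumor's most recent common
#' ancestor) divided by the total tree length. On a homoplasy-free matrix
#' this equals one minus the ITH index.
#'
#' @param tree An `mrith_tree`.
#' @return Fraction in \[0, 1\].
#' @export
trunk_fraction_from_tree <- function(tree) {
  stopifnot(inherits(tree, "mrith_tree"))
  tree$trunk_len / sum(tree$edges$length)
}

#' Root-to-leaf path lengths of a phylogeny
#'
#' @param tree An `mrith_tree`.
#' @return Named numeric vector: for each region leaf, the sum of edge
#'   lengths on its path to the germline root (its total mutation count on
#'   a homoplasy-free tree).
#' @export
path_lengths <- function(tree) {
  stopifnot(inherits(tree, "mrith_tree"))
  edges <- tree$edges
  depth <- c(`1` = 0)
  # edges are stored parent-before-child
  for (i in seq_len(nrow(edges))) {
    depth[as.character(edges$child[i])] <-
      depth[as.character(edges$parent[i])] + edges$length[i]
  }
  leaves <- tree$nodes[tree$nodes$is_leaf, ]
  structure(unname(depth[as.character(leaves$id)]), names = leaves$label)
}

#' @export
print.mrith_tree <- function(x, ...) {
  cat(sprintf("mrith_tree%s: %d regions, parsimony score %d, trunk %d, %s\n",
              if (is.na(x$patient_id)) "" else paste0(" [", x$patient_id, "]"),
              length(x$region_ids), x$parsimony_score, x$trunk_len,
              x$pattern))
  cat(" ", x$newick, "\n")
  invisible(x)
}
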