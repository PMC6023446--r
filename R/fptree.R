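# FP-tree internals for frequent-itemset mining.
#
# Items are integer ids, 1 = highest-ranked item in the fixed mining order
# (global support descending, ties lexicographic). Transactions inserted into
# a tree must list items in increasing id (i.e. decreasing support) so that
# shared prefixes collapse; the header table chains all nodes of one item.
# Node storage is flat vectors inside an environment, grown by doubling.

fp_tree_new <- function(n_items, capacity = 64L) {
  tree <- new.env(parent = emptyenv())
  tree$item <- integer(capacity)
  tree$cnt <- numeric(capacity)
  tree$parent <- integer(capacity)
  tree$children <- vector("list", capacity)  # named integer vectors
  tree$header <- vector("list", n_items)     # node indices per item
  tree$n_nodes <- 1L                         # node 1 is the root
  tree$item[1] <- 0L
  tree
}

fp_tree_grow <- function(tree) {
  cap <- length(tree$item)
  new_cap <- cap * 2L
  length(tree$item) <- new_cap
  length(tree$cnt) <- new_cap
  length(tree$parent) <- new_cap
  length(tree$children) <- new_cap
  tree$item[(cap + 1L):new_cap] <- 0L
  tree$cnt[(cap + 1L):new_cap] <- 0
  tree$parent[(cap + 1L):new_cap] <- 0L
  invisible(tree)
}

# Insert one ordered item vector with multiplicity `count`.
fp_tree_insert <- function(tree, items, count) {
  node <- 1L
  for (it in items) {
    key <- as.character(it)
    child <- tree$children[[node]][key]
    if (length(child) == 0 || is.na(child)) {
      if (tree$n_nodes >= length(tree$item)) fp_tree_grow(tree)
      tree$n_nodes <- tree$n_nodes + 1L
      new <- tree$n_nodes
      tree$item[new] <- it
      tree$cnt[new] <- 0
      tree$parent[new] <- node
      tree$children[[node]] <- c(tree$children[[node]], setNames(new, key))
      tree$header[[it]] <- c(tree$header[[it]], new)
      child <- new
    }
    node <- unname(child)
    tree$cnt[node] <- tree$cnt[node] + count
  }
  invisible(tree)
}

fp_tree_build <- function(item_vecs, counts, n_items) {
  tree <- fp_tree_new(n_items)
  for (i in seq_along(item_vecs)) {
    if (length(item_vecs[[i]]) > 0) {
      fp_tree_insert(tree, item_vecs[[i]], counts[i])
    }
  }
  tree
}

# Support of item `it` in the tree = sum of counts along its header chain.
fp_tree_item_support <- function(tree, it) {
  sum(tree$cnt[tree$header[[it]]])
}

# Path from a node up to (excluding) the root, returned root-to-node.
fp_tree_path <- function(tree, node) {
  path <- integer(0)
  while (node != 1L) {
    path <- c(tree$item[node], path)
    node <- tree$parent[node]
  }
  path
}

# TRUE when the tree is one chain from the root (every node <= 1 child).
fp_tree_single_path <- function(tree) {
  node <- 1L
  repeat {
    kids <- tree$children[[node]]
    if (length(kids) == 0) return(TRUE)
    if (length(kids) > 1) return(FALSE)
    node <- unname(kids[1])
  }
}

fp_tree_the_path <- function(tree) {
  items <- integer(0); cnts <- numeric(0)
  node <- 1L
  repeat {
    kids <- tree$children[[node]]
    if (length(kids) == 0) break
    node <- unname(kids[1])
    items <- c(items, tree$item[node])
    cnts <- c(cnts, tree$cnt[node])
  }
  list(items = items, counts = cnts)
}

# Recursive FP-Growth over a tree. `present` lists item ids present in the
# tree in increasing id order; emits (itemset, count) pairs into `acc`.
fp_mine <- function(tree, present, min_count, suffix, acc) {
  if (fp_tree_single_path(tree)) {
    path <- fp_tree_the_path(tree)
    k <- length(path$items)
    if (k > 0) {
      if (k <= 16L) {
        for (mask in seq_len(2^k - 1L)) {
          sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
          cnt <- min(path$counts[sel])
          if (cnt >= min_count) {
            acc$push(c(suffix, path$items[sel]), cnt)
          }
        }
      } else {
        # very deep single paths fall back to the generic recursion
        fp_mine_generic(tree, present, min_count, suffix, acc)
      }
    }
    return(invisible(NULL))
  }
  fp_mine_generic(tree, present, min_count, suffix, acc)
}

fp_mine_generic <- function(tree, present, min_count, suffix, acc) {
  # least-frequent first: largest item id first in the fixed order
  for (it in rev(present)) {
    sup <- fp_tree_item_support(tree, it)
    if (sup < min_count) next
    new_suffix <- c(suffix, it)
    acc$push(new_suffix, sup)
    # conditional pattern base of `it`
    nodes <- tree$header[[it]]
    paths <- lapply(nodes, function(nd) fp_tree_path(tree, tree$parent[nd]))
    cnts <- tree$cnt[nodes]
    nonempty <- lengths(paths) > 0
    if (!any(nonempty)) next
    paths <- paths[nonempty]; cnts <- cnts[nonempty]
    cond_support <- tapply(rep(cnts, lengths(paths)), unlist(paths), sum)
    keep <- as.integer(names(cond_support))[cond_support >= min_count]
    if (length(keep) == 0) next
    pruned <- lapply(paths, function(p) p[p %in% keep])
    cond_tree <- fp_tree_build(pruned, cnts, max(keep))
    fp_mine(cond_tree, sort(keep), min_count, new_suffix, acc)
  }
  invisible(NULL)
}

itemset_accumulator <- function() {
  sets <- vector("list", 256L)
  counts <- numeric(256L)
  n <- 0L
  push <- function(items, count) {
    if (n >= length(sets)) {
      length(sets) <<- 2L * length(sets)
      length(counts) <<- 2L * length(counts)
    }
    n <<- n + 1L
    sets[[n]] <<- items
    counts[n] <<- count
  }
  collect <- function() list(sets = sets[seq_len(n)], counts = counts[seq_len(n)])
  list(push = push, collect = collect)
}
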