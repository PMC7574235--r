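# Duplication/loss reconciliation of a rooted gene tree against a rooted
# binary species tree by the classic last-common-ancestor mapping.

#' Check that a species tree is strictly binary
#'
#' Reconciliation requires a fully resolved species tree; any polytomy
#' must be resolved by the caller first.
#'
#' @param tree Rooted `ape::phylo`.
#' @return Invisibly `TRUE`; otherwise an error naming the first
#'   offending node.
#' @export
check_binary <- function(tree) {
  ntip <- length(tree$tip.label)
  for (v in sort(unique(tree$edge[, 1L]))) {
    k <- sum(tree$edge[, 1L] == v)
    if (k != 2L) {
      desc <- tree$tip.label[intersect(phangorn::Descendants(tree, v, "tips")[[1L]],
                                       seq_len(ntip))]
      stop(sprintf("polytomy (%d children) at the ancestor of {%s}", k,
                   paste(utils::head(desc, 4L), collapse = ",")), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Build a gene-leaf to species map from leaf names
#'
#' Leaf names follow the `Species_gene` convention: the token before the
#' first underscore must be a species-tree leaf label.
#'
#' @param gene_leaves Character vector of gene-tree leaf names.
#' @param species Character vector of species-tree leaf labels.
#' @return Named character vector mapping each gene leaf to a species.
#' @export
leaf_map_from_names <- function(gene_leaves, species) {
  sp <- sub("^([^_]+)_.*$", "\\1", gene_leaves)
  bad <- setdiff(unique(sp), species)
  if (length(bad))
    stop("leaf species token(s) not in the species tree: ",
         paste(bad, collapse = ", "), call. = FALSE)
  stats::setNames(sp, gene_leaves)
}

species_node_labels <- function(sp) {
  ntip <- length(sp$tip.label)
  nnode <- sp$Nnode
  labs <- character(ntip + nnode)
  labs[seq_len(ntip)] <- sp$tip.label
  for (v in (ntip + 1L):(ntip + nnode)) {
    labs[v] <- if (!is.null(sp$node.label) && nzchar(sp$node.label[v - ntip]))
      sp$node.label[v - ntip] else paste0("n", v)
  }
  labs
}

#' LCA reconciliation of a gene tree with a species tree
#'
#' Maps every gene-tree node to the last common ancestor of its leaves'
#' species; a node is a duplication iff its mapping equals the mapping of
#' at least one child; losses are counted from the depth gaps between a
#' node's mapping and its children's mappings (with a one-edge discount
#' per speciation child).  The resulting totals are the minimum
#' duplication+loss reconciliation for the given rooted gene tree.
#'
#' @param gene_tree Rooted binary `ape::phylo`.
#' @param species_tree Rooted binary `ape::phylo`.
#' @param leaf_map Named character vector gene-leaf -> species-leaf;
#'   `NULL` to parse `Species_gene` leaf names.
#' @return A `reconciliation` list: `map`, `events` (per gene node),
#'   `duplications`, `losses`, and per-species-branch tallies.
#' @export
lca_reconcile <- function(gene_tree, species_tree, leaf_map = NULL) {
  check_binary(species_tree)
  sp <- species_tree
  gt <- gene_tree
  sntip <- length(sp$tip.label)
  snn <- sntip + sp$Nnode
  parent <- integer(snn); parent[sntip + 1L] <- 0L
  for (e in seq_len(nrow(sp$edge))) parent[sp$edge[e, 2L]] <- sp$edge[e, 1L]
  sroot <- sntip + 1L
  depth <- integer(snn)
  depth[sroot] <- 0L   # depths by relaxation from the root
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(sp$edge))) {
      v <- sp$edge[e, 1L]; c <- sp$edge[e, 2L]
      if (depth[c] != depth[v] + 1L) { depth[c] <- depth[v] + 1L; changed <- TRUE }
    }
    if (!changed) break
  }
  anc_path <- function(v) {
    out <- v
    while (parent[v] != 0L) { v <- parent[v]; out <- c(out, v) }
    out
  }
  lca <- function(a, b) {
    pa <- anc_path(a)
    pb <- anc_path(b)
    intersect(pa, pb)[1L]
  }
  if (is.null(leaf_map))
    leaf_map <- leaf_map_from_names(gt$tip.label, sp$tip.label)
  miss <- setdiff(gt$tip.label, names(leaf_map))
  if (length(miss))
    stop("gene leaf without species mapping: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sp_index <- stats::setNames(seq_len(sntip), sp$tip.label)
  gntip <- length(gt$tip.label)
  gnn <- gntip + gt$Nnode
  M <- integer(gnn)
  for (i in seq_len(gntip)) M[i] <- sp_index[[leaf_map[[gt$tip.label[i]]]]]
  po <- ape::reorder.phylo(gt, "postorder")$edge
  kids <- split(po[, 2L], po[, 1L])
  # in ape postorder every edge of a subtree precedes the subtree's own
  # parent edge, so first-appearance order of parents is a valid postorder
  internal_order <- unique(po[, 1L])
  events <- rep(NA_character_, gnn)
  slabs <- species_node_labels(sp)
  dup_by <- stats::setNames(numeric(snn), slabs)
  loss_by <- stats::setNames(numeric(snn), slabs)
  for (v in internal_order) {
    ch <- kids[[as.character(v)]]
    if (length(ch) != 2L)
      stop("gene tree is not binary at an internal node", call. = FALSE)
    M[v] <- lca(M[ch[1L]], M[ch[2L]])
    dup <- M[v] == M[ch[1L]] || M[v] == M[ch[2L]]
    events[v] <- if (dup) "duplication" else "speciation"
    if (dup) dup_by[M[v]] <- dup_by[M[v]] + 1
    for (c in ch) {
      k <- depth[M[c]] - depth[M[v]]
      nl <- k - if (dup) 0L else 1L
      if (nl > 0L) {
        # attribute each loss to the sibling branch left at each step
        path <- rev(anc_path(M[c]))          # root .. M[c]
        i0 <- match(M[v], path)
        steps <- seq.int(i0, length(path) - 1L)
        if (!dup) steps <- steps[-1L]        # first step covered by sibling
        for (s in steps) {
          u <- path[s]; on_path <- path[s + 1L]
          sib <- setdiff(sp$edge[sp$edge[, 1L] == u, 2L], on_path)
          loss_by[sib] <- loss_by[sib] + 1
        }
      }
    }
  }
  structure(list(map = M, events = events,
                 duplications = sum(dup_by), losses = sum(loss_by),
                 dup_by_branch = dup_by, loss_by_branch = loss_by,
                 species_labels = slabs, leaf_map = leaf_map,
                 gene_tree = gt, species_tree = sp),
            class = "reconciliation")
}

#' Per-branch duplication/loss table
#'
#' One row per species-tree node (the branch leading into it; the root row
#' holds events placed above the earliest speciation), plus a TOTAL row
#' equal to the reconciliation totals.
#'
#' @param rec A `reconciliation` from [lca_reconcile()].
#' @return Data frame with `branch`, `duplications`, `losses`.
#' @export
event_report <- function(rec) {
  stopifnot(inherits(rec, "reconciliation"))
  df <- data.frame(branch = rec$species_labels,
                   duplications = as.numeric(rec$dup_by_branch),
                   losses = as.numeric(rec$loss_by_branch),
                   stringsAsFactors = FALSE)
  rbind(df, data.frame(branch = "TOTAL", duplications = rec$duplications,
                       losses = rec$losses, stringsAsFactors = FALSE))
}
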