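# Independent oracles used to cross-check the package's own algorithms.
# They deliberately share no code with the implementations under test:
# alignment scores come from Biostrings::pairwiseAlignment, parses from
# exhaustive enumeration, reconciliations from brute-force search over
# valid mappings.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62 + 0.0
})

# best local protein-vs-six-frame score; hits may not cross in-frame stops
oracle_search_best <- function(query, seq, gap_open = -11, gap_extend = -1) {
  best <- -Inf
  for (fr in six_frame(seq)) {
    for (seg in strsplit(fr$aa, "*", fixed = TRUE)[[1L]]) {
      if (nchar(seg) < 1L) next
      s <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(query), Biostrings::AAString(seg),
        substitutionMatrix = blosum62, gapOpening = -gap_open,
        gapExtension = -gap_extend, type = "local", scoreOnly = TRUE)
      best <- max(best, s)
    }
  }
  best
}

# exhaustive GT..AG parse enumeration for <= 2 introns: splice every
# admissible intron combination out of the window, score the query against
# all three frame translations by local alignment (stop rows overridden as
# in the DP), subtract the per-intron penalty, and take the maximum.
oracle_splice_best <- function(query, win, params) {
  mat <- score_matrix(params$matrix, stop_score = params$stop_score)
  n <- nchar(win)
  ch <- strsplit(win, "")[[1L]]
  gt <- which(ch == "G" & c(ch[-1L], "") == "T")          # donor starts (1-based)
  ag <- which(ch == "A" & c(ch[-1L], "") == "G") + 2L     # acceptor ends (exclusive+1)
  introns <- list()
  for (d in gt) for (a in ag) {
    if (a - d >= params$min_intron && a <= n + 1L)
      introns[[length(introns) + 1L]] <- c(d, a)          # [d, a) 1-based excl
  }
  splice <- function(combo) {
    keep <- rep(TRUE, n)
    for (iv in combo) keep[iv[1L]:(iv[2L] - 1L)] <- FALSE
    paste(ch[keep], collapse = "")
  }
  cands <- list(list())
  for (k in seq_along(introns)) cands[[length(cands) + 1L]] <- introns[k]
  if (length(introns) >= 2L) {
    for (i in seq_along(introns)) for (j in seq_along(introns)) {
      if (introns[[i]][2L] <= introns[[j]][1L])
        cands[[length(cands) + 1L]] <- list(introns[[i]], introns[[j]])
    }
  }
  seqs <- character(); pen <- numeric()
  for (cb in cands) {
    s <- splice(cb)
    for (f in 0:2) {
      aa <- translate_dna(s, f)
      if (nchar(aa) == 0L) next
      seqs <- c(seqs, aa)
      pen <- c(pen, length(cb) * params$intron_penalty)
    }
  }
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(seqs), Biostrings::AAString(query),
    substitutionMatrix = mat, gapOpening = -params$gap_open,
    gapExtension = -params$gap_extend, type = "local", scoreOnly = TRUE)
  max(sc + pen)
}

# plain recursive affine-gap global alignment score (no memoization)
oracle_global_score <- function(a, b, mat, open = -11, ext = -1) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  rec <- function(i, j, state) {
    if (i == 0L && j == 0L) return(if (state == 0L) 0 else -Inf)
    best <- -Inf
    if (i > 0L && j > 0L && state == 0L) {
      best <- max(best, max(rec(i - 1L, j - 1L, 0L), rec(i - 1L, j - 1L, 1L),
                            rec(i - 1L, j - 1L, 2L)) + mat[av[i], bv[j]])
    }
    if (state == 1L && i > 0L) {   # gap in b consuming a
      best <- max(best, rec(i - 1L, j, 1L) + ext,
                  max(rec(i - 1L, j, 0L), rec(i - 1L, j, 2L)) + open + ext)
    }
    if (state == 2L && j > 0L) {
      best <- max(best, rec(i, j - 1L, 2L) + ext,
                  max(rec(i, j - 1L, 0L), rec(i, j - 1L, 1L)) + open + ext)
    }
    best
  }
  n <- length(av); m <- length(bv)
  max(rec(n, m, 0L), rec(n, m, 1L), rec(n, m, 2L))
}

# exhaustive Fitch: minimize changes over all internal-state assignments,
# per column; '-' is a real state, '?'/'X' match anything
oracle_fitch <- function(tree, msa) {
  m <- do.call(rbind, strsplit(unname(unclass(msa[tree$tip.label])), ""))
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  total <- 0L
  for (col in seq_len(ncol(m))) {
    states <- setdiff(unique(m[, col]), c("?", "X", "*"))
    if (!length(states)) next
    leafcost <- function(ch, s) {
      if (ch %in% c("?", "X", "*")) 0L else as.integer(ch != s)
    }
    combos <- as.matrix(expand.grid(rep(list(states), tree$Nnode),
                                    stringsAsFactors = FALSE))
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      asg <- character(nn)
      asg[(ntip + 1L):nn] <- combos[r, ]
      cost <- 0L
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
        if (c <= ntip) cost <- cost + leafcost(m[c, col], asg[p])
        else cost <- cost + as.integer(asg[c] != asg[p])
      }
      best <- min(best, cost)
    }
    total <- total + best
  }
  total
}

# brute-force duplication-loss reconciliation: enumerate every valid map
# of internal gene nodes (each node to an ancestor-or-equal of its
# children's images), count events per the standard rules, minimize.
oracle_reconcile <- function(gene_tree, species_tree, leaf_map) {
  sp <- species_tree
  sntip <- length(sp$tip.label)
  snn <- sntip + sp$Nnode
  parent <- integer(snn)
  for (e in seq_len(nrow(sp$edge))) parent[sp$edge[e, 2L]] <- sp$edge[e, 1L]
  depth <- integer(snn)
  for (v in seq_len(snn)) {
    d <- 0L; u <- v
    while (u != sntip + 1L) { u <- parent[u]; d <- d + 1L }
    depth[v] <- d
  }
  ancs <- lapply(seq_len(snn), function(v) {
    out <- v; u <- v
    while (u != sntip + 1L) { u <- parent[u]; out <- c(out, u) }
    out
  })
  is_anc <- function(a, b) a %in% ancs[[b]]   # a ancestor-or-equal of b
  gt <- gene_tree
  gntip <- length(gt$tip.label)
  po <- ape::reorder.phylo(gt, "postorder")$edge
  kids <- split(po[, 2L], po[, 1L])
  internal <- unique(po[, 1L])
  leafM <- integer(gntip)
  spi <- stats::setNames(seq_len(sntip), sp$tip.label)
  for (i in seq_len(gntip)) leafM[i] <- spi[[leaf_map[[gt$tip.label[i]]]]]
  best <- Inf; best_d <- NA; best_l <- NA
  M <- integer(gntip + gt$Nnode)
  M[seq_len(gntip)] <- leafM
  rec <- function(k) {
    if (k > length(internal)) {
      d <- 0L; l <- 0L
      for (v in internal) {
        ch <- kids[[as.character(v)]]
        if (M[v] == M[ch[1L]] || M[v] == M[ch[2L]]) {
          dup <- TRUE
        } else {
          # speciation iff the children's images lie under distinct
          # children of this node's image
          sch <- sp$edge[sp$edge[, 1L] == M[v], 2L]
          u1 <- sch[vapply(sch, function(s) is_anc(s, M[ch[1L]]), logical(1))]
          u2 <- sch[vapply(sch, function(s) is_anc(s, M[ch[2L]]), logical(1))]
          dup <- length(u1) == 0L || length(u2) == 0L || u1 == u2
        }
        if (dup) d <- d + 1L
        for (c in ch) l <- l + (depth[M[c]] - depth[M[v]]) - if (dup) 0L else 1L
      }
      if (d + l < best) { best <<- d + l; best_d <<- d; best_l <<- l }
      return(invisible())
    }
    v <- internal[k]
    ch <- kids[[as.character(v)]]
    cands <- intersect(ancs[[M[ch[1L]]]], ancs[[M[ch[2L]]]])
    for (m in cands) {
      M[v] <<- m
      rec(k + 1L)
    }
  }
  # internal nodes in postorder: children assigned before parents
  rec(1L)
  list(total = best, duplications = best_d, losses = best_l)
}

# naive non-overlapping leftmost-shortest motif scan
oracle_motif_scan <- function(protein, pattern) {
  n <- nchar(protein)
  out <- list()
  i <- 1L
  while (i <= n) {
    found <- FALSE
    for (l in 1:(n - i + 1L)) {
      if (grepl(paste0("^(?:", pattern, ")$"), substr(protein, i, i + l - 1L),
                perl = TRUE)) {
        out[[length(out) + 1L]] <- c(start = i, end = i + l - 1L)
        i <- i + l
        found <- TRUE
        break
      }
    }
    if (!found) i <- i + 1L
  }
  out
}

# random additive distance matrix from a random topology; returns both
random_additive_case <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.5, 3)
  list(tree = tr, D = stats::cophenetic(tr)[tr$tip.label, tr$tip.label])
}

same_unrooted_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1L] == 0
}
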