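# Protein alignment and tree building for annotated families: pairwise
# global alignment (Gotoh, via Biostrings), center-star progressive MSA,
# alignment trimming, distance matrices, neighbor joining, Fitch parsimony
# scoring and bootstrap support with low-support collapse.

#' Global pairwise protein alignment
#'
#' Optimal global affine-gap alignment; a gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param a,b Protein strings (may be empty).
#' @param matrix Substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend Negative gap penalties.
#' @return `list(a, b, score)` with the gapped aligned strings.
#' @export
global_align <- function(a, b, matrix = NULL, gap_open = -11, gap_extend = -1) {
  if (is.null(matrix)) matrix <- score_matrix("BLOSUM62")
  if (nchar(a) == 0L && nchar(b) == 0L) return(list(a = "", b = "", score = 0))
  if (nchar(a) == 0L) {
    return(list(a = strrep("-", nchar(b)), b = b,
                score = gap_open + nchar(b) * gap_extend))
  }
  if (nchar(b) == 0L) {
    return(list(a = a, b = strrep("-", nchar(a)),
                score = gap_open + nchar(a) * gap_extend))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = matrix, gapOpening = -gap_open,
    gapExtension = -gap_extend, type = "global")
  list(a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

pairwise_score_matrix <- function(seqs, matrix, gap_open, gap_extend) {
  n <- length(seqs)
  S <- matrix(0, n, n)
  set <- Biostrings::AAStringSet(unname(seqs))
  for (i in seq_len(n)) {
    S[i, ] <- Biostrings::pairwiseAlignment(
      set, Biostrings::AAString(seqs[[i]]),
      substitutionMatrix = matrix, gapOpening = -gap_open,
      gapExtension = -gap_extend, type = "global", scoreOnly = TRUE)
  }
  (S + t(S)) / 2   # symmetrize; identical up to floating error
}

#' Center-star multiple sequence alignment
#'
#' The center is the sequence maximizing the summed pairwise global-
#' alignment score; all others are merged onto it under the
#' "once a gap, always a gap" rule.
#'
#' @param seqs Named character vector of >= 2 proteins.
#' @param matrix,gap_open,gap_extend As in [global_align()].
#' @return An `msa` object: named character vector of equal-length gapped
#'   rows, in input order, with the center id in `attr(,"center")`.
#' @export
center_star_msa <- function(seqs, matrix = NULL, gap_open = -11,
                            gap_extend = -1) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  if (is.null(matrix)) matrix <- score_matrix("BLOSUM62")
  S <- pairwise_score_matrix(seqs, matrix, gap_open, gap_extend)
  center <- which.max(rowSums(S) - diag(S))
  master <- strsplit(seqs[[center]], "")[[1L]]   # center row, gaps accumulate
  rows <- list()                                  # aligned others (char vecs)
  for (i in seq_along(seqs)) {
    if (i == center) next
    al <- global_align(paste(master[master != "-"], collapse = ""), seqs[[i]],
                       matrix, gap_open, gap_extend)
    ca <- strsplit(al$a, "")[[1L]]
    sa <- strsplit(al$b, "")[[1L]]
    # walk master vs ca, reconciling gap columns on either side
    new_master <- character(); new_sa <- character()
    patch <- vapply(rows, function(r) "", character(1))
    new_rows <- lapply(rows, function(r) character())
    mi <- 1L; ci <- 1L
    while (mi <= length(master) || ci <= length(ca)) {
      m_gap <- mi <= length(master) && master[mi] == "-"
      c_gap <- ci <= length(ca) && ca[ci] == "-"
      if (mi <= length(master) && m_gap && !(ci <= length(ca) && c_gap)) {
        # master-only gap column: existing rows keep their char, new row gets '-'
        new_master <- c(new_master, "-")
        for (k in seq_along(rows)) new_rows[[k]] <- c(new_rows[[k]], rows[[k]][mi])
        new_sa <- c(new_sa, "-")
        mi <- mi + 1L
      } else if (ci <= length(ca) && c_gap) {
        # gap introduced by the new sequence: propagate into all old rows
        new_master <- c(new_master, "-")
        for (k in seq_along(rows)) new_rows[[k]] <- c(new_rows[[k]], "-")
        new_sa <- c(new_sa, sa[ci])
        ci <- ci + 1L
      } else {
        new_master <- c(new_master, master[mi])
        for (k in seq_along(rows)) new_rows[[k]] <- c(new_rows[[k]], rows[[k]][mi])
        new_sa <- c(new_sa, sa[ci])
        mi <- mi + 1L; ci <- ci + 1L
      }
    }
    master <- new_master
    rows <- new_rows
    rows[[length(rows) + 1L]] <- new_sa
  }
  others <- setdiff(seq_along(seqs), center)
  out <- character(length(seqs))
  out[center] <- paste(master, collapse = "")
  for (k in seq_along(others)) out[others[k]] <- paste(rows[[k]], collapse = "")
  names(out) <- names(seqs)
  structure(out, center = names(seqs)[center], class = "msa")
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unclass(unname(msa)), ""))
}

matrix_msa <- function(m, ids) {
  structure(stats::setNames(apply(m, 1L, paste, collapse = ""), ids),
            class = "msa")
}

#' Trim a protein alignment
#'
#' Three curation steps commonly applied before tree building: rows whose
#' gap fraction exceeds `max_gap_fraction` are deleted; leading and
#' trailing columns are removed while their residue agreement (modal
#' non-gap residue frequency over all rows) is below
#' `end_agreement`; internal gap runs longer than `gap_run` columns are
#' rewritten to `?` (missing), reflecting uncertainty about the underlying
#' annotation rather than a true deletion.
#'
#' @param msa An `msa`.
#' @param max_gap_fraction Row-deletion threshold (default 0.5).
#' @param end_agreement End-column agreement threshold (default 0.3).
#' @param gap_run Internal gap-run length threshold (default 20).
#' @return Trimmed `msa`.
#' @export
trim_alignment <- function(msa, max_gap_fraction = 0.5, end_agreement = 0.3,
                           gap_run = 20L) {
  m <- msa_matrix(msa)
  ids <- names(msa)
  gap_frac <- rowMeans(m == "-")
  keep <- gap_frac <= max_gap_fraction
  if (sum(keep) < 2L)
    stop("fewer than 2 rows survive gap-fraction trimming", call. = FALSE)
  m <- m[keep, , drop = FALSE]
  ids <- ids[keep]
  agree <- apply(m, 2L, function(col) {
    r <- col[col != "-" & col != "?"]
    if (!length(r)) return(0)
    max(table(r)) / length(col)
  })
  lo <- 1L
  while (lo <= ncol(m) && agree[lo] < end_agreement) lo <- lo + 1L
  hi <- ncol(m)
  while (hi >= lo && agree[hi] < end_agreement) hi <- hi - 1L
  if (hi < lo) stop("trimming removed every column", call. = FALSE)
  m <- m[, lo:hi, drop = FALSE]
  for (r in seq_len(nrow(m))) {
    rl <- rle(m[r, ] == "-")
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (k in seq_along(rl$values)) {
      if (rl$values[k] && rl$lengths[k] > gap_run &&
          starts[k] > 1L && ends[k] < ncol(m)) {
        m[r, starts[k]:ends[k]] <- "?"
      }
    }
  }
  matrix_msa(m, ids)
}

#' Pairwise distance matrix from an alignment
#'
#' Pairs are compared over columns where neither row has `-` or `?`;
#' `p` is the mismatch fraction and `poisson` is `-ln(1 - p)`.
#'
#' @param msa An `msa` (>= 2 rows).
#' @param correction "p" or "poisson".
#' @param incomparable "error" (default) to fail when a pair shares no
#'   columns, or "max" to assign the capped maximum distance (used by the
#'   bootstrap resampler).
#' @return Symmetric matrix with zero diagonal and id dimnames.
#' @export
distance_matrix <- function(msa, correction = c("p", "poisson"),
                            incomparable = c("error", "max")) {
  correction <- match.arg(correction)
  incomparable <- match.arg(incomparable)
  m <- msa_matrix(msa)
  n <- nrow(m)
  stopifnot(n >= 2L)
  ok <- m != "-" & m != "?"
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  capped <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- ok[i, ] & ok[j, ]
    if (!any(shared)) {
      if (incomparable == "error")
        stop("no shared columns between ", names(msa)[i], " and ", names(msa)[j],
             call. = FALSE)
      p <- 1
    } else {
      p <- mean(m[i, shared] != m[j, shared])
    }
    if (p >= 1) { p <- 1 - 1e-6; capped <- TRUE }
    d <- if (correction == "p") min(p, 1) else -log(1 - p)
    D[i, j] <- D[j, i] <- d
  }
  if (capped) warning("saturated pair(s): p-distance capped below 1")
  D
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei NJ; negative branch lengths are clamped to zero
#' with a warning, and the unrooted result is given a root at the final
#' join (re-rootable with [root_tree()]).
#'
#' @param D Symmetric distance matrix with id dimnames (n >= 3).
#' @return Rooted `ape::phylo`.
#' @export
neighbor_joining <- function(D) {
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix is not symmetric", call. = FALSE)
  stopifnot(nrow(D) >= 3L)
  tr <- ape::nj(D)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  ape::multi2di(tr, random = FALSE)
}

#' Reroot a tree on the pendant edge of an outgroup leaf
#'
#' @param tree `ape::phylo`.
#' @param outgroup Leaf label.
#' @param drop Remove the outgroup leaf after rooting.
#' @return Rooted tree.
#' @export
root_tree <- function(tree, outgroup, drop = FALSE) {
  stopifnot(outgroup %in% tree$tip.label)
  tr <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  if (drop) tr <- ape::drop.tip(tr, outgroup)
  tr
}

#' Fitch parsimony score of a tree on an alignment
#'
#' Minimum number of state changes summed over columns; `-` is a 21st
#' state ("gaps treated as a character") while `?`, `X` and `*` are fully
#' ambiguous.
#'
#' @param tree `ape::phylo`; its leaves must all have alignment rows.
#' @param msa An `msa`.
#' @return Integer parsimony score.
#' @export
fitch_parsimony_score <- function(tree, msa) {
  missing <- setdiff(tree$tip.label, names(msa))
  if (length(missing))
    stop("leaf without alignment row: ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- msa_matrix(msa[tree$tip.label])
  m[m == "*"] <- "?"
  rownames(m) <- tree$tip.label
  dat <- phangorn::phyDat(m, type = "USER", levels = c(AA20, "-"),
                          ambiguity = c("?", "X"))
  as.integer(phangorn::parsimony(tree, dat, method = "fitch"))
}

default_tree_builder <- function(msa) {
  neighbor_joining(distance_matrix(msa, "poisson", incomparable = "max"))
}

#' Bootstrap support with low-support collapse
#'
#' Columns are resampled with replacement `n_reps` times; each replicate
#' alignment is passed to `tree_builder`; the support of every internal
#' split of the full-data tree is the percentage of replicate trees
#' containing it.  Splits below `collapse_cutoff` are collapsed to
#' polytomies.
#'
#' @param msa An `msa`.
#' @param tree_builder Function `msa -> phylo` (default: NJ on Poisson
#'   distances).
#' @param n_reps Number of replicates (default 100).
#' @param seed RNG seed.
#' @param collapse_cutoff Support percentage below which splits collapse
#'   (default 50; 0 collapses nothing).
#' @return The full-data tree with `node.label` supports, collapsed.
#' @export
bootstrap_support <- function(msa, tree_builder = default_tree_builder,
                              n_reps = 100L, seed = 1L, collapse_cutoff = 50) {
  stopifnot(n_reps >= 1L)
  full <- tree_builder(msa)
  m <- msa_matrix(msa)
  boots <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      suppressWarnings(tree_builder(matrix_msa(m[, cols, drop = FALSE],
                                               names(msa))))
    })
  })
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_reps)
  support[1L] <- 100L   # root split is not a hypothesis
  full$node.label <- as.character(support)
  if (collapse_cutoff > 0) {
    full <- phangorn::pruneTree(full, collapse_cutoff)
  }
  full
}
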