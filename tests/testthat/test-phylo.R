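test_that("global alignment scores match a naive affine-gap recursion", {
  id <- global_align("MKVW", "MKVW")
  expect_identical(id$a, "MKVW")
  expect_equal(id$score, sum(blosum62[cbind(c("M", "K", "V", "W"),
                                            c("M", "K", "V", "W"))]))
  gap <- global_align("A", "")
  expect_identical(gap$b, "-")
  expect_equal(gap$score, -12)

  set.seed(51)
  for (rep in 1:40) {
    a <- random_protein(sample(1:8, 1), start_met = FALSE)
    b <- random_protein(sample(1:8, 1), start_met = FALSE)
    expect_equal(global_align(a, b)$score,
                 oracle_global_score(a, b, blosum62))
  }
})

test_that("center-star alignment behaves on degenerate and random inputs", {
  pair <- center_star_msa(c(x = "MKVWLL", y = "MKWLL"))
  al <- global_align("MKVWLL", "MKWLL")
  expect_identical(as.character(pair), c(al$a, al$b))

  same <- center_star_msa(c(a = "MKVW", b = "MKVW", c = "MKVW"))
  expect_false(any(grepl("-", same)))

  # rows always ungap back to their inputs
  set.seed(52)
  for (rep in 1:10) {
    seqs <- stats::setNames(
      vapply(1:4, function(i) mutate_protein(random_protein(60), 0.7),
             character(1)), paste0("s", 1:4))
    msa <- center_star_msa(seqs)
    expect_identical(stats::setNames(gsub("-", "", as.character(msa),
                                          fixed = TRUE), names(msa)),
                     seqs)
    expect_identical(length(unique(nchar(msa))), 1L)
  }
})

test_that("alignment trimming removes gappy rows, ragged ends and long gap runs", {
  msa <- structure(c(a = "MKVWLLRR", b = "MKVWLLRA", c = "MKVWLARR"),
                   class = "msa")
  expect_identical(trim_alignment(msa), msa)

  gappy <- structure(c(a = "MKVWLLRR", b = "MKVWLLRA", c = "M-------"),
                     class = "msa")
  expect_identical(names(trim_alignment(gappy, max_gap_fraction = 0.5)),
                   c("a", "b"))

  run <- structure(c(a = paste0("MKVW", strrep("-", 25), "LLRR"),
                     b = paste0("MKVW", strrep("A", 25), "LLRR"),
                     c = paste0("MKVW", strrep("A", 25), "LLRA")),
                   class = "msa")
  out <- trim_alignment(run, max_gap_fraction = 0.9, gap_run = 20L)
  expect_match(unclass(out)[["a"]], "^MKVW\\?{25}LLRR$")
  # never longer after trimming
  expect_lte(nchar(gsub("[-?]", "", out[["a"]])), 8L)
  expect_error(trim_alignment(structure(c(a = "M---", b = "M---"),
                                        class = "msa"),
                              max_gap_fraction = 0.3), "fewer than 2")
})

test_that("distance matrices follow the stated p / Poisson rules", {
  msa <- structure(c(a = "MKVW", b = "MKVW"), class = "msa")
  expect_equal(distance_matrix(msa)["a", "b"], 0)

  two <- structure(c(a = "MK--", b = "MA?A"), class = "msa")
  expect_equal(distance_matrix(two, "p")["a", "b"], 0.5)
  expect_equal(distance_matrix(two, "poisson")["a", "b"], -log(0.5))

  none <- structure(c(a = "MK--", b = "--AA"), class = "msa")
  expect_error(distance_matrix(none), "no shared columns.*a.*b")

  set.seed(53)
  for (rep in 1:10) {
    seqs <- stats::setNames(vapply(1:4, function(i)
      mutate_protein(random_protein(50), 0.8), character(1)), letters[1:4])
    D <- distance_matrix(center_star_msa(seqs))
    expect_identical(D, t(D))
    expect_true(all(diag(D) == 0))
  }
})

test_that("neighbor joining is exact on additive matrices", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  truth <- read_newick("((A:1,B:2):1,(C:3,D:4):0);")
  expect_true(same_unrooted_topology(tr, truth))
  expect_identical(tr$tip.label[order(tr$tip.label)], c("A", "B", "C", "D"))
  # pendant branch lengths recovered exactly
  pend <- tr$edge.length[match(seq_len(4L), tr$edge[, 2L])]
  expect_equal(pend[match(c("A", "B", "C", "D"), tr$tip.label)],
               c(1, 2, 3, 4))
  # path lengths reproduce the matrix (additivity)
  expect_equal(stats::cophenetic(tr)[rownames(D), colnames(D)], D)

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")

  for (sd in 1:10) {
    case <- random_additive_case(8L, sd)
    rec <- neighbor_joining(case$D)
    expect_true(same_unrooted_topology(rec, case$tree))
  }
})

test_that("Fitch parsimony counts changes with gaps as a 21st state", {
  tree <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  one <- structure(c(A = "A", B = "A", C = "T", D = "T"), class = "msa")
  expect_identical(fitch_parsimony_score(tree, one), 1L)
  flat <- structure(c(A = "A", B = "A", C = "A", D = "A"), class = "msa")
  expect_identical(fitch_parsimony_score(tree, flat), 0L)
  gap <- structure(c(A = "-", B = "-", C = "A", D = "A"), class = "msa")
  expect_identical(fitch_parsimony_score(tree, gap), 1L)
  amb <- structure(c(A = "?", B = "A", C = "A", D = "A"), class = "msa")
  expect_identical(fitch_parsimony_score(tree, amb), 0L)
  expect_error(fitch_parsimony_score(tree,
                                     structure(c(A = "A"), class = "msa")),
               "without alignment row")

  set.seed(54)
  for (rep in 1:6) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
    m <- stats::setNames(vapply(seq_len(n), function(i)
      paste(sample(c("A", "R", "N", "-", "?"), 6, replace = TRUE),
            collapse = ""), character(1)), tr$tip.label)
    msa <- structure(m, class = "msa")
    expect_identical(fitch_parsimony_score(tr, msa),
                     as.integer(oracle_fitch(tr, msa)))
    # invariant under rerooting
    for (tip in tr$tip.label[1:2]) {
      rr <- root_tree(ape::unroot(tr), tip)
      expect_identical(fitch_parsimony_score(rr, msa),
                       fitch_parsimony_score(tr, msa))
    }
  }
})

test_that("bootstrap support is deterministic and respects the cutoff", {
  set.seed(55)
  base <- random_protein(80)
  seqs <- stats::setNames(c(
    base,
    mutate_protein(base, 0.95), mutate_protein(base, 0.7),
    mutate_protein(base, 0.68), mutate_protein(base, 0.5)),
    paste0("s", 1:5))
  msa <- center_star_msa(seqs)
  t1 <- bootstrap_support(msa, n_reps = 30L, seed = 9L, collapse_cutoff = 0)
  t2 <- bootstrap_support(msa, n_reps = 30L, seed = 9L, collapse_cutoff = 0)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_true(is_binary_tree(t1))   # cutoff 0 collapses nothing

  # unanimous columns: every split supported at 100
  strong <- structure(c(a = "AAAAAARRRR", b = "AAAAAARRRV",
                        c = "RRRAAAAAAL", d = "RRRAAAAAAI"), class = "msa")
  ts <- bootstrap_support(strong, n_reps = 20L, seed = 1L,
                          collapse_cutoff = 50)
  sup <- suppressWarnings(as.numeric(ts$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
})
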