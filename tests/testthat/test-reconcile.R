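sp3 <- read_newick("((a:1,b:1):1,c:2);")

test_that("binary check names the offending node", {
  expect_silent(check_binary(read_newick("((a,b),(c,d));")))
  expect_silent(check_binary(read_newick("((a,b),c);")))
  expect_error(check_binary(read_newick("(a,b,c);")), "polytomy")
})

test_that("leaf maps parse the Species_gene convention", {
  lm <- leaf_map_from_names(c("a_g1", "b_g2"), c("a", "b", "c"))
  expect_identical(unname(lm), c("a", "b"))
  expect_error(leaf_map_from_names("zz_g1", c("a", "b")), "zz")
})

test_that("worked reconciliation cases give the known event counts", {
  sp2 <- read_newick("(a:1,b:1);")
  r0 <- lca_reconcile(read_newick("(a_g1:1,b_g1:1);"), sp2)
  expect_identical(c(r0$duplications, r0$losses), c(0, 0))

  r1 <- lca_reconcile(read_newick("((a_g1:1,b_g1:1):1,(a_g2:1,b_g2:1):1);"),
                      sp2)
  expect_identical(c(r1$duplications, r1$losses), c(1, 0))
  # the duplication sits on the root branch
  rep1 <- event_report(r1)
  expect_equal(rep1$duplications[rep1$branch == "n3"], 1)

  r2 <- lca_reconcile(read_newick("(a_g1:1,(a_g2:1,b_g1:1):1);"), sp2)
  expect_identical(c(r2$duplications, r2$losses), c(1, 1))

  # congruent case: all-zero table
  rep0 <- event_report(r0)
  expect_true(all(rep0$duplications == 0) && all(rep0$losses == 0))
})

test_that("LCA totals equal brute-force minima for all small gene trees", {
  # all rooted binary topologies with n leaves (as nested index lists)
  topologies <- function(n) {
    if (n == 1L) return(list(1L))
    out <- list()
    for (k in seq_len(n - 1L)) {
      for (l in topologies(k)) for (r in topologies(n - k)) {
        out[[length(out) + 1L]] <- list(l, r)
      }
    }
    out
  }
  to_newick <- function(t, labels, env = new.env()) {
    if (is.null(env$i)) env$i <- 0L
    if (is.integer(t)) {               # leaves take labels left to right
      env$i <- env$i + 1L
      return(labels[env$i])
    }
    paste0("(", to_newick(t[[1L]], labels, env), ",",
           to_newick(t[[2L]], labels, env), ")")
  }
  species <- c("a", "b", "c")
  check_case <- function(topo, n, assign) {
    labels <- paste0(species[assign], "_g", seq_len(n))
    gt <- read_newick(paste0(to_newick(topo, labels), ";"))
    lm <- leaf_map_from_names(gt$tip.label, species)
    mine <- lca_reconcile(gt, sp3, lm)
    oracle <- oracle_reconcile(gt, sp3, lm)
    expect_equal(mine$duplications + mine$losses, oracle$total)
  }
  for (n in 2:4) {
    for (topo in topologies(n)) {
      # fix the topology leaf order; enumerate all species labelings
      grid <- as.matrix(expand.grid(rep(list(1:3), n)))
      for (r in seq_len(nrow(grid))) check_case(topo, n, grid[r, ])
    }
  }
  # 5-leaf trees: a seeded sample of labeled topologies
  set.seed(61)
  topo5 <- topologies(5L)
  for (rep in 1:25) {
    topo <- topo5[[sample.int(length(topo5), 1L)]]
    check_case(topo, 5L, sample(1:3, 5L, replace = TRUE))
  }
})

test_that("event reports tally exactly the reconciliation totals", {
  sp <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  set.seed(62)
  for (rep in 1:20) {
    f <- simulate_family(family_scenario(sp, lambda = 0.6, mu = 0.2,
                                         seed = rep))
    if (is.null(f$gene_tree)) next
    rec <- lca_reconcile(f$gene_tree, sp)
    tab <- event_report(rec)
    tot <- tab[tab$branch == "TOTAL", ]
    body <- tab[tab$branch != "TOTAL", ]
    expect_equal(sum(body$duplications), tot$duplications)
    expect_equal(sum(body$losses), tot$losses)
  }
})

test_that("reconciliation recovers simulated birth-and-death counts", {
  sp <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  # mu = 0: inferred duplications equal the event log exactly
  for (sd in 1:10) {
    f <- simulate_family(family_scenario(sp, lambda = 0.5, mu = 0, seed = sd))
    if (length(f$leaf_names) < 2L) next
    rec <- lca_reconcile(f$gene_tree, sp)
    expect_equal(rec$duplications, sum(f$events$event == "duplication"))
    expect_equal(rec$losses, 0)
  }
  # mu > 0: parsimony is a lower bound on both event counts
  for (sd in 1:10) {
    f <- simulate_family(family_scenario(sp, lambda = 0.5, mu = 0.3,
                                         seed = 100 + sd))
    if (is.null(f$gene_tree)) next
    rec <- lca_reconcile(f$gene_tree, sp)
    expect_lte(rec$duplications, sum(f$events$event == "duplication"))
    expect_lte(rec$losses, sum(f$events$event == "loss"))
  }
})
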