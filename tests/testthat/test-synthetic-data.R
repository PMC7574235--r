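test_that("mutate_protein hits the target identity and preserves the start", {
  p <- random_protein(500, seed = 3)
  expect_identical(mutate_protein(p, 1.0, seed = 1), p)
  m <- mutate_protein(p, 0.7, seed = 1)
  id <- protein_identity(p, m)
  expect_gte(id, 0.67)
  expect_lte(id, 0.73)
  expect_identical(substr(m, 1, 1), substr(p, 1, 1))
  expect_false(grepl("*", m, fixed = TRUE))
  expect_error(mutate_protein(p, 0.01), "0.05")
})

test_that("plant_gene inserts a spliceable gene that translates back exactly", {
  contig <- famtrace:::random_dna(6000)
  p <- random_protein(120, seed = 9)
  res <- plant_gene(contig, p, 3L, c(70L, 90L), 1000L, "+", seed = 4)
  tr <- res$truth
  expect_identical(nrow(tr$exons), 3L)
  cds <- extract_cds(res$contig, tr$exons, "+")
  expect_identical(translate_dna(cds), paste0(p, "*"))
  # both introns start GT and end AG
  for (k in 1:2) {
    istart <- tr$exons[k, 2L]; iend <- tr$exons[k + 1L, 1L]
    intron <- substr(res$contig, istart + 1L, iend)
    expect_match(intron, "^GT.*AG$")
  }
  # minus strand: extraction through reverse complement reproduces protein
  resm <- plant_gene(contig, p, 3L, c(70L, 90L), 1000L, "-", seed = 4)
  expect_identical(translate_dna(extract_cds(resm$contig, resm$truth$exons, "-")),
                   paste0(p, "*"))
  expect_error(plant_gene(substr(contig, 1, 300), p, 1L, integer(), 100L, "+"),
               "too short")
})

test_that("pseudogenize produces the advertised defect signatures", {
  contig <- famtrace:::random_dna(6000)
  p <- random_protein(120, seed = 10)
  base <- plant_gene(contig, p, 3L, c(70L, 90L), 1000L, "+", seed = 5)

  ps <- pseudogenize(base$truth, base$contig, "premature_stop", seed = 6)
  expect_identical(ps$truth$status, "pseudogene")
  body <- substr(ps$truth$protein, 1, nchar(ps$truth$protein) - 1L)
  expect_match(body, "\\*")   # stop strictly before the final codon

  fs <- pseudogenize(base$truth, base$contig, "frameshift", seed = 6)
  cds_len <- sum(fs$truth$exons[, 2L] - fs$truth$exons[, 1L])
  parent_len <- sum(base$truth$exons[, 2L] - base$truth$exons[, 1L])
  expect_true((cds_len - parent_len) %% 3L != 0L)

  tc <- pseudogenize(base$truth, base$contig, "truncated", seed = 6)
  expect_identical(nrow(tc$truth$exons), 2L)
  expect_identical(tc$truth$defects, "truncated")

  one <- plant_gene(contig, "M", 1L, integer(), 500L, "+", seed = 7)
  expect_error(pseudogenize(one$truth, one$contig, "premature_stop"), "1 codon")
})

test_that("simulate_genome is deterministic and honors the spec", {
  spec <- genome_spec(contig_lengths = c(chr1 = 30000L), n_singletons = 0L,
                      tandem_clusters = 3L, identity_range = c(0.8, 0.9),
                      pseudogene_fraction = 0, n_repeats = 1L, seed = 77L)
  a <- simulate_genome(spec)
  b <- simulate_genome(spec)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth_table, b$truth_table)
  # one tandem cluster of 3 on one contig, disjoint, in genomic order
  tt <- a$truth_table
  expect_identical(nrow(tt), 3L)
  expect_true(all(tt$contig == "chr1"))
  expect_true(all(tt$start[-1L] > tt$end[-3L]))

  empty <- simulate_genome(genome_spec(contig_lengths = c(chr1 = 5000L),
                                       n_singletons = 0L,
                                       tandem_clusters = integer(),
                                       n_repeats = 0L, seed = 1L))
  expect_identical(nrow(empty$truth_table), 0L)
  expect_identical(nchar(empty$genome[[1L]]), 5000L)
})

test_that("planted functional genes translate cleanly across many random specs", {
  set.seed(100)
  for (rep in 1:40) {
    spec <- genome_spec(
      contig_lengths = c(chr1 = 20000L),
      n_singletons = sample(1:2, 1), tandem_clusters = integer(),
      exon_count_range = c(1L, 4L),
      identity_range = sort(stats::runif(2, 0.5, 1)),
      pseudogene_fraction = sample(c(0, 0.5, 1), 1),
      pseudogene_modes = "premature_stop",
      n_repeats = 0L,
      seed_protein = synthetic_seed_protein(150L, seed = rep),
      seed = rep)
    sim <- simulate_genome(spec)
    for (tr in sim$truth) {
      aa <- translate_dna(extract_cds(sim$genome[[tr$contig]], tr$exons,
                                      tr$strand))
      internal <- substr(aa, 1, nchar(aa) - 1L)
      if (tr$status == "functional") {
        expect_false(grepl("*", internal, fixed = TRUE))
      } else {
        expect_match(internal, "\\*")
      }
    }
  }
})

test_that("split-contig artifact emits the cut gene on two contigs", {
  spec <- genome_spec(contig_lengths = c(chr1 = 40000L), n_singletons = 2L,
                      tandem_clusters = integer(), pseudogene_fraction = 0,
                      split_contig = TRUE, seed = 5L)
  sim <- simulate_genome(spec)
  expect_identical(length(sim$genome), 2L)
  frag <- sim$truth_table[sim$truth_table$split, ]
  expect_identical(nrow(frag), 2L)
  expect_setequal(frag$contig, c("chr1_part1", "chr1_part2"))
})

test_that("family simulation matches its event log", {
  sp <- "((A:1,B:1):1,(C:1,D:1):1);"
  # no events possible: gene tree congruent with the species tree
  f0 <- simulate_family(family_scenario(sp, lambda = 0, mu = 0, seed = 1))
  expect_identical(nrow(f0$events), 0L)
  expect_setequal(f0$leaf_names, c("A_g1", "B_g1", "C_g1", "D_g1"))
  expect_equal(ape::dist.topo(
    f0$gene_tree,
    read_newick("((A_g1:1,B_g1:1):1,(C_g1:1,D_g1:1):1);"))[1L], 0)

  # with mu = 0 a duplication on branch b adds one surviving lineage to
  # every species below b, so the leaf count is fully determined by the
  # event log; per species, leaves = 1 + duplications on its root path
  sp_tr <- read_newick(sp)
  tips_below <- function(lbl) {
    if (lbl %in% sp_tr$tip.label) return(1L)
    v <- as.integer(sub("^n", "", lbl))
    length(phangorn::Descendants(sp_tr, v, "tips")[[1L]])
  }
  for (sd in 1:10) {
    f <- simulate_family(family_scenario(sp, lambda = 0.5, mu = 0, seed = sd))
    dup_br <- f$events$species_branch[f$events$event == "duplication"]
    expected <- 4L + sum(vapply(dup_br, tips_below, integer(1)))
    expect_identical(length(f$leaf_names), as.integer(expected))
  }

  # determinism
  f1 <- simulate_family(family_scenario(sp, lambda = 0.5, mu = 0.2, seed = 99))
  f2 <- simulate_family(family_scenario(sp, lambda = 0.5, mu = 0.2, seed = 99))
  expect_identical(f1$events, f2$events)
  expect_identical(f1$proteins, f2$proteins)
})
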