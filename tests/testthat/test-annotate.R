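mk_model <- function(contig = "c1", strand = "+", exons, score,
                     status = "functional", protein = "MKV", id = "m") {
  structure(list(gene_id = id, contig = contig, strand = strand,
                 exons = exons, introns = matrix(0L, 0L, 2L),
                 frameshifts = matrix(0L, 0L, 2L), cds = "",
                 protein = protein, q_start = 0L, q_end = 3L, query_len = 3L,
                 score = score, query_id = "q", status = status,
                 defects = character(), locus_label = NA_character_),
            class = "gene_model")
}

test_that("model merging keeps the best copy of reciprocal duplicates", {
  a <- mk_model(exons = cbind(100L, 400L), score = 10)
  expect_length(merge_models(list(a), list(a)), 1L)

  minus <- mk_model(strand = "-", exons = cbind(100L, 400L), score = 5)
  expect_length(merge_models(list(a), list(minus)), 2L)

  b <- mk_model(exons = cbind(120L, 420L), score = 20)
  c <- mk_model(exons = cbind(140L, 440L), score = 30)
  kept <- merge_models(list(a, b, c))
  expect_length(kept, 1L)
  expect_equal(kept[[1L]]$score, 30)
  # brute force over subsets: max-score overlap-free subset is {score 30}
  subsets <- list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), 1:3)
  all_models <- list(a, b, c)
  free <- Filter(function(s) {
    length(s) < 2L || all(apply(utils::combn(s, 2L), 2L, function(pr) {
      !famtrace:::models_duplicate(all_models[[pr[1L]]], all_models[[pr[2L]]])
    }))
  }, subsets)
  best <- free[[which.max(vapply(free, function(s) {
    sum(vapply(all_models[s], `[[`, numeric(1), "score"))
  }, numeric(1)))]]
  expect_identical(best, 3L)
})

test_that("iteration converges and an empty genome yields nothing", {
  p <- random_protein(150, seed = 41)
  contig <- famtrace:::random_dna(12000)
  res <- plant_gene(contig, mutate_protein(p, 0.8, seed = 42), 2L, 80L,
                    4000L, "+", seed = 43)
  ann <- iterate_annotation(c(chr = res$contig), c(seed = p),
                            search_params(min_score = 40),
                            model_params(max_intron = 2000L,
                                         min_locus_score = 60,
                                         min_model_score = 200),
                            max_iter = 4L)
  expect_length(ann$models, 1L)
  expect_true(ann$converged)
  # found in round 1, confirmed-converged in round 2
  expect_identical(ann$iterations$n_new_models, c(1L, 0L))

  empty <- iterate_annotation(c(chr = famtrace:::random_dna(5000)),
                              c(seed = p), search_params(),
                              model_params(), max_iter = 4L)
  expect_length(empty$models, 0L)
  expect_true(empty$converged)
  expect_identical(nrow(empty$iterations), 1L)
})

test_that("iteration rescues a paralog invisible to the seed query", {
  sc <- chain_scenario(7)
  without <- chain_recall(sc, max_iter = 1L)
  with <- chain_recall(sc, max_iter = 4L)
  expect_identical(without$recall, 1L)
  expect_identical(with$recall, 2L)
  expect_true(with$ann$converged)
  expect_lte(nrow(with$ann$iterations), 4L)
  # monotone growth of the cumulative model set
  expect_true(all(diff(with$ann$iterations$n_models) >= 0L))
})

test_that("synteny labels come from the nearest flanking neighbors", {
  nb <- data.frame(
    seqid = "c1", source = "x", type = "gene",
    start = c(1000L, 9000L), end = c(1300L, 9300L), score = ".",
    strand = "+", phase = ".",
    attributes = c("ID=MARKA;Name=MARKA", "ID=MARKB;Name=MARKB"),
    stringsAsFactors = FALSE)
  m1 <- mk_model(exons = cbind(2000L, 2900L), score = 50, id = "m1")
  m2 <- mk_model(exons = cbind(4000L, 4900L), score = 50, id = "m2")
  m3 <- mk_model(exons = cbind(6000L, 6900L), score = 50, id = "m3")
  res <- assign_locus(list(m1, m2, m3), nb)
  expect_identical(unique(vapply(res$models, `[[`, character(1), "locus_label")),
                   "MARKA-MARKB")
  expect_identical(nrow(res$loci), 1L)
  expect_identical(res$loci$n_members, 3L)

  lone <- mk_model(contig = "c9", exons = cbind(100L, 400L), score = 50,
                   id = "m9")
  res2 <- assign_locus(list(lone), nb)
  expect_identical(res2$models[[1L]]$locus_label, ".-.")

  # out of range
  far <- assign_locus(list(m1), nb, max_distance = 100)
  expect_identical(far$models[[1L]]$locus_label, ".-.")
})
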