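`%||%` <- function(a, b) if (is.null(a)) b else a
make_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query_id = r[["q"]] %||% "q", contig = r[["c"]] %||% "c1",
               strand = r[["s"]] %||% "+", frame = 0L,
               g_start = r[["g"]][1L], g_end = r[["g"]][2L],
               q_start = r[["qi"]][1L], q_end = r[["qi"]][2L],
               score = r[["sc"]] %||% 100,
               aligned_query = "", aligned_target = "",
               stringsAsFactors = FALSE)
  }))
}

test_that("hit clustering follows gap and colinearity rules", {
  lens <- c(c1 = 100000L)
  h <- make_hits(list(g = c(1000L, 1300L), qi = c(0L, 100L)),
                 list(g = c(2300L, 2600L), qi = c(100L, 200L)))
  p_wide <- model_params(max_intron = 20000L, min_locus_score = 50)
  expect_length(cluster_hits(h, lens, p_wide), 1L)
  p_narrow <- model_params(max_intron = 500L, min_locus_score = 50)
  expect_length(cluster_hits(h, lens, p_narrow), 2L)

  # overlapping hits with inverted query order: a tandem restart
  h2 <- make_hits(list(g = c(1000L, 1300L), qi = c(100L, 200L)),
                  list(g = c(1250L, 1550L), qi = c(0L, 100L)))
  expect_length(cluster_hits(h2, lens, p_wide), 2L)

  # brute force over colinear chains confirms the two-locus split
  ord <- order(h2$g_start)
  chains <- list(c(1L), c(2L), c(1L, 2L))
  valid <- Filter(function(ch) {
    length(ch) == 1L ||
      (h2$g_start[ch[2L]] - h2$g_end[ch[1L]] <= 20000L &&
         h2$q_start[ch[2L]] >= h2$q_start[ch[1L]])
  }, chains)
  expect_identical(length(Filter(function(ch) length(ch) == 2L, valid)), 0L)
})

test_that("windows are clipped at disjoint neighboring loci", {
  lens <- c(c1 = 100000L)
  h <- make_hits(list(g = c(10000L, 10900L), qi = c(0L, 300L)),
                 list(g = c(12000L, 12900L), qi = c(0L, 300L)))
  loci <- cluster_hits(h, lens, model_params(max_intron = 5000L,
                                             min_locus_score = 50))
  expect_length(loci, 2L)
  first <- loci[[which.min(vapply(loci, `[[`, numeric(1), "core_start"))]]
  second <- loci[[which.max(vapply(loci, `[[`, numeric(1), "core_start"))]]
  expect_lte(first$win_end, second$core_start)
  expect_gte(second$win_start, first$core_end)
})

test_that("splice alignment recovers a planted gene exactly", {
  p <- random_protein(150, seed = 31)
  contig <- famtrace:::random_dna(5000)
  res <- plant_gene(contig, p, 2L, 90L, 1500L, "+", seed = 32)
  win0 <- 1200L
  win <- substr(res$contig, win0 + 1L, 3000L)
  mp <- model_params(min_model_score = 100)
  sa <- splice_align(p, win, mp)
  expect_identical(unname(sa$exons + win0),
                   unname(res$truth$exons - c(0L, 0L, 0L, 3L)))  # stop codon
  expect_identical(sa$protein, p)
  expect_identical(nrow(sa$introns), 1L)

  # pure background is rejected at the score floor
  expect_null(splice_align(p, famtrace:::random_dna(2000),
                           model_params(min_model_score = 300)))
})

test_that("splice DP matches exhaustive GT..AG parse enumeration", {
  set.seed(33)
  mp <- model_params(min_intron = 40L, min_model_score = 20)
  for (rep in 1:8) {
    n_ex <- sample(1:3, 1L)
    p <- random_protein(sample(30:50, 1L))
    contig <- famtrace:::random_dna(1200)
    ilen <- if (n_ex > 1L) sample(60:80, n_ex - 1L, replace = TRUE) else integer()
    res <- plant_gene(contig, p, n_ex, ilen, 400L, "+")
    glen <- max(res$truth$exons[, 2L]) - 400L
    win <- substr(res$contig, 400L - 15L + 1L, 400L + glen + 15L)
    sa <- splice_align(p, win, mp)
    expect_equal(sa$score, oracle_splice_best(p, win, mp))
  }
})

test_that("splice DP never scores below the best single-exon interpretation", {
  set.seed(34)
  mp <- model_params(min_model_score = 15)
  for (rep in 1:5) {
    q <- random_protein(40)
    win <- famtrace:::random_dna(600)
    win <- famtrace:::overwrite_seq(win, 200L,
                                    reverse_translate(mutate_protein(q, 0.8)))
    sa <- splice_align(q, win, mp)
    single <- oracle_search_best(q, win)   # no-intron local optimum
    if (!is.null(sa)) expect_gte(sa$score + 1e-9, single)
  }
})

test_that("status classification lists every defect cause", {
  base <- list(protein = "MKVLLRW", frameshifts = matrix(0L, 0L, 2L),
               cds = "ATGAAAGTGCTTCTTCGTTGGTAA",
               q_start = 0L, q_end = 7L, query_len = 7L)
  clean <- classify_status(structure(base, class = "gene_model"))
  expect_identical(clean$status, "functional")
  expect_length(clean$defects, 0L)

  ps <- base; ps$protein <- "MKV*LLR"
  ps <- classify_status(structure(ps, class = "gene_model"))
  expect_identical(ps$status, "pseudogene")
  expect_identical(ps$defects, "premature_stop")

  fs <- base; fs$frameshifts <- matrix(c(10L, 1L), 1L, 2L)
  fs <- classify_status(structure(fs, class = "gene_model"))
  expect_identical(fs$defects, "frameshift")

  tr <- base; tr$protein <- "KVLLRW"
  tr <- classify_status(structure(tr, class = "gene_model"))
  expect_identical(tr$defects, "truncated")

  nostop <- base; nostop$cds <- substr(base$cds, 1L, 21L)
  nostop <- classify_status(structure(nostop, class = "gene_model"))
  expect_identical(nostop$defects, "truncated")
})

test_that("motif scanning matches a naive substring oracle", {
  hits <- scan_motifs("AAGGLLLWAA", c(ggw = "GG.{1,5}?W"))
  expect_identical(nrow(hits), 1L)
  expect_identical(c(hits$start, hits$end), c(3L, 8L))
  expect_identical(nrow(scan_motifs("AAGGLLLAA", c(ggw = "GG.{1,5}?W"))), 0L)
  expect_error(scan_motifs("AAA", c(bad = "((")), "malformed")

  set.seed(35)
  pats <- c(ggw = "GG.{1,8}?W", dd = "D.{0,3}?D")
  for (rep in 1:30) {
    p <- random_protein(60)
    for (nm in names(pats)) {
      mine <- scan_motifs(p, pats[nm])
      naive <- oracle_motif_scan(p, pats[[nm]])
      expect_identical(nrow(mine), length(naive))
      for (k in seq_along(naive)) {
        expect_identical(c(mine$start[k], mine$end[k]),
                         unname(naive[[k]]))
      }
    }
  }
})

test_that("default motifs hit the synthetic seed protein", {
  hits <- scan_motifs(synthetic_seed_protein(450))
  expect_setequal(unique(hits$motif), c("macpf_ggxw", "c2_ca_site"))
})
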