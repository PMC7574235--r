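# End-to-end driver: simulate a family along a species tree, plant each
# species' gene complement in a synthetic genome, annotate every genome
# iteratively, build the family tree, and reconcile it against the
# species tree to recover the birth-and-death event history.

#' Default pipeline configuration
#'
#' A single nested list drives every stage; unknown keys are rejected.
#' All randomness flows from `seed` via per-stage derived seeds.
#'
#' @param species_tree Newick string for the species tree (binary, with
#'   branch lengths).
#' @param lambda,mu,subst_rate Birth-and-death scenario parameters.
#' @param protein_length Root protein length.
#' @param exon_count_range,intron_length_range Gene-planting ranges.
#' @param search,model Overrides (named lists) for [search_params()] /
#'   [model_params()] fields.
#' @param max_iter Annotation iteration cap.
#' @param trim Named list: `max_gap_fraction`, `end_agreement`, `gap_run`.
#' @param bootstrap Named list: `n_reps`, `collapse_cutoff`.
#' @param locus_max_distance Synteny neighbor search distance.
#' @param outgroup_identity Identity of the synthetic outgroup sequence to
#'   the root protein.
#' @param seed Root RNG seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(species_tree = "((SpA:1,SpB:1):1,(SpC:1,SpD:1):1);",
                            lambda = 0.5, mu = 0, subst_rate = 0.05,
                            protein_length = 450L,
                            exon_count_range = c(2L, 4L),
                            intron_length_range = c(60L, 200L),
                            search = list(), model = list(),
                            max_iter = 4L,
                            trim = list(max_gap_fraction = 0.5,
                                        end_agreement = 0.3, gap_run = 20L),
                            bootstrap = list(n_reps = 100L,
                                             collapse_cutoff = 50),
                            locus_max_distance = 1e6,
                            outgroup_identity = 0.5,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg A `pipeline_config` (or plain list with the same keys).
#' @return The validated config, invisibly usable downstream.
#' @export
validate_config <- function(cfg) {
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "), call. = FALSE)
  sp <- do.call(search_params, cfg$search)
  mp <- do.call(model_params, cfg$model)
  if (mp$max_intron < mp$min_intron)
    stop("max_intron < min_intron", call. = FALSE)
  stopifnot(cfg$lambda >= 0, cfg$mu >= 0, cfg$max_iter >= 1L,
            cfg$bootstrap$n_reps >= 1L,
            cfg$trim$max_gap_fraction > 0, cfg$locus_max_distance > 0)
  tr <- read_newick(cfg$species_tree)
  if (!is_binary_tree(tr)) stop("species tree must be binary", call. = FALSE)
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys missing from the file keep their defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(pipeline_config, raw)
}

#' Plant a given set of proteins as genes in one synthetic genome
#'
#' Used by the end-to-end driver: each protein becomes a multi-exon gene
#' on a fresh background contig, the whole set flanked by marker genes so
#' synteny labeling has anchors.
#'
#' @param proteins Named character vector.
#' @param contig_id Contig identifier.
#' @param exon_count_range,intron_length_range Planting ranges.
#' @param gc Background GC fraction.
#' @param seed RNG seed.
#' @return Same structure as [simulate_genome()].
#' @export
plant_family_genome <- function(proteins, contig_id = "chr1",
                                exon_count_range = c(2L, 4L),
                                intron_length_range = c(60L, 200L),
                                gc = 0.42, seed = 1L) {
  with_seed(seed, {
    est <- sum(3L * nchar(proteins) + 3L +
                 (exon_count_range[2L] - 1L) * intron_length_range[2L])
    clen <- as.integer(est + 4000L * (length(proteins) + 2L) + 10000L)
    contig <- random_dna(clen, gc)
    truths <- list()
    markers <- list()
    cursor <- 2000L + sample.int(500L, 1L)
    marker_letter <- 0L
    next_marker <- function(pos) {
      marker_letter <<- marker_letter + 1L
      id <- paste0("MARK", LETTERS[marker_letter])
      markers[[length(markers) + 1L]] <<- list(id = id, start = pos,
                                               end = pos + 300L, contig = contig_id)
      pos + 300L
    }
    cursor <- next_marker(cursor) + 300L + sample.int(300L, 1L)
    for (k in seq_along(proteins)) {
      n_ex <- sample(exon_count_range[1L]:exon_count_range[2L], 1L)
      ilen <- if (n_ex > 1L)
        sample(intron_length_range[1L]:intron_length_range[2L], n_ex - 1L,
               replace = TRUE) else integer()
      strand <- sample(c("+", "-"), 1L)
      res <- plant_gene(contig, proteins[[k]], n_ex, ilen, cursor, strand,
                        gene_id = names(proteins)[k], lineage = "family")
      contig <- res$contig
      tr <- res$truth
      tr$contig <- contig_id
      truths[[length(truths) + 1L]] <- tr
      cursor <- max(tr$exons[, 2L]) + 500L + sample.int(500L, 1L)
    }
    cursor <- next_marker(cursor + 300L + sample.int(300L, 1L))
    list(genome = stats::setNames(contig, contig_id), truth = truths,
         truth_table = truth_table(truths), truth_gff = truth_to_gff3(truths),
         neighbors = markers_to_gff3(markers), markers = markers,
         seed_protein = NULL)
  })
}

#' Run the full pipeline on a simulated scenario
#'
#' simulate -> annotate (iteratively, per species) -> align/trim/tree with
#' bootstrap -> reconcile -> report.  Deterministic for a fixed config
#' seed; every output file is plain text.
#'
#' @param cfg [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results and file paths.
#'   Files written: `models.gff3`, `proteins.faa`, `loci.tsv`,
#'   `iterations.tsv`, `msa.faa`, `tree.nwk`, `events.tsv`, `counts.tsv`,
#'   `truth.tsv`, `manifest.yaml`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, 4L))
  root_protein <- synthetic_seed_protein(cfg$protein_length, seed = seeds[1L])
  sp_tree <- read_newick(cfg$species_tree)
  scen <- family_scenario(sp_tree, cfg$lambda, cfg$mu, cfg$subst_rate,
                          root_protein, seed = seeds[2L])
  fam <- simulate_family(scen)
  if (fam$extinct || length(fam$proteins) == 0L)
    stop("stage simulate: the whole family went extinct; nothing to annotate",
         call. = FALSE)
  species <- unique(sub("_.*$", "", names(fam$proteins)))
  sparams <- do.call(search_params, cfg$search)
  mparams <- do.call(model_params, cfg$model)

  genomes <- list(); annos <- list(); loci_all <- list()
  gff_all <- list(); prot_all <- character(); iter_all <- list()
  counts <- list()
  gseeds <- with_seed(seeds[3L],
                      sample.int(.Machine$integer.max - 1L, length(species)))
  for (si in seq_along(species)) {
    spn <- species[si]
    prots <- fam$proteins[sub("_.*$", "", names(fam$proteins)) == spn]
    gen <- plant_family_genome(prots, contig_id = paste0(spn, "_chr1"),
                               exon_count_range = cfg$exon_count_range,
                               intron_length_range = cfg$intron_length_range,
                               seed = gseeds[si])
    ann <- tryCatch(
      iterate_annotation(gen$genome, c(SEED = root_protein), sparams, mparams,
                         cfg$max_iter),
      error = function(e) stop("stage annotate (", spn, "): ",
                               conditionMessage(e), call. = FALSE))
    al <- assign_locus(ann$models, gen$neighbors, cfg$locus_max_distance)
    genomes[[spn]] <- gen
    annos[[spn]] <- ann
    loci_all[[spn]] <- al$loci
    gff_all[[spn]] <- models_to_gff3(al$models)
    prot_all <- c(prot_all, models_to_proteins(al$models))
    it <- ann$iterations; it$species <- spn
    iter_all[[spn]] <- it
    st <- vapply(al$models, function(m) m$status, character(1))
    counts[[spn]] <- data.frame(species = spn,
                                functional = sum(st == "functional"),
                                pseudogene = sum(st == "pseudogene"),
                                total = length(st), stringsAsFactors = FALSE)
  }

  # family phylogeny from recovered functional proteins plus an outgroup
  func <- prot_all[vapply(prot_all, function(p) !grepl("*", p, fixed = TRUE),
                          logical(1))]
  phylo_res <- NULL
  rec <- NULL
  events <- data.frame(branch = "TOTAL", duplications = 0, losses = 0,
                       stringsAsFactors = FALSE)
  if (length(func) >= 3L) {
    og <- mutate_protein(root_protein, cfg$outgroup_identity, seed = seeds[4L])
    seqs <- c(func, OUT_g1 = og)
    msa <- center_star_msa(seqs)
    msa <- trim_alignment(msa, cfg$trim$max_gap_fraction,
                          cfg$trim$end_agreement, cfg$trim$gap_run)
    support_tree <- bootstrap_support(msa, n_reps = cfg$bootstrap$n_reps,
                                      seed = seeds[4L],
                                      collapse_cutoff = cfg$bootstrap$collapse_cutoff)
    nj_tree <- default_tree_builder(msa)
    rooted <- root_tree(nj_tree, "OUT_g1", drop = TRUE)
    rec <- tryCatch(lca_reconcile(rooted, sp_tree), error = function(e) NULL)
    if (!is.null(rec)) events <- event_report(rec)
    phylo_res <- list(msa = msa, tree = support_tree, rooted = rooted)
  }

  p <- function(f) file.path(out_dir, f)
  write_gff3(do.call(rbind, gff_all), p("models.gff3"))
  if (length(prot_all)) write_fasta(prot_all, p("proteins.faa"))
  utils::write.table(do.call(rbind, loci_all), p("loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, iter_all), p("iterations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, lapply(genomes, function(g) g$truth_table)),
                     p("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(phylo_res)) {
    write_fasta(unclass(phylo_res$msa), p("msa.faa"))
    write_newick(phylo_res$tree, p("tree.nwk"))
  }
  utils::write.table(events, p("events.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  count_df <- do.call(rbind, counts)
  utils::write.table(count_df, p("counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(package = "famtrace",
                   version = as.character(utils::packageVersion("famtrace")),
                   seed = cfg$seed,
                   config = unclass(cfg))
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(list(family = fam, genomes = genomes, annotations = annos,
                 counts = count_df, events = events, reconciliation = rec,
                 phylo = phylo_res, out_dir = out_dir))
}
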