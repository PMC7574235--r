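# Iterative annotation: search with seed queries, refine loci into gene
# models, recycle newly found functional paralogs as queries until no new
# model appears, then deduplicate and assign synteny locus labels.

model_span <- function(m) c(min(m$exons[, 1L]), max(m$exons[, 2L]))

exon_overlap_bases <- function(ex_a, ex_b) {
  tot <- 0L
  for (i in seq_len(nrow(ex_a))) for (j in seq_len(nrow(ex_b))) {
    tot <- tot + max(0L, min(ex_a[i, 2L], ex_b[j, 2L]) -
                       max(ex_a[i, 1L], ex_b[j, 1L]))
  }
  tot
}

models_duplicate <- function(a, b) {
  if (a$contig != b$contig || a$strand != b$strand) return(FALSE)
  ov <- exon_overlap_bases(a$exons, b$exons)
  la <- sum(a$exons[, 2L] - a$exons[, 1L])
  lb <- sum(b$exons[, 2L] - b$exons[, 1L])
  ov > 0.5 * la && ov > 0.5 * lb
}

#' Merge and deduplicate gene models
#'
#' Two models are duplicates iff they lie on the same strand with
#' reciprocal CDS overlap above 50%; the higher-scoring one is kept.
#' Models on opposite strands never merge.
#'
#' @param existing,new Lists of `gene_model`s (one genome).
#' @return Overlap-free list of models, sorted by contig and start.
#' @export
merge_models <- function(existing, new = list()) {
  all <- c(existing, new)
  if (!length(all)) return(list())
  ord <- order(-vapply(all, function(m) m$score, numeric(1)))
  kept <- list()
  for (i in ord) {
    dup <- any(vapply(kept, function(k) models_duplicate(k, all[[i]]), logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- all[[i]]
  }
  key <- order(vapply(kept, function(m) m$contig, character(1)),
               vapply(kept, function(m) m$exons[1L, 1L], numeric(1)))
  kept[key]
}

search_all_contigs <- function(query, query_id, genome, sparams) {
  do.call(rbind, c(list(empty_hits()), lapply(names(genome), function(cid) {
    translated_search(query, cid, genome[[cid]], sparams, query_id = query_id)
  })))
}

#' Iterative annotation of a genome with a growing query set
#'
#' Iteration n searches with the seed queries plus the conceptual
#' translations of every functional model found so far (pseudogene
#' products, which carry stops, are never recycled).  Iteration stops when
#' a round adds no model after merging, or at `max_iter` (flagged in the
#' log).  Search results are cached per query sequence, so re-runs of old
#' queries cost nothing.
#'
#' @param genome Named character vector of contig sequences.
#' @param seed_queries Named character vector of seed proteins.
#' @param sparams [search_params()].
#' @param mparams [model_params()].
#' @param max_iter Maximum number of iterations (>= 1).
#' @return List: `models` (classified, deduplicated, with gene ids),
#'   `iterations` (per-round log), `converged`, `hits` (cumulative).
#' @export
iterate_annotation <- function(genome, seed_queries,
                               sparams = search_params(),
                               mparams = model_params(), max_iter = 4L) {
  stopifnot(max_iter >= 1L)
  contig_lengths <- vapply(genome, nchar, integer(1))
  queries <- seed_queries
  searched <- character()          # query ids already searched
  hit_pool <- empty_hits()
  models <- list()
  log <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    todo <- setdiff(names(queries), searched)
    for (qid in todo) {
      hit_pool <- rbind(hit_pool,
                        search_all_contigs(queries[[qid]], qid, genome, sparams))
      searched <- c(searched, qid)
    }
    loci <- cluster_hits(hit_pool, contig_lengths, mparams)
    added <- 0L
    for (locus in loci) {
      # skip loci whose hit span is already well inside a known model
      hs <- c(min(hit_pool$g_start[locus$hit_rows]),
              max(hit_pool$g_end[locus$hit_rows]))
      covered <- any(vapply(models, function(m) {
        if (m$contig != locus$contig || m$strand != locus$strand) return(FALSE)
        sp <- model_span(m)
        ov <- max(0L, min(sp[2L], hs[2L]) - max(sp[1L], hs[1L]))
        ov > 0.5 * (hs[2L] - hs[1L])
      }, logical(1)))
      if (covered) next
      m <- refine_locus(locus, genome[[locus$contig]], queries, mparams)
      if (is.null(m)) next
      m <- classify_status(m)
      before <- length(models)
      models <- merge_models(models, list(m))
      if (length(models) > before) added <- added + 1L
    }
    # recycle functional translations as new queries
    for (m in models) {
      if (m$status != "functional") next
      if (m$protein %in% unlist(queries)) next
      qid <- sprintf("iter%d_%s_%d", it, m$contig, m$exons[1L, 1L])
      queries[[qid]] <- m$protein
    }
    log[[it]] <- data.frame(iteration = it, n_queries = length(searched),
                            n_new_models = added, n_models = length(models),
                            stringsAsFactors = FALSE)
    if (added == 0L) { converged <- TRUE; break }
  }
  # stable gene ids in genomic order
  for (k in seq_along(models)) {
    models[[k]]$gene_id <- sprintf("%s_m%02d", models[[k]]$contig, k)
  }
  list(models = models, iterations = do.call(rbind, log),
       converged = converged, hits = hit_pool)
}

#' Assign synteny locus labels from flanking neighbor genes
#'
#' For each model the nearest non-family neighbor gene strictly upstream
#' and downstream (gene-body distance on the forward strand, within
#' `max_distance`) define the label `"UP-DOWN"`; a missing neighbor
#' becomes `"."`.  Models sharing a label form one synteny locus, so a
#' tandem amplification maps to a single locus.
#'
#' @param models List of `gene_model`s.
#' @param neighbors Feature data frame (see [read_gff3()]) of neighbor
#'   gene annotations; `Name` or `ID` attribute names the gene.
#' @param max_distance Maximum gene-body distance (default 1 Mb).
#' @return List: `models` (labels filled in) and `loci` data frame
#'   (`label`, `upstream`, `downstream`, `n_members`, `members`).
#' @export
assign_locus <- function(models, neighbors, max_distance = 1e6) {
  nb <- neighbors[neighbors$type == "gene", , drop = FALSE]
  nb_name <- ifelse(is.na(gff_attr(nb$attributes, "Name")),
                    gff_attr(nb$attributes, "ID"),
                    gff_attr(nb$attributes, "Name"))
  for (k in seq_along(models)) {
    m <- models[[k]]
    sp <- model_span(m)
    on_contig <- which(nb$seqid == m$contig)
    up <- "."; down <- "."
    if (length(on_contig)) {
      s0 <- nb$start[on_contig] - 1L   # to 0-based
      e0 <- nb$end[on_contig]
      dup_ <- sp[1L] - e0              # distance to upstream candidates
      dn_ <- s0 - sp[2L]               # distance to downstream candidates
      iu <- which(dup_ >= 0 & dup_ <= max_distance)
      idn <- which(dn_ >= 0 & dn_ <= max_distance)
      if (length(iu)) up <- nb_name[on_contig[iu[which.min(dup_[iu])]]]
      if (length(idn)) down <- nb_name[on_contig[idn[which.min(dn_[idn])]]]
    }
    models[[k]]$locus_label <- paste0(up, "-", down)
  }
  labels <- vapply(models, function(m) m$locus_label, character(1))
  ids <- vapply(models, function(m) m$gene_id, character(1))
  uniq <- unique(labels)
  loci <- do.call(rbind, lapply(uniq, function(lb) {
    mem <- ids[labels == lb]
    parts <- strsplit(lb, "-", fixed = TRUE)[[1L]]
    data.frame(label = lb, upstream = parts[1L], downstream = parts[2L],
               n_members = length(mem), members = paste(mem, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(loci))
    loci <- data.frame(label = character(), upstream = character(),
                       downstream = character(), n_members = integer(),
                       members = character(), stringsAsFactors = FALSE)
  list(models = models, loci = loci)
}
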