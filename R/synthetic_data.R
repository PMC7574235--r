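# Synthetic genomes with known ground truth.
#
# The generator emulates the situations a curator meets when annotating a
# multi-copy gene family across genome assemblies: multi-exon gene copies
# at controlled divergence from a seed protein, tandem amplifications,
# pseudogenized copies (premature stops, frameshifts, truncated genes),
# flanking marker genes that define synteny loci, transposon-like repeat
# insertions, and genes split across two contigs by assembly breaks.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sub_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)

#' Random protein sequence
#'
#' @param length Number of residues.
#' @param seed RNG seed.
#' @param start_met Force an initial methionine.
#' @return Protein string.
#' @export
random_protein <- function(length, seed = NULL, start_met = TRUE) {
  gen <- function() {
    aa <- sample(AA20, length, replace = TRUE)
    if (start_met) aa[1L] <- "M"
    paste(aa, collapse = "")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Synthetic seed protein for the planted family
#'
#' A random protein (this is a fully synthetic stand-in, not a real
#' perforin sequence) carrying the two default screening motifs --- a
#' GG...W block and an aspartate cluster --- so that motif scanning behaves
#' as it would on genuine family members.
#'
#' @param length Total length in residues (>= 120).
#' @param seed RNG seed.
#' @return Protein string.
#' @export
synthetic_seed_protein <- function(length = 450L, seed = 1001L) {
  stopifnot(length >= 120L)
  with_seed(seed, {
    p <- strsplit(random_protein(length, start_met = TRUE), "")[[1L]]
    g <- length %/% 3L
    p[g:(g + 1L)] <- c("G", "G"); p[g + 8L] <- "W"
    d <- length - 40L
    p[d:(d + 6L)] <- c("D", "A", "D", "G", "S", "S", "D")
    paste(p, collapse = "")
  })
}

#' Mutate a protein to a target identity
#'
#' Substitution-only divergence: `round((1 - target) * L)` positions drawn
#' from 2..L (the initial methionine is preserved, as in a functional
#' ortholog) are replaced by a different residue; `*` is never created.
#'
#' @param protein Protein string.
#' @param target_identity In (0.05, 1].
#' @param seed RNG seed.
#' @return Mutated protein string.
#' @export
mutate_protein <- function(protein, target_identity, seed = NULL) {
  if (target_identity < 0.05)
    stop("target identity below 0.05 is alignment-meaningless", call. = FALSE)
  stopifnot(target_identity <= 1)
  gen <- function() {
    p <- strsplit(protein, "")[[1L]]
    L <- length(p)
    nsub <- round((1 - target_identity) * L)
    if (nsub == 0L) return(protein)
    pos <- sample(2:L, min(nsub, L - 1L))
    for (i in pos) p[i] <- sample(setdiff(AA20, p[i]), 1L)
    paste(p, collapse = "")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Protein sequence identity (ungapped, positionwise)
#'
#' @param a,b Equal-length protein strings.
#' @return Fraction of identical positions.
#' @export
protein_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mean(strsplit(a, "")[[1L]] == strsplit(b, "")[[1L]])
}

#' Reverse-translate a protein with uniform synonymous codon choice
#'
#' @param protein Protein string (no `*`).
#' @return DNA string, 3x protein length (no stop codon appended).
#' @export
reverse_translate <- function(protein) {
  gc <- .genetic_code()
  by_aa <- split(names(gc), unname(gc))
  aa <- strsplit(protein, "")[[1L]]
  stopifnot(all(aa %in% names(by_aa)), !any(aa == "*"))
  paste(vapply(aa, function(a) {
    cs <- by_aa[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1)), collapse = "")
}

random_dna <- function(n, gc_frac = 0.42) {
  p <- c(A = (1 - gc_frac) / 2, C = gc_frac / 2, G = gc_frac / 2,
         T = (1 - gc_frac) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

overwrite_seq <- function(contig, pos0, insert) {
  # write `insert` over contig bases starting at 0-based pos0
  n <- nchar(insert)
  stopifnot(pos0 >= 0L, pos0 + n <= nchar(contig))
  paste0(substr(contig, 1L, pos0), insert,
         substr(contig, pos0 + n + 1L, nchar(contig)))
}

#' Plant a multi-exon gene in a contig
#'
#' The coding sequence is a uniform-synonymous reverse translation of
#' `protein` plus one stop codon; `n_exons - 1` introns (each starting GT
#' and ending AG) are inserted at uniformly chosen codon-phase-0/1/2
#' points, so the spliced CDS translates back to `protein` exactly.  The
#' gene overwrites background bases at `position`.
#'
#' @param contig Contig DNA string.
#' @param protein Protein to encode.
#' @param n_exons Number of exons (>= 1).
#' @param intron_lengths Integer vector of `n_exons - 1` intron lengths
#'   (each >= 60).
#' @param position 0-based start of the gene on the forward strand.
#' @param strand "+" or "-".
#' @param seed RNG seed.
#' @param gene_id Identifier for the truth record.
#' @param lineage Parent gene id, or "root".
#' @return `list(contig, truth)`; `truth` is a `truth_record` with 0-based
#'   half-open forward-strand exon coordinates.
#' @export
plant_gene <- function(contig, protein, n_exons, intron_lengths = integer(),
                       position, strand = "+", seed = NULL,
                       gene_id = "gene1", lineage = "root") {
  stopifnot(n_exons >= 1L, length(intron_lengths) == n_exons - 1L,
            all(intron_lengths >= 60L))
  gen <- function() {
    cds <- paste0(reverse_translate(protein),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    L <- nchar(cds)
    if (n_exons > 1L) {
      # junction points in CDS nucleotide coordinates, any phase,
      # keeping every exon at least 12 nt
      ok <- FALSE
      for (try in 1:200) {
        cut <- sort(sample(12:(L - 12L), n_exons - 1L))
        if (n_exons == 2L || min(diff(cut)) >= 12L) { ok <- TRUE; break }
      }
      if (!ok) stop("cannot place exon junctions (CDS too short)", call. = FALSE)
    } else cut <- integer()
    introns <- vapply(intron_lengths, function(n) {
      paste0("GT", random_dna(n - 4L), "AG")
    }, character(1))
    pieces <- character()
    prev <- 0L
    ex_len <- integer()
    for (k in seq_along(cut)) {
      pieces <- c(pieces, substr(cds, prev + 1L, cut[k]), introns[k])
      ex_len <- c(ex_len, cut[k] - prev)
      prev <- cut[k]
    }
    pieces <- c(pieces, substr(cds, prev + 1L, L))
    ex_len <- c(ex_len, L - prev)
    gene_seq <- paste(pieces, collapse = "")
    glen <- nchar(gene_seq)
    if (position + glen > nchar(contig))
      stop("contig too short for gene plus introns", call. = FALSE)
    # exon intervals in gene-local coordinates (coding strand)
    starts <- cumsum(c(0L, head(ex_len, -1L) + intron_lengths))
    local_ex <- cbind(starts, starts + ex_len)
    placed <- if (strand == "+") gene_seq else reverse_complement(gene_seq)
    fwd_ex <- if (strand == "+") {
      cbind(position + local_ex[, 1L], position + local_ex[, 2L])
    } else {
      m <- cbind(position + glen - local_ex[, 2L],
                 position + glen - local_ex[, 1L])
      m[rev(seq_len(nrow(m))), , drop = FALSE]
    }
    storage.mode(fwd_ex) <- "integer"
    truth <- structure(list(
      gene_id = gene_id, contig = NA_character_, strand = strand,
      exons = fwd_ex, protein = protein, status = "functional",
      defects = character(), lineage = lineage, split = FALSE),
      class = "truth_record")
    list(contig = overwrite_seq(contig, position, placed), truth = truth)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Extract and splice a CDS given truth/model exons
#'
#' @param contig_seq Contig DNA.
#' @param exons Matrix of 0-based half-open forward-strand intervals,
#'   ascending.
#' @param strand "+" or "-".
#' @return Spliced CDS on the coding strand.
#' @export
extract_cds <- function(contig_seq, exons, strand = "+") {
  parts <- vapply(seq_len(nrow(exons)), function(k) {
    substr(contig_seq, exons[k, 1L] + 1L, exons[k, 2L])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-") reverse_complement(s) else s
}

# map a CDS nucleotide index (0-based, coding strand) to a forward-strand
# contig position, given ascending forward exons and the strand
cds_pos_to_genome <- function(exons, strand, p) {
  lens <- exons[, 2L] - exons[, 1L]
  if (strand == "-") {
    ord <- rev(seq_len(nrow(exons)))
  } else ord <- seq_len(nrow(exons))
  cum <- 0L
  for (k in ord) {
    if (p < cum + lens[k]) {
      off <- p - cum
      return(if (strand == "+") exons[k, 1L] + off else exons[k, 2L] - 1L - off)
    }
    cum <- cum + lens[k]
  }
  stop("CDS position out of range")
}

#' Pseudogenize a planted gene
#'
#' Modes: `premature_stop` replaces one internal codon (lying wholly inside
#' one exon) with a stop codon; `frameshift` deletes 1 or 2 bases inside an
#' exon (a compensating random insertion just after the gene keeps all
#' downstream coordinates on the contig unchanged); `truncated` overwrites
#' the terminal exon with background sequence and drops it from the truth.
#'
#' @param truth `truth_record` from [plant_gene()].
#' @param contig Contig DNA holding the gene.
#' @param mode One of `premature_stop`, `frameshift`, `truncated`.
#' @param seed RNG seed.
#' @return `list(contig, truth)` with status `pseudogene`, the defect
#'   recorded, and the conceptual translation updated.
#' @export
pseudogenize <- function(truth, contig, mode = c("premature_stop", "frameshift",
                                                 "truncated"), seed = NULL) {
  mode <- match.arg(mode)
  if (nchar(truth$protein) < 2L) stop("gene of 1 codon cannot be pseudogenized",
                                      call. = FALSE)
  gen <- function() {
    ex <- truth$exons
    strand <- truth$strand
    lens <- ex[, 2L] - ex[, 1L]
    cds_len <- sum(lens)
    if (mode == "premature_stop") {
      # internal codons fully inside one exon
      n_codon <- cds_len %/% 3L
      cand <- integer()
      for (cc in 1:(n_codon - 2L)) {   # skip first and last codon
        g <- vapply(0:2, function(o) cds_pos_to_genome(ex, strand, 3L * cc + o),
                    integer(1))
        if (max(g) - min(g) == 2L) cand <- c(cand, cc)
      }
      stopifnot(length(cand) > 0L)
      cc <- sample(cand, 1L)
      stopc <- sample(c("TAA", "TAG", "TGA"), 1L)
      g0 <- cds_pos_to_genome(ex, strand, 3L * cc)
      piece <- if (strand == "+") stopc else reverse_complement(stopc)
      pos <- if (strand == "+") g0 else g0 - 2L
      contig <- overwrite_seq(contig, pos, piece)
      truth$defects <- c(truth$defects, "premature_stop")
    } else if (mode == "frameshift") {
      k <- sample(1:2, 1L)
      # delete k bases from the middle of the longest exon
      e <- which.max(lens)
      p <- ex[e, 1L] + lens[e] %/% 2L
      gene_end <- max(ex[, 2L])
      contig <- paste0(substr(contig, 1L, p),                 # up to p (0-based)
                       substr(contig, p + k + 1L, gene_end),  # rest of gene
                       random_dna(k),                         # compensate
                       substr(contig, gene_end + 1L, nchar(contig)))
      # shift coordinates past p left by k
      ex[, 1L] <- ifelse(ex[, 1L] > p, ex[, 1L] - k, ex[, 1L])
      ex[, 2L] <- ifelse(ex[, 2L] > p, ex[, 2L] - k, ex[, 2L])
      truth$exons <- ex
      truth$defects <- c(truth$defects, "frameshift")
    } else { # truncated: remove the terminal exon (transcription order)
      stopifnot(nrow(ex) >= 2L)
      e <- if (strand == "+") nrow(ex) else 1L
      contig <- overwrite_seq(contig, ex[e, 1L], random_dna(lens[e]))
      truth$exons <- ex[-e, , drop = FALSE]
      truth$defects <- c(truth$defects, "truncated")
    }
    truth$status <- "pseudogene"
    cds <- extract_cds(contig, truth$exons, strand)
    truth$protein <- translate_dna(cds, 0L)
    list(contig = contig, truth = truth)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Specification of one synthetic genome
#'
#' Defaults describe a desk-scale stand-in for a real assembly: a single
#' 200 kb contig at 42% GC carrying a handful of 2-5-exon gene copies at
#' 0.6-0.9 identity to the seed protein, introns of 60-300 bases, tandem
#' clusters flanked by marker genes, one fifth of copies pseudogenized,
#' and a few transposon-like repeat insertions.
#'
#' @param contig_lengths Named integer vector of contig lengths.
#' @param gc GC fraction of the background.
#' @param n_singletons Number of single-copy genes planted.
#' @param tandem_clusters Integer vector of tandem cluster sizes.
#' @param exon_count_range,intron_length_range,identity_range Ranges for
#'   per-gene draws.
#' @param pseudogene_fraction Fraction of planted copies pseudogenized.
#' @param pseudogene_modes Modes cycled over the pseudogenized copies.
#' @param n_repeats,repeat_length Transposon-like insertions (5% per-site
#'   mutated copies of a fixed repeat seed).
#' @param split_contig When `TRUE`, the last planted multi-exon gene is cut
#'   at an intron and its halves emitted on two contigs (assembly-break
#'   artifact).
#' @param seed_protein Seed protein (default [synthetic_seed_protein()]).
#' @param seed RNG seed.
#' @return List of class `genome_spec`.
#' @export
genome_spec <- function(contig_lengths = c(chr1 = 200000L), gc = 0.42,
                        n_singletons = 2L, tandem_clusters = c(3L, 3L),
                        exon_count_range = c(2L, 5L),
                        intron_length_range = c(60L, 300L),
                        identity_range = c(0.6, 0.9),
                        pseudogene_fraction = 0.2,
                        pseudogene_modes = c("premature_stop", "frameshift"),
                        n_repeats = 3L, repeat_length = 400L,
                        split_contig = FALSE,
                        seed_protein = synthetic_seed_protein(),
                        seed = 1L) {
  stopifnot(n_singletons >= 0L, all(tandem_clusters >= 1L),
            identity_range[1L] > 0, identity_range[2L] <= 1,
            intron_length_range[1L] >= 60L, n_repeats >= 0L)
  structure(as.list(environment()), class = "genome_spec")
}

repeat_seed_sequence <- function(length = 400L) {
  with_seed(424243L, random_dna(length, 0.5))
}

#' Simulate a genome with planted ground truth
#'
#' Deterministic for a fixed spec seed.  Marker genes (`MARKA`, `MARKB`,
#' ...) are placed flanking every planted cluster and singleton, in the
#' manner of the conserved neighbors that define real synteny loci, and are
#' reported in a neighbor-annotation feature table.
#'
#' @param spec A [genome_spec()].
#' @return List with `genome` (named character vector of contigs), `truth`
#'   (list of `truth_record`s), `truth_table` (data frame), `truth_gff`
#'   and `neighbors` (feature data frames), `markers` (marker placements),
#'   and `seed_protein`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    contig_id <- names(spec$contig_lengths)[1L]
    contig <- random_dna(spec$contig_lengths[[1L]], spec$gc)
    units <- c(as.list(spec$tandem_clusters), as.list(rep(1L, spec$n_singletons)))
    n_genes <- sum(unlist(units))
    # which copies become pseudogenes, and how
    n_pseudo <- round(spec$pseudogene_fraction * n_genes)
    pseudo_idx <- if (n_pseudo > 0L) sample.int(n_genes, n_pseudo) else integer()
    pseudo_mode <- rep(spec$pseudogene_modes, length.out = n_pseudo)

    truths <- list()
    markers <- list()
    cursor <- 2000L + sample.int(1000L, 1L)
    gi <- 0L
    marker_letter <- 0L
    next_marker <- function(pos) {
      marker_letter <<- marker_letter + 1L
      id <- paste0("MARK", LETTERS[marker_letter])
      markers[[length(markers) + 1L]] <<- list(id = id, start = pos,
                                               end = pos + 300L)
      pos + 300L
    }
    for (u in units) {
      cursor <- next_marker(cursor) + 200L + sample.int(400L, 1L)
      for (k in seq_len(u)) {
        gi <- gi + 1L
        ident <- stats::runif(1L, spec$identity_range[1L], spec$identity_range[2L])
        prot <- mutate_protein(spec$seed_protein, ident)
        n_ex <- sample(spec$exon_count_range[1L]:spec$exon_count_range[2L], 1L)
        ilen <- if (n_ex > 1L)
          sample(spec$intron_length_range[1L]:spec$intron_length_range[2L],
                 n_ex - 1L, replace = TRUE) else integer()
        strand <- sample(c("+", "-"), 1L)
        res <- plant_gene(contig, prot, n_ex, ilen, cursor, strand,
                          gene_id = sprintf("%s_g%02d", contig_id, gi),
                          lineage = "seed")
        contig <- res$contig
        tr <- res$truth
        tr$contig <- contig_id
        tr$identity <- ident
        w <- which(pseudo_idx == gi)
        if (length(w)) {
          ps <- pseudogenize(tr, contig, pseudo_mode[w[1L]])
          contig <- ps$contig
          tr <- ps$truth
        }
        truths[[length(truths) + 1L]] <- tr
        cursor <- max(tr$exons[, 2L]) + 400L + sample.int(800L, 1L)
      }
      cursor <- next_marker(cursor + 200L + sample.int(400L, 1L)) + 1500L
    }
    # transposon-like repeats in the remaining tail
    rep_seed <- repeat_seed_sequence(spec$repeat_length)
    for (r in seq_len(spec$n_repeats)) {
      if (cursor + spec$repeat_length + 100L > nchar(contig)) break
      mut <- strsplit(rep_seed, "")[[1L]]
      flip <- which(stats::runif(length(mut)) < 0.05)
      for (i in flip) mut[i] <- sample(setdiff(c("A", "C", "G", "T"), mut[i]), 1L)
      contig <- overwrite_seq(contig, cursor, paste(mut, collapse = ""))
      cursor <- cursor + spec$repeat_length + 500L + sample.int(1000L, 1L)
    }
    if (cursor > nchar(contig))
      stop("planted elements exceed the contig; enlarge contig_lengths",
           call. = FALSE)

    genome <- stats::setNames(contig, contig_id)

    # assembly-break artifact: cut the last multi-exon gene at an intron
    if (isTRUE(spec$split_contig)) {
      multi <- which(vapply(truths, function(t) nrow(t$exons) >= 2L, logical(1)))
      stopifnot(length(multi) > 0L)
      t <- truths[[multi[length(multi)]]]
      cutpt <- t$exons[1L, 2L] + (t$exons[2L, 1L] - t$exons[1L, 2L]) %/% 2L
      a <- substr(contig, 1L, cutpt)
      b <- substr(contig, cutpt + 1L, nchar(contig))
      genome <- stats::setNames(c(a, b), paste0(contig_id, c("_part1", "_part2")))
      new_truths <- list()
      for (tr in truths) {
        if (max(tr$exons[, 2L]) <= cutpt) {
          tr$contig <- paste0(contig_id, "_part1")
        } else if (min(tr$exons[, 1L]) >= cutpt) {
          tr$contig <- paste0(contig_id, "_part2")
          tr$exons <- tr$exons - cutpt
        } else { # the cut gene: one truth row per fragment
          left <- tr; right <- tr
          left$contig <- paste0(contig_id, "_part1")
          left$exons <- tr$exons[tr$exons[, 2L] <= cutpt, , drop = FALSE]
          left$gene_id <- paste0(tr$gene_id, "_5p")
          left$split <- TRUE
          right$contig <- paste0(contig_id, "_part2")
          right$exons <- tr$exons[tr$exons[, 1L] >= cutpt, , drop = FALSE] - cutpt
          right$gene_id <- paste0(tr$gene_id, "_3p")
          right$split <- TRUE
          new_truths <- c(new_truths, list(left, right))
          next
        }
        new_truths <- c(new_truths, list(tr))
      }
      truths <- new_truths
      markers <- lapply(markers, function(mk) {
        if (mk$end <= cutpt) mk$contig <- paste0(contig_id, "_part1")
        else { mk$contig <- paste0(contig_id, "_part2")
               mk$start <- mk$start - cutpt; mk$end <- mk$end - cutpt }
        mk
      })
    } else {
      markers <- lapply(markers, function(mk) { mk$contig <- contig_id; mk })
    }

    list(genome = genome, truth = truths,
         truth_table = truth_table(truths),
         truth_gff = truth_to_gff3(truths),
         neighbors = markers_to_gff3(markers),
         markers = markers, seed_protein = spec$seed_protein)
  })
}

truth_table <- function(truths) {
  if (!length(truths)) {
    return(data.frame(gene_id = character(), contig = character(),
                      strand = character(), start = integer(), end = integer(),
                      n_exons = integer(), status = character(),
                      defects = character(), lineage = character(),
                      split = logical(), exons = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(truths, function(t) {
    data.frame(gene_id = t$gene_id, contig = t$contig, strand = t$strand,
               start = min(t$exons[, 1L]) + 1L, end = max(t$exons[, 2L]),
               n_exons = nrow(t$exons), status = t$status,
               defects = if (length(t$defects)) paste(t$defects, collapse = ",") else ".",
               lineage = t$lineage, split = isTRUE(t$split),
               exons = paste(sprintf("%d-%d", t$exons[, 1L] + 1L, t$exons[, 2L]),
                             collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

truth_to_gff3 <- function(truths) {
  rows <- list()
  for (t in truths) {
    span <- internal_to_gff(min(t$exons[, 1L]), max(t$exons[, 2L]))
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = t$contig, source = "famtrace_sim", type = "gene",
      start = span[1L], end = span[2L], score = ".", strand = t$strand,
      phase = ".",
      attributes = sprintf("ID=%s;status=%s;defects=%s", t$gene_id, t$status,
                           if (length(t$defects)) paste(t$defects, collapse = ",") else "."),
      stringsAsFactors = FALSE)
    for (k in seq_len(nrow(t$exons))) {
      g <- internal_to_gff(t$exons[k, 1L], t$exons[k, 2L])
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = t$contig, source = "famtrace_sim", type = "CDS",
        start = g[1L], end = g[2L], score = ".", strand = t$strand, phase = ".",
        attributes = sprintf("ID=%s.cds%d;Parent=%s", t$gene_id, k, t$gene_id),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

markers_to_gff3 <- function(markers) {
  if (!length(markers)) {
    return(data.frame(seqid = character(), source = character(), type = character(),
                      start = integer(), end = integer(), score = character(),
                      strand = character(), phase = character(),
                      attributes = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(markers, function(mk) {
    data.frame(seqid = mk$contig, source = "famtrace_sim", type = "gene",
               start = mk$start + 1L, end = mk$end, score = ".", strand = "+",
               phase = ".", attributes = sprintf("ID=%s;Name=%s", mk$id, mk$id),
               stringsAsFactors = FALSE)
  }))
}
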