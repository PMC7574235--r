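# From translated hits to exon/intron gene models.

#' Parameters for gene-model construction
#'
#' @param max_intron Maximum genomic gap (bases) joining two hits into one
#'   candidate locus; also the window padding on each side.
#' @param min_intron Minimum intron length accepted by the splice DP.
#' @param intron_penalty Fixed score penalty per intron (matrix units).
#' @param frameshift_penalty Penalty for a 1-2 base frameshift jump.
#' @param stop_score Score of an in-frame stop codon against any residue;
#'   heavy but finite, so pseudogene parses stay traversable and the stop
#'   is recorded rather than avoided.
#' @param gap_open,gap_extend Affine gap penalties (codon units).
#' @param min_locus_score Minimum aggregate hit score to keep a locus.
#' @param min_model_score Score floor below which a refined parse is
#'   rejected.
#' @param matrix Substitution matrix name.
#' @return List of class `model_params`.
#' @export
model_params <- function(max_intron = 20000L, min_intron = 40L,
                         intron_penalty = -12, frameshift_penalty = -30,
                         stop_score = -15, gap_open = -11, gap_extend = -1,
                         min_locus_score = 80, min_model_score = 300,
                         matrix = "BLOSUM62") {
  stopifnot(max_intron >= min_intron, min_intron >= 4L,
            intron_penalty < 0, frameshift_penalty < 0, stop_score < 0)
  structure(list(max_intron = as.integer(max_intron),
                 min_intron = as.integer(min_intron),
                 intron_penalty = intron_penalty,
                 frameshift_penalty = frameshift_penalty,
                 stop_score = stop_score,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_locus_score = min_locus_score,
                 min_model_score = min_model_score,
                 matrix = matrix),
            class = "model_params")
}

codon_table_string <- function() {
  gc <- .genetic_code()
  b <- c("A", "C", "G", "T")
  codons <- character(64)   # b0-major order, matching the C++ index
  k <- 1L
  for (b0 in b) for (b1 in b) for (b2 in b) {
    codons[k] <- paste0(b0, b1, b2); k <- k + 1L
  }
  paste(unname(gc[codons]), collapse = "")
}

#' Cluster translated hits into candidate loci
#'
#' Single-linkage chaining of same-contig, same-strand hits whose genomic
#' gap is at most `max_intron` and whose query intervals run colinearly
#' with genomic order (so a tandem second copy, which restarts the query,
#' opens a new locus).  Windows are padded by `max_intron` on both sides
#' and clipped to the contig.
#'
#' @param hits Hit data frame from [translated_search()] (one genome).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param params [model_params()].
#' @return List of candidate loci: `contig`, `strand`, `win_start`,
#'   `win_end` (0-based half-open), `query_id` (best member), `score`
#'   (aggregate), `hit_rows` (row indices into `hits`).
#' @export
cluster_hits <- function(hits, contig_lengths, params = model_params()) {
  out <- list()
  if (nrow(hits) == 0L) return(out)
  for (key in unique(paste(hits$contig, hits$strand, hits$query_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    idx <- which(hits$contig == parts[1L] & hits$strand == parts[2L] &
                   hits$query_id == parts[3L])
    idx <- idx[order(hits$g_start[idx])]
    grp <- integer(length(idx))
    g <- 1L
    grp[1L] <- 1L
    if (length(idx) > 1L) {
      for (k in 2:length(idx)) {
        prev <- idx[k - 1L]; cur <- idx[k]
        gap_ok <- hits$g_start[cur] - hits$g_end[prev] <= params$max_intron
        # strict query progression: a tandem copy re-hitting the same
        # query stretch must open a new locus
        colinear <- if (parts[2L] == "+") {
          hits$q_start[cur] >= hits$q_start[prev] &&
            hits$q_end[cur] > hits$q_end[prev]
        } else {
          hits$q_end[cur] <= hits$q_end[prev] &&
            hits$q_start[cur] < hits$q_start[prev]
        }
        if (!(gap_ok && colinear)) g <- g + 1L
        grp[k] <- g
      }
    }
    for (gi in unique(grp)) {
      rows <- idx[grp == gi]
      score <- sum(hits$score[rows])
      if (score < params$min_locus_score) next
      clen <- contig_lengths[[parts[1L]]]
      best <- rows[which.max(hits$score[rows])]
      core <- c(min(hits$g_start[rows]), max(hits$g_end[rows]))
      out[[length(out) + 1L]] <- list(
        contig = parts[1L], strand = parts[2L],
        core_start = core[1L], core_end = core[2L],
        win_start = max(0L, core[1L] - params$max_intron),
        win_end = min(clen, core[2L] + params$max_intron),
        query_id = hits$query_id[best], score = score, hit_rows = rows)
    }
  }
  # clip each window at the hit span of any disjoint neighboring locus, so
  # a tandem neighbor copy can never be absorbed into this locus's parse
  for (i in seq_along(out)) {
    for (k in seq_along(out)) {
      if (k == i || out[[k]]$contig != out[[i]]$contig) next
      a <- out[[i]]; b <- out[[k]]
      if (b$core_end <= a$core_start) {
        out[[i]]$win_start <- max(out[[i]]$win_start, b$core_end)
      } else if (b$core_start >= a$core_end) {
        out[[i]]$win_end <- min(out[[i]]$win_end, b$core_start)
      }
    }
  }
  out
}

#' Splice-aware alignment of a protein query to a genomic window
#'
#' Dynamic program over (genome position, query position, codon-phase /
#' intron state) maximizing substitution score with affine codon gaps;
#' introns enter at GT and leave at AG only, with length >= `min_intron`
#' and a fixed penalty; phase-1/2 introns split codons and the donor-side
#' bases are carried across; frameshifts are 1-2 base jumps with a heavy
#' penalty; in-frame stops score `stop_score` and are recorded as `*` in
#' the conceptual translation.
#'
#' @param query Protein string.
#' @param window_dna DNA of the window on the coding strand.
#' @param params [model_params()].
#' @return `NULL` when no parse reaches `min_model_score`; otherwise a list
#'   with `score`, `exons` / `introns` (0-based half-open window
#'   coordinates, coding strand), `frameshifts`, `cds`, `protein`
#'   (conceptual translation, `*` at stops), `q_start`, `q_end`,
#'   `aligned_query`, `aligned_target`.
#' @export
splice_align <- function(query, window_dna, params = model_params()) {
  mat <- score_matrix(params$matrix, stop_score = params$stop_score)
  res <- cpp_splice_align(toupper(window_dna), query, mat,
                          paste(rownames(mat), collapse = ""),
                          codon_table_string(),
                          params$gap_open, params$gap_extend,
                          params$intron_penalty, params$min_intron,
                          params$frameshift_penalty, params$min_model_score)
  if (!isTRUE(res$found)) return(NULL)
  res
}

#' Refine one candidate locus into a gene model
#'
#' Runs [splice_align()] on the locus window (reverse-complemented for
#' minus-strand loci) and lifts coordinates back to the forward strand of
#' the contig.
#'
#' @param locus One element of [cluster_hits()] output.
#' @param contig_seq DNA of the locus contig.
#' @param queries Named character vector holding at least the locus query.
#' @param params [model_params()].
#' @return A `gene_model` list or `NULL` (rejected locus).
#' @export
refine_locus <- function(locus, contig_seq, queries, params = model_params()) {
  w0 <- locus$win_start; w1 <- locus$win_end
  win <- substr(contig_seq, w0 + 1L, w1)
  if (locus$strand == "-") win <- reverse_complement(win)
  q <- queries[[locus$query_id]]
  res <- splice_align(q, win, params)
  if (is.null(res)) return(NULL)
  res <- extend_to_query_ends(res, q, win, params)
  # include a directly following in-frame stop codon in the CDS, as
  # conventional for annotated coding sequences
  ne <- nrow(res$exons)
  e <- res$exons[ne, 2L]
  stopc <- substr(win, e + 1L, e + 3L)
  if (res$q_end == nchar(q) && stopc %in% c("TAA", "TAG", "TGA")) {
    res$exons[ne, 2L] <- e + 3L
    res$cds <- paste0(res$cds, stopc)
  }
  # start-codon selection is "first M in the parse": a chance-shifted
  # prefix register can otherwise hide a genuine ATG start
  if (substr(res$protein, 1L, 1L) != "M") {
    mpos <- regexpr("M", substr(res$protein, 1L, 10L), fixed = TRUE)[1L]
    trim <- mpos - 1L
    first_ex <- res$exons[1L, 2L] - res$exons[1L, 1L]
    fs_early <- nrow(res$frameshifts) > 0L &&
      min(res$frameshifts[, 1L]) < res$exons[1L, 1L] + 3L * trim + 3L
    if (mpos > 0L && trim > 0L && first_ex > 3L * trim + 3L && !fs_early &&
        substr(res$cds, 3L * trim + 1L, 3L * trim + 3L) == "ATG") {
      res$exons[1L, 1L] <- res$exons[1L, 1L] + 3L * trim
      res$cds <- substr(res$cds, 3L * trim + 1L, nchar(res$cds))
      res$protein <- substr(res$protein, mpos, nchar(res$protein))
      res$q_start <- res$q_start + trim
    }
  }
  W <- nchar(win)
  lift <- function(m) {
    if (nrow(m) == 0L) return(m)
    out <- if (locus$strand == "+") {
      cbind(w0 + m[, 1L], w0 + m[, 2L])
    } else {
      cbind(w0 + W - m[, 2L], w0 + W - m[, 1L])
    }
    storage.mode(out) <- "integer"
    out[order(out[, 1L]), , drop = FALSE]
  }
  model <- list(
    gene_id = NA_character_, contig = locus$contig, strand = locus$strand,
    exons = lift(res$exons), introns = lift(res$introns),
    frameshifts = res$frameshifts,
    cds = res$cds, protein = res$protein,
    q_start = res$q_start, q_end = res$q_end, query_len = nchar(q),
    score = res$score, query_id = locus$query_id,
    status = NA_character_, defects = character(), locus_label = NA_character_)
  class(model) <- "gene_model"
  model
}

# Local alignment drops mismatching query termini; a real terminal exon
# boundary then falls a few codons short.  Extend the outer exons
# ungapped, codon by codon, to cover the whole query, accepting the
# extension only when its summed score stays above -end_extend_drop and
# no stop codon or window edge intervenes.
extend_to_query_ends <- function(res, q, win, params, end_extend_drop = 25) {
  mat <- score_matrix(params$matrix, stop_score = params$stop_score)
  gc <- .genetic_code()
  aa_of <- function(codon) {
    a <- gc[codon]
    if (is.na(a)) "X" else unname(a)
  }
  ne <- nrow(res$exons)
  qv <- strsplit(q, "")[[1L]]
  # forward
  need <- nchar(q) - res$q_end
  if (need > 0L) {
    e <- res$exons[ne, 2L]; sc <- 0; add <- character()
    ok <- TRUE
    for (k in seq_len(need)) {
      codon <- substr(win, e + 1L, e + 3L)
      if (nchar(codon) < 3L || codon %in% c("TAA", "TAG", "TGA")) { ok <- FALSE; break }
      a <- aa_of(codon)
      sc <- sc + mat[a, qv[res$q_end + k]]
      add <- c(add, codon)
      e <- e + 3L
    }
    if (ok && sc >= -end_extend_drop) {
      res$exons[ne, 2L] <- e
      res$cds <- paste0(res$cds, paste(add, collapse = ""))
      res$protein <- paste0(res$protein,
                            paste(vapply(add, aa_of, character(1)), collapse = ""))
      res$q_end <- nchar(q)
    }
  }
  need <- res$q_start
  if (need > 0L) {
    s <- res$exons[1L, 1L]; sc <- 0; add <- character()
    ok <- TRUE
    for (k in seq_len(need)) {
      if (s - 3L < 0L) { ok <- FALSE; break }
      codon <- substr(win, s - 2L, s)
      if (codon %in% c("TAA", "TAG", "TGA")) { ok <- FALSE; break }
      a <- aa_of(codon)
      sc <- sc + mat[a, qv[res$q_start - k + 1L]]
      add <- c(codon, add)
      s <- s - 3L
    }
    if (ok && sc >= -end_extend_drop) {
      res$exons[1L, 1L] <- s
      res$cds <- paste0(paste(add, collapse = ""), res$cds)
      res$protein <- paste0(paste(vapply(add, aa_of, character(1)), collapse = ""),
                            res$protein)
      res$q_start <- 0L
    }
  }
  res
}

#' Classify a gene model as functional or pseudogene
#'
#' A model is a pseudogene iff its conceptual translation contains a
#' premature stop, the optimal parse needed a frameshift jump, or the model
#' lacks the expected terminal structure: an initial methionine and a
#' terminal stop codon (`truncated` — also how assembly fragments
#' surface).  Every cause is listed in `defects`.
#'
#' @param model A `gene_model`.
#' @return The model with `status` and `defects` filled in.
#' @export
classify_status <- function(model) {
  defects <- character()
  if (grepl("*", model$protein, fixed = TRUE)) defects <- c(defects, "premature_stop")
  if (nrow(model$frameshifts) > 0L) defects <- c(defects, "frameshift")
  n <- nchar(model$cds)
  has_stop <- n >= 3L && substr(model$cds, n - 2L, n) %in% c("TAA", "TAG", "TGA")
  if (substr(model$protein, 1L, 1L) != "M" || !has_stop)
    defects <- c(defects, "truncated")
  model$defects <- defects
  model$status <- if (length(defects)) "pseudogene" else "functional"
  model
}

#' Default motif patterns for family membership screening
#'
#' Schematic, position-free patterns in the spirit of the MACPF signature,
#' the MACPF GGXnW motif and a C2 Ca2+-binding aspartate cluster.  They are
#' stand-ins meant to be overridden with curated patterns for real data.
#'
#' @return Named character vector of regular expressions.
#' @export
default_motifs <- function() {
  c(macpf_ggxw = "GG.{3,60}?W",
    c2_ca_site = "D.DG.{1,10}?D")
}

#' Scan a protein for motif patterns
#'
#' Reports all non-overlapping matches (leftmost, shortest under lazy
#' quantifiers; scanning resumes after each match).
#'
#' @param protein Protein string.
#' @param patterns Named character vector of regular expressions.
#' @return `data.frame` with `motif`, `start`, `end` (1-based inclusive),
#'   `match`.
#' @export
scan_motifs <- function(protein, patterns = default_motifs()) {
  rows <- list()
  for (nm in names(patterns)) {
    pat <- patterns[[nm]]
    bad <- function(e) stop("malformed motif pattern '", nm, "': ",
                            conditionMessage(e), call. = FALSE)
    m <- tryCatch(suppressWarnings(gregexpr(pat, protein, perl = TRUE)[[1L]]),
                  error = bad, warning = bad)
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      rows[[length(rows) + 1L]] <- data.frame(
        motif = nm, start = m[k], end = m[k] + len[k] - 1L,
        match = substr(protein, m[k], m[k] + len[k] - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(motif = character(), start = integer(), end = integer(),
                      match = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Gene models as a GFF3 feature table
#'
#' Emits gene/mRNA/CDS rows with status, defects and locus label in the
#' column-9 attributes; coordinates become 1-based inclusive here.
#'
#' @param models List of classified `gene_model`s.
#' @return 9-column feature data frame (see [write_gff3()]).
#' @export
models_to_gff3 <- function(models) {
  rows <- list()
  for (m in models) {
    span <- internal_to_gff(min(m$exons[, 1L]), max(m$exons[, 2L]))
    base <- sprintf("ID=%s;status=%s;defects=%s;locus=%s;query=%s;score=%.1f",
                    m$gene_id, m$status,
                    if (length(m$defects)) paste(m$defects, collapse = ",") else ".",
                    ifelse(is.na(m$locus_label), ".", m$locus_label),
                    m$query_id, m$score)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = m$contig, source = "famtrace", type = "gene",
      start = span[1L], end = span[2L], score = sprintf("%.1f", m$score),
      strand = m$strand, phase = ".", attributes = base,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = m$contig, source = "famtrace", type = "mRNA",
      start = span[1L], end = span[2L], score = ".", strand = m$strand,
      phase = ".", attributes = sprintf("ID=%s.t1;Parent=%s", m$gene_id, m$gene_id),
      stringsAsFactors = FALSE)
    ex <- m$exons
    if (m$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    phase <- 0L
    for (k in seq_len(nrow(ex))) {
      g <- internal_to_gff(ex[k, 1L], ex[k, 2L])
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = m$contig, source = "famtrace", type = "CDS",
        start = g[1L], end = g[2L], score = ".", strand = m$strand,
        phase = as.character(phase),
        attributes = sprintf("ID=%s.cds%d;Parent=%s.t1", m$gene_id, k, m$gene_id),
        stringsAsFactors = FALSE)
      phase <- (3L - ((ex[k, 2L] - ex[k, 1L] - phase) %% 3L)) %% 3L
    }
  }
  if (!length(rows)) {
    return(data.frame(seqid = character(), source = character(), type = character(),
                      start = integer(), end = integer(), score = character(),
                      strand = character(), phase = character(),
                      attributes = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Conceptual translations of a model set as a named vector
#'
#' @param models List of `gene_model`s.
#' @return Named character vector (ids are gene ids).
#' @export
models_to_proteins <- function(models) {
  out <- vapply(models, function(m) m$protein, character(1))
  names(out) <- vapply(models, function(m) m$gene_id, character(1))
  out
}
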