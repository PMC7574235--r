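# Six-frame translated homology search (the tblastn-like stage).

#' Scoring/search parameter set for the translated search
#'
#' Defaults mirror common protein-vs-translated-DNA practice: BLOSUM62,
#' affine gaps costing open + L*extend, 4-residue neighborhood seeds, and a
#' raw-score reporting threshold (no E-value statistics; candidate
#' selection downstream is score- and synteny-driven).
#'
#' @param matrix Substitution matrix name (only "BLOSUM62" shipped).
#' @param word_size Seed word length k (>= 2).
#' @param seed_threshold Minimum score of a diagonal k-mer to seed an
#'   extension, in matrix units.
#' @param x_drop X-drop bound for gapped extension, in matrix units (> 0).
#' @param gap_open,gap_extend Gap penalties (negative; a gap of length L
#'   costs `gap_open + L * gap_extend`).
#' @param min_score Minimum reported hit score.
#' @param max_hits_per_segment Cap on hits reported from one stop-free
#'   segment of one frame.
#' @return A list of class `search_params`.
#' @export
search_params <- function(matrix = "BLOSUM62", word_size = 4L,
                          seed_threshold = 14, x_drop = 20,
                          gap_open = -11, gap_extend = -1,
                          min_score = 50, max_hits_per_segment = 16L) {
  stopifnot(word_size >= 2L, gap_open < 0, gap_extend < 0, x_drop > 0)
  structure(list(matrix = matrix, word_size = as.integer(word_size),
                 seed_threshold = seed_threshold, x_drop = x_drop,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_score = min_score,
                 max_hits_per_segment = as.integer(max_hits_per_segment)),
            class = "search_params")
}

#' Fetch a substitution matrix, optionally overriding the stop row
#'
#' @param name Matrix name (currently "BLOSUM62", from Biostrings).
#' @param stop_score When non-`NULL`, every score involving `*` is set to
#'   this value.  The splice-aware aligner uses this to make in-frame stop
#'   codons expensive but traversable.
#' @return Numeric matrix with amino-acid row/column names.
#' @export
score_matrix <- function(name = "BLOSUM62", stop_score = NULL) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  m <- m + 0.0
  if (!is.null(stop_score)) {
    m["*", ] <- stop_score
    m[, "*"] <- stop_score
    m["*", "*"] <- stop_score
  }
  m
}

#' Six-frame translation with coordinate maps
#'
#' Frames +0,+1,+2 come from the forward strand, -0,-1,-2 from the reverse
#' complement.  Each frame records its strand, offset and the contig
#' length, which determine a bijection between protein positions and
#' forward-strand codon intervals (see [frame_to_genome()]).
#'
#' @param seq Contig DNA sequence (length >= 3).
#' @return List of six frames, each `list(strand, offset, aa, contig_len)`.
#' @export
six_frame <- function(seq) {
  stopifnot(nchar(seq) >= 3L)
  rc <- reverse_complement(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (off in 0:2) {
      out[[length(out) + 1L]] <- list(
        strand = strand, offset = off,
        aa = translate_dna(s, off), contig_len = nchar(seq))
    }
  }
  out
}

#' Map a protein interval in one reading frame to forward-strand nucleotides
#'
#' @param p0,p1 0-based half-open protein interval within the frame.
#' @param strand "+" or "-".
#' @param offset Frame offset 0..2 (on the translated strand).
#' @param contig_len Contig length in bases.
#' @return Integer vector `c(g_start, g_end)`, 0-based half-open,
#'   forward strand.
#' @export
frame_to_genome <- function(p0, p1, strand, offset, contig_len) {
  a <- offset + 3L * p0
  b <- offset + 3L * p1
  if (strand == "+") c(a, b) else c(contig_len - b, contig_len - a)
}

#' Map a forward-strand codon interval back to a protein index
#'
#' Inverse of [frame_to_genome()] for a single codon.
#'
#' @param g_start 0-based forward-strand start of the codon.
#' @param strand,offset,contig_len As in [frame_to_genome()].
#' @return 0-based protein index within the frame.
#' @export
genome_to_frame <- function(g_start, strand, offset, contig_len) {
  if (strand == "+") (g_start - offset) %/% 3L
  else (contig_len - g_start - 3L - offset) %/% 3L
}

#' Translated search of a protein query against a genome contig
#'
#' Seed-and-extend over all six reading frames: diagonal k-mer words
#' scoring at least `seed_threshold` seed a gapped extension (exact
#' affine-gap local DP bounded by the X-drop criterion) inside the
#' stop-free segment containing the seed.  Hits never cross an in-frame
#' stop codon: stops bound the searchable segments, so pseudogenes surface
#' as split hits for the downstream stages to see.
#'
#' @param query Named single-element character vector, or plain string with
#'   `query_id` given.
#' @param contig_id,seq Contig identifier and DNA sequence.
#' @param params [search_params()].
#' @param query_id Identifier used in the hit table.
#' @return `data.frame` of hits, sorted by score descending: `query_id`,
#'   `contig`, `strand`, `frame`, `g_start`, `g_end` (0-based half-open,
#'   forward strand), `q_start`, `q_end` (0-based half-open in the query),
#'   `score`, `aligned_query`, `aligned_target`.
#' @export
translated_search <- function(query, contig_id, seq, params = search_params(),
                              query_id = NULL) {
  if (is.null(query_id)) {
    query_id <- if (!is.null(names(query))) names(query)[1L] else "query"
  }
  query <- unname(query[1L])
  if (nchar(query) < params$word_size)
    stop("query shorter than the seed word size", call. = FALSE)
  mat <- score_matrix(params$matrix)
  frames <- six_frame(seq)
  rows <- list()
  for (fr in frames) {
    if (nchar(fr$aa) == 0L) next
    hits <- cpp_frame_search(query, fr$aa, mat, paste(rownames(mat), collapse = ""),
                             params$word_size, params$seed_threshold,
                             params$gap_open, params$gap_extend,
                             params$min_score, params$max_hits_per_segment,
                             params$x_drop)
    for (h in hits) {
      g <- frame_to_genome(h$t_start, h$t_end, fr$strand, fr$offset, fr$contig_len)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = query_id, contig = contig_id,
        strand = fr$strand, frame = fr$offset,
        g_start = g[1L], g_end = g[2L],
        q_start = h$q_start, q_end = h$q_end,
        score = h$score,
        aligned_query = h$aligned_query, aligned_target = h$aligned_target,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_hits()
  out <- merge_frame_overlaps(out)
  out[order(-out$score), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(query_id = character(), contig = character(), strand = character(),
             frame = integer(), g_start = integer(), g_end = integer(),
             q_start = integer(), q_end = integer(), score = numeric(),
             aligned_query = character(), aligned_target = character(),
             stringsAsFactors = FALSE)
}

# keep the higher-scoring of two genomically overlapping hits in one frame
merge_frame_overlaps <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  keep <- rep(TRUE, nrow(hits))
  ord <- order(-hits$score)
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq_along(ord)) {
      k <- ord[b]
      if (k == i || !keep[k]) next
      if (hits$contig[k] == hits$contig[i] && hits$strand[k] == hits$strand[i] &&
          hits$frame[k] == hits$frame[i] &&
          hits$g_start[k] < hits$g_end[i] && hits$g_end[k] > hits$g_start[i] &&
          hits$score[k] <= hits$score[i]) {
        keep[k] <- FALSE
      }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Recompute a hit's score from its aligned strings
#'
#' Rescores the gapped alignment columns with the same matrix and gap
#' convention as the search; every emitted hit must reproduce its `score`.
#'
#' @param aligned_query,aligned_target Gapped aligned strings.
#' @param params [search_params()].
#' @return Numeric score.
#' @export
rescore_alignment <- function(aligned_query, aligned_target,
                              params = search_params()) {
  mat <- score_matrix(params$matrix)
  qa <- strsplit(aligned_query, "")[[1L]]
  ta <- strsplit(aligned_target, "")[[1L]]
  stopifnot(length(qa) == length(ta))
  sc <- 0
  side <- ""   # a switch between query-side and target-side gaps reopens
  for (k in seq_along(qa)) {
    if (qa[k] == "-" || ta[k] == "-") {
      this <- if (qa[k] == "-") "q" else "t"
      sc <- sc + params$gap_extend + if (side == this) 0 else params$gap_open
      side <- this
    } else {
      sc <- sc + mat[ta[k], qa[k]]
      side <- ""
    }
  }
  sc
}

#' Write hits as a tab-separated table (1-based inclusive coordinates)
#'
#' @param hits Hit data frame from [translated_search()].
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- hits[, c("query_id", "contig", "strand", "frame",
                  "g_start", "g_end", "q_start", "q_end", "score")]
  out$g_start <- out$g_start + 1L
  out$q_start <- out$q_start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
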