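# FASTA / GFF3 / newick input-output and elementary sequence operations.
#
# Coordinate convention: everything inside the package is 0-based,
# half-open, on the forward strand; conversion to the 1-based inclusive
# GFF3 convention happens only in read_gff3()/write_gff3() and in the
# tabular reports.  Minus-strand features are stored with forward-strand
# coordinates plus a strand flag.

.pkg <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.pkg$gc)) .pkg$gc <- Biostrings::GENETIC_CODE
  .pkg$gc
}

.validate_dna <- function(dna, what = "sequence") {
  bad <- gsub("[ACGTN]", "", dna)
  if (any(nzchar(bad))) {
    stop(sprintf("invalid character(s) '%s' in %s (alphabet is A,C,G,T,N)",
                 paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]), collapse = ""),
                 what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a FASTA file
#'
#' Returns a named character vector, one element per record, sequences
#' uppercased with all whitespace stripped.  Works for both nucleotide and
#' protein FASTA; no alphabet check is applied here because conceptual
#' translations of pseudogenes legitimately contain `*`.
#'
#' @param path Path to a FASTA file (plain text, wrapped or single-line).
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("malformed FASTA (does not start with '>'): ", path, call. = FALSE)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  if (any(!nzchar(ids))) stop("FASTA record with empty identifier in ", path, call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
  seqs <- toupper(gsub("\\s", "", seqs))
  if (length(seqs) != length(ids) || any(!nzchar(seqs)))
    stop("FASTA record with empty sequence in ", path, call. = FALSE)
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Translate DNA in a fixed frame
#'
#' Standard genetic code (table 1); the trailing partial codon is dropped;
#' stop codons are rendered `*`; any codon containing `N` becomes `X`.
#'
#' @param dna DNA string over A,C,G,T,N.
#' @param offset Frame offset, 0, 1 or 2.
#' @return Amino-acid string.
#' @export
translate_dna <- function(dna, offset = 0L) {
  stopifnot(length(dna) == 1L, offset %in% 0:2)
  dna <- toupper(dna)
  .validate_dna(dna)
  n <- nchar(dna)
  if (n - offset < 3L) return("")
  starts <- seq.int(offset + 1L, n - 2L, by = 3L)
  codons <- substring(dna, starts, starts + 2L)
  gc <- .genetic_code()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"          # codons containing N
  paste(aa, collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param dna DNA string over A,C,G,T,N.
#' @return The reverse complement; an involution, with N mapping to N.
#' @export
reverse_complement <- function(dna) {
  stopifnot(length(dna) == 1L)
  dna <- toupper(dna)
  .validate_dna(dna)
  comp <- chartr("ACGTN", "TGCAN", dna)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# ---- GFF3 ------------------------------------------------------------------

#' Read a GFF3 file into a 9-column data frame
#'
#' Coordinates are kept 1-based inclusive exactly as in the file; the raw
#' column-9 attribute string is preserved so that a write/read round trip
#' is lossless.  Use [gff_attr()] to pull individual attribute values.
#'
#' @param path Path to a GFF3 file.
#' @return `data.frame` with columns `seqid`, `source`, `type`, `start`,
#'   `end`, `score`, `strand`, `phase`, `attributes`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !grepl("^#", lines)
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nbad <- lengths(parts) != 9L
  if (any(nbad))
    stop("GFF3 line ", lineno[which(nbad)[1L]], " does not have 9 tab-separated columns",
         call. = FALSE)
  m <- do.call(rbind, parts)
  df <- data.frame(
    seqid = m[, 1L], source = m[, 2L], type = m[, 3L],
    start = as.integer(m[, 4L]), end = as.integer(m[, 5L]),
    score = m[, 6L], strand = m[, 7L], phase = m[, 8L],
    attributes = m[, 9L], stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start > df$end)
  if (length(bad))
    stop("GFF3 line ", lineno[bad[1L]], ": start > end (or non-numeric coordinate)",
         call. = FALSE)
  df
}

#' Write a 9-column feature data frame as GFF3
#'
#' @param features Data frame as produced by [read_gff3()].
#' @param path Output path.
#' @export
write_gff3 <- function(features, path) {
  need <- c("seqid", "source", "type", "start", "end", "score", "strand",
            "phase", "attributes")
  stopifnot(all(need %in% names(features)))
  if (any(features$start > features$end)) stop("feature with start > end", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features))
    writeLines(do.call(paste, c(features[need], sep = "\t")), con)
  invisible(path)
}

#' Extract one attribute value from GFF3 column-9 strings
#'
#' @param attributes Character vector of `key=value;...` strings.
#' @param key Attribute key.
#' @return Character vector of values (`NA` where the key is absent).
#' @export
gff_attr <- function(attributes, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attributes, regexpr(pat, attributes, perl = TRUE))
  out <- rep(NA_character_, length(attributes))
  hit <- grepl(pat, attributes, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

# 0-based half-open <-> 1-based inclusive (the only conversion point)
gff_to_internal <- function(start, end) cbind(start - 1L, end)
internal_to_gff <- function(start0, end0) cbind(start0 + 1L, end0)

# ---- newick ----------------------------------------------------------------

#' Read a newick tree
#'
#' @param text Newick string (with the trailing semicolon), or `NULL`.
#' @param path Path to a newick file, used when `text` is `NULL`.
#' @return An `ape::phylo` tree.  Fails on unbalanced parentheses and on
#'   duplicate leaf labels; polytomies are accepted (flag them with
#'   [is_binary_tree()]).
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(path))
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  no <- gsub("[^()]", "", text)
  if (nchar(gsub("\\(", "", no)) != nchar(gsub("\\)", "", no)))
    stop("malformed newick: unbalanced parentheses", call. = FALSE)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed newick string", call. = FALSE)
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  tr
}

#' Write a tree as newick
#'
#' Internal node labels (e.g. bootstrap supports) are emitted when present.
#'
#' @param tree `ape::phylo` object.
#' @param path Optional output path; when `NULL` the string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' Is a tree strictly binary?
#'
#' @param tree Rooted `ape::phylo`.
#' @return `TRUE` iff every internal node has exactly two children.
#' @export
is_binary_tree <- function(tree) {
  tab <- tabulate(tree$edge[, 1L])
  kids <- tab[tab > 0L]
  all(kids == 2L)
}
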