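# File formats touched by the pipeline: FASTA/FASTQ in (gzip-transparent),
# unitig FASTA, GFA1 and a mapping TSV out. All output coordinates are
# 0-based, half-open.

.dedup_ids <- function(ids) {
  occ <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  dup <- occ > 1L
  ids[dup] <- paste0(ids[dup], "/", occ[dup])
  ids
}

.read_fastq <- function(path) {
  lines <- readLines(path) # file() decompresses gzip transparently
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    .stopf("malformed FASTQ '%s': truncated record starting at line %d",
           path, (n %/% 4L) * 4L + 1L)
  }
  hdr <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) .stopf("malformed FASTQ '%s': line %d does not start with '@'",
                          path, (bad[1L] - 1L) * 4L + 1L)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) .stopf("malformed FASTQ '%s': line %d does not start with '+'",
                          path, (bad[1L] - 1L) * 4L + 3L)
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad)) {
    .stopf("malformed FASTQ '%s': quality length differs from sequence length at line %d",
           path, (bad[1L] - 1L) * 4L + 4L)
  }
  ids <- sub("^@", "", hdr)
  ids <- sub("\\s.*$", "", ids)
  data.frame(id = ids, seq = toupper(seqs), qual = qual, stringsAsFactors = FALSE)
}

.read_fasta <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(xs))
  data.frame(id = ids, seq = toupper(as.character(xs)), qual = NA_character_,
             stringsAsFactors = FALSE)
}

#' Read sequences from FASTA or FASTQ
#'
#' Format is auto-detected from the first character (`>` vs `@`) unless given
#' explicitly; gzip compression is handled transparently. Sequences are
#' uppercased; duplicate ids are suffixed `/2`, `/3`, ... in encounter order.
#' An empty file yields an empty (zero-row) result, not an error.
#'
#' @param path path to a (possibly gzipped) FASTA or FASTQ file.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return data frame with columns `id`, `seq`, `qual` (`NA` for FASTA), in
#'   file order.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("no such file: '%s'", path)
  empty <- data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    if (length(first) == 0L || !nzchar(first)) return(empty)
    format <- if (startsWith(first, ">")) "fasta"
              else if (startsWith(first, "@")) "fastq"
              else .stopf("cannot auto-detect format of '%s': first line starts with '%s'",
                          path, substr(first, 1L, 1L))
  }
  out <- if (format == "fasta") {
    if (length(readLines(path, n = 1L)) == 0L) empty else .read_fasta(path)
  } else {
    .read_fastq(path)
  }
  if (nrow(out)) {
    if (any(!nzchar(out$seq))) {
      .stopf("empty sequence for record '%s' in '%s'",
             out$id[which(!nzchar(out$seq))[1L]], path)
    }
    out$id <- .dedup_ids(out$id)
  }
  out
}

#' Write reads as FASTQ
#'
#' Records with missing qualities get a constant `I` quality string.
#'
#' @param reads data frame with `id`, `seq` and optionally `qual` columns.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else rep(NA_character_, nrow(reads))
  miss <- is.na(qual)
  qual[miss] <- vapply(nchar(reads$seq[miss]), function(n) strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual)), path)
}

#' Write the unitigs of a graph as FASTA
#'
#' One record per unitig, in ascending id order (the graph's native order),
#' so the output is deterministic.
#'
#' @param graph a `cdbg`.
#' @param path output path.
#' @export
write_unitigs_fasta <- function(graph, path) {
  stopifnot(inherits(graph, "cdbg"))
  U <- graph$unitigs
  if (nrow(U) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(as.vector(rbind(paste0(">", U$id), U$seq)), path)
  invisible(path)
}

#' Write a graph as GFA1
#'
#' Emits one `S` line per unitig and one `L` line per directed adjacency
#' (ordered unitig pair glued on a shared (k-1)-mer), with overlap CIGAR
#' `(k-1)M`. The header carries the graph order in a `kk:i:` tag so the graph
#' can be reloaded without guessing k.
#'
#' @param graph a `cdbg`.
#' @param path output path.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "cdbg"))
  U <- graph$unitigs
  adj <- .adjacency_pairs(graph)
  lines <- c(
    sprintf("H\tVN:Z:1.0\tkk:i:%d", graph$k),
    if (nrow(U)) sprintf("S\t%s\t%s", U$id, U$seq),
    if (nrow(adj)) sprintf("L\t%s\t+\t%s\t+\t%dM",
                           U$id[adj$from], U$id[adj$to], graph$k - 1L)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Reload a graph written by the `build` subcommand
#'
#' Expects `<prefix>.unitigs.fa` and `<prefix>.gfa` (for k) side by side.
#'
#' @param prefix output prefix used at build time.
#' @return a `cdbg`.
#' @export
load_graph <- function(prefix) {
  fa <- paste0(prefix, ".unitigs.fa")
  gfa <- paste0(prefix, ".gfa")
  if (!file.exists(fa)) .stopf("no such file: '%s'", fa)
  if (!file.exists(gfa)) .stopf("no such file: '%s'", gfa)
  hdr <- readLines(gfa, n = 1L)
  m <- regmatches(hdr, regexpr("kk:i:[0-9]+", hdr))
  if (!length(m)) .stopf("GFA '%s' has no kk:i: tag in its header", gfa)
  k <- as.integer(sub("kk:i:", "", m))
  recs <- read_sequences(fa, format = "fasta")
  graph_from_unitigs(recs$seq, k, ids = recs$id)
}

#' Write mapping results as TSV
#'
#' Tab-separated, one row per read, columns `read_id`, `status`, `orientation`
#' (`+`/`-`), `path` (comma-joined unitig ids), `start_offset` (0-based on the
#' first unitig) and `mismatches`; the last three are empty for unmapped
#' reads. The header line starts with `#`.
#'
#' @param mappings list of `graph_mapping` results (e.g. `ggmap(...)$mappings`).
#' @param path output path.
#' @export
write_mappings <- function(mappings, path) {
  fmt <- vapply(mappings, function(m) {
    mapped <- startsWith(m$status, "MAPPED")
    paste(m$read_id, m$status,
          if (identical(m$orientation, "reverse")) "-" else "+",
          if (mapped) paste(m$walk, collapse = ",") else "",
          if (mapped) m$start_offset else "",
          if (mapped) m$mismatches else "",
          sep = "\t")
  }, character(1))
  writeLines(c("#read_id\tstatus\torientation\tpath\tstart_offset\tmismatches",
               fmt), path)
  invisible(path)
}

#' Read a mapping TSV back
#'
#' @param path a file written by [write_mappings()].
#' @return data frame with columns `read_id`, `status`, `orientation`,
#'   `walk` (list column of id vectors), `start_offset`, `mismatches`.
#' @export
read_mappings <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parts <- lapply(parts, function(p) c(p, rep("", 6L - length(p))))
  m <- do.call(rbind, parts)
  if (is.null(m)) m <- matrix(character(0), ncol = 6L)
  data.frame(
    read_id = m[, 1L],
    status = m[, 2L],
    orientation = ifelse(m[, 3L] == "-", "reverse", "forward"),
    walk = I(lapply(m[, 4L], function(x) if (nzchar(x)) strsplit(x, ",", fixed = TRUE)[[1L]] else character(0))),
    start_offset = suppressWarnings(as.integer(m[, 5L])),
    mismatches = suppressWarnings(as.integer(m[, 6L])),
    stringsAsFactors = FALSE
  )
}
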