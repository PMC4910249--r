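# k-mer counting, abundance filtering, and compaction of the de Bruijn graph
# into unitigs.
#
# The de Bruijn graph of order k has the solid k-mers as nodes and an arc
# d -> d' whenever the (k-1)-suffix of d equals the (k-1)-prefix of d'. The
# compacted graph (CDBG) merges every maximal non-branching path into a single
# node whose spelled sequence is a unitig. Unitig ids are "u1", "u2", ...
# assigned by ascending unitig sequence (C locale) so outputs are reproducible.

#' Count k-mers of a sequence collection
#'
#' Every length-k window over \{A,C,G,T\} of every sequence is counted;
#' windows containing any other character (e.g. `N`) are skipped. With
#' `strand_mode = "with_reverse_complements"` each sequence additionally
#' contributes the k-mers of its reverse complement, which is the right
#' default for strand-agnostic sequencing data; `"forward_only"` keeps toy
#' examples deterministic.
#'
#' @param sequences character vector of sequences, or a data frame with a
#'   `seq` column as returned by [read_sequences()].
#' @param k integer word size, at least 2.
#' @param strand_mode `"with_reverse_complements"` (default) or
#'   `"forward_only"`.
#' @return an object of class `kmer_table`: a list with elements `k` and
#'   `counts` (named integer vector).
#' @export
#' @examples
#' count_kmers(c("TAAGC", "CAAGC"), k = 3, strand_mode = "forward_only")
count_kmers <- function(sequences, k,
                        strand_mode = c("with_reverse_complements", "forward_only")) {
  strand_mode <- match.arg(strand_mode)
  if (is.data.frame(sequences)) sequences <- sequences$seq
  k <- as.integer(k)
  if (is.na(k) || k < 2L) .stopf("k must be an integer >= 2 (got %s)", k)
  if (length(sequences) == 0L) .stopf("no input sequences")
  sequences <- toupper(sequences)
  if (strand_mode == "with_reverse_complements") {
    sequences <- c(sequences, rc_seq(sequences))
  }
  words <- unlist(lapply(sequences, .windows, k = k), use.names = FALSE)
  if (length(words) == 0L) {
    counts <- integer(0)
  } else {
    tab <- table(words)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
  }
  structure(list(k = k, counts = counts), class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: %d distinct %d-mers, total count %d\n",
              length(x$counts), x$k, sum(x$counts)))
  invisible(x)
}

#' Solid k-mers at abundance threshold c
#'
#' Keeps exactly the k-mers whose count is at least `c`. Filtering low-count
#' k-mers before graph construction is the classical way of removing
#' sequencing errors from the graph.
#'
#' @param table a `kmer_table` from [count_kmers()].
#' @param c integer abundance threshold, at least 1.
#' @return sorted character vector of solid k-mers.
#' @export
solid_kmers <- function(table, c = 2L) {
  stopifnot(inherits(table, "kmer_table"))
  c <- as.integer(c)
  if (is.na(c) || c < 1L) .stopf("abundance threshold c must be >= 1")
  .csort(names(table$counts)[table$counts >= c])
}

# Internal: vectorised compaction of a k-mer set into maximal unitigs.
# Returns the character vector of unitig sequences (unsorted).
.compact_kmers <- function(kmers, k) {
  n <- length(kmers)
  if (n == 0L) return(character(0))
  pref <- substr(kmers, 1L, k - 1L)
  suf <- substr(kmers, 2L, k)
  vals <- unique(c(pref, suf))
  pi <- match(pref, vals)
  si <- match(suf, vals)
  nv <- length(vals)
  pref_count <- tabulate(pi, nbins = nv) # how many nodes start with each (k-1)-mer
  suf_count <- tabulate(si, nbins = nv) # how many nodes end with each (k-1)-mer

  # owner[v] = the unique node whose prefix is vals[v], if unique
  owner <- rep(NA_integer_, nv)
  uniq <- which(pref_count[pi] == 1L)
  owner[pi[uniq]] <- uniq

  # link i -> j iff the arc is the only one out of i and the only one into j;
  # such arcs (and only such arcs) are merged during compaction.
  link <- owner[si]
  link[!is.na(link) & suf_count[pi[link]] != 1L] <- NA_integer_
  link[!is.na(link) & link == seq_len(n)] <- NA_integer_ # self-loop: never merged

  has_in <- logical(n)
  has_in[link[!is.na(link)]] <- TRUE

  visited <- logical(n)
  chains <- vector("list", n)
  nc <- 0L

  follow <- function(start) {
    buf <- integer(32L)
    len <- 0L
    cur <- start
    repeat {
      len <- len + 1L
      if (len > length(buf)) buf <- c(buf, integer(length(buf)))
      buf[len] <- cur
      visited[cur] <<- TRUE
      nxt <- link[cur]
      if (is.na(nxt) || visited[nxt]) break
      cur <- nxt
    }
    buf[seq_len(len)]
  }

  for (s in which(!has_in)) {
    nc <- nc + 1L
    chains[[nc]] <- follow(s)
  }

  # Leftover nodes sit on isolated simple cycles (every node linked in and
  # out). Each cycle is broken at its lexicographically smallest k-mer and
  # emitted as one linear unitig.
  for (s in which(!visited)) {
    if (visited[s]) next
    cyc <- follow(s) # stops when it would revisit s
    best <- which(kmers[cyc] == min(kmers[cyc]))[1L]
    if (best > 1L) cyc <- c(cyc[best:length(cyc)], cyc[seq_len(best - 1L)])
    nc <- nc + 1L
    chains[[nc]] <- cyc
  }

  vapply(chains[seq_len(nc)], function(ch) {
    if (length(ch) == 1L) return(kmers[ch])
    paste0(kmers[ch[1L]], paste(substr(kmers[ch[-1L]], k, k), collapse = ""))
  }, character(1))
}

#' Build the compacted de Bruijn graph of a k-mer set
#'
#' Nodes of the underlying graph are the given k-mers; there is an arc
#' `d -> d'` whenever the (k-1)-suffix of `d` equals the (k-1)-prefix of `d'`.
#' Arcs that are the unique out-arc of their source and the unique in-arc of
#' their target are merged, yielding maximal unitigs. Each solid k-mer occurs
#' exactly once across the unitig set. Isolated simple cycles are broken at
#' their lexicographically smallest k-mer.
#'
#' @param kmers character vector of distinct k-mers (all the same length `k`).
#' @param k integer word size.
#' @param strand_mode recorded on the graph object; has no effect on
#'   construction (the k-mer set already encodes the strand convention).
#' @return an object of class `cdbg`; see Details.
#' @details A `cdbg` is a list with elements `k`, `strand_mode`, and
#'   `unitigs`, a data frame with columns `id`, `seq`, `len`, `prefix_ov`
#'   and `suffix_ov` (the boundary (k-1)-mers), ordered by id rank.
#' @export
#' @examples
#' g <- build_cdbg(c("TAA", "AAG", "AGC", "CAA"), k = 3)
#' g$unitigs$seq # "AAGC" "CAA" "TAA"
build_cdbg <- function(kmers, k, strand_mode = "forward_only") {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) .stopf("k must be an integer >= 2")
  kmers <- unique(as.character(kmers))
  if (length(kmers) > 0L && any(nchar(kmers) != k)) {
    .stopf("all k-mers must have length k = %d", k)
  }
  seqs <- .csort(.compact_kmers(kmers, k))
  graph_from_unitigs(seqs, k, strand_mode = strand_mode, sorted = TRUE)
}

#' Assemble a `cdbg` object from known unitig sequences
#'
#' Used to reload a graph written by [write_unitigs_fasta()] without
#' recompacting, and as the shared constructor behind [build_cdbg()].
#'
#' @param seqs character vector of unitig sequences (each of length >= k).
#' @param k integer order of the graph.
#' @param ids optional ids; defaults to `"u1"..."uN"` over the
#'   sequence-sorted order.
#' @param strand_mode recorded on the object.
#' @param sorted set to `TRUE` when `seqs` is already sequence-sorted.
#' @return a `cdbg` object.
#' @export
graph_from_unitigs <- function(seqs, k, ids = NULL, strand_mode = "forward_only",
                               sorted = FALSE) {
  k <- as.integer(k)
  seqs <- as.character(seqs)
  if (length(seqs) > 0L && any(nchar(seqs) < k)) {
    .stopf("every unitig must be at least k = %d characters long", k)
  }
  if (!sorted && is.null(ids)) seqs <- .csort(seqs)
  n <- length(seqs)
  if (is.null(ids)) ids <- if (n) paste0("u", seq_len(n)) else character(0)
  lens <- nchar(seqs)
  unitigs <- data.frame(
    id = ids,
    seq = seqs,
    len = lens,
    prefix_ov = substr(seqs, 1L, k - 1L),
    suffix_ov = substr(seqs, lens - k + 2L, lens),
    stringsAsFactors = FALSE
  )
  cache <- new.env(parent = emptyenv())
  cache$id2rank <- new.env(parent = emptyenv())
  if (n > 0L) {
    ranks <- as.list(seq_len(n))
    names(ranks) <- ids
    list2env(ranks, envir = cache$id2rank)
  }
  structure(list(k = k, strand_mode = strand_mode, unitigs = unitigs,
                 cache = cache),
            class = "cdbg")
}

#' @export
print.cdbg <- function(x, ...) {
  cat(sprintf("cdbg: k = %d, %d unitigs, total length %d (%s)\n",
              x$k, nrow(x$unitigs), sum(x$unitigs$len), x$strand_mode))
  invisible(x)
}

# id -> row rank lookup (ids are not assumed to be "u<rank>")
.ranks_of <- function(graph, ids) {
  if (length(ids) == 0L) return(integer(0))
  r <- unlist(mget(ids, envir = graph$cache$id2rank, ifnotfound = NA_integer_),
              use.names = FALSE)
  if (anyNA(r)) .stopf("unknown unitig id(s): %s",
                       paste(ids[is.na(r)], collapse = ", "))
  r
}

#' Spell the sequence generated by a walk of unitigs
#'
#' Consecutive unitigs must be adjacent, i.e. glued on a shared (k-1)-mer.
#' The result is the first unitig from `entry_offset` (0-based) onward,
#' followed by everything after the shared (k-1)-mer of each subsequent
#' unitig. For a walk of `l` single-k-mer nodes starting at offset 0 the
#' spelled sequence has length `k + l - 1`.
#'
#' @param graph a `cdbg`.
#' @param walk character vector of unitig ids, in walk order.
#' @param entry_offset 0-based offset into the first unitig.
#' @return the spelled DNA string.
#' @export
spell_walk <- function(graph, walk, entry_offset = 0L) {
  stopifnot(inherits(graph, "cdbg"))
  if (length(walk) == 0L) .stopf("empty walk")
  r <- .ranks_of(graph, walk)
  U <- graph$unitigs
  entry_offset <- as.integer(entry_offset)
  if (entry_offset < 0L || entry_offset >= U$len[r[1L]]) {
    .stopf("entry_offset %d out of range for unitig %s", entry_offset, walk[1L])
  }
  if (length(r) > 1L) {
    a <- r[-length(r)]
    b <- r[-1L]
    bad <- which(U$suffix_ov[a] != U$prefix_ov[b])
    if (length(bad)) {
      .stopf("walk step %d: %s and %s are not adjacent", bad[1L],
             walk[bad[1L]], walk[bad[1L] + 1L])
    }
  }
  first <- substr(U$seq[r[1L]], entry_offset + 1L, U$len[r[1L]])
  if (length(r) == 1L) return(first)
  rest <- substr(U$seq[r[-1L]], graph$k, U$len[r[-1L]])
  paste0(first, paste(rest, collapse = ""))
}

#' Unitig adjacency
#'
#' Out-neighbours of a unitig are the unitigs whose (k-1)-prefix equals its
#' (k-1)-suffix; in-neighbours are symmetric. Results are in ascending id
#' (rank) order.
#'
#' @param graph a `cdbg`.
#' @param unitig_id a single unitig id.
#' @param direction `"out"` or `"in"`.
#' @return character vector of unitig ids (possibly empty).
#' @export
neighbors <- function(graph, unitig_id, direction = c("out", "in")) {
  stopifnot(inherits(graph, "cdbg"))
  direction <- match.arg(direction)
  r <- .ranks_of(graph, unitig_id)
  U <- graph$unitigs
  hits <- if (direction == "out") {
    which(U$prefix_ov == U$suffix_ov[r])
  } else {
    which(U$suffix_ov == U$prefix_ov[r])
  }
  U$id[hits]
}

# All directed adjacencies (a_rank, b_rank) of the graph, ordered by a then b.
.adjacency_pairs <- function(graph) {
  U <- graph$unitigs
  n <- nrow(U)
  if (n == 0L) return(data.frame(from = integer(0), to = integer(0)))
  starters <- split(seq_len(n), U$prefix_ov)
  to <- starters[U$suffix_ov]
  lens <- lengths(to)
  # suffixes with no matching prefix produce NULL entries
  lens[vapply(to, is.null, logical(1))] <- 0L
  from <- rep.int(seq_len(n), lens)
  data.frame(from = from, to = unlist(to, use.names = FALSE))
}
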