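# Mapping reads on branching paths of the CDBG (seed-and-extend over unitig
# boundaries under a cumulative Hamming budget), the exhaustive reference
# mode, the unitig-containment stage, and the composed pipeline.
#
# Conventions shared by every routine here:
#   * reads are uppercase character scalars; positions are 0-based;
#   * a mapping result ("graph_mapping") is a list with read_id, status,
#     orientation, walk (unitig ids), start_offset (0-based offset of the
#     read start inside the first walk unitig), mismatches, and
#     max_step_candidates (instrumentation: the largest number of candidate
#     unitigs aligned at any single greedy extension step);
#   * ties are broken by smallest unitig id rank, then forward orientation,
#     so results are deterministic and independent of input order.

MAPPING_STATUSES <- c("MAPPED_PATH", "MAPPED_UNITIG", "UNMAPPED_TOO_SHORT",
                      "UNMAPPED_UNANCHORED", "UNMAPPED_OVER_BUDGET")

#' Mapping parameters
#'
#' @param max_mismatches cumulative Hamming budget `t` (inclusive bound);
#'   default 2, the value used throughout the reference experiments.
#' @param anchor_failures number `n` of unusable extremal anchors tolerated
#'   per direction before a read is declared unanchorable; default 2.
#' @param exhaustive if `TRUE`, [ggmap()] uses the exhaustive mapper.
#' @param try_reverse_complement also map the reverse complement of each read
#'   and keep the lower-mismatch result (tie: forward). Default `TRUE`.
#' @return a `mapping_params` object.
#' @export
mapping_params <- function(max_mismatches = 2L, anchor_failures = 2L,
                           exhaustive = FALSE, try_reverse_complement = TRUE) {
  max_mismatches <- as.integer(max_mismatches)
  anchor_failures <- as.integer(anchor_failures)
  if (is.na(max_mismatches) || max_mismatches < 0L) .stopf("max_mismatches must be >= 0")
  if (is.na(anchor_failures) || anchor_failures < 0L) .stopf("anchor_failures must be >= 0")
  structure(list(max_mismatches = max_mismatches,
                 anchor_failures = anchor_failures,
                 exhaustive = isTRUE(exhaustive),
                 try_reverse_complement = isTRUE(try_reverse_complement)),
            class = "mapping_params")
}

#' Hamming distance between two equal-length sequences
#'
#' Counts the positions where the characters differ; `N` against anything
#' (including `N`) counts as a mismatch.
#'
#' @param a,b equal-length DNA strings.
#' @return integer mismatch count.
#' @export
hamming_cost <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L || length(b) != 1L) {
    .stopf("hamming_cost expects two character scalars")
  }
  if (nchar(a) != nchar(b)) {
    .stopf("hamming_cost: length mismatch (%d vs %d)", nchar(a), nchar(b))
  }
  as.integer(.hm(a, b))
}

#' Locate index anchors in a read
#'
#' Every read position whose (k-1)-mer is a key of the overlap index yields an
#' anchor. Words containing `N` are never keys and therefore never anchor.
#'
#' @param read a DNA string.
#' @param index an `overlap_index`.
#' @return an `anchor_set`: list with parallel elements `pos` (0-based
#'   positions, ascending), `word` and `hit` (the index entries).
#' @export
find_anchors <- function(read, index) {
  stopifnot(inherits(index, "overlap_index"))
  w <- index$k - 1L
  L <- nchar(read)
  empty <- structure(list(pos = integer(0), word = character(0), hit = list()),
                     class = "anchor_set")
  if (L < w) return(empty)
  words <- substring(read, seq_len(L - w + 1L), w:L)
  hits <- mget(words, envir = index$env, ifnotfound = list(NULL))
  keep <- !vapply(hits, is.null, logical(1))
  if (!any(keep)) return(empty)
  structure(list(pos = unname(which(keep)) - 1L, word = words[keep],
                 hit = unname(hits[keep])),
            class = "anchor_set")
}

# Mismatches contributed by aligning candidate unitig r from overlap position
# i (0-based) onward, counting only read positions beyond the overlap itself
# and truncating at the read end.
.step_mm <- function(read, L, k, i, useq, ulen) {
  a <- substr(read, i + k, min(i + ulen, L))
  b <- substr(useq, k, k - 1L + nchar(a))
  as.integer(.hm(a, b))
}

#' Anchor one read extremity on a unitig
#'
#' For the left side, anchors are tried in ascending position order; an anchor
#' at position `p` with word `w` proposes the unitigs ending with `w`
#' (`enders`); a candidate succeeds if it is long enough to cover the whole
#' left flank `read[0, p+k-1)` and the flank aligns against its suffix within
#' the mismatch budget. The minimum-mismatch candidate wins (tie: smallest
#' id). An anchor whose candidates all fail counts one failure; once
#' `anchor_failures` failures accumulate the extremity is declared
#' unanchorable. The right side is symmetric (descending anchors, `starters`,
#' prefix of the candidate against the right flank).
#'
#' @param read DNA string.
#' @param anchors an `anchor_set` from [find_anchors()].
#' @param graph a `cdbg`.
#' @param params a `mapping_params`.
#' @param side `"left"` or `"right"`.
#' @return `NULL` on failure, else list with `pos` (anchor position),
#'   `unitig` (id), `rank`, and `mismatches`.
#' @export
anchor_extremity <- function(read, anchors, graph, params = mapping_params(),
                             side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(graph, "cdbg"), inherits(anchors, "anchor_set"))
  U <- graph$unitigs
  k <- graph$k
  L <- nchar(read)
  t <- params$max_mismatches
  nmax <- params$anchor_failures
  ord <- if (side == "left") seq_along(anchors$pos) else rev(seq_along(anchors$pos))
  failures <- 0L
  for (a in ord) {
    p <- anchors$pos[a]
    hit <- anchors$hit[[a]]
    cand <- if (side == "left") hit$enders else hit$starters
    flank <- if (side == "left") p + k - 1L else L - p
    best_rank <- NA_integer_
    best_mm <- NA_integer_
    if (length(cand)) {
      cr <- .ranks_of(graph, cand) # ascending
      for (r in cr) {
        if (U$len[r] < flank) next
        mm <- if (side == "left") {
          as.integer(.hm(substr(read, 1L, flank),
                         substr(U$seq[r], U$len[r] - flank + 1L, U$len[r])))
        } else {
          as.integer(.hm(substr(read, p + 1L, L), substr(U$seq[r], 1L, flank)))
        }
        if (mm <= t && (is.na(best_mm) || mm < best_mm)) {
          best_mm <- mm
          best_rank <- r
        }
      }
    }
    if (!is.na(best_rank)) {
      return(list(pos = p, unitig = U$id[best_rank], rank = best_rank,
                  mismatches = best_mm))
    }
    failures <- failures + 1L
    if (failures >= nmax) return(NULL)
  }
  NULL
}

.mk_mapping <- function(status, walk = character(0), start_offset = NA_integer_,
                        mismatches = NA_integer_, max_step_candidates = 0L) {
  list(read_id = NA_character_, status = status, orientation = "forward",
       walk = walk, start_offset = start_offset, mismatches = mismatches,
       max_step_candidates = max_step_candidates)
}

# Shared anchoring for the greedy and exhaustive mappers. Returns either an
# unmapped result (element $fail) or the initial extension state.
#
# When the chosen left anchor sits at read position 0, the read covers no base
# of any predecessor unitig beyond the shared (k-1)-mer, so no extremity
# unitig is prepended: the walk starts with the first unitig accepted by the
# extension itself (which then compares its full prefix against the read,
# exactly the right-extremity rule).
.anchor_read <- function(read, graph, index, params) {
  k <- graph$k
  L <- nchar(read)
  if (L < k) return(list(fail = .mk_mapping("UNMAPPED_TOO_SHORT")))
  anc <- find_anchors(read, index)
  if (length(anc$pos) == 0L) return(list(fail = .mk_mapping("UNMAPPED_UNANCHORED")))
  left <- anchor_extremity(read, anc, graph, params, "left")
  if (is.null(left)) return(list(fail = .mk_mapping("UNMAPPED_UNANCHORED")))
  right <- anchor_extremity(read, anc, graph, params, "right")
  if (is.null(right)) return(list(fail = .mk_mapping("UNMAPPED_UNANCHORED")))
  if (left$pos > 0L) {
    list(anc = anc, p = left$pos, walk0 = left$rank, cum0 = left$mismatches,
         i0 = left$pos)
  } else {
    list(anc = anc, p = 0L, walk0 = integer(0), cum0 = 0L, i0 = 0L)
  }
}

# Overlap word at the current extension state.
.state_word <- function(read, graph, walk, k) {
  if (length(walk)) graph$unitigs$suffix_ov[walk[length(walk)]]
  else substr(read, 1L, k - 1L)
}

.finish_mapping <- function(graph, walk, p, k, cum, maxc) {
  U <- graph$unitigs
  off <- if (p > 0L) U$len[walk[1L]] - (p + k - 1L) else 0L
  .mk_mapping("MAPPED_PATH", walk = U$id[walk], start_offset = off,
              mismatches = cum, max_step_candidates = maxc)
}

.greedy_core <- function(read, graph, index, params) {
  st <- .anchor_read(read, graph, index, params)
  if (!is.null(st$fail)) return(st$fail)
  U <- graph$unitigs
  k <- graph$k
  L <- nchar(read)
  t <- params$max_mismatches
  anc <- st$anc
  first_pos <- anc$pos[1L]
  last_pos <- anc$pos[length(anc$pos)]
  walk <- st$walk0
  cum <- st$cum0
  i <- st$i0
  maxc <- 0L
  steps <- 0L
  while (i + k - 1L < L) {
    w <- .state_word(read, graph, walk, k)
    entry <- get0(w, envir = index$env, ifnotfound = NULL)
    cand <- if (is.null(entry)) character(0) else entry$starters
    if (!length(cand)) {
      return(.mk_mapping("UNMAPPED_OVER_BUDGET", max_step_candidates = maxc))
    }
    cr <- .ranks_of(graph, cand)
    maxc <- max(maxc, length(cr))
    accepted <- NA_integer_
    amm <- NA_integer_
    # speed shortcut: a candidate whose own end-overlap is the anchor detected
    # right where the candidate would end is tested first and accepted early
    # if it stays within budget; disabled at the first/last overlap of the read
    if (length(cr) > 1L && i != first_pos && i != last_pos) {
      for (r in cr) {
        endpos <- i + U$len[r] - (k - 1L)
        ai <- match(endpos, anc$pos)
        if (!is.na(ai) && anc$word[ai] == U$suffix_ov[r]) {
          mm <- .step_mm(read, L, k, i, U$seq[r], U$len[r])
          if (cum + mm <= t) {
            accepted <- r
            amm <- mm
            break
          }
        }
      }
    }
    if (is.na(accepted)) {
      mms <- vapply(cr, function(r) .step_mm(read, L, k, i, U$seq[r], U$len[r]),
                    integer(1))
      ok <- which(cum + mms <= t)
      if (!length(ok)) {
        return(.mk_mapping("UNMAPPED_OVER_BUDGET", max_step_candidates = maxc))
      }
      b <- ok[which.min(mms[ok])] # first minimum = smallest rank
      accepted <- cr[b]
      amm <- mms[b]
    }
    cum <- cum + amm
    walk <- c(walk, accepted)
    i <- i + U$len[accepted] - (k - 1L)
    steps <- steps + 1L
    if (steps > L) {
      return(.mk_mapping("UNMAPPED_OVER_BUDGET", max_step_candidates = maxc))
    }
  }
  .finish_mapping(graph, walk, st$p, k, cum, maxc)
}

# TRUE if rank walk a orders strictly before b (element-wise, prefix wins).
.walk_less <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0L) {
    for (j in seq_len(n)) {
      if (a[j] != b[j]) return(a[j] < b[j])
    }
  }
  length(a) < length(b)
}

.exhaustive_core <- function(read, graph, index, params, state_cap = 1e6) {
  st <- .anchor_read(read, graph, index, params)
  if (!is.null(st$fail)) return(st$fail)
  U <- graph$unitigs
  k <- graph$k
  L <- nchar(read)
  t <- params$max_mismatches
  best <- NULL
  states <- 0L
  maxc <- 0L
  rec <- function(walk, cum, i, steps) {
    if (i + k - 1L >= L) {
      if (is.null(best) || cum < best$cum ||
          (cum == best$cum && .walk_less(walk, best$walk))) {
        best <<- list(walk = walk, cum = cum)
      }
      return(invisible(NULL))
    }
    if (steps > L) return(invisible(NULL))
    states <<- states + 1L
    if (states > state_cap) {
      .stopf("exhaustive search exceeded the %g expanded-state cap", state_cap)
    }
    w <- .state_word(read, graph, walk, k)
    entry <- get0(w, envir = index$env, ifnotfound = NULL)
    if (is.null(entry) || !length(entry$starters)) return(invisible(NULL))
    cr <- .ranks_of(graph, entry$starters)
    maxc <<- max(maxc, length(cr))
    for (r in cr) {
      mm <- .step_mm(read, L, k, i, U$seq[r], U$len[r])
      if (cum + mm <= t) {
        rec(c(walk, r), cum + mm, i + U$len[r] - (k - 1L), steps + 1L)
      }
    }
    invisible(NULL)
  }
  rec(st$walk0, st$cum0, st$i0, 0L)
  if (is.null(best)) {
    return(.mk_mapping("UNMAPPED_OVER_BUDGET", max_step_candidates = maxc))
  }
  .finish_mapping(graph, best$walk, st$p, k, best$cum, maxc)
}

.status_mapped <- function(status) startsWith(status, "MAPPED")

# Run a single-orientation core on both strands and keep the better result:
# mapped beats unmapped; two mapped results compare by mismatches with ties
# going to the forward orientation; two unmapped results keep the forward one.
.map_both <- function(read, graph, index, params, core, ...) {
  read <- toupper(read)
  fwd <- core(read, graph, index, params, ...)
  if (!params$try_reverse_complement) return(fwd)
  rev <- core(rc_seq(read), graph, index, params, ...)
  if (.status_mapped(rev$status) &&
      (!.status_mapped(fwd$status) || rev$mismatches < fwd$mismatches)) {
    rev$orientation <- "reverse"
    return(rev)
  }
  fwd
}

#' Map one read on branching paths of the graph (greedy)
#'
#' Seed-and-extend: the read must anchor on an indexed unitig boundary at both
#' extremities (tolerating up to `anchor_failures` unusable anchors per
#' direction), then the walk is grown left to right; at each boundary the at
#' most four successor unitigs are aligned against the read and the
#' minimum-mismatch one is kept, without backtracking, while the cumulative
#' mismatch count stays within `max_mismatches`.
#'
#' @param read a DNA string.
#' @param graph a `cdbg`.
#' @param index the graph's `overlap_index`.
#' @param params a `mapping_params`.
#' @param read_id optional id recorded on the result.
#' @return a `graph_mapping` list (see package docs); `status` is one of
#'   `MAPPED_PATH`, `UNMAPPED_TOO_SHORT`, `UNMAPPED_UNANCHORED`,
#'   `UNMAPPED_OVER_BUDGET`.
#' @export
map_read_greedy <- function(read, graph, index, params = mapping_params(),
                            read_id = NA_character_) {
  m <- .map_both(read, graph, index, params, .greedy_core)
  m$read_id <- read_id
  m
}

#' Map one read exploring all anchored walks (exhaustive)
#'
#' Identical anchoring to [map_read_greedy()], then a depth-first enumeration
#' of every candidate succession, pruned only when the cumulative mismatch
#' count exceeds the budget. Returns the minimum-mismatch mapping
#' (ties: lexicographically smallest walk). Errors out, rather than silently
#' truncating, if more than `state_cap` states are expanded.
#'
#' @inheritParams map_read_greedy
#' @param state_cap maximum number of expanded search states.
#' @return a `graph_mapping` list.
#' @export
map_read_exhaustive <- function(read, graph, index, params = mapping_params(),
                                read_id = NA_character_, state_cap = 1e6) {
  m <- .map_both(read, graph, index, params, .exhaustive_core,
                 state_cap = state_cap)
  m$read_id <- read_id
  m
}

# Positions of every unitig k-mer, built once per graph and memoised on the
# graph's cache environment.
.kmer_pos_index <- function(graph) {
  cache <- graph$cache
  if (!is.null(cache$kpi)) return(cache$kpi)
  U <- graph$unitigs
  k <- graph$k
  per <- lapply(seq_len(nrow(U)), function(r) {
    n <- U$len[r] - k + 1L
    list(km = substring(U$seq[r], seq_len(n), k:U$len[r]),
         rank = rep.int(r, n), off = seq_len(n) - 1L)
  })
  km <- unlist(lapply(per, `[[`, "km"), use.names = FALSE)
  env <- new.env(parent = emptyenv())
  if (length(km)) list2env(split(seq_along(km), km), envir = env)
  kpi <- list(env = env,
              rank = unlist(lapply(per, `[[`, "rank"), use.names = FALSE),
              off = unlist(lapply(per, `[[`, "off"), use.names = FALSE))
  cache$kpi <- kpi
  kpi
}

.contain_core <- function(read, graph, params) {
  U <- graph$unitigs
  k <- graph$k
  L <- nchar(read)
  t <- params$max_mismatches
  if (L < k) return(.mk_mapping("UNMAPPED_TOO_SHORT"))
  kpi <- .kmer_pos_index(graph)
  geometric <- FALSE
  for (s in c(0L, k, 2L * k)) { # fall back if the first seed k-mer holds an error
    if (s + k > L) break
    idx <- get0(substr(read, s + 1L, s + k), envir = kpi$env, ifnotfound = NULL)
    if (is.null(idx)) next
    best <- NULL
    for (j in idx) { # j ascending => rank then offset ascending: first strict
      r <- kpi$rank[j] # improvement realises the tie-break
      us <- kpi$off[j] - s
      if (us < 0L || us + L > U$len[r]) next
      geometric <- TRUE
      mm <- as.integer(.hm(read, substr(U$seq[r], us + 1L, us + L)))
      if (mm <= t && (is.null(best) || mm < best$mm)) {
        best <- list(rank = r, off = us, mm = mm)
      }
    }
    if (!is.null(best)) {
      return(.mk_mapping("MAPPED_UNITIG", walk = U$id[best$rank],
                         start_offset = best$off, mismatches = best$mm))
    }
  }
  if (geometric) .mk_mapping("UNMAPPED_OVER_BUDGET")
  else .mk_mapping("UNMAPPED_UNANCHORED")
}

#' Map one read fully inside a unitig (containment stage)
#'
#' Seeds the read's first k-mer against an index of all unitig k-mer
#' positions, verifying full containment by Hamming comparison within the
#' budget; if the first k-mer finds nothing (e.g. it holds a sequencing
#' error), seeding is retried with the k-mers at read positions `k` and `2k`.
#'
#' @inheritParams map_read_greedy
#' @return a `graph_mapping` with status `MAPPED_UNITIG` (walk of length 1) or
#'   an `UNMAPPED_*` status.
#' @export
map_on_unitigs <- function(read, graph, params = mapping_params(),
                           read_id = NA_character_) {
  read <- toupper(read)
  fwd <- .contain_core(read, graph, params)
  m <- fwd
  if (params$try_reverse_complement) {
    rev <- .contain_core(rc_seq(read), graph, params)
    if (.status_mapped(rev$status) &&
        (!.status_mapped(fwd$status) || rev$mismatches < fwd$mismatches)) {
      rev$orientation <- "reverse"
      m <- rev
    }
  }
  m$read_id <- read_id
  m
}

# one unmapped reason from the two stages: budget overruns are the more
# informative outcome (the read anchored or placed somewhere)
.combine_unmapped <- function(s1, s2) {
  if (s1 == "UNMAPPED_TOO_SHORT" || s2 == "UNMAPPED_TOO_SHORT") return("UNMAPPED_TOO_SHORT")
  if (s1 == "UNMAPPED_OVER_BUDGET" || s2 == "UNMAPPED_OVER_BUDGET") return("UNMAPPED_OVER_BUDGET")
  "UNMAPPED_UNANCHORED"
}

#' Map a read set on the graph (full pipeline)
#'
#' Each read first goes through the branching-path mapper ([map_read_greedy()]
#' or [map_read_exhaustive()] per `params$exhaustive`). A branching-path
#' result whose walk stays inside a single unitig is reclassified as
#' `MAPPED_UNITIG` (the alignment crosses no unitig boundary). Reads not
#' mapped on a branching path are then handed to the containment stage
#' ([map_on_unitigs()]).
#'
#' @param reads a data frame with `id` and `seq` columns (from
#'   [read_sequences()] or [simulate_reads()]) or a character vector of
#'   sequences.
#' @param graph a `cdbg`.
#' @param index the graph's `overlap_index`.
#' @param params a `mapping_params`.
#' @return list with `mappings` (list of `graph_mapping`, input order) and
#'   `summary` (a `mapping_summary`).
#' @export
ggmap <- function(reads, graph, index, params = mapping_params()) {
  if (is.character(reads)) {
    ids <- if (length(reads)) paste0("r", seq_along(reads)) else character(0)
    reads <- data.frame(id = ids, seq = reads, stringsAsFactors = FALSE)
  }
  mapper <- if (params$exhaustive) map_read_exhaustive else map_read_greedy
  n <- nrow(reads)
  maps <- vector("list", n)
  for (j in seq_len(n)) {
    m <- mapper(reads$seq[j], graph, index, params, read_id = reads$id[j])
    if (m$status == "MAPPED_PATH" && length(m$walk) == 1L) {
      m$status <- "MAPPED_UNITIG"
    }
    if (!.status_mapped(m$status)) {
      m2 <- map_on_unitigs(reads$seq[j], graph, params, read_id = reads$id[j])
      if (.status_mapped(m2$status)) {
        m2$max_step_candidates <- m$max_step_candidates
        m <- m2
      } else {
        m$status <- .combine_unmapped(m$status, m2$status)
      }
    }
    maps[[j]] <- m
  }
  statuses <- vapply(maps, `[[`, character(1), "status")
  summary <- structure(list(
    n_reads = n,
    n_mapped_path = sum(statuses == "MAPPED_PATH"),
    n_mapped_unitig = sum(statuses == "MAPPED_UNITIG"),
    n_unmapped_too_short = sum(statuses == "UNMAPPED_TOO_SHORT"),
    n_unmapped_unanchored = sum(statuses == "UNMAPPED_UNANCHORED"),
    n_unmapped_over_budget = sum(statuses == "UNMAPPED_OVER_BUDGET")
  ), class = "mapping_summary")
  list(mappings = maps, summary = summary)
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "reads: %d\n  mapped on branching paths: %d\n  mapped within a unitig:  %d\n",
    "  unmapped (too short):     %d\n  unmapped (unanchored):    %d\n",
    "  unmapped (over budget):   %d\n"),
    x$n_reads, x$n_mapped_path, x$n_mapped_unitig, x$n_unmapped_too_short,
    x$n_unmapped_unanchored, x$n_unmapped_over_budget))
  invisible(x)
}
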