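# Shared fixtures and independent oracles. The oracles deliberately use
# different algorithms and different string plumbing (strsplit-based hamming,
# merge-to-fixpoint compaction, full-walk spelling) than the package so that
# agreement is meaningful.

fixture_kmers <- function() c("TAA", "AAG", "AGC", "CAA")

fixture_graph <- function() build_cdbg(fixture_kmers(), 3L)

fixture_index <- function() build_overlap_index(fixture_graph())

fixture_params <- function(...) {
  mapping_params(try_reverse_complement = FALSE, ...)
}

# character-level hamming, independent of the package's raw-byte version
oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  sum(ca != cb | ca == "N" | cb == "N")
}

# Naive compaction: repeatedly merge ANY mergeable arc (unique out of a,
# unique into b, a != b) until fixpoint; then canonicalise isolated cycles by
# rotating them to start at their lexicographically smallest k-mer.
oracle_compact <- function(kmers, k) {
  us <- unique(kmers)
  repeat {
    n <- length(us)
    if (n <= 1L) break
    lens <- nchar(us)
    pref <- substr(us, 1L, k - 1L)
    suf <- substr(us, lens - k + 2L, lens)
    merged <- FALSE
    for (a in seq_len(n)) {
      outs <- which(pref == suf[a])
      if (length(outs) != 1L || outs == a) next
      b <- outs
      if (length(which(suf == pref[b])) != 1L) next
      us[a] <- paste0(us[a], substr(us[b], k, nchar(us[b])))
      us <- us[-b]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  lens <- nchar(us)
  pref <- substr(us, 1L, k - 1L)
  suf <- substr(us, lens - k + 2L, lens)
  for (a in seq_along(us)) {
    outs <- which(pref == suf[a])
    ins <- which(suf == pref[a])
    if (length(outs) == 1L && outs == a && length(ins) == 1L && ins == a &&
        nchar(us[a]) > k) {
      core_len <- nchar(us[a]) - (k - 1L)
      rep_core <- strrep(substr(us[a], 1L, core_len),
                         ceiling((core_len + 2L * k) / core_len))
      kms <- substring(rep_core, seq_len(core_len), k:(core_len + k - 1L))
      m <- which(kms == min(kms))[1L]
      us[a] <- substr(rep_core, m, m + core_len + k - 2L)
    }
  }
  sort(us, method = "radix")
}

# Naive exhaustive mapper: same documented contract as map_read_exhaustive
# (anchor both extremities under the failure allowance; no extremity unitig
# prepended when the left anchor is at position 0), but implemented by
# enumerating whole walks and re-spelling them as strings.
oracle_map <- function(read, graph, t = 2L, nfail = 2L) {
  U <- graph$unitigs
  k <- graph$k
  L <- nchar(read)
  useqs <- U$seq
  lens <- U$len
  pref <- U$prefix_ov
  suf <- U$suffix_ov
  if (L < k) return(list(status = "UNMAPPED_TOO_SHORT"))
  words <- substring(read, seq_len(L - k + 2L), (k - 1L):L)
  apos <- which(words %in% unique(c(pref, suf))) # 1-based anchor positions
  unanch <- list(status = "UNMAPPED_UNANCHORED")
  if (!length(apos)) return(unanch)

  anchor_side <- function(positions, left) {
    fails <- 0L
    for (p1 in positions) {
      p <- p1 - 1L
      cands <- if (left) which(suf == words[p1]) else which(pref == words[p1])
      flank <- if (left) p + k - 1L else L - p
      best <- NULL
      for (r in cands) {
        if (lens[r] < flank) next
        mm <- if (left) {
          oracle_hamming(substr(read, 1L, flank),
                         substr(useqs[r], lens[r] - flank + 1L, lens[r]))
        } else {
          oracle_hamming(substr(read, p + 1L, L), substr(useqs[r], 1L, flank))
        }
        if (mm <= t && (is.null(best) || mm < best$mm)) best <- list(r = r, mm = mm)
      }
      if (!is.null(best)) return(list(p = p, r = best$r, mm = best$mm))
      fails <- fails + 1L
      if (fails >= nfail) return(NULL)
    }
    NULL
  }

  left <- anchor_side(apos, left = TRUE)
  if (is.null(left)) return(unanch)
  if (is.null(anchor_side(rev(apos), left = FALSE))) return(unanch)

  if (left$p > 0L) {
    walk0 <- left$r
    spelled0 <- substr(useqs[left$r], lens[left$r] - (left$p + k - 1L) + 1L,
                       lens[left$r])
    i0 <- left$p
  } else {
    walk0 <- integer(0)
    spelled0 <- ""
    i0 <- 0L
  }

  best <- NULL
  walk_less <- function(a, b) {
    n <- min(length(a), length(b))
    for (j in seq_len(n)) if (a[j] != b[j]) return(a[j] < b[j])
    length(a) < length(b)
  }
  recurse <- function(walk, spelled, i) {
    cov <- min(nchar(spelled), L)
    cum <- if (cov > 0L) oracle_hamming(substr(read, 1L, cov),
                                        substr(spelled, 1L, cov)) else 0L
    if (cum > t) return(invisible(NULL))
    if (i + k - 1L >= L) {
      if (is.null(best) || cum < best$cum ||
          (cum == best$cum && walk_less(walk, best$walk))) {
        best <<- list(walk = walk, cum = cum)
      }
      return(invisible(NULL))
    }
    if (length(walk) > L) return(invisible(NULL))
    w <- if (length(walk)) suf[walk[length(walk)]] else substr(read, 1L, k - 1L)
    for (r in which(pref == w)) {
      piece <- if (length(walk) || left$p > 0L) substr(useqs[r], k, lens[r]) else useqs[r]
      recurse(c(walk, r), paste0(spelled, piece), i + lens[r] - (k - 1L))
    }
    invisible(NULL)
  }
  recurse(walk0, spelled0, i0)
  if (is.null(best)) return(list(status = "UNMAPPED_OVER_BUDGET"))
  list(status = "MAPPED_PATH", walk = U$id[best$walk],
       start_offset = if (left$p > 0L) lens[best$walk[1L]] - (left$p + k - 1L) else 0L,
       mismatches = best$cum)
}

# genome -> forward-only c=1 graph
make_genome_graph <- function(genome, k) {
  tab <- count_kmers(genome, k, "forward_only")
  build_cdbg(solid_kmers(tab, 1L), k)
}

# soundness of every mapped result: the spelled walk reproduces the read with
# exactly the reported number of mismatches, within budget
expect_sound <- function(mappings, seqs, graph, t = 2L) {
  for (j in seq_along(mappings)) {
    m <- mappings[[j]]
    if (!startsWith(m$status, "MAPPED")) next
    q <- if (identical(m$orientation, "reverse")) rc_seq(seqs[j]) else seqs[j]
    spelled <- substr(spell_walk(graph, m$walk, m$start_offset), 1L, nchar(q))
    expect_equal(nchar(spelled), nchar(q))
    expect_equal(oracle_hamming(q, spelled), m$mismatches)
    expect_lte(m$mismatches, t)
    if (length(m$walk) > 1L) {
      U <- graph$unitigs
      r <- match(m$walk, U$id)
      expect_true(all(U$suffix_ov[r[-length(r)]] == U$prefix_ov[r[-1L]]))
    }
  }
  invisible(NULL)
}

# conservation + maximality of a built graph against its solid set
expect_conserved <- function(graph, solid) {
  kms <- as.character(unlist(lapply(graph$unitigs$seq, function(s) {
    n <- nchar(s)
    substring(s, seq_len(n - graph$k + 1L), graph$k:n)
  }), use.names = FALSE))
  expect_equal(sort(kms, method = "radix"), sort(solid, method = "radix"))
  expect_equal(anyDuplicated(kms), 0L)
  U <- graph$unitigs
  for (r in seq_len(nrow(U))) {
    outs <- which(U$prefix_ov == U$suffix_ov[r])
    if (length(outs) != 1L || outs == r) next
    ins <- which(U$suffix_ov == U$prefix_ov[outs])
    expect_false(length(ins) == 1L && ins == r,
                 label = sprintf("unmerged adjacent pair %s -> %s",
                                 U$id[r], U$id[outs]))
  }
  invisible(NULL)
}
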