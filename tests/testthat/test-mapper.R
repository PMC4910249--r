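test_that("hamming_cost counts differing positions, N always mismatches", {
  expect_equal(hamming_cost("AAGC", "AAGA"), 1L)
  expect_equal(hamming_cost("ACGT", "ACGT"), 0L)
  expect_equal(hamming_cost("ANGT", "ACGT"), 1L)
  expect_equal(hamming_cost("NNNN", "NNNN"), 4L)
  expect_error(hamming_cost("AC", "ACG"), "length mismatch")
  set.seed(5)
  for (rep in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T", "N"), 30, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "N"), 30, replace = TRUE), collapse = "")
    expect_equal(hamming_cost(a, b), oracle_hamming(a, b))
  }
})

test_that("find_anchors reports every indexed (k-1)-mer position", {
  idx <- fixture_index()
  a <- find_anchors("TAAGC", idx)
  expect_equal(a$pos, c(0L, 1L, 3L))
  expect_equal(a$word, c("TA", "AA", "GC"))

  a <- find_anchors("TATGC", idx) # the substitution destroys the "AA" anchor
  expect_equal(a$pos, c(0L, 3L))

  expect_equal(find_anchors("GGGGG", idx)$pos, integer(0))
  expect_equal(find_anchors("T", idx)$pos, integer(0))
})

test_that("anchor_extremity walks anchors under the failure allowance", {
  g <- fixture_graph()
  idx <- fixture_index()
  p <- fixture_params()

  # TAAGC: "TA"@0 has no enders (failure 1); "AA"@1 picks TAA (0 mm) over CAA
  a <- find_anchors("TAAGC", idx)
  left <- anchor_extremity("TAAGC", a, g, p, "left")
  expect_equal(left$pos, 1L)
  expect_equal(left$unitig, "u3")
  expect_equal(left$mismatches, 0L)

  # TATGC: "TA"@0 no enders, "GC"@3 needs a length-5 suffix of a 4 bp unitig
  # -> two failures with n = 2 -> unanchorable
  a <- find_anchors("TATGC", idx)
  expect_null(anchor_extremity("TATGC", a, g, p, "left"))

  # anchor at position 0: the flank is the (k-1)-mer itself, any ender works
  a <- find_anchors("AAGC", idx)
  left <- anchor_extremity("AAGC", a, g, p, "left")
  expect_equal(left$pos, 0L)
  expect_equal(left$mismatches, 0L)
  expect_equal(left$unitig, "u2") # tie at 0 mm -> smallest id
})

test_that("map_read_greedy reproduces the fixture traces", {
  g <- fixture_graph()
  idx <- fixture_index()
  p <- fixture_params()

  m <- map_read_greedy("TAAGC", g, idx, p)
  expect_equal(m$status, "MAPPED_PATH")
  expect_equal(m$walk, c("u3", "u1"))
  expect_equal(m$start_offset, 0L)
  expect_equal(m$mismatches, 0L)

  m <- map_read_greedy("TAAGA", g, idx, p)
  expect_equal(m$status, "MAPPED_PATH")
  expect_equal(m$walk, c("u3", "u1"))
  expect_equal(m$mismatches, 1L)

  expect_equal(map_read_greedy("TATGC", g, idx, p)$status, "UNMAPPED_UNANCHORED")
  expect_equal(map_read_greedy("TA", g, idx, p)$status, "UNMAPPED_TOO_SHORT")
  expect_sound(list(map_read_greedy("TAAGA", g, idx, p)), "TAAGA", g)
})

test_that("map_on_unitigs places contained reads and reports failures", {
  g <- fixture_graph()
  p <- fixture_params()

  m <- map_on_unitigs("AAGC", g, p)
  expect_equal(m$status, "MAPPED_UNITIG")
  expect_equal(m$walk, "u1")
  expect_equal(m$start_offset, 0L)
  expect_equal(m$mismatches, 0L)

  m <- map_on_unitigs("AGC", g, p)
  expect_equal(m$status, "MAPPED_UNITIG")
  expect_equal(m$start_offset, 1L)

  # longer than every unitig: no containment possible
  expect_equal(map_on_unitigs("TAAGC", g, p)$status, "UNMAPPED_UNANCHORED")
  expect_equal(map_on_unitigs("AA", g, p)$status, "UNMAPPED_TOO_SHORT")

  # seeding falls back to positions k and 2k when the first k-mer is mutated
  genome <- random_genome(40, 3)
  g2 <- make_genome_graph(genome, 15) # repeat-free: a single 40 bp unitig
  expect_equal(nrow(g2$unitigs), 1L)
  read <- substr(genome, 3, 36)
  substr(read, 2, 2) <- setdiff(c("A", "C", "G", "T"), substr(read, 2, 2))[1]
  m <- map_on_unitigs(read, g2, fixture_params())
  expect_equal(m$status, "MAPPED_UNITIG")
  expect_equal(m$start_offset, 2L)
  expect_equal(m$mismatches, 1L)
})

test_that("ggmap composes the stages and tallies the summary", {
  g <- fixture_graph()
  idx <- fixture_index()
  res <- ggmap(c("TAAGC", "CAAGC", "AAGC"), g, idx, mapping_params())
  expect_equal(res$summary$n_mapped_path, 2L)
  expect_equal(res$summary$n_mapped_unitig, 1L)
  expect_equal(res$summary$n_reads, 3L)
  statuses <- vapply(res$mappings, `[[`, character(1), "status")
  expect_equal(statuses, c("MAPPED_PATH", "MAPPED_PATH", "MAPPED_UNITIG"))

  res0 <- ggmap(character(0), g, idx, mapping_params())
  expect_equal(res0$summary$n_reads, 0L)
  expect_equal(res0$summary$n_mapped_path, 0L)
})

test_that("reverse-complement queries map with reverse orientation", {
  g <- fixture_graph()
  idx <- fixture_index()
  m <- map_read_greedy(rc_seq("TAAGC"), g, idx, mapping_params())
  expect_equal(m$status, "MAPPED_PATH")
  expect_equal(m$orientation, "reverse")
  expect_equal(m$walk, c("u3", "u1"))
  expect_equal(m$mismatches, 0L)
  # with rc disabled the same query cannot anchor usefully
  m2 <- map_read_greedy(rc_seq("TAAGC"), g, idx, fixture_params())
  expect_false(startsWith(m2$status, "MAPPED"))
})

test_that("greedy dead-ends on an adversarial branch that exhaustive resolves", {
  # CCCAG matches the read perfectly but has no successor; CCCGTTT costs two
  # mismatches and completes. Greedy commits to the local best and runs out.
  g <- graph_from_unitigs(c("AAATCCC", "CCCAG", "CCCGTTT"), 4)
  idx <- build_overlap_index(g)
  p <- fixture_params()
  read <- "AAATCCCAGTT"

  mg <- map_read_greedy(read, g, idx, p)
  expect_equal(mg$status, "UNMAPPED_OVER_BUDGET")

  me <- map_read_exhaustive(read, g, idx, p)
  expect_equal(me$status, "MAPPED_PATH")
  expect_equal(me$walk, c("u1", "u3"))
  expect_equal(me$mismatches, 2L)
  expect_sound(list(me), read, g)

  # oracle agreement on the same instance
  o <- oracle_map(read, g)
  expect_equal(o$status, me$status)
  expect_equal(o$walk, me$walk)
  expect_equal(o$mismatches, me$mismatches)
})

test_that("exhaustive dominates greedy and matches the oracle on random instances", {
  set.seed(6001)
  n_checked <- 0L
  for (rep in 1:60) {
    k <- 5L
    genome <- paste(sample(c("A", "C", "G", "T"), sample(50:90, 1),
                           replace = TRUE), collapse = "")
    g <- make_genome_graph(genome, k)
    if (nrow(g$unitigs) > 30L) next
    idx <- build_overlap_index(g)
    p <- fixture_params()
    for (j in 1:4) {
      len <- sample(15:30, 1)
      start <- sample(nchar(genome) - len + 1, 1)
      read <- substr(genome, start, start + len - 1)
      nerr <- sample(0:2, 1)
      if (nerr > 0) {
        for (pos in sample(len, nerr)) {
          substr(read, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                                   substr(read, pos, pos)), 1)
        }
      }
      me <- map_read_exhaustive(read, g, idx, p)
      mo <- oracle_map(read, g)
      expect_equal(me$status, mo$status)
      if (startsWith(me$status, "MAPPED")) {
        expect_equal(me$walk, mo$walk)
        expect_equal(me$mismatches, mo$mismatches)
        expect_equal(me$start_offset, mo$start_offset)
        expect_sound(list(me), read, g)
      }
      mg <- map_read_greedy(read, g, idx, p)
      if (startsWith(mg$status, "MAPPED")) {
        expect_true(startsWith(me$status, "MAPPED"))
        expect_lte(me$mismatches, mg$mismatches)
        expect_sound(list(mg), read, g)
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 100L)
})

test_that("raising the mismatch budget never unmaps reads", {
  genome <- random_genome(3000, 99)
  g <- make_genome_graph(genome, 9)
  idx <- build_overlap_index(g)
  sims <- simulate_reads(genome, 150, 60, 0.03, 100)
  counts <- vapply(0:3, function(t) {
    res <- ggmap(sims, g, idx,
                 mapping_params(max_mismatches = t, try_reverse_complement = FALSE))
    res$summary$n_mapped_path + res$summary$n_mapped_unitig
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("mapping defaults match the reference configuration", {
  p <- mapping_params()
  expect_equal(p$max_mismatches, 2L)
  expect_equal(p$anchor_failures, 2L)
  expect_false(p$exhaustive)
  expect_true(p$try_reverse_complement)
})
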