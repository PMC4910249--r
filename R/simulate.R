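# Synthetic data and the accuracy methodology: random genomes, uniformly
# sampled fixed-length reads with i.i.d. substitution errors at a stated
# rate (error positions recorded), recall, and the "distance to optimum" of
# each mapped read: among the error-free positions of a simulated read, the
# number of mismatches between the read and the sequence spelled by its
# mapped walk. A read mapped at its true origin always has distance 0.

#' Generate a random genome
#'
#' i.i.d. uniform bases, reproducible from the seed. Stands in for a real
#' reference chromosome in the evaluation experiments.
#'
#' @param length genome length in bp.
#' @param seed integer RNG seed.
#' @return a DNA string.
#' @export
random_genome <- function(length, seed) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) .stopf("genome length must be >= 1")
  withr::with_seed(seed,
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = ""))
}

#' Simulate substitution-error reads from a genome
#'
#' Read origins are uniform over all valid offsets; every position is
#' independently substituted with probability `error_rate`, the replacement
#' base drawn uniformly from the three alternatives; error positions are
#' recorded so distance-to-optimum can be computed later. Reads are sampled
#' from the forward strand only, keeping the true origin path unambiguous.
#'
#' @param genome DNA string.
#' @param n number of reads.
#' @param read_len read length (at most the genome length).
#' @param error_rate per-base substitution probability.
#' @param seed integer RNG seed.
#' @return data frame of class `simulated_reads` with columns `id`, `seq`,
#'   `origin` (0-based genome offset) and `error_positions` (list column of
#'   0-based read positions).
#' @export
simulate_reads <- function(genome, n, read_len, error_rate, seed) {
  L <- nchar(genome)
  n <- as.integer(n)
  read_len <- as.integer(read_len)
  if (read_len > L) .stopf("read_len (%d) exceeds genome length (%d)", read_len, L)
  if (error_rate < 0 || error_rate > 1) .stopf("error_rate must be in [0, 1]")
  withr::with_seed(seed, {
    origins <- sample.int(L - read_len + 1L, n, replace = TRUE) - 1L
    seqs <- substring(genome, origins + 1L, origins + read_len)
    nerr <- rbinom(n, read_len, error_rate)
    errpos <- vector("list", n)
    for (i in seq_len(n)) {
      if (nerr[i] == 0L) {
        errpos[[i]] <- integer(0)
        next
      }
      pos <- sort(sample.int(read_len, nerr[i]))
      s <- seqs[i]
      for (p in pos) {
        orig <- substr(s, p, p)
        substr(s, p, p) <- sample(setdiff(DNA_BASES, orig), 1L)
      }
      seqs[i] <- s
      errpos[[i]] <- pos - 1L
    }
    out <- data.frame(id = paste0("r", seq_len(n)), seq = seqs,
                      origin = origins, stringsAsFactors = FALSE)
    out$error_positions <- errpos
    class(out) <- c("simulated_reads", "data.frame")
    out
  })
}

#' Distance to optimum of a mapped simulated read
#'
#' Spells the mapped walk over the read span and counts the mismatching
#' positions that are NOT recorded error positions of the simulated read. For
#' reverse-orientation mappings the comparison is done on the reverse
#' complement of the read, with error positions reflected accordingly.
#' Undefined (`NA`) for unmapped reads.
#'
#' @param mapping a `graph_mapping` with a `MAPPED_*` status.
#' @param sim one simulated read: either a one-row slice of a
#'   `simulated_reads` frame or a list with `seq` and `error_positions`.
#' @param graph the `cdbg` the read was mapped on.
#' @return integer distance, or `NA` for unmapped reads.
#' @export
distance_to_optimum <- function(mapping, sim, graph) {
  if (!startsWith(mapping$status, "MAPPED")) return(NA_integer_)
  seq <- if (is.data.frame(sim)) sim$seq[[1L]] else sim$seq
  ep <- if (is.data.frame(sim)) sim$error_positions[[1L]] else sim$error_positions
  L <- nchar(seq)
  if (identical(mapping$orientation, "reverse")) {
    seq <- rc_seq(seq)
    ep <- (L - 1L) - ep
  }
  spelled <- substr(spell_walk(graph, mapping$walk, mapping$start_offset), 1L, L)
  diff <- which(charToRaw(seq) != charToRaw(spelled)) - 1L # 0-based
  sum(!(diff %in% ep))
}

#' Recall and distance-to-optimum table over error rates
#'
#' For each error rate, simulates `n_per_rate` reads, maps them with the full
#' pipeline and tallies recall (mapped / simulated) and the
#' distance-to-optimum histogram of the mapped reads in bins 0, 1, 2, 3, >=4.
#'
#' @param graph a `cdbg` (typically built from all genome k-mers, c = 1).
#' @param index the graph's `overlap_index`.
#' @param params a `mapping_params`.
#' @param genome the DNA string reads are simulated from.
#' @param error_rates numeric vector of per-base substitution rates.
#' @param n_per_rate reads per rate.
#' @param read_len read length.
#' @param seed integer seed; rate i uses `seed + i`.
#' @return data frame with one row per rate: `error_rate`, `n_reads`,
#'   `n_mapped`, `recall`, and distance bins `d0`..`d3`, `d4plus` (counts).
#' @export
evaluate <- function(graph, index, params, genome, error_rates, n_per_rate,
                     read_len, seed) {
  rows <- lapply(seq_along(error_rates), function(i) {
    sims <- simulate_reads(genome, n_per_rate, read_len, error_rates[i], seed + i)
    res <- ggmap(sims, graph, index, params)
    mapped <- vapply(res$mappings, function(m) startsWith(m$status, "MAPPED"),
                     logical(1))
    d <- vapply(which(mapped), function(j) {
      distance_to_optimum(res$mappings[[j]],
                          list(seq = sims$seq[j],
                               error_positions = sims$error_positions[[j]]),
                          graph)
    }, integer(1))
    bins <- tabulate(pmin(d, 4L) + 1L, nbins = 5L)
    data.frame(error_rate = error_rates[i], n_reads = n_per_rate,
               n_mapped = sum(mapped), recall = mean(mapped),
               d0 = bins[1L], d1 = bins[2L], d2 = bins[3L], d3 = bins[4L],
               d4plus = bins[5L])
  })
  do.call(rbind, rows)
}
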