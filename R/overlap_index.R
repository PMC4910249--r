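# Index of unitig-boundary (k-1)-mers ("overlaps"), the only seeds the
# branching-path mapper uses. Interior (k-1)-mers of unitigs are deliberately
# not indexed: reads falling wholly inside a long unitig are handled by the
# containment stage instead. Because each solid k-mer occurs exactly once
# across the unitigs, an overlap can be shared by at most four unitigs
# starting with it and four ending with it (one per extending base), i.e.
# by at most eight unitigs in total.

#' Build the overlap index of a CDBG
#'
#' Maps every distinct unitig-boundary (k-1)-mer to the unitigs that start
#' with it (`starters`) and the unitigs that end with it (`enders`), each list
#' in ascending id order. This is the exact-map counterpart of a minimal
#' perfect hash table: semantics identical, memory optimisation omitted.
#'
#' @param graph a `cdbg`.
#' @return an object of class `overlap_index`: list with `k`, `keys`
#'   (character vector of indexed (k-1)-mers) and an internal lookup
#'   environment.
#' @export
#' @examples
#' g <- build_cdbg(c("TAA", "AAG", "AGC", "CAA"), k = 3)
#' idx <- build_overlap_index(g)
#' query_overlap(idx, "AA")
build_overlap_index <- function(graph) {
  stopifnot(inherits(graph, "cdbg"))
  U <- graph$unitigs
  st <- split(U$id, U$prefix_ov) # groups keep ascending rank order
  en <- split(U$id, U$suffix_ov)
  keys <- .csort(unique(c(names(st), names(en))))
  entries <- lapply(keys, function(w) {
    list(starters = if (is.null(st[[w]])) character(0) else st[[w]],
         enders = if (is.null(en[[w]])) character(0) else en[[w]])
  })
  names(entries) <- keys
  env <- new.env(parent = emptyenv())
  if (length(entries)) list2env(entries, envir = env)
  structure(list(k = graph$k, keys = keys, env = env),
            class = "overlap_index")
}

#' @export
print.overlap_index <- function(x, ...) {
  cat(sprintf("overlap_index: %d keys of length %d\n", length(x$keys), x$k - 1L))
  invisible(x)
}

#' Query the overlap index
#'
#' @param index an `overlap_index`.
#' @param word a (k-1)-mer.
#' @return `NULL` if `word` is not a unitig boundary, otherwise a list with
#'   `starters` and `enders` (character vectors of unitig ids).
#' @export
query_overlap <- function(index, word) {
  stopifnot(inherits(index, "overlap_index"))
  if (!is.character(word) || length(word) != 1L || nchar(word) != index$k - 1L) {
    .stopf("query word must be a single (k-1)-mer of length %d", index$k - 1L)
  }
  get0(word, envir = index$env, ifnotfound = NULL)
}
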