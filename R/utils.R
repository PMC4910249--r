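# Small shared helpers. Sequences are plain uppercase character scalars over
# {A,C,G,T,N}; all coordinates handed to users are 0-based half-open, all
# internal substr() arithmetic is 1-based inclusive.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; `N` maps to `N`, case is preserved.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' rc_seq("ACGTN")
rc_seq <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(s)
    rawToChar(rev(charToRaw(chartr("ACGTNacgtn", "TGCANtgcan", s))))
  }, character(1), USE.NAMES = FALSE)
}

# Hamming distance between two equal-length strings; 'N' mismatches anything
# (including another 'N'). No length check: callers guarantee it.
.hm <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  nn <- as.raw(78L) # 'N'
  sum(ra != rb | ra == nn | rb == nn)
}

# All k-length windows of a string, NA-free; windows containing a non-ACGT
# character are dropped when `acgt_only`.
.windows <- function(s, k, acgt_only = TRUE) {
  n <- nchar(s)
  if (n < k) return(character(0))
  w <- substring(s, seq_len(n - k + 1L), k:n)
  if (acgt_only) w <- w[!grepl("[^ACGT]", w)]
  w
}

# C-locale (radix) sort, so unitig ids never depend on the session locale.
.csort <- function(x) sort(x, method = "radix")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
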