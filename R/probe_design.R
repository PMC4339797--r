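#' Maximum probe tiling of a transcript
#'
#' How many non-overlapping probes of `probe_length` nucleotides, separated
#' by at least `min_gap` nucleotides, fit on a transcript of `seq_length`
#' nucleotides, and where. The left-packed greedy tiling
#' `[k*(p+g), k*(p+g)+p)` is optimal for this interval-packing problem, so
#' the count is `floor((seq_length + min_gap) / (probe_length + min_gap))`.
#' Intervals are 0-based half-open.
#'
#' @param seq_length transcript length, nt.
#' @param probe_length probe length, nt (default 20).
#' @param min_gap minimum separation between consecutive probes, nt
#'   (default 2).
#' @return `list(count, intervals = count x 2 matrix of [start, end)
#'   positions)`.
#' @examples
#' max_tiling(720)$count   # 32 probes on a 720-nt target
#' @export
max_tiling <- function(seq_length, probe_length = 20L, min_gap = 2L) {
  seq_length <- as.integer(seq_length)
  probe_length <- as.integer(probe_length)
  min_gap <- as.integer(min_gap)
  if (seq_length < 0L || probe_length < 1L || min_gap < 0L)
    stop("lengths must be positive (gap may be 0)")
  count <- max(0L, (seq_length + min_gap) %/% (probe_length + min_gap))
  starts <- (seq_len(count) - 1L) * (probe_length + min_gap)
  list(count = count,
       intervals = cbind(start = starts, end = starts + probe_length))
}

#' Minimum transcript length for a required probe count
#'
#' The shortest transcript on which `count` probes fit:
#' `count * probe_length + (count - 1) * min_gap`. Adjoint to [max_tiling()]:
#' `max_tiling(min_length_for(c))$count == c` and one nucleotide less drops
#' the count to `c - 1`.
#'
#' @param count required number of probes (>= 1).
#' @inheritParams max_tiling
#' @return Length in nucleotides.
#' @examples
#' min_length_for(32)  # 702 nt for a 32-probe set
#' @export
min_length_for <- function(count, probe_length = 20L, min_gap = 2L) {
  count <- as.integer(count)
  if (count < 1L) stop("count must be >= 1")
  count * as.integer(probe_length) + (count - 1L) * as.integer(min_gap)
}
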