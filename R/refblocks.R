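# Bounding reference-block length.  Both strategies trade a few extra blocks
# for a bounded backward search window during point-query densification: after
# splitting with parameter K, any block overlapping a locus starts within the
# preceding K bases.  Neither strategy changes per-base coverage.

split_blocks <- function(ds, piece_fun) {
  if (nrow(ds$ref)) {
    pieces <- vector("list", nrow(ds$ref))
    for (i in seq_len(nrow(ds$ref))) {
      b <- ds$ref[i, ]
      starts <- piece_fun(b$pos, b$len)
      ends <- c(starts[-1L] - 1L, b$pos + b$len - 1L)
      n <- length(starts)
      pieces[[i]] <- data.frame(contig = b$contig, pos = starts, sample = b$sample,
                                len = ends - starts + 1L, dp = b$dp, gq = b$gq,
                                lgt = b$lgt, ref_base = if (n == 1L) b$ref_base else
                                  c(b$ref_base, rep("N", n - 1L)),
                                meta = I(rep(b$meta, n)), stringsAsFactors = FALSE)
    }
    ds$ref <- do.call(rbind, pieces)
  }
  ds$max_ref_block_length <- if (nrow(ds$ref)) max(ds$ref$len) else 0L
  sort_dataset(ds)
}

#' Split reference blocks at a size threshold
#'
#' Every block spanning more than `k` bases is replaced by `ceiling(len/k)`
#' consecutive blocks, all but the last spanning exactly `k`, starting at
#' the original start; DP/GQ/LGT are copied to every piece.  This introduces
#' the minimum number of new blocks that guarantees `len <= k` everywhere.
#'
#' @param ds an `svcr_dataset`.
#' @param k maximum block span in base pairs (>= 1).
#' @return the dataset with bounded blocks and updated
#'   `max_ref_block_length`.
#' @export
split_size_threshold <- function(ds, k) {
  stopifnot(k >= 1L)
  k <- as.integer(k)
  split_blocks(ds, function(pos, len) pos + k * (seq_len(ceiling(len / k)) - 1L))
}

#' Split reference blocks at fixed genomic periods
#'
#' Blocks are cut at every period boundary they span, where boundaries sit at
#' positions `p` with `(p - 1) %% k == 0`; partition `p` of the genome covers
#' `[(p-1)k + 1, pk]`.  After splitting, no block crosses a partition
#' boundary, so the dense sub-matrix of any `k`-sized partition can be
#' realized from that partition's rows alone.
#'
#' @param ds an `svcr_dataset`.
#' @param k period in base pairs (>= 1).
#' @return the dataset with cut blocks and updated `max_ref_block_length`.
#' @export
split_fixed_period <- function(ds, k) {
  stopifnot(k >= 1L)
  k <- as.integer(k)
  split_blocks(ds, function(pos, len) {
    end <- pos + len - 1L
    first_boundary <- (pos %/% k) * k + 1L
    if (first_boundary <= pos) first_boundary <- first_boundary + k
    boundaries <- if (first_boundary <= end)
      seq.int(first_boundary, end, by = k) else integer()
    c(pos, boundaries)
  })
}

#' Expand one sample's reference blocks to a per-base coverage map
#'
#' A test/verification oracle: every covered base with its DP and GQ.
#' Intended for small regions only (it materializes one row per base).
#'
#' @param ds an `svcr_dataset`.
#' @param sample sample id.
#' @return data frame `contig`, `pos`, `dp`, `gq`, sorted, one row per
#'   covered base.
#' @export
coverage_map <- function(ds, sample) {
  if (!sample %in% ds$samples) stop("unknown sample: ", sample)
  b <- ds$ref[ds$ref$sample == sample, , drop = FALSE]
  if (!nrow(b)) {
    return(data.frame(contig = character(), pos = integer(), dp = integer(),
                      gq = integer(), stringsAsFactors = FALSE))
  }
  out <- data.frame(contig = rep(b$contig, b$len),
                    pos = unlist(lapply(seq_len(nrow(b)),
                                        function(i) seq.int(b$pos[i], length.out = b$len[i]))),
                    dp = rep(b$dp, b$len), gq = rep(b$gq, b$len),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(paste(out$contig, out$pos)))
    stop("overlapping reference blocks for sample ", sample)
  out <- out[locus_order(out$contig, out$pos, ds$contigs), , drop = FALSE]
  rownames(out) <- NULL
  out
}
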