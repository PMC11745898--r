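# Shared fixtures and independent oracles for the test suite.

# Build a gvcf object from body lines (tab-separated VCF data rows).
make_gvcf <- function(body, sample = "S1", contigs = "chr1") {
  meta <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Stop position\">",
            sprintf("##contig=<ID=%s>", contigs))
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", sample), collapse = "\t")
  svcr:::parse_gvcf_lines(c(meta, header, body))
}

gvcf_line <- function(chrom, pos, ref, alt, info, format, value,
                      id = ".", qual = ".", filter = ".") {
  paste(chrom, pos, id, ref, alt, qual, filter, info, format, value, sep = "\t")
}

# Independent oracle for VCF genotype ordering: enumerate allele pairs
# (j <= k) in order of increasing k then j (diploid), or single alleles
# (haploid).  Returns a matrix with one row per genotype.
enumerate_genotypes <- function(n_alleles, ploidy) {
  if (ploidy == 1L) return(matrix(seq_len(n_alleles) - 1L, ncol = 1L))
  out <- list()
  for (k in 0:(n_alleles - 1L)) for (j in 0:k)
    out[[length(out) + 1L]] <- c(j, k)
  do.call(rbind, out)
}

# Oracle for dropping an allele from a G-ordered array: keep entries whose
# enumerated pair avoids the dropped allele.
enumerate_pl_keep <- function(n_alleles, drop) {
  pairs <- enumerate_genotypes(n_alleles, 2L)
  which(pairs[, 1L] != drop & pairs[, 2L] != drop)
}

# ---- brute-force per-base join oracle ---------------------------------------
# Resolves, directly from the input GVCF records and independently of the
# merge/densify code, the genotype of every sample at every variant locus.
# Alleles are compared as normalized keys ("REF" or trimmed ref>alt strings)
# so right-extension differences cannot mask disagreements; depths are
# compared as key=depth sets with zero entries dropped.  Coverage lookups use
# IRanges as independent interval machinery.

normalize_allele_key <- function(ref, alt) {
  if (alt == "<NON_REF>" || alt == "*") return(alt)
  t <- svcr::trim_shared_suffix(ref, alt)
  paste0(t$ref, ">", t$alts)
}

ad_key_string <- function(keys, depths) {
  keep <- which(!is.na(depths) & depths != 0L & keys != "<NON_REF>")
  if (!length(keep)) return("")
  o <- order(keys[keep])
  paste(paste0(keys[keep][o], "=", depths[keep][o]), collapse = ";")
}

# Per-base join of raw GVCF records: data frame keyed by (pos, sample).
oracle_join_df <- function(gvcfs) {
  loci <- sort(unique(unlist(lapply(gvcfs, function(g) {
    rec <- g$records
    rec$pos[!gvcf_is_ref_row(rec)]
  }))))
  out <- list()
  for (g in gvcfs) {
    rec <- g$records
    is_ref <- gvcf_is_ref_row(rec)
    vpos <- rec$pos[!is_ref]
    vrow <- which(!is_ref)
    starts <- rec$pos[is_ref]
    ends <- ifelse(is.na(rec$end[is_ref]),
                   rec$pos[is_ref] + nchar(rec$ref[is_ref]) - 1L, rec$end[is_ref])
    brow <- which(is_ref)
    cover <- IRanges::findOverlaps(IRanges::IRanges(loci, loci),
                                   IRanges::IRanges(starts, ends))
    block_at <- rep(NA_integer_, length(loci))
    block_at[S4Vectors::queryHits(cover)] <- brow[S4Vectors::subjectHits(cover)]
    for (li in seq_along(loci)) {
      p <- loci[li]
      vi <- vrow[match(p, vpos)]
      if (!is.na(vi)) {
        alts <- strsplit(rec$alt[vi], ",", fixed = TRUE)[[1]]
        called <- svcr:::parse_call(rec$gt[vi])$alleles
        keys <- vapply(called, function(a)
          if (a == 0L) "REF" else normalize_allele_key(rec$ref[vi], alts[a]),
          character(1))
        all_keys <- c("REF", vapply(alts, function(x)
          normalize_allele_key(rec$ref[vi], x), character(1)))
        ad <- rec$ad[[vi]]
        out[[length(out) + 1L]] <- data.frame(
          pos = p, sample = g$sample, status = "variant",
          gt = paste(sort(keys), collapse = "|"),
          dp = rec$dp[vi], gq = rec$gq[vi],
          ad = if (is.null(ad)) "" else ad_key_string(all_keys, ad),
          stringsAsFactors = FALSE)
      } else if (!is.na(block_at[li])) {
        bi <- block_at[li]
        out[[length(out) + 1L]] <- data.frame(
          pos = p, sample = g$sample, status = "block", gt = "REF|REF",
          dp = rec$dp[bi], gq = rec$gq[bi], ad = "", stringsAsFactors = FALSE)
      } else {
        out[[length(out) + 1L]] <- data.frame(
          pos = p, sample = g$sample, status = "missing", gt = "",
          dp = NA_integer_, gq = NA_integer_, ad = "", stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$pos, res$sample), , drop = FALSE]
  rownames(res) <- NULL
  res
}

gvcf_is_ref_row <- function(rec) {
  vapply(rec$gt, function(x) {
    a <- svcr:::parse_call(x)$alleles
    length(a) > 0 && all(!is.na(a)) && all(a == 0L)
  }, logical(1), USE.NAMES = FALSE)
}

# The same table computed from densified rows of a merged dataset.
dense_join_df <- function(rows) {
  out <- lapply(rows, function(r) {
    keys <- c("REF", vapply(r$alts, function(a) normalize_allele_key(r$ref, a),
                            character(1)))
    do.call(rbind, lapply(names(r$calls), function(smp) {
      x <- r$calls[[smp]]
      if (x$src == "missing") {
        return(data.frame(pos = r$pos, sample = smp, status = "missing",
                          gt = "", dp = NA_integer_, gq = NA_integer_, ad = "",
                          stringsAsFactors = FALSE))
      }
      alleles <- svcr:::parse_call(x$gt)$alleles
      data.frame(pos = r$pos, sample = smp, status = x$src,
                 gt = paste(sort(keys[alleles + 1L]), collapse = "|"),
                 dp = x$dp, gq = x$gq,
                 ad = if (is.null(x$ad)) "" else ad_key_string(keys, x$ad),
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$pos, res$sample), , drop = FALSE]
  rownames(res) <- NULL
  res
}

expect_matches_bruteforce <- function(rows, gvcfs) {
  expect_identical(dense_join_df(rows), oracle_join_df(gvcfs))
}
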