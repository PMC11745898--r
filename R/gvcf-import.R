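# Lossless conversion between a single-sample GVCF and a single-sample SVCR
# dataset.  The transformation is the three-step one: reference rows gain a
# LEN (END - POS + 1), allele-indexed fields gain an "L" prefix, and an LA
# field is added as the identity map over the row's own alleles.

#' Drop one allele from a G-ordered likelihood array
#'
#' Keeps entries for genotype pairs not involving the dropped allele and
#' renumbers the remaining alleles, preserving VCF genotype ordering.
#'
#' @param pl integer PL/LPL array, G-numbered over `n_alleles`.
#' @param n_alleles allele count including the reference.
#' @param drop 0-based index of the allele to remove.
#' @param ploidy 1 or 2.
#' @return the shortened integer array.
#' @export
pl_drop_allele <- function(pl, n_alleles, drop, ploidy = 2L) {
  keep <- setdiff(seq_len(n_alleles) - 1L, drop)
  if (ploidy == 1L) return(pl[keep + 1L])
  out <- integer(n_genotypes(length(keep), 2L))
  for (k2 in seq_along(keep)) {
    for (j2 in seq_len(k2)) {
      out[genotype_index(j2 - 1L, k2 - 1L) + 1L] <-
        pl[genotype_index(min(keep[j2], keep[k2]), max(keep[j2], keep[k2])) + 1L]
    }
  }
  out
}

parse_info_string <- function(info) {
  if (is.na(info) || info == "." || info == "") return(character())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  has_eq <- grepl("=", parts, fixed = TRUE)
  vals <- ifelse(has_eq, sub("^[^=]*=", "", parts), NA_character_)
  names(vals) <- sub("=.*$", "", parts)
  vals
}

render_info_string <- function(kv) {
  if (!length(kv)) return(".")
  paste(ifelse(is.na(kv), names(kv), paste0(names(kv), "=", kv)), collapse = ";")
}

#' Import a single-sample GVCF as an SVCR dataset
#'
#' Homozygous-reference rows (all called GT alleles equal to the reference)
#' become reference blocks with `LEN = END - POS + 1` (rows without an END
#' key get `LEN = nchar(REF)`).  Variant rows become variant sites with one
#' genotype entry whose LA is the identity map and whose LGT/LAD/LPL are the
#' row's GT/AD/PL verbatim; remaining INFO keys are kept per sample in
#' `gvcf_info`.
#'
#' Under `non_ref_policy = "drop"` the sample-local `<NON_REF>` allele is
#' removed from variant rows: its AD entry and every PL entry involving it
#' are deleted and the remaining alleles renumbered.  `"retain"` keeps it,
#' which is what makes the conversion exactly invertible.
#'
#' @param g a `gvcf` object from [read_gvcf()], or a file path.
#' @param sample_id sample name (defaults to the GVCF's).
#' @param non_ref_policy `"drop"` or `"retain"`.
#' @return an `svcr_dataset` with one sample.
#' @export
import_gvcf <- function(g, sample_id = NULL, non_ref_policy = c("drop", "retain")) {
  non_ref_policy <- match.arg(non_ref_policy)
  if (is.character(g)) g <- read_gvcf(g)
  if (is.null(sample_id)) sample_id <- g$sample
  rec <- g$records
  n <- nrow(rec)

  if (n) {
    r <- match(rec$chrom, g$contigs)
    if (anyNA(r)) stop("record on contig absent from header contig list")
    key <- r * 2^32 + rec$pos
    if (is.unsorted(key, strictly = TRUE))
      stop("GVCF records are not sorted (or repeat a locus); first breach near ",
           rec$chrom[which(diff(key) <= 0)[1L] + 1L], ":",
           rec$pos[which(diff(key) <= 0)[1L] + 1L])
  }

  gt_alleles <- lapply(rec$gt, function(g2) parse_call(g2)$alleles)
  if (any(is.na(rec$gt)))
    stop("record without GT at ", rec$chrom[is.na(rec$gt)][1L], ":",
         rec$pos[is.na(rec$gt)][1L])
  is_ref <- vapply(gt_alleles, function(a) length(a) > 0 && all(!is.na(a)) && all(a == 0L),
                   logical(1))

  # ---- reference rows -> blocks
  ridx <- which(is_ref)
  ref_rows <- lapply(ridx, function(i) {
    if (!is.na(rec$end[i]) && rec$end[i] < rec$pos[i])
      stop("END < POS at ", rec$chrom[i], ":", rec$pos[i])
    len <- if (!is.na(rec$end[i])) rec$end[i] - rec$pos[i] + 1L else nchar(rec$ref[i])
    info_kv <- parse_info_string(rec$info[i])
    had_end <- "END" %in% names(info_kv)
    info_extra <- info_kv[setdiff(names(info_kv), "END")]
    meta <- c(id = rec$id[i], qual = rec$qual[i], filter = rec$filter[i],
              alt = rec$alt[i], format = rec$format[i],
              had_end = if (had_end) "1" else "0",
              info_extra = render_info_string(info_extra),
              min_dp = if (is.na(rec$min_dp[i])) NA_character_ else as.character(rec$min_dp[i]))
    if (non_ref_policy == "retain") {
      meta <- c(meta, ad = render_int_array(rec$ad[[i]]),
                pl = render_int_array(rec$pl[[i]]))
    }
    list(contig = rec$chrom[i], pos = rec$pos[i], len = len,
         dp = rec$dp[i], gq = rec$gq[i], lgt = rec$gt[i],
         ref_base = rec$ref[i], meta = meta)
  })

  # ---- variant rows -> sites + entries
  vidx <- which(!is_ref)
  sites <- vector("list", length(vidx))
  entries <- vector("list", length(vidx))
  for (s in seq_along(vidx)) {
    i <- vidx[s]
    alts <- strsplit(rec$alt[i], ",", fixed = TRUE)[[1]]
    alts <- alts[alts != "."]
    n_all <- length(alts) + 1L
    gt <- parse_call(rec$gt[i])
    ploidy <- length(gt$alleles)
    if (!ploidy %in% c(1L, 2L))
      stop("unsupported ploidy ", ploidy, " at ", rec$chrom[i], ":", rec$pos[i])
    ad <- rec$ad[[i]]; pl <- rec$pl[[i]]
    if (!is.null(ad) && length(ad) != n_all)
      stop("AD length ", length(ad), " != ", n_all, " alleles at ",
           rec$chrom[i], ":", rec$pos[i])
    if (!is.null(pl) && length(pl) != n_genotypes(n_all, ploidy))
      stop("PL length ", length(pl), " != ", n_genotypes(n_all, ploidy), " at ",
           rec$chrom[i], ":", rec$pos[i])
    if (non_ref_policy == "drop") {
      nri <- which(alts == "<NON_REF>")
      if (length(nri)) {
        if (any(gt$alleles %in% nri))
          stop("GT calls <NON_REF> at ", rec$chrom[i], ":", rec$pos[i],
               "; cannot drop it")
        if (!is.null(ad)) ad <- ad[-(nri + 1L)]
        if (!is.null(pl)) pl <- pl_drop_allele(pl, n_all, nri, ploidy)
        alts <- alts[-nri]
        n_all <- n_all - 1L
      }
    }
    info_kv <- parse_info_string(rec$info[i])
    meta <- c(id = rec$id[i], qual = rec$qual[i], filter = rec$filter[i],
              format = rec$format[i],
              min_dp = if (is.na(rec$min_dp[i])) NA_character_ else as.character(rec$min_dp[i]))
    sites[[s]] <- list(contig = rec$chrom[i], pos = rec$pos[i],
                       ref = rec$ref[i], alts = alts)
    entries[[s]] <- list(contig = rec$chrom[i], pos = rec$pos[i],
                         la = seq_len(n_all) - 1L, lgt = rec$gt[i],
                         lad = ad, lpl = pl, dp = rec$dp[i], gq = rec$gq[i],
                         gvcf_info = info_kv, meta = meta)
  }

  ref <- if (length(ref_rows)) {
    data.frame(contig = vapply(ref_rows, `[[`, character(1), "contig"),
               pos = vapply(ref_rows, `[[`, integer(1), "pos"),
               sample = sample_id,
               len = vapply(ref_rows, `[[`, integer(1), "len"),
               dp = vapply(ref_rows, `[[`, integer(1), "dp"),
               gq = vapply(ref_rows, `[[`, integer(1), "gq"),
               lgt = vapply(ref_rows, `[[`, character(1), "lgt"),
               ref_base = vapply(ref_rows, `[[`, character(1), "ref_base"),
               meta = I(lapply(ref_rows, `[[`, "meta")),
               stringsAsFactors = FALSE)
  } else empty_ref_table()

  site_tab <- if (length(sites)) {
    data.frame(contig = vapply(sites, `[[`, character(1), "contig"),
               pos = vapply(sites, `[[`, integer(1), "pos"),
               ref = vapply(sites, `[[`, character(1), "ref"),
               alts = I(lapply(sites, `[[`, "alts")),
               stringsAsFactors = FALSE)
  } else empty_site_table()

  entry_tab <- if (length(entries)) {
    data.frame(contig = vapply(entries, `[[`, character(1), "contig"),
               pos = vapply(entries, `[[`, integer(1), "pos"),
               sample = sample_id,
               la = I(lapply(entries, `[[`, "la")),
               lgt = vapply(entries, `[[`, character(1), "lgt"),
               lad = I(lapply(entries, `[[`, "lad")),
               lpl = I(lapply(entries, `[[`, "lpl")),
               dp = vapply(entries, `[[`, integer(1), "dp"),
               gq = vapply(entries, `[[`, integer(1), "gq"),
               gvcf_info = I(lapply(entries, `[[`, "gvcf_info")),
               meta = I(lapply(entries, `[[`, "meta")),
               stringsAsFactors = FALSE)
  } else empty_entry_table()

  svcr_dataset(samples = sample_id, contigs = g$contigs, ref = ref,
               sites = site_tab, entries = entry_tab,
               max_ref_block_length = if (nrow(ref)) max(ref$len) else 0L,
               header_meta = g$meta)
}

#' Export a single-sample SVCR dataset as a GVCF
#'
#' The inverse of [import_gvcf()]: reference blocks become END-tagged
#' homozygous-reference rows, variant entries become variant rows with the
#' local fields un-prefixed.  Under policy `"retain"` every entry's LA must
#' be the identity map (anything else would silently reorder alleles and be
#' lossy); datasets that went through merging should be passed through
#' [subset_samples()] and [prune_alleles()] first.
#'
#' @param ds a single-sample `svcr_dataset`.
#' @param non_ref_policy `"retain"` (default, exact inverse) or `"drop"`
#'   (additionally removes `<NON_REF>` from variant rows).
#' @return a `gvcf` object.
#' @export
export_gvcf <- function(ds, non_ref_policy = c("retain", "drop")) {
  non_ref_policy <- match.arg(non_ref_policy)
  if (length(ds$samples) != 1L)
    stop("export_gvcf requires a single-sample dataset (got ",
         length(ds$samples), " samples)")
  sample_id <- ds$samples

  meta_get <- function(m, key, default = ".") {
    if (!is.null(m) && key %in% names(m) && !is.na(m[[key]])) m[[key]] else default
  }

  rows <- list()
  # reference blocks -> reference rows
  for (i in seq_len(nrow(ds$ref))) {
    b <- ds$ref[i, ]
    m <- b$meta[[1L]]
    had_end <- meta_get(m, "had_end", "1") == "1" || b$len != nchar(b$ref_base)
    extra <- meta_get(m, "info_extra", ".")
    info_parts <- c(if (had_end) paste0("END=", b$pos + b$len - 1L),
                    if (extra != ".") extra)
    fmt <- meta_get(m, "format", "GT:DP:GQ")
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = b$contig, pos = b$pos, id = meta_get(m, "id"),
      ref = b$ref_base, alt = meta_get(m, "alt", "<NON_REF>"),
      qual = meta_get(m, "qual"), filter = meta_get(m, "filter"),
      info = if (length(info_parts)) paste(info_parts, collapse = ";") else ".",
      format = fmt, value = NA_character_,
      gt = if (is.na(b$lgt)) "0/0" else b$lgt,
      ad = I(list(parse_int_array(meta_get(m, "ad", NA_character_)))),
      pl = I(list(parse_int_array(meta_get(m, "pl", NA_character_)))),
      dp = b$dp, gq = b$gq,
      min_dp = as.integer(meta_get(m, "min_dp", NA_character_)),
      end = if (had_end) b$pos + b$len - 1L else NA_integer_,
      stringsAsFactors = FALSE)
  }

  # variant entries -> variant rows
  site_key <- locus_key(ds$sites$contig, ds$sites$pos)
  for (i in seq_len(nrow(ds$entries))) {
    e <- ds$entries[i, ]
    s <- match(locus_key(e$contig, e$pos), site_key)
    alts <- ds$sites$alts[[s]]
    la <- e$la[[1L]]
    lgt <- e$lgt; lad <- e$lad[[1L]]; lpl <- e$lpl[[1L]]
    if (!identical(as.integer(la), seq_along(la) - 1L) ||
        length(la) != length(alts) + 1L) {
      stop("entry at ", e$contig, ":", e$pos, " has non-identity LA [",
           paste(la, collapse = ","),
           "]; run prune_alleles() before export (refusing a lossy export)")
    }
    if (non_ref_policy == "drop") {
      nri <- which(alts == "<NON_REF>")
      if (length(nri)) {
        gt <- parse_call(lgt)
        if (any(gt$alleles %in% nri))
          stop("LGT calls <NON_REF> at ", e$contig, ":", e$pos)
        if (!is.null(lad)) lad <- lad[-(nri + 1L)]
        if (!is.null(lpl)) lpl <- pl_drop_allele(lpl, length(alts) + 1L, nri,
                                                 call_ploidy(lgt))
        alts <- alts[-nri]
      }
    }
    m <- e$meta[[1L]]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = e$contig, pos = e$pos, id = meta_get(m, "id"),
      ref = ds$sites$ref[s], alt = if (length(alts)) paste(alts, collapse = ",") else ".",
      qual = meta_get(m, "qual"), filter = meta_get(m, "filter"),
      info = render_info_string(e$gvcf_info[[1L]]),
      format = meta_get(m, "format", "GT:AD:PL:DP:GQ"), value = NA_character_,
      gt = lgt, ad = I(list(lad)), pl = I(list(lpl)), dp = e$dp, gq = e$gq,
      min_dp = as.integer(meta_get(m, "min_dp", NA_character_)),
      end = NA_integer_, stringsAsFactors = FALSE)
  }

  rec <- if (length(rows)) do.call(rbind, rows) else parse_gvcf_body(character())
  if (nrow(rec)) {
    rec <- rec[locus_order(rec$chrom, rec$pos, ds$contigs), , drop = FALSE]
    rownames(rec) <- NULL
    rec$value <- render_gvcf_value(rec)
  }
  meta <- if (!is.null(ds$header_meta)) ds$header_meta else
    default_gvcf_meta(sample_id, ds$contigs)
  structure(list(sample = sample_id, contigs = ds$contigs, meta = meta,
                 records = rec), class = "gvcf")
}
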