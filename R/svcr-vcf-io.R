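# SVCR-VCF serialization: VCF 4.3 text with the two required FORMAT fields,
# LA (array of integers) and LEN (integer), plus LGT/LAD/LPL.  Reference
# blocks carry a nonmissing LEN and missing LA/LAD/LPL; variant genotypes the
# reverse.  The longest block length is recorded in the header under
# MAXIMUM_REFERENCE_BLOCK_LENGTH.

SVCR_FORMAT <- "LGT:LA:LEN:LAD:LPL:DP:GQ"

svcr_vcf_header <- function(ds, contig_lengths = NULL) {
  lens <- if (is.null(contig_lengths)) rep(NA_integer_, length(ds$contigs)) else contig_lengths
  contig_lines <- ifelse(is.na(lens),
    sprintf("##contig=<ID=%s>", ds$contigs),
    sprintf("##contig=<ID=%s,length=%d>", ds$contigs, lens))
  c("##fileformat=VCFv4.3",
    sprintf("##MAXIMUM_REFERENCE_BLOCK_LENGTH=%d", ds$max_ref_block_length),
    contig_lines,
    "##ALT=<ID=NON_REF,Description=\"Represents any possible alternative allele not already represented at this location by REF and ALT\">",
    "##FORMAT=<ID=LGT,Number=1,Type=String,Description=\"Genotype over local allele indices\">",
    "##FORMAT=<ID=LA,Number=.,Type=Integer,Description=\"Local alleles: injective map from local to global allele indices, first element 0\">",
    "##FORMAT=<ID=LEN,Number=1,Type=Integer,Description=\"Reference block length in base pairs\">",
    "##FORMAT=<ID=LAD,Number=.,Type=Integer,Description=\"Allelic depths over local alleles (LR-numbered)\">",
    "##FORMAT=<ID=LPL,Number=.,Type=Integer,Description=\"Phred-scaled genotype likelihoods over local alleles (LG-numbered)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$samples), collapse = "\t"))
}

#' Write an SVCR dataset as SVCR-VCF
#'
#' One data row per locus appearing in either matrix.  A sample's block
#' start is stored in that row with a nonmissing LEN; variant genotypes have
#' missing LEN and nonmissing LA.  Rows that exist only for block starts
#' carry `ALT=.`.  Output is byte-stable: writing the same dataset twice
#' produces identical text.
#'
#' @param ds a valid `svcr_dataset` (validated before writing).
#' @param path output path; ".gz" selects gzip compression.
#' @param emit_block_lgt also write LGT on reference blocks (default off;
#'   blocks may, but need not, carry a genotype).
#' @return `path`, invisibly.
#' @export
write_svcr_vcf <- function(ds, path, emit_block_lgt = FALSE) {
  assert_valid(ds)
  lines <- c(svcr_vcf_header(ds), render_svcr_body(ds, emit_block_lgt))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

render_svcr_body <- function(ds, emit_block_lgt = FALSE) {
  loci <- unique(rbind(ds$sites[c("contig", "pos")], ds$ref[c("contig", "pos")]))
  if (!nrow(loci)) return(character())
  loci <- loci[locus_order(loci$contig, loci$pos, ds$contigs), , drop = FALSE]
  key <- locus_key(loci$contig, loci$pos)
  site_at <- match(key, locus_key(ds$sites$contig, ds$sites$pos))
  ent_by <- split(seq_len(nrow(ds$entries)),
                  locus_key(ds$entries$contig, ds$entries$pos))
  ref_by <- split(seq_len(nrow(ds$ref)), locus_key(ds$ref$contig, ds$ref$pos))

  vapply(seq_len(nrow(loci)), function(i) {
    s <- site_at[i]
    ref_rows <- ds$ref[ref_by[[key[i]]], , drop = FALSE]
    ent_rows <- ds$entries[ent_by[[key[i]]], , drop = FALSE]
    ref_allele <- if (!is.na(s)) ds$sites$ref[s] else
      if (nrow(ref_rows) && !is.na(ref_rows$ref_base[1L])) ref_rows$ref_base[1L] else "N"
    alt <- if (!is.na(s) && length(ds$sites$alts[[s]]))
      paste(ds$sites$alts[[s]], collapse = ",") else "."
    vals <- vapply(ds$samples, function(smp) {
      e <- ent_rows[ent_rows$sample == smp, , drop = FALSE]
      b <- ref_rows[ref_rows$sample == smp, , drop = FALSE]
      if (nrow(e)) {
        paste(c(e$lgt[1L], paste(e$la[[1L]], collapse = ","), ".",
                render_int_array(e$lad[[1L]]), render_int_array(e$lpl[[1L]]),
                if (is.na(e$dp[1L])) "." else e$dp[1L],
                if (is.na(e$gq[1L])) "." else e$gq[1L]), collapse = ":")
      } else if (nrow(b)) {
        paste(c(if (emit_block_lgt && !is.na(b$lgt[1L])) b$lgt[1L] else ".",
                ".", b$len[1L], ".", ".",
                if (is.na(b$dp[1L])) "." else b$dp[1L],
                if (is.na(b$gq[1L])) "." else b$gq[1L]), collapse = ":")
      } else "."
    }, character(1))
    paste(c(loci$contig[i], loci$pos[i], ".", ref_allele, alt, ".", ".", ".",
            SVCR_FORMAT, vals), collapse = "\t")
  }, character(1))
}

#' Read an SVCR-VCF file back into an SVCR dataset
#'
#' Reconstructs both matrices from the LEN/LA dichotomy, takes
#' `max_ref_block_length` from the header (verifying it against the blocks
#' actually present, else computing it), and enforces the representation's
#' encoding rules: LEN and LA may not both be present in one genotype, and a
#' sample may not have any nonmissing FORMAT data at a locus strictly inside
#' one of its reference blocks.
#'
#' @param path an SVCR-VCF file (plain or gzip).
#' @return an `svcr_dataset`.
#' @export
read_svcr_vcf <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  meta <- lines[startsWith(lines, "##")]
  header <- lines[startsWith(lines, "#CHROM")]
  if (length(header) != 1L) stop("not a VCF: missing #CHROM header")
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  if (!any(grepl("^##FORMAT=<ID=LA,", meta)) || !any(grepl("^##FORMAT=<ID=LEN,", meta)))
    stop("not an SVCR-VCF: header must declare the LA and LEN FORMAT fields")
  contigs <- regmatches(meta, regexpr("(?<=##contig=<ID=)[^,>]+", meta, perl = TRUE))
  max_len_hdr <- suppressWarnings(as.integer(sub("##MAXIMUM_REFERENCE_BLOCK_LENGTH=", "",
    grep("^##MAXIMUM_REFERENCE_BLOCK_LENGTH=", meta, value = TRUE))))

  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  ref_rows <- list(); site_rows <- list(); entry_rows <- list()
  for (line in body) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    contig <- f[1L]; pos <- as.integer(f[2L]); ref_allele <- f[4L]
    alts <- if (f[5L] == ".") character() else strsplit(f[5L], ",", fixed = TRUE)[[1]]
    fkeys <- strsplit(f[9L], ":", fixed = TRUE)[[1]]
    any_entry <- FALSE
    for (j in seq_along(samples)) {
      raw <- f[9L + j]
      if (raw == ".") next
      vv <- strsplit(raw, ":", fixed = TRUE)[[1]]
      get <- function(key) {
        idx <- match(key, fkeys)
        if (is.na(idx) || idx > length(vv) || vv[idx] == ".") NA_character_ else vv[idx]
      }
      len <- as.integer(get("LEN")); la_raw <- get("LA")
      if (!is.na(len) && !is.na(la_raw))
        stop("sample ", samples[j], " at ", contig, ":", pos,
             " has both LEN and LA — a genotype is a block or a variant, not both")
      if (!is.na(len)) {
        ref_rows[[length(ref_rows) + 1L]] <- list(
          contig = contig, pos = pos, sample = samples[j], len = len,
          dp = as.integer(get("DP")), gq = as.integer(get("GQ")),
          lgt = get("LGT"), ref_base = substr(ref_allele, 1L, 1L))
      } else if (!is.na(la_raw)) {
        entry_rows[[length(entry_rows) + 1L]] <- list(
          contig = contig, pos = pos, sample = samples[j],
          la = parse_int_array(la_raw), lgt = get("LGT"),
          lad = parse_int_array(get("LAD") %||% NA_character_),
          lpl = parse_int_array(get("LPL") %||% NA_character_),
          dp = as.integer(get("DP")), gq = as.integer(get("GQ")))
        any_entry <- TRUE
      } else {
        stop("sample ", samples[j], " at ", contig, ":", pos,
             " has FORMAT data but neither LEN nor LA")
      }
    }
    if (length(alts))
      site_rows[[length(site_rows) + 1L]] <- list(contig = contig, pos = pos,
                                                  ref = ref_allele, alts = alts)
  }

  ref <- if (length(ref_rows)) data.frame(
    contig = vapply(ref_rows, `[[`, character(1), "contig"),
    pos = vapply(ref_rows, `[[`, integer(1), "pos"),
    sample = vapply(ref_rows, `[[`, character(1), "sample"),
    len = vapply(ref_rows, `[[`, integer(1), "len"),
    dp = vapply(ref_rows, `[[`, integer(1), "dp"),
    gq = vapply(ref_rows, `[[`, integer(1), "gq"),
    lgt = vapply(ref_rows, `[[`, character(1), "lgt"),
    ref_base = vapply(ref_rows, `[[`, character(1), "ref_base"),
    meta = I(rep(list(NULL), length(ref_rows))), stringsAsFactors = FALSE)
    else empty_ref_table()
  sites <- if (length(site_rows)) data.frame(
    contig = vapply(site_rows, `[[`, character(1), "contig"),
    pos = vapply(site_rows, `[[`, integer(1), "pos"),
    ref = vapply(site_rows, `[[`, character(1), "ref"),
    alts = I(lapply(site_rows, `[[`, "alts")), stringsAsFactors = FALSE)
    else empty_site_table()
  entries <- if (length(entry_rows)) data.frame(
    contig = vapply(entry_rows, `[[`, character(1), "contig"),
    pos = vapply(entry_rows, `[[`, integer(1), "pos"),
    sample = vapply(entry_rows, `[[`, character(1), "sample"),
    la = I(lapply(entry_rows, `[[`, "la")),
    lgt = vapply(entry_rows, `[[`, character(1), "lgt"),
    lad = I(lapply(entry_rows, `[[`, "lad")),
    lpl = I(lapply(entry_rows, `[[`, "lpl")),
    dp = vapply(entry_rows, `[[`, integer(1), "dp"),
    gq = vapply(entry_rows, `[[`, integer(1), "gq"),
    gvcf_info = I(rep(list(character()), length(entry_rows))),
    meta = I(rep(list(NULL), length(entry_rows))), stringsAsFactors = FALSE)
    else empty_entry_table()

  actual_max <- if (nrow(ref)) max(ref$len) else 0L
  if (length(max_len_hdr) && !is.na(max_len_hdr)) {
    if (max_len_hdr < actual_max)
      stop("header MAXIMUM_REFERENCE_BLOCK_LENGTH=", max_len_hdr,
           " is smaller than an actual block length ", actual_max)
    max_len <- max_len_hdr
  } else max_len <- actual_max

  if (!length(contigs)) contigs <- unique(c(ref$contig, sites$contig))
  ds <- svcr_dataset(samples = samples, contigs = contigs, ref = ref,
                     sites = sites, entries = entries,
                     max_ref_block_length = max_len)

  # no FORMAT data strictly inside another of the sample's blocks
  occupied <- rbind(ds$ref[c("contig", "pos", "sample")],
                    ds$entries[c("contig", "pos", "sample")])
  for (i in seq_len(nrow(ds$ref))) {
    b <- ds$ref[i, ]
    if (b$len < 2L) next
    inside <- occupied$sample == b$sample & occupied$contig == b$contig &
      occupied$pos > b$pos & occupied$pos <= b$pos + b$len - 1L
    if (any(inside))
      stop("sample ", b$sample, " has FORMAT data at ", b$contig, ":",
           occupied$pos[inside][1L], ", strictly inside its reference block [",
           b$pos, ",", b$pos + b$len - 1L, "]")
  }
  ds
}

#' Export a hardcalls PVCF
#'
#' A dense project VCF with no A-, R-, or G-numbered FORMAT fields and no
#' reference blocks: one row per variant site, FORMAT is GT only.  Genotypes
#' are globally indexed via the LA projection; samples covered only by a
#' reference block are written hom-ref; uncovered samples are missing.
#'
#' @param ds an `svcr_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_hardcalls_pvcf <- function(ds, path) {
  rows <- densify_stream(ds)
  lines <- c("##fileformat=VCFv4.3",
             sprintf("##contig=<ID=%s>", ds$contigs),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ds$samples), collapse = "\t"),
             vapply(rows, function(r) {
               paste(c(r$contig, r$pos, ".", r$ref,
                       if (length(r$alts)) paste(r$alts, collapse = ",") else ".",
                       ".", ".", ".", "GT",
                       vapply(r$calls, `[[`, character(1), "gt")), collapse = "\t")
             }, character(1)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Export a dense PVCF with quality fields
#'
#' Streaming densification rendered as a conventional PVCF with
#' GT:AD:PL:DP:GQ.  Dense output grows super-linearly in samples by design;
#' intended for small regions and verification.
#'
#' @param ds an `svcr_dataset`.
#' @param path output path.
#' @param fill string written for PL entries of genotypes involving alleles
#'   the sample did not observe (default ".", or a numeric sentinel).
#' @param region optional `list(contig=, start=, end=)` passed to
#'   [densify_stream()].
#' @return `path`, invisibly.
#' @export
export_dense_pvcf <- function(ds, path, fill = ".", region = NULL) {
  rows <- densify_stream(ds, region = region)
  render <- function(x) {
    if (is.null(x)) "." else paste(ifelse(is.na(x), fill, as.character(x)),
                                   collapse = ",")
  }
  lines <- c("##fileformat=VCFv4.3",
             sprintf("##contig=<ID=%s>", ds$contigs),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
             "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ds$samples), collapse = "\t"),
             vapply(rows, function(r) {
               vals <- vapply(r$calls, function(x) {
                 paste(c(x$gt, render(x$ad), render(x$pl),
                         if (is.na(x$dp %||% NA)) "." else x$dp,
                         if (is.na(x$gq %||% NA)) "." else x$gq), collapse = ":")
               }, character(1))
               paste(c(r$contig, r$pos, ".", r$ref,
                       if (length(r$alts)) paste(r$alts, collapse = ",") else ".",
                       ".", ".", ".", "GT:AD:PL:DP:GQ", vals), collapse = "\t")
             }, character(1)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
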