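# Reading and writing single-sample GVCF text.
#
# A GVCF here is a list(sample, contigs, meta, records) where `records` is a
# data frame with the raw VCF columns plus typed views of the FORMAT fields
# this toolkit models (GT, AD, PL, DP, GQ) and the END INFO key.  The raw
# per-record strings are regenerated canonically on write (integers plain,
# arrays comma-joined, missing "."), which makes read -> write byte-stable
# for canonically formatted inputs.

GVCF_FORMAT_KEYS <- c("GT", "AD", "PL", "DP", "GQ", "MIN_DP")

#' Read a single-sample GVCF
#'
#' Accepts plain or gzip/bgzip-compressed VCF 4.2/4.3 text with the GVCF
#' dialect: END-tagged homozygous-reference rows and the `<NON_REF>`
#' symbolic allele.  FORMAT keys are restricted to GT, AD, PL, DP, GQ and
#' MIN_DP; others are rejected rather than silently dropped.
#'
#' @param path file path (".gz" handled transparently) .
#' @return a `gvcf` object: `list(sample, contigs, meta, records)`.
#' @export
read_gvcf <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  parse_gvcf_lines(lines)
}

parse_gvcf_lines <- function(lines) {
  meta <- lines[startsWith(lines, "##")]
  header <- lines[startsWith(lines, "#CHROM")]
  if (length(header) != 1L) stop("GVCF must have exactly one #CHROM header line")
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if (length(cols) != 10L) stop("expected a single-sample GVCF (10 columns), got ",
                                length(cols))
  sample <- cols[10L]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  contig_meta <- regmatches(meta, regexpr("(?<=##contig=<ID=)[^,>]+", meta, perl = TRUE))
  rec <- parse_gvcf_body(body)
  contigs <- if (length(contig_meta)) contig_meta else unique(rec$chrom)
  structure(list(sample = sample, contigs = contigs, meta = meta, records = rec),
            class = "gvcf")
}

parse_gvcf_body <- function(body) {
  if (!length(body)) {
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(), qual = character(),
                      filter = character(), info = character(), format = character(),
                      value = character(), gt = character(), ad = I(list()),
                      pl = I(list()), dp = integer(), gq = integer(),
                      min_dp = integer(), end = integer(), stringsAsFactors = FALSE))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) != 10L)) stop("malformed GVCF data line (expected 10 fields)")
  m <- matrix(unlist(f), ncol = 10L, byrow = TRUE)
  rec <- data.frame(chrom = m[, 1L], pos = as.integer(m[, 2L]), id = m[, 3L],
                    ref = m[, 4L], alt = m[, 5L], qual = m[, 6L], filter = m[, 7L],
                    info = m[, 8L], format = m[, 9L], value = m[, 10L],
                    stringsAsFactors = FALSE)
  has_end <- grepl("(^|;)END=[0-9]+", rec$info)
  end <- rep(NA_integer_, nrow(rec))
  end[has_end] <- as.integer(sub(".*?(^|;)END=([0-9]+).*", "\\2", rec$info[has_end],
                                 perl = TRUE))
  rec$end <- end

  fkeys <- strsplit(rec$format, ":", fixed = TRUE)
  vvals <- strsplit(rec$value, ":", fixed = TRUE)
  bad <- vapply(fkeys, function(k) any(!k %in% GVCF_FORMAT_KEYS), logical(1))
  if (any(bad))
    stop("unsupported FORMAT key(s) at ", rec$chrom[bad][1L], ":", rec$pos[bad][1L],
         " — supported: ", paste(GVCF_FORMAT_KEYS, collapse = ","))
  get_key <- function(i, key) {
    j <- match(key, fkeys[[i]])
    if (is.na(j) || j > length(vvals[[i]])) NA_character_ else {
      v <- vvals[[i]][j]
      if (v == ".") NA_character_ else v
    }
  }
  n <- nrow(rec)
  rec$gt <- vapply(seq_len(n), get_key, character(1), key = "GT")
  rec$ad <- I(lapply(seq_len(n), function(i) parse_int_array(get_key(i, "AD"))))
  rec$pl <- I(lapply(seq_len(n), function(i) parse_int_array(get_key(i, "PL"))))
  rec$dp <- as.integer(vapply(seq_len(n), get_key, character(1), key = "DP"))
  rec$gq <- as.integer(vapply(seq_len(n), get_key, character(1), key = "GQ"))
  rec$min_dp <- as.integer(vapply(seq_len(n), get_key, character(1), key = "MIN_DP"))
  rec
}

parse_int_array <- function(x) {
  if (is.null(x) || is.na(x) || x == ".") return(NULL)
  as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

render_int_array <- function(x) {
  if (is.null(x) || !length(x)) "." else paste(x, collapse = ",")
}

# Render the per-sample value column from typed fields, honoring each
# record's FORMAT key order.
render_gvcf_value <- function(rec) {
  fkeys <- strsplit(rec$format, ":", fixed = TRUE)
  vapply(seq_len(nrow(rec)), function(i) {
    vals <- vapply(fkeys[[i]], function(k) {
      switch(k,
        GT = if (is.na(rec$gt[i])) "." else rec$gt[i],
        AD = render_int_array(rec$ad[[i]]),
        PL = render_int_array(rec$pl[[i]]),
        DP = if (is.na(rec$dp[i])) "." else as.character(rec$dp[i]),
        GQ = if (is.na(rec$gq[i])) "." else as.character(rec$gq[i]),
        MIN_DP = if (is.na(rec$min_dp[i])) "." else as.character(rec$min_dp[i]),
        stop("unsupported FORMAT key: ", k))
    }, character(1))
    paste(vals, collapse = ":")
  }, character(1))
}

render_gvcf_lines <- function(g) {
  rec <- g$records
  value <- render_gvcf_value(rec)
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", g$sample), collapse = "\t")
  body <- if (nrow(rec)) {
    paste(rec$chrom, rec$pos, rec$id, rec$ref, rec$alt, rec$qual, rec$filter,
          rec$info, rec$format, value, sep = "\t")
  } else character()
  c(g$meta, header, body)
}

#' Write a single-sample GVCF
#'
#' @param g a `gvcf` object.
#' @param path output path; a ".gz" suffix selects gzip compression.
#' @return `path`, invisibly.
#' @export
write_gvcf <- function(g, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(render_gvcf_lines(g), con)
  invisible(path)
}

default_gvcf_meta <- function(sample, contigs, contig_lengths = NULL) {
  lens <- if (is.null(contig_lengths)) rep(NA_integer_, length(contigs)) else contig_lengths
  contig_lines <- ifelse(is.na(lens),
    sprintf("##contig=<ID=%s>", contigs),
    sprintf("##contig=<ID=%s,length=%d>", contigs, lens))
  c("##fileformat=VCFv4.2",
    "##ALT=<ID=NON_REF,Description=\"Represents any possible alternative allele not already represented at this location by REF and ALT\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Stop position of the interval\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=MIN_DP,Number=1,Type=Integer,Description=\"Minimum depth in the reference block\">",
    contig_lines)
}
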