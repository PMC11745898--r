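#' svcr: Scalable Variant Call Representation toolkit
#'
#' The SVCR is a multi-sample generalization of the GVCF.  Two techniques give
#' it linear size scaling in the number of samples: run-length encoded
#' *reference blocks* (a per-sample interval of homozygous-reference calls
#' stored once, at its start locus, with a LEN field and summary DP/GQ) and
#' *local allele indexing* (per-sample allele-indexed fields expressed over
#' the small set of alleles that sample actually observed, connected to the
#' site's global allele list by an injective LA map).
#'
#' The main entry points are [import_gvcf()] / [export_gvcf()] for lossless
#' single-sample conversion, [merge_datasets()] for N+K combining,
#' [split_size_threshold()] / [split_fixed_period()] for bounding block
#' length, [densify_stream()] / [densify_at_locus()] for recovering dense
#' project-level rows, [write_svcr_vcf()] / [read_svcr_vcf()] for
#' serialization, and [simulate_cohort()] / [fit_loglog()] for synthetic
#' scaling experiments.
#'
#' @name svcr-package
"_PACKAGE"

# ---- genotype / allele index arithmetic --------------------------------------

#' Number of genotype configurations for a given allele count and ploidy
#'
#' For diploid calls the count is `n*(n+1)/2`; for haploid calls it is `n`.
#' This is the "G number" of the VCF specification and equally the "LG
#' number" when `n_alleles` counts local alleles.
#'
#' @param n_alleles number of alleles, including the reference (>= 1).
#' @param ploidy 1 or 2.
#' @return integer genotype count.
#' @export
n_genotypes <- function(n_alleles, ploidy = 2L) {
  stopifnot(is.numeric(n_alleles), n_alleles >= 1)
  n <- as.integer(n_alleles)
  if (length(ploidy) != 1L || !ploidy %in% c(1L, 2L))
    stop("unsupported ploidy: ", paste(ploidy, collapse = ","),
         " (only 1 and 2 are supported)")
  if (ploidy == 1L) n else (n * (n + 1L)) %/% 2L
}

#' Position of an unordered diploid genotype in G-ordered arrays
#'
#' VCF orders diploid genotype-indexed arrays (e.g. PL) by enumerating allele
#' pairs `j <= k` with `k` increasing, then `j`: the entry for alleles
#' `(j, k)` sits at `k*(k+1)/2 + j`.
#'
#' @param allele_j,allele_k 0-based allele indices with `allele_j <= allele_k`.
#' @return 0-based position in the G-ordered array (vectorized).
#' @export
genotype_index <- function(allele_j, allele_k) {
  j <- as.integer(allele_j); k <- as.integer(allele_k)
  if (any(j < 0L) || any(k < 0L)) stop("allele indices must be >= 0")
  if (any(j > k)) stop("genotype_index requires allele_j <= allele_k; canonicalize the pair first")
  (k * (k + 1L)) %/% 2L + j
}

#' Expected length of a FORMAT array under a Number code
#'
#' Supports the classic VCF codes `A`, `R`, `G`, `1` and the local-allele
#' codes `LA` (alternate local alleles), `LR` (local alleles including the
#' reference, e.g. LAD) and `LG` (local genotype configurations, e.g. LPL).
#'
#' @param number_code one of "LA","LR","LG","A","R","G","1".
#' @param n_local number of local alleles including the reference.
#' @param n_global number of global alleles including the reference.
#' @param ploidy 1 or 2.
#' @return expected integer array length.
#' @export
expected_length <- function(number_code, n_local, n_global, ploidy = 2L) {
  stopifnot(n_local >= 1, n_global >= 1)
  switch(as.character(number_code),
    "LA" = as.integer(n_local) - 1L,
    "LR" = as.integer(n_local),
    "LG" = n_genotypes(n_local, ploidy),
    "A"  = as.integer(n_global) - 1L,
    "R"  = as.integer(n_global),
    "G"  = n_genotypes(n_global, ploidy),
    "1"  = 1L,
    stop("unknown Number code: ", number_code))
}

# ---- genotype-call strings ---------------------------------------------------

# A genotype call (GT/LGT) is kept as its VCF string ("0/1", "0|2", "1").
# parse_call() returns list(alleles = integer (NA for "."), phased = logical).
parse_call <- function(gt) {
  if (is.na(gt) || gt == ".") return(list(alleles = NA_integer_, phased = FALSE))
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[/|]")[[1]]
  alleles <- suppressWarnings(as.integer(ifelse(parts == ".", NA, parts)))
  list(alleles = alleles, phased = phased)
}

render_call <- function(alleles, phased) {
  sep <- if (phased) "|" else "/"
  paste(ifelse(is.na(alleles), ".", alleles), collapse = sep)
}

call_ploidy <- function(gt) {
  if (is.na(gt) || gt == ".") return(NA_integer_)
  length(strsplit(gt, "[/|]")[[1]])
}

# ---- locus ordering ----------------------------------------------------------

# Total order on loci: rank of contig in the declared contig list, then
# 1-based position.  All dataset tables are kept sorted under this order.
locus_order <- function(contig, pos, contigs) {
  r <- match(contig, contigs)
  if (anyNA(r)) stop("contig not in declared contig list: ",
                     paste(unique(contig[is.na(r)]), collapse = ","))
  order(r, pos)
}

locus_key <- function(contig, pos) paste0(contig, ":", pos)

empty_ref_table <- function() {
  data.frame(contig = character(), pos = integer(), sample = character(),
             len = integer(), dp = integer(), gq = integer(),
             lgt = character(), ref_base = character(),
             meta = I(list()), stringsAsFactors = FALSE)
}

empty_site_table <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alts = I(list()), stringsAsFactors = FALSE)
}

empty_entry_table <- function() {
  data.frame(contig = character(), pos = integer(), sample = character(),
             la = I(list()), lgt = character(), lad = I(list()),
             lpl = I(list()), dp = integer(), gq = integer(),
             gvcf_info = I(list()), meta = I(list()),
             stringsAsFactors = FALSE)
}

# ---- the dataset container ---------------------------------------------------

#' Construct an SVCR dataset
#'
#' An SVCR dataset is a split pair of sorted, locus-keyed matrices over a
#' shared sample list: a reference-block matrix (long format, one row per
#' block) and a variant matrix (a site table with the global allele list and
#' an entry table with one row per stored per-sample genotype), plus the
#' `max_ref_block_length` bound used by point-query densification.
#'
#' @param samples character vector of unique sample ids.
#' @param contigs character vector fixing the contig order.
#' @param ref reference-block table: columns `contig`, `pos`, `sample`,
#'   `len`, `dp`, `gq`, `lgt`, `ref_base`, `meta`.
#' @param sites variant-site table: `contig`, `pos`, `ref`, `alts`
#'   (list column of character vectors; global allele index 0 is `ref`,
#'   alternate `i` has global index `i`).
#' @param entries per-sample variant-genotype table: `contig`, `pos`,
#'   `sample`, `la` (list of integer vectors, first element always 0),
#'   `lgt`, `lad`, `lpl` (list columns), `dp`, `gq`, `gvcf_info`, `meta`.
#' @param max_ref_block_length upper bound on any block's `len`.
#' @param header_meta optional character vector of originating GVCF header
#'   meta lines (kept so a single-sample round trip is byte-faithful).
#' @return an object of class `svcr_dataset`.
#' @export
svcr_dataset <- function(samples, contigs, ref = empty_ref_table(),
                         sites = empty_site_table(),
                         entries = empty_entry_table(),
                         max_ref_block_length = 0L,
                         header_meta = NULL) {
  ds <- structure(list(samples = as.character(samples),
                       contigs = as.character(contigs),
                       ref = ref, sites = sites, entries = entries,
                       max_ref_block_length = as.integer(max_ref_block_length),
                       header_meta = header_meta),
                  class = "svcr_dataset")
  sort_dataset(ds)
}

sort_dataset <- function(ds) {
  if (nrow(ds$ref))
    ds$ref <- ds$ref[order(match(ds$ref$contig, ds$contigs), ds$ref$pos,
                           match(ds$ref$sample, ds$samples)), , drop = FALSE]
  if (nrow(ds$sites))
    ds$sites <- ds$sites[locus_order(ds$sites$contig, ds$sites$pos, ds$contigs), ,
                         drop = FALSE]
  if (nrow(ds$entries))
    ds$entries <- ds$entries[order(match(ds$entries$contig, ds$contigs),
                                   ds$entries$pos,
                                   match(ds$entries$sample, ds$samples)), ,
                             drop = FALSE]
  rownames(ds$ref) <- rownames(ds$sites) <- rownames(ds$entries) <- NULL
  ds
}

#' @export
print.svcr_dataset <- function(x, ...) {
  cat("SVCR dataset\n")
  cat("  samples:            ", length(x$samples), "\n")
  cat("  contigs:            ", paste(x$contigs, collapse = ", "), "\n")
  cat("  variant sites:      ", nrow(x$sites), "\n")
  cat("  variant genotypes:  ", nrow(x$entries), "\n")
  cat("  reference blocks:   ", nrow(x$ref), "\n")
  cat("  max ref block len:  ", x$max_ref_block_length, "\n")
  invisible(x)
}

# ---- validation --------------------------------------------------------------

violation <- function(rule, contig = NA, pos = NA, sample = NA, message = "") {
  data.frame(rule = rule, contig = as.character(contig), pos = as.integer(pos),
             sample = as.character(sample), message = message,
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(rule = character(), contig = character(), pos = integer(),
             sample = character(), message = character(),
             stringsAsFactors = FALSE)
}

#' Validate an SVCR dataset against the representation's invariants
#'
#' Checks sortedness and locus uniqueness of both matrices, per-sample
#' disjointness of reference blocks, LA injectivity and the leading-zero
#' requirement, LR/LG length laws for LAD/LPL, LGT index range, and the
#' `max_ref_block_length` bound.  Violations are returned as data, one row
#' per breach, not raised as errors.
#'
#' @param ds an `svcr_dataset`.
#' @return a data frame of violations; zero rows means the dataset is valid.
#' @export
validate_dataset <- function(ds) {
  v <- list(no_violations())
  if (anyDuplicated(ds$samples))
    v[[length(v) + 1L]] <- violation("dup_sample",
      message = paste("duplicate sample ids:",
                      paste(unique(ds$samples[duplicated(ds$samples)]), collapse = ",")))

  # sortedness + uniqueness of keyed loci
  if (nrow(ds$sites)) {
    o <- locus_order(ds$sites$contig, ds$sites$pos, ds$contigs)
    if (!identical(o, seq_len(nrow(ds$sites))))
      v[[length(v) + 1L]] <- violation("unsorted_sites", message = "variant matrix not sorted")
    key <- locus_key(ds$sites$contig, ds$sites$pos)
    if (anyDuplicated(key)) {
      d <- ds$sites[duplicated(key), , drop = FALSE]
      v[[length(v) + 1L]] <- violation("dup_site_locus", d$contig, d$pos,
                                       message = "more than one variant site at locus")
    }
  }
  if (nrow(ds$ref)) {
    o <- order(match(ds$ref$contig, ds$contigs), ds$ref$pos,
               match(ds$ref$sample, ds$samples))
    if (!identical(o, seq_len(nrow(ds$ref))))
      v[[length(v) + 1L]] <- violation("unsorted_ref", message = "reference matrix not sorted")
  }

  # per-sample reference-block disjointness
  if (nrow(ds$ref)) {
    by <- split(seq_len(nrow(ds$ref)), paste(ds$ref$sample, ds$ref$contig))
    for (idx in by) {
      b <- ds$ref[idx, , drop = FALSE]
      b <- b[order(b$pos), , drop = FALSE]
      if (nrow(b) > 1L) {
        end <- b$pos + b$len - 1L
        bad <- which(b$pos[-1L] <= end[-nrow(b)])
        for (i in bad)
          v[[length(v) + 1L]] <- violation("block_overlap", b$contig[i + 1L],
            b$pos[i + 1L], b$sample[i + 1L],
            sprintf("block at %d overlaps preceding block [%d,%d]",
                    b$pos[i + 1L], b$pos[i], end[i]))
      }
      if (any(b$len < 1L))
        v[[length(v) + 1L]] <- violation("bad_block_len", b$contig[1L],
          b$pos[which(b$len < 1L)[1L]], b$sample[1L], "block LEN < 1")
    }
    if (ds$max_ref_block_length < max(ds$ref$len))
      v[[length(v) + 1L]] <- violation("max_len_understated",
        message = sprintf("max_ref_block_length %d < longest block %d",
                          ds$max_ref_block_length, max(ds$ref$len)))
    bad_sample <- !ds$ref$sample %in% ds$samples
    if (any(bad_sample))
      v[[length(v) + 1L]] <- violation("unknown_sample", ds$ref$contig[bad_sample][1L],
        ds$ref$pos[bad_sample][1L], ds$ref$sample[bad_sample][1L],
        "reference block for sample not in sample list")
  }

  # entries: site membership, LA/LGT/LAD/LPL laws
  if (nrow(ds$entries)) {
    site_key <- locus_key(ds$sites$contig, ds$sites$pos)
    ek <- locus_key(ds$entries$contig, ds$entries$pos)
    site_row <- match(ek, site_key)
    n_alleles <- rep(NA_integer_, nrow(ds$entries))
    known <- !is.na(site_row)
    if (any(!known)) {
      d <- ds$entries[!known, , drop = FALSE]
      v[[length(v) + 1L]] <- violation("entry_without_site", d$contig[1L], d$pos[1L],
                                       d$sample[1L], "genotype entry at locus with no variant site")
    }
    n_alleles[known] <- lengths(ds$sites$alts[site_row[known]]) + 1L
    if (anyDuplicated(paste(ek, ds$entries$sample)))
      v[[length(v) + 1L]] <- violation("dup_entry",
        message = "more than one genotype entry for a (locus, sample) pair")
    for (i in seq_len(nrow(ds$entries))) {
      e <- ds$entries[i, ]
      la <- e$la[[1L]]
      if (length(la) == 0L || la[1L] != 0L)
        v[[length(v) + 1L]] <- violation("la_first_nonzero", e$contig, e$pos, e$sample,
                                         "first element of LA must be 0")
      if (anyDuplicated(la))
        v[[length(v) + 1L]] <- violation("la_not_injective", e$contig, e$pos, e$sample,
                                         paste("LA has duplicates:", paste(la, collapse = ",")))
      if (!is.na(n_alleles[i]) && any(la >= n_alleles[i]))
        v[[length(v) + 1L]] <- violation("la_out_of_range", e$contig, e$pos, e$sample,
          sprintf("LA element >= %d global alleles", n_alleles[i]))
      pl_ploidy <- call_ploidy(e$lgt)
      if (!is.na(e$lgt) && e$lgt != ".") {
        alleles <- parse_call(e$lgt)$alleles
        if (any(!is.na(alleles) & alleles >= length(la)))
          v[[length(v) + 1L]] <- violation("lgt_out_of_range", e$contig, e$pos, e$sample,
                                           sprintf("LGT %s indexes beyond LA length %d", e$lgt, length(la)))
        if (!pl_ploidy %in% c(1L, 2L))
          v[[length(v) + 1L]] <- violation("bad_ploidy", e$contig, e$pos, e$sample,
                                           sprintf("unsupported ploidy %d", pl_ploidy))
      }
      lad <- e$lad[[1L]]
      if (!is.null(lad) && length(lad) && length(lad) != length(la))
        v[[length(v) + 1L]] <- violation("lad_length", e$contig, e$pos, e$sample,
          sprintf("LAD length %d != LR number %d", length(lad), length(la)))
      lpl <- e$lpl[[1L]]
      if (!is.null(lpl) && length(lpl)) {
        pl2 <- if (is.na(pl_ploidy)) 2L else pl_ploidy
        want <- tryCatch(n_genotypes(length(la), pl2), error = function(e) NA_integer_)
        if (!is.na(want) && length(lpl) != want)
          v[[length(v) + 1L]] <- violation("lpl_length", e$contig, e$pos, e$sample,
            sprintf("LPL length %d != LG number %d", length(lpl), want))
      }
    }
  }
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

#' Stop unless a dataset validates cleanly
#' @param ds an `svcr_dataset`.
#' @return `ds`, invisibly.
#' @export
assert_valid <- function(ds) {
  v <- validate_dataset(ds)
  if (nrow(v))
    stop("invalid SVCR dataset: ", nrow(v), " violation(s); first: [",
         v$rule[1L], "] ", v$message[1L])
  invisible(ds)
}

# ---- subsetting / allele pruning --------------------------------------------

#' Subset an SVCR dataset to a set of samples
#'
#' Keeps the variant-site table (and thus global allele lists) untouched:
#' alleles no longer observed by any remaining sample are *not* pruned
#' (see [prune_alleles()]); sites left with no genotype entry are retained
#' only if some remaining sample still has an entry there.
#'
#' @param ds an `svcr_dataset`.
#' @param samples character vector, subset of `ds$samples`.
#' @return an `svcr_dataset`.
#' @export
subset_samples <- function(ds, samples) {
  if (!all(samples %in% ds$samples))
    stop("unknown sample(s): ", paste(setdiff(samples, ds$samples), collapse = ","))
  ds$samples <- samples
  ds$ref <- ds$ref[ds$ref$sample %in% samples, , drop = FALSE]
  ds$entries <- ds$entries[ds$entries$sample %in% samples, , drop = FALSE]
  keep <- locus_key(ds$sites$contig, ds$sites$pos) %in%
    locus_key(ds$entries$contig, ds$entries$pos)
  ds$sites <- ds$sites[keep, , drop = FALSE]
  if (nrow(ds$ref)) ds$max_ref_block_length <- max(ds$ref$len) else ds$max_ref_block_length <- 0L
  sort_dataset(ds)
}

#' Drop global alleles no longer observed by any sample
#'
#' Removing a global allele only requires rewriting the LA maps: LGT, LAD and
#' LPL are expressed over local indices and are untouched — the core
#' convenience of local allele indexing.  Kept alternate alleles retain their
#' relative order.
#'
#' @param ds an `svcr_dataset`.
#' @return an `svcr_dataset`.
#' @export
prune_alleles <- function(ds) {
  if (!nrow(ds$sites)) return(ds)
  site_key <- locus_key(ds$sites$contig, ds$sites$pos)
  ekey <- locus_key(ds$entries$contig, ds$entries$pos)
  by_site <- split(seq_len(nrow(ds$entries)), factor(ekey, levels = site_key))
  for (s in seq_len(nrow(ds$sites))) {
    idx <- by_site[[s]]
    n_all <- length(ds$sites$alts[[s]]) + 1L
    # keep alleles in order of first local appearance (entries in sample
    # order): for a single-sample dataset this renumbers every LA to the
    # identity, which export_gvcf requires
    used <- unique(c(0L, unlist(ds$entries$la[idx])))
    if (length(used) == n_all && identical(used, seq_len(n_all) - 1L)) next
    trans <- rep(NA_integer_, n_all)           # old global -> new global
    trans[used + 1L] <- seq_along(used) - 1L
    ds$sites$alts[[s]] <- ds$sites$alts[[s]][used[-1L]]
    for (i in idx) ds$entries$la[[i]] <- trans[ds$entries$la[[i]] + 1L]
  }
  ds
}

# ---- misc shared helpers -----------------------------------------------------

#' Trim a shared trailing suffix from a site's alleles
#'
#' Merging right-extends shorter alleles so all inputs share the longest
#' reference; this reverses that extension: trailing bases common to the
#' reference and every (non-symbolic) alternate are removed, leaving every
#' allele at least one base.
#'
#' @param ref reference allele string.
#' @param alts character vector of alternate alleles (symbolic alleles such
#'   as `<NON_REF>` and `*` are passed through untouched).
#' @return `list(ref=, alts=)`.
#' @export
trim_shared_suffix <- function(ref, alts) {
  symbolic <- is_symbolic(alts)
  seqs <- c(ref, alts[!symbolic])
  while (all(nchar(seqs) > 1L)) {
    last <- substr(seqs, nchar(seqs), nchar(seqs))
    if (length(unique(last)) != 1L) break
    seqs <- substr(seqs, 1L, nchar(seqs) - 1L)
  }
  alts[!symbolic] <- seqs[-1L]
  list(ref = seqs[1L], alts = alts)
}

is_symbolic <- function(allele) startsWith(allele, "<") | allele == "*"

#' Compare the genetic content of two SVCR datasets
#'
#' Equality of samples, contigs, reference blocks (locus/LEN/DP/GQ) and
#' variant entries (alleles, LA, LGT, LAD, LPL, DP, GQ); per-sample
#' provenance metadata (`gvcf_info`, record meta) is ignored.
#'
#' @param a,b `svcr_dataset` objects.
#' @return TRUE or FALSE.
#' @export
datasets_equal <- function(a, b) {
  core_ref <- function(d) {
    x <- d$ref[c("contig", "pos", "sample", "len", "dp", "gq")]
    x[order(x$contig, x$pos, x$sample), , drop = FALSE]
  }
  core_sites <- function(d) d$sites[c("contig", "pos", "ref")]
  eq <- function(x, y) isTRUE(all.equal(`rownames<-`(x, NULL), `rownames<-`(y, NULL),
                                        check.attributes = FALSE))
  if (!identical(sort(a$samples), sort(b$samples))) return(FALSE)
  if (!identical(a$contigs, b$contigs)) return(FALSE)
  if (!eq(core_ref(a), core_ref(b))) return(FALSE)
  if (!eq(core_sites(a), core_sites(b))) return(FALSE)
  if (!identical(unname(a$sites$alts), unname(b$sites$alts))) return(FALSE)
  ea <- a$entries[order(a$entries$contig, a$entries$pos, a$entries$sample), , drop = FALSE]
  eb <- b$entries[order(b$entries$contig, b$entries$pos, b$entries$sample), , drop = FALSE]
  if (nrow(ea) != nrow(eb)) return(FALSE)
  for (col in c("contig", "pos", "sample", "lgt", "dp", "gq"))
    if (!isTRUE(all.equal(unname(ea[[col]]), unname(eb[[col]])))) return(FALSE)
  for (col in c("la", "lad", "lpl"))
    if (!identical(lapply(ea[[col]], as.integer), lapply(eb[[col]], as.integer)))
      return(FALSE)
  TRUE
}
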