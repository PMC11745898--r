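# Synthetic GVCF cohorts with realistic sharing structure.
#
# Samples draw their nonreference records from a shared site pool whose
# allele-frequency spectrum has density proportional to 1/f (truncated to
# [1/pool, 0.5] and normalized) — the neutral-spectrum shape under which the
# number of distinct variant sites discovered grows sub-linearly in sample
# count, while each sample's own record count stays roughly constant.
# Non-variant positions are tiled by GQ-banded reference blocks, emulating
# GATK-style whole-genome GVCFs.

#' Describe a synthetic cohort
#'
#' @param n_samples number of samples to simulate.
#' @param k_variants_per_sample expected nonreference (variant) records per
#'   sample; desk-scale default 500 (genome-scale callers produce 3-6
#'   million).
#' @param site_pool_size number of shared pool variants; `NULL` (default)
#'   calibrates the pool so the expected per-sample record count under the
#'   frequency law equals `k_variants_per_sample`.
#' @param genome_length simulated contig length in bp.
#' @param contig contig name.
#' @param f_max upper truncation of the allele-frequency spectrum.
#' @param indel_fraction fraction of pool variants that are indels (these
#'   create length-varying alleles and, with pool position collisions,
#'   multiallelic sites).
#' @param max_indel_len maximum inserted/deleted length in bp.
#' @param max_alts_per_locus cap on distinct pool alternates at one position.
#' @param block_gq_bands data frame `gq`, `mean_len`, `weight`: reference
#'   blocks are emitted in quality bands with geometric lengths, mimicking
#'   GQ-banded GVCF output.
#' @param depth_mean mean per-record read depth (Poisson).
#' @param seed root seed; per-sample streams derive child seeds from it by
#'   sample index, so extending a cohort does not change existing samples.
#' @return a `cohort_model`.
#' @export
cohort_model <- function(n_samples = 8L, k_variants_per_sample = 500,
                         site_pool_size = NULL, genome_length = 100000L,
                         contig = "chr1", f_max = 0.5, indel_fraction = 0.15,
                         max_indel_len = 3L, max_alts_per_locus = 4L,
                         block_gq_bands = data.frame(
                           gq = c(99L, 45L, 15L),
                           mean_len = c(1000, 300, 150),
                           weight = c(0.7, 0.2, 0.1)),
                         depth_mean = 30, seed = 1L) {
  stopifnot(n_samples >= 1, k_variants_per_sample > 0, genome_length > 100,
            f_max > 0, f_max <= 1, indel_fraction >= 0, indel_fraction <= 1,
            depth_mean > 0)
  if (is.null(site_pool_size))
    site_pool_size <- calibrate_pool_size(k_variants_per_sample, f_max)
  structure(list(n_samples = as.integer(n_samples),
                 k_variants_per_sample = k_variants_per_sample,
                 site_pool_size = as.integer(site_pool_size),
                 genome_length = as.integer(genome_length), contig = contig,
                 f_max = f_max, indel_fraction = indel_fraction,
                 max_indel_len = as.integer(max_indel_len),
                 max_alts_per_locus = as.integer(max_alts_per_locus),
                 block_gq_bands = block_gq_bands, depth_mean = depth_mean,
                 seed = as.integer(seed)),
            class = "cohort_model")
}

# Expected diploid carriage probability E[1 - (1-f)^2] under density 1/f on
# [1/P, f_max]; solve P * E = K for the pool size P.
calibrate_pool_size <- function(k, f_max) {
  expected_records <- function(p) {
    f_min <- 1 / p
    z <- log(f_max / f_min)
    e_f <- (f_max - f_min) / z
    e_f2 <- (f_max^2 - f_min^2) / (2 * z)
    p * (2 * e_f - e_f2)
  }
  round(stats::uniroot(function(p) expected_records(p) - k,
                       interval = c(k, 1e8), tol = 1)$root)
}

# Deterministic reference base at a position (a hashed "genome" shared by
# the pool and all samples, so overlapping deletion alleles stay consistent).
base_at <- function(pos, seed) {
  h <- (as.double(pos) * 2654435761 + as.double(seed) * 97 + 13) %% 2^31
  c("A", "C", "G", "T")[(floor(h) %% 4) + 1]
}

child_seed <- function(seed, i) as.integer((as.double(seed) * 7919 + i * 104729 + 1) %% 2147483647)

# Draw the shared site pool.  Returns a data frame sorted by position:
# pos, ref, alt, f (population allele frequency).
draw_site_pool <- function(model) {
  set.seed(model$seed)
  p <- model$site_pool_size
  f_min <- 1 / p
  pos <- sample.int(model$genome_length - model$max_indel_len - 1L, p,
                    replace = TRUE) + 1L
  f <- f_min * (model$f_max / f_min)^stats::runif(p)   # density proportional to 1/f
  type <- sample(c("snp", "ins", "del"), p, replace = TRUE,
                 prob = c(1 - model$indel_fraction, model$indel_fraction / 2,
                          model$indel_fraction / 2))
  ref_base <- base_at(pos, model$seed)
  indel_len <- sample.int(model$max_indel_len, p, replace = TRUE)
  ref <- ref_base
  alt <- ref_base
  for (i in seq_len(p)) {
    if (type[i] == "snp") {
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), ref_base[i]), 1L)
    } else if (type[i] == "ins") {
      alt[i] <- paste0(ref_base[i],
                       paste(sample(c("A", "C", "G", "T"), indel_len[i],
                                    replace = TRUE), collapse = ""))
    } else {
      ref[i] <- paste0(ref_base[i],
                       paste(base_at(pos[i] + seq_len(indel_len[i]), model$seed),
                             collapse = ""))
    }
  }
  pool <- data.frame(pos = pos, ref = ref, alt = alt, f = f,
                     stringsAsFactors = FALSE)
  pool <- pool[!duplicated(pool[c("pos", "ref", "alt")]), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(pool)), pool$pos),
                        function(ix) ix[seq_len(min(length(ix), model$max_alts_per_locus))]))
  pool <- pool[sort(keep), , drop = FALSE]
  pool <- pool[order(pool$pos), , drop = FALSE]
  rownames(pool) <- NULL
  pool
}

#' Simulate a cohort of single-sample GVCFs
#'
#' Each sample carries pool variant `i` with probability
#' `1 - (1 - f_i)^2` (diploid), het/hom split by Hardy-Weinberg; carried
#' variants at one position form one multiallelic record; AD/PL/DP/GQ are
#' generated consistently (PL is 0 at the called genotype), `<NON_REF>` is
#' appended to every variant row, and all remaining genome positions are
#' tiled by GQ-banded reference blocks.  Deterministic given the model seed;
#' sample `i` depends only on (seed, pool, i).
#'
#' @param model a [cohort_model()].
#' @param n_samples optionally override `model$n_samples`.
#' @return list of `gvcf` objects, one per sample (`S1`, `S2`, ...).
#' @export
simulate_cohort <- function(model, n_samples = model$n_samples) {
  pool <- draw_site_pool(model)
  lapply(seq_len(n_samples), function(i)
    simulate_sample_gvcf(model, pool, i))
}

simulate_sample_gvcf <- function(model, pool, i) {
  set.seed(child_seed(model$seed, i))
  sample_id <- sprintf("S%d", i)
  g_carry <- 1 - (1 - pool$f)^2
  carried <- which(stats::runif(nrow(pool)) < g_carry)
  hom <- stats::runif(length(carried)) < pool$f[carried]^2 / g_carry[carried]

  # one record per carried position; skip variants overlapping the previous
  # record's reference span (real callers emit * alleles there; out of scope)
  rec_list <- list()
  last_end <- 0L
  for (grp in split(seq_along(carried), pool$pos[carried])) {
    ix <- carried[grp]
    pos <- pool$pos[ix[1L]]
    if (pos <= last_end) next
    refs <- pool$ref[ix]
    ref <- refs[which.max(nchar(refs))]
    suffixes <- substring(ref, nchar(refs) + 1L, nchar(ref))
    alts <- paste0(pool$alt[ix], suffixes)
    is_hom <- hom[grp]
    n_alt <- length(alts)
    gt <- if (n_alt >= 2L) "1/2" else if (is_hom[1L]) "1/1" else "0/1"
    alleles <- c(ref, alts, "<NON_REF>")
    n_all <- length(alleles)
    dp <- max(2L, stats::rpois(1L, model$depth_mean))
    ad <- integer(n_all)
    called <- parse_call(gt)$alleles
    if (length(unique(called)) == 1L) {
      ad[called[1L] + 1L] <- dp
    } else {
      a_dp <- stats::rbinom(1L, dp, 0.5)
      ad[called[1L] + 1L] <- a_dp
      ad[called[2L] + 1L] <- dp - a_dp
    }
    pl <- 40L + stats::rpois(n_genotypes(n_all, 2L), 10 * dp / 3)
    pl[genotype_index(min(called), max(called)) + 1L] <- 0L
    gq <- min(99L, sort(pl)[2L])
    rec_list[[length(rec_list) + 1L]] <- list(
      pos = pos, ref = ref, alt = paste(alleles[-1L], collapse = ","),
      gt = gt, ad = ad, pl = pl, dp = dp, gq = gq)
    last_end <- pos + nchar(ref) - 1L
  }

  v_pos <- vapply(rec_list, `[[`, integer(1), "pos")
  v_len <- vapply(rec_list, function(r) nchar(r$ref), integer(1))

  # GQ-banded reference blocks tiling the gaps
  bands <- model$block_gq_bands
  gaps <- gap_intervals(model$genome_length, v_pos, v_len)
  blk <- list()
  for (gi in seq_len(nrow(gaps))) {
    at <- gaps$start[gi]
    while (at <= gaps$end[gi]) {
      b <- sample.int(nrow(bands), 1L, prob = bands$weight)
      len <- min(1L + stats::rgeom(1L, 1 / bands$mean_len[b]),
                 gaps$end[gi] - at + 1L)
      blk[[length(blk) + 1L]] <- list(pos = at, end = at + len - 1L,
                                      dp = max(1L, stats::rpois(1L, model$depth_mean)),
                                      gq = bands$gq[b])
      at <- at + len
    }
  }

  # assemble records
  var_df <- if (length(rec_list)) data.frame(
    chrom = model$contig, pos = v_pos, id = ".",
    ref = vapply(rec_list, `[[`, character(1), "ref"),
    alt = vapply(rec_list, `[[`, character(1), "alt"),
    qual = sprintf("%.2f", 30 + vapply(rec_list, `[[`, integer(1), "gq")),
    filter = ".",
    info = sprintf("DP=%d;MQ=60.00", vapply(rec_list, `[[`, integer(1), "dp")),
    format = "GT:AD:PL:DP:GQ", value = NA_character_,
    gt = vapply(rec_list, `[[`, character(1), "gt"),
    ad = I(lapply(rec_list, `[[`, "ad")),
    pl = I(lapply(rec_list, `[[`, "pl")),
    dp = vapply(rec_list, `[[`, integer(1), "dp"),
    gq = vapply(rec_list, `[[`, integer(1), "gq"),
    min_dp = NA_integer_, end = NA_integer_, stringsAsFactors = FALSE)
    else NULL
  blk_df <- if (length(blk)) data.frame(
    chrom = model$contig,
    pos = vapply(blk, `[[`, integer(1), "pos"), id = ".",
    ref = base_at(vapply(blk, `[[`, integer(1), "pos"), model$seed),
    alt = "<NON_REF>", qual = ".", filter = ".",
    info = sprintf("END=%d", vapply(blk, `[[`, integer(1), "end")),
    format = "GT:DP:GQ", value = NA_character_, gt = "0/0",
    ad = I(rep(list(NULL), length(blk))), pl = I(rep(list(NULL), length(blk))),
    dp = vapply(blk, `[[`, integer(1), "dp"),
    gq = vapply(blk, `[[`, integer(1), "gq"),
    min_dp = NA_integer_, end = vapply(blk, `[[`, integer(1), "end"),
    stringsAsFactors = FALSE)
    else NULL
  rec <- rbind(var_df, blk_df)
  if (is.null(rec)) rec <- parse_gvcf_body(character())
  if (nrow(rec)) {
    rec <- rec[order(rec$pos), , drop = FALSE]
    rownames(rec) <- NULL
    rec$value <- render_gvcf_value(rec)
  }
  structure(list(sample = sample_id, contigs = model$contig,
                 meta = default_gvcf_meta(sample_id, model$contig,
                                          model$genome_length),
                 records = rec), class = "gvcf")
}

# maximal intervals of [1, genome_length] not covered by variant spans
gap_intervals <- function(genome_length, v_pos, v_len) {
  if (!length(v_pos)) return(data.frame(start = 1L, end = genome_length))
  v_end <- v_pos + v_len - 1L
  start <- c(1L, v_end + 1L)
  end <- c(v_pos - 1L, genome_length)
  keep <- start <= end
  data.frame(start = start[keep], end = end[keep])
}

#' Size statistics of a dataset, dense versus stored
#'
#' `n_genotype_records` counts the dense matrix (samples x variant sites) a
#' conventional project VCF would materialize; `n_svcr_records` counts what
#' the sparse representation actually stores (variant genotype entries plus
#' reference blocks).  Optionally reports the encoded SVCR-VCF size in
#' bytes (informational; linearity claims are made on record counts).
#'
#' @param ds an `svcr_dataset`.
#' @param bytes also write a gzip SVCR-VCF to a temp file and report its size.
#' @return `list(n_variant_sites, n_genotype_records, n_svcr_records,
#'   bytes_encoded)`.
#' @export
count_stats <- function(ds, bytes = FALSE) {
  out <- list(n_variant_sites = nrow(ds$sites),
              n_genotype_records = nrow(ds$sites) * length(ds$samples),
              n_svcr_records = nrow(ds$entries) + nrow(ds$ref),
              bytes_encoded = NA_real_)
  if (bytes) {
    tmp <- tempfile(fileext = ".vcf.gz")
    on.exit(unlink(tmp))
    write_svcr_vcf(ds, tmp)
    out$bytes_encoded <- file.size(tmp)
  }
  out
}

#' Fit a power law in log-log space
#'
#' Least squares for `log10(m) = a + b * log10(n)`: the standard way to
#' measure how a size measure `m` scales with sample count `n` (`b = 1` is
#' linear scaling).
#'
#' @param n sample counts (>= 3 values, all positive).
#' @param m measured sizes (positive).
#' @return a `scaling_fit`: `list(a, b, r2)`.
#' @export
fit_loglog <- function(n, m) {
  stopifnot(length(n) == length(m))
  if (length(n) < 3L) stop("need at least 3 points to fit a scaling law")
  if (any(n <= 0) || any(m <= 0)) stop("scaling fits need positive values")
  fit <- stats::lm(log10(m) ~ log10(n))
  y <- log10(m)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(a = unname(stats::coef(fit)[1L]), b = unname(stats::coef(fit)[2L]),
                 r2 = r2),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("scaling fit: log10(M) = %.4f + %.4f log10(N)   (R^2 = %.4f)\n",
              x$a, x$b, x$r2))
  invisible(x)
}

#' Measure size scaling over nested sub-cohorts
#'
#' Simulates one cohort at the largest requested size, then merges nested
#' prefixes (sample extensibility of the generator makes prefixes exactly
#' the cohorts a smaller simulation would produce) and collects
#' [count_stats()] per size.
#'
#' @param model a [cohort_model()].
#' @param sizes increasing sample counts.
#' @param bytes also record encoded byte sizes.
#' @return data frame with one row per size.
#' @export
scaling_sweep <- function(model, sizes = c(8L, 16L, 32L, 64L, 128L),
                          bytes = FALSE) {
  sizes <- sort(unique(as.integer(sizes)))
  gvcfs <- simulate_cohort(model, n_samples = max(sizes))
  singles <- lapply(gvcfs, import_gvcf, non_ref_policy = "drop")
  rows <- vector("list", length(sizes))
  ds <- NULL
  done <- 0L
  for (i in seq_along(sizes)) {
    chunk <- merge_datasets(singles[(done + 1L):sizes[i]])
    ds <- if (is.null(ds)) chunk else merge_datasets(list(ds, chunk))
    done <- sizes[i]
    st <- count_stats(ds, bytes = bytes)
    rows[[i]] <- data.frame(n_samples = sizes[i],
                            n_variant_sites = st$n_variant_sites,
                            n_genotype_records = st$n_genotype_records,
                            n_svcr_records = st$n_svcr_records,
                            bytes_encoded = st$bytes_encoded)
  }
  do.call(rbind, rows)
}
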