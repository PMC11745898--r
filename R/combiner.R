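# N+K combining of SVCR datasets.  Reference blocks pass through untouched at
# their start locus; at shared variant sites the global allele lists are
# unified (reference harmonization by right-extension, alternate union in
# first-appearance order) and each input's LA maps are rewritten through the
# resulting translation.  Local fields (LGT/LAD/LPL) never change: that is
# the point of the local-allele indirection.

#' Unify the allele lists of several inputs at one locus
#'
#' The merged reference is the longest input reference; every shorter input's
#' reference must be a prefix of it (inputs disagreeing on the underlying
#' sequence are rejected), and its non-symbolic alternates are right-extended
#' with the missing suffix.  Merged alternates are the union of extended
#' alternates, ordered by first appearance (input rank, then the input's own
#' alternate order).  Symbolic alleles (`<NON_REF>`, `*`) unify by exact
#' string match and are never extended.
#'
#' @param allele_lists list of `list(ref=, alts=)`, one per input, in source
#'   rank order.
#' @return `list(alleles = list(ref, alts), translations = list of integer
#'   vectors)` where `translations[[i]][g + 1]` is the merged global index of
#'   input `i`'s global allele `g`.
#' @export
unify_alleles <- function(allele_lists) {
  refs <- vapply(allele_lists, `[[`, character(1), "ref")
  merged_ref <- refs[which.max(nchar(refs))]
  if (!all(substring(merged_ref, 1L, nchar(refs)) == refs))
    stop("inputs disagree on the reference sequence at this locus: ",
         paste(unique(refs), collapse = " vs "))
  merged_alts <- character()
  translations <- vector("list", length(allele_lists))
  for (i in seq_along(allele_lists)) {
    alts <- allele_lists[[i]]$alts
    suffix <- substr(merged_ref, nchar(refs[i]) + 1L, nchar(merged_ref))
    ext <- ifelse(is_symbolic(alts), alts, paste0(alts, suffix))
    tr <- integer(length(alts) + 1L)   # ref -> ref
    for (j in seq_along(ext)) {
      at <- match(ext[j], merged_alts)
      if (is.na(at)) {
        merged_alts <- c(merged_alts, ext[j])
        at <- length(merged_alts)
      }
      tr[j + 1L] <- at
    }
    translations[[i]] <- tr
  }
  list(alleles = list(ref = merged_ref, alts = merged_alts),
       translations = translations)
}

#' Rewrite a genotype's LA map through an allele translation
#'
#' Only the LA map changes; LGT, LAD, LPL, DP, GQ and `gvcf_info` are
#' expressed over local indices and are translation-invariant.
#'
#' @param genotype a list with at least an `la` integer vector (other fields
#'   are passed through).
#' @param translation integer vector mapping old global index `g` (0-based)
#'   to `translation[g + 1]`.
#' @return the genotype with `la` remapped.
#' @export
remap_genotype <- function(genotype, translation) {
  la <- genotype$la
  if (any(la + 1L > length(translation)) || any(la < 0L))
    stop("LA element outside the translation's domain")
  genotype$la <- translation[la + 1L]
  genotype
}

#' Merge SVCR datasets
#'
#' Locus-keyed outer join of both matrices over pairwise-disjoint sample
#' sets.  Reference blocks are preserved verbatim at their start loci; shared
#' variant sites go through [unify_alleles()] and [remap_genotype()].  The
#' stored record count of the result is exactly the sum of the inputs' — the
#' structural source of linear size scaling.
#'
#' @param inputs list of `svcr_dataset` objects (a single dataset is
#'   returned with identity allele maps).
#' @return the merged `svcr_dataset`.
#' @export
merge_datasets <- function(inputs) {
  if (inherits(inputs, "svcr_dataset")) inputs <- list(inputs)
  stopifnot(length(inputs) >= 1L)
  samples <- unlist(lapply(inputs, `[[`, "samples"))
  if (anyDuplicated(samples))
    stop("duplicate sample ids across inputs: ",
         paste(unique(samples[duplicated(samples)]), collapse = ","))

  # contig order: first input's order extended by unseen contigs, with a
  # consistency check on relative order
  contigs <- inputs[[1L]]$contigs
  for (ds in inputs[-1L]) {
    shared <- intersect(contigs, ds$contigs)
    if (!identical(match(shared, contigs), sort(match(shared, contigs))) ||
        is.unsorted(match(shared, ds$contigs)))
      stop("inputs declare incompatible contig orders")
    contigs <- c(contigs, setdiff(ds$contigs, contigs))
  }

  ref <- do.call(rbind, lapply(inputs, `[[`, "ref"))

  # site union with allele unification
  site_list <- lapply(seq_along(inputs), function(i) {
    s <- inputs[[i]]$sites
    if (nrow(s)) s$input <- i
    s
  })
  all_sites <- do.call(rbind, site_list)
  merged_sites <- empty_site_table()
  trans_by_input_locus <- new.env(parent = emptyenv())
  if (!is.null(all_sites) && nrow(all_sites)) {
    key <- locus_key(all_sites$contig, all_sites$pos)
    grp <- split(seq_len(nrow(all_sites)), factor(key, levels = unique(key)))
    out <- vector("list", length(grp))
    for (gi in seq_along(grp)) {
      idx <- grp[[gi]]
      idx <- idx[order(all_sites$input[idx])]
      u <- unify_alleles(lapply(idx, function(r)
        list(ref = all_sites$ref[r], alts = all_sites$alts[[r]])))
      out[[gi]] <- list(contig = all_sites$contig[idx[1L]],
                        pos = all_sites$pos[idx[1L]],
                        ref = u$alleles$ref, alts = u$alleles$alts)
      for (j in seq_along(idx)) {
        assign(paste0(all_sites$input[idx[j]], "|", key[idx[j]]),
               u$translations[[j]], envir = trans_by_input_locus)
      }
    }
    merged_sites <- data.frame(
      contig = vapply(out, `[[`, character(1), "contig"),
      pos = vapply(out, `[[`, integer(1), "pos"),
      ref = vapply(out, `[[`, character(1), "ref"),
      alts = I(lapply(out, `[[`, "alts")), stringsAsFactors = FALSE)
  }

  # entries with LA rewritten per (input, locus)
  entry_list <- lapply(seq_along(inputs), function(i) {
    e <- inputs[[i]]$entries
    if (nrow(e)) {
      tkey <- paste0(i, "|", locus_key(e$contig, e$pos))
      for (k in unique(tkey)) {
        tr <- get(k, envir = trans_by_input_locus)
        if (identical(tr, seq_along(tr) - 1L)) next
        rows <- which(tkey == k)
        e$la[rows] <- lapply(e$la[rows], function(la) tr[la + 1L])
      }
    }
    e
  })
  entries <- do.call(rbind, entry_list)

  svcr_dataset(samples = samples, contigs = contigs,
               ref = if (is.null(ref)) empty_ref_table() else ref,
               sites = merged_sites,
               entries = if (is.null(entries)) empty_entry_table() else entries,
               max_ref_block_length = max(0L, vapply(inputs, `[[`, integer(1),
                                                     "max_ref_block_length")))
}

#' Plan a hierarchical (tree-structured) merge
#'
#' Builds the bottom-up task tree used for scatter/gather combining: inputs
#' are chunked into groups of at most `fanout`, each group is one merge task,
#' and the groups' outputs are chunked again until one dataset remains.
#' Executing the tree yields the same dataset as one flat merge because
#' merging is associative up to allele order.
#'
#' @param n_inputs number of inputs (>= 1).
#' @param fanout maximum children per merge task (>= 2).
#' @return `list(levels=, n_tasks=)`; `levels[[l]]` is a list of integer
#'   vectors indexing the previous level's outputs (level 1 indexes inputs).
#' @export
plan_hierarchical <- function(n_inputs, fanout) {
  stopifnot(n_inputs >= 1L, fanout >= 2L)
  levels <- list()
  width <- n_inputs
  while (width > 1L) {
    groups <- split(seq_len(width), ceiling(seq_len(width) / fanout))
    names(groups) <- NULL
    levels[[length(levels) + 1L]] <- groups
    width <- length(groups)
  }
  structure(list(levels = levels,
                 n_tasks = sum(lengths(lapply(levels, identity))),
                 n_inputs = n_inputs, fanout = fanout),
            class = "svcr_merge_plan")
}

#' @export
print.svcr_merge_plan <- function(x, ...) {
  cat("hierarchical merge plan:", x$n_inputs, "inputs, fanout", x$fanout, "\n")
  cat("  levels:", length(x$levels),
      "| tasks per level:", paste(lengths(x$levels), collapse = " + "),
      "| total tasks:", x$n_tasks, "\n")
  invisible(x)
}

#' Execute a hierarchical merge plan
#'
#' @param plan from [plan_hierarchical()].
#' @param inputs list of `svcr_dataset` objects, length `plan$n_inputs`.
#' @return the merged `svcr_dataset`.
#' @export
execute_plan <- function(plan, inputs) {
  stopifnot(length(inputs) == plan$n_inputs)
  current <- inputs
  for (level in plan$levels)
    current <- lapply(level, function(idx) merge_datasets(current[idx]))
  current[[1L]]
}
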