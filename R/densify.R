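# Densification: resolving the sparse representation into conventional dense
# rows with global-indexed fields.  Local fields project through the LA map;
# samples without a variant entry are resolved from their overlapping
# reference block (hom-ref) or reported missing.

#' Project a local allele-depth array to the global R-numbered AD
#'
#' `ad[la[i] + 1] = lad[i]`; alleles the sample did not observe get depth 0
#' (zero informative reads, not missing).
#'
#' @param lad integer LR-numbered depths.
#' @param la integer LA map.
#' @param n_global number of global alleles including the reference.
#' @return integer vector of length `n_global`.
#' @export
project_lad_to_ad <- function(lad, la, n_global) {
  if (length(lad) != length(la))
    stop("LAD length ", length(lad), " != LA length ", length(la))
  ad <- integer(n_global)
  ad[la + 1L] <- lad
  ad
}

#' Project a local likelihood array to the global G-numbered PL
#'
#' The entry for global genotype `(la[i], la[j])` equals the local entry for
#' `(i, j)`; genotypes involving an allele outside LA have no likelihood and
#' are left missing (`NA`) or set to a numeric sentinel.
#'
#' @param lpl integer LG-numbered likelihoods.
#' @param la integer LA map.
#' @param n_global number of global alleles including the reference.
#' @param ploidy 1 or 2.
#' @param fill value for non-local genotype entries (default `NA`).
#' @return vector of length `n_genotypes(n_global, ploidy)`.
#' @export
project_lpl_to_pl <- function(lpl, la, n_global, ploidy = 2L, fill = NA_integer_) {
  if (length(lpl) != n_genotypes(length(la), ploidy))
    stop("LPL length ", length(lpl), " != LG number ",
         n_genotypes(length(la), ploidy))
  pl <- rep(as.integer(fill), n_genotypes(n_global, ploidy))
  if (ploidy == 1L) {
    pl[la + 1L] <- lpl
    return(pl)
  }
  for (k in seq_along(la)) {
    for (j in seq_len(k)) {
      g_local <- genotype_index(j - 1L, k - 1L)
      gj <- min(la[j], la[k]); gk <- max(la[j], la[k])
      pl[genotype_index(gj, gk) + 1L] <- lpl[g_local + 1L]
    }
  }
  pl
}

#' Project a local genotype call to the global GT
#'
#' Each LGT allele index becomes the corresponding LA entry; phase separator
#' and allele order are preserved verbatim.
#'
#' @param lgt genotype string over local indices (e.g. "0/1", "0|2").
#' @param la integer LA map.
#' @return genotype string over global indices.
#' @export
project_lgt_to_gt <- function(lgt, la) {
  if (is.na(lgt) || lgt == ".") return(lgt)
  call <- parse_call(lgt)
  if (any(!is.na(call$alleles) & call$alleles >= length(la)))
    stop("LGT ", lgt, " indexes beyond LA of length ", length(la))
  g <- ifelse(is.na(call$alleles), NA_integer_, la[call$alleles + 1L])
  render_call(g, call$phased)
}

missing_call <- function(ploidy = 2L) if (ploidy == 1L) "." else "./."

# Resolve one (site, sample) pair given an optional entry row and an optional
# covering block; returns the per-sample slot of a dense row.
resolve_sample <- function(entry, block, n_global, hom_ref_ploidy = 2L) {
  if (!is.null(entry)) {
    la <- entry$la[[1L]]
    list(gt = project_lgt_to_gt(entry$lgt, la),
         ad = if (length(entry$lad[[1L]])) project_lad_to_ad(entry$lad[[1L]], la, n_global),
         pl = if (length(entry$lpl[[1L]])) {
           project_lpl_to_pl(entry$lpl[[1L]], la, n_global,
                             ploidy = call_ploidy(entry$lgt))
         },
         dp = entry$dp, gq = entry$gq, src = "variant")
  } else if (!is.null(block)) {
    list(gt = if (hom_ref_ploidy == 1L) "0" else "0/0",
         ad = NULL, pl = NULL, dp = block$dp, gq = block$gq, src = "block")
  } else {
    list(gt = missing_call(hom_ref_ploidy), ad = NULL, pl = NULL,
         dp = NA_integer_, gq = NA_integer_, src = "missing")
  }
}

#' Densify the dataset at a single locus (point query)
#'
#' For each sample: a variant entry at the locus is projected to global
#' fields; otherwise the sample's reference blocks are searched for one
#' overlapping the locus — the search is restricted to start positions
#' within the preceding `max_ref_block_length - 1` bases, which is what the
#' dataset-level bound buys; otherwise the sample is missing.
#'
#' @param ds an `svcr_dataset`.
#' @param contig,pos the query locus.
#' @param hom_ref_ploidy ploidy of hom-ref calls synthesized from blocks.
#' @return a `dense_row`: `list(contig, pos, ref, alts, calls)` with one
#'   per-sample slot in `calls`.
#' @export
densify_at_locus <- function(ds, contig, pos, hom_ref_ploidy = 2L) {
  if (!contig %in% ds$contigs) stop("unknown contig: ", contig)
  s <- which(ds$sites$contig == contig & ds$sites$pos == pos)
  ref_allele <- if (length(s)) ds$sites$ref[s] else "N"
  alts <- if (length(s)) ds$sites$alts[[s]] else character()
  n_global <- length(alts) + 1L

  win_lo <- pos - ds$max_ref_block_length + 1L
  cand <- ds$ref[ds$ref$contig == contig & ds$ref$pos >= win_lo &
                   ds$ref$pos <= pos, , drop = FALSE]
  cand <- cand[cand$pos + cand$len - 1L >= pos, , drop = FALSE]

  ent <- ds$entries[ds$entries$contig == contig & ds$entries$pos == pos, ,
                    drop = FALSE]
  calls <- lapply(ds$samples, function(smp) {
    e <- ent[ent$sample == smp, , drop = FALSE]
    b <- cand[cand$sample == smp, , drop = FALSE]
    resolve_sample(if (nrow(e)) e[1L, ] else NULL,
                   if (nrow(b)) b[1L, ] else NULL,
                   n_global, hom_ref_ploidy)
  })
  names(calls) <- ds$samples
  structure(list(contig = contig, pos = pos, ref = ref_allele, alts = alts,
                 calls = calls), class = "dense_row")
}

#' Streaming densification over all variant sites
#'
#' A single forward pass over the merged, sorted stream of reference-block
#' starts and variant sites; per-sample state holds at most one active block
#' (block disjointness guarantees uniqueness).  Emits one dense row per
#' variant site, identical to [densify_at_locus()] at that locus.
#'
#' @param ds an `svcr_dataset`.
#' @param region optional `list(contig=, start=, end=)` restricting the
#'   emitted sites (blocks overlapping in from the left are still found).
#' @param hom_ref_ploidy ploidy of synthesized hom-ref calls.
#' @return list of `dense_row` objects.
#' @export
densify_stream <- function(ds, region = NULL, hom_ref_ploidy = 2L) {
  sites <- ds$sites
  refs <- ds$ref
  if (!is.null(region)) {
    keep <- sites$contig == region$contig & sites$pos >= region$start &
      sites$pos <= region$end
    sites <- sites[keep, , drop = FALSE]
    rkeep <- refs$contig == region$contig &
      refs$pos + refs$len - 1L >= region$start & refs$pos <= region$end
    refs <- refs[rkeep, , drop = FALSE]
  }
  if (!nrow(sites)) return(list())

  ent_by_key <- split(seq_len(nrow(ds$entries)),
                      locus_key(ds$entries$contig, ds$entries$pos))
  rows <- vector("list", nrow(sites))
  sample_index <- stats::setNames(seq_along(ds$samples), ds$samples)

  for (cg in unique(sites$contig)) {
    s_here <- which(sites$contig == cg)
    r_here <- refs[refs$contig == cg, , drop = FALSE]
    # event stream: block starts and variant sites in position order;
    # blocks starting at a site's locus are swapped in before emitting.
    ri <- 1L
    r_ord <- order(r_here$pos)
    r_here <- r_here[r_ord, , drop = FALSE]
    active <- vector("list", length(ds$samples))   # per-sample active block
    for (si in s_here) {
      p <- sites$pos[si]
      while (ri <= nrow(r_here) && r_here$pos[ri] <= p) {
        active[[sample_index[[r_here$sample[ri]]]]] <- r_here[ri, ]
        ri <- ri + 1L
      }
      n_global <- length(sites$alts[[si]]) + 1L
      ent <- ds$entries[ent_by_key[[locus_key(cg, p)]], , drop = FALSE]
      calls <- lapply(seq_along(ds$samples), function(k) {
        e <- ent[ent$sample == ds$samples[k], , drop = FALSE]
        b <- active[[k]]
        if (!is.null(b) && (b$pos > p || b$pos + b$len - 1L < p)) b <- NULL
        resolve_sample(if (nrow(e)) e[1L, ] else NULL, b, n_global,
                       hom_ref_ploidy)
      })
      names(calls) <- ds$samples
      rows[[si]] <- structure(list(contig = cg, pos = p, ref = sites$ref[si],
                                   alts = sites$alts[[si]], calls = calls),
                              class = "dense_row")
    }
  }
  rows
}

#' Flatten dense rows to a data frame
#'
#' One row per (site, sample); AD and PL become comma-joined strings with
#' `.` for missing entries.
#'
#' @param rows list of `dense_row` objects.
#' @return a data frame.
#' @export
dense_to_df <- function(rows) {
  out <- lapply(rows, function(r) {
    data.frame(contig = r$contig, pos = r$pos, ref = r$ref,
               alt = paste(r$alts, collapse = ","),
               sample = names(r$calls),
               gt = vapply(r$calls, `[[`, character(1), "gt"),
               dp = vapply(r$calls, function(x) as.integer(x$dp %||% NA), integer(1)),
               gq = vapply(r$calls, function(x) as.integer(x$gq %||% NA), integer(1)),
               ad = vapply(r$calls, function(x) render_mixed_array(x$ad), character(1)),
               pl = vapply(r$calls, function(x) render_mixed_array(x$pl), character(1)),
               src = vapply(r$calls, `[[`, character(1), "src"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

render_mixed_array <- function(x) {
  if (is.null(x) || !length(x)) "." else
    paste(ifelse(is.na(x), ".", as.character(x)), collapse = ",")
}
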