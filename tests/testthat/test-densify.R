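# Local-to-global projection and densification.

test_that("project_lad_to_ad scatters depths to global indices", {
  # worked example: LAD [0,14,16] under LA [0,1,3] at a 5-allele site
  expect_identical(project_lad_to_ad(c(0L, 14L, 16L), c(0L, 1L, 3L), 5L),
                   c(0L, 14L, 0L, 16L, 0L))
  expect_identical(project_lad_to_ad(c(3L, 4L), c(0L, 1L), 2L), c(3L, 4L))
  expect_identical(project_lad_to_ad(5L, 0L, 4L), c(5L, 0L, 0L, 0L))
  expect_error(project_lad_to_ad(c(1L, 2L), c(0L, 1L, 2L), 3L), "length")
})

test_that("project_lpl_to_pl populates exactly the local genotype entries", {
  # identity LA: PL equals LPL
  lpl <- c(10L, 0L, 20L, 30L, 40L, 50L)
  expect_identical(project_lpl_to_pl(lpl, 0:2, 3L), lpl)
  # LA [0,1,3], 5 global alleles: 15 slots, 6 populated
  out <- project_lpl_to_pl(lpl, c(0L, 1L, 3L), 5L)
  expect_identical(length(out), n_genotypes(5, 2))
  expect_identical(sum(!is.na(out)), n_genotypes(3, 2))
  # the populated entries land at the genotype indices of the mapped pairs
  for (k in 1:3) for (j in 1:k) {
    la <- c(0L, 1L, 3L)
    expect_identical(out[genotype_index(la[j], la[k]) + 1L],
                     lpl[genotype_index(j - 1L, k - 1L) + 1L])
  }
  # hom-ref-only local set
  expect_identical(project_lpl_to_pl(0L, 0L, 2L), c(0L, NA_integer_, NA_integer_))
  # sentinel fill
  expect_identical(project_lpl_to_pl(0L, 0L, 2L, fill = 999L)[2:3], c(999L, 999L))
  expect_error(project_lpl_to_pl(c(0L, 1L), 0:1, 3L), "LG number")
})

test_that("project_lgt_to_gt maps indices and preserves phase", {
  expect_identical(project_lgt_to_gt("1/2", c(0L, 1L, 3L)), "1/3")
  expect_identical(project_lgt_to_gt("0/0", c(0L, 4L)), "0/0")
  expect_identical(project_lgt_to_gt("0|1", c(0L, 4L)), "0|4")
  expect_identical(project_lgt_to_gt("1|0", c(0L, 2L)), "2|0")
  expect_identical(project_lgt_to_gt(".", c(0L, 1L)), ".")
  expect_error(project_lgt_to_gt("0/3", c(0L, 1L)), "beyond LA")
})

test_that("projection on identity LA reproduces the GVCF fields exactly", {
  g <- make_gvcf(gvcf_line("chr1", 100, "A", "C,G", "DP=30", "GT:AD:PL:DP:GQ",
                           "1/2:2,13,10:50,40,45,0,9,9:30:40"))
  ds <- import_gvcf(g, non_ref_policy = "retain")
  e <- ds$entries[1, ]
  la <- e$la[[1]]
  expect_identical(project_lad_to_ad(e$lad[[1]], la, 3L), g$records$ad[[1]])
  expect_identical(project_lpl_to_pl(e$lpl[[1]], la, 3L), g$records$pl[[1]])
  expect_identical(project_lgt_to_gt(e$lgt, la), g$records$gt[1])
})

test_that("read depth is conserved under AD projection", {
  set.seed(99)
  for (i in 1:20) {
    n_global <- sample(2:10, 1)
    n_local <- sample(1:min(3, n_global), 1)
    la <- c(0L, sort(sample(seq_len(n_global - 1L), n_local - 1L)))
    lad <- sample.int(30L, length(la), replace = TRUE)
    expect_identical(sum(project_lad_to_ad(lad, la, n_global)), sum(lad))
  }
})

test_that("point-query densification resolves variants, blocks, and missing", {
  a <- import_gvcf(make_gvcf(c(
    gvcf_line("chr1", 4500, "A", "<NON_REF>", "END=14499", "GT:DP:GQ", "0/0:30:50"),
    gvcf_line("chr1", 20000, "C", "T", ".", "GT:AD:DP:GQ", "0/1:5,6:11:30")),
    sample = "A"))
  b <- import_gvcf(make_gvcf(
    gvcf_line("chr1", 9000, "G", "GA", ".", "GT:AD:DP:GQ", "1/1:0,12:12:36"),
    sample = "B"))
  ds <- merge_datasets(list(a, b))
  row <- densify_at_locus(ds, "chr1", 9000)
  # sample A has no record at 9000 but its block chr1:4500 len 10000 covers it
  expect_identical(row$calls$A$src, "block")
  expect_identical(row$calls$A$gt, "0/0")
  expect_identical(row$calls$A$dp, 30L)
  expect_identical(row$calls$A$gq, 50L)
  expect_identical(row$calls$B$src, "variant")
  expect_identical(row$calls$B$gt, "1/1")
  # at 20000, B is neither variant nor covered: missing
  row2 <- densify_at_locus(ds, "chr1", 20000)
  expect_identical(row2$calls$B$src, "missing")
  expect_identical(row2$calls$B$gt, "./.")
  expect_identical(row2$calls$A$src, "variant")
  expect_error(densify_at_locus(ds, "chrZ", 1), "unknown contig")
})

test_that("the point query agrees with a brute-force scan over all rows", {
  m <- cohort_model(n_samples = 3, k_variants_per_sample = 30,
                    genome_length = 8000, seed = 31)
  ds <- merge_datasets(lapply(simulate_cohort(m), import_gvcf))
  set.seed(1)
  for (pos in sample(ds$sites$pos, 10)) {
    row <- densify_at_locus(ds, "chr1", pos)
    for (smp in ds$samples) {
      # oracle: scan every block of the sample with no search-window shortcut
      blocks <- ds$ref[ds$ref$sample == smp, ]
      covered <- any(blocks$pos <= pos & blocks$pos + blocks$len - 1L >= pos)
      has_entry <- any(ds$entries$sample == smp & ds$entries$pos == pos)
      want <- if (has_entry) "variant" else if (covered) "block" else "missing"
      expect_identical(row$calls[[smp]]$src, want)
    }
  }
})

test_that("streaming densification equals the point query at every site", {
  m <- cohort_model(n_samples = 4, k_variants_per_sample = 40,
                    genome_length = 10000, seed = 37)
  ds <- merge_datasets(lapply(simulate_cohort(m), import_gvcf))
  rows <- densify_stream(ds)
  expect_identical(length(rows), nrow(ds$sites))
  point <- lapply(seq_len(nrow(ds$sites)),
                  function(i) densify_at_locus(ds, ds$sites$contig[i], ds$sites$pos[i]))
  expect_identical(dense_to_df(rows), dense_to_df(point))
  # no variant sites -> empty stream
  empty <- svcr_dataset(samples = "S1", contigs = "chr1")
  expect_identical(densify_stream(empty), list())
})

test_that("a fixed-period partition densifies from its own rows alone", {
  m <- cohort_model(n_samples = 3, k_variants_per_sample = 40,
                    genome_length = 10000, seed = 43)
  ds <- merge_datasets(lapply(simulate_cohort(m), import_gvcf))
  k <- 2000L
  split <- split_fixed_period(ds, k)
  full <- dense_to_df(densify_stream(split))
  for (part in 1:3) {
    region <- list(contig = "chr1", start = (part - 1L) * k + 1L, end = part * k)
    sub <- dense_to_df(densify_stream(split, region = region))
    want <- full[full$pos >= region$start & full$pos <= region$end, ]
    rownames(want) <- NULL
    expect_identical(sub, want)
  }
})
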