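# SVCR-VCF serialization and dense/hardcalls export.

two_sample_ds <- function(seed = 47) {
  m <- cohort_model(n_samples = 2, k_variants_per_sample = 30,
                    genome_length = 8000, seed = seed)
  merge_datasets(lapply(simulate_cohort(m), import_gvcf))
}

test_that("write_svcr_vcf emits the required header and one row per locus", {
  ds <- two_sample_ds()
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_svcr_vcf(ds, tmp)
  lines <- readLines(tmp)
  hdr <- lines[startsWith(lines, "##")]
  for (key in c("LA", "LEN", "LGT", "LAD", "LPL"))
    expect_true(any(grepl(sprintf("^##FORMAT=<ID=%s,", key), hdr)), label = key)
  expect_true(any(grepl("^##MAXIMUM_REFERENCE_BLOCK_LENGTH=[0-9]+$", hdr)))
  expect_match(grep("MAXIMUM", hdr, value = TRUE),
               as.character(ds$max_ref_block_length))
  body <- lines[!startsWith(lines, "#")]
  n_loci <- nrow(unique(rbind(ds$sites[c("contig", "pos")],
                              ds$ref[c("contig", "pos")])))
  expect_identical(length(body), n_loci)
  # block-only rows carry ALT="."
  alt <- vapply(strsplit(body, "\t"), `[[`, character(1), 5)
  pos <- as.integer(vapply(strsplit(body, "\t"), `[[`, character(1), 2))
  expect_true(all(alt[!pos %in% ds$sites$pos] == "."))
})

test_that("SVCR-VCF round trips and is byte-stable", {
  ds <- two_sample_ds()
  t1 <- withr::local_tempfile(fileext = ".vcf")
  t2 <- withr::local_tempfile(fileext = ".vcf")
  write_svcr_vcf(ds, t1)
  write_svcr_vcf(ds, t2)
  expect_identical(readLines(t1), readLines(t2))
  ds2 <- read_svcr_vcf(t1)
  expect_true(datasets_equal(ds, ds2))
  expect_identical(ds2$max_ref_block_length, ds$max_ref_block_length)
  # and a second round trip is exact at the byte level
  t3 <- withr::local_tempfile(fileext = ".vcf.gz")
  write_svcr_vcf(ds2, t3)
  expect_identical(readLines(gzfile(t1)), readLines(gzfile(t3)))
})

test_that("a row can hold one sample's block start and another's variant", {
  a <- import_gvcf(make_gvcf(c(
    gvcf_line("chr1", 100, "A", "<NON_REF>", "END=499", "GT:DP:GQ", "0/0:30:50")),
    sample = "A"))
  b <- import_gvcf(make_gvcf(c(
    gvcf_line("chr1", 100, "A", "G", ".", "GT:AD:DP:GQ", "0/1:4,5:9:33")),
    sample = "B"))
  ds <- merge_datasets(list(a, b))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_svcr_vcf(ds, tmp)
  body <- grep("^[^#]", readLines(tmp), value = TRUE)
  expect_identical(length(body), 1L)
  f <- strsplit(body, "\t")[[1]]
  keys <- strsplit(f[9], ":")[[1]]
  va <- strsplit(f[10], ":")[[1]]; vb <- strsplit(f[11], ":")[[1]]
  expect_identical(va[match("LEN", keys)], "400")
  expect_identical(va[match("LA", keys)], ".")
  expect_identical(vb[match("LEN", keys)], ".")
  expect_identical(vb[match("LA", keys)], "0,1")
  expect_identical(vb[match("LGT", keys)], "0/1")
  ds2 <- read_svcr_vcf(tmp)
  expect_true(datasets_equal(ds, ds2))
})

test_that("the reader enforces the encoding rules", {
  ds <- two_sample_ds()
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_svcr_vcf(ds, tmp)
  lines <- readLines(tmp)

  # header bound smaller than an actual block
  broken <- sub("^##MAXIMUM_REFERENCE_BLOCK_LENGTH=[0-9]+$",
                "##MAXIMUM_REFERENCE_BLOCK_LENGTH=1", lines)
  t2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(broken, t2)
  expect_error(read_svcr_vcf(t2), "smaller than an actual block")

  # LEN and LA together in one genotype
  hand <- c("##fileformat=VCFv4.3",
            "##contig=<ID=chr1>",
            "##FORMAT=<ID=LGT,Number=1,Type=String,Description=\"g\">",
            "##FORMAT=<ID=LA,Number=.,Type=Integer,Description=\"a\">",
            "##FORMAT=<ID=LEN,Number=1,Type=Integer,Description=\"l\">",
            paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO",
                    "FORMAT","S1"), collapse = "\t"),
            paste(c("chr1","10",".","A","C",".",".",".","LGT:LA:LEN","0/1:0,1:50"),
                  collapse = "\t"))
  t3 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(hand, t3)
  expect_error(read_svcr_vcf(t3), "both LEN and LA")

  # FORMAT data strictly inside the same sample's reference block
  hand2 <- c(hand[1:6],
             paste(c("chr1","10",".","A",".",".",".",".","LGT:LA:LEN",".:.:100"),
                   collapse = "\t"),
             paste(c("chr1","50",".","A","C",".",".",".","LGT:LA:LEN","0/1:0,1:."),
                   collapse = "\t"))
  t4 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(hand2, t4)
  expect_error(read_svcr_vcf(t4), "strictly inside")

  # a file without LA/LEN declarations is not an SVCR-VCF
  t5 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.3", hand[6]), t5)
  expect_error(read_svcr_vcf(t5), "LA and LEN")
})

test_that("a hand-written two-sample SVCR-VCF densifies to the expected calls", {
  # 20 bp of two samples: S1 carries a SNP at 7 inside S2's reference block;
  # S2 carries an insertion at 12 inside S1's block
  hand <- c("##fileformat=VCFv4.3",
            "##MAXIMUM_REFERENCE_BLOCK_LENGTH=14",
            "##contig=<ID=chr1>",
            "##FORMAT=<ID=LGT,Number=1,Type=String,Description=\"g\">",
            "##FORMAT=<ID=LA,Number=.,Type=Integer,Description=\"a\">",
            "##FORMAT=<ID=LEN,Number=1,Type=Integer,Description=\"l\">",
            "##FORMAT=<ID=LAD,Number=.,Type=Integer,Description=\"d\">",
            "##FORMAT=<ID=LPL,Number=.,Type=Integer,Description=\"p\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"D\">",
            "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"G\">",
            paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO",
                    "FORMAT","S1","S2"), collapse = "\t"),
            paste(c("chr1","1",".","A",".",".",".",".",
                    "LGT:LA:LEN:LAD:LPL:DP:GQ",
                    ".:.:6:.:.:31:50", ".:.:11:.:.:27:99"), collapse = "\t"),
            paste(c("chr1","7",".","T","C",".",".",".",
                    "LGT:LA:LEN:LAD:LPL:DP:GQ",
                    "0/1:0,1:.:15,16:40,0,37:31:40", "."), collapse = "\t"),
            paste(c("chr1","8",".","C",".",".",".",".",
                    "LGT:LA:LEN:LAD:LPL:DP:GQ",
                    ".:.:13:.:.:30:99", "."), collapse = "\t"),
            paste(c("chr1","12",".","G","GTT",".",".",".",
                    "LGT:LA:LEN:LAD:LPL:DP:GQ",
                    ".", "1/1:0,1:.:0,22:90,20,0:22:20"), collapse = "\t"),
            paste(c("chr1","13",".","A",".",".",".",".",
                    "LGT:LA:LEN:LAD:LPL:DP:GQ",
                    ".", ".:.:8:.:.:25:45"), collapse = "\t"))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(hand, tmp)
  ds <- read_svcr_vcf(tmp)
  expect_identical(nrow(validate_dataset(ds)), 0L)
  rows <- densify_stream(ds)
  expect_identical(length(rows), 2L)
  # SNP site: S1 het from its variant entry, S2 hom-ref from block chr1:1 len 11
  expect_identical(rows[[1]]$calls$S1$gt, "0/1")
  expect_identical(rows[[1]]$calls$S1$ad, c(15L, 16L))
  expect_identical(rows[[1]]$calls$S2$gt, "0/0")
  expect_identical(rows[[1]]$calls$S2$dp, 27L)
  # insertion site: S2 hom-alt, S1 hom-ref from block chr1:8 len 13
  expect_identical(rows[[2]]$calls$S2$gt, "1/1")
  expect_identical(rows[[2]]$calls$S1$gt, "0/0")
  expect_identical(rows[[2]]$calls$S1$gq, 99L)
})

test_that("single-sample SVCR-VCF equals the GVCF modulo LA and LEN", {
  g <- make_gvcf(c(
    gvcf_line("chr1", 100, "A", "<NON_REF>", "END=199", "GT:DP:GQ", "0/0:30:50"),
    gvcf_line("chr1", 200, "A", "C", "DP=25", "GT:AD:PL:DP:GQ",
              "0/1:12,13:50,0,45:25:45")))
  ds <- import_gvcf(g, non_ref_policy = "drop")
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_svcr_vcf(ds, tmp)
  body <- strsplit(grep("^[^#]", readLines(tmp), value = TRUE), "\t")
  keys <- strsplit(body[[2]][9], ":")[[1]]
  vals <- strsplit(body[[2]][10], ":")[[1]]
  # un-prefixing LGT/LAD/LPL recovers the GVCF FORMAT values
  expect_identical(vals[match("LGT", keys)], "0/1")
  expect_identical(vals[match("LAD", keys)], "12,13")
  expect_identical(vals[match("LPL", keys)], "50,0,45")
  expect_identical(vals[match("LA", keys)], "0,1")   # the identity addition
  expect_identical(strsplit(body[[1]][10], ":")[[1]][match("LEN", keys)], "100")
})

test_that("hardcalls export has GT only; dense export carries projected fields", {
  ds <- two_sample_ds()
  hc <- withr::local_tempfile(fileext = ".vcf")
  export_hardcalls_pvcf(ds, hc)
  lines <- readLines(hc)
  body <- grep("^[^#]", lines, value = TRUE)
  expect_identical(length(body), nrow(ds$sites))
  fmt <- unique(vapply(strsplit(body, "\t"), `[[`, character(1), 9))
  expect_identical(fmt, "GT")
  expect_false(any(grepl("LEN|LA|LAD|LPL|AD|PL", fmt)))
  # GT column equals the densified genotypes
  rows <- densify_stream(ds)
  gts <- vapply(strsplit(body, "\t"), `[[`, character(1), 10)
  expect_identical(gts, vapply(rows, function(r) r$calls[[1]]$gt, character(1)))

  dn <- withr::local_tempfile(fileext = ".vcf")
  export_dense_pvcf(ds, dn)
  dbody <- grep("^[^#]", readLines(dn), value = TRUE)
  f <- strsplit(dbody[[1]], "\t")[[1]]
  expect_identical(f[9], "GT:AD:PL:DP:GQ")
  # empty dataset: header only
  e <- withr::local_tempfile(fileext = ".vcf")
  export_dense_pvcf(svcr_dataset("S1", "chr1"), e)
  expect_identical(grep("^[^#]", readLines(e), value = TRUE), character())
})

test_that("an independent VCF parser reads our SVCR-VCF", {
  ds <- two_sample_ds()
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_svcr_vcf(ds, tmp)
  v <- suppressWarnings(VariantAnnotation::readVcf(tmp))
  expect_identical(colnames(v), ds$samples)
  n_loci <- nrow(unique(rbind(ds$sites[c("contig", "pos")],
                              ds$ref[c("contig", "pos")])))
  expect_identical(nrow(v), n_loci)
  len <- VariantAnnotation::geno(v)$LEN
  got <- len[cbind(match(paste0("chr1:", ds$ref$pos), sub("_.*", "", rownames(len))),
                   match(ds$ref$sample, colnames(len)))]
  expect_identical(as.integer(got), ds$ref$len)
})
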