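test_that("VCF round trip reproduces the simulator's records exactly", {
  sim <- simulate_family_exome(sim_config(n_background = 300, seed = 11))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$variants, sim$genotypes, path, pedigree = sim$pedigree)
  back <- read_vcf(path)
  expect_equal(back$variants$variant_id, sim$variants$variant_id)
  expect_equal(back$variants$pos, sim$variants$pos)
  expect_equal(back$variants$gene, sim$variants$gene)
  expect_equal(back$variants$region_class, sim$variants$region_class)
  m_in <- digenicscan:::gt_matrix(sim$genotypes,
                                  variant_ids = sim$variants$variant_id,
                                  sample_ids = sim$pedigree$sample_id)
  m_out <- digenicscan:::gt_matrix(back$genotypes,
                                   variant_ids = sim$variants$variant_id,
                                   sample_ids = sim$pedigree$sample_id)
  expect_identical(m_in, m_out)
})

test_that("genotype codes map from GT strings, with phase ignored", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    paste("chr1", "100", ".", "A", "G", ".", "PASS", "GENE=G1;REGION=exonic",
          "GT", "0/1", "1|0", "1/1", "./.", sep = "\t")
  ), path)
  out <- read_vcf(path)
  expect_equal(nrow(out$variants), 1)
  expect_equal(out$variants$gene, "G1")
  expect_equal(out$genotypes$gt, c(1L, 1L, 2L, NA))
})

test_that("multiallelic sites split into per-alt records with biallelic recoding", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("chr2", "500", ".", "C", "A,G", ".", "PASS", ".",
          "GT", "1/2", "2/2", sep = "\t")
  ), path)
  out <- read_vcf(path)
  expect_equal(out$variants$variant_id,
               c("chr2:500:C:A", "chr2:500:C:G"))
  m <- digenicscan:::gt_matrix(out$genotypes)
  # s1 is 1/2: dosage 1 of each alt; s2 is 2/2: dosage 2 of alt G only
  expect_equal(unname(m["chr2:500:C:A", ]), c(1L, 0L))
  expect_equal(unname(m["chr2:500:C:G", ]), c(1L, 2L))
  # splitting conserves total alt dosage per sample
  expect_equal(colSums(m), c(s1 = 2, s2 = 2))
})

test_that("a 50-site quartet fixture yields 50 records x 4 samples", {
  sim <- simulate_family_exome(sim_config(n_background = 50, seed = 5,
                                          plant = FALSE))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$variants, sim$genotypes, path, pedigree = sim$pedigree)
  # independent line scan of the written file
  lines <- readLines(path)
  n_data <- sum(!startsWith(lines, "#"))
  out <- read_vcf(path)
  expect_equal(nrow(out$variants), n_data)
  expect_equal(nrow(out$variants), 50)
  expect_equal(nrow(out$genotypes), 50 * 4)
})

test_that("VCF errors: zero samples and malformed headers are rejected", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  ), path)
  expect_error(read_vcf(path), "zero sample")
  writeLines(c("not a vcf", "x"), path)
  expect_error(read_vcf(path), "malformed VCF header")
})

test_that("pedigree parsing: quartet, founders, affected flags", {
  path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c(
    "FAM1\tfather\t0\t0\t1\t1",
    "FAM1\tmother\t0\t0\t2\t1",
    "FAM1\tproband\tfather\tmother\t2\t2",
    "FAM1\tsibling\tfather\tmother\t2\t2"
  ), path)
  ped <- read_pedigree(path)
  expect_equal(sum(ped$affected), 2)
  non_founders <- ped[!is.na(ped$father_id), ]
  expect_true(all(non_founders$affected))
  expect_setequal(ped$sample_id[is.na(ped$father_id)],
                  c("father", "mother"))
})

test_that("pedigree validation: single member ok, structural defects fatal", {
  path <- withr::local_tempfile(fileext = ".ped")
  writeLines("FAM1\tonly\t0\t0\t2\t2", path)
  expect_equal(nrow(read_pedigree(path)), 1)

  writeLines(c("FAM1\tkid\tghost\t0\t1\t2"), path)
  expect_error(read_pedigree(path), "unknown parent")

  writeLines(c("FAM1\tdup\t0\t0\t1\t2", "FAM1\tdup\t0\t0\t1\t1"), path)
  expect_error(read_pedigree(path), "duplicate sample")
})

test_that("pedigree validation rejects randomized cyclic constructions", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    ids <- paste0("m", seq_len(n))
    # a directed parent cycle over all members, random rotation
    shift <- sample(n, 1)
    ped <- tibble::tibble(
      family_id = "F", sample_id = ids,
      father_id = ids[(seq_len(n) + shift - 1) %% n + 1],
      mother_id = NA_character_,
      sex = 1L, affected = c(TRUE, rep(FALSE, n - 1))
    )
    expect_error(as_pedigree(ped), "cycle")
  }
  # self-parenting is the degenerate cycle
  expect_error(as_pedigree(tibble::tibble(
    family_id = "F", sample_id = "x", father_id = "x",
    mother_id = NA_character_, sex = 1L, affected = TRUE)), "cycle")
})

test_that("GMT parsing: dedup, empty file, field-count error, round trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines("FGF21_PATHWAY\tdesc\tFGFR1\tKLB\tKLB", path)
  gs <- read_geneset(path)
  expect_equal(nrow(gs), 2)
  expect_setequal(gs$gene, c("FGFR1", "KLB"))

  writeLines(character(0), path)
  expect_equal(nrow(read_geneset(path)), 0)

  writeLines("BROKEN\tonly_two_fields", path)
  expect_error(read_geneset(path), "line 1")

  gs2 <- tibble::tibble(set_name = rep(c("A", "B"), each = 2),
                        description = "d",
                        gene = c("g1", "g2", "g2", "g3"))
  write_geneset(gs2, path)
  back <- read_geneset(path)
  expect_equal(digenicscan:::geneset_list(back),
               digenicscan:::geneset_list(gs2))
})

test_that("report writing: header-only when empty, JSON round trip", {
  k <- kindred_example()
  scan <- scan_digenic(k$variants, k$genotypes, k$pedigree,
                       k$annotations, k$genesets)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")

  write_report(scan$pairs[0, ], tsv, "tsv")
  lines <- readLines(tsv)
  expect_length(lines, 1)
  expect_match(lines, "^rank\tgene_a")

  write_report(scan$pairs, tsv, "tsv")
  expect_equal(nrow(read_report(tsv)), 1)

  write_report(scan$pairs, js, "json")
  back <- read_report(js)
  expect_equal(as.data.frame(back),
               as.data.frame(digenicscan:::report_table(scan$pairs)))
})
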