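test_that("a fixed seed makes the simulator byte-identical", {
  cfg <- sim_config(n_background = 120, seed = 99)
  s1 <- simulate_family_exome(cfg)
  s2 <- simulate_family_exome(cfg)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$annotations, s2$annotations)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_simulation(s1, d1)
  p2 <- write_simulation(s2, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     label = sprintf("file %s", f))
  }
})

test_that("degenerate allele frequencies produce degenerate founders", {
  cfg0 <- sim_config(n_background = 60, af_fixed = 0, plant = FALSE,
                     seed = 1)
  set.seed(1)
  f0 <- simulate_founders(cfg0)
  expect_true(all(f0$genotypes$gt == 0))

  cfg1 <- sim_config(n_background = 60, af_fixed = 1, plant = FALSE,
                     seed = 1)
  set.seed(1)
  f1 <- simulate_founders(cfg1)
  expect_true(all(f1$genotypes$gt == 2))
})

test_that("background allele frequencies respect the truncation bounds", {
  cfg <- sim_config(n_background = 2000, seed = 31)
  set.seed(31)
  f <- simulate_founders(cfg)
  expect_true(all(f$variants$af >= cfg$af_min))
  expect_true(all(f$variants$af <= cfg$af_max))
})

test_that("transmission follows Mendel: het x hom-ref and hom x hom", {
  ped <- quartet_pedigree()
  n <- 10000
  ids <- sprintf("t%05d", seq_len(n))
  founder_gt <- dplyr::bind_rows(
    tibble::tibble(variant_id = ids, sample_id = "father", gt = 0L),
    tibble::tibble(variant_id = ids, sample_id = "mother", gt = 1L)
  )
  out <- transmit(ped, founder_gt, seed = 7)
  child <- out$gt[out$sample_id == "proband"]
  frac <- mean(child == 1)
  se <- sqrt(0.25 / n)
  expect_lt(abs(frac - 0.5), 3 * se)
  expect_true(all(child %in% 0:1))

  hom_gt <- dplyr::bind_rows(
    tibble::tibble(variant_id = "v", sample_id = "father", gt = 2L),
    tibble::tibble(variant_id = "v", sample_id = "mother", gt = 2L)
  )
  out2 <- transmit(ped, hom_gt, seed = 8)
  expect_true(all(out2$gt[out2$sample_id %in%
                            c("proband", "sibling")] == 2))
})

test_that("transmission fairness holds across seeds (chi-square at 0.001)", {
  n <- 10000
  ids <- sprintf("t%05d", seq_len(n))
  ped <- quartet_pedigree()
  founder_gt <- dplyr::bind_rows(
    tibble::tibble(variant_id = ids, sample_id = "father", gt = 0L),
    tibble::tibble(variant_id = ids, sample_id = "mother", gt = 1L)
  )
  fair <- vapply(1:100, function(s) {
    out <- transmit(ped, founder_gt, seed = s)
    k <- sum(out$gt[out$sample_id == "proband"])
    p <- stats::chisq.test(c(k, n - k), p = c(0.5, 0.5))$p.value
    p > 0.001
  }, logical(1))
  expect_gte(sum(fair), 95)
})

test_that("a non-founder with a single recorded parent is an error", {
  ped <- tibble::tibble(
    family_id = "F", sample_id = c("mom", "kid"),
    father_id = c(NA, NA), mother_id = c(NA, "mom"),
    sex = c(2L, 1L), affected = c(FALSE, TRUE))
  g <- tibble::tibble(variant_id = "v", sample_id = "mom", gt = 1L)
  expect_error(transmit(ped, g), "only one parent")
})

test_that("planted pair has the designed cross-parental architecture", {
  sim <- simulate_family_exome(sim_config(n_background = 200, seed = 13))
  tr <- sim$truth
  m <- digenicscan:::gt_matrix(sim$genotypes,
                               sample_ids = sim$pedigree$sample_id)
  expect_equal(unname(m[tr$variant_a, c("mother", "father")]), c(1L, 0L))
  expect_equal(unname(m[tr$variant_b, c("mother", "father")]), c(0L, 1L))
  expect_true(all(m[tr$variant_a, c("proband", "sibling")] == 1))
  expect_true(all(m[tr$variant_b, c("proband", "sibling")] == 1))
  expect_false(tr$gene_a == tr$gene_b)
  # planted AFs pass the rarity rule at the default threshold
  ann <- sim$annotations
  planted_ann <- ann[ann$variant_id %in% c(tr$variant_a, tr$variant_b), ]
  expect_true(all(rarity_pass(planted_ann)))
  # and the causal gene set contains both genes
  causal <- sim$genesets[sim$genesets$set_name == "CAUSAL_PATHWAY", ]
  expect_true(all(c(tr$gene_a, tr$gene_b) %in% causal$gene))
})

test_that("planting requires an affected child", {
  ped <- tibble::tibble(
    family_id = "F", sample_id = c("father", "mother"),
    father_id = NA_character_, mother_id = NA_character_,
    sex = c(1L, 2L), affected = FALSE)
  cfg <- suppressWarnings(
    sim_config(n_background = 10, pedigree = ped, seed = 1))
  expect_error(simulate_family_exome(cfg), "no affected")
})

test_that("degenerate annotation rates yield clean calls", {
  cfg <- sim_config(n_background = 150, seed = 17,
                    p_predictor_sensitivity = 1,
                    p_predictor_false_damaging = 0,
                    p_missing_call = 0)
  sim <- simulate_family_exome(cfg)
  cls <- classify_variants(sim$annotations)
  planted <- cls$variant_id %in% c(sim$truth$variant_a,
                                   sim$truth$variant_b)
  expect_true(all(cls$n_damaging[planted] == 7))
  expect_true(all(cls$n_damaging[!planted] == 0))
  expect_true(all(cls$n_informative == 7))

  # all calls missing -> min_informative blocks every verdict
  cfg2 <- sim_config(n_background = 50, seed = 18, p_missing_call = 1)
  sim2 <- simulate_family_exome(cfg2)
  cls2 <- classify_variants(sim2$annotations)
  expect_false(any(cls2$deleterious))
  expect_true(all(cls2$insufficient_evidence))
})

test_that("genotype errors perturb roughly the configured fraction", {
  cfg <- sim_config(n_background = 2000, seed = 19, plant = FALSE,
                    genotype_error_rate = 0.1)
  sim <- simulate_family_exome(cfg)
  clean <- simulate_family_exome(
    sim_config(n_background = 2000, seed = 19, plant = FALSE,
               genotype_error_rate = 0))
  # an error draw may coincide with the original value, so the observed
  # change rate is ~ rate * 3/4 (uniform over 4 codes)
  a <- sim$genotypes$gt
  b <- clean$genotypes$gt
  changed <- mean((is.na(a) != is.na(b)) | (!is.na(a) & !is.na(b) & a != b))
  expect_gt(changed, 0.05)
  expect_lt(changed, 0.11)
})

test_that("recovery metrics score the planted pair correctly", {
  truth <- list(gene_a = "G1", gene_b = "G2")
  pair <- function(ga, gb) {
    tibble::tibble(gene_a = ga, variant_a = "x", origin_a = "maternal",
                   gene_b = gb, variant_b = "y", origin_b = "paternal",
                   shared_affected = list(c("p", "s")),
                   shared_affected_count = 2L,
                   genesets = NA_character_, score = 1, rank = 1L)
  }
  sole <- evaluate_recovery(truth, pair("G1", "G2"))
  expect_equal(sole$recall, 1L)
  expect_equal(sole$precision, 1)

  four <- evaluate_recovery(truth, dplyr::bind_rows(
    pair("G1", "G2"), pair("G3", "G4"), pair("G5", "G6"), pair("G7", "G8")))
  expect_equal(four$precision, 0.25)

  # unordered gene-pair match
  swapped <- evaluate_recovery(truth, pair("G2", "G1"))
  expect_equal(swapped$recall, 1L)

  absent <- evaluate_recovery(truth, pair("G3", "G4"))
  expect_equal(absent$recall, 0L)
  expect_equal(absent$precision, 0)
  expect_equal(evaluate_recovery(truth, pair("G1", "G2")[0, ])$recall, 0L)
})
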