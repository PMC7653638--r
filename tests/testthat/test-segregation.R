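quartet <- quartet_pedigree()

test_that("de novo scan: definition, carrier parent, missing data", {
  v <- make_variants(c("v1", "v2", "v3"), c("G1", "G2", "G3"))
  g <- make_genotypes(list(
    v1 = c(father = 0, mother = 0, proband = 1, sibling = 1), # de novo
    v2 = c(father = 0, mother = 1, proband = 1, sibling = 1), # inherited
    v3 = c(father = NA, mother = 0, proband = 1, sibling = 1) # missing
  ))
  out <- de_novo_scan(v, g, quartet)
  expect_equal(out$variant_id, "v1")
  expect_equal(out$pattern, "de_novo")
  expect_setequal(out$affected_carriers[[1]], c("proband", "sibling"))
})

test_that("de novo scan requires every affected child to carry", {
  v <- make_variants("v1", "G1")
  g <- make_genotypes(list(
    v1 = c(father = 0, mother = 0, proband = 1, sibling = 0)
  ))
  expect_equal(nrow(de_novo_scan(v, g, quartet)), 0)
})

test_that("affected child without both parents is skipped with a warning", {
  ped <- tibble::tibble(
    family_id = "F", sample_id = c("solo"),
    father_id = NA_character_, mother_id = NA_character_,
    sex = 2L, affected = TRUE
  )
  v <- make_variants("v1", "G1")
  g <- make_genotypes(list(v1 = c(solo = 1)))
  expect_warning(out <- de_novo_scan(v, g, ped), "without both parents")
  expect_equal(nrow(out), 0)
})

test_that("recessive scan: homozygous model", {
  v <- make_variants(c("v1", "v2"), c("G1", "G2"))
  g <- make_genotypes(list(
    v1 = c(father = 1, mother = 1, proband = 2, sibling = 2),
    v2 = c(father = 1, mother = 0, proband = 2, sibling = 2) # impossible/err
  ))
  out <- recessive_scan(v, g, quartet)
  hom <- out[out$pattern == "hom_recessive", ]
  expect_equal(hom$variant_id, "v1")
})

test_that("recessive scan: compound het needs opposite origins in one gene", {
  v <- make_variants(c("m1", "p1"), c("G1", "G1"))
  g <- make_genotypes(list(
    m1 = c(father = 0, mother = 1, proband = 1, sibling = 1),
    p1 = c(father = 1, mother = 0, proband = 1, sibling = 1)
  ))
  out <- recessive_scan(v, g, quartet)
  ch <- out[out$pattern == "comphet_partner", ]
  expect_equal(nrow(ch), 2)
  expect_setequal(ch$variant_id, c("m1", "p1"))
  expect_equal(ch$partner_variant[ch$variant_id == "m1"], "p1")
  expect_setequal(ch$origin, c("maternal", "paternal"))
})

test_that("compound het rejected when an unaffected member carries both", {
  ped <- dplyr::bind_rows(quartet, tibble::tibble(
    family_id = "FAM1", sample_id = "unaffected_sib",
    father_id = "father", mother_id = "mother", sex = 1L,
    affected = FALSE))
  v <- make_variants(c("m1", "p1"), c("G1", "G1"))
  g <- make_genotypes(list(
    m1 = c(father = 0, mother = 1, proband = 1, sibling = 1,
           unaffected_sib = 1),
    p1 = c(father = 1, mother = 0, proband = 1, sibling = 1,
           unaffected_sib = 1)
  ))
  out <- recessive_scan(v, g, ped)
  expect_equal(nrow(out[out$pattern == "comphet_partner", ]), 0)
})

test_that("phase by transmission resolves parental origin", {
  v <- make_variants(c("v1", "v2", "v3"), c("G1", "G2", "G3"))
  g <- make_genotypes(list(
    v1 = c(father = 0, mother = 1, proband = 1, sibling = 1),
    v2 = c(father = 1, mother = 1, proband = 1, sibling = 1),
    v3 = c(father = 0, mother = 0, proband = 1, sibling = 1)
  ))
  out <- phase_by_transmission(v, g, quartet, "proband")
  expect_equal(out$origin, c("maternal", "ambiguous", "ambiguous"))
})

test_that("phase by transmission enforces the heterozygous-child contract", {
  v <- make_variants("v1", "G1")
  g <- make_genotypes(list(
    v1 = c(father = 1, mother = 1, proband = 2, sibling = 1)
  ))
  expect_error(phase_by_transmission(v, g, quartet, "proband"),
               "heterozygous")
})

test_that("shared monoallelic scan mirrors the kindred configuration", {
  k <- kindred_example()
  out <- shared_monoallelic_scan(k$variants, k$genotypes, k$pedigree)
  expect_equal(nrow(out), 2)
  expect_equal(out$origin[out$gene == "FGFR1"], "maternal")
  expect_equal(out$origin[out$gene == "KLB"], "paternal")
  expect_setequal(out$affected_carriers[[1]], c("proband", "sibling"))
})

test_that("shared monoallelic scan excludes partial sharing and ambiguity", {
  v <- make_variants(c("v1", "v2", "v3"), c("G1", "G2", "G3"))
  g <- make_genotypes(list(
    v1 = c(father = 0, mother = 1, proband = 1, sibling = 0), # not shared
    v2 = c(father = 1, mother = 1, proband = 1, sibling = 1), # ambiguous
    v3 = c(father = 0, mother = 1, proband = 1, sibling = 1)  # maternal
  ))
  out <- shared_monoallelic_scan(v, g, quartet)
  expect_equal(out$variant_id, "v3")
  expect_equal(out$origin, "maternal")
})

test_that("strict vs permissive mode differ on a missing other-parent genotype", {
  v <- make_variants("v1", "G1")
  g <- make_genotypes(list(
    v1 = c(father = NA, mother = 1, proband = 1, sibling = 1)
  ))
  strict <- shared_monoallelic_scan(v, g, quartet)
  expect_equal(nrow(strict), 0)
  permissive <- shared_monoallelic_scan(v, g, quartet,
                                        allow_other_parent_carrier = TRUE)
  expect_equal(permissive$origin, "maternal")
})

test_that("de novo and shared monoallelic are mutually exclusive", {
  for (seed in 1:5) {
    sim <- random_instance(seed, n_background = 80)
    dn <- de_novo_scan(sim$variants, sim$genotypes, sim$pedigree)
    sm <- shared_monoallelic_scan(sim$variants, sim$genotypes,
                                  sim$pedigree)
    expect_length(intersect(dn$variant_id, sm$variant_id), 0)
    # output is a subset of input
    expect_true(all(dn$variant_id %in% sim$variants$variant_id))
    expect_true(all(sm$variant_id %in% sim$variants$variant_id))
  }
})

test_that("noise-free simulator output contains exactly the injected de novos", {
  cfg <- sim_config(n_background = 400, n_de_novo = 3, plant = TRUE,
                    seed = 21)
  sim <- simulate_family_exome(cfg)
  dn <- de_novo_scan(sim$variants, sim$genotypes, sim$pedigree)
  expect_setequal(dn$variant_id, sim$truth$de_novo_ids)

  cfg0 <- sim_config(n_background = 400, n_de_novo = 0, plant = FALSE,
                     seed = 22)
  sim0 <- simulate_family_exome(cfg0)
  dn0 <- de_novo_scan(sim0$variants, sim0$genotypes, sim0$pedigree)
  expect_equal(nrow(dn0), 0)
})
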