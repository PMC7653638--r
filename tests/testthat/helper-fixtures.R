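# Fixture builders shared across the suite. Everything is generated in code
# at test time; nothing is read from disk except files the tests themselves
# write to tempdir().

# Long genotype tibble from a per-variant named list of sample genotypes.
make_genotypes <- function(gt_by_variant) {
  dplyr::bind_rows(lapply(names(gt_by_variant), function(v) {
    g <- gt_by_variant[[v]]
    tibble::tibble(variant_id = v, sample_id = names(g),
                   gt = as.integer(unname(g)))
  }))
}

# Minimal variant table for hand-built scenarios.
make_variants <- function(ids, genes, region = "exonic",
                          chrom = NULL) {
  n <- length(ids)
  tibble::tibble(
    variant_id = ids,
    chrom = if (is.null(chrom)) rep("chr1", n) else chrom,
    pos = seq_len(n) * 100L,
    ref = rep("A", n),
    alt = rep("G", n),
    gene = genes,
    region_class = rep(region, length.out = n)
  )
}

# Annotation row(s) with every predictor damaging and the given AF.
all_damaging_annotations <- function(variants, af_global,
                                     af_popmax = af_global) {
  n <- nrow(variants)
  tibble::tibble(
    variant_id = variants$variant_id,
    gene = variants$gene,
    region_class = variants$region_class,
    af_global = rep(af_global, length.out = n),
    af_popmax = rep(af_popmax, length.out = n),
    cadd_phred = 30, sift_score = 0.001, polyphen2_score = 0.99,
    lrt_pred = "D", mutationtaster_pred = "D", gerp_rs = 5,
    phylop_score = 3
  )
}

# Randomized small instance for oracle-equivalence and property tests:
# simulator output with moderately noisy annotations, sometimes without a
# planted pair, so background variants occasionally survive filters.
random_instance <- function(seed, n_background = NULL) {
  set.seed(seed)
  n <- if (is.null(n_background)) sample(50:200, 1) else n_background
  cfg <- sim_config(
    n_background = n,
    p_predictor_sensitivity = runif(1, 0.7, 1),
    p_predictor_false_damaging = runif(1, 0.05, 0.35),
    p_missing_call = runif(1, 0, 0.25),
    plant = runif(1) < 0.7,
    n_genes = sample(c(10L, 30L, 80L), 1),
    n_decoy_sets = sample(2:6, 1),
    seed = seed + 1000L
  )
  simulate_family_exome(cfg)
}
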