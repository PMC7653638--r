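#' Simulation configuration for synthetic family exomes
#'
#' Parameters of the generative model the benchmark rests on: a quartet
#' pedigree, thousands of unlinked background coding variants with a
#' rare-skewed allele-frequency spectrum (truncated Beta), Mendelian
#' transmission, noisy seven-predictor annotation, and one planted trans
#' digenic pair (one variant contributed by each parent, both carried by
#' every affected child).
#'
#' @param n_background Number of background variants (default 5000,
#'   roughly the scale of a rare coding variant set in a family exome).
#' @param af_alpha,af_beta Shape parameters of the Beta allele-frequency
#'   spectrum (default Beta(0.2, 6): heavily rare-skewed so the MAF filter
#'   is consequential).
#' @param af_min,af_max Truncation bounds of the spectrum (default
#'   `[1e-5, 0.5]`).
#' @param af_fixed Optional single frequency overriding the spectrum
#'   (degenerate distributions for testing, e.g. 0 or 1).
#' @param p_predictor_sensitivity Probability that a causal variant draws a
#'   damaging call from one predictor (default 0.9).
#' @param p_predictor_false_damaging Per-predictor false damaging rate on
#'   background variants (default 0.1).
#' @param p_missing_call Per-predictor probability a call is missing
#'   (default 0.05).
#' @param genotype_error_rate Per-genotype corruption rate: with this
#'   probability a genotype is replaced by a random draw from
#'   `{0, 1, 2, NA}` (default 0).
#' @param n_de_novo Number of transmission-rule violations to inject:
#'   variants het in every affected child with hom-ref parents (default 0).
#' @param plant Plant the causal trans digenic pair (default `TRUE`).
#' @param planted_af_max Upper bound of the planted variants' population
#'   frequency; drawn uniformly from `[af_min, planted_af_max]`
#'   (default 0.002, so both planted variants pass rarity at 0.01 by
#'   construction).
#' @param n_genes Size of the synthetic gene catalog (default one gene per
#'   five background variants, at least 50).
#' @param region_props Named proportions of `exonic`, `splicing`, `other`
#'   region classes for background variants (default 0.85/0.10/0.05).
#' @param n_decoy_sets,geneset_size Decoy gene sets written alongside the
#'   causal set (default 5 sets of 10 genes; the causal set holds the two
#'   planted genes plus 8 others).
#' @param pedigree Pedigree tibble (default [quartet_pedigree()]).
#' @param seed Integer seed; a fixed seed makes the simulator's outputs
#'   byte-identical across runs.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_background = 5000,
                       af_alpha = 0.2, af_beta = 6,
                       af_min = 1e-5, af_max = 0.5,
                       af_fixed = NULL,
                       p_predictor_sensitivity = 0.9,
                       p_predictor_false_damaging = 0.1,
                       p_missing_call = 0.05,
                       genotype_error_rate = 0,
                       n_de_novo = 0,
                       plant = TRUE,
                       planted_af_max = 0.002,
                       n_genes = NULL,
                       region_props = c(exonic = 0.85, splicing = 0.10,
                                        other = 0.05),
                       n_decoy_sets = 5,
                       geneset_size = 10,
                       pedigree = quartet_pedigree(),
                       seed = 1L) {
  probs <- c(p_predictor_sensitivity, p_predictor_false_damaging,
             p_missing_call, genotype_error_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("simulation probabilities must lie in [0, 1]")
  }
  if (n_background < 0) abort("n_background must be >= 0")
  if (af_alpha <= 0 || af_beta <= 0) {
    abort("allele-frequency spectrum shape parameters must be positive")
  }
  if (af_min > af_max || af_min < 0 || af_max > 1) {
    abort("allele-frequency truncation bounds must satisfy 0 <= min <= max <= 1")
  }
  region_props <- region_props / sum(region_props)
  structure(list(
    n_background = as.integer(n_background),
    af_alpha = af_alpha, af_beta = af_beta,
    af_min = af_min, af_max = af_max, af_fixed = af_fixed,
    p_predictor_sensitivity = p_predictor_sensitivity,
    p_predictor_false_damaging = p_predictor_false_damaging,
    p_missing_call = p_missing_call,
    genotype_error_rate = genotype_error_rate,
    n_de_novo = as.integer(n_de_novo),
    plant = isTRUE(plant),
    planted_af_max = planted_af_max,
    n_genes = as.integer(n_genes %||%
                           max(50, round(n_background / 5))),
    region_props = region_props,
    n_decoy_sets = as.integer(n_decoy_sets),
    geneset_size = as.integer(geneset_size),
    pedigree = as_pedigree(pedigree),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Truncated Beta draws via the inverse CDF, so the bounds are respected
# exactly rather than by clamping.
rbeta_trunc <- function(n, alpha, beta, lo, hi) {
  u <- runif(n, pbeta(lo, alpha, beta), pbeta(hi, alpha, beta))
  qbeta(u, alpha, beta)
}

gene_catalog <- function(n_genes) sprintf("GENE%05d", seq_len(n_genes))

random_variant_records <- function(n, cfg, prefix_pos) {
  bases <- c("A", "C", "G", "T")
  chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
  pos <- prefix_pos + seq_len(n) # unique, strictly increasing
  ref <- sample(bases, n, replace = TRUE)
  alt_offset <- sample(1:3, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1 + alt_offset) %% 4 + 1]
  tibble::tibble(
    variant_id = variant_key(chrom, pos, ref, alt),
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt
  )
}

#' Draw background variants and founder genotypes
#'
#' Each background variant receives a population allele frequency from the
#' truncated Beta spectrum; each founder's genotype is the sum of two
#' independent Bernoulli(AF) alleles. Gene symbols come from a synthetic
#' catalog and region classes follow the configured proportions.
#'
#' @param cfg A [sim_config()]. Note: callers that need reproducibility
#'   should seed the RNG (the [simulate_family_exome()] wrapper seeds from
#'   `cfg$seed`).
#' @return List with `variants` (tibble including `af` — the true
#'   frequency), and `genotypes` (long tibble for the founders).
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_background
  variants <- random_variant_records(n, cfg, prefix_pos = 1e6)
  variants$gene <- sample(gene_catalog(cfg$n_genes), n, replace = TRUE)
  variants$region_class <- sample(names(cfg$region_props), n,
                                  replace = TRUE, prob = cfg$region_props)
  variants$af <- if (!is.null(cfg$af_fixed)) rep(cfg$af_fixed, n) else
    rbeta_trunc(n, cfg$af_alpha, cfg$af_beta, cfg$af_min, cfg$af_max)
  founders <- founder_ids(cfg$pedigree)
  geno <- lapply(founders, function(f) {
    tibble::tibble(
      variant_id = variants$variant_id,
      sample_id = f,
      gt = rbinom(n, 1, variants$af) + rbinom(n, 1, variants$af)
    )
  })
  list(variants = variants, genotypes = dplyr::bind_rows(geno))
}

#' Transmit founder genotypes through the pedigree
#'
#' Every non-founder receives one allele per parent, chosen uniformly from
#' that parent's two alleles, independently across variants (unlinked
#' loci): the transmitted allele is alternate with probability
#' `parent_gt / 2`. Non-founders are processed in generational order so
#' multi-generation pedigrees work; a non-founder with only one recorded
#' parent is an error.
#'
#' @param pedigree Pedigree tibble.
#' @param genotypes Long genotype table covering all founders.
#' @param seed Optional integer seed for this step alone.
#' @return Long genotype table for all pedigree members.
#' @export
transmit <- function(pedigree, genotypes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  non_founders <- pedigree[!(is.na(pedigree$father_id) &
                               is.na(pedigree$mother_id)), , drop = FALSE]
  bad <- is.na(non_founders$father_id) | is.na(non_founders$mother_id)
  if (any(bad)) {
    abort(sprintf("non-founder(s) with only one parent: %s",
                  paste(non_founders$sample_id[bad], collapse = ", ")))
  }
  variant_ids <- unique(genotypes$variant_id)
  m <- gt_matrix(genotypes, variant_ids = variant_ids,
                 sample_ids = pedigree$sample_id)
  draw_allele <- function(parent_gt) {
    out <- rep(NA_integer_, length(parent_gt))
    ok <- !is.na(parent_gt)
    out[ok] <- rbinom(sum(ok), 1, parent_gt[ok] / 2)
    out
  }
  pending <- non_founders$sample_id
  while (length(pending) > 0) {
    progressed <- FALSE
    for (id in pending) {
      row <- non_founders[non_founders$sample_id == id, ]
      # parents must already be genotyped (founders are; deeper generations
      # become available as the sweep progresses)
      if (row$mother_id %in% pending || row$father_id %in% pending) next
      m[, id] <- draw_allele(m[, row$mother_id]) +
        draw_allele(m[, row$father_id])
      pending <- setdiff(pending, id)
      progressed <- TRUE
    }
    if (!progressed) abort("pedigree transmission did not converge")
  }
  gt_long(m)
}

#' Plant the causal trans digenic pair
#'
#' Adds two new rare variants in two distinct genes: variant A carried
#' heterozygously by the mother only among founders, variant B by the
#' father only. Transmission is overridden so every affected child is
#' heterozygous for both, and unaffected children carry at most one (one of
#' the two is zeroed at random if both were transmitted). The planted
#' architecture — one monoallelic variant inherited from each parent,
#' shared by all affecteds — is exactly the configuration the scan is built
#' to recover.
#'
#' @param variants,genotypes Background tables from [simulate_founders()] /
#'   [transmit()].
#' @param pedigree Pedigree tibble; must contain at least one affected
#'   child with both parents.
#' @param cfg A [sim_config()].
#' @return List with updated `variants`, `genotypes`, and `truth` — the
#'   SimTruth record (`variant_a/b`, `gene_a/b`, origins, true AFs,
#'   `de_novo_ids` placeholder).
#' @export
plant_digenic <- function(variants, genotypes, pedigree, cfg) {
  trios <- affected_trios(pedigree, "plant_digenic")
  if (nrow(trios) == 0) {
    abort("cannot plant a digenic pair: no affected child with both parents")
  }
  catalog <- gene_catalog(cfg$n_genes)
  if (length(catalog) < 2) abort("gene catalog must hold >= 2 genes")
  genes <- sample(catalog, 2)
  mothers <- unique(trios$mother)
  fathers <- unique(trios$father)
  planted <- random_variant_records(2, cfg, prefix_pos = 5e7)
  planted$gene <- genes
  planted$region_class <- "exonic"
  planted$af <- runif(2, cfg$af_min, cfg$planted_af_max)
  members <- pedigree$sample_id
  gt_a <- setNames(rep(0L, length(members)), members)
  gt_b <- gt_a
  gt_a[mothers] <- 1L
  gt_b[fathers] <- 1L
  gt_a[trios$child] <- 1L
  gt_b[trios$child] <- 1L
  unaffected_children <- setdiff(
    pedigree$sample_id[!pedigree$affected &
                         !(is.na(pedigree$father_id) &
                             is.na(pedigree$mother_id))],
    trios$child)
  for (u in unaffected_children) {
    row <- pedigree[pedigree$sample_id == u, ]
    a <- rbinom(1, 1, gt_a[row$mother_id] / 2) +
      rbinom(1, 1, gt_a[row$father_id] / 2)
    b <- rbinom(1, 1, gt_b[row$mother_id] / 2) +
      rbinom(1, 1, gt_b[row$father_id] / 2)
    if (a >= 1 && b >= 1) {
      if (runif(1) < 0.5) a <- 0L else b <- 0L # at most one planted variant
    }
    gt_a[u] <- as.integer(a)
    gt_b[u] <- as.integer(b)
  }
  planted_gt <- tibble::tibble(
    variant_id = rep(planted$variant_id, each = length(members)),
    sample_id = rep(members, times = 2),
    gt = c(unname(gt_a), unname(gt_b))
  )
  truth <- list(
    variant_a = planted$variant_id[1], gene_a = genes[1],
    origin_a = "maternal", af_a = planted$af[1],
    variant_b = planted$variant_id[2], gene_b = genes[2],
    origin_b = "paternal", af_b = planted$af[2],
    de_novo_ids = character(0)
  )
  list(variants = dplyr::bind_rows(variants, planted),
       genotypes = dplyr::bind_rows(genotypes, planted_gt),
       truth = truth)
}

# Injected transmission-rule violations: variants het in every affected
# child with hom-ref parents (what the de novo scan must recover exactly).
inject_de_novo <- function(variants, genotypes, pedigree, cfg) {
  if (cfg$n_de_novo == 0) {
    return(list(variants = variants, genotypes = genotypes,
                ids = character(0)))
  }
  trios <- affected_trios(pedigree, "inject_de_novo")
  dn <- random_variant_records(cfg$n_de_novo, cfg, prefix_pos = 9e7)
  dn$gene <- sample(gene_catalog(cfg$n_genes), cfg$n_de_novo,
                    replace = TRUE)
  dn$region_class <- "exonic"
  dn$af <- rep(cfg$af_min, cfg$n_de_novo)
  members <- pedigree$sample_id
  gt <- matrix(0L, nrow = cfg$n_de_novo, ncol = length(members),
               dimnames = list(dn$variant_id, members))
  gt[, trios$child] <- 1L
  list(variants = dplyr::bind_rows(variants, dn),
       genotypes = dplyr::bind_rows(genotypes, gt_long(gt)),
       ids = dn$variant_id)
}

apply_genotype_errors <- function(genotypes, rate) {
  if (rate <= 0) return(genotypes)
  hit <- runif(nrow(genotypes)) < rate
  if (any(hit)) {
    genotypes$gt[hit] <- sample(c(0L, 1L, 2L, NA_integer_), sum(hit),
                                replace = TRUE)
  }
  genotypes
}

#' Synthesize noisy predictor annotations
#'
#' Generates the seven-predictor annotation profile for every variant. A
#' causal (planted) variant draws a damaging call from each predictor with
#' probability `p_predictor_sensitivity`; a background variant with the
#' false-damaging rate; each call is then independently missing with
#' `p_missing_call`. Raw scores are sampled uniformly from the damaging or
#' benign side of each predictor's conventional cutoff so the thresholding
#' logic is genuinely exercised. Frequency fields carry the true simulated
#' AF (`af_popmax` is the global AF inflated by a uniform factor, mimicking
#' ancestry-subset enrichment).
#'
#' @param variants Variant table with `af` column (true frequencies).
#' @param truth SimTruth list from [plant_digenic()], or `NULL` when no
#'   causal pair exists.
#' @param cfg A [sim_config()].
#' @return Annotation tibble with the standard columns (see
#'   [read_annotations()]).
#' @export
annotate_synthetic <- function(variants, truth, cfg) {
  n <- nrow(variants)
  causal <- if (is.null(truth)) rep(FALSE, n) else
    variants$variant_id %in% c(truth$variant_a, truth$variant_b)
  p_dam <- ifelse(causal, cfg$p_predictor_sensitivity,
                  cfg$p_predictor_false_damaging)
  state <- function() {
    s <- ifelse(runif(n) < p_dam, "damaging", "benign")
    s[runif(n) < cfg$p_missing_call] <- "missing"
    s
  }
  num_score <- function(s, dam_lo, dam_hi, ben_lo, ben_hi) {
    out <- ifelse(s == "damaging", runif(n, dam_lo, dam_hi),
                  runif(n, ben_lo, ben_hi))
    out[s == "missing"] <- NA_real_
    round(out, 4)
  }
  cat_call <- function(s, dam_values, ben_values) {
    out <- ifelse(s == "damaging",
                  sample(dam_values, n, replace = TRUE),
                  sample(ben_values, n, replace = TRUE))
    out[s == "missing"] <- NA_character_
    out
  }
  af <- variants$af
  tibble::tibble(
    variant_id = variants$variant_id,
    gene = variants$gene,
    region_class = variants$region_class,
    af_global = round(af, 6),
    af_popmax = round(pmin(af * runif(n, 1, 10), 1), 6),
    cadd_phred = num_score(state(), 20, 45, 0, 19.99),
    sift_score = num_score(state(), 0, 0.05, 0.051, 1),
    polyphen2_score = num_score(state(), 0.446, 1, 0, 0.4459),
    lrt_pred = cat_call(state(), "D", c("N", "U")),
    mutationtaster_pred = cat_call(state(), c("A", "D"), c("N", "P")),
    gerp_rs = num_score(state(), 2, 6.2, -3, 1.99),
    phylop_score = num_score(state(), 1.5, 5, -2, 1.49)
  )
}

build_genesets <- function(cfg, truth) {
  catalog <- gene_catalog(cfg$n_genes)
  causal_genes <- if (is.null(truth)) character(0) else
    c(truth$gene_a, truth$gene_b)
  available <- setdiff(catalog, causal_genes)
  filler <- sample(available,
                   min(length(available),
                       max(0, cfg$geneset_size - length(causal_genes))))
  sets <- list()
  if (length(causal_genes) > 0) {
    sets[["CAUSAL_PATHWAY"]] <- c(causal_genes, filler)
  }
  for (k in seq_len(cfg$n_decoy_sets)) {
    sets[[sprintf("DECOY_PATHWAY_%02d", k)]] <-
      sample(available, min(cfg$geneset_size, length(available)))
  }
  dplyr::bind_rows(lapply(names(sets), function(nm) {
    tibble::tibble(set_name = nm, description = "synthetic gene set",
                   gene = unique(sets[[nm]]))
  }))
}

#' Simulate a complete synthetic family exome
#'
#' End-to-end generator: background variants and founder genotypes,
#' Mendelian transmission to the children, the planted trans digenic pair,
#' optional injected de novo violations and genotype errors, noisy
#' predictor annotations, and gene sets (a causal set containing the two
#' planted genes plus decoys). Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"family_sim"` with components `variants`,
#'   `genotypes`, `pedigree`, `annotations`, `genesets`, `truth`, `config`.
#' @export
#' @examples
#' sim <- simulate_family_exome(sim_config(n_background = 100, seed = 7))
#' sim$truth$gene_a
simulate_family_exome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  founders <- simulate_founders(cfg)
  genotypes <- transmit(cfg$pedigree, founders$genotypes)
  variants <- founders$variants
  truth <- NULL
  if (cfg$plant) {
    planted <- plant_digenic(variants, genotypes, cfg$pedigree, cfg)
    variants <- planted$variants
    genotypes <- planted$genotypes
    truth <- planted$truth
  }
  dn <- inject_de_novo(variants, genotypes, cfg$pedigree, cfg)
  variants <- dn$variants
  genotypes <- dn$genotypes
  if (!is.null(truth)) {
    truth$de_novo_ids <- dn$ids
  } else if (length(dn$ids) > 0) {
    truth <- list(de_novo_ids = dn$ids)
  }
  genotypes <- apply_genotype_errors(genotypes, cfg$genotype_error_rate)
  annotations <- annotate_synthetic(variants, truth, cfg)
  genesets <- build_genesets(cfg, truth)
  structure(list(
    variants = variants, genotypes = genotypes, pedigree = cfg$pedigree,
    annotations = annotations, genesets = genesets, truth = truth,
    config = cfg
  ), class = "family_sim")
}

#' Write a simulated family exome to disk
#'
#' Emits `cohort.vcf`, `family.ped`, `annotations.tsv`, `genesets.gmt` and
#' `truth.json` into a directory, in the same dialects the readers consume.
#' The VCF header is fixed and date-free, so identical simulations produce
#' byte-identical files.
#'
#' @param sim A `"family_sim"` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "family_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    ped = file.path(dir, "family.ped"),
    annotations = file.path(dir, "annotations.tsv"),
    genesets = file.path(dir, "genesets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(sim$variants, sim$genotypes, paths["vcf"],
            pedigree = sim$pedigree)
  write_pedigree(sim$pedigree, paths["ped"])
  write_annotations(sim$annotations, paths["annotations"])
  write_geneset(sim$genesets, paths["genesets"])
  jsonlite::write_json(sim$truth %||% list(), paths["truth"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Score recovery of the planted pair
#'
#' @param truth SimTruth list (needs `gene_a`, `gene_b`).
#' @param pairs CandidatePair tibble reported by the scan.
#' @return Tibble with one row: `recall` (1 iff the planted gene pair,
#'   unordered, appears among the candidates), `precision` (`1/n` when
#'   present among `n` candidates, else 0), `n_candidates`.
#' @export
evaluate_recovery <- function(truth, pairs) {
  n <- nrow(pairs)
  hit <- FALSE
  if (!is.null(truth$gene_a) && n > 0) {
    hit <- any((pairs$gene_a == truth$gene_a &
                  pairs$gene_b == truth$gene_b) |
                 (pairs$gene_a == truth$gene_b &
                    pairs$gene_b == truth$gene_a))
  }
  tibble::tibble(
    recall = as.integer(hit),
    precision = if (hit) 1 / n else 0,
    n_candidates = as.integer(n)
  )
}
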