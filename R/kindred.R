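#' Bundled worked example: the FGFR1/KLB quartet
#'
#' A two-variant synthetic reconstruction of the canonical digenic kindred
#' configuration the pipeline is designed to detect: a quartet in which the
#' proband and her affected sister are heterozygous for a maternally
#' inherited FGFR1 missense variant (gnomAD-style global MAF 0.00039) and a
#' paternally inherited KLB missense variant (global MAF 0.002, with a
#' popmax-style subset frequency of 0.02), each parent carrying exactly one
#' of the two, with all seven in-silico predictors calling both variants
#' damaging, and a gene set covering the FGF21 signaling pathway (FGFR1,
#' KLB, FGF21). Running [scan_digenic()] on it yields exactly one candidate
#' pair: FGFR1 (maternal) x KLB (paternal).
#'
#' @return A list with `variants`, `genotypes`, `pedigree`, `annotations`,
#'   `genesets` — ready to feed to [scan_digenic()].
#' @export
#' @examples
#' k <- kindred_example()
#' scan <- scan_digenic(k$variants, k$genotypes, k$pedigree,
#'                      k$annotations, k$genesets)
#' tidy(scan)
kindred_example <- function() {
  pedigree <- quartet_pedigree()
  variants <- tibble::tibble(
    variant_id = c(variant_key("chr8", 38428531, "C", "T"),
                   variant_key("chr4", 39447371, "C", "A")),
    chrom = c("chr8", "chr4"),
    pos = c(38428531L, 39447371L),
    ref = c("C", "C"),
    alt = c("T", "A"),
    gene = c("FGFR1", "KLB"),
    region_class = c("exonic", "exonic")
  )
  # FGFR1: het mother + both sisters, father hom-ref (maternal origin);
  # KLB: het father + both sisters, mother hom-ref (paternal origin).
  genotypes <- tibble::tibble(
    variant_id = rep(variants$variant_id, each = 4),
    sample_id = rep(pedigree$sample_id, times = 2),
    gt = c(0L, 1L, 1L, 1L,   # father, mother, proband, sibling (FGFR1)
           1L, 0L, 1L, 1L)   # father, mother, proband, sibling (KLB)
  )
  annotations <- tibble::tibble(
    variant_id = variants$variant_id,
    gene = variants$gene,
    region_class = variants$region_class,
    af_global = c(0.00039, 0.002),
    af_popmax = c(0.00045, 0.02),
    cadd_phred = c(28.1, 24.3),
    sift_score = c(0.01, 0.02),
    polyphen2_score = c(0.98, 0.91),
    lrt_pred = c("D", "D"),
    mutationtaster_pred = c("D", "A"),
    gerp_rs = c(4.6, 3.9),
    phylop_score = c(2.8, 2.1)
  )
  genesets <- tibble::tibble(
    set_name = "FGF21_PATHWAY",
    description = "FGF21 receptor-complex signaling",
    gene = c("FGFR1", "KLB", "FGF21")
  )
  list(variants = variants, genotypes = genotypes, pedigree = pedigree,
       annotations = annotations, genesets = genesets)
}
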