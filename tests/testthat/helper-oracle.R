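# Independent brute-force reference for the end-to-end scan. Deliberately
# naive: scalar loops over variants, samples, pairs and gene sets, with the
# filter rules restated literally rather than calling any package predicate.
# Used to check that the vectorized pipeline computes the same candidate
# set on small instances.

oracle_damaging_count <- function(ann_row) {
  calls <- c(
    cadd = if (is.na(ann_row$cadd_phred)) NA else
      ann_row$cadd_phred >= 20,
    sift = if (is.na(ann_row$sift_score)) NA else
      ann_row$sift_score <= 0.05,
    polyphen2 = if (is.na(ann_row$polyphen2_score)) NA else
      ann_row$polyphen2_score >= 0.446,
    lrt = if (is.na(ann_row$lrt_pred)) NA else
      ann_row$lrt_pred == "D",
    mutationtaster = if (is.na(ann_row$mutationtaster_pred)) NA else
      ann_row$mutationtaster_pred %in% c("A", "D"),
    gerp = if (is.na(ann_row$gerp_rs)) NA else ann_row$gerp_rs >= 2,
    phylop = if (is.na(ann_row$phylop_score)) NA else
      ann_row$phylop_score >= 1.5
  )
  c(n_damaging = sum(calls, na.rm = TRUE),
    n_informative = sum(!is.na(calls)))
}

# Returns a character vector of "variant_a|variant_b" keys (maternal first).
oracle_candidate_pairs <- function(variants, genotypes, pedigree,
                                   annotations, genesets,
                                   max_af = 0.01, min_informative = 4) {
  gt <- function(v, s) {
    hit <- genotypes$variant_id == v & genotypes$sample_id == s
    if (!any(hit)) return(NA_integer_)
    genotypes$gt[hit][1]
  }
  affected <- pedigree$sample_id[pedigree$affected]
  surviving <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants$variant_id[i]
    a <- annotations[annotations$variant_id == v, ]
    if (nrow(a) != 1) next
    # autosomes only
    chrom <- sub("^chr", "", variants$chrom[i])
    if (!chrom %in% as.character(1:22)) next
    # coding region
    if (is.na(a$region_class) ||
        !a$region_class %in% c("exonic", "splicing")) next
    # rare or novel
    if (!is.na(a$af_global) && a$af_global >= max_af) next
    # majority-vote deleterious
    cnt <- oracle_damaging_count(a)
    if (cnt["n_informative"] < min_informative) next
    if (!(cnt["n_damaging"] > cnt["n_informative"] / 2)) next
    # shared monoallelic: het in every affected, identical unambiguous
    # origin, other parent observed hom-ref
    origins <- character(0)
    ok <- TRUE
    for (s in affected) {
      child <- gt(v, s)
      if (is.na(child) || child != 1) { ok <- FALSE; break }
      prow <- pedigree[pedigree$sample_id == s, ]
      if (is.na(prow$mother_id) || is.na(prow$father_id)) {
        ok <- FALSE; break
      }
      mo <- gt(v, prow$mother_id)
      fa <- gt(v, prow$father_id)
      if (is.na(mo) || is.na(fa)) { ok <- FALSE; break }
      if (mo >= 1 && fa == 0) {
        origins <- c(origins, "maternal")
      } else if (fa >= 1 && mo == 0) {
        origins <- c(origins, "paternal")
      } else {
        ok <- FALSE; break
      }
    }
    if (!ok || length(origins) == 0 ||
        length(unique(origins)) != 1) next
    surviving[[length(surviving) + 1]] <- list(
      id = v, gene = a$gene, origin = origins[1])
  }
  sets <- split(genesets$gene, genesets$set_name)
  keys <- character(0)
  for (x in surviving) for (y in surviving) {
    if (x$origin != "maternal" || y$origin != "paternal") next
    if (x$gene == y$gene) next
    in_same_set <- FALSE
    for (s in sets) {
      if (x$gene %in% s && y$gene %in% s) { in_same_set <- TRUE; break }
    }
    if (!in_same_set) next
    keys <- c(keys, paste(x$id, y$id, sep = "|"))
  }
  sort(keys)
}
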