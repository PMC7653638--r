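# Shared machinery for the pedigree scans. All scans take the same
# (variants, genotypes, pedigree) triple and return SegregationResult rows:
# variant_id, gene, pattern, origin, affected_carriers (list of sample ids),
# partner_variant (compound-het partner, NA elsewhere).
#
# Missing-data rule (conservative, no imputation): a missing genotype in any
# member a pattern needs disqualifies the variant for that pattern.

# Returns list(children = tibble(child, mother, father)) for affected
# members with both parents; warns (once per scan) about affecteds missing a
# parent, which are dropped from evaluation.
affected_trios <- function(pedigree, scan) {
  aff <- pedigree[pedigree$affected, , drop = FALSE]
  ok <- !is.na(aff$father_id) & !is.na(aff$mother_id)
  if (any(!ok)) {
    warn(sprintf(
      "%s: affected member(s) without both parents skipped: %s",
      scan, paste(aff$sample_id[!ok], collapse = ", ")))
  }
  tibble::tibble(child = aff$sample_id[ok],
                 mother = aff$mother_id[ok],
                 father = aff$father_id[ok])
}

# Per-variant parental origin for one child, vectorized over variants.
# Strict mode requires the non-carrier parent to be observed hom-ref;
# permissive mode ignores the other parent's genotype (missing counts as
# non-carrier). Returns "maternal", "paternal", "ambiguous" or NA (required
# genotype missing under strict mode).
origin_vector <- function(mo, fa, strict = TRUE) {
  if (strict) {
    unname(ifelse(is.na(mo) | is.na(fa), NA_character_,
                  ifelse(mo >= 1 & fa == 0, "maternal",
                         ifelse(fa >= 1 & mo == 0, "paternal",
                                "ambiguous"))))
  } else {
    mo_c <- !is.na(mo) & mo >= 1
    fa_c <- !is.na(fa) & fa >= 1
    unname(ifelse(mo_c & !fa_c, "maternal",
                  ifelse(fa_c & !mo_c, "paternal", "ambiguous")))
  }
}

#' Infer parental origin of a child's heterozygous variant by transmission
#'
#' Phase is never taken from the VCF; the parent of origin is re-derived
#' from parental genotypes: maternal iff the mother is a carrier and the
#' father homozygous reference, paternal for the converse, and ambiguous
#' when both parents carry the allele or neither does (the latter being a
#' possible de novo event or genotyping error).
#'
#' @param variants Variant table restricted to the variants of interest, or
#'   a character vector of variant ids.
#' @param genotypes Long genotype table.
#' @param pedigree Pedigree tibble.
#' @param child Sample id of the (heterozygous) child.
#' @return Tibble with `variant_id` and `origin` in
#'   `{"maternal", "paternal", "ambiguous"}`.
#' @export
phase_by_transmission <- function(variants, genotypes, pedigree, child) {
  ids <- if (is.data.frame(variants)) variants$variant_id else variants
  row <- pedigree[pedigree$sample_id == child, , drop = FALSE]
  if (nrow(row) != 1) abort(sprintf("unknown child '%s'", child))
  if (is.na(row$mother_id) || is.na(row$father_id)) {
    abort(sprintf("child '%s' does not have both parents in the pedigree",
                  child))
  }
  m <- gt_matrix(genotypes, variant_ids = ids,
                 sample_ids = c(child, row$mother_id, row$father_id))
  het <- m[, child]
  if (any(is.na(het) | het != 1)) {
    abort(sprintf(
      "phase_by_transmission requires child '%s' heterozygous at: %s",
      child, paste(ids[is.na(het) | het != 1], collapse = ", ")))
  }
  orig <- origin_vector(m[, row$mother_id], m[, row$father_id],
                        strict = FALSE)
  # With both-parent genotypes missing the permissive rule says ambiguous
  # already; strictness is not meaningful when the child is known het.
  tibble::tibble(variant_id = ids, origin = orig)
}

#' Scan for de novo variants shared by all affected children
#'
#' Returns variants carried (genotype >= 1) by every affected child whose
#' parents are both homozygous reference. Any missing genotype in a trio
#' disqualifies the variant.
#'
#' @param variants Variant table (`variant_id`, `gene`, ...).
#' @param genotypes Long genotype table.
#' @param pedigree Pedigree tibble.
#' @return SegregationResult tibble (`pattern = "de_novo"`).
#' @export
de_novo_scan <- function(variants, genotypes, pedigree) {
  trios <- affected_trios(pedigree, "de_novo_scan")
  if (nrow(trios) == 0 || nrow(variants) == 0) return(empty_segregation())
  m <- gt_matrix(genotypes, variant_ids = variants$variant_id,
                 sample_ids = pedigree$sample_id)
  ok <- rep(TRUE, nrow(variants))
  for (i in seq_len(nrow(trios))) {
    child <- m[, trios$child[i]]
    mo <- m[, trios$mother[i]]
    fa <- m[, trios$father[i]]
    ok <- ok & !is.na(child) & !is.na(mo) & !is.na(fa) &
      child >= 1 & mo == 0 & fa == 0
  }
  seg_result(variants, ok, pattern = "de_novo", origin = "n/a",
             carriers = trios$child)
}

#' Scan for autosomal recessive patterns
#'
#' Two models. Homozygous: every affected member is homozygous for the
#' alternate allele and each parent is heterozygous. Compound heterozygous:
#' two distinct variants in the same gene, one of maternal and one of
#' paternal origin (by transmission), heterozygous in every affected member,
#' with no unaffected member carrying both.
#'
#' @inheritParams de_novo_scan
#' @return SegregationResult tibble with `pattern` in
#'   `{"hom_recessive", "comphet_partner"}`; compound-het rows carry the
#'   partner's id in `partner_variant` and their own parental origin.
#' @export
recessive_scan <- function(variants, genotypes, pedigree) {
  trios <- affected_trios(pedigree, "recessive_scan")
  if (nrow(trios) == 0 || nrow(variants) == 0) return(empty_segregation())
  m <- gt_matrix(genotypes, variant_ids = variants$variant_id,
                 sample_ids = pedigree$sample_id)

  hom_ok <- rep(TRUE, nrow(variants))
  for (i in seq_len(nrow(trios))) {
    child <- m[, trios$child[i]]
    mo <- m[, trios$mother[i]]
    fa <- m[, trios$father[i]]
    hom_ok <- hom_ok & !is.na(child) & !is.na(mo) & !is.na(fa) &
      child == 2 & mo == 1 & fa == 1
  }
  hom <- seg_result(variants, hom_ok, pattern = "hom_recessive",
                    origin = "n/a", carriers = trios$child)

  # Compound-het: reuse the shared-monoallelic machinery to find variants
  # het in all affecteds with a single unambiguous origin, then pair
  # opposite origins within a gene.
  mono <- shared_monoallelic_core(variants, m, trios, strict = TRUE)
  comphet <- empty_segregation()
  if (nrow(mono) > 0) {
    unaffected <- pedigree$sample_id[!pedigree$affected]
    by_gene <- split(seq_len(nrow(mono)), mono$gene)
    rows <- list()
    for (idx in by_gene) {
      mat <- idx[mono$origin[idx] == "maternal"]
      pat <- idx[mono$origin[idx] == "paternal"]
      for (a in mat) for (b in pat) {
        va <- mono$variant_id[a]
        vb <- mono$variant_id[b]
        # unaffected-carrier exclusion: reject the pair when any unaffected
        # member carries both variants
        double_carrier <- FALSE
        for (u in unaffected) {
          ga <- m[va, u]
          gb <- m[vb, u]
          if (!is.na(ga) && !is.na(gb) && ga >= 1 && gb >= 1) {
            double_carrier <- TRUE
            break
          }
        }
        if (double_carrier) next
        rows[[length(rows) + 1]] <- tibble::tibble(
          variant_id = c(va, vb),
          gene = mono$gene[c(a, b)],
          pattern = "comphet_partner",
          origin = c("maternal", "paternal"),
          affected_carriers = list(trios$child, trios$child),
          partner_variant = c(vb, va)
        )
      }
    }
    if (length(rows) > 0) comphet <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(hom, comphet)
}

#' Scan for shared monoallelic variants with unambiguous parental origin
#'
#' Returns variants heterozygous in every affected member whose parental
#' origin is unambiguous and identical across all affecteds: exactly one
#' parent is a carrier and (in the default strict mode) the other parent is
#' observed homozygous reference — the configuration under which a trans
#' digenic assignment is possible. The permissive mode
#' (`allow_other_parent_carrier = TRUE`) ignores the other parent's
#' genotype, so a missing genotype there no longer disqualifies a variant.
#'
#' @inheritParams de_novo_scan
#' @param allow_other_parent_carrier Permissive mode flag (default strict).
#' @return SegregationResult tibble (`pattern = "shared_monoallelic"`,
#'   `origin` in `{"maternal", "paternal"}`).
#' @export
shared_monoallelic_scan <- function(variants, genotypes, pedigree,
                                    allow_other_parent_carrier = FALSE) {
  trios <- affected_trios(pedigree, "shared_monoallelic_scan")
  if (nrow(trios) == 0 || nrow(variants) == 0) return(empty_segregation())
  m <- gt_matrix(genotypes, variant_ids = variants$variant_id,
                 sample_ids = pedigree$sample_id)
  shared_monoallelic_core(variants, m, trios,
                          strict = !isTRUE(allow_other_parent_carrier))
}

shared_monoallelic_core <- function(variants, m, trios, strict) {
  all_het <- rep(TRUE, nrow(variants))
  origin <- NULL
  consistent <- rep(TRUE, nrow(variants))
  for (i in seq_len(nrow(trios))) {
    child <- m[, trios$child[i]]
    all_het <- all_het & !is.na(child) & child == 1
    orig_i <- origin_vector(m[, trios$mother[i]], m[, trios$father[i]],
                            strict = strict)
    if (is.null(origin)) {
      origin <- orig_i
    } else {
      consistent <- consistent & !is.na(origin) & !is.na(orig_i) &
        origin == orig_i
    }
  }
  ok <- all_het & consistent & !is.na(origin) &
    origin %in% c("maternal", "paternal")
  seg_result(variants, ok, pattern = "shared_monoallelic",
             origin = origin, carriers = trios$child)
}

seg_result <- function(variants, keep, pattern, origin, carriers) {
  keep[is.na(keep)] <- FALSE
  n <- sum(keep)
  if (n == 0) return(empty_segregation())
  tibble::tibble(
    variant_id = variants$variant_id[keep],
    gene = if ("gene" %in% names(variants)) variants$gene[keep]
      else NA_character_,
    pattern = pattern,
    origin = if (length(origin) == 1) origin else origin[keep],
    affected_carriers = rep(list(carriers), n),
    partner_variant = NA_character_
  )
}
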