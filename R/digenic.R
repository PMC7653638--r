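#' Pair maternal and paternal candidates into trans digenic gene pairs
#'
#' Forms the Cartesian product of maternal-origin and paternal-origin
#' shared-monoallelic candidates, keeping pairs in distinct genes — the two
#' variants then sit on chromosomes contributed by different parents (trans
#' configuration). Same-gene cross-parental pairs are compound
#' heterozygotes, a recessive pattern reported by [recessive_scan()] only,
#' never here. Output order is deterministic (lexicographic on
#' `gene_a`, `gene_b`).
#'
#' @param maternal,paternal Shared-monoallelic SegregationResult tibbles
#'   (from [shared_monoallelic_scan()]) with origins `"maternal"` and
#'   `"paternal"` respectively; an ambiguous origin anywhere is an error.
#' @param pedigree Pedigree tibble (defines the full affected set).
#' @param require_all_affected When `TRUE` (default) a pair is kept only if
#'   carried by every affected member; otherwise any non-empty shared
#'   affected set qualifies.
#' @return CandidatePair tibble: `gene_a`, `variant_a`, `origin_a`
#'   (maternal), `gene_b`, `variant_b`, `origin_b` (paternal),
#'   `shared_affected` (list), `shared_affected_count`, plus placeholder
#'   `genesets`, `score`, `rank` columns filled by later stages.
#' @export
pair_trans <- function(maternal, paternal, pedigree,
                       require_all_affected = TRUE) {
  for (side in list(maternal, paternal)) {
    if (nrow(side) > 0 &&
        !all(side$origin %in% c("maternal", "paternal"))) {
      abort("pair_trans inputs must have resolved parental origins")
    }
  }
  if (nrow(maternal) > 0 && !all(maternal$origin == "maternal")) {
    abort("'maternal' input contains non-maternal origins")
  }
  if (nrow(paternal) > 0 && !all(paternal$origin == "paternal")) {
    abort("'paternal' input contains non-paternal origins")
  }
  if (nrow(maternal) == 0 || nrow(paternal) == 0) return(empty_pairs())
  aff <- affected_ids(pedigree)
  grid <- tidyr::expand_grid(a = seq_len(nrow(maternal)),
                             b = seq_len(nrow(paternal)))
  out <- tibble::tibble(
    gene_a = maternal$gene[grid$a],
    variant_a = maternal$variant_id[grid$a],
    origin_a = "maternal",
    gene_b = paternal$gene[grid$b],
    variant_b = paternal$variant_id[grid$b],
    origin_b = "paternal",
    shared_affected = purrr::map2(maternal$affected_carriers[grid$a],
                                  paternal$affected_carriers[grid$b],
                                  intersect)
  )
  out <- out[out$gene_a != out$gene_b, , drop = FALSE]
  n_shared <- vapply(out$shared_affected, length, integer(1))
  keep <- if (isTRUE(require_all_affected)) {
    vapply(out$shared_affected, function(s) setequal(s, aff), logical(1))
  } else {
    n_shared > 0
  }
  out <- out[keep, , drop = FALSE]
  out$shared_affected_count <- vapply(out$shared_affected, length,
                                      integer(1))
  out$genesets <- NA_character_
  out$score <- NA_real_
  out$rank <- NA_integer_
  dplyr::arrange(out, .data$gene_a, .data$gene_b, .data$variant_a,
                 .data$variant_b)
}

#' Restrict candidate pairs by gene-set membership
#'
#' Membership-based narrowing to biologically relevant pathways; no
#' enrichment statistic is computed. In `"both_in_same_set"` mode (default)
#' a pair survives when its two genes co-occur in at least one set, and the
#' names of all such sets are recorded (comma-separated) in `genesets`;
#' `"either"` keeps pairs with at least one gene in at least one set;
#' `"off"` is the identity.
#'
#' @param pairs CandidatePair tibble.
#' @param genesets Gene-set tibble (`set_name`, `gene`), e.g. from
#'   [read_geneset()].
#' @param mode `"both_in_same_set"`, `"either"` or `"off"`.
#' @return Filtered CandidatePair tibble with `genesets` filled in.
#' @export
geneset_restrict <- function(pairs, genesets,
                             mode = c("both_in_same_set", "either", "off")) {
  mode <- match.arg(mode)
  if (mode == "off") return(pairs)
  if (is.null(genesets) || nrow(genesets) == 0) {
    abort("gene-set restriction requested but the collection is empty")
  }
  sets <- geneset_list(genesets)
  if (nrow(pairs) == 0) return(pairs)
  hits <- purrr::map2(pairs$gene_a, pairs$gene_b, function(ga, gb) {
    names(sets)[vapply(sets, function(g) {
      if (mode == "both_in_same_set") ga %in% g && gb %in% g
      else ga %in% g || gb %in% g
    }, logical(1))]
  })
  keep <- vapply(hits, length, integer(1)) > 0
  out <- pairs[keep, , drop = FALSE]
  out$genesets <- vapply(hits[keep], function(h) {
    paste(sort(h), collapse = ",")
  }, character(1))
  out
}

#' Rank candidate pairs
#'
#' Convenience ordering of the surviving pairs; the score is reporting
#' plumbing, not part of the inference. Each variant contributes
#' `(n_damaging / n_informative) * (1 - af_global)` (a missing frequency —
#' a novel variant — counts as 0) and the pair's score is the mean of its
#' two variants', so scores lie in `[0, 1]`. Pairs are sorted by
#' descending score with lexicographic `(gene_a, gene_b)` tie-breaking, and
#' `rank` is assigned 1..n.
#'
#' @param pairs CandidatePair tibble.
#' @param classified Output of [classify_variants()] covering every paired
#'   variant (supplies `n_damaging`, `n_informative`).
#' @param annotations Annotation tibble covering every paired variant
#'   (supplies `af_global`).
#' @return The pairs, scored, sorted and ranked.
#' @export
rank_pairs <- function(pairs, classified, annotations) {
  if (nrow(pairs) == 0) {
    pairs$rank <- integer(0)
    return(pairs)
  }
  ids <- unique(c(pairs$variant_a, pairs$variant_b))
  missing_cls <- setdiff(ids, classified$variant_id)
  missing_ann <- setdiff(ids, annotations$variant_id)
  if (length(missing_cls) > 0 || length(missing_ann) > 0) {
    abort(sprintf("no deleteriousness call or annotation for: %s",
                  paste(union(missing_cls, missing_ann), collapse = ", ")))
  }
  score_one <- function(id) {
    k <- match(id, classified$variant_id)
    a <- match(id, annotations$variant_id)
    frac <- ifelse(classified$n_informative[k] > 0,
                   classified$n_damaging[k] / classified$n_informative[k], 0)
    af <- annotations$af_global[a]
    frac * (1 - ifelse(is.na(af), 0, af))
  }
  pairs$score <- (score_one(pairs$variant_a) +
                    score_one(pairs$variant_b)) / 2
  out <- dplyr::arrange(pairs, dplyr::desc(.data$score), .data$gene_a,
                        .data$gene_b, .data$variant_a, .data$variant_b)
  out$rank <- seq_len(nrow(out))
  out
}
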