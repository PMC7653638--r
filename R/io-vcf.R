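#' Read a multi-sample VCF into normalized variant records and genotypes
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) into the two tables the pipeline
#' works with: one row per normalized biallelic site and one row per
#' (variant, sample) genotype. Multiallelic sites are split into one record
#' per alternate allele; each split record's genotypes are recoded as the
#' dosage of that allele only, with every other allele counted as reference
#' (biallelic reduction — downstream logic is purely carrier/non-carrier).
#' Phased separators (`|`) are accepted but phase is discarded: parental
#' origin is always re-derived by transmission (see
#' [phase_by_transmission()]). Gene symbols and region classes are taken
#' from the `GENE` and `REGION` INFO keys when present; a side annotation
#' table is authoritative when both exist.
#'
#' @param path Path to a VCF file with at least one sample column and a
#'   `GT` FORMAT field.
#' @return A list with components:
#'   \describe{
#'     \item{variants}{Tibble with columns `variant_id`, `chrom`, `pos`,
#'       `ref`, `alt`, `gene`, `region_class`, in file order (multiallelic
#'       alternates expanded in ALT order).}
#'     \item{genotypes}{Tibble with columns `variant_id`, `sample_id`, `gt`
#'       where `gt` is 0 (hom-ref), 1 (het), 2 (hom-alt) or `NA` (missing).}
#'   }
#' @export
#' @examples
#' sim <- simulate_family_exome(sim_config(n_background = 20, seed = 1))
#' path <- tempfile(fileext = ".vcf")
#' write_vcf(sim$variants, sim$genotypes, path, pedigree = sim$pedigree)
#' vcf <- read_vcf(path)
#' nrow(vcf$variants)
read_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !startsWith(first, "##fileformat=VCF")) {
    abort(sprintf(
      "malformed VCF header at line 1 of %s: expected ##fileformat=VCF",
      path))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_mat <- vcf@gt
  if (is.null(gt_mat) || ncol(gt_mat) < 2) {
    abort(sprintf("VCF %s has zero sample columns", path))
  }
  samples <- colnames(gt_mat)[-1]
  fix <- vcf@fix
  n <- nrow(fix)
  if (n == 0) {
    return(list(variants = empty_variants(), genotypes = empty_genotypes()))
  }
  info <- unname(fix[, "INFO"])
  genes <- unname(info_field(info, "GENE"))
  regions <- unname(info_field(info, "REGION"))

  # Data lines start after the #CHROM line; used for parse-error messages.
  header_lines <- sum(startsWith(readLines(path, warn = FALSE), "#"))

  out_var <- vector("list", n)
  out_gt <- vector("list", n)
  for (i in seq_len(n)) {
    fmt <- strsplit(gt_mat[i, 1], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) {
      abort(sprintf("VCF parse error at line %d of %s: FORMAT has no GT field",
                    header_lines + i, path))
    }
    raw <- gt_mat[i, -1]
    gt_str <- vapply(strsplit(raw, ":", fixed = TRUE), function(x) {
      if (length(x) < gt_idx) NA_character_ else x[[gt_idx]]
    }, character(1))
    alleles <- parse_gt_alleles(gt_str, header_lines + i, path)
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    pos <- as.integer(fix[i, "POS"])
    ids <- variant_key(fix[i, "CHROM"], pos, fix[i, "REF"], alts)
    out_var[[i]] <- tibble::tibble(
      variant_id = ids,
      chrom = fix[i, "CHROM"],
      pos = pos,
      ref = fix[i, "REF"],
      alt = alts,
      gene = genes[[i]],
      region_class = regions[[i]]
    )
    codes <- lapply(seq_along(alts), function(k) {
      unname(vapply(alleles, function(a) {
        if (anyNA(a)) NA_integer_ else sum(a == k)
      }, integer(1)))
    })
    out_gt[[i]] <- tibble::tibble(
      variant_id = rep(ids, each = length(samples)),
      sample_id = rep(samples, times = length(alts)),
      gt = unlist(codes, use.names = FALSE)
    )
  }
  variants <- dplyr::bind_rows(out_var)
  dup <- duplicated(variants$variant_id)
  if (any(dup)) {
    abort(sprintf("duplicate variant id(s) in %s: %s", path,
                  paste(unique(variants$variant_id[dup]), collapse = ", ")))
  }
  list(variants = variants, genotypes = dplyr::bind_rows(out_gt))
}

empty_variants <- function() {
  tibble::tibble(variant_id = character(), chrom = character(),
                 pos = integer(), ref = character(), alt = character(),
                 gene = character(), region_class = character())
}

empty_genotypes <- function() {
  tibble::tibble(variant_id = character(), sample_id = character(),
                 gt = integer())
}

info_field <- function(info, key) {
  pattern <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexec(pattern, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

# "0/1", "0|1", "./." ... -> integer allele vectors; NA marks missing.
parse_gt_alleles <- function(gt_str, line, path) {
  lapply(strsplit(gsub("|", "/", gt_str, fixed = TRUE), "/", fixed = TRUE),
         function(parts) {
           if (length(parts) == 0) {
             abort(sprintf("VCF parse error at line %d of %s: empty GT",
                           line, path))
           }
           # "." alleles (and NA from upstream missing-value conversion)
           # mark a missing genotype
           if (anyNA(parts) || any(parts == ".")) return(NA_integer_)
           a <- suppressWarnings(as.integer(parts))
           if (anyNA(a)) {
             abort(sprintf(
               "VCF parse error at line %d of %s: malformed GT '%s'",
               line, path, paste(parts, collapse = "/")))
           }
           a
         })
}

#' Write variant records and genotypes as a multi-sample VCF
#'
#' Emits VCF v4.2 with a fixed, date-free header so that identical inputs
#' produce byte-identical files (the simulator relies on this for
#' determinism checks). Gene symbol and region class are stored in the
#' `GENE` and `REGION` INFO keys and round-trip through [read_vcf()].
#'
#' @param variants Variant table (`variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, optionally `gene`, `region_class`).
#' @param genotypes Long genotype table (`variant_id`, `sample_id`, `gt`).
#' @param path Output file.
#' @param pedigree Optional pedigree; when given, sample columns are written
#'   in pedigree order.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path, pedigree = NULL) {
  assert_columns(variants, c("variant_id", "chrom", "pos", "ref", "alt"),
                 "variant table")
  samples <- if (!is.null(pedigree)) pedigree$sample_id else
    unique(genotypes$sample_id)
  m <- gt_matrix(genotypes, variant_ids = variants$variant_id,
                 sample_ids = samples)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[m + 1L], nrow = nrow(m))
  gt_str[is.na(gt_str)] <- "./."
  gene <- if ("gene" %in% names(variants)) variants$gene else
    rep(NA_character_, nrow(variants))
  region <- if ("region_class" %in% names(variants)) variants$region_class
    else rep(NA_character_, nrow(variants))
  info <- ifelse(
    is.na(gene) & is.na(region), ".",
    paste0(ifelse(is.na(gene), "", paste0("GENE=", gene)),
           ifelse(is.na(gene) | is.na(region), "", ";"),
           ifelse(is.na(region), "", paste0("REGION=", region))))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=digenicscan",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    paste0("##INFO=<ID=REGION,Number=1,Type=String,",
           "Description=\"Region class: exonic, splicing or other\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(variants$chrom, variants$pos, variants$variant_id,
                variants$ref, variants$alt, ".", "PASS", info, "GT",
                sep = "\t")
  if (nrow(variants) > 0) {
    body <- paste(body, apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  } else {
    body <- character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}
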