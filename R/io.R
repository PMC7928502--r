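# Cohort input/output: multi-sample VCF v4.2 plus annotation and phenotype
# tables with documented column contracts.

#' Write a cohort as VCF plus annotation and phenotype tables
#'
#' Emits `cohort.vcf` (VCF v4.2, GT-only biallelic records; missing calls as
#' `./.`), `annotations.tsv` (chrom, pos, ref, alt, gene, exonic_function,
#' cadd, af_public, ... ) and `phenotypes.tsv` (sample, status, covariates).
#'
#' @param cohort An [rv_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rv_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- cohort$variants
  N <- nrow(cohort$samples)
  P <- nrow(v)

  gt <- matrix("0/0", nrow = P, ncol = N)
  tr <- Matrix::summary(cohort$G)
  if (nrow(tr)) {
    gt[cbind(tr$j, tr$i)] <- ifelse(tr$x >= 2, "1/1", "0/1")
  }
  if (!is.null(cohort$miss)) {
    mt <- Matrix::summary(cohort$miss)
    if (nrow(mt)) gt[cbind(mt$j, mt$i)] <- "./."
  }

  vcf_path <- file.path(dir, "cohort.vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rvbati",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples$sample), collapse = "\t")
  )
  body <- do.call(paste, c(
    list(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".", "GT"),
    lapply(seq_len(N), function(i) gt[, i]),
    sep = "\t"))
  writeLines(c(header, body), vcf_path)

  ann_path <- file.path(dir, "annotations.tsv")
  ann_cols <- setdiff(names(v), "variant_id")
  write.table(v[c("chrom", "pos", "ref", "alt",
                  setdiff(ann_cols, c("chrom", "pos", "ref", "alt")))],
              ann_path, sep = "\t", quote = FALSE, row.names = FALSE)

  phe_path <- file.path(dir, "phenotypes.tsv")
  write.table(cohort$samples, phe_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(vcf = vcf_path, annotations = ann_path, phenotypes = phe_path))
}

#' Read a cohort from VCF plus annotation and phenotype tables
#'
#' Parses a multi-sample VCF v4.2 (via the `vcfR` reader), splits
#' multi-allelic records into biallelic ones (a `1/2` genotype contributes
#' dosage 1 to each alternate allele), converts GT strings to minor-allele
#' dosages, joins the annotation table by (chrom, pos, ref, alt) and aligns
#' phenotypes by sample id. VCF samples without a phenotype row are dropped
#' with a warning; VCF variants without an annotation row are an error
#' naming the offenders. Per-variant call rates are computed from missing
#' genotypes, which are stored as missing (imputation happens at design
#' assembly).
#'
#' @param vcf_file,annotation_file,phenotype_file Input paths. The
#'   annotation TSV must carry chrom, pos, ref, alt, gene, exonic_function,
#'   cadd, af_public; the phenotype TSV must carry sample, status.
#' @return An [rv_cohort()].
#' @export
read_cohort <- function(vcf_file, annotation_file, phenotype_file) {
  vc <- vcfR::read.vcfR(vcf_file, verbose = FALSE)
  fix <- vcfR::getFIX(vc)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vc, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  nrec <- nrow(fix)

  rows <- list()
  dos <- list()
  k <- 0L
  for (r in seq_len(nrec)) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    for (a in seq_along(alts)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        chrom = fix[r, "CHROM"], pos = as.integer(fix[r, "POS"]),
        ref = fix[r, "REF"], alt = alts[a], stringsAsFactors = FALSE)
      dos[[k]] <- dosage_from_gt(gt[r, ], allele = a)
    }
  }
  var_df <- do.call(rbind, rows)
  var_df$variant_id <- sprintf("%s:%d:%s:%s", var_df$chrom, var_df$pos,
                               var_df$ref, var_df$alt)
  D <- do.call(cbind, dos)
  rownames(D) <- samples
  colnames(D) <- var_df$variant_id

  ann <- read.delim(annotation_file, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene", "exonic_function", "cadd",
            "af_public")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols)) {
    stopf("annotation table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  ann_key <- sprintf("%s:%d:%s:%s", ann$chrom, as.integer(ann$pos), ann$ref,
                     ann$alt)
  idx <- match(var_df$variant_id, ann_key)
  if (anyNA(idx)) {
    stopf("no annotation for variant(s): %s",
          paste(head(var_df$variant_id[is.na(idx)], 5), collapse = ", "))
  }
  keep_cols <- setdiff(names(ann), c("chrom", "pos", "ref", "alt"))
  variants <- cbind(var_df[c("variant_id", "chrom", "pos", "ref", "alt")],
                    ann[idx, keep_cols, drop = FALSE])
  rownames(variants) <- NULL

  phe <- read.delim(phenotype_file, stringsAsFactors = FALSE)
  if (!all(c("sample", "status") %in% names(phe))) {
    stopf("phenotype table must have 'sample' and 'status' columns")
  }
  phe$sample <- as.character(phe$sample)
  known <- samples %in% phe$sample
  if (!all(known)) {
    warning(sprintf("dropping %d sample(s) without phenotype: %s",
                    sum(!known),
                    paste(head(samples[!known], 5), collapse = ", ")),
            call. = FALSE)
    D <- D[known, , drop = FALSE]
    samples <- samples[known]
  }
  phe <- phe[match(samples, phe$sample), , drop = FALSE]
  rownames(phe) <- NULL

  miss_dense <- is.na(D)
  if (!"call_rate" %in% names(variants)) {
    variants$call_rate <- 1 - colMeans(miss_dense)
  }
  D[miss_dense] <- 0
  G <- methods::as(Matrix::Matrix(D, sparse = TRUE), "CsparseMatrix")
  miss <- methods::as(Matrix::Matrix(miss_dense, sparse = TRUE),
                      "CsparseMatrix")
  rv_cohort(G, variants, phe, miss = miss)
}

#' Read a run configuration from YAML
#'
#' The YAML file groups input paths (`vcf`, `annotations`, `phenotypes`),
#' filter settings (`af_max`, `score_min`, `drop_synonymous`,
#' `call_rate_min`, `call_rate_strict`), model settings (any argument of
#' [bati_config()]), and harness settings (`levels`, `S`, `n_pcs`, `seed`,
#' `out_dir`).
#'
#' @param path YAML file path.
#' @return List with elements `paths`, `filters`, `config` (a
#'   [bati_config()]), `levels`, `S`, `n_pcs`, `seed`, `out_dir`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  paths <- y$inputs %||% list()
  for (f in c("vcf", "annotations", "phenotypes")) {
    if (!is.null(paths[[f]]) && !file.exists(paths[[f]])) {
      stopf("input file not found: %s", paths[[f]])
    }
  }
  filters <- utils::modifyList(
    list(af_max = 0.01, score_min = 10, drop_synonymous = TRUE,
         call_rate_min = 0.85, call_rate_strict = TRUE),
    y$filters %||% list())
  cfg_args <- y$model %||% list()
  config <- do.call(bati_config, cfg_args)
  levels <- as.numeric(y$levels %||% c(0.05, 0.001, 1e-4))
  stopifnot(all(levels > 0 & levels < 1))
  list(paths = paths, filters = filters, config = config, levels = levels,
       S = as.integer(y$S %||% 10L), n_pcs = as.integer(y$n_pcs %||% 0L),
       seed = as.integer(y$seed %||% 1L), out_dir = y$out_dir %||% ".")
}
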