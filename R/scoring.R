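#' Per-individual polygenic scores from dosages
#'
#' A polygenic score for an individual is the weighted sum of alternative
#' allele dosages, the weights being the harmonized per-alt-allele effect
#' sizes. Scores are deliberately NOT standardized here: standardization
#' happens only inside the mixing step (with training-set statistics) and
#' in evaluation, so raw score values remain reproducible.
#'
#' @name scoring
NULL

#' Construct a genotype matrix object
#'
#' @param dosages numeric samples x variants matrix with entries in `[0, 2]`
#'   or `NA` for missing; row names are sample ids
#' @param variants a `variant_panel` (or data frame with chr/pos/ref/alt),
#'   one row per dosage column, in column order
#' @param sample_ids optional; defaults to `rownames(dosages)` or `s1..sn`
#' @return an object of class `genotype_matrix`
#' @export
genotype_matrix <- function(dosages, variants, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  stopifnot(ncol(dosages) == nrow(variants))
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (is.null(sample_ids))
    sample_ids <- rownames(dosages) %||% paste0("s", seq_len(nrow(dosages)))
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variant_key(variants$chr, variants$pos,
                                   variants$ref, variants$alt)
  structure(list(dosages = dosages,
                 variants = as.data.frame(variants),
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$sample_ids), " samples x ",
      nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}

#' Read a tabular dosage matrix
#'
#' Expects a TSV whose first column is the sample id and whose remaining
#' column names are `chr:pos:ref:alt` variant keys; entries are alt-allele
#' dosages in `[0, 2]` (`NA` allowed).
#'
#' @param path TSV path
#' @return a `genotype_matrix`
#' @export
read_dosage_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  d <- as.matrix(tab[, -1, drop = FALSE])
  parts <- strsplit(colnames(d), ":", fixed = TRUE)
  if (any(lengths(parts) != 4))
    stop("dosage column names must be chr:pos:ref:alt variant keys")
  v <- variant_panel(chr = vapply(parts, `[`, "", 1L),
                     pos = as.integer(vapply(parts, `[`, "", 2L)),
                     ref = vapply(parts, `[`, "", 3L),
                     alt = vapply(parts, `[`, "", 4L))
  genotype_matrix(d, v, sample_ids = ids)
}

#' Compute one polygenic score over a genotype matrix
#'
#' For sample n, `score_n = sum_j dosage_nj * weight_j` over the variants
#' present in both the harmonized scoring and the genotype panel. Missing
#' dosages are imputed as `2 * af`, the alt-allele frequency computed from
#' the non-missing entries of the same variant.
#'
#' @param genotypes a `genotype_matrix`
#' @param scoring a `harmonized_scoring`
#' @return numeric vector of scores (one per sample) with attribute
#'   `n_overlap`, the number of scoring variants found in the panel
#' @export
compute_prs <- function(genotypes, scoring) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(scoring, "harmonized_scoring"))
  keys <- variant_key(scoring$records$chr, scoring$records$pos,
                      scoring$records$ref, scoring$records$alt)
  idx <- match(keys, colnames(genotypes$dosages))
  use <- !is.na(idx)
  if (!any(use))
    stop("score '", scoring$score_id,
         "' shares no variants with the genotype panel")
  D <- genotypes$dosages[, idx[use], drop = FALSE]
  if (anyNA(D)) {
    af2 <- colMeans(D, na.rm = TRUE)        # = 2 * alt-allele frequency
    na_idx <- which(is.na(D), arr.ind = TRUE)
    D[na_idx] <- af2[na_idx[, 2]]
  }
  s <- drop(D %*% scoring$records$weight[use])
  names(s) <- genotypes$sample_ids
  attr(s, "n_overlap") <- sum(use)
  s
}

#' Build a samples x scores panel
#'
#' Computes one column per harmonized scoring via [compute_prs()]. Scorings
#' with zero variant overlap are omitted with a warning rather than
#' aborting the panel.
#'
#' @param genotypes a `genotype_matrix`
#' @param scorings list of `harmonized_scoring` objects
#' @return an object of class `score_panel`: list with `values` (samples x
#'   scores matrix), `score_ids`, `sample_ids` and `meta` (per-score
#'   `trait_label` and `n_overlap`)
#' @export
build_panel <- function(genotypes, scorings) {
  stopifnot(length(scorings) >= 1)
  cols <- vector("list", length(scorings))
  keep <- logical(length(scorings))
  for (i in seq_along(scorings)) {
    s <- tryCatch(compute_prs(genotypes, scorings[[i]]),
                  error = function(e) NULL)
    if (is.null(s)) {
      warning("dropping score '", scorings[[i]]$score_id,
              "': no overlapping variants", call. = FALSE)
    } else {
      cols[[i]] <- s
      keep[i] <- TRUE
    }
  }
  if (!any(keep)) stop("no scoring overlaps the genotype panel")
  values <- do.call(cbind, cols[keep])
  ids <- vapply(scorings[keep], `[[`, "", "score_id")
  colnames(values) <- ids
  meta <- data.frame(
    score_id = ids,
    trait_label = vapply(scorings[keep],
                         function(s) s$trait_label %||% NA_character_, ""),
    n_overlap = vapply(cols[keep], function(s) attr(s, "n_overlap"), 0L),
    stringsAsFactors = FALSE
  )
  score_panel(values, meta, sample_ids = genotypes$sample_ids)
}

#' Construct a score panel directly from a values matrix
#'
#' @param values samples x scores numeric matrix (column names = score ids)
#' @param meta optional data frame with `score_id` and `trait_label`
#' @param sample_ids optional sample ids
#' @return a `score_panel`
#' @export
score_panel <- function(values, meta = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("score", seq_len(ncol(values)))
  if (is.null(sample_ids))
    sample_ids <- rownames(values) %||% paste0("s", seq_len(nrow(values)))
  rownames(values) <- sample_ids
  if (is.null(meta))
    meta <- data.frame(score_id = colnames(values),
                       trait_label = NA_character_,
                       stringsAsFactors = FALSE)
  stopifnot(identical(meta$score_id, colnames(values)))
  if (any(apply(values, 2, function(x) all(is.na(x)))))
    stop("score panel contains an all-missing column")
  structure(list(values = values, score_ids = colnames(values),
                 sample_ids = sample_ids, meta = meta),
            class = "score_panel")
}

#' @export
print.score_panel <- function(x, ...) {
  cat("<score_panel> ", length(x$sample_ids), " samples x ",
      length(x$score_ids), " scores\n", sep = "")
  invisible(x)
}
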