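#' Read, harmonize and write polygenic scoring files
#'
#' Functions for working with PGS-Catalog-style scoring files: tab-separated
#' per-variant weight tables with "#"-prefixed metadata headers. Harmonization
#' re-expresses every published weight per copy of the alternative allele of a
#' target genotype panel, so that scores from heterogeneous sources can be
#' applied to one dosage matrix with a single allele convention.
#'
#' @name pgs_io
NULL

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Build a variant key string
#'
#' Variants are keyed as `chr:pos:ref:alt` with 1-based positions and
#' uppercase alleles.
#'
#' @param chr chromosome label
#' @param pos 1-based position
#' @param ref,alt reference / alternative allele (A/C/G/T)
#' @return character vector of keys
#' @export
variant_key <- function(chr, pos, ref, alt) {
  paste(chr, pos, toupper(ref), toupper(alt), sep = ":")
}

#' Define a variant panel
#'
#' A variant panel is the target cohort's variant universe: one row per
#' variant, keyed by chromosome, 1-based position and the ref/alt allele
#' pair. Effect weights are harmonized to be per copy of `alt`.
#'
#' @param chr,pos,ref,alt vectors of equal length
#' @return a `data.frame` of class `variant_panel` with uppercase alleles
#' @export
variant_panel <- function(chr, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(all(pos >= 1), all(ref != alt))
  panel <- data.frame(chr = as.character(chr), pos = as.integer(pos),
                      ref = ref, alt = alt, stringsAsFactors = FALSE)
  if (anyDuplicated(variant_key(panel$chr, panel$pos, panel$ref, panel$alt)))
    stop("duplicate variant keys in panel")
  class(panel) <- c("variant_panel", "data.frame")
  panel
}

.meta_kv <- function(lines) {
  kv <- sub("^#+\\s*", "", lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- trimws(sub("=.*$", "", kv))
  vals <- trimws(sub("^[^=]*=", "", kv))
  stats::setNames(vals, tolower(keys))
}

#' Parse a PGS-Catalog-style scoring file
#'
#' Reads a tab-separated scoring file whose metadata lines begin with `#`.
#' Recognized body columns are `rsID`, `chr_name`, `chr_position`,
#' `effect_allele`, `other_allele` and `effect_weight`; `effect_allele` and
#' `effect_weight` are mandatory. The score identifier and trait label are
#' taken from `#pgs_id=` / `#trait_reported=` metadata when present, else
#' from the file name.
#'
#' @param path path to the scoring file
#' @return an object of class `scoring_file`: a list with `score_id`,
#'   `trait_label` and a `records` data frame (one row per body row)
#' @export
parse_scoring_file <- function(path) {
  if (!file.exists(path)) stop("scoring file not found: ", path)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- .meta_kv(lines[is_meta])
  body <- lines[!is_meta]
  body <- body[nzchar(body)]
  score_id <- if (!is.na(meta["pgs_id"])) unname(meta["pgs_id"]) else
    sub("\\.[^.]*$", "", basename(path))
  trait_label <- if (!is.na(meta["trait_reported"])) unname(meta["trait_reported"]) else NA_character_

  if (length(body) == 0) {   # metadata-only file: valid, zero records
    records <- data.frame(rsid = character(), chr = character(),
                          pos = integer(), effect_allele = character(),
                          other_allele = character(), weight = numeric(),
                          stringsAsFactors = FALSE)
    return(structure(list(score_id = score_id, trait_label = trait_label,
                          records = records), class = "scoring_file"))
  }
  tab <- utils::read.delim(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  for (col in c("effect_allele", "effect_weight"))
    if (!col %in% names(tab))
      stop("scoring file missing mandatory column '", col, "': ", path)

  n <- nrow(tab)
  get_col <- function(nm, default) if (nm %in% names(tab)) tab[[nm]] else rep(default, n)
  records <- data.frame(
    rsid = get_col("rsID", NA_character_),
    chr = get_col("chr_name", NA_character_),
    pos = suppressWarnings(as.integer(get_col("chr_position", NA_character_))),
    effect_allele = toupper(tab[["effect_allele"]]),
    other_allele = toupper(get_col("other_allele", NA_character_)),
    weight = as.numeric(tab[["effect_weight"]]),
    stringsAsFactors = FALSE
  )
  for (col in c("rsid", "chr", "effect_allele", "other_allele"))
    records[[col]][!nzchar(records[[col]]) | is.na(records[[col]])] <- NA
  if (n > 0 && any(!is.finite(records$weight)))
    stop("non-finite effect weights in ", path)

  id <- ifelse(is.na(records$chr) | is.na(records$pos),
               records$rsid,
               paste(records$chr, records$pos,
                     pmin(records$effect_allele, records$other_allele),
                     pmax(records$effect_allele, records$other_allele),
                     sep = ":"))
  dup <- unique(id[duplicated(id) & !is.na(id)])
  if (length(dup))
    stop("duplicate variant identifiers in ", path, ": ",
         paste(dup, collapse = ", "))

  structure(list(score_id = score_id, trait_label = trait_label,
                 records = records),
            class = "scoring_file")
}

#' @export
print.scoring_file <- function(x, ...) {
  cat("<scoring_file> ", x$score_id,
      if (!is.na(x$trait_label)) paste0(" (", x$trait_label, ")"),
      ": ", nrow(x$records), " variants\n", sep = "")
  invisible(x)
}

.is_palindromic <- function(a1, a2) {
  ok <- a1 %in% names(.COMPLEMENT) & a2 %in% names(.COMPLEMENT)
  out <- rep(FALSE, length(a1))
  out[ok] <- .COMPLEMENT[a1[ok]] == a2[ok]
  out
}

#' Harmonize a scoring file against a variant panel
#'
#' Re-expresses every effect weight per copy of the panel's alternative
#' allele. A record whose effect allele equals the panel alt keeps its
#' weight; one whose effect allele equals the panel ref has its weight
#' negated (counted in `n_flipped`). Records absent from the panel, with
#' allele pairs that do not match the panel's ref/alt pair, or at
#' strand-ambiguous (palindromic A/T or C/G) sites are excluded and counted
#' in `n_dropped`. Records carrying only an rsID are positioned through
#' `rsid_map` when supplied, else dropped.
#'
#' @param scoring a `scoring_file`
#' @param panel a `variant_panel` (or data frame with chr/pos/ref/alt)
#' @param keep_ambiguous keep palindromic variants (default `FALSE`)
#' @param rsid_map optional data frame with columns `rsid`, `chr`, `pos`
#' @return an object of class `harmonized_scoring`: list with `score_id`,
#'   `trait_label`, `records` (chr, pos, ref, alt, weight — weight per alt
#'   allele), `n_flipped`, `n_dropped`
#' @export
harmonize <- function(scoring, panel, keep_ambiguous = FALSE, rsid_map = NULL) {
  stopifnot(inherits(scoring, "scoring_file"))
  rec <- scoring$records
  n_in <- nrow(rec)

  # fill coordinates from the rsID map where positional keys are absent
  no_pos <- is.na(rec$chr) | is.na(rec$pos)
  if (any(no_pos) && !is.null(rsid_map)) {
    m <- match(rec$rsid[no_pos], rsid_map$rsid)
    rec$chr[no_pos] <- as.character(rsid_map$chr[m])
    rec$pos[no_pos] <- as.integer(rsid_map$pos[m])
  }

  pkey <- paste(panel$chr, panel$pos, sep = ":")
  multi <- pkey %in% pkey[duplicated(pkey)]   # multi-allelic: excluded
  rkey <- paste(rec$chr, rec$pos, sep = ":")
  m <- match(rkey, pkey)
  m[is.na(rec$chr) | is.na(rec$pos)] <- NA
  hit <- which(!is.na(m))
  m[hit[multi[m[hit]]]] <- NA

  ref <- panel$ref[m]; alt <- panel$alt[m]
  ea <- rec$effect_allele; oa <- rec$other_allele

  pal <- .is_palindromic(ea, oa)
  keep_dir  <- !is.na(m) & ea == alt & (is.na(oa) | oa == ref)
  keep_flip <- !is.na(m) & ea == ref & (is.na(oa) | oa == alt)
  if (!keep_ambiguous) {
    keep_dir <- keep_dir & !pal
    keep_flip <- keep_flip & !pal
  }

  kept <- keep_dir | keep_flip
  out <- data.frame(chr = rec$chr[kept], pos = rec$pos[kept],
                    ref = ref[kept], alt = alt[kept],
                    weight = ifelse(keep_flip[kept], -rec$weight[kept],
                                    rec$weight[kept]),
                    stringsAsFactors = FALSE)
  structure(list(score_id = scoring$score_id,
                 trait_label = scoring$trait_label,
                 records = out,
                 n_flipped = sum(keep_flip),
                 n_dropped = n_in - sum(kept)),
            class = "harmonized_scoring")
}

#' @export
print.harmonized_scoring <- function(x, ...) {
  cat("<harmonized_scoring> ", x$score_id, ": ", nrow(x$records),
      " variants kept (", x$n_flipped, " flipped, ", x$n_dropped,
      " dropped)\n", sep = "")
  invisible(x)
}

#' Write combined per-allele effects as a scoring file
#'
#' Writes an [adjusted_effects] object (or a `harmonized_scoring`) in the
#' PGS-Catalog column layout: `#`-prefixed metadata, then tab-separated
#' `chr_name`, `chr_position`, `effect_allele`, `other_allele`,
#' `effect_weight`. The effect allele is the panel alt allele. Weights are
#' written with 17 significant digits so that
#' `parse_scoring_file(write_scoring_file(x))` round-trips within 1e-12.
#'
#' @param effects an `adjusted_effects` or `harmonized_scoring` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_scoring_file <- function(effects, path) {
  if (inherits(effects, "adjusted_effects")) {
    rec <- effects$variants
    rec$weight <- effects$gamma
    id <- effects$score_id %||% "combined"
    trait <- effects$trait_label %||% NA_character_
  } else if (inherits(effects, "harmonized_scoring")) {
    rec <- effects$records
    id <- effects$score_id
    trait <- effects$trait_label
  } else stop("effects must be adjusted_effects or harmonized_scoring")
  if (nrow(rec) == 0) stop("refusing to write an empty scoring file")

  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(paste0("#pgs_id=", id),
               if (!is.na(trait)) paste0("#trait_reported=", trait)), con)
  body <- data.frame(chr_name = rec$chr, chr_position = rec$pos,
                     effect_allele = rec$alt, other_allele = rec$ref,
                     effect_weight = formatC(rec$weight, digits = 17,
                                             format = "g"),
                     stringsAsFactors = FALSE)
  utils::write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
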