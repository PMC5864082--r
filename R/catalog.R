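#' @name catalog
#' @title Strain/barcode catalog and sample sheet
#'
#' @description
#' The catalog maps each deletion strain to its two molecular barcodes (the
#' UPTAG and DOWNTAG integrated with the deletion cassette) and records the
#' ncRNA class of the deleted feature. The sample sheet maps 6-mer
#' multiplexing indices to samples (condition, growth stage, replicate).
#' Every downstream module consumes these two tables.
NULL

NCRNA_CLASSES <- c("tRNA", "snoRNA", "snRNA", "SUT", "CUT", "other")
CONDITIONS    <- c("Clim30", "Clim36", "Clim30LiCl", "Nlim30", "Nlim36", "Nlim30LiCl")
STAGES        <- c("P", "B", "ESS", "MSS", "LSS")

MIN_TAG_LEN <- 15L

is_dna <- function(x, extra = "") {
  grepl(paste0("^[ACGT", extra, "]+$"), x)
}

#' Infer the ncRNA class from a feature name
#'
#' Used when the catalog lacks an explicit class column. Compound names from
#' deletions removing overlapping features (e.g. "SUT233/CUT707") take the
#' class of the first-listed feature; the full compound name is preserved
#' elsewhere.
#'
#' @param name character vector of ncRNA names.
#' @return character vector of classes from
#'   `c("tRNA","snoRNA","snRNA","SUT","CUT","other")`.
#' @export
#' @examples
#' infer_ncrna_class(c("SUT233/CUT707", "tL(CAA)A", "SNR10"))
infer_ncrna_class <- function(name) {
  first <- sub("/.*$", "", name)
  cls <- rep("other", length(first))
  cls[grepl("^SUT", first)] <- "SUT"
  cls[grepl("^CUT", first)] <- "CUT"
  cls[grepl("^SNR", first)] <- "snoRNA"
  cls[grepl("^LSR", first)] <- "snRNA"
  cls[grepl("^t[A-Z]\\(", first)] <- "tRNA"
  cls
}

validate_catalog_df <- function(df) {
  need <- c("strain_id", "ncrna_name", "uptag", "downtag")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    bf_schema_error(paste0("catalog is missing column(s): ",
                           paste(miss, collapse = ", ")))
  if (!"ncrna_class" %in% names(df) || all(is.na(df$ncrna_class)) ||
      all(df$ncrna_class == "")) {
    df$ncrna_class <- infer_ncrna_class(df$ncrna_name)
  }
  if (nrow(df) == 0) return(df)

  if (anyDuplicated(df$strain_id))
    bf_validation_error(paste0("duplicate strain_id: ",
      paste(unique(df$strain_id[duplicated(df$strain_id)]), collapse = ", ")))
  bad_cls <- !df$ncrna_class %in% NCRNA_CLASSES
  if (any(bad_cls))
    bf_validation_error(paste0("unknown ncrna_class '",
      df$ncrna_class[which(bad_cls)[1]], "' at row ", which(bad_cls)[1]))
  for (col in c("uptag", "downtag")) {
    bad <- !is_dna(df[[col]])
    if (any(bad))
      bf_validation_error(paste0("non-ACGT character in ", col, " at row ",
                                 which(bad)[1]))
    short <- nchar(df[[col]]) < MIN_TAG_LEN
    if (any(short))
      bf_validation_error(paste0(col, " shorter than ", MIN_TAG_LEN,
                                 " nt at row ", which(short)[1]))
  }
  same <- df$uptag == df$downtag
  if (any(same))
    bf_validation_error(paste0("uptag equals downtag for strain ",
                               df$strain_id[which(same)[1]]))
  tags <- c(df$uptag, df$downtag)
  owner <- rep(df$strain_id, 2L)
  dup <- duplicated(tags) | duplicated(tags, fromLast = TRUE)
  if (any(dup)) {
    t1 <- tags[dup][1]
    who <- unique(owner[tags == t1])
    bf_validation_error(paste0("TAG sequence ", t1,
      " is shared by strains: ", paste(who, collapse = ", ")))
  }
  df
}

new_barcode_catalog <- function(df) {
  tag_index <- data.frame(
    tag       = c(df$uptag, df$downtag),
    strain_id = rep(df$strain_id, 2L),
    which     = rep(c("up", "down"), each = nrow(df)),
    stringsAsFactors = FALSE
  )
  structure(list(records = df, tag_index = tag_index),
            class = "barcode_catalog")
}

#' Load and validate a strain/barcode catalog
#'
#' Reads a tab-separated catalog with columns `strain_id`, `ncrna_name`,
#' `ncrna_class`, `uptag`, `downtag` (lines starting with `#` are ignored).
#' When the class column is absent it is inferred from the name with
#' [infer_ncrna_class()]. TAG sequences must be ACGT-only, at least 15 nt,
#' and globally unique across the union of UPTAGs and DOWNTAGs (a read can
#' then never legitimately match two strains exactly).
#'
#' @param path path to the catalog TSV.
#' @return a `barcode_catalog`: list with `records` (data.frame, input row
#'   order preserved) and `tag_index` (data.frame tag / strain_id / which).
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) bf_schema_error(paste0("no such file: ", path))
  df <- read.delim(path, comment.char = "#", colClasses = "character",
                   stringsAsFactors = FALSE)
  df <- validate_catalog_df(df)
  new_barcode_catalog(df)
}

#' Build a catalog from an in-memory data frame
#'
#' Same validation as [load_catalog()].
#'
#' @param df data.frame with the catalog columns.
#' @return a `barcode_catalog`.
#' @export
as_barcode_catalog <- function(df) {
  df[] <- lapply(df, as.character)
  new_barcode_catalog(validate_catalog_df(df))
}

#' Write a catalog back to TSV
#'
#' Inverse of [load_catalog()]: writing then re-loading reproduces the
#' records exactly.
#'
#' @param catalog a `barcode_catalog`.
#' @param path output path.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "barcode_catalog"))
  df <- catalog$records[, c("strain_id", "ncrna_name", "ncrna_class",
                            "uptag", "downtag")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.barcode_catalog <- function(x, ...) {
  cat("barcode_catalog:", nrow(x$records), "strains,",
      nrow(x$tag_index), "TAGs\n")
  if (nrow(x$records) > 0) {
    tab <- table(x$records$ncrna_class)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Load and validate a sample sheet
#'
#' Tab-separated columns `sample_id`, `index6`, `condition`, `stage`,
#' `replicate`. Indices are the 6-mer multiplexing tags; they must be unique
#' within a sheet (one sequencing run), 6 nt and ACGT-only. Conditions and
#' stages are restricted to the chemostat competition design: carbon- or
#' nitrogen-limited medium at 30 or 36 degrees C, optionally with LiCl, and
#' stages pool (P), batch (B) and early/mid/late steady state.
#'
#' @param path path to the sample sheet TSV.
#' @return a validated data.frame of class `sample_sheet`.
#' @export
load_sample_sheet <- function(path) {
  if (!file.exists(path)) bf_schema_error(paste0("no such file: ", path))
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = "character")
  as_sample_sheet(df)
}

#' @rdname load_sample_sheet
#' @param df data.frame with the sample-sheet columns.
#' @export
as_sample_sheet <- function(df) {
  need <- c("sample_id", "index6", "condition", "stage", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    bf_schema_error(paste0("sample sheet is missing column(s): ",
                           paste(miss, collapse = ", ")))
  df$replicate <- suppressWarnings(as.integer(df$replicate))
  if (nrow(df) > 0) {
    if (anyDuplicated(df$sample_id))
      bf_validation_error("duplicate sample_id in sample sheet")
    if (anyDuplicated(df$index6))
      bf_validation_error(paste0("duplicate index6 in one run: ",
        paste(unique(df$index6[duplicated(df$index6)]), collapse = ", ")))
    bad <- nchar(df$index6) != 6L | !is_dna(df$index6)
    if (any(bad))
      bf_validation_error(paste0("index6 must be 6 nt over ACGT; row ",
                                 which(bad)[1]))
    bad <- !df$condition %in% CONDITIONS
    if (any(bad))
      bf_validation_error(paste0("unknown condition '",
        df$condition[which(bad)[1]], "' at row ", which(bad)[1]))
    bad <- !df$stage %in% STAGES
    if (any(bad))
      bf_validation_error(paste0("unknown stage '", df$stage[which(bad)[1]],
                                 "' at row ", which(bad)[1]))
    if (any(is.na(df$replicate) | df$replicate < 1))
      bf_validation_error("replicate must be a positive integer")
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Published composition of the ncRNA deletion strain collections
#'
#' Strain counts per collection background as published: the original
#' deletion collections and the strains added by the expansion. Summing the
#' table gives the total number of strains available for functional
#' analysis; 532 distinct ncRNAs are deleted in at least one background, of
#' which 17 proved essential on rich medium.
#'
#' @return data.frame with columns `collection`, `original`, `added`.
#' @export
#' @examples
#' sum(ncrna_collection_sizes()[, c("original", "added")])  # 1779
ncrna_collection_sizes <- function() {
  data.frame(
    collection = c("heterozygous_diploid", "haploid_MATa",
                   "haploid_MATalpha", "homozygous_diploid"),
    original = c(428L, 373L, 370L, 331L),
    added    = c(81L, 66L, 67L, 63L),
    stringsAsFactors = FALSE
  )
}

#' Total strains across all collections
#'
#' @param sizes a table as returned by [ncrna_collection_sizes()].
#' @return integer total strain count.
#' @export
collection_total <- function(sizes = ncrna_collection_sizes()) {
  sum(sizes$original) + sum(sizes$added)
}

#' Percentage of essential ncRNA deletions, rounded as printed
#'
#' @param n_essential essential deletions (17 on rich medium).
#' @param n_total distinct ncRNAs deleted (532).
#' @return integer percentage.
#' @export
essential_percentage <- function(n_essential = 17L, n_total = 532L) {
  round(100 * n_essential / n_total)
}

#' Independent barcode measurements per strain
#'
#' Each strain carries two TAGs (UPTAG and DOWNTAG) and each condition is
#' grown in biological repeats, so each strain is measured by
#' `n_tags * n_bio_reps` independent barcode libraries.
#'
#' @param n_tags TAGs per strain (2).
#' @param n_bio_reps biological repeats per condition (2).
#' @return integer count.
#' @export
barcodes_per_strain <- function(n_tags = 2L, n_bio_reps = 2L) {
  n_tags * n_bio_reps
}
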