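# Core record types and delimited-text I/O for GWAS summary statistics.

#' Default column mapping for a generic GWAS summary-statistics TSV
#'
#' Maps the package's field names to the column names of a generic
#' tab-separated summary-statistics file (`snp`, `ea`, `oa`, `eaf`, `beta`,
#' `se`, `p`, `n`). Pass a modified copy to [read_summary_table()] for files
#' with other dialects.
#'
#' @return Named character vector: names are internal fields, values are file
#'   column names.
#' @export
default_column_map <- function() {
  c(snp = "snp", ea = "ea", oa = "oa", eaf = "eaf",
    beta = "beta", se = "se", p = "p", n = "n")
}

#' Construct a GWAS summary table
#'
#' A `gwas_table` is a data frame of per-SNP association records for one
#' trait, with columns `snp`, `ea`, `oa`, `eaf`, `beta`, `se`, `p`, `n`.
#' Effect sizes are per effect-allele copy, in SD units of the trait unless
#' `trait_units` says otherwise. Alleles are upper-cased on construction;
#' indel alleles are kept verbatim.
#'
#' @param records Data frame with the columns above (`eaf` and `n` may
#'   contain `NA`).
#' @param trait_id Trait identifier.
#' @param trait_units Unit label for `beta` (default `"SD"`).
#' @param permissive If `TRUE`, rows violating record invariants are dropped
#'   (counted in `attr(x, "n_rejected")` with reasons in
#'   `attr(x, "rejected")`) instead of raising an error.
#' @return A `gwas_table` object (data frame with attributes `trait_id`,
#'   `trait_units`, `n_rejected`, `rejected`).
#' @export
gwas_table <- function(records, trait_id, trait_units = "SD",
                       permissive = FALSE) {
  required <- c("snp", "ea", "oa", "eaf", "beta", "se", "p")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"n" %in% names(records)) records$n <- NA_real_
  records <- records[, c(required, "n"), drop = FALSE]
  records$snp <- as.character(records$snp)
  records$ea <- toupper(as.character(records$ea))
  records$oa <- toupper(as.character(records$oa))
  for (col in c("eaf", "beta", "se", "p", "n")) {
    records[[col]] <- as.numeric(records[[col]])
  }

  bad <- validate_snp_records(records)
  if (nrow(bad) > 0L && !permissive) {
    stop("invalid summary rows in trait '", trait_id, "':\n",
         paste(sprintf("  row %d (%s): %s", bad$row, bad$snp, bad$reason),
               collapse = "\n"))
  }
  if (nrow(bad) > 0L) records <- records[-bad$row, , drop = FALSE]

  dup <- unique(records$snp[duplicated(records$snp)])
  if (length(dup) > 0L) {
    stop("duplicate snp ids in trait '", trait_id, "': ",
         paste(dup, collapse = ", "))
  }
  rownames(records) <- NULL
  structure(records,
            trait_id = trait_id,
            trait_units = trait_units,
            n_rejected = nrow(bad),
            rejected = if (nrow(bad) > 0L) bad else NULL,
            class = c("gwas_table", "data.frame"))
}

# Per-row invariant checks; returns data.frame(row, snp, reason).
validate_snp_records <- function(records) {
  reasons <- character(nrow(records))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    reasons[cond] <<- ifelse(reasons[cond] == "", msg,
                             paste(reasons[cond], msg, sep = "; "))
  }
  flag(is.na(records$snp) | records$snp == "", "missing snp id")
  flag(!is.na(records$se) & records$se <= 0, "se must be > 0")
  flag(is.na(records$se), "missing se")
  flag(is.na(records$beta), "missing beta")
  flag(!is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1),
       "eaf outside [0,1]")
  flag(is.na(records$p) | records$p <= 0 | records$p > 1,
       "pvalue outside (0,1]")
  flag(records$ea == records$oa, "effect allele equals other allele")
  bad <- which(reasons != "")
  data.frame(row = bad, snp = records$snp[bad], reason = reasons[bad],
             stringsAsFactors = FALSE)
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("GWAS summary table: trait '%s' (%s units), %d SNPs\n",
              attr(x, "trait_id"), attr(x, "trait_units"), nrow(x)))
  if (isTRUE(attr(x, "n_rejected") > 0)) {
    cat(sprintf("  (%d rows rejected at ingest)\n", attr(x, "n_rejected")))
  }
  print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Trait identifier of a GWAS table
#' @param x A `gwas_table`.
#' @return Character scalar.
#' @export
trait_id <- function(x) attr(x, "trait_id")

#' Read a GWAS summary-statistics table from a delimited file
#'
#' Reads a tab-separated file, renames columns according to `column_map`, and
#' validates every row against the record invariants (`se > 0`, `eaf` in
#' \[0,1\], `p` in (0,1\], distinct alleles). Malformed rows raise an error
#' naming each offending row unless `permissive = TRUE`, in which case they
#' are dropped and counted.
#'
#' @param path File path.
#' @param trait_id Trait identifier; defaults to the file name without
#'   extension.
#' @param column_map Named character vector mapping internal fields to file
#'   columns; see [default_column_map()].
#' @param trait_units Unit label (default `"SD"`).
#' @param permissive Drop (and count) invalid rows instead of erroring.
#' @return A [gwas_table()].
#' @export
read_summary_table <- function(path, trait_id = NULL,
                               column_map = default_column_map(),
                               trait_units = "SD", permissive = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(trait_id)) {
    trait_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), check.names = FALSE)
  needed <- column_map[setdiff(names(column_map), "n")]
  absent <- setdiff(unname(needed), names(raw))
  if (length(absent) > 0L) {
    stop("columns mapped but absent from ", path, ": ",
         paste(absent, collapse = ", "))
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in names(column_map)) {
    col <- column_map[[field]]
    out[[field]] <- if (col %in% names(raw)) raw[[col]] else NA_real_
  }
  gwas_table(out, trait_id = trait_id, trait_units = trait_units,
             permissive = permissive)
}

#' Write a GWAS summary table to a tab-separated file
#'
#' Writes the fixed header `snp ea oa eaf beta se p n` (tab-separated).
#' Numeric fields are written with 17 significant digits so that
#' [read_summary_table()] inverts the file to full double precision; missing
#' values are written as the literal token `NA`.
#'
#' @param table A [gwas_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(table, path) {
  stopifnot(inherits(table, "gwas_table"))
  df <- as.data.frame(table)
  for (col in c("eaf", "beta", "se", "p", "n")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "NA",
                        formatC(df[[col]], digits = 17, format = "g"))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trait classes recognised in trait metadata
#' @return Character vector of valid `trait_class` tokens.
#' @export
trait_classes <- function() {
  c("amino acids", "apolipoproteins", "cholesterol", "cholesterol esters",
    "fatty acids", "fluid balance", "glycolysis", "inflammation",
    "ketone bodies", "lipoprotein subclasses", "other lipids",
    "phospholipids", "triglycerides", "other")
}

#' Lipoprotein roles recognised in trait metadata
#' @return Character vector of valid `lipoprotein_role` tokens.
#' @export
lipoprotein_roles <- function() {
  c("total-lipids-in-subclass", "within-subclass-component",
    "composition-measure", "none")
}

#' Construct a trait-metadata table
#'
#' One row per trait: `trait_id`, `display_name`, `trait_class` (one of
#' [trait_classes()]), logical flags `is_ratio` and `is_composite`, and
#' `lipoprotein_role` (one of [lipoprotein_roles()]; defaults to `"none"`).
#'
#' @param df Data frame with at least `trait_id`, `trait_class`; missing
#'   `display_name` defaults to `trait_id`, missing flags to `FALSE`.
#' @return A validated `trait_info` data frame.
#' @export
trait_info <- function(df) {
  if (!all(c("trait_id", "trait_class") %in% names(df))) {
    stop("trait metadata needs at least trait_id and trait_class")
  }
  df$trait_id <- as.character(df$trait_id)
  if (is.null(df$display_name)) df$display_name <- df$trait_id
  if (is.null(df$is_ratio)) df$is_ratio <- FALSE
  if (is.null(df$is_composite)) df$is_composite <- FALSE
  if (is.null(df$lipoprotein_role)) df$lipoprotein_role <- "none"
  df$is_ratio <- as.logical(df$is_ratio)
  df$is_composite <- as.logical(df$is_composite)
  if (anyNA(df$is_ratio) || anyNA(df$is_composite)) {
    stop("is_ratio / is_composite must be logical, no NA")
  }
  bad_class <- setdiff(unique(df$trait_class), trait_classes())
  if (length(bad_class) > 0L) {
    stop("unknown trait_class: ", paste(bad_class, collapse = ", "))
  }
  bad_role <- setdiff(unique(df$lipoprotein_role), lipoprotein_roles())
  if (length(bad_role) > 0L) {
    stop("unknown lipoprotein_role: ", paste(bad_role, collapse = ", "))
  }
  if (anyDuplicated(df$trait_id)) {
    stop("duplicate trait_id in metadata")
  }
  df <- df[, c("trait_id", "display_name", "trait_class", "is_ratio",
               "is_composite", "lipoprotein_role"), drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("trait_info", "data.frame"))
}

#' Read trait metadata from a tab-separated file
#'
#' Expects columns `trait_id`, `display_name`, `trait_class`, `is_ratio`,
#' `is_composite`, `lipoprotein_role`; validates class and role vocabulary.
#'
#' @param path File path.
#' @return A [trait_info()] data frame.
#' @export
read_trait_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  trait_info(raw)
}

#' Write trait metadata to a tab-separated file
#' @param info A [trait_info()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_metadata <- function(info, path) {
  utils::write.table(as.data.frame(info), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
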