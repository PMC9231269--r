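# Harmonisation of exposure/outcome summary statistics and LD clumping.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_allele <- function(a) {
  out <- unname(COMPLEMENT[a])
  out[is.na(out)] <- a[is.na(out)]  # indels carry through verbatim
  out
}

is_palindromic <- function(ea, oa) {
  (ea %in% names(COMPLEMENT)) & (unname(COMPLEMENT[ea]) == oa)
}

#' Construct an LD matrix
#'
#' Pairwise allelic correlations (r, not r-squared) over a set of SNPs.
#' Validates symmetry, unit diagonal and \eqn{|r| \le 1}.
#'
#' @param r Square numeric matrix with snp ids as dimnames, or a data frame
#'   read from a square TSV.
#' @return A validated matrix of class `ld_matrix`.
#' @export
ld_matrix <- function(r) {
  r <- as.matrix(r)
  if (is.null(rownames(r)) || is.null(colnames(r))) {
    stop("LD matrix needs snp ids as row and column names")
  }
  if (!identical(rownames(r), colnames(r))) {
    stop("LD matrix row and column snp ids differ")
  }
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  if (max(abs(r)) > 1 + 1e-8) stop("LD entries must lie in [-1, 1]")
  structure((r + t(r)) / 2, class = c("ld_matrix", "matrix"))
}

#' Read an LD matrix from a square TSV
#'
#' The file has a header row of snp ids and the same ids in the first column.
#'
#' @param path File path.
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  ld_matrix(as.matrix(raw))
}

#' Write an LD matrix to a square TSV
#' @param ld An [ld_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(snp = rownames(ld), as.data.frame(unclass(ld)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a harmonised exposure/outcome instrument set
#'
#' @param exposure_id,outcome_id Trait identifiers.
#' @param records Data frame with columns `snp`, `beta_x`, `se_x`, `beta_y`,
#'   `se_y`, `eaf`, `palindromic`, `flipped`.
#' @param removed Data frame with columns `snp`, `reason` for SNPs dropped
#'   during harmonisation.
#' @return A `harmonised_set` object.
#' @export
harmonised_set <- function(exposure_id, outcome_id, records,
                           removed = data.frame(snp = character(),
                                                reason = character())) {
  if (nrow(records) > 0L) {
    stopifnot(all(records$se_x > 0), all(records$se_y > 0),
              !anyDuplicated(records$snp))
    if (any(records$snp %in% removed$snp)) {
      stop("a SNP cannot be both kept and removed")
    }
  }
  rownames(records) <- NULL
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 records = records, removed = removed),
            class = "harmonised_set")
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("Harmonised set: %s -> %s, K = %d instruments (%d removed)\n",
              x$exposure_id, x$outcome_id, nrow(x$records), nrow(x$removed)))
  invisible(x)
}

#' Number of instruments in a harmonised set
#' @param set A [harmonised_set()].
#' @return Integer count.
#' @export
n_instruments <- function(set) nrow(set$records)

#' Harmonise an exposure and an outcome summary table
#'
#' Aligns the outcome's effect estimates to the exposure's effect allele for
#' every shared SNP. Alleles matching after swap have the outcome beta
#' negated and eaf reflected; alleles matching only after strand complement
#' are complemented first. Palindromic SNPs (A/T or C/G) cannot be resolved
#' by letters: if the minor-allele frequency on either side exceeds
#' `maf_palindrome_limit` they are removed as ambiguous, otherwise the strand
#' is inferred by requiring the exposure and outcome allele frequencies to
#' fall on the same side of 0.5, flipping the outcome effect when they do
#' not. Exposure effect signs are never altered.
#'
#' @param exposure,outcome [gwas_table()] objects.
#' @param maf_palindrome_limit Palindromic SNPs with minor-allele frequency
#'   above this value (on either side) are removed (default 0.42).
#' @return A [harmonised_set()]; `removed` holds dropped SNPs with reasons
#'   `"ambiguous_palindrome"`, `"missing_eaf"` or `"incompatible_alleles"`.
#' @export
harmonise_pair <- function(exposure, outcome, maf_palindrome_limit = 0.42) {
  stopifnot(inherits(exposure, "gwas_table"), inherits(outcome, "gwas_table"))
  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0L) stop("no shared SNPs between exposure and outcome")

  ex <- as.data.frame(exposure)[match(shared, exposure$snp), ]
  ou <- as.data.frame(outcome)[match(shared, outcome$snp), ]

  kept <- vector("list", length(shared))
  removed <- list()
  for (i in seq_along(shared)) {
    snp <- shared[i]
    e <- ex[i, ]; o <- ou[i, ]
    pal <- is_palindromic(e$ea, e$oa)

    if (pal) {
      # Outcome alleles must be the same base pair.
      if (!((o$ea == e$ea && o$oa == e$oa) || (o$ea == e$oa && o$oa == e$ea))) {
        removed[[length(removed) + 1L]] <-
          data.frame(snp = snp, reason = "incompatible_alleles")
        next
      }
      if (is.na(e$eaf) || is.na(o$eaf)) {
        removed[[length(removed) + 1L]] <-
          data.frame(snp = snp, reason = "missing_eaf")
        next
      }
      # Nominal letter alignment first (swap on a palindrome is
      # indistinguishable from a strand flip; frequency arbitrates below).
      beta_y <- o$beta; eaf_y <- o$eaf; flipped <- FALSE
      if (o$ea == e$oa) {
        beta_y <- -beta_y; eaf_y <- 1 - eaf_y; flipped <- TRUE
      }
      maf_x <- min(e$eaf, 1 - e$eaf)
      maf_y <- min(eaf_y, 1 - eaf_y)
      if (maf_x > maf_palindrome_limit || maf_y > maf_palindrome_limit) {
        removed[[length(removed) + 1L]] <-
          data.frame(snp = snp, reason = "ambiguous_palindrome")
        next
      }
      if (sign(e$eaf - 0.5) != sign(eaf_y - 0.5)) {
        beta_y <- -beta_y; eaf_y <- 1 - eaf_y; flipped <- !flipped
      }
      kept[[i]] <- data.frame(snp = snp, beta_x = e$beta, se_x = e$se,
                              beta_y = beta_y, se_y = o$se, eaf = e$eaf,
                              palindromic = TRUE, flipped = flipped)
      next
    }

    o_ea <- o$ea; o_oa <- o$oa
    direct <- (o_ea == e$ea && o_oa == e$oa)
    swapped <- (o_ea == e$oa && o_oa == e$ea)
    if (!direct && !swapped) {
      # try strand complement
      o_ea <- complement_allele(o$ea); o_oa <- complement_allele(o$oa)
      direct <- (o_ea == e$ea && o_oa == e$oa)
      swapped <- (o_ea == e$oa && o_oa == e$ea)
    }
    if (!direct && !swapped) {
      removed[[length(removed) + 1L]] <-
        data.frame(snp = snp, reason = "incompatible_alleles")
      next
    }
    beta_y <- o$beta; flipped <- FALSE
    if (swapped) { beta_y <- -beta_y; flipped <- TRUE }
    kept[[i]] <- data.frame(snp = snp, beta_x = e$beta, se_x = e$se,
                            beta_y = beta_y, se_y = o$se, eaf = e$eaf,
                            palindromic = FALSE, flipped = flipped)
  }

  records <- do.call(rbind, kept[!vapply(kept, is.null, logical(1))])
  if (is.null(records)) {
    records <- data.frame(snp = character(), beta_x = numeric(),
                          se_x = numeric(), beta_y = numeric(),
                          se_y = numeric(), eaf = numeric(),
                          palindromic = logical(), flipped = logical())
  }
  removed_df <- if (length(removed) > 0L) do.call(rbind, removed) else
    data.frame(snp = character(), reason = character())
  harmonised_set(trait_id(exposure), trait_id(outcome), records, removed_df)
}

#' Greedy LD clumping of a summary table
#'
#' Restricts to SNPs with `p < p_threshold`, sorts by p-value (ties broken by
#' snp id), and greedily accepts SNPs, discarding any remaining SNP whose
#' squared correlation with an accepted SNP is at least `r2_threshold`. SNPs
#' absent from the LD matrix are dropped with a warning.
#'
#' @param table A [gwas_table()].
#' @param ld An [ld_matrix()] covering the candidate SNPs.
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param r2_threshold Squared-correlation independence threshold
#'   (default 0.01).
#' @return A [gwas_table()] restricted to the accepted SNPs (in acceptance
#'   order).
#' @export
clump <- function(table, ld, p_threshold = 5e-8, r2_threshold = 0.01) {
  stopifnot(inherits(table, "gwas_table"))
  cand <- as.data.frame(table)
  cand <- cand[!is.na(cand$p) & cand$p < p_threshold, , drop = FALSE]
  missing_ld <- setdiff(cand$snp, rownames(ld))
  if (length(missing_ld) > 0L) {
    warning("dropping ", length(missing_ld),
            " SNP(s) absent from the LD matrix: ",
            paste(utils::head(missing_ld, 5L), collapse = ", "))
    cand <- cand[!cand$snp %in% missing_ld, , drop = FALSE]
  }
  cand <- cand[order(cand$p, cand$snp), , drop = FALSE]
  accepted <- character()
  remaining <- cand$snp
  while (length(remaining) > 0L) {
    best <- remaining[1L]
    accepted <- c(accepted, best)
    r2 <- ld[remaining, best]^2
    remaining <- remaining[r2 < r2_threshold]
  }
  out <- cand[match(accepted, cand$snp), , drop = FALSE]
  gwas_table(out, trait_id = trait_id(table),
             trait_units = attr(table, "trait_units"))
}

#' Select and harmonise instruments for one exposure
#'
#' Composition of [clump()] (genome-wide significance + LD independence,
#' applied to `selection_table` if given, else to `exposure`) and
#' [harmonise_pair()] against the outcome. Supports the two-source design in
#' which SNPs are selected in one GWAS and effect sizes extracted from
#' another: selected SNPs are looked up in `exposure` for their effects.
#'
#' @param exposure [gwas_table()] supplying the SNP-exposure effects.
#' @param outcome [gwas_table()] for the outcome.
#' @param ld [ld_matrix()].
#' @param p_threshold,r2_threshold,maf_palindrome_limit Thresholds as in
#'   [clump()] and [harmonise_pair()].
#' @param selection_table Optional [gwas_table()] in which instruments are
#'   selected (defaults to `exposure`).
#' @return A [harmonised_set()]; zero instruments yields an empty set, not an
#'   error.
#' @export
select_instruments <- function(exposure, outcome, ld,
                               p_threshold = 5e-8, r2_threshold = 0.01,
                               maf_palindrome_limit = 0.42,
                               selection_table = NULL) {
  sel_src <- if (is.null(selection_table)) exposure else selection_table
  selected <- clump(sel_src, ld, p_threshold, r2_threshold)
  snps <- selected$snp
  if (!is.null(selection_table)) {
    snps <- intersect(snps, exposure$snp)
  }
  if (length(snps) == 0L) {
    return(harmonised_set(trait_id(exposure), trait_id(outcome),
                          data.frame(snp = character(), beta_x = numeric(),
                                     se_x = numeric(), beta_y = numeric(),
                                     se_y = numeric(), eaf = numeric(),
                                     palindromic = logical(),
                                     flipped = logical())))
  }
  sub <- as.data.frame(exposure)[exposure$snp %in% snps, , drop = FALSE]
  sub_table <- gwas_table(sub, trait_id = trait_id(exposure),
                          trait_units = attr(exposure, "trait_units"))
  harmonise_pair(sub_table, outcome, maf_palindrome_limit)
}
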