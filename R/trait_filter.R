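# Trait-panel reduction: ratio/composite exclusion, lipoprotein-subclass
# selection, and genetic-correlation pruning.

#' Construct a filter report
#'
#' @param kept Character vector of retained trait ids.
#' @param excluded Data frame with columns `trait_id`, `stage` (one of
#'   `ratio_composite`, `lipoprotein_subset`, `genetic_correlation`),
#'   `reason`.
#' @param input_ids All trait ids that entered the stage (for the
#'   conservation invariant kept + excluded = input).
#' @return A `filter_report` object.
#' @export
filter_report <- function(kept, excluded, input_ids) {
  stopifnot(setequal(c(kept, excluded$trait_id), input_ids),
            length(intersect(kept, excluded$trait_id)) == 0L)
  structure(list(kept = kept, excluded = excluded, input_ids = input_ids),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: %d in, %d kept, %d excluded\n",
              length(x$input_ids), length(x$kept), nrow(x$excluded)))
  if (nrow(x$excluded) > 0L) {
    print(table(x$excluded$stage))
  }
  invisible(x)
}

empty_exclusions <- function() {
  data.frame(trait_id = character(), stage = character(),
             reason = character(), stringsAsFactors = FALSE)
}

#' Exclude derived ratios and composite measures
#'
#' Drops every trait flagged `is_ratio` or `is_composite` in the metadata.
#' Ratios duplicate the information of their numerator/denominator traits and
#' composites are sums of panel members, so both are redundant with the
#' retained concentration measures.
#'
#' @param traits A [trait_info()] data frame.
#' @return A [filter_report()] (stage `ratio_composite`).
#' @export
filter_ratios_composites <- function(traits) {
  drop <- traits$is_ratio | traits$is_composite
  reason <- ifelse(traits$is_ratio[drop], "derived ratio",
                   "composite measure")
  excl <- data.frame(trait_id = traits$trait_id[drop],
                     stage = rep("ratio_composite", sum(drop)),
                     reason = reason, stringsAsFactors = FALSE)
  filter_report(traits$trait_id[!drop],
                if (nrow(excl)) excl else empty_exclusions(),
                traits$trait_id)
}

#' Restrict lipoprotein traits to total lipids per subclass
#'
#' Within-subclass lipid measures (cholesterol, triglycerides, phospholipids
#' etc. inside one lipoprotein subclass) are too genetically correlated to be
#' separated in a joint model, so only the total-lipids measure of each
#' subclass is retained, alongside all non-lipoprotein traits and the named
#' lipid-composition / apolipoprotein measures. Driven entirely by the
#' `lipoprotein_role` metadata column: `within-subclass-component` is
#' excluded, everything else kept.
#'
#' @param traits A [trait_info()] data frame.
#' @return A [filter_report()] (stage `lipoprotein_subset`).
#' @export
select_lipoprotein_subset <- function(traits) {
  drop <- traits$lipoprotein_role == "within-subclass-component"
  excl <- data.frame(trait_id = traits$trait_id[drop],
                     stage = rep("lipoprotein_subset", sum(drop)),
                     reason = rep("within-subclass lipid component", sum(drop)),
                     stringsAsFactors = FALSE)
  filter_report(traits$trait_id[!drop],
                if (nrow(excl)) excl else empty_exclusions(),
                traits$trait_id)
}

#' Construct a trait genetic-correlation matrix
#'
#' @param rg Square numeric matrix of genetic correlations with trait ids as
#'   dimnames; symmetric, unit diagonal, entries in \[-1, 1\].
#' @return A `trait_cor_matrix` object.
#' @export
trait_cor_matrix <- function(rg) {
  rg <- as.matrix(rg)
  if (is.null(rownames(rg)) || !identical(rownames(rg), colnames(rg))) {
    stop("genetic-correlation matrix needs matching trait ids as dimnames")
  }
  if (max(abs(rg - t(rg))) > 1e-8) stop("matrix must be symmetric")
  if (max(abs(diag(rg) - 1)) > 1e-8) stop("diagonal must be 1")
  if (max(abs(rg)) > 1 + 1e-8) stop("entries must lie in [-1, 1]")
  structure((rg + t(rg)) / 2, class = c("trait_cor_matrix", "matrix"))
}

#' Estimate pairwise genetic correlation from instrument effect estimates
#'
#' For each pair of traits, computes the weighted Pearson correlation of the
#' per-SNP effect estimates over the instrument union, with weights
#' \eqn{1/(\sigma_{jk}\sigma_{jl})}; values are clipped to \[-1, 1\]. This is
#' a summary-statistic approximation adequate for flagging near-duplicate
#' traits; the matrix can alternatively be supplied directly to
#' [prune_genetic_correlation()].
#'
#' @param tables Named list of [gwas_table()] objects (>= 2 traits).
#' @param instrument_union Character vector of snp ids over which to
#'   correlate effects.
#' @return A [trait_cor_matrix()].
#' @export
genetic_correlation_matrix <- function(tables, instrument_union) {
  if (length(tables) < 2L) stop("need at least 2 traits")
  if (length(instrument_union) == 0L) stop("empty instrument union")
  ids <- vapply(tables, trait_id, character(1))
  names(tables) <- ids

  eff <- se <- matrix(NA_real_, nrow = length(instrument_union),
                      ncol = length(ids), dimnames = list(instrument_union, ids))
  for (id in ids) {
    tab <- tables[[id]]
    idx <- match(instrument_union, tab$snp)
    miss <- mean(is.na(idx))
    if (miss > 0.5) {
      stop("trait '", id, "' is missing more than 50% of the instrument union")
    }
    eff[, id] <- tab$beta[idx]
    se[, id] <- tab$se[idx]
  }

  K <- length(ids)
  rg <- diag(1, K)
  dimnames(rg) <- list(ids, ids)
  for (k in seq_len(K - 1L)) {
    for (l in (k + 1L):K) {
      ok <- !is.na(eff[, k]) & !is.na(eff[, l])
      w <- 1 / (se[ok, k] * se[ok, l])
      x <- eff[ok, k]; y <- eff[ok, l]
      mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
      cov_xy <- sum(w * (x - mx) * (y - my))
      v_x <- sum(w * (x - mx)^2); v_y <- sum(w * (y - my)^2)
      r <- cov_xy / sqrt(v_x * v_y)
      rg[k, l] <- rg[l, k] <- max(-1, min(1, r))
    }
  }
  trait_cor_matrix(rg)
}

#' Prune near-duplicate traits by genetic correlation
#'
#' Traits whose squared genetic correlation exceeds `r2_limit` are
#' genetically indistinguishable and cannot enter a joint model together.
#' Pairs with \eqn{r_g^2 >} `r2_limit` are visited in decreasing
#' \eqn{r_g^2} order (ties broken by trait ids); within a pair the trait
#' later in `priority` is removed; pairs whose members are already removed
#' are skipped.
#'
#' @param matrix A [trait_cor_matrix()].
#' @param r2_limit Squared-correlation limit (default 0.985).
#' @param priority Ordered character vector of trait ids; earlier = retained
#'   preferentially. Defaults to the matrix order.
#' @return A [filter_report()] (stage `genetic_correlation`).
#' @export
prune_genetic_correlation <- function(matrix, r2_limit = 0.985,
                                      priority = NULL) {
  ids <- rownames(matrix)
  if (is.null(priority)) priority <- ids
  stopifnot(setequal(priority, ids))
  rank <- match(ids, priority)

  pairs <- which(upper.tri(matrix), arr.ind = TRUE)
  r2 <- matrix[pairs]^2
  sel <- r2 > r2_limit
  pairs <- pairs[sel, , drop = FALSE]
  r2 <- r2[sel]
  ord <- order(-r2, ids[pairs[, 1L]], ids[pairs[, 2L]])
  pairs <- pairs[ord, , drop = FALSE]
  r2 <- r2[ord]

  removed <- character()
  reasons <- character()
  for (i in seq_len(nrow(pairs))) {
    a <- ids[pairs[i, 1L]]; b <- ids[pairs[i, 2L]]
    if (a %in% removed || b %in% removed) next
    victim <- if (rank[match(a, ids)] <= rank[match(b, ids)]) b else a
    survivor <- setdiff(c(a, b), victim)
    removed <- c(removed, victim)
    reasons <- c(reasons,
                 sprintf("rg^2 = %.4f with %s", r2[i], survivor))
  }
  excl <- data.frame(trait_id = removed,
                     stage = rep("genetic_correlation", length(removed)),
                     reason = reasons, stringsAsFactors = FALSE)
  filter_report(setdiff(ids, removed),
                if (nrow(excl)) excl else empty_exclusions(),
                ids)
}

#' Write a filter report's exclusions to TSV
#' @param report A [filter_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  rows <- rbind(
    data.frame(trait_id = report$kept, stage = "kept", reason = "",
               stringsAsFactors = FALSE),
    report$excluded)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
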