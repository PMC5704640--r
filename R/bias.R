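#' Average technical replicates
#'
#' Collapses replicate columns to their arithmetic mean, one output column
#' per group, in group order.
#'
#' @param x expression matrix.
#' @param groups either a named list of sample-id vectors, or a character /
#'   factor vector (one group label per column of `x`). Groups must
#'   partition the samples: every column in exactly one group.
#' @return matrix with one column per group (an `ExpressionMatrix` if the
#'   input was one).
#' @export
replicate_average <- function(x, groups) {
  v <- as_values(x)
  if (!is.list(groups)) {
    if (length(groups) != ncol(v))
      stop("grouping vector must have one label per sample", call. = FALSE)
    groups <- split(colnames(v), factor(groups, levels = unique(groups)))
  }
  member <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(member))
    stop("replicate groups overlap", call. = FALSE)
  missing <- setdiff(member, colnames(v))
  if (length(missing) > 0)
    stop_sprintf("group member not present in matrix: %s",
                 paste(head(missing, 5L), collapse = ", "))
  orphan <- setdiff(colnames(v), member)
  if (length(orphan) > 0)
    stop_sprintf("sample referenced in no group: %s",
                 paste(head(orphan, 5L), collapse = ", "))
  if (any(lengths(groups) == 0L))
    stop("empty replicate group", call. = FALSE)
  out <- vapply(groups, function(s) rowMeans(v[, s, drop = FALSE]),
                numeric(nrow(v)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(v))
  dimnames(out) <- list(rownames(v), names(groups))
  if (inherits(x, "ExpressionMatrix"))
    out <- expression_matrix(out, unit = expr_unit(x))
  out
}

#' Per-gene fold changes between paired low- and high-input profiles
#'
#' Computes the directional ratio low/high and the symmetric fold change
#' `max(low/high, high/low)` for each gene. Genes whose ratio is undefined
#' under `zero_policy = "exclude"` (either value zero) are flagged `NA` and
#' counted in `n_undefined`; with `zero_policy = "pseudocount"` the ratio is
#' `(low + c)/(high + c)` and always defined.
#'
#' @param low,high single profiles (named vectors or one-column matrices)
#'   over the same gene universe, typically replicate averages from
#'   [replicate_average()].
#' @param zero_policy `"exclude"` (default) or `"pseudocount"`.
#' @param pseudocount the constant c added under the pseudocount policy.
#' @return a `FoldChangeTable` data frame with columns `gene_id`, `low`,
#'   `high`, `fc_directional`, `fc_symmetric`, plus attributes
#'   `n_undefined` and `n_evaluated`.
#' @export
fold_change <- function(low, high, zero_policy = c("exclude", "pseudocount"),
                        pseudocount = 1) {
  zero_policy <- match.arg(zero_policy)
  lv <- as_values(low); hv <- as_values(high)
  if (ncol(lv) != 1L || ncol(hv) != 1L)
    stop("fold_change expects single profiles; average replicates first",
         call. = FALSE)
  if (!setequal(rownames(lv), rownames(hv)))
    stop("mismatched gene universes; use intersect_genes first",
         call. = FALSE)
  hv <- hv[rownames(lv), , drop = FALSE]
  l <- lv[, 1L]; h <- hv[, 1L]
  if (zero_policy == "pseudocount") {
    fc <- (l + pseudocount) / (h + pseudocount)
  } else {
    fc <- ifelse(l > 0 & h > 0, l / h, NA_real_)
  }
  out <- data.frame(gene_id = rownames(lv), low = l, high = h,
                    fc_directional = fc,
                    fc_symmetric = pmax(fc, 1 / fc),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_undefined") <- sum(is.na(fc))
  attr(out, "n_evaluated") <- sum(!is.na(fc))
  class(out) <- c("FoldChangeTable", "data.frame")
  out
}

#' Proportion of genes at or above a symmetric fold change
#'
#' The headline bias metric: the fraction of evaluable genes whose
#' symmetric fold change between the low- and high-input profile is at
#' least `threshold` (default 2).
#'
#' @param fc a [fold_change()] table, or a numeric vector of symmetric
#'   fold changes.
#' @param threshold fold-change cutoff, >= 1.
#' @return fraction in \[0, 1\] over the defined (non-`NA`) genes.
#' @export
proportion_fc_at_least <- function(fc, threshold = 2) {
  if (threshold < 1) stop("threshold must be >= 1", call. = FALSE)
  v <- if (is.data.frame(fc)) fc$fc_symmetric else as.numeric(fc)
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop("no genes with a defined fold change", call. = FALSE)
  mean(v >= threshold)
}

#' Directional fold changes for every replicate pairing
#'
#' Computes the directional FC for each (low replicate, high replicate)
#' column pairing, the ingredient of the fold-change CV.
#'
#' @param low,high replicate matrices over the same gene universe.
#' @inheritParams fold_change
#' @return numeric matrix, genes x pairings (colnames `low|high`), `NA`
#'   where the exclude policy applies.
#' @export
fold_change_pairings <- function(low, high,
                                 zero_policy = c("exclude", "pseudocount"),
                                 pseudocount = 1) {
  zero_policy <- match.arg(zero_policy)
  lv <- as_values(low); hv <- as_values(high)
  if (!setequal(rownames(lv), rownames(hv)))
    stop("mismatched gene universes; use intersect_genes first",
         call. = FALSE)
  hv <- hv[rownames(lv), , drop = FALSE]
  combos <- expand.grid(l = seq_len(ncol(lv)), h = seq_len(ncol(hv)))
  out <- mapply(function(li, hi) {
    l <- lv[, li]; h <- hv[, hi]
    if (zero_policy == "pseudocount") (l + pseudocount) / (h + pseudocount)
    else ifelse(l > 0 & h > 0, l / h, NA_real_)
  }, combos$l, combos$h)
  colnames(out) <- paste(colnames(lv)[combos$l], colnames(hv)[combos$h],
                         sep = "|")
  rownames(out) <- rownames(lv)
  out
}

#' Coefficient of variation of fold changes
#'
#' For a plain vector of fold changes this is simply sd/mean (sample
#' standard deviation, denominator n - 1). For a genes-by-pairings matrix
#' from [fold_change_pairings()], `axis = "over_genes"` (default) first
#' averages each gene's FC across replicate pairings and returns the CV of
#' those per-gene means across genes; `axis = "over_replicate_pairs"`
#' computes each gene's CV across its pairings and returns the mean of
#' those per-gene CVs.
#'
#' @param fcs numeric vector, or genes x pairings FC matrix (`NA` entries
#'   are dropped).
#' @param axis see above; ignored for vector input.
#' @return a single non-negative CV.
#' @export
cv_of_fold_changes <- function(fcs,
                               axis = c("over_genes",
                                        "over_replicate_pairs")) {
  axis <- match.arg(axis)
  cv1 <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L)
      stop("need >= 2 fold-change values along the chosen axis",
           call. = FALSE)
    m <- mean(v)
    if (m == 0) stop("mean fold change is zero; CV undefined", call. = FALSE)
    sd(v) / m
  }
  if (is.null(dim(fcs))) return(cv1(as.numeric(fcs)))
  if (axis == "over_genes") {
    g <- rowMeans(fcs, na.rm = TRUE)
    g <- g[rowSums(!is.na(fcs)) > 0]
    return(cv1(g))
  }
  per_gene <- apply(fcs, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    if (mean(v) == 0) return(NA_real_)
    sd(v) / mean(v)
  })
  per_gene <- per_gene[!is.na(per_gene)]
  if (length(per_gene) == 0L)
    stop("no gene has >= 2 defined pairings", call. = FALSE)
  mean(per_gene)
}

#' Summarize amplification bias for one dilution level
#'
#' Convenience wrapper tying the bias primitives together: averages the
#' replicates of each side, computes per-gene fold changes, the proportion
#' of genes at the fold-change threshold, and the CV of the per-pairing
#' fold changes.
#'
#' @param low,high replicate matrices for the low- and high-input profiles
#'   of one condition/level (same gene universe).
#' @param threshold symmetric fold-change cutoff.
#' @inheritParams fold_change
#' @param cv_axis passed to [cv_of_fold_changes()].
#' @return list with elements `fold_changes` (the per-gene table),
#'   `prop_fc_ge_threshold`, `cv`, `n_genes_evaluated`, `n_genes_undefined`.
#' @export
bias_summary <- function(low, high, threshold = 2,
                         zero_policy = c("exclude", "pseudocount"),
                         pseudocount = 1,
                         cv_axis = c("over_genes", "over_replicate_pairs")) {
  zero_policy <- match.arg(zero_policy)
  cv_axis <- match.arg(cv_axis)
  lv <- as_values(low); hv <- as_values(high)
  lm <- replicate_average(lv, rep("low", ncol(lv)))
  hm <- replicate_average(hv, rep("high", ncol(hv)))
  fc <- fold_change(lm, hm, zero_policy = zero_policy,
                    pseudocount = pseudocount)
  pair_fcs <- fold_change_pairings(lv, hv, zero_policy = zero_policy,
                                   pseudocount = pseudocount)
  list(fold_changes = fc,
       prop_fc_ge_threshold = proportion_fc_at_least(fc, threshold),
       cv = cv_of_fold_changes(pair_fcs, axis = cv_axis),
       n_genes_evaluated = attr(fc, "n_evaluated"),
       n_genes_undefined = attr(fc, "n_undefined"))
}
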