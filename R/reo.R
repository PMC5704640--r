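#' Rank profile of expression values
#'
#' Ascending ranks (rank 1 = lowest expression) with average ranks at ties,
#' computed per sample for matrix input. All REO computations depend on
#' expression values only through these ranks.
#'
#' @param x named numeric vector (one sample) or genes x samples matrix.
#' @return numeric vector or matrix of ranks with the same dimnames.
#' @examples
#' rank_profile(c(a = 5, b = 1, c = 3, d = 3))  # 4, 1, 2.5, 2.5
#' @export
rank_profile <- function(x) {
  if (is.null(dim(x)) && !inherits(x, "ExpressionMatrix")) {
    if (anyNA(x)) stop("NA values in profile; pre-filter first",
                       call. = FALSE)
    if (length(x) < 2L) stop("need >= 2 genes to rank", call. = FALSE)
    return(rank(x, ties.method = "average"))
  }
  v <- as_values(x)
  if (anyNA(v)) stop("NA values in profile; pre-filter first", call. = FALSE)
  if (nrow(v) < 2L) stop("need >= 2 genes to rank", call. = FALSE)
  out <- apply(v, 2, rank, ties.method = "average")
  dimnames(out) <- dimnames(v)
  out
}

# Shared constructor for stable-pair sets. `values` is the genes x samples
# matrix of the defining samples. Materialized sets carry an explicit pair
# table (gene ids canonicalized so gene_i < gene_j lexicographically,
# direction = +1 when gene_i is the higher-expressed gene); implicit sets
# carry only the defining rank profiles plus the pair count, so that
# genome-scale references never materialize O(G^2) records.
new_stable_pair_set <- function(values, f, strict, rule, materialize) {
  ranks <- rank_profile(values)
  gn <- rownames(values)
  if (materialize) {
    res <- cpp_stable_pairs(ranks, f, strict)
    gi <- gn[res$i]; gj <- gn[res$j]; dir <- res$direction
    swap <- gi > gj
    tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
    dir[swap] <- -dir[swap]
    pairs <- data.frame(gene_i = gi, gene_j = gj, direction = dir,
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$gene_i, pairs$gene_j), , drop = FALSE]
    rownames(pairs) <- NULL
    n_pairs <- nrow(pairs)
  } else {
    pairs <- NULL
    n_pairs <- cpp_count_stable(ranks, f, strict)
  }
  structure(list(pairs = pairs, genes = gn, rank_profiles = ranks,
                 rule = rule, f = f, strict = strict,
                 n_pairs = n_pairs, implicit = !materialize),
            class = "StablePairSet")
}

#' @export
print.StablePairSet <- function(x, ...) {
  cat(sprintf(
    "StablePairSet: %s pairs over %d genes (rule: %s%s)%s\n",
    format(x$n_pairs, big.mark = ","), length(x$genes), x$rule,
    if (x$rule == "frequency")
      sprintf(", f %s %.4g", if (x$strict) ">" else ">=", x$f) else "",
    if (x$implicit) " [implicit]" else ""))
  invisible(x)
}

#' Stable gene pairs from two technical replicates
#'
#' A pair is stable when it has the identical strict REO direction in both
#' technical replicates; pairs tied in either replicate are excluded. This
#' is the replicate-identity rule used to define the high-input reference
#' pair set.
#'
#' @param rep1,rep2 named vectors or one-column matrices over the same gene
#'   universe.
#' @param materialize if `FALSE`, only the defining rank profiles and the
#'   pair count are stored; genome-scale references stay O(G) in memory and
#'   [consistency_score()] evaluates them in a streaming pass.
#' @return a `StablePairSet`.
#' @export
stable_pairs_replicates <- function(rep1, rep2, materialize = TRUE) {
  r1 <- as_values(rep1); r2 <- as_values(rep2)
  if (!setequal(rownames(r1), rownames(r2)))
    stop("replicates have mismatched gene universes", call. = FALSE)
  r2 <- r2[rownames(r1), , drop = FALSE]
  v <- cbind(r1[, 1L], r2[, 1L])
  dimnames(v) <- list(rownames(r1), c("rep1", "rep2"))
  new_stable_pair_set(v, f = 1, strict = FALSE, rule = "replicate-identity",
                      materialize = materialize)
}

#' Stable gene pairs by cohort frequency
#'
#' A pair is stable when one strict direction holds in more than `f`
#' (default, `strict = TRUE`) or in at least `f` (`strict = FALSE`) of the
#' samples; ties count against stability. The conventional highly-stable
#' rule is f = 0.99 strict ("more than 99% of samples"); unanimity across
#' a cohort is f = 1 with `strict = FALSE`.
#'
#' @param x genes x samples matrix with >= 2 samples.
#' @param f frequency threshold in (0.5, 1\].
#' @param strict require the frequency to exceed (`TRUE`) or reach
#'   (`FALSE`) `f`.
#' @inheritParams stable_pairs_replicates
#' @return a `StablePairSet`.
#' @export
stable_pairs_frequency <- function(x, f = 0.99, strict = TRUE,
                                   materialize = TRUE) {
  v <- as_values(x)
  if (ncol(v) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (f <= 0.5 || f > 1)
    stop("f must be in (0.5, 1]; below 0.5 the direction is ambiguous",
         call. = FALSE)
  new_stable_pair_set(v, f = f, strict = strict, rule = "frequency",
                      materialize = materialize)
}

#' REO consistency score of a query profile
#'
#' The fraction k/n of a reference stable-pair set whose REO direction is
#' maintained in the query profile: n is the number of reference pairs and
#' k the number whose strict query ordering matches the reference
#' direction. Under the default `tie_policy = "discordant"` a query tie
#' counts against consistency (it stays in n); `"drop"` removes query-tied
#' pairs from both n and k.
#'
#' `exclude_fraction = x` first removes the `floor(x * n)` reference pairs
#' with the smallest mean absolute rank difference over the defining
#' samples (ties at the cut broken lexicographically by gene-id pair),
#' since close-ranked pairs are the ones sensitive to measurement noise.
#'
#' @param reference a `StablePairSet`.
#' @param query named vector or one-column matrix covering all reference
#'   genes.
#' @param tie_policy `"discordant"` (default) or `"drop"`.
#' @param exclude_fraction fraction in \[0, 1) of smallest-rank-difference
#'   pairs to exclude before scoring.
#' @return a `ConsistencyResult` list: `n`, `k`, `score = k/n`,
#'   `exclude_fraction`, `n_before_exclusion`.
#' @export
consistency_score <- function(reference, query,
                              tie_policy = c("discordant", "drop"),
                              exclude_fraction = 0) {
  stopifnot(inherits(reference, "StablePairSet"))
  tie_policy <- match.arg(tie_policy)
  if (exclude_fraction < 0 || exclude_fraction >= 1)
    stop("exclude_fraction must be in [0, 1)", call. = FALSE)
  q <- as_values(query)
  if (ncol(q) != 1L)
    stop("query must be a single profile", call. = FALSE)
  missing <- setdiff(reference$genes, rownames(q))
  if (length(missing) > 0)
    stop_sprintf(
      "reference gene(s) absent from query (use intersect_genes): %s",
      paste(head(missing, 5L), collapse = ", "))
  qv <- q[reference$genes, 1L]
  if (anyNA(qv)) stop("NA values in query", call. = FALSE)

  if (reference$implicit) {
    lex <- order(reference$genes)
    res <- cpp_consistency_implicit(
      reference$rank_profiles, qv, reference$f, reference$strict,
      exclude_fraction, tie_policy == "drop", as.integer(lex - 1L))
    n_before <- res$n_before; n <- res$n; k <- res$k
  } else {
    set <- reference
    n_before <- nrow(set$pairs)
    if (exclude_fraction > 0)
      set <- exclude_small_rank_diff(set, exclude_fraction)
    qi <- qv[set$pairs$gene_i]
    qj <- qv[set$pairs$gene_j]
    sgn <- sign(qi - qj)
    if (tie_policy == "drop") {
      n <- sum(sgn != 0)
      k <- sum(sgn == set$pairs$direction)
    } else {
      n <- nrow(set$pairs)
      k <- sum(sgn == set$pairs$direction)
    }
  }
  n <- as.numeric(n); k <- as.numeric(k)
  if (n == 0) warning("no scoreable pairs; score is NA")
  structure(list(n = n, k = k, score = if (n > 0) k / n else NA_real_,
                 exclude_fraction = exclude_fraction,
                 n_before_exclusion = n_before,
                 tie_policy = tie_policy),
            class = "ConsistencyResult")
}

#' @export
print.ConsistencyResult <- function(x, ...) {
  cat(sprintf(
    "ConsistencyResult: k/n = %s/%s = %.4f (excluded fraction %.2f)\n",
    format(x$k, big.mark = ","), format(x$n, big.mark = ","),
    x$score, x$exclude_fraction))
  invisible(x)
}

#' Exclude reference pairs with the smallest rank differences
#'
#' Scores each pair by the mean over the defining samples of the absolute
#' rank difference between its genes and removes the `floor(fraction * n)`
#' lowest-scoring pairs; ties at the cut are broken by lexicographic
#' gene-id pair order for determinism.
#'
#' Only materialized sets can be filtered standalone; for implicit
#' (streaming) references pass `exclude_fraction` to [consistency_score()],
#' which applies the identical rule without materializing pairs.
#'
#' @param reference a materialized `StablePairSet`.
#' @param fraction fraction in \[0, 1) to remove.
#' @return the filtered `StablePairSet`.
#' @export
exclude_small_rank_diff <- function(reference, fraction) {
  stopifnot(inherits(reference, "StablePairSet"))
  if (fraction < 0 || fraction >= 1)
    stop("fraction must be in [0, 1)", call. = FALSE)
  if (reference$implicit)
    stop(paste("implicit reference: use consistency_score(...,",
               "exclude_fraction =) instead"), call. = FALSE)
  if (fraction == 0) return(reference)
  p <- reference$pairs
  rp <- reference$rank_profiles
  d <- rowMeans(abs(rp[p$gene_i, , drop = FALSE] -
                    rp[p$gene_j, , drop = FALSE]))
  drop_n <- floor(fraction * nrow(p))
  if (drop_n > 0) {
    ord <- order(d, p$gene_i, p$gene_j)
    keep <- setdiff(seq_len(nrow(p)), ord[seq_len(drop_n)])
    p <- p[keep, , drop = FALSE]
    rownames(p) <- NULL
  }
  out <- reference
  out$pairs <- p
  out$n_pairs <- nrow(p)
  out
}
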