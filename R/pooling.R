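#' Random partition of single cells into pseudo-bulk groups
#'
#' Default group sizing follows the round-then-remainder scheme: the first
#' `n_groups - 1` groups get `round(n_cells / n_groups)` cells and the
#' last group the remainder, e.g. 272 cells in 11 groups gives ten groups
#' of 25 plus one of 22, and 157 cells gives ten groups of 14 plus one of
#' 17. The assignment itself is a uniform random permutation partition,
#' reproducible from the seed.
#'
#' @param n_cells number of cells.
#' @param n_groups number of pseudo-bulk groups (ignored when `sizes` is
#'   given).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param sizes optional explicit group sizes summing to `n_cells`.
#' @return a `PoolingPlan` list: `n_cells`, `sizes`, `assignment` (group
#'   index per cell), `seed`.
#' @export
make_pooling_plan <- function(n_cells, n_groups, seed = NULL, sizes = NULL) {
  if (is.null(sizes)) {
    if (n_groups < 1L) stop("n_groups must be >= 1", call. = FALSE)
    if (n_groups == 1L) {
      sizes <- n_cells
    } else {
      base <- round(n_cells / n_groups)
      last <- n_cells - (n_groups - 1L) * base
      if (last <= 0L)
        stop("default sizing leaves an empty last group; give explicit sizes",
             call. = FALSE)
      sizes <- c(rep(base, n_groups - 1L), last)
    }
  }
  sizes <- as.integer(sizes)
  if (any(sizes < 1L) || sum(sizes) != n_cells)
    stop("sizes must be positive and sum to n_cells", call. = FALSE)
  perm <- with_seed(seed, sample.int(n_cells))
  assignment <- integer(n_cells)
  assignment[perm] <- rep.int(seq_along(sizes), sizes)
  structure(list(n_cells = n_cells, sizes = sizes,
                 assignment = assignment, seed = seed),
            class = "PoolingPlan")
}

#' @export
print.PoolingPlan <- function(x, ...) {
  cat(sprintf("PoolingPlan: %d cells -> %d groups (sizes: %s)\n",
              x$n_cells, length(x$sizes),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Sum single cells into pseudo-bulk profiles
#'
#' Each pseudo-bulk expression value is the per-gene sum of the member
#' cells' values; the grand total of the matrix is conserved exactly.
#'
#' @param cells genes x cells matrix.
#' @param plan a [make_pooling_plan()] covering exactly the cells of the
#'   matrix.
#' @return genes x groups matrix (columns `pool1`, `pool2`, ...), same
#'   unit as the input.
#' @export
pool_sum <- function(cells, plan) {
  stopifnot(inherits(plan, "PoolingPlan"))
  v <- as_values(cells)
  if (ncol(v) != plan$n_cells)
    stop("plan does not cover the cells of the matrix", call. = FALSE)
  out <- vapply(seq_along(plan$sizes), function(g) {
    rowSums(v[, plan$assignment == g, drop = FALSE])
  }, numeric(nrow(v)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(v))
  dimnames(out) <- list(rownames(v), paste0("pool", seq_along(plan$sizes)))
  if (inherits(cells, "ExpressionMatrix"))
    out <- expression_matrix(out, unit = expr_unit(cells))
  out
}

#' Repeated pseudo-bulk pooling and classification experiment
#'
#' In each repeat, cells of both classes are independently re-partitioned
#' into pseudo-bulk groups (separate seed streams per class), pooled by
#' summation, and classified against the signature, optionally after
#' pruning small-rank-difference pairs at each filter fraction. Reported
#' are the per-repeat sensitivity/specificity and their arithmetic means
#' per fraction.
#'
#' @param positive_cells,negative_cells genes x cells matrices for the
#'   positive (e.g. tumor) and negative (e.g. normal) class.
#' @param signature a `ReoSignature` carrying training rank differences
#'   (needed when `filter_fractions` includes nonzero values).
#' @param n_repeats number of random repeats (default 100).
#' @param seed master seed; per-repeat, per-class plan seeds are derived
#'   from it.
#' @param filter_fractions fractions passed to
#'   [filter_signature_rank_diff()].
#' @param n_groups pseudo-bulk groups per class (default 11).
#' @param sizes_positive,sizes_negative optional explicit group sizes.
#' @param min_evaluated passed to [classify_samples()].
#' @return list with `per_repeat` (data frame: `repeat_index`, `fraction`,
#'   `sensitivity`, `specificity`) and `summary` (data frame: `fraction`,
#'   `n_pairs`, `mean_sensitivity`, `mean_specificity`).
#' @export
repeat_pooling_experiment <- function(positive_cells, negative_cells,
                                      signature, n_repeats = 100L,
                                      seed = 1L,
                                      filter_fractions = c(0, 0.1, 0.2),
                                      n_groups = 11L,
                                      sizes_positive = NULL,
                                      sizes_negative = NULL,
                                      min_evaluated = 1L) {
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  pv <- as_values(positive_cells)
  nv <- as_values(negative_cells)
  sigs <- lapply(filter_fractions, function(x)
    filter_signature_rank_diff(signature, x))
  rows <- vector("list", n_repeats * length(filter_fractions))
  ri <- 0L
  for (r in seq_len(n_repeats)) {
    plan_pos <- make_pooling_plan(ncol(pv), n_groups,
                                  seed = derive_seed(seed, "pool-pos", r),
                                  sizes = sizes_positive)
    plan_neg <- make_pooling_plan(ncol(nv), n_groups,
                                  seed = derive_seed(seed, "pool-neg", r),
                                  sizes = sizes_negative)
    pooled_pos <- pool_sum(pv, plan_pos)
    pooled_neg <- pool_sum(nv, plan_neg)
    for (fi in seq_along(filter_fractions)) {
      sig <- sigs[[fi]]
      lp <- classify_samples(pooled_pos, sig, min_evaluated = min_evaluated)
      ln <- classify_samples(pooled_neg, sig, min_evaluated = min_evaluated)
      truth <- c(rep(sig$positive_class, nrow(lp)),
                 rep(sig$negative_class, nrow(ln)))
      out <- evaluate_classification(c(lp$label, ln$label), truth,
                                     sig$positive_class)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(repeat_index = r,
                               fraction = filter_fractions[fi],
                               sensitivity = out$sensitivity,
                               specificity = out$specificity)
    }
  }
  per_repeat <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(seq_along(filter_fractions),
                                   function(fi) {
    sub <- per_repeat[per_repeat$fraction == filter_fractions[fi], ]
    data.frame(fraction = filter_fractions[fi],
               n_pairs = sigs[[fi]]$k,
               mean_sensitivity = mean(sub$sensitivity),
               mean_specificity = mean(sub$specificity))
  }))
  list(per_repeat = per_repeat, summary = summary)
}
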