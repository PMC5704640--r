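#' Reversal gene pairs between two classes
#'
#' Finds pairs with a stable REO direction within each class (default:
#' identical direction in all samples of each class) but opposite
#' directions between the classes. Each pair carries its class-wise mean
#' absolute rank differences and the reversal degree, the geometric mean
#' of the two — pairs whose genes are far apart in rank in both classes
#' reverse "harder" and make more robust signature candidates.
#'
#' @param class_a,class_b genes x samples matrices over the same gene
#'   universe.
#' @param f,strict within-class stability rule as in
#'   [stable_pairs_frequency()]; the default (`f = 1`, `strict = FALSE`)
#'   is unanimity.
#' @return data frame sorted by descending `degree` (ties broken
#'   lexicographically by gene-id pair): `gene_i`, `gene_j` (canonical
#'   lexicographic order), `direction_a` (+1 when `gene_i` is higher in
#'   class A; class B is the opposite by construction),
#'   `mean_rank_diff_a`, `mean_rank_diff_b`, `degree`.
#' @export
find_reversal_pairs <- function(class_a, class_b, f = 1, strict = FALSE) {
  va <- as_values(class_a); vb <- as_values(class_b)
  if (!setequal(rownames(va), rownames(vb)))
    stop("classes have mismatched gene universes; use intersect_genes",
         call. = FALSE)
  vb <- vb[rownames(va), , drop = FALSE]
  if (f <= 0.5 || f > 1) stop("f must be in (0.5, 1]", call. = FALSE)
  ra <- rank_profile(va)
  rb <- rank_profile(vb)
  res <- cpp_reversal_pairs(ra, rb, f, strict)
  gn <- rownames(va)
  gi <- gn[res$i]; gj <- gn[res$j]; dir_a <- res$direction_a
  swap <- gi > gj
  tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
  dir_a[swap] <- -dir_a[swap]
  out <- data.frame(gene_i = gi, gene_j = gj, direction_a = dir_a,
                    mean_rank_diff_a = res$mean_rank_diff_a,
                    mean_rank_diff_b = res$mean_rank_diff_b,
                    degree = reversal_degree(res$mean_rank_diff_a,
                                             res$mean_rank_diff_b),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene_i, out$gene_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reversal degree of a gene pair
#'
#' Geometric mean of the pair's mean absolute rank differences in the two
#' classes.
#'
#' @param mean_rank_diff_a,mean_rank_diff_b non-negative class-wise mean
#'   absolute rank differences (vectorized).
#' @return non-negative numeric vector.
#' @examples
#' reversal_degree(100, 400)  # 200
#' @export
reversal_degree <- function(mean_rank_diff_a, mean_rank_diff_b) {
  if (any(mean_rank_diff_a < 0) || any(mean_rank_diff_b < 0))
    stop("rank differences must be non-negative", call. = FALSE)
  sqrt(mean_rank_diff_a * mean_rank_diff_b)
}

#' Assemble a majority-vote REO signature
#'
#' Wraps reversal pairs into a classifier: a sample is labelled with the
#' positive class when more than half of its measurable signature pairs
#' match the positive-class REO pattern.
#'
#' @param pairs data frame from [find_reversal_pairs()] (sorted descending
#'   by degree).
#' @param positive_class,negative_class class labels.
#' @param positive which input class of the discovery run is the positive
#'   class, `"a"` or `"b"`.
#' @param k number of top pairs to keep: a positive integer or `"all"`.
#'   During automatic selection ([select_signature()]) k is odd so that
#'   full votes cannot tie.
#' @return a `ReoSignature`: list with `pairs` (columns `gene_i`, `gene_j`,
#'   `direction_positive`, `degree`, `mean_rank_diff_pos`,
#'   `mean_rank_diff_neg`), `positive_class`, `negative_class`, `k`.
#' @export
reo_signature <- function(pairs, positive_class, negative_class,
                          positive = c("a", "b"), k = "all") {
  positive <- match.arg(positive)
  if (nrow(pairs) == 0L) stop("no candidate pairs", call. = FALSE)
  pairs <- pairs[order(-pairs$degree, pairs$gene_i, pairs$gene_j), ,
                 drop = FALSE]
  if (!identical(k, "all")) {
    k <- as.integer(k)
    if (is.na(k) || k < 1L || k > nrow(pairs))
      stop("k must be 'all' or an integer in [1, number of pairs]",
           call. = FALSE)
    pairs <- pairs[seq_len(k), , drop = FALSE]
  }
  flip <- if (positive == "a") 1L else -1L
  sig_pairs <- data.frame(
    gene_i = pairs$gene_i, gene_j = pairs$gene_j,
    direction_positive = flip * pairs$direction_a,
    degree = pairs$degree,
    mean_rank_diff_pos = if (positive == "a") pairs$mean_rank_diff_a
                         else pairs$mean_rank_diff_b,
    mean_rank_diff_neg = if (positive == "a") pairs$mean_rank_diff_b
                         else pairs$mean_rank_diff_a,
    stringsAsFactors = FALSE)
  rownames(sig_pairs) <- NULL
  structure(list(pairs = sig_pairs, positive_class = positive_class,
                 negative_class = negative_class, k = nrow(sig_pairs)),
            class = "ReoSignature")
}

#' @export
print.ReoSignature <- function(x, ...) {
  cat(sprintf("ReoSignature: %d pair(s), positive class '%s' vs '%s'\n",
              x$k, x$positive_class, x$negative_class))
  print(head(x$pairs, 5L))
  if (x$k > 5L) cat("...\n")
  invisible(x)
}

#' Select the smallest best top-k signature
#'
#' Walks k = 1, 3, 5, ... up to `k_max` over the degree-sorted candidates,
#' classifies the training samples by majority vote at each k, and returns
#' the signature with the smallest k achieving the highest geometric mean
#' of sensitivity and specificity. The full k-path is attached for
#' inspection.
#'
#' @param candidates data frame from [find_reversal_pairs()].
#' @param train_pos,train_neg training matrices for the positive and
#'   negative class.
#' @inheritParams reo_signature
#' @param k_max largest (odd) k to evaluate; default: the largest odd
#'   number not exceeding `min(nrow(candidates), 25)`.
#' @return a `ReoSignature` with an extra element `k_path`
#'   (data frame: `k`, `sensitivity`, `specificity`, `gmean`).
#' @export
select_signature <- function(candidates, train_pos, train_neg,
                             positive_class = "positive",
                             negative_class = "negative",
                             positive = c("a", "b"), k_max = NULL) {
  positive <- match.arg(positive)
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("no candidate reversal pairs", call. = FALSE)
  k_max <- k_max %||% min(nrow(candidates), 25L)
  k_max <- min(k_max, nrow(candidates))
  if (k_max %% 2L == 0L) k_max <- k_max - 1L
  ks <- seq(1L, k_max, by = 2L)
  path <- lapply(ks, function(k) {
    sig <- reo_signature(candidates, positive_class, negative_class,
                         positive = positive, k = k)
    lp <- classify_samples(train_pos, sig)
    ln <- classify_samples(train_neg, sig)
    truth <- c(rep(positive_class, nrow(lp)), rep(negative_class, nrow(ln)))
    out <- evaluate_classification(c(lp$label, ln$label), truth,
                                   positive_class)
    data.frame(k = k, sensitivity = out$sensitivity,
               specificity = out$specificity,
               gmean = sqrt(out$sensitivity * out$specificity))
  })
  path <- do.call(rbind, path)
  best <- max(path$gmean)
  k_star <- path$k[which(path$gmean >= best - 1e-12)[1L]]
  sig <- reo_signature(candidates, positive_class, negative_class,
                       positive = positive, k = k_star)
  sig$k_path <- path
  sig
}

#' Classify samples by majority vote over signature pairs
#'
#' For each sample, every signature pair whose two genes are measured and
#' not tied (two zeros are a tie — dropout must not fabricate votes) casts
#' a vote for the positive class when the sample's strict ordering matches
#' the positive-class pattern. A sample is labelled positive when the
#' positive votes exceed half of the evaluated votes, negative when they
#' fall short, and `"unclassified"` on an exact split (counted as wrong by
#' [evaluate_classification()]). Pairs with a gene absent from the matrix
#' are dropped from the vote.
#'
#' @param x genes x samples matrix.
#' @param signature a `ReoSignature`.
#' @param min_evaluated minimum measurable pairs per sample; a sample
#'   below it is an error (the sample cannot be voted on).
#' @return data frame: `sample_id`, `votes_positive`, `votes_evaluated`,
#'   `label`.
#' @export
classify_samples <- function(x, signature, min_evaluated = 1L) {
  stopifnot(inherits(signature, "ReoSignature"))
  v <- as_values(x)
  p <- signature$pairs
  xi <- v[match(p$gene_i, rownames(v)), , drop = FALSE]
  xj <- v[match(p$gene_j, rownames(v)), , drop = FALSE]
  sgn <- sign(xi - xj)                       # pairs x samples, NA if absent
  measurable <- !is.na(sgn) & sgn != 0
  agree <- sgn == p$direction_positive       # recycles down columns
  votes_pos <- colSums(measurable & !is.na(agree) & agree)
  evaluated <- colSums(measurable)
  short <- evaluated < min_evaluated
  if (any(short))
    stop_sprintf("sample(s) with fewer than %d measurable pairs: %s",
                 min_evaluated,
                 paste(head(colnames(v)[short], 5L), collapse = ", "))
  label <- ifelse(2 * votes_pos > evaluated, signature$positive_class,
                  ifelse(2 * votes_pos < evaluated,
                         signature$negative_class, "unclassified"))
  data.frame(sample_id = colnames(v), votes_positive = votes_pos,
             votes_evaluated = evaluated, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sensitivity and specificity of predicted labels
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP). Any label
#' other than the true class (including `"unclassified"`) is wrong for
#' that class.
#'
#' @param labels predicted labels.
#' @param truth true labels, aligned with `labels`; labels not equal to
#'   `positive_class` are treated as the negative class.
#' @param positive_class label of the positive class.
#' @return a `ClassificationOutcome` list: `TP`, `TN`, `FP`, `FN`,
#'   `sensitivity`, `specificity` (`NA` with a warning when a class is
#'   absent).
#' @export
evaluate_classification <- function(labels, truth, positive_class) {
  if (length(labels) != length(truth))
    stop("labels and truth must be aligned", call. = FALSE)
  is_pos <- truth == positive_class
  TP <- sum(is_pos & labels == positive_class)
  FN <- sum(is_pos & labels != positive_class)
  FP <- sum(!is_pos & labels == positive_class)
  TN <- sum(!is_pos & labels != positive_class)
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  if (is.na(sens)) warning("no positive samples; sensitivity undefined")
  if (is.na(spec)) warning("no negative samples; specificity undefined")
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 sensitivity = sens, specificity = spec),
            class = "ClassificationOutcome")
}

#' @export
print.ClassificationOutcome <- function(x, ...) {
  cat(sprintf(
    "ClassificationOutcome: TP=%d TN=%d FP=%d FN=%d | sens=%.4f spec=%.4f\n",
    x$TP, x$TN, x$FP, x$FN, x$sensitivity, x$specificity))
  invisible(x)
}

#' Filter signature pairs by training rank differences
#'
#' Removes the union of the `floor(fraction * n)` pairs with the smallest
#' mean absolute rank difference in the positive-class training samples
#' and the corresponding bottom set for the negative class (ties broken
#' lexicographically). Close-ranked pairs vote unreliably in noisy,
#' high-dropout profiles; pruning them trades votes for vote quality.
#'
#' @param signature a `ReoSignature` whose pairs carry the training mean
#'   rank differences.
#' @param fraction fraction in \[0, 1) to remove per class.
#' @return the filtered `ReoSignature` (pair order preserved).
#' @export
filter_signature_rank_diff <- function(signature, fraction) {
  stopifnot(inherits(signature, "ReoSignature"))
  if (fraction < 0 || fraction >= 1)
    stop("fraction must be in [0, 1)", call. = FALSE)
  if (fraction == 0) return(signature)
  p <- signature$pairs
  if (anyNA(p$mean_rank_diff_pos) || anyNA(p$mean_rank_diff_neg))
    stop("signature lacks training rank differences; cannot filter",
         call. = FALSE)
  drop_n <- floor(fraction * nrow(p))
  bottom <- function(d) {
    ord <- order(d, p$gene_i, p$gene_j)
    ord[seq_len(drop_n)]
  }
  drop_idx <- if (drop_n > 0)
    union(bottom(p$mean_rank_diff_pos), bottom(p$mean_rank_diff_neg))
  else integer(0)
  keep <- setdiff(seq_len(nrow(p)), drop_idx)
  if (length(keep) == 0L)
    stop("filtering removed every pair; choose a smaller fraction",
         call. = FALSE)
  signature$pairs <- p[keep, , drop = FALSE]
  rownames(signature$pairs) <- NULL
  signature$k <- length(keep)
  signature
}

#' Read and write signature files
#'
#' The on-disk signature format is a tab-separated table with columns
#' `gene_i`, `gene_j`, `direction_positive`, `degree`,
#' `mean_rank_diff_pos`, `mean_rank_diff_neg`, preceded by comment lines
#' `# positive_class: ...` and `# negative_class: ...`.
#'
#' @param signature a `ReoSignature`.
#' @param path file path.
#' @return `read_signature_file()` returns a `ReoSignature`;
#'   `write_signature_file()` returns `path` invisibly.
#' @export
write_signature_file <- function(signature, path) {
  stopifnot(inherits(signature, "ReoSignature"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# positive_class: %s", signature$positive_class),
               sprintf("# negative_class: %s", signature$negative_class)),
             con)
  write.table(signature$pairs, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_file
#' @export
read_signature_file <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit) == 0L) stop_sprintf("signature file lacks '%s'", key)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1L]))
  }
  pairs <- read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  required <- c("gene_i", "gene_j", "direction_positive")
  if (!all(required %in% colnames(pairs)))
    stop("signature file must contain gene_i, gene_j, direction_positive",
         call. = FALSE)
  for (col in c("degree", "mean_rank_diff_pos", "mean_rank_diff_neg"))
    if (!col %in% colnames(pairs)) pairs[[col]] <- NA_real_
  structure(list(pairs = pairs[, c("gene_i", "gene_j",
                                   "direction_positive", "degree",
                                   "mean_rank_diff_pos",
                                   "mean_rank_diff_neg")],
                 positive_class = get_field("positive_class"),
                 negative_class = get_field("negative_class"),
                 k = nrow(pairs)),
            class = "ReoSignature")
}
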