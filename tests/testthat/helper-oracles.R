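# Independent brute-force oracles: plain double loops over all gene
# pairs, written against the definitions only and kept free of any code
# shared with the production implementation.

oracle_direction <- function(vals, i, j, f, strict) {
  S <- ncol(vals)
  hi <- sum(vals[i, ] > vals[j, ])
  lo <- sum(vals[i, ] < vals[j, ])
  ok <- function(cnt) if (strict) cnt / S > f else cnt / S >= f
  if (ok(hi)) return(1L)
  if (ok(lo)) return(-1L)
  0L
}

# All stable pairs of a genes x samples value matrix, canonical
# lexicographic gene order, sorted by (gene_i, gene_j).
oracle_stable_pairs <- function(vals, f = 1, strict = FALSE) {
  gn <- rownames(vals)
  G <- nrow(vals)
  rows <- list()
  for (i in seq_len(G - 1)) {
    for (j in seq(i + 1, G)) {
      d <- oracle_direction(vals, i, j, f, strict)
      if (d == 0L) next
      gi <- gn[i]; gj <- gn[j]
      if (gi > gj) { tmp <- gi; gi <- gj; gj <- tmp; d <- -d }
      rows[[length(rows) + 1L]] <-
        data.frame(gene_i = gi, gene_j = gj, direction = d,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene_i = character(), gene_j = character(),
                      direction = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_i, out$gene_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# k and n of a query profile against an explicit pair table.
oracle_consistency <- function(pairs, query, tie_policy = "discordant") {
  n <- 0L; k <- 0L
  for (r in seq_len(nrow(pairs))) {
    qi <- query[[pairs$gene_i[r]]]
    qj <- query[[pairs$gene_j[r]]]
    s <- sign(qi - qj)
    if (s == 0) {
      if (tie_policy == "discordant") n <- n + 1L
      next
    }
    n <- n + 1L
    if (s == pairs$direction[r]) k <- k + 1L
  }
  list(n = n, k = k)
}

# Reversal pairs between two classes by exhaustive enumeration.
oracle_reversal_pairs <- function(a, b, f = 1, strict = FALSE) {
  gn <- rownames(a)
  G <- nrow(a)
  ra <- apply(a, 2, rank)
  rb <- apply(b, 2, rank)
  rows <- list()
  for (i in seq_len(G - 1)) {
    for (j in seq(i + 1, G)) {
      da <- oracle_direction(a, i, j, f, strict)
      if (da == 0L) next
      db <- oracle_direction(b, i, j, f, strict)
      if (db != -da) next
      gi <- gn[i]; gj <- gn[j]; d <- da
      if (gi > gj) { tmp <- gi; gi <- gj; gj <- tmp; d <- -d }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_i = gi, gene_j = gj, direction_a = d,
        mean_rank_diff_a = mean(abs(ra[i, ] - ra[j, ])),
        mean_rank_diff_b = mean(abs(rb[i, ] - rb[j, ])),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene_i = character(), gene_j = character(),
                      direction_a = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_i, out$gene_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random expression matrix with distinct values (tie-free w.h.p.).
random_expr <- function(G, S, seed, prefix = "g") {
  set.seed(seed)
  m <- matrix(rlnorm(G * S, meanlog = 2, sdlog = 1), G, S)
  dimnames(m) <- list(sprintf("%s%03d", prefix, seq_len(G)),
                      sprintf("s%02d", seq_len(S)))
  m
}

# A random strictly increasing transform on [0, Inf).
random_monotone <- function(seed) {
  set.seed(seed)
  c1 <- runif(1, 0.1, 3); c2 <- runif(1, 0.01, 1); c3 <- runif(1, 0.1, 2)
  function(x) c1 * x + c2 * x^1.5 + c3 * log1p(x)
}

pair_key <- function(d) paste(d$gene_i, d$gene_j)
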