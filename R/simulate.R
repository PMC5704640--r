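#' Configuration for the synthetic-data generators
#'
#' Describes a dilution-ladder experiment (a high-input reference profiled
#' in technical replicates, plus serially diluted low-input levels with
#' stronger multiplicative noise and more expression-dependent dropout as
#' input mass falls), a two-class cohort with planted reversal gene pairs,
#' and high-dropout single cells.
#'
#' Defaults mirror a two-replicate, four-level dilution ladder
#' (1000/100/50/25 pg) with a noise schedule calibrated so the proportion
#' of genes at symmetric fold change >= 2 spans roughly 0.1-0.65 across
#' the ladder, and a two-class design of 2,000 genes with 50 planted
#' reversal pairs at rank separation 200 and ~90% single-cell dropout.
#'
#' @param n_genes number of genes (>= 10).
#' @param n_samples_per_class cohort size per class for the two-class
#'   design.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   true expression levels.
#' @param dilution_levels data frame with columns `input_mass_pg`,
#'   `noise_sigma` (sd of the multiplicative log-normal noise, log scale)
#'   and `dropout_base` (dropout probability scale); noise and dropout
#'   must be non-decreasing as input mass decreases.
#' @param n_technical_replicates technical replicates per level.
#' @param high_input_sigma noise sd of the high-input replicates (an order
#'   of magnitude below any dilution sigma).
#' @param cohort_sigma per-sample noise sd of the two-class cohorts.
#' @param n_reversal_pairs,rank_separation planted reversal pairs and
#'   their guaranteed within-class rank separation.
#' @param sc_dropout_target expected per-cell zero fraction of simulated
#'   single cells (in \[0, 1)).
#' @param sc_noise_sigma per-cell multiplicative noise sd.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_samples_per_class = 20L,
                              baseline_meanlog = 3,
                              baseline_sdlog = 1.5,
                              dilution_levels = data.frame(
                                input_mass_pg = c(1000, 100, 50, 25),
                                noise_sigma = c(0.65, 1.1, 1.5, 1.9),
                                dropout_base = c(0.02, 0.08, 0.15, 0.25)),
                              n_technical_replicates = 2L,
                              high_input_sigma = 0.05,
                              cohort_sigma = 0.05,
                              n_reversal_pairs = 50L,
                              rank_separation = 200L,
                              sc_dropout_target = 0.9,
                              sc_noise_sigma = 0.3) {
  if (n_genes < 10L) stop("n_genes must be >= 10", call. = FALSE)
  if (baseline_sdlog <= 0) stop("baseline_sdlog must be > 0", call. = FALSE)
  dl <- dilution_levels[order(-dilution_levels$input_mass_pg), ,
                        drop = FALSE]
  if (any(diff(dl$noise_sigma) < 0))
    stop("noise_sigma must be non-decreasing as input mass decreases",
         call. = FALSE)
  if (any(diff(dl$dropout_base) < 0))
    stop("dropout_base must be non-decreasing as input mass decreases",
         call. = FALSE)
  if (any(dl$dropout_base < 0 | dl$dropout_base > 1))
    stop("dropout_base must lie in [0, 1]", call. = FALSE)
  if (sc_dropout_target < 0 || sc_dropout_target >= 1)
    stop("sc_dropout_target must lie in [0, 1)", call. = FALSE)
  if (nrow(dl) > 0 && high_input_sigma > min(dl$noise_sigma))
    stop("high_input_sigma must not exceed any dilution noise_sigma",
         call. = FALSE)
  if (2L * n_reversal_pairs > n_genes)
    stop("too many reversal pairs for n_genes", call. = FALSE)
  if (rank_separation >= n_genes)
    stop("rank_separation infeasible for n_genes", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_class = as.integer(n_samples_per_class),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dilution_levels = dl,
                 n_technical_replicates = as.integer(n_technical_replicates),
                 high_input_sigma = high_input_sigma,
                 cohort_sigma = cohort_sigma,
                 n_reversal_pairs = as.integer(n_reversal_pairs),
                 rank_separation = as.integer(rank_separation),
                 sc_dropout_target = sc_dropout_target,
                 sc_noise_sigma = sc_noise_sigma),
            class = "SimulationConfig")
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

# Expression-dependent dropout weight: linear in rank, weight 1 for the
# lowest-expressed gene, 0 for the highest (lowly expressed genes drop
# out more, the dominant failure mode of amplified low-input material).
dropout_weight <- function(truth) {
  G <- length(truth)
  (G - rank(truth, ties.method = "average")) / (G - 1)
}

#' Simulate a high-input reference profile
#'
#' Draws true per-gene expression levels from the configured log-normal
#' and profiles them in `n_technical_replicates` with small multiplicative
#' log-normal noise (`high_input_sigma`).
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `truth` (named numeric vector) and `matrix`
#'   (genes x replicates).
#' @export
simulate_high_input <- function(config, seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(seed, {
    G <- config$n_genes
    truth <- rlnorm(G, config$baseline_meanlog, config$baseline_sdlog)
    names(truth) <- gene_ids(G)
    reps <- vapply(seq_len(config$n_technical_replicates), function(r)
      truth * exp(rnorm(G, 0, config$high_input_sigma)), numeric(G))
    if (is.null(dim(reps))) reps <- matrix(reps, nrow = G)
    dimnames(reps) <- list(names(truth),
                           paste0("high_rep",
                                  seq_len(config$n_technical_replicates)))
    list(truth = truth, matrix = reps)
  })
}

#' Simulate low-input replicates of a profile
#'
#' Each replicate is the truth distorted by multiplicative log-normal
#' noise of sd `noise_sigma`, followed by expression-dependent dropout:
#' a gene is zeroed with probability `dropout_base * w`, where the weight
#' w falls linearly with the gene's expression rank from 1 (lowest) to 0
#' (highest).
#'
#' @param truth named numeric vector of true expression levels.
#' @param noise_sigma sd of the log-scale noise.
#' @param dropout_base dropout probability scale in \[0, 1\].
#' @param n_replicates technical replicates to draw (independent).
#' @param seed integer seed.
#' @return genes x replicates matrix.
#' @export
simulate_low_input <- function(truth, noise_sigma, dropout_base,
                               n_replicates = 2L, seed = NULL) {
  if (dropout_base < 0 || dropout_base > 1)
    stop("dropout_base must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    G <- length(truth)
    p_drop <- dropout_base * dropout_weight(truth)
    reps <- vapply(seq_len(n_replicates), function(r) {
      v <- truth * exp(rnorm(G, 0, noise_sigma))
      v[runif(G) < p_drop] <- 0
      v
    }, numeric(G))
    if (is.null(dim(reps))) reps <- matrix(reps, nrow = G)
    dimnames(reps) <- list(names(truth),
                           paste0("low_rep", seq_len(n_replicates)))
    reps
  })
}

#' Simulate a two-class cohort with planted reversal gene pairs
#'
#' Class B shares class A's generative truth except that the two genes of
#' each planted pair swap their levels, which guarantees opposite strict
#' orderings between the classes at the configured rank separation. Note
#' that the swap also reverses every pair formed by a planted gene and a
#' gene ranked between the swapped levels, so discovery on this design
#' returns a superset of the planted list in which the planted pairs carry
#' the largest reversal degrees.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @param n_samples samples per class (default
#'   `config$n_samples_per_class`); request extra columns and split them
#'   to obtain training and held-out cohorts from one consistent truth.
#' @return list with `class_a`, `class_b` (genes x samples matrices),
#'   `truth_a`, `truth_b`, and `planted` (data frame `gene_i`, `gene_j`,
#'   `direction_a`, canonical lexicographic pair order).
#' @export
simulate_two_class <- function(config, seed = NULL, n_samples = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  n_samples <- n_samples %||% config$n_samples_per_class
  with_seed(seed, {
    G <- config$n_genes
    sep <- config$rank_separation
    npairs <- config$n_reversal_pairs
    truth_a <- rlnorm(G, config$baseline_meanlog, config$baseline_sdlog)
    names(truth_a) <- gene_ids(G)
    ord <- order(truth_a)              # ascending positions
    low_pos <- integer(0)
    if (npairs > 0L) {
      for (attempt in seq_len(10000L)) {
        low_pos <- sort(sample.int(G - sep, npairs))
        if (!any((low_pos + sep) %in% low_pos)) break
        low_pos <- integer(0)
      }
      if (length(low_pos) == 0L)
        stop("could not place non-overlapping planted pairs; reduce",
             " n_reversal_pairs or rank_separation", call. = FALSE)
    }
    g_low <- names(truth_a)[ord[low_pos]]
    g_high <- names(truth_a)[ord[low_pos + sep]]
    truth_b <- truth_a
    truth_b[g_low] <- truth_a[g_high]
    truth_b[g_high] <- truth_a[g_low]
    gi <- pmin(g_low, g_high)
    gj <- pmax(g_low, g_high)
    planted <- data.frame(
      gene_i = gi, gene_j = gj,
      direction_a = ifelse(truth_a[gi] > truth_a[gj], 1L, -1L),
      stringsAsFactors = FALSE)
    planted <- planted[order(planted$gene_i, planted$gene_j), ]
    rownames(planted) <- NULL
    draw <- function(truth, prefix) {
      m <- vapply(seq_len(n_samples), function(s)
        truth * exp(rnorm(G, 0, config$cohort_sigma)), numeric(G))
      if (is.null(dim(m))) m <- matrix(m, nrow = G)
      dimnames(m) <- list(names(truth),
                          sprintf("%s_s%02d", prefix, seq_len(n_samples)))
      m
    }
    list(class_a = draw(truth_a, "A"), class_b = draw(truth_b, "B"),
         truth_a = truth_a, truth_b = truth_b, planted = planted)
  })
}

#' Simulate single cells with heavy expression-dependent dropout
#'
#' Each cell is the bulk truth under per-cell multiplicative log-normal
#' noise, then independently zeroed per gene with probability
#' `min(0.995, c * w)`, where w is the linear rank weight of
#' [simulate_low_input()] and c is calibrated so the expected per-cell
#' zero fraction equals `dropout_target`.
#'
#' @param truth named numeric vector of bulk true levels for the class.
#' @param n_cells number of cells.
#' @param dropout_target expected per-cell zero fraction in \[0, 1);
#'   must be below the 0.995 per-gene cap times the achievable mean.
#' @param noise_sigma per-cell log-scale noise sd.
#' @param seed integer seed.
#' @return genes x cells matrix (columns `cell0001`, ...).
#' @export
simulate_single_cells <- function(truth, n_cells, dropout_target = 0.9,
                                  noise_sigma = 0.3, seed = NULL) {
  if (dropout_target < 0 || dropout_target >= 1)
    stop("dropout_target must lie in [0, 1)", call. = FALSE)
  G <- length(truth)
  w <- dropout_weight(truth)
  if (dropout_target == 0) {
    p_drop <- rep(0, G)
  } else {
    cap <- 0.995
    if (dropout_target >= cap)
      stop("dropout_target must be below the per-gene cap 0.995",
           call. = FALSE)
    cc <- uniroot(function(c) mean(pmin(cap, c * w)) - dropout_target,
                  interval = c(1e-8, 1e8), tol = 1e-10)$root
    p_drop <- pmin(cap, cc * w)
  }
  with_seed(seed, {
    cells <- vapply(seq_len(n_cells), function(i) {
      v <- truth * exp(rnorm(G, 0, noise_sigma))
      v[runif(G) < p_drop] <- 0
      v
    }, numeric(G))
    if (is.null(dim(cells))) cells <- matrix(cells, nrow = G)
    dimnames(cells) <- list(names(truth),
                            sprintf("cell%04d", seq_len(n_cells)))
    cells
  })
}
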