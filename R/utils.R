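# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. seed = NULL runs unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed from a master seed and a stage label,
# kept well inside 32-bit integer range.
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 131 + index) %% 2147483587L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce an ExpressionMatrix or plain numeric matrix to a numeric matrix
# with gene rownames and sample colnames.
as_values <- function(x, arg = deparse(substitute(x))) {
  if (inherits(x, "ExpressionMatrix")) x <- unclass_em(x)
  if (is.numeric(x) && is.null(dim(x))) {
    if (is.null(names(x))) stop(arg, " must carry gene names", call. = FALSE)
    x <- matrix(x, ncol = 1L, dimnames = list(names(x), "sample"))
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop(arg, " must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(x)))
    stop(arg, " must have gene identifiers as rownames", call. = FALSE)
  x
}

stop_sprintf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
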