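# Internal helpers.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive n reproducible child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# One Dirichlet draw with concentration vector `alpha` (gamma construction).
# Entries with alpha == 0 stay exactly zero.
rdirichlet1 <- function(alpha) {
  x <- numeric(length(alpha))
  pos <- alpha > 0
  g <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  if (all(g == 0)) g[sample.int(length(g), 1L)] <- 1   # guard vs underflow
  x[pos] <- g / sum(g)
  x
}

# Zero the diagonal of a square matrix and renormalize rows to sum 1.
# Rows that are all zero after masking raise an error if `strict`.
zero_diag_renorm <- function(m, strict = TRUE) {
  diag(m) <- 0
  rs <- rowSums(m)
  if (strict && any(rs <= 0)) {
    stop("degenerate transition matrix: row(s) ",
         paste(rownames(m)[rs <= 0], collapse = ", "),
         " have no off-diagonal mass", call. = FALSE)
  }
  rs[rs <= 0] <- 1
  sweep(m, 1L, rs, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
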