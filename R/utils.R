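# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never clobbers user RNG.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# Maximum-likelihood covariance (1/n denominator), samples in rows.
covML <- function(X) {
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  crossprod(Xc) / n
}

# log-determinant of a symmetric positive-definite matrix via Cholesky.
logDetPd <- function(S, context = "covariance") {
  ch <- tryCatch(chol(S), error = function(e) {
    stop("degenerate ", context, " matrix (not positive definite)",
         call. = FALSE)
  })
  2 * sum(log(diag(ch)))
}

invPd <- function(S, context = "covariance") {
  ch <- tryCatch(chol(S), error = function(e) {
    stop("degenerate ", context, " matrix (not positive definite)",
         call. = FALSE)
  })
  chol2inv(ch)
}

# Full-precision decimal rendering of doubles: %.17g guarantees exact
# read-back of IEEE doubles from decimal text.
fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# Deterministic label-permutation matrix (nPerm rows, each a permutation of
# 1..n). All permutation tests that must share a stream draw from this.
makePerms <- function(n, nPerm, seed) {
  withSeed(seed, {
    t(vapply(seq_len(nPerm), function(i) sample.int(n), integer(n)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# join / split for provenance sets serialized as ";"-separated strings
provJoin <- function(x) paste(sort(unique(x)), collapse = ";")
provUnion <- function(a, b) provJoin(c(strsplit(a, ";", fixed = TRUE)[[1]],
                                       strsplit(b, ";", fixed = TRUE)[[1]]))

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
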