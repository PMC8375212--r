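#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up in magnitude), used for every
#' reported percentage so that printed rates are reproducible regardless of
#' the IEEE round-half-even behaviour of [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Stable 31-bit string hash (polynomial, mod the Mersenne prime 2^31-1);
# used to derive deterministic per-location sub-seeds.
str_hash <- function(s, seed = 0L) {
  v <- utf8ToInt(s)
  h <- as.numeric(seed) %% 2147483647
  for (ch in v) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Merge a set of [c0, c1] intervals (two-column data.frame) into a minimal
# disjoint set; touching intervals are coalesced. Zero-width intervals are
# kept unless absorbed by a wider one.
merge_intervals <- function(iv, tol = 1e-9) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv$c0, iv$c1), , drop = FALSE]
  out_c0 <- iv$c0[1]
  out_c1 <- iv$c1[1]
  k <- 1L
  if (nrow(iv) > 1L) {
    for (i in 2:nrow(iv)) {
      if (iv$c0[i] <= out_c1[k] + tol) {
        out_c1[k] <- max(out_c1[k], iv$c1[i])
      } else {
        k <- k + 1L
        out_c0[k] <- iv$c0[i]
        out_c1[k] <- iv$c1[i]
      }
    }
  }
  data.frame(c0 = out_c0, c1 = out_c1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_streetaudit <- function(msg, class) {
  stop(structure(class = c(class, "streetaudit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
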