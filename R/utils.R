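# Internal helpers shared across modules.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package functions never perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Number of forest (==1) neighbours of every pixel, under 4- or
# 8-connectivity, computed with padded shifts (vectorized).
neighbour_count <- function(values, connectivity = 8) {
  f <- !is.na(values) & values == 1L
  nr <- nrow(f)
  nc <- ncol(f)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- f
  shifts4 <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  shifts8 <- c(shifts4, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  shifts <- if (connectivity == 8) shifts8 else shifts4
  out <- matrix(0L, nr, nc)
  for (s in shifts) {
    out <- out + pad[(2L + s[1]):(nr + 1L + s[1]), (2L + s[2]):(nc + 1L + s[2])]
  }
  out
}

check_connectivity <- function(connectivity) {
  if (!connectivity %in% c(4, 8)) {
    abort("`connectivity` must be 4 or 8.")
  }
  as.integer(connectivity)
}

# seed for the i-th stochastic stage, derived so that inserting a stage does
# not shift the streams of unrelated stages
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 99991 * as.numeric(index)) %% 2147483647)
}
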