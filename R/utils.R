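#' Derive a per-stage child seed from a master seed
#'
#' Deterministic scheme used by [runPipeline()] and the standalone stage
#' functions so that adding a stage never perturbs another stage's random
#' stream: `child = (master * 48271 + hash(stage)) mod (2^31 - 1)`, with
#' `hash` a fixed polynomial over the stage name's bytes.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return integer in [1, 2^31 - 1].
#' @export
childSeed <- function(master, stage) {
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  as.integer((as.numeric(master) %% 2147483647 * 48271 + h) %% 2147483647 + 1) - 1L
}

# empirical inclusive (type-7) quantile, recorded once here
.quant <- function(x, p) as.numeric(stats::quantile(x, p, type = 7, names = FALSE))

.lowerTri <- function(m) m[lower.tri(m)]

# validate a distance object/matrix and return the full symmetric matrix
.asDistanceMatrix <- function(d, what = "distance matrix") {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop(what, " must be square")
  if (max(abs(m - t(m))) > 1e-12) stop(what, " must be symmetric")
  if (any(diag(m) != 0)) stop(what, " must have a zero diagonal")
  if (any(m < 0)) stop(what, " must be non-negative")
  m
}
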