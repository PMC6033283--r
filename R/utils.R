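# Internal helpers shared across modules.

# Geometric mean; a set containing any zero has geometric mean 0 (this is the
# QC error path, deliberately not hidden behind pseudocounts).
geomean <- function(x) {
  if (any(x < 0)) stop("geometric mean undefined for negative values")
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

STRATA <- c("ER+RT+", "ER+RT-", "ER-RT+", "ER-RT-")

stratum_of <- function(er_status, rt) {
  paste0(ifelse(er_status == "pos", "ER+", "ER-"), ifelse(rt, "RT+", "RT-"))
}
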