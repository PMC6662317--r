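# Deterministic positive-integer seed for a named RNG stream. Each
# (landscape, index, subgroup) combination gets its own stream derived from
# the master seed, so adding a subgroup or index never perturbs the draws of
# another. Polynomial string hash mod (2^31 - 1), kept inside R's integer
# range.
stream_seed <- function(master, ...) {
  key <- paste(c(...), collapse = "\r")
  m <- 2147483647
  h <- as.double(master) %% m
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% m
  as.integer(h)
}

# Quadratic form p' D p with names aligned; D symmetric, zero diagonal.
quad_form <- function(d, p) {
  as.numeric(crossprod(p, d %*% p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
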