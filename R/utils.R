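# Small shared helpers.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. All stochastic package code funnels through this, which is what makes
# the simulator and the training loops bit-reproducible.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Stable content hash used for provenance stamps in sidecars/manifests.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

msg_log <- function(...) message("[lightmyo] ", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
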