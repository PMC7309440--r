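# evaluate code under a temporary RNG state so seeded helpers do not
# clobber the caller's random stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# xgboost's text dump dislikes spaces/punctuation in feature names; map the
# human-readable names to safe tokens and remember the originals
sanitize_names <- function(nms) {
  safe <- gsub("[^A-Za-z0-9]+", "_", nms)
  safe <- make.unique(safe, sep = "_")
  stats::setNames(nms, safe)
}
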