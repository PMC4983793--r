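# internal helpers

# Run `expr` under a fixed RNG seed and restore the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Euclidean distance of every pixel centre of an nr x nc frame from (row, col).
centreDistance <- function(nr, nc, row, col) {
  sqrt(outer((seq_len(nr) - row)^2, (seq_len(nc) - col)^2, "+"))
}

# Stable short hash of an R object (used for provenance stamping).
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::serializeJSON(x), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
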