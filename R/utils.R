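## Internal helpers.

## Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  rs <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (!is.null(rs)) assign(".Random.seed", rs, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Stars matching the usual convention: *** < 0.001, ** < 0.01, * < 0.05.
.pStars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
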