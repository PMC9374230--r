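# internal helpers shared across modules

# "  poa   ANNUA " -> "Poa annua"; matching is exact after this normalisation
normalizeSpeciesNames <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  x <- tolower(x)
  substr(x, 1, 1) <- toupper(substr(x, 1, 1))
  x
}

# round-half-up at d decimals (base round() is round-half-even)
roundHalfUp <- function(x, d = 2) {
  s <- sign(x)
  s * floor(abs(x) * 10^d + 0.5) / 10^d
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive independent sub-stream seeds from one run seed (kept < 2^31)
deriveSeed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

stopWithClass <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
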