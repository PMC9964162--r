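## 20 canonical residues, fixed order used by every emission vector
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GROUP_LEVELS <- c("plant", "bacteria", "fungi", "insect", "unknown")

## run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## stable 31-bit seed derived from a base seed and a stage label
derive_seed <- function(seed, label) {
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

## round half away from zero to `digits` decimals (reporting convention;
## base round() is banker's)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
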