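# Internal helpers: stable hashing for seed derivation, pair keys.

# Deterministic 31-bit string hash (polynomial rolling hash). Used to derive
# per-stage / per-(subsample, target) RNG seeds from names rather than
# positions, so results are invariant to row and column order.
.hash_string <- function(s) {
  ints <- utf8ToInt(s)
  h <- 0
  for (i in ints) h <- (h * 31 + i) %% 2147483629
  as.integer(h)
}

# Derive a child seed from a base seed and a path of labels.
derive_seed <- function(seed, ...) {
  path <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                collapse = "/")
  .hash_string(path)
}

# Canonical unordered-pair key: sorted names joined by "|".
pair_key <- function(a, b) {
  as.character(ifelse(a < b, paste(a, b, sep = "|"),
                      paste(b, a, sep = "|")))
}

split_pair_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(var1 = vapply(parts, `[`, "", 1L),
             var2 = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
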