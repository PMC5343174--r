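# Seed hygiene: run seeded code without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Small deterministic polynomial string hash (31-adic, mod 2^31 - 1), used to
# derive per-taxon RNG seeds that do not depend on taxon processing order.
.str_hash <- function(x) {
  h <- 0
  for (cp in utf8ToInt(x)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}
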