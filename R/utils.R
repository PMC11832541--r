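# Shared internal helpers.

# round() in R rounds half to even; proportional-threshold edge quotas use
# round-half-away-from-zero to match the common connectivity-toolbox behaviour.
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Derive a child RNG seed from a user seed and a small offset, staying inside
# the 32-bit integer range set.seed() accepts.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %%
               2147483647L)
}

stop_if_not_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < min) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
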