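`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic per-label RNG stream seed derived from a master seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
stream_seed <- function(master, ...) {
  labs <- paste(c(...), collapse = "\r")
  h <- (as.numeric(master) %% 2147483647) * 48271 %% 2147483647
  for (v in utf8ToInt(labs)) h <- (h * 31 + v) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

sorted_unique <- function(x) sort(unique(as.character(x)))

# sample() without the length-1 numeric expansion surprise
resample <- function(x, size) x[sample.int(length(x), size)]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
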