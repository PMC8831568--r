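# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# md5 of an R object via its serialization; used for content-addressed caching
.object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

# derive a reproducible child seed (kept well below .Machine$integer.max)
.child_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed)
  for (k in ks) s <- (s * 69069 + k) %% 2147483562
  as.integer(s) + 1L
}
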