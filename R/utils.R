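# Internal helpers shared across modules.

# Strip a BiGG-style compartment suffix ("_c", "_e", "_p", ...) from a
# metabolite id. Returns the id unchanged when no suffix is recognisable.
met_base_id <- function(id) {
  sub("_[a-zA-Z0-9]{1,2}$", "", id)
}

met_compartment <- function(id) {
  m <- regexpr("_([a-zA-Z0-9]{1,2})$", id)
  out <- rep("", length(id))
  out[m > 0] <- sub("^_", "", regmatches(id, m))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Large finite bound used in place of +/-Inf when handing problems to the
# dense QP solver; matches the conventional COBRA default bound.
BIG_BOUND <- 1000

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
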