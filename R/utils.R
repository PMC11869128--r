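#' @keywords internal
"_PACKAGE"

#' @importFrom methods new validObject slot is
#' @importFrom stats dnorm pnorm qnorm rnorm runif lm coef optim sd var
#'   cor predict setNames complete.cases
#' @importFrom utils head read.delim write.table modifyList
NULL

## 32-bit string hash (FNV-1a style, kept below 2^31 so it can seed R's RNG).
## Used to derive order-independent per-(id, fidelity) noise substreams.
hash32 <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% 2147483647)
}

## Derive a deterministic child seed from a parent seed and a stream label,
## so adding a consumer of randomness does not perturb other streams.
child_seed <- function(seed, label) {
  hash32(as.integer(seed), label)
}

## Evaluate expr with a local RNG state seeded from `seed`; the caller's RNG
## state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

clip01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

mfbo_log <- function(...) {
  if (isTRUE(getOption("mfbo.verbose", FALSE)))
    message("[mfbo] ", ...)
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
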