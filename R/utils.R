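#' @keywords internal
"_PACKAGE"

## Small shared helpers. Images travel between modules as plain numeric
## matrices with values in [0, 1]; these checks enforce that contract once,
## at module boundaries.

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stop_rnst <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "rnst_error")))
}

check_image <- function(x, arg = "image", require_range = TRUE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_rnst(arg, " must be a numeric matrix (2-D grayscale image)",
              class = "rnst_validation_error")
  }
  if (any(!is.finite(x))) {
    stop_rnst(arg, " contains non-finite pixels", class = "rnst_validation_error")
  }
  if (require_range && (min(x) < -1e-8 || max(x) > 1 + 1e-8)) {
    stop_rnst(arg, " must have intensities in [0, 1]; normalize first ",
              "(see normalize_intensity())", class = "rnst_validation_error")
  }
  invisible(x)
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b))) {
    stop_rnst(what, " have mismatched shapes: ",
              paste(dim(a), collapse = "x"), " vs ",
              paste(dim(b), collapse = "x"),
              class = "rnst_validation_error")
  }
  invisible(NULL)
}

check_scalar <- function(x, arg, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    stop_rnst(arg, " must be a finite scalar ",
              if (strict) "> " else ">= ", lower,
              class = "rnst_validation_error")
  }
  invisible(x)
}

## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards so package randomness never perturbs user
## simulations.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
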