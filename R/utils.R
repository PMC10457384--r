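#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif rexp sd quantile fft lm coef confint vcov
#'   setNames nls approx median complete.cases qnorm rbinom
#' @importFrom utils head tail
NULL

R_GAS <- 8.314462618  # J / (mol K)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Derive reproducible child seeds from a parent seed.
spawn_seeds_ <- function(seed, n) {
  with_seed_(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Parse a concentration given with units
#'
#' Accepts molar floats or strings such as `"5 nM"`, `"1 uM"`, `"100 nM"`,
#' `"1e-6 M"` and returns the value in mol/L.
#'
#' @param x Numeric (already mol/L) or character with a unit suffix among
#'   `M`, `mM`, `uM`/`µM`, `nM`, `pM`.
#' @return Numeric vector, mol/L.
#' @examples
#' parse_concentration(c("5 nM", "1 uM", 2e-7))
#' @export
parse_concentration <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  if (is.list(x)) {
    return(vapply(x, parse_concentration, numeric(1)))
  }
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9, pM = 1e-12)
  out <- vapply(as.character(x), function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^([0-9.eE+-]+)\\s*([A-Za-zµ]*)$", s))[[1]]
    if (length(m) == 0L) {
      abort(paste0("Cannot parse concentration: '", s, "'"))
    }
    val <- suppressWarnings(as.numeric(m[2]))
    if (is.na(val)) {
      abort(paste0("Cannot parse concentration: '", s, "'"))
    }
    unit <- m[3]
    if (unit == "") {
      return(val)
    }
    if (!unit %in% names(scale)) {
      abort(paste0("Unknown concentration unit '", unit, "' in '", s, "'"))
    }
    val * scale[[unit]]
  }, numeric(1))
  unname(out)
}

#' Convert Celsius to Kelvin
#'
#' @param celsius Temperature in degrees Celsius.
#' @return Temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(celsius) celsius + 273.15
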