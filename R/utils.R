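#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the previous
#' RNG state afterwards, so seeded helpers do not perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

## 32-bit FNV-1a over a character string or raw vector; returned as an
## 8-hex-digit string. Used for content hashes in run manifests (no
## cryptographic requirement, only change detection / determinism checks).
fnv1a <- function(x) {
  if (is.character(x)) x <- charToRaw(paste(x, collapse = "\n"))
  h <- 2166136261
  two32 <- 4294967296
  for (b in as.integer(x)) {
    h <- bitwXor(as.integer(h %% 2147483648) , b) + (h %/% 2147483648) * 2147483648
    ## multiply by 16777619 mod 2^32 without losing double precision:
    ## 16777619 = 403 + 2^24
    h <- ((h * 403) %% two32 + ((h %% 256) * 16777216)) %% two32
  }
  ## h is a double in [0, 2^32); format as two 16-bit halves since %x
  ## needs integer input and 2^31 <= h overflows R's integer type
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## hash a file's bytes
fileHash <- function(path) {
  fnv1a(readBin(path, what = "raw", n = file.info(path)$size))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
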