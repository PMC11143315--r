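#' @useDynLib trisimnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm dist predict quantile median
#' @importFrom utils read.csv write.csv write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# 32-bit FNV-1a over a character scalar; used for config provenance hashes.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # h * 16777619 mod 2^32, split as 403 + 2^24 to stay within double precision
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  # h is a double holding a 32-bit value; format as hex manually
  paste0(format.hexmode(as.integer(h %/% 65536), width = 4),
         format.hexmode(as.integer(h %% 65536), width = 4))
}

# Serialize a (possibly nested) config list into a stable string for hashing.
config_string <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
}

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

# Largest-remainder apportionment of `total` among groups with weights `w`.
apportion <- function(w, total) {
  if (total <= 0) return(integer(length(w)))
  raw <- w / sum(w) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
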