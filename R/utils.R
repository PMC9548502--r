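# Internal helpers shared across the package.

#' @keywords internal
"_PACKAGE"

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so library code never
#' perturbs the caller's random stream.
#' @keywords internal
#' @noRd
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
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministically fan one seed out into n independent substream seeds,
# all strictly below 2^31 so they remain valid R integers.
derive_seeds <- function(seed, n, salt = 0L) {
  with_seed(as.integer(seed) + as.integer(salt),
            sample.int(.Machine$integer.max - 1L, n))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Two-class label vector -> factor with the positive class as second level.
as_binary_label <- function(labels, positive) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) < 2L) stopf("both classes must be present in 'labels'")
  if (length(lev) > 2L) stopf("expected two classes, got %d", length(lev))
  if (!positive %in% lev) {
    stopf("positive class '%s' not found in labels (%s)",
          positive, paste(lev, collapse = ", "))
  }
  negative <- setdiff(lev, positive)
  factor(labels, levels = c(negative, positive))
}
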