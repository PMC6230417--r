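# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_ctb <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "ctburden_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dice overlap between two logical arrays of identical shape.

#' Dice similarity coefficient
#'
#' Overlap score `2|A n B| / (|A| + |B|)` between two binary masks of the
#' same shape; 1 for identical masks, and defined as 1 when both are empty.
#'
#' @param a,b logical arrays or `ct_mask` objects of identical shape.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- mask_data(a)
  b <- mask_data(b)
  if (!identical(dim(a), dim(b))) {
    stop_ctb("dice: masks have different shapes", class = "ctb_contract_error")
  }
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

mask_data <- function(m) {
  if (inherits(m, "ct_mask")) m$data else if (is.logical(m)) m else (m != 0)
}
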