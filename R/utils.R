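#' @keywords internal
#' @importFrom stats rnorm runif rbinom sd var quantile qt pnorm dnorm
#'   uniroot qlogis setNames
#' @importFrom utils read.csv write.csv
"_PACKAGE"

# logistic function on any numeric array
sigmoid <- function(x) 1 / (1 + exp(-x))

# row-wise numerically stable softmax of a matrix
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# ---- parameter-tree helpers -------------------------------------------------
# model parameters are nested named lists whose leaves are numeric arrays;
# gradients mirror the structure exactly.

tree_map <- function(tree, f) {
  if (is.list(tree)) lapply(tree, tree_map, f = f) else f(tree)
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

tree_zeros_like <- function(tree) tree_map(tree, function(x) x * 0)

# total number of scalar parameters
tree_count <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_count, numeric(1))) else length(tree)
}

# global L2 norm of all leaves
tree_norm <- function(tree) {
  sq <- function(t) {
    if (is.list(t)) sum(vapply(t, sq, numeric(1))) else sum(t^2)
  }
  sqrt(sq(tree))
}

# accumulate gradients: a + b where either may be NULL
tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  tree_map2(a, b, `+`)
}
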