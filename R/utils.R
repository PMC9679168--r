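# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb the global random stream.
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

#' Derive a per-stage seed from a global seed
#'
#' Deterministic, label-dependent and kept within the 32-bit integer range so
#' one pipeline seed fans out into independent stage streams.
#'
#' @param seed integer global seed.
#' @param label character stage label.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(as.numeric(seed)) * 2654435.0 + h * 97.0) %% 214748329)
}

# upper-triangle edge list of an n x n symmetric matrix, column-major order
# matching which(upper.tri(m)).  Columns: i (row), j (col), i < j.
ut_edges <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}

# flatten the upper triangle of a symmetric matrix into an edge-weight vector
ut_vec <- function(m) m[upper.tri(m)]

# rebuild a symmetric zero-diagonal matrix from an upper-triangle vector
ut_unvec <- function(v, n, dimnames = NULL) {
  m <- matrix(0, n, n, dimnames = dimnames)
  m[upper.tri(m)] <- v
  m + t(m)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop_invalid(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

# midrank transform (average ranks for ties)
midrank <- function(x) rank(x, ties.method = "average")

# Jaccard index between two edge sets given as 2-column matrices (i, j; i<j)
edge_jaccard <- function(a, b) {
  key <- function(e) {
    if (is.null(dim(e)) || nrow(e) == 0L) return(character(0))
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "-")
  }
  ka <- unique(key(a)); kb <- unique(key(b))
  if (length(ka) == 0L && length(kb) == 0L) return(1)
  length(intersect(ka, kb)) / length(union(ka, kb))
}
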