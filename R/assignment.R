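#' Minimum-cost assignment between two sets
#'
#' Solves the rectangular linear assignment problem: given a cost matrix
#' with one row per element of the first set and one column per element of
#' the second, finds the matching of every row to a distinct column that
#' minimises total cost. Used to align seminal (and lateral) roots of two
#' plants before accumulating curve-to-curve costs.
#'
#' @param cost numeric matrix of pairwise costs; `nrow(cost)` need not
#'   equal `ncol(cost)` (the smaller side is fully matched).
#' @return list with `cols` (for each row of the *original* matrix, the
#'   matched column index, or `NA` for unmatched rows when
#'   `nrow > ncol`) and `cost`, the total cost of the matching.
#' @examples
#' solve_assignment(matrix(c(4, 2, 8, 4, 3, 7, 3, 1, 6), 3, 3))
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (any(!is.finite(cost))) stop("assignment costs must be finite")
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(list(cols = rep(NA_integer_, n), cost = 0))
  if (n <= m) {
    cols <- solve_assignment_cpp(cost)
  } else {
    rows <- solve_assignment_cpp(t(cost))
    cols <- rep(NA_integer_, n)
    cols[rows] <- seq_len(m)
  }
  matched <- which(!is.na(cols))
  list(cols = cols, cost = sum(cost[cbind(matched, cols[matched])]))
}
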