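#' Construct a step cumulative hazard function
#'
#' @param times strictly increasing numeric event-time grid (may be empty).
#' @param hazard non-decreasing cumulative hazard values, same length.
#' @return a [StepCHF-class] object.
#' @examples
#' H <- StepCHF(c(1, 2, 3), c(1/3, 1/3 + 1/2, 11/6))
#' chfAt(H, 2.5)  # 1/3 + 1/2
#' @export
StepCHF <- function(times = numeric(0), hazard = numeric(0)) {
  new("StepCHF", times = as.numeric(times), hazard = as.numeric(hazard))
}

#' Evaluate a step cumulative hazard
#'
#' Step convention: \code{H(t)} is the hazard value at the largest grid
#' time \eqn{\le t}; 0 for \code{t} below the grid.
#'
#' @param chf a [StepCHF-class].
#' @param t numeric vector of evaluation times.
#' @return numeric vector \code{H(t)}.
#' @export
chfAt <- function(chf, t) {
  stopifnot(is(chf, "StepCHF"))
  .stepEval(chf@times, chf@hazard, t)
}

# core step evaluation on plain vectors (hot path, no S4 dispatch)
.stepEval <- function(times, hazard, t) {
  if (!length(times)) return(numeric(length(t)))
  idx <- findInterval(t, times)
  c(0, hazard)[idx + 1L]
}

# re-sample a hazard matrix (rows = curves on `from` grid) onto `to` grid
.resampleHazard <- function(hazMatrix, from, to) {
  if (!length(from))
    return(matrix(0, nrow = nrow(hazMatrix), ncol = length(to)))
  idx <- findInterval(to, from)
  cbind(0, hazMatrix)[, idx + 1L, drop = FALSE]
}
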