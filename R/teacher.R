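# Mean-teacher state: the teacher's parameters are an exponential moving
# average (EMA) of the student's, theta'_t = alpha * theta'_{t-1} +
# (1 - alpha) * theta_t.  The teacher is never trained directly; it provides
# the consistency reference, the pseudo-labels, and the evaluation model.

#' Initialise the teacher as a copy of the student
#'
#' @param student A `segnet` or its flat parameter list.
#' @param alpha Smoothing coefficient in `[0, 1]`; `alpha = 0` makes the
#'   teacher track the student exactly (a pi-model variant), `alpha = 1`
#'   freezes it.  Default 0.999.
#' @return A `teacher_state` with `shadow` (parameter copy), `alpha`, and
#'   `step = 0`.
#' @export
init_teacher <- function(student, alpha = 0.999) {
  params <- if (inherits(student, "segnet")) student$params else student
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1], got %g", alpha)
  structure(list(shadow = params, alpha = alpha, step = 0L),
            class = "teacher_state")
}

#' One EMA update of the teacher
#'
#' Every shadow parameter becomes
#' `alpha * shadow + (1 - alpha) * student`; the student is untouched and the
#' step counter increments.
#'
#' @param state A `teacher_state`.
#' @param student The current student `segnet` or parameter list.
#' @return The updated `teacher_state`.
#' @export
ema_update <- function(state, student) {
  stopifnot(inherits(state, "teacher_state"))
  params <- if (inherits(student, "segnet")) student$params else student
  if (!identical(names(state$shadow), names(params)))
    stopf("teacher and student parameter sets differ in structure")
  a <- state$alpha
  for (nm in names(params)) {
    if (!identical(dim(state$shadow[[nm]]), dim(params[[nm]])) ||
        length(state$shadow[[nm]]) != length(params[[nm]]))
      stopf("shape mismatch for parameter %s", nm)
    state$shadow[[nm]] <- a * state$shadow[[nm]] + (1 - a) * params[[nm]]
  }
  state$step <- state$step + 1L
  state
}

# A segnet whose parameters are the teacher shadow, for prediction.
teacher_net <- function(state, net) {
  stopifnot(inherits(state, "teacher_state"), inherits(net, "segnet"))
  net$params <- state$shadow
  net
}
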