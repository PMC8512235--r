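#' Ischemia-reperfusion class labels
#'
#' The experiment follows intestinal segments over an 8 h time course at one
#' hour resolution and assigns each image to one of 18 classes: class 0 is the
#' healthy control; classes 1-8 are 1-8 h of ischemia; classes 9-13 are 3 h of
#' ischemia followed by 1-5 h of reperfusion; classes 14-17 are 4 h of
#' ischemia followed by 1-4 h of reperfusion. `class_label()` maps an index to
#' its `(phase, ischemia_hours, reperfusion_hours)` state and
#' `label_from_state()` is the inverse.
#'
#' @param index integer class index in `[0, 17]`.
#' @return `class_label()` returns an object of class `ir_label`: a list with
#'   fields `index`, `phase` (one of `"control"`, `"ischemia"`,
#'   `"reperfusion"`), `ischemia_hours` and `reperfusion_hours`.
#' @examples
#' class_label(0)   # control
#' class_label(10)  # 3 h ischemia + 2 h reperfusion
#' label_table()
#' @export
class_label <- function(index) {
  if (length(index) != 1L || is.na(index) || index != as.integer(index) ||
      index < 0L || index > 17L) {
    stopf("class index must be a single integer in [0, 17] (got %s)",
          paste(index, collapse = ","))
  }
  index <- as.integer(index)
  if (index == 0L) {
    lab <- list(index = 0L, phase = "control",
                ischemia_hours = 0L, reperfusion_hours = 0L)
  } else if (index <= 8L) {
    lab <- list(index = index, phase = "ischemia",
                ischemia_hours = index, reperfusion_hours = 0L)
  } else if (index <= 13L) {
    lab <- list(index = index, phase = "reperfusion",
                ischemia_hours = 3L, reperfusion_hours = index - 8L)
  } else {
    lab <- list(index = index, phase = "reperfusion",
                ischemia_hours = 4L, reperfusion_hours = index - 13L)
  }
  structure(lab, class = "ir_label")
}

#' @rdname class_label
#' @param phase `"control"`, `"ischemia"` or `"reperfusion"`.
#' @param ischemia_hours hours of ischemia (0-8).
#' @param reperfusion_hours hours of reperfusion (0-5).
#' @export
label_from_state <- function(phase, ischemia_hours = 0L, reperfusion_hours = 0L) {
  phase <- match.arg(phase, c("control", "ischemia", "reperfusion"))
  i <- as.integer(ischemia_hours)
  r <- as.integer(reperfusion_hours)
  idx <- switch(phase,
    control = {
      if (i != 0L || r != 0L) stopf("control has no ischemia/reperfusion hours")
      0L
    },
    ischemia = {
      if (i < 1L || i > 8L || r != 0L) stopf("ischemia classes cover 1-8 h, no reperfusion")
      i
    },
    reperfusion = {
      if (i == 3L && r >= 1L && r <= 5L) 8L + r
      else if (i == 4L && r >= 1L && r <= 4L) 13L + r
      else stopf("reperfusion classes are 3 h ischemia + 1-5 h or 4 h ischemia + 1-4 h")
    })
  class_label(idx)
}

#' @rdname class_label
#' @export
label_table <- function() {
  labs <- lapply(0:17, class_label)
  data.frame(
    index = vapply(labs, `[[`, integer(1), "index"),
    phase = vapply(labs, `[[`, character(1), "phase"),
    ischemia_hours = vapply(labs, `[[`, integer(1), "ischemia_hours"),
    reperfusion_hours = vapply(labs, `[[`, integer(1), "reperfusion_hours"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ir_label <- function(x, ...) {
  desc <- switch(x$phase,
    control = "control",
    ischemia = sprintf("%d h ischemia", x$ischemia_hours),
    reperfusion = sprintf("%d h ischemia + %d h reperfusion",
                          x$ischemia_hours, x$reperfusion_hours))
  cat(sprintf("<ir_label %d: %s>\n", x$index, desc))
  invisible(x)
}
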