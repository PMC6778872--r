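#' Tidy an event evaluation
#'
#' @param x An `event_evaluation` from [evaluate_events()].
#' @param ... Unused.
#' @return A tibble with one row per matched event/annotation pair.
#' @method tidy event_evaluation
#' @export
tidy.event_evaluation <- function(x, ...) x$matches

#' One-row summary of an event evaluation
#'
#' @param x An `event_evaluation` from [evaluate_events()].
#' @param ... Unused.
#' @return A tibble with columns `tp`, `fp`, `precision`, `n_missed`.
#' @method glance event_evaluation
#' @export
glance.event_evaluation <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, precision = x$precision,
                 n_missed = length(x$missed))
}

#' Tidy a tailored parameter fit
#'
#' @param x A `tailored_params` from [fit_from_annotations()] or
#'   [iterate_feedback()].
#' @param ... Unused.
#' @return A tibble with one row per detector parameter (term/value).
#' @method tidy tailored_params
#' @export
tidy.tailored_params <- function(x, ...) {
  p <- unclass(x$params)
  num <- p[vapply(p, is.numeric, logical(1))]
  tibble::tibble(term = names(num), value = unlist(num, use.names = FALSE))
}

#' One-row summary of a tailored parameter fit
#'
#' @param x A `tailored_params`.
#' @param ... Unused.
#' @return A tibble with columns `precision`, `tp`, `fp`, `n_candidates`.
#' @method glance tailored_params
#' @export
glance.tailored_params <- function(x, ...) {
  tibble::tibble(precision = x$precision, tp = x$tp, fp = x$fp,
                 n_candidates = x$n_candidates)
}
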