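#' Health states of the cardiovascular disease model
#'
#' The model distinguishes six mutually exclusive health states: alive
#' without coronary heart disease (CHD) or stroke (\code{WELL}), alive after
#' a first CHD event (\code{CHD}), alive after a first stroke
#' (\code{STROKE}), alive after both (\code{CHD_AND_STROKE}), death from
#' cardiovascular causes (\code{CVD_DEATH}) and death from any other cause
#' (\code{NON_CVD_DEATH}). The two death states are absorbing.
#'
#' @return Character vector of the six state labels, in canonical order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("WELL", "CHD", "STROKE", "CHD_AND_STROKE", "CVD_DEATH", "NON_CVD_DEATH")
}

#' @rdname health_states
#' @param state Character vector of state labels.
#' @return \code{is_absorbing}: logical vector, \code{TRUE} for death states.
#' @export
is_absorbing <- function(state) {
  state %in% c("CVD_DEATH", "NON_CVD_DEATH")
}

#' Permitted state transitions
#'
#' Each transition is identified by its source state and an event type; the
#' destination follows from both. A CHD event suffered while in the
#' \code{STROKE} state (or vice versa) moves the individual to
#' \code{CHD_AND_STROKE}. Repeat events of a kind already suffered do not
#' change the state and are not modelled as transitions.
#'
#' @return Data frame with columns \code{source}, \code{event} (one of
#'   \code{CHD}, \code{STROKE}, \code{CVD_DEATH}, \code{NON_CVD_DEATH}) and
#'   \code{target} (the destination state).
#' @export
#' @examples
#' transition_topology()
transition_topology <- function() {
  rbind(
    data.frame(source = "WELL",
               event  = c("CHD", "STROKE", "CVD_DEATH", "NON_CVD_DEATH"),
               target = c("CHD", "STROKE", "CVD_DEATH", "NON_CVD_DEATH")),
    data.frame(source = "CHD",
               event  = c("STROKE", "CVD_DEATH", "NON_CVD_DEATH"),
               target = c("CHD_AND_STROKE", "CVD_DEATH", "NON_CVD_DEATH")),
    data.frame(source = "STROKE",
               event  = c("CHD", "CVD_DEATH", "NON_CVD_DEATH"),
               target = c("CHD_AND_STROKE", "CVD_DEATH", "NON_CVD_DEATH")),
    data.frame(source = "CHD_AND_STROKE",
               event  = c("CVD_DEATH", "NON_CVD_DEATH"),
               target = c("CVD_DEATH", "NON_CVD_DEATH"))
  )
}

#' @rdname transition_topology
#' @param source,event Scalars identifying one permitted transition.
#' @return \code{transition_target}: the destination state label.
#' @export
transition_target <- function(source, event) {
  topo <- transition_topology()
  hit <- topo$source == source & topo$event == event
  if (!any(hit)) {
    stop("no permitted transition from state '", source,
         "' for event '", event, "'")
  }
  topo$target[hit]
}

#' Event types counted by the tracker variables
#' @return Character vector of the four tracked event types.
#' @export
event_types <- function() {
  c("CHD", "STROKE", "CVD_DEATH", "NON_CVD_DEATH")
}

# canonical key for a transition, used in parameter sets
transition_key <- function(source, event) paste(source, event, sep = "->")
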