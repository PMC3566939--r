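#' Bundle transition functions into a linked parameter set
#'
#' A parameter set is one internally consistent ("linked") collection of
#' transition functions, e.g. all fits from a single bootstrap resample of
#' the calibration cohort. The simulation engine requires full coverage of
#' the permitted transition topology.
#'
#' @param transitions List of \code{\link{cox_transition}} objects.
#' @param replicate_id Integer identifier of the bootstrap replicate
#'   (0 for a fit on the original data).
#' @return Object of class \code{cvd_parameter_set}: a named list of
#'   transitions keyed \code{"SOURCE->EVENT"}.
#' @export
parameter_set <- function(transitions, replicate_id = 0L) {
  stopifnot(is.list(transitions))
  ok <- vapply(transitions, inherits, logical(1), what = "cvd_transition")
  if (!all(ok)) stop("all elements must be cox_transition objects")
  keys <- vapply(transitions, function(f) transition_key(f$source, f$event),
                 character(1))
  if (anyDuplicated(keys)) stop("duplicate transitions: ",
                                paste(keys[duplicated(keys)], collapse = ", "))
  topo <- transition_topology()
  need <- transition_key(topo$source, topo$event)
  missing <- setdiff(need, keys)
  if (length(missing)) {
    stop("parameter set does not cover the full transition topology; missing: ",
         paste(missing, collapse = ", "))
  }
  names(transitions) <- keys
  structure(list(transitions = transitions[need],
                 replicate_id = as.integer(replicate_id)),
            class = "cvd_parameter_set")
}

#' @export
print.cvd_parameter_set <- function(x, ...) {
  cat(sprintf("<cvd_parameter_set> replicate %d, %d transitions\n",
              x$replicate_id, length(x$transitions)))
  invisible(x)
}

# pull one transition function out of a set
get_transition <- function(params, source, event) {
  params$transitions[[transition_key(source, event)]]
}

PARAMS_SCHEMA_VERSION <- "1.0"

#' Read and write model-parameter files
#'
#' Parameter sets are stored as JSON: a mandatory \code{version} field and a
#' \code{replicates} array; each replicate carries its \code{replicate_id}
#' and a \code{transitions} array of
#' \code{\{source, target, coefficients, means, baseline_cum_hazard\}}
#' records. The event type is recovered from the (source, target) pair.
#'
#' @param sets List of \code{\link{parameter_set}} objects (or a single one).
#' @param path File path.
#' @return \code{read_params} returns a list of parameter sets.
#' @export
write_params <- function(sets, path) {
  if (inherits(sets, "cvd_parameter_set")) sets <- list(sets)
  reps <- lapply(sets, function(ps) {
    list(replicate_id = ps$replicate_id,
         transitions = lapply(unname(ps$transitions), function(f) {
           list(source = f$source, target = f$target,
                coefficients = as.list(f$coefficients),
                means = as.list(f$means),
                baseline_cum_hazard = f$baseline_cum_hazard)
         }))
  })
  jsonlite::write_json(list(version = PARAMS_SCHEMA_VERSION, replicates = reps),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$version)) stop("parameter file has no 'version' field")
  if (!identical(as.character(doc$version), PARAMS_SCHEMA_VERSION)) {
    stop("parameter file schema version '", doc$version,
         "' does not match supported version '", PARAMS_SCHEMA_VERSION, "'")
  }
  topo <- transition_topology()
  lapply(doc$replicates, function(rep) {
    trans <- lapply(rep$transitions, function(tr) {
      hit <- topo$source == tr$source & topo$target == tr$target
      if (sum(hit) != 1) {
        stop("unknown transition ", tr$source, " -> ", tr$target)
      }
      cox_transition(tr$source, topo$event[hit],
                     coefficients = unlist(tr$coefficients),
                     means = unlist(tr$means),
                     baseline_cum_hazard = unlist(tr$baseline_cum_hazard))
    })
    parameter_set(trans, replicate_id = rep$replicate_id)
  })
}
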